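#' Parse gene coordinates from a GFF3 file
#'
#' Reads a GFF3 annotation and returns one row per retained feature with
#' 1-based inclusive coordinates, exactly as printed in the file.  Lines with
#' malformed mandatory columns (wrong column count, non-numeric coordinates,
#' end < start, or a strand other than `+`/`-`) are skipped with one warning
#' per offending line; an input with no feature lines yields an empty table.
#'
#' Domain hits address protein products, so the default feature filter keeps
#' `CDS` records; pass `feature_types = c("gene", "CDS")` (or any other set)
#' to widen it.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome identifier attached to every returned feature.
#' @param feature_types Character vector of GFF3 `type` values to retain.
#' @return A tibble of gene features with columns `genome_id`, `contig_id`,
#'   `gene_id`, `start`, `end` (1-based inclusive) and `strand`
#'   (`"forward"`/`"reverse"`).
#' @seealso [parse_domain_hits()], [build_presence_matrix()]
#' @export
parse_gff <- function(path, genome_id, feature_types = "CDS") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (!file.exists(path)) {
    stop("cannot read GFF3 file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    return(empty_features())
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) == 9L &&
      !is.na(suppressWarnings(as.numeric(f[4]))) &&
      !is.na(suppressWarnings(as.numeric(f[5]))) &&
      as.numeric(f[5]) >= as.numeric(f[4]) &&
      as.numeric(f[4]) >= 1 &&
      f[7] %in% c("+", "-")
  }, logical(1))
  for (bad in body[!ok]) {
    warning("skipping malformed GFF3 line: ", substr(bad, 1, 80), call. = FALSE)
  }
  body <- body[ok]
  if (length(body) == 0L) {
    return(empty_features())
  }

  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c("##gff-version 3", body), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) {
    return(empty_features())
  }

  meta <- as.data.frame(S4Vectors::mcols(gr))
  gene_id <- rep(NA_character_, length(gr))
  for (col in c("ID", "locus_tag", "Name")) {
    if (col %in% names(meta)) {
      val <- as.character(meta[[col]])
      gene_id <- ifelse(is.na(gene_id) & !is.na(val) & nzchar(val), val, gene_id)
    }
  }
  fallback <- sprintf(
    "%s:%d-%d",
    as.character(GenomicRanges::seqnames(gr)),
    GenomicRanges::start(gr), GenomicRanges::end(gr)
  )
  gene_id[is.na(gene_id)] <- fallback[is.na(gene_id)]

  tibble::tibble(
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = gene_id,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                    "forward", "reverse")
  )
}

empty_features <- function() {
  tibble::tibble(
    genome_id = character(), contig_id = character(), gene_id = character(),
    start = integer(), end = integer(), strand = character()
  )
}

#' Parse protein-family domain hits
#'
#' Reads family-to-gene assignments from HMMER tabular output (`tblout` or
#' `domtblout`, whitespace-delimited with `#` comment lines) or from a
#' simplified five-column TSV.  Version suffixes on family accessions
#' (`PF18330.5` -> `PF18330`) are stripped and accessions are upper-cased so
#' that comparisons are case-insensitive.  Rows with a non-numeric e-value
#' are skipped with a warning.
#'
#' The simplified TSV carries its own `genome_id` column; HMMER files are
#' per-genome scan outputs, so `genome_id` must be supplied for those
#' dialects.
#'
#' @param path Path to the hits file.
#' @param dialect One of `"tsv"`, `"tblout"`, `"domtblout"`.
#' @param genome_id Genome identifier; required for the HMMER dialects,
#'   ignored for `"tsv"`.
#' @return A tibble with columns `genome_id`, `gene_id`, `family_id`,
#'   `bit_score`, `e_value`.
#' @export
parse_domain_hits <- function(path, dialect = c("tsv", "tblout", "domtblout"),
                              genome_id = NULL) {
  dialect <- tryCatch(match.arg(dialect),
    error = function(e) stop("unknown hits dialect: ", dialect[1], call. = FALSE)
  )
  if (!file.exists(path)) {
    stop("cannot read hits file: ", path)
  }

  if (dialect == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    if (nrow(tab) == 0L) {
      return(empty_hits())
    }
    names(tab) <- tolower(names(tab))
    if ("score" %in% names(tab) && !"bit_score" %in% names(tab)) {
      tab$bit_score <- tab$score
    }
    req <- c("genome_id", "gene_id", "family_id", "bit_score", "e_value")
    missing_cols <- setdiff(req, names(tab))
    if (length(missing_cols) > 0L) {
      stop("hits TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    out <- tibble::tibble(
      genome_id = as.character(tab$genome_id),
      gene_id = as.character(tab$gene_id),
      family_id = as.character(tab$family_id),
      bit_score = suppressWarnings(as.numeric(tab$bit_score)),
      e_value = suppressWarnings(as.numeric(tab$e_value))
    )
  } else {
    if (is.null(genome_id)) {
      stop("genome_id is required for HMMER ", dialect, " input")
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(empty_hits())
    }
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    # tblout: target name, target acc, query name, query acc, E-value, score, ...
    # domtblout: target name, target acc, tlen, query name, query acc, qlen,
    #            full-seq E-value, full-seq score, ...
    idx <- if (dialect == "tblout") {
      list(gene = 1L, fam_acc = 4L, fam_name = 3L, e = 5L, score = 6L, min = 6L)
    } else {
      list(gene = 1L, fam_acc = 5L, fam_name = 4L, e = 7L, score = 8L, min = 8L)
    }
    ok <- lengths(fields) >= idx$min
    for (bad in lines[!ok]) {
      warning("skipping malformed ", dialect, " line: ", substr(bad, 1, 80),
              call. = FALSE)
    }
    fields <- fields[ok]
    if (length(fields) == 0L) {
      return(empty_hits())
    }
    get <- function(i) vapply(fields, `[[`, character(1), i)
    fam <- get(idx$fam_acc)
    fam_name <- get(idx$fam_name)
    fam <- ifelse(fam == "-", fam_name, fam)
    out <- tibble::tibble(
      genome_id = genome_id,
      gene_id = get(idx$gene),
      family_id = fam,
      bit_score = suppressWarnings(as.numeric(get(idx$score))),
      e_value = suppressWarnings(as.numeric(get(idx$e)))
    )
  }

  bad_e <- is.na(out$e_value)
  if (any(bad_e)) {
    warning(sum(bad_e), " hit row(s) with non-numeric e-value skipped",
            call. = FALSE)
    out <- out[!bad_e, ]
  }
  out$family_id <- normalize_family_id(out$family_id)
  out
}

empty_hits <- function() {
  tibble::tibble(
    genome_id = character(), gene_id = character(), family_id = character(),
    bit_score = numeric(), e_value = numeric()
  )
}

# One place where family accessions are canonicalized: version suffix dropped,
# upper-cased (Pfam releases vary both).
normalize_family_id <- function(x) {
  toupper(sub("\\.[0-9]+$", "", x))
}

#' Read genome metadata
#'
#' Reads a per-genome metadata TSV with columns `genome_id`,
#' `domain_of_life` (`archaea`/`bacteria`, any case), the taxon path
#' (`phylum`, `order`, `genus`) and an optional free-text
#' `isolation_source`.  Genome identifiers must be unique.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble, one row per genome.
#' @export
read_genome_metadata <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  req <- c("genome_id", "domain_of_life")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab$genome_id <- as.character(tab$genome_id)
  tab$domain_of_life <- tolower(as.character(tab$domain_of_life))
  bad_dom <- !tab$domain_of_life %in% c("archaea", "bacteria")
  if (any(bad_dom)) {
    stop("domain_of_life must be archaea or bacteria; offending genomes: ",
         paste(utils::head(tab$genome_id[bad_dom], 5), collapse = ", "))
  }
  dup <- duplicated(tab$genome_id)
  if (any(dup)) {
    stop("duplicate genome_id in metadata: ",
         paste(unique(tab$genome_id[dup]), collapse = ", "))
  }
  for (col in c("phylum", "order", "genus", "isolation_source")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab[, c("genome_id", "domain_of_life", "phylum", "order", "genus",
          "isolation_source")]
}
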