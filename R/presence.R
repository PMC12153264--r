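#' Presence-calling policy
#'
#' A qualifying domain hit must satisfy `e_value <= max_evalue` and, when a
#' bit-score floor is set, `bit_score >= min_bitscore`.  The default
#' (e-value at most 1e-5, no bit-score floor) is conventional Pfam-screen
#' practice; every pipeline run logs the policy it used because presence
#' calls are only interpretable together with their thresholds.
#'
#' @param max_evalue Maximum e-value for a qualifying hit.
#' @param min_bitscore Optional minimum bit score; `NULL` disables the floor.
#' @return A `presence_policy` object.
#' @export
presence_policy <- function(max_evalue = 1e-5, min_bitscore = NULL) {
  stopifnot(is.numeric(max_evalue), length(max_evalue) == 1L, max_evalue >= 0)
  if (!is.null(min_bitscore)) {
    stopifnot(is.numeric(min_bitscore), length(min_bitscore) == 1L)
  }
  structure(list(max_evalue = max_evalue, min_bitscore = min_bitscore),
            class = "presence_policy")
}

#' @export
print.presence_policy <- function(x, ...) {
  cat("presence policy: e-value <=", format(x$max_evalue),
      if (is.null(x$min_bitscore)) "(no bit-score floor)" else
        paste("and bit score >=", format(x$min_bitscore)), "\n")
  invisible(x)
}

hit_qualifies <- function(hits, policy) {
  ok <- hits$e_value <= policy$max_evalue
  if (!is.null(policy$min_bitscore)) {
    ok <- ok & !is.na(hits$bit_score) & hits$bit_score >= policy$min_bitscore
  }
  ok & !is.na(hits$e_value)
}

#' Build a genomes-by-families presence/absence matrix
#'
#' A genome is called positive for a family when it has at least one hit to
#' that family passing the policy; multiple hits collapse to a single
#' genome-level presence call.  Every genome listed in the metadata gets a
#' row, so genomes without any qualifying hit form the all-zero background
#' (the anchor-negative set of the enrichment screen).  Hits referencing a
#' genome absent from the metadata are an error: silent dropping would shrink
#' the denominator of every downstream contingency table.
#'
#' Family alias groups merge several accessions into one named column
#' (e.g. `list(RNL3 = c("PF18330", "TIGR01209"))` unions the two ligase
#' models into a single family); member columns are replaced by the group
#' column.
#'
#' @param hits Tibble of domain hits as returned by [parse_domain_hits()].
#' @param metadata Tibble of genome metadata as returned by
#'   [read_genome_metadata()].
#' @param policy A [presence_policy()].
#' @param aliases Optional named list mapping a group family id to member
#'   accessions.
#' @param extra_families Optional accessions forced to appear as (possibly
#'   all-zero) columns even without qualifying hits.
#' @return A `presence_matrix` object.
#' @export
build_presence_matrix <- function(hits, metadata, policy = presence_policy(),
                                  aliases = NULL, extra_families = NULL) {
  stopifnot(inherits(policy, "presence_policy"))
  unknown <- setdiff(unique(hits$genome_id), metadata$genome_id)
  if (length(unknown) > 0L) {
    stop("hits reference genome_id(s) absent from metadata: ",
         paste(utils::head(sort(unknown), 10), collapse = ", "))
  }

  hits <- hits[hit_qualifies(hits, policy), , drop = FALSE]
  hits$family_id <- normalize_family_id(hits$family_id)
  if (!is.null(aliases)) {
    names(aliases) <- normalize_family_id(names(aliases))
    for (grp in names(aliases)) {
      members <- normalize_family_id(aliases[[grp]])
      hits$family_id[hits$family_id %in% members] <- grp
    }
  }

  genome_ids <- metadata$genome_id
  family_ids <- sort(unique(c(hits$family_id,
                              normalize_family_id(extra_families))))
  m <- matrix(0L, nrow = length(genome_ids), ncol = length(family_ids),
              dimnames = list(genome_ids, family_ids))
  if (nrow(hits) > 0L) {
    m[cbind(match(hits$genome_id, genome_ids),
            match(hits$family_id, family_ids))] <- 1L
  }
  new_presence_matrix(m, metadata, policy)
}

new_presence_matrix <- function(m, metadata, policy = presence_policy()) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)),
            !anyDuplicated(rownames(m)), !anyDuplicated(colnames(m)),
            nrow(m) == nrow(metadata),
            nrow(m) == 0L || identical(rownames(m), metadata$genome_id))
  structure(list(m = m, metadata = metadata, policy = policy),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence/absence matrix:", nrow(x$m), "genomes x", ncol(x$m),
      "families\n")
  print(x$policy)
  pos <- sort(colSums(x$m), decreasing = TRUE)
  show <- utils::head(pos, 5)
  cat("top families (positive genomes):",
      paste(sprintf("%s=%d", names(show), show), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$m)

#' @export
#' @method as.matrix presence_matrix
as.matrix.presence_matrix <- function(x, ...) x$m

#' Extract one family's presence column
#'
#' Case-insensitive on the accession; errors with the missing name when the
#' family is not a matrix column.
#'
#' @param pa A `presence_matrix`.
#' @param family_id Family accession.
#' @return Named integer vector of 0/1 over genomes.
#' @export
pa_column <- function(pa, family_id) {
  fid <- normalize_family_id(family_id)
  if (!fid %in% colnames(pa$m)) {
    stop("family not present in matrix: ", family_id)
  }
  pa$m[, fid]
}

#' Write a presence/absence matrix as TSV
#'
#' Genomes are rows, families are columns, entries 0/1; the first column is
#' `genome_id`.
#'
#' @param pa A `presence_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pa, path) {
  tab <- tibble::as_tibble(pa$m)
  tab <- tibble::add_column(tab, genome_id = rownames(pa$m), .before = 1)
  readr::write_tsv(tab, path)
  invisible(path)
}
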