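#' Construct a single gene feature
#'
#' Convenience constructor for a one-row gene-feature table using 1-based
#' inclusive coordinates, mainly for examples and tests.
#'
#' @param genome_id,contig_id,gene_id Identifiers.
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @param strand `"forward"` or `"reverse"`.
#' @return One-row tibble with the gene-feature columns.
#' @export
gene_feature <- function(genome_id = "G", contig_id = "c1", gene_id = "g",
                         start, end, strand = "forward") {
  stopifnot(start >= 1, end >= start, strand %in% c("forward", "reverse"))
  tibble::tibble(
    genome_id = genome_id, contig_id = contig_id, gene_id = gene_id,
    start = as.integer(start), end = as.integer(end), strand = strand
  )
}

# Central 1-based-inclusive -> 0-based half-open conversion; the only place
# the coordinate convention changes.  Used by the gap computation and the
# BED export.
to_zero_half_open <- function(start, end) {
  list(start = start - 1L, end = end)
}

#' Intergenic distance between two genes
#'
#' Boundary-to-boundary gap between two genes on the same contig: with the
#' genes ordered by start, `gap = max(0, start_right - end_left - 1)`.
#' Overlapping or abutting genes have distance 0, and the result is symmetric
#' in its arguments.  Genes on different contigs have no defined linear
#' distance and yield `NA`.
#'
#' For a circular replicon (`circular = TRUE` with a known `contig_length`)
#' the wraparound gap is also considered and the smaller of the two is
#' returned.
#'
#' @param g1,g2 One-row gene-feature tables (see [gene_feature()]).
#' @param circular Treat the contig as circular.
#' @param contig_length Contig length in bp; required when `circular`.
#' @return Gap in base pairs (>= 0), or `NA` for different contigs.
#' @export
intergenic_distance <- function(g1, g2, circular = FALSE, contig_length = NULL) {
  if (!identical(g1$genome_id, g2$genome_id)) {
    stop("genes belong to different genomes")
  }
  if (!identical(g1$contig_id, g2$contig_id)) {
    return(NA_real_)
  }
  gap_between(g1$start, g1$end, g2$start, g2$end, circular, contig_length)
}

gap_between <- function(s1, e1, s2, e2, circular = FALSE, contig_length = NULL) {
  h1 <- to_zero_half_open(s1, e1)
  h2 <- to_zero_half_open(s2, e2)
  # half-open: gap = start_right - end_left, clamped at 0
  left_end <- ifelse(h1$start <= h2$start, h1$end, h2$end)
  right_start <- pmax(h1$start, h2$start)
  lin <- pmax(0, right_start - left_end)
  if (!circular) {
    return(as.numeric(lin))
  }
  if (is.null(contig_length)) {
    stop("contig_length is required for circular distance")
  }
  span <- pmax(h1$end, h2$end) - pmin(h1$start, h2$start)
  wrap <- pmax(0, contig_length - span)
  as.numeric(pmin(lin, wrap))
}

#' Classify the relative orientation of two neighboring genes
#'
#' `tandem` (co-linear) when both genes are on the same strand; otherwise the
#' genes are ordered by position and the pair is `divergent` (bidirectional,
#' head-to-head promoters: left gene on the reverse strand, right gene
#' forward) or `convergent` (transcribed toward each other: left gene
#' forward, right gene reverse).  The classification depends only on
#' positions and strands, so it is invariant to argument order.
#'
#' @param g1,g2 One-row gene-feature tables on the same contig.
#' @return One of `"divergent"`, `"convergent"`, `"tandem"`.
#' @export
classify_orientation <- function(g1, g2) {
  if (!identical(g1$contig_id, g2$contig_id)) {
    stop("orientation is defined only for genes on the same contig")
  }
  orientation_of(g1$start, g1$strand, g2$start, g2$strand)
}

orientation_of <- function(s1, strand1, s2, strand2) {
  ifelse(strand1 == strand2, "tandem",
    ifelse(
      # strand of the left-most gene decides; ties resolved by taking g1 left
      ifelse(s1 <= s2, strand1, strand2) == "reverse",
      "divergent", "convergent"
    )
  )
}

#' Minimal-distance anchor-partner pair per dual-positive genome
#'
#' For every genome carrying at least one qualifying anchor gene and one
#' qualifying partner gene, scans all anchor x partner combinations on a
#' shared contig and keeps the pair with the smallest intergenic gap (ties
#' broken by lower anchor start, then lower partner start).  When no shared
#' contig exists the genome still contributes one pair (the left-most anchor
#' and partner genes) with `same_contig = FALSE` and undefined distance and
#' orientation.  A gene may carry hits to both families but is never paired
#' with itself.  Each genome contributes exactly one pair because the
#' downstream tallies count genomes, not gene pairs.
#'
#' Hits whose gene has no coordinate record are dropped with a warning.
#'
#' @param features Gene-feature tibble over the collection.
#' @param hits Domain-hit tibble over the collection.
#' @param anchor,partner Family accessions.
#' @param policy A [presence_policy()] applied to the hits.
#' @param circular Treat contigs as circular when computing gaps.
#' @param contig_lengths Named vector of contig lengths (names
#'   `genome_id:contig_id`); required when `circular`.
#' @return Tibble with one row per dual-positive genome: gene ids,
#'   coordinates and strands for both genes, `same_contig`, `distance`,
#'   `orientation`.
#' @export
nearest_pairs <- function(features, hits, anchor, partner,
                          policy = presence_policy(),
                          circular = FALSE, contig_lengths = NULL) {
  anchor <- normalize_family_id(anchor)
  partner <- normalize_family_id(partner)
  hits <- hits[hit_qualifies(hits, policy), , drop = FALSE]
  hits$family_id <- normalize_family_id(hits$family_id)
  hits <- hits[hits$family_id %in% c(anchor, partner), , drop = FALSE]

  key <- paste(hits$genome_id, hits$gene_id)
  fkey <- paste(features$genome_id, features$gene_id)
  located <- key %in% fkey
  if (any(!located)) {
    warning(sum(!located),
            " hit(s) to genes without coordinates excluded from pairing",
            call. = FALSE)
    hits <- hits[located, , drop = FALSE]
  }
  genes <- dplyr::inner_join(
    hits[, c("genome_id", "gene_id", "family_id")],
    features, by = c("genome_id", "gene_id")
  )
  genes <- dplyr::distinct(genes)

  dual <- intersect(
    unique(genes$genome_id[genes$family_id == anchor]),
    unique(genes$genome_id[genes$family_id == partner])
  )
  rows <- lapply(sort(dual), function(g) {
    ag <- genes[genes$genome_id == g & genes$family_id == anchor, ]
    pg <- genes[genes$genome_id == g & genes$family_id == partner, ]
    combos <- tidyr::crossing(ai = seq_len(nrow(ag)), pi_ = seq_len(nrow(pg)))
    combos <- combos[ag$gene_id[combos$ai] != pg$gene_id[combos$pi_], ,
                     drop = FALSE]
    if (nrow(combos) == 0L) return(NULL)
    same <- ag$contig_id[combos$ai] == pg$contig_id[combos$pi_]
    if (any(same)) {
      combos <- combos[same, , drop = FALSE]
      clen <- if (circular) {
        contig_lengths[paste0(g, ":", ag$contig_id[combos$ai])]
      } else NULL
      gaps <- gap_between(
        ag$start[combos$ai], ag$end[combos$ai],
        pg$start[combos$pi_], pg$end[combos$pi_],
        circular, clen
      )
      ord <- order(gaps, ag$start[combos$ai], pg$start[combos$pi_])
      i <- combos$ai[ord[1]]; j <- combos$pi_[ord[1]]
      pair_row(g, ag[i, ], pg[j, ], TRUE, gaps[ord[1]],
               orientation_of(ag$start[i], ag$strand[i],
                              pg$start[j], pg$strand[j]))
    } else {
      i <- order(ag$start)[1]; j <- order(pg$start)[1]
      pair_row(g, ag[i, ], pg[j, ], FALSE, NA_real_, NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty_pairs() else out
}

pair_row <- function(genome_id, a, p, same_contig, distance, orientation) {
  tibble::tibble(
    genome_id = genome_id,
    anchor_gene_id = a$gene_id, anchor_contig = a$contig_id,
    anchor_start = a$start, anchor_end = a$end, anchor_strand = a$strand,
    partner_gene_id = p$gene_id, partner_contig = p$contig_id,
    partner_start = p$start, partner_end = p$end, partner_strand = p$strand,
    same_contig = same_contig, distance = distance, orientation = orientation
  )
}

empty_pairs <- function() {
  pair_row(character(0),
           tibble::tibble(gene_id = character(0), contig_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0)),
           tibble::tibble(gene_id = character(0), contig_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0)),
           logical(0), numeric(0), character(0))
}

#' Flag co-localized pairs
#'
#' A pair is co-localized when both genes share a contig and the intergenic
#' gap is strictly below the threshold (default 5 kb, so a gap of exactly
#' 5,000 bp does not qualify; abutting genes, gap 0, do).
#'
#' @param pairs Tibble from [nearest_pairs()].
#' @param threshold Distance threshold in bp (exclusive).
#' @return `pairs` with a logical `co_localized` column.
#' @export
flag_colocalized <- function(pairs, threshold = 5000) {
  stopifnot(threshold > 0)
  pairs$co_localized <- pairs$same_contig & !is.na(pairs$distance) &
    pairs$distance < threshold
  pairs
}

#' Co-localization summary per stratum
#'
#' Tallies dual-positive genomes, co-localized genomes, the co-localized
#' fraction, and the orientation mix among co-localized pairs, globally and
#' per domain of life.  Orientation counts always sum to the co-localized
#' count.
#'
#' @param pairs Tibble from [nearest_pairs()].
#' @param metadata Genome metadata tibble.
#' @param threshold Distance threshold in bp (exclusive; default 5,000).
#' @return List with `global` (one-row tibble) and `by_stratum`.
#' @export
colocalization_summary <- function(pairs, metadata, threshold = 5000) {
  pairs <- flag_colocalized(pairs, threshold)
  dom <- metadata$domain_of_life[match(pairs$genome_id, metadata$genome_id)]
  if (nrow(pairs) > 0L && anyNA(dom)) {
    stop("pairs reference genomes absent from metadata")
  }

  tally <- function(keep, label) {
    p <- pairs[keep, , drop = FALSE]
    coloc <- p[p$co_localized, , drop = FALSE]
    tibble::tibble(
      stratum = label,
      n_dual_positive = nrow(p),
      n_co_localized = nrow(coloc),
      fraction_co_localized =
        if (nrow(p) > 0) nrow(coloc) / nrow(p) else NA_real_,
      pct_co_localized_1dp =
        if (nrow(p) > 0) round(100 * nrow(coloc) / nrow(p), 1) else NA_real_,
      n_divergent = sum(coloc$orientation == "divergent"),
      n_convergent = sum(coloc$orientation == "convergent"),
      n_tandem = sum(coloc$orientation == "tandem")
    )
  }

  by_stratum <- dplyr::bind_rows(lapply(
    sort(unique(dom)),
    function(s) tally(dom == s, s)
  ))
  list(global = tally(rep(TRUE, nrow(pairs)), "all"), by_stratum = by_stratum)
}

#' Write neighbor pairs as TSV
#'
#' @param pairs Tibble from [nearest_pairs()] (optionally flagged).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Export paired loci as BED
#'
#' Writes both genes of every pair in BED6 (0-based half-open) for
#' genome-browser inspection; the name field is
#' `<genome>|<role>|<gene>`.
#'
#' @param pairs Tibble from [nearest_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_bed <- function(pairs, path) {
  bed_rows <- function(contig, start, end, name, strand) {
    h <- to_zero_half_open(start, end)
    sprintf("%s\t%d\t%d\t%s\t0\t%s", contig, h$start, h$end, name,
            ifelse(strand == "forward", "+", "-"))
  }
  lines <- c(
    bed_rows(pairs$anchor_contig, pairs$anchor_start, pairs$anchor_end,
             paste(pairs$genome_id, "anchor", pairs$anchor_gene_id, sep = "|"),
             pairs$anchor_strand),
    bed_rows(pairs$partner_contig, pairs$partner_start, pairs$partner_end,
             paste(pairs$genome_id, "partner", pairs$partner_gene_id, sep = "|"),
             pairs$partner_strand)
  )
  writeLines(lines, path)
  invisible(path)
}
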