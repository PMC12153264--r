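# Independent oracles used to cross-check the implementation.

# Brute-force two-sided exact test: enumerate every table attainable under
# the observed margins with stats::dhyper and sum the probabilities not
# exceeding the observed table's (same 1e-7 relative tie guard as the
# conventional definition).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(xs, m1, m2, k)
  min(1, sum(pr[pr <= pr[xs == a] * (1 + 1e-7)]))
}

# Brute-force minimal-distance pair: explicit double loop with the gap
# computed directly from the ordered 1-based coordinates.
oracle_nearest <- function(anchor_genes, partner_genes) {
  best <- NULL
  for (i in seq_len(nrow(anchor_genes))) {
    for (j in seq_len(nrow(partner_genes))) {
      a <- anchor_genes[i, ]; p <- partner_genes[j, ]
      if (a$gene_id == p$gene_id || a$contig_id != p$contig_id) next
      if (a$start <= p$start) {
        gap <- max(0, p$start - a$end - 1)
      } else {
        gap <- max(0, a$start - p$end - 1)
      }
      cand <- list(gap = gap, a_start = a$start, p_start = p$start, i = i, j = j)
      if (is.null(best) ||
          gap < best$gap ||
          (gap == best$gap && (cand$a_start < best$a_start ||
            (cand$a_start == best$a_start && cand$p_start < best$p_start)))) {
        best <- cand
      }
    }
  }
  best
}

# Minimal hits table builder for matrix tests.
make_hits <- function(genome_id, gene_id, family_id, e_value = 1e-30,
                      bit_score = 100) {
  tibble::tibble(
    genome_id = genome_id, gene_id = gene_id, family_id = family_id,
    bit_score = bit_score, e_value = e_value
  )
}

make_metadata <- function(genome_ids, domain = "archaea") {
  tibble::tibble(
    genome_id = genome_ids,
    domain_of_life = rep(domain, length.out = length(genome_ids)),
    phylum = "P", order = "O", genus = "G",
    isolation_source = NA_character_
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
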