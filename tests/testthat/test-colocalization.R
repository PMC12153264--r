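test_that("intergenic distance follows the boundary-gap convention", {
  g1 <- gene_feature(start = 100, end = 200)
  g2 <- gene_feature(start = 301, end = 400, gene_id = "h")
  expect_equal(intergenic_distance(g1, g2), 100)
  # abutting
  expect_equal(intergenic_distance(g1, gene_feature(start = 201, end = 300)), 0)
  # overlapping clamps to zero
  expect_equal(intergenic_distance(gene_feature(start = 100, end = 250),
                                   gene_feature(start = 200, end = 400)), 0)
  # nested gene
  expect_equal(intergenic_distance(gene_feature(start = 100, end = 500),
                                   gene_feature(start = 200, end = 300)), 0)
})

test_that("distance is undefined across contigs and symmetric within one", {
  g1 <- gene_feature(contig_id = "cA", start = 100, end = 200)
  g2 <- gene_feature(contig_id = "cB", start = 300, end = 400)
  expect_true(is.na(intergenic_distance(g1, g2)))

  set.seed(31)
  for (i in 1:30) {
    s1 <- sample(1:5000, 1); e1 <- s1 + sample(100:1000, 1)
    s2 <- sample(1:5000, 1); e2 <- s2 + sample(100:1000, 1)
    a <- gene_feature(start = s1, end = e1)
    b <- gene_feature(start = s2, end = e2, gene_id = "h")
    expect_equal(intergenic_distance(a, b), intergenic_distance(b, a))
  }
})

test_that("circular contigs use the shorter of linear and wraparound gaps", {
  g1 <- gene_feature(start = 101, end = 200)
  g2 <- gene_feature(start = 9801, end = 9900, gene_id = "h")
  expect_equal(intergenic_distance(g1, g2), 9600)
  expect_equal(intergenic_distance(g1, g2, circular = TRUE,
                                   contig_length = 10000), 200)
  expect_error(intergenic_distance(g1, g2, circular = TRUE), "contig_length")
})

test_that("orientation classes are exhaustive, exclusive and symmetric", {
  combos <- expand.grid(s1 = c("forward", "reverse"),
                        s2 = c("forward", "reverse"),
                        left_first = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    starts <- if (combos$left_first[i]) c(100, 1000) else c(1000, 100)
    g1 <- gene_feature(start = starts[1], end = starts[1] + 50,
                       strand = combos$s1[i])
    g2 <- gene_feature(start = starts[2], end = starts[2] + 50,
                       strand = combos$s2[i], gene_id = "h")
    cls <- classify_orientation(g1, g2)
    expect_true(cls %in% c("divergent", "convergent", "tandem"))
    expect_equal(cls, classify_orientation(g2, g1))
    if (combos$s1[i] == combos$s2[i]) {
      expect_equal(cls, "tandem")
    } else {
      left_strand <- if (g1$start <= g2$start) g1$strand else g2$strand
      expect_equal(cls, if (left_strand == "reverse") "divergent"
                        else "convergent")
    }
  }
})

test_that("orientation matches the stated archetypes", {
  left_rev <- gene_feature(start = 100, end = 600, strand = "reverse")
  right_fwd <- gene_feature(start = 1000, end = 1500, strand = "forward",
                            gene_id = "h")
  expect_equal(classify_orientation(left_rev, right_fwd), "divergent")
  left_fwd <- gene_feature(start = 100, end = 600, strand = "forward")
  right_rev <- gene_feature(start = 1000, end = 1500, strand = "reverse",
                            gene_id = "h")
  expect_equal(classify_orientation(left_fwd, right_rev), "convergent")
  expect_equal(classify_orientation(left_fwd,
                                    gene_feature(start = 1000, end = 1500,
                                                 gene_id = "h")), "tandem")
})

test_that("nearest_pairs picks the minimal-gap pair per genome", {
  feats <- dplyr::bind_rows(
    gene_feature("G1", "c1", "anch", 1000, 2000),
    gene_feature("G1", "c1", "part_near", 6001, 7000),
    gene_feature("G1", "c1", "part_far", 42001, 43000)
  )
  hits <- make_hits("G1", c("anch", "part_near", "part_far"),
                    c("A", "P", "P"))
  pr <- nearest_pairs(feats, hits, "A", "P")
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$partner_gene_id, "part_near")
  expect_equal(pr$distance, 4000)
})

test_that("cross-contig-only genomes are reported with same_contig = FALSE", {
  feats <- dplyr::bind_rows(
    gene_feature("G1", "cA", "anch", 1000, 2000),
    gene_feature("G1", "cB", "part", 1000, 2000)
  )
  hits <- make_hits("G1", c("anch", "part"), c("A", "P"))
  pr <- flag_colocalized(nearest_pairs(feats, hits, "A", "P"))
  expect_false(pr$same_contig)
  expect_true(is.na(pr$distance))
  expect_false(pr$co_localized)
})

test_that("hits without coordinates are excluded with a warning", {
  feats <- dplyr::bind_rows(
    gene_feature("G1", "c1", "anch", 1000, 2000),
    gene_feature("G1", "c1", "part", 9000, 9800)
  )
  hits <- make_hits("G1", c("anch", "part", "ghost"), c("A", "P", "P"))
  expect_warning(pr <- nearest_pairs(feats, hits, "A", "P"), "coordinates")
  expect_equal(pr$partner_gene_id, "part")
})

test_that("nearest_pairs matches a brute-force all-pairs scan", {
  set.seed(77)
  for (rep in 1:20) {
    n_a <- sample(1:4, 1); n_p <- sample(1:4, 1)
    mk <- function(role, k) {
      starts <- sample(seq(1, 50000, by = 100), k)
      dplyr::bind_rows(lapply(seq_len(k), function(i) {
        gene_feature("G1", sample(c("c1", "c1", "c2"), 1),
                     paste0(role, i), starts[i], starts[i] + 500,
                     sample(c("forward", "reverse"), 1))
      }))
    }
    ag <- mk("a", n_a); pg <- mk("p", n_p)
    feats <- dplyr::bind_rows(ag, pg)
    hits <- make_hits("G1", feats$gene_id,
                      c(rep("A", n_a), rep("P", n_p)))
    pr <- nearest_pairs(feats, hits, "A", "P")
    best <- oracle_nearest(ag, pg)
    if (is.null(best)) {
      expect_false(pr$same_contig)
    } else {
      expect_true(pr$same_contig)
      expect_equal(pr$distance, best$gap)
      expect_equal(pr$anchor_gene_id, ag$gene_id[best$i])
      expect_equal(pr$partner_gene_id, pg$gene_id[best$j])
    }
  }
})

test_that("a gene hitting both families is never paired with itself", {
  feats <- dplyr::bind_rows(
    gene_feature("G1", "c1", "dual", 1000, 2000),
    gene_feature("G1", "c1", "part", 8000, 8800)
  )
  hits <- make_hits("G1", c("dual", "dual", "part"), c("A", "P", "P"))
  pr <- nearest_pairs(feats, hits, "A", "P")
  expect_equal(pr$anchor_gene_id, "dual")
  expect_equal(pr$partner_gene_id, "part")
})

test_that("the 5 kb threshold is strict and monotone in the threshold", {
  feats <- dplyr::bind_rows(
    gene_feature("G1", "c1", "anch", 1000, 2000),
    gene_feature("G1", "c1", "part", 7001, 8000)
  )
  hits <- make_hits("G1", c("anch", "part"), c("A", "P"))
  pr <- nearest_pairs(feats, hits, "A", "P")
  expect_equal(pr$distance, 5000)
  expect_false(flag_colocalized(pr, 5000)$co_localized)
  expect_true(flag_colocalized(pr, 5001)$co_localized)

  sim <- simulate_collection(simulation_params(n_genomes = 60, seed = 13))
  pairs <- nearest_pairs(sim$features, sim$hits, "PF09745", "PF18330")
  meta <- sim$metadata
  counts <- vapply(c(1000, 2500, 5000, 10000, 50000), function(th) {
    colocalization_summary(pairs, meta, th)$global$n_co_localized
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("co-localization summary reports exact per-domain fractions", {
  fx <- fixture_from_counts(501, 72, 164, 14,
                            n_coloc_arch = 163, n_coloc_bact = 127)
  cs <- colocalization_summary(fx$pairs, fx$metadata)
  arch <- cs$by_stratum[cs$by_stratum$stratum == "archaea", ]
  bact <- cs$by_stratum[cs$by_stratum$stratum == "bacteria", ]
  expect_equal(arch$n_dual_positive, 501L)
  expect_equal(arch$fraction_co_localized, 163 / 501)
  expect_equal(arch$pct_co_localized_1dp, 32.5)
  expect_equal(bact$fraction_co_localized, 127 / 164)
  expect_equal(bact$pct_co_localized_1dp, 77.4)
  expect_equal(arch$n_divergent + arch$n_convergent + arch$n_tandem,
               arch$n_co_localized)
})

test_that("an empty pair collection gives all-zero tallies", {
  cs <- colocalization_summary(profscreen:::empty_pairs(), make_metadata("G1"))
  expect_equal(cs$global$n_dual_positive, 0L)
  expect_equal(cs$global$n_co_localized, 0L)
  expect_true(is.na(cs$global$fraction_co_localized))
})
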