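test_that("parameter validation rejects infeasible or inconsistent settings", {
  expect_error(simulation_params(p_anchor = 1.2), "\\[0, 1\\]")
  expect_error(simulation_params(orientation_mix = c(divergent = 0.7,
                                                     convergent = 0.2,
                                                     tandem = 0.2)),
               "orientation_mix")
  expect_error(simulation_params(contig_length = 10000), "too short")
  expect_error(simulation_params(far_gap_range = c(3000, 40000)))
  expect_error(simulation_params(genes_per_genome = 2))
})

test_that("degenerate probabilities give an all-dual, all-co-localized, tandem collection", {
  params <- simulation_params(
    n_genomes = 15, p_anchor = 1, p_partner_given_anchor = 1,
    p_coloc_given_both = 1,
    orientation_mix = c(divergent = 0, convergent = 0, tandem = 1),
    n_background_families = 0, seed = 5
  )
  sim <- simulate_collection(params)
  expect_true(all(sim$manifest$per_genome$anchor))
  expect_true(all(sim$manifest$per_genome$partner))
  expect_true(all(sim$manifest$per_genome$co_localized))
  pairs <- flag_colocalized(
    nearest_pairs(sim$features, sim$hits, "PF09745", "PF18330")
  )
  expect_equal(nrow(pairs), 15L)
  expect_true(all(pairs$co_localized))
  expect_true(all(pairs$orientation == "tandem"))
})

test_that("the same seed reproduces every emitted file byte for byte", {
  params <- simulation_params(n_genomes = 12, n_background_families = 8,
                              seed = 99)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  d3 <- file.path(tempdir(), "det3")
  simulate_collection(params, out_dir = d1)
  simulate_collection(params, out_dir = d2)
  simulate_collection(params, out_dir = d3, seed = 100)

  files <- function(d) {
    f <- list.files(d, recursive = TRUE, full.names = TRUE)
    stats::setNames(tools::md5sum(f), list.files(d, recursive = TRUE))
  }
  expect_identical(files(d1), files(d2))
  expect_false(identical(unname(files(d1)["hits.tsv"]),
                         unname(files(d3)["hits.tsv"])))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("re-ingesting emitted files reproduces the manifest counts exactly", {
  for (seed in c(2, 17, 404)) {
    dir <- file.path(tempdir(), paste0("sc", seed))
    sim <- simulate_collection(
      simulation_params(n_genomes = 25, n_background_families = 10,
                        seed = seed),
      out_dir = dir
    )
    hits <- parse_domain_hits(sim$paths$hits, "tsv")
    meta <- read_genome_metadata(sim$paths$metadata)
    feats <- dplyr::bind_rows(lapply(sim$paths$gff, function(p) {
      parse_gff(p, sub("\\.gff3$", "", basename(p)))
    }))
    pa <- build_presence_matrix(hits, meta,
                                extra_families = c("PF09745", "PF18330"))
    cs <- cooccurrence_summary(pa, "PF09745", "PF18330")
    counts <- sim$manifest$counts$all
    expect_equal(cs$global$n_anchor_pos, counts$n_anchor_pos)
    expect_equal(cs$global$n_partner_pos, counts$n_partner_pos)
    expect_equal(cs$global$n_both, counts$n_both)

    pairs <- nearest_pairs(feats, hits, "PF09745", "PF18330")
    cl <- colocalization_summary(pairs, meta)
    expect_equal(cl$global$n_dual_positive, counts$n_both)
    expect_equal(cl$global$n_co_localized, counts$n_co_localized)
    unlink(dir, recursive = TRUE)
  }
})

test_that("planted distances and orientations are recovered per genome", {
  sim <- simulate_collection(simulation_params(n_genomes = 80, seed = 21))
  pairs <- flag_colocalized(
    nearest_pairs(sim$features, sim$hits, "PF09745", "PF18330")
  )
  truth <- sim$manifest$per_genome
  merged <- dplyr::inner_join(pairs, truth, by = "genome_id")
  planted <- merged[merged$co_localized.y, ]
  expect_gt(nrow(planted), 0)
  expect_equal(planted$distance, as.numeric(planted$planted_distance))
  expect_equal(planted$orientation, planted$planted_orientation)
  expect_true(all(merged$co_localized.x == merged$co_localized.y))
  # partner on a second contig is recovered as a cross-contig pair
  second <- merged[merged$partner_on_second_contig, ]
  if (nrow(second) > 0) expect_true(all(!second$same_contig))
})

test_that("realized conditional prevalence is calibrated to the planted value", {
  params <- simulation_params(n_genomes = 500, n_background_families = 0,
                              seed = 1)
  reps <- 200
  frac <- vapply(seq_len(reps), function(i) {
    sim <- simulate_presence_matrix(params, seed = 1000 + i)
    with(sim$truth, sum(anchor & partner) / sum(anchor))
  }, numeric(1))
  # mean over replicates within 3 standard errors of p_partner_given_anchor
  se <- stats::sd(frac) / sqrt(reps)
  expect_lt(abs(mean(frac) - params$p_partner_given_anchor), 3 * se)
})

test_that("fixture_from_counts validates contradictory counts", {
  expect_error(fixture_from_counts(-1, 0, 0, 0), "non-negative")
  expect_error(fixture_from_counts(10, 0, 5, 0, n_coloc_arch = 11),
               "dual-positive")
  expect_error(fixture_from_counts(10, 0, 5, 0, n_coloc_arch = 5,
                                   n_tandem_arch = 6), "tandem")
  empty <- fixture_from_counts(0, 0, 0, 0)
  expect_equal(nrow(empty$pairs), 0L)
  expect_equal(sum(as.matrix(empty$pa)), 0)
})

test_that("genes never overlap and planted pairs are adjacent at the planted gap", {
  sim <- simulate_collection(simulation_params(n_genomes = 30, seed = 8))
  by_contig <- split(sim$features,
                     paste(sim$features$genome_id, sim$features$contig_id))
  for (f in by_contig) {
    f <- f[order(f$start), ]
    if (nrow(f) > 1) {
      expect_true(all(f$start[-1] > f$end[-nrow(f)]))
    }
  }
})
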