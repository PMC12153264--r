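test_that("parse_gff maps coordinates and strand as printed", {
  path <- write_lines_tmp(c(
    "##gff-version 3",
    "ctg1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=geneA",
    "ctg1\tsrc\tCDS\t500\t900\t.\t-\t0\tID=geneB"
  ), ".gff3")
  feats <- parse_gff(path, "G1")
  expect_equal(nrow(feats), 2L)
  expect_equal(feats$start, c(100L, 500L))
  expect_equal(feats$end, c(200L, 900L))
  expect_equal(feats$strand, c("forward", "reverse"))
  expect_equal(feats$gene_id, c("geneA", "geneB"))
  expect_equal(unique(feats$genome_id), "G1")
})

test_that("parse_gff on header-only input returns an empty collection", {
  path <- write_lines_tmp(c("##gff-version 3", "# just a comment"), ".gff3")
  feats <- parse_gff(path, "G1")
  expect_equal(nrow(feats), 0L)
  expect_named(feats, c("genome_id", "contig_id", "gene_id", "start", "end",
                        "strand"))
})

test_that("parse_gff skips malformed lines with a warning and keeps the rest", {
  path <- write_lines_tmp(c(
    "##gff-version 3",
    "ctg1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=ok1",
    "ctg1\tsrc\tCDS\tnotanumber\t200\t.\t+\t0\tID=bad1",
    "ctg1\tsrc\tCDS\t300\t250\t.\t+\t0\tID=bad2",
    "ctg1\tsrc\tCDS\t400\t450\t.\t?\t0\tID=bad3",
    "ctg1\tsrc\tCDS\t600\t700\t.\t-\t0\tID=ok2"
  ), ".gff3")
  expect_warning(expect_warning(expect_warning(
    feats <- parse_gff(path, "G1")
  )))
  expect_equal(feats$gene_id, c("ok1", "ok2"))
})

test_that("parse_gff honors the feature-type filter", {
  path <- write_lines_tmp(c(
    "##gff-version 3",
    "ctg1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "ctg1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=c1",
    "ctg1\tsrc\ttRNA\t300\t400\t.\t+\t.\tID=t1"
  ), ".gff3")
  expect_equal(parse_gff(path, "G")$gene_id, "c1")
  both <- parse_gff(path, "G", feature_types = c("gene", "CDS"))
  expect_setequal(both$gene_id, c("g1", "c1"))
})

test_that("parse_gff errors on an unreadable file", {
  expect_error(parse_gff(tempfile(), "G"), "cannot read")
})

test_that("simplified TSV hits parse with accession normalization", {
  path <- write_lines_tmp(c(
    "genome_id\tgene_id\tfamily_id\tscore\te_value",
    "G1\tgeneA\tPF09745\t120.0\t1e-30",
    "G1\tgeneB\tpf18330.5\t80.0\t1e-12"
  ), ".tsv")
  hits <- parse_domain_hits(path, "tsv")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$family_id, c("PF09745", "PF18330"))
  expect_equal(hits$e_value, c(1e-30, 1e-12))
  expect_equal(hits$bit_score, c(120, 80))
})

test_that("hits rows with non-numeric e-values are skipped with a warning", {
  path <- write_lines_tmp(c(
    "genome_id\tgene_id\tfamily_id\tscore\te_value",
    "G1\tgeneA\tPF09745\t120.0\t1e-30",
    "G1\tgeneB\tPF00001\t80.0\tnot_a_number"
  ), ".tsv")
  expect_warning(hits <- parse_domain_hits(path, "tsv"), "non-numeric")
  expect_equal(hits$gene_id, "geneA")
})

test_that("HMMER tblout and domtblout dialects map target/query columns", {
  tbl <- write_lines_tmp(c(
    "# comment line",
    "geneA  -  HARP  PF09745.12  1.2e-30  120.5  0.1  1  1  0  0  0  0  0  0 -",
    "geneB  -  Rnl   -           3e-08     55.0  0.0  1  1  0  0  0  0  0  0 -"
  ))
  hits <- parse_domain_hits(tbl, "tblout", genome_id = "G7")
  expect_equal(hits$family_id, c("PF09745", "RNL"))
  expect_equal(hits$e_value, c(1.2e-30, 3e-08))
  expect_equal(unique(hits$genome_id), "G7")

  dom <- write_lines_tmp(c(
    "# comment",
    "geneA - 200 HARP PF09745.3 180 4e-25 110.0 0.1 1 1 0 0 0 0 0 0 - - -"
  ))
  dhits <- parse_domain_hits(dom, "domtblout", genome_id = "G7")
  expect_equal(dhits$family_id, "PF09745")
  expect_equal(dhits$e_value, 4e-25)
  expect_equal(dhits$bit_score, 110)
})

test_that("comment-only HMMER input yields an empty collection", {
  path <- write_lines_tmp(c("# one", "# two"))
  expect_equal(nrow(parse_domain_hits(path, "domtblout", genome_id = "G")), 0L)
})

test_that("unknown hits dialect is a configuration error", {
  path <- write_lines_tmp("x")
  expect_error(parse_domain_hits(path, "csv"), "unknown hits dialect")
})

test_that("metadata reader validates domains and uniqueness", {
  ok <- write_lines_tmp(c(
    "genome_id\tdomain_of_life\tphylum\torder\tgenus\tisolation_source",
    "G1\tArchaea\tHalobacteriota\tO1\tGen1\tsaltern",
    "G2\tbacteria\tAquificota\tO2\tGen2\tvent"
  ), ".tsv")
  meta <- read_genome_metadata(ok)
  expect_equal(meta$domain_of_life, c("archaea", "bacteria"))

  dup <- write_lines_tmp(c("genome_id\tdomain_of_life",
                           "G1\tarchaea", "G1\tarchaea"), ".tsv")
  expect_error(read_genome_metadata(dup), "duplicate")

  bad <- write_lines_tmp(c("genome_id\tdomain_of_life", "G1\teukarya"), ".tsv")
  expect_error(read_genome_metadata(bad), "archaea or bacteria")
})

test_that("generator files round-trip through the parsers to the manifest", {
  for (seed in 1:5) {
    params <- simulation_params(n_genomes = 8, n_background_families = 5,
                                seed = seed)
    dir <- file.path(tempdir(), paste0("rt", seed))
    sim <- simulate_collection(params, out_dir = dir)

    feats <- dplyr::bind_rows(lapply(sim$paths$gff, function(p) {
      parse_gff(p, sub("\\.gff3$", "", basename(p)))
    }))
    expect_equal(
      dplyr::arrange(feats, genome_id, contig_id, start),
      dplyr::arrange(sim$features, genome_id, contig_id, start)
    )

    hits <- parse_domain_hits(sim$paths$hits, "tsv")
    meta <- read_genome_metadata(sim$paths$metadata)
    pa <- build_presence_matrix(hits, meta,
                                extra_families = c("PF09745", "PF18330"))
    truth <- sim$manifest$per_genome
    expect_equal(unname(pa_column(pa, "PF09745")), as.integer(truth$anchor))
    expect_equal(unname(pa_column(pa, "PF18330")), as.integer(truth$partner))
    unlink(dir, recursive = TRUE)
  }
})
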