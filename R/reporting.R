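#' Write an iToL binary ring annotation
#'
#' Emits an iToL `DATASET_BINARY` flat file: a comma-separated header block
#' (`SEPARATOR COMMA`, `DATASET_LABEL`, `COLOR`, `FIELD_SHAPES`,
#' `FIELD_LABELS`) followed by one `label,value` line per genome.  Values are
#' 1 (present), 0 (absent ring symbol) or -1 (no symbol; used for `NA`
#' indicators).  One file per concentric ring.
#'
#' @param labels Unique genome/leaf labels.
#' @param indicator Binary (0/1, `NA` allowed) vector, one per label.
#' @param dataset_label Ring name shown in the legend.
#' @param color Hex color for the ring.
#' @param path Optional output path; when given the lines are written there.
#' @param shape iToL field shape code (default 2, circle).
#' @return Character vector of file lines, invisibly when `path` is set.
#' @export
write_itol_binary_dataset <- function(labels, indicator, dataset_label,
                                      color = "#d62728", path = NULL,
                                      shape = 2) {
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  stopifnot(length(labels) == length(indicator))
  vals <- ifelse(is.na(indicator), -1L, as.integer(indicator))
  if (!all(vals %in% c(-1L, 0L, 1L))) {
    stop("indicator values must be 0, 1 or NA")
  }
  lines <- c(
    "DATASET_BINARY",
    "SEPARATOR COMMA",
    paste0("DATASET_LABEL,", dataset_label),
    paste0("COLOR,", color),
    paste0("FIELD_SHAPES,", shape),
    paste0("FIELD_LABELS,", dataset_label),
    paste0("FIELD_COLORS,", color),
    "DATA",
    if (length(labels) > 0) paste0(labels, ",", vals) else character(0)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Validate and prune a Newick tree against a genome set
#'
#' Reads a Newick tree (file path or literal string), prunes leaves that are
#' not in the genome label set, and reports the mismatch in both directions.
#' Tree inference itself is out of scope: the tree is a passthrough for
#' visualization alongside the ring annotations.
#'
#' @param newick Path to a Newick file, or a Newick string.
#' @param labels Genome labels expected at the leaves.
#' @return List with `tree` (an `ape::phylo`), `dropped_tips` (leaves pruned
#'   because they match no genome) and `labels_missing_from_tree`.
#' @export
attach_tree <- function(newick, labels) {
  tree <- if (file.exists(newick)) {
    ape::read.tree(newick)
  } else {
    ape::read.tree(text = newick)
  }
  if (is.null(tree)) {
    stop("could not parse Newick input")
  }
  keep <- intersect(tree$tip.label, labels)
  if (length(keep) == 0L) {
    stop("no tree leaf matches any genome label")
  }
  drop <- setdiff(tree$tip.label, labels)
  if (length(drop) > 0L) {
    tree <- ape::drop.tip(tree, drop)
  }
  list(
    tree = tree,
    dropped_tips = drop,
    labels_missing_from_tree = setdiff(labels, keep)
  )
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (paths to a GFF3 directory, hits file and metadata
#' file) or `scenario` (a [simulation_params()] object or a list of its
#' arguments) must be given.
#'
#' @param input List with `gff_dir`, `hits`, `metadata` and optionally
#'   `hits_dialect` (default `"tsv"`).
#' @param scenario A [simulation_params()] object or argument list.
#' @param anchor,partner Family accessions.
#' @param anchor_aliases,partner_aliases Optional accession vectors unioned
#'   into the anchor/partner call.
#' @param max_evalue,min_bitscore Presence policy thresholds.
#' @param alpha FDR level of the enrichment screen.
#' @param coloc_threshold Co-localization distance threshold (bp, exclusive).
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed for the simulated scenario.
#' @param tree Optional Newick path/string for the iToL export.
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            anchor = "PF09745", partner = "RNL3",
                            anchor_aliases = NULL,
                            partner_aliases = c("PF18330", "TIGR01209"),
                            max_evalue = 1e-5, min_bitscore = NULL,
                            alpha = 0.05, coloc_threshold = 5000,
                            out_dir, seed = 1L, tree = NULL) {
  if (is.null(input) == is.null(scenario)) {
    stop("exactly one of `input` or `scenario` must be set")
  }
  stopifnot(alpha > 0, alpha < 1, coloc_threshold > 0)
  if (!is.null(input)) {
    missing_keys <- setdiff(c("gff_dir", "hits", "metadata"), names(input))
    if (length(missing_keys) > 0L) {
      stop("input config is missing: ", paste(missing_keys, collapse = ", "))
    }
    for (p in unlist(input[c("gff_dir", "hits", "metadata")])) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    if (is.null(input$hits_dialect)) input$hits_dialect <- "tsv"
  }
  if (!is.null(scenario) && !inherits(scenario, "simulation_params")) {
    scenario <- do.call(simulation_params, scenario)
  }
  structure(
    list(input = input, scenario = scenario,
         anchor = normalize_family_id(anchor),
         partner = normalize_family_id(partner),
         anchor_aliases = anchor_aliases, partner_aliases = partner_aliases,
         policy = presence_policy(max_evalue, min_bitscore),
         alpha = alpha, coloc_threshold = coloc_threshold,
         out_dir = out_dir, seed = as.integer(seed), tree = tree),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file's keys map one-to-one onto the arguments of [pipeline_config()];
#' a `scenario` block maps onto [simulation_params()].
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full profiling pipeline
#'
#' Orchestrates every stage over either real inputs or a simulated scenario:
#' parse gene coordinates and domain hits, build the presence/absence matrix
#' (with alias groups folded into the anchor/partner columns), run the
#' enrichment screen, summarize anchor-partner co-occurrence, find
#' minimal-distance neighbor pairs, summarize co-localization, and write the
#' report bundle: presence matrix, enrichment table, summary tables, pairs
#' table (TSV + BED), three iToL ring annotations (anchor-positive,
#' partner-positive, co-localized), a run log recording every threshold and
#' convention in effect, and a provenance JSON.
#'
#' @param config A `pipeline_config` object (or path to a config file).
#' @return Invisibly, a list with all in-memory stage results and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    "profscreen pipeline run",
    paste0("anchor: ", config$anchor,
           if (length(config$anchor_aliases) > 0)
             paste0(" (aliases: ",
                    paste(config$anchor_aliases, collapse = ", "), ")")
           else ""),
    paste0("partner: ", config$partner,
           if (length(config$partner_aliases) > 0)
             paste0(" (aliases: ",
                    paste(config$partner_aliases, collapse = ", "), ")")
           else ""),
    paste0("presence policy: e-value <= ", format(config$policy$max_evalue),
           if (is.null(config$policy$min_bitscore)) ", no bit-score floor"
           else paste0(", bit score >= ", config$policy$min_bitscore)),
    "enrichment test: two-sided exact hypergeometric (conditional on margins)",
    paste0("multiple testing: Benjamini-Hochberg FDR, alpha = ", config$alpha),
    paste0("co-localization: same contig, gap < ", config$coloc_threshold,
           " bp (boundary-to-boundary, overlap/abutment = 0)"),
    "orientation: divergent = head-to-head, convergent = tail-to-tail, tandem = same strand"
  )

  if (!is.null(config$scenario)) {
    sim_dir <- file.path(config$out_dir, "simulated_input")
    sim <- simulate_collection(config$scenario, out_dir = sim_dir,
                               seed = config$seed)
    features <- sim$features
    hits <- sim$hits
    metadata <- sim$metadata
    log_lines <- c(log_lines,
                   paste0("input: simulated scenario, seed ", config$seed,
                          ", ", config$scenario$n_genomes, " genomes"))
  } else {
    gff_files <- sort(list.files(config$input$gff_dir,
                                 pattern = "\\.gff3?$", full.names = TRUE))
    if (length(gff_files) == 0L) {
      stop("no GFF3 files found in ", config$input$gff_dir)
    }
    features <- dplyr::bind_rows(lapply(gff_files, function(p) {
      parse_gff(p, genome_id = sub("\\.gff3?$", "", basename(p)))
    }))
    hits <- parse_domain_hits(config$input$hits, config$input$hits_dialect)
    metadata <- read_genome_metadata(config$input$metadata)
    log_lines <- c(log_lines,
                   paste0("input: ", length(gff_files), " GFF3 files, ",
                          nrow(hits), " hit rows, ", nrow(metadata),
                          " genomes"))
  }

  aliases <- list()
  if (length(config$anchor_aliases) > 0) {
    aliases[[config$anchor]] <- c(config$anchor, config$anchor_aliases)
  }
  if (length(config$partner_aliases) > 0) {
    aliases[[config$partner]] <- c(config$partner, config$partner_aliases)
  }
  pa <- build_presence_matrix(hits, metadata, config$policy,
                              aliases = if (length(aliases)) aliases else NULL,
                              extra_families = c(config$anchor, config$partner))
  log_lines <- c(log_lines,
                 paste0("presence matrix: ", nrow(pa$m), " genomes x ",
                        ncol(pa$m), " families"))

  enrichment <- screen_all_families(pa, config$anchor, config$alpha)
  cooc <- cooccurrence_summary(pa, config$anchor, config$partner)
  # map alias members onto the group columns for the neighborhood stage too
  nhits <- hits
  nhits$family_id <- normalize_family_id(nhits$family_id)
  for (grp in names(aliases)) {
    nhits$family_id[nhits$family_id %in%
                      normalize_family_id(aliases[[grp]])] <- grp
  }
  pairs <- nearest_pairs(features, nhits, config$anchor, config$partner,
                         config$policy)
  pairs <- flag_colocalized(pairs, config$coloc_threshold)
  coloc <- colocalization_summary(pairs, metadata, config$coloc_threshold)
  log_lines <- c(log_lines,
                 paste0("enrichment screen: ", nrow(enrichment), " families"),
                 paste0("dual-positive genomes paired: ", nrow(pairs)),
                 paste0("co-localized genomes: ", sum(pairs$co_localized)))

  out <- function(f) file.path(config$out_dir, f)
  write_presence_matrix(pa, out("presence_matrix.tsv"))
  write_enrichment_tsv(enrichment, out("enrichment.tsv"))
  readr::write_tsv(dplyr::bind_rows(cooc$global, cooc$by_stratum),
                   out("cooccurrence_summary.tsv"))
  write_pairs_tsv(pairs, out("pairs.tsv"))
  write_pairs_bed(pairs, out("pairs.bed"))
  readr::write_tsv(dplyr::bind_rows(coloc$global, coloc$by_stratum),
                   out("colocalization_summary.tsv"))

  anchor_pos <- pa_column(pa, config$anchor)
  partner_pos <- pa_column(pa, config$partner)
  coloc_ind <- as.integer(metadata$genome_id %in%
                            pairs$genome_id[pairs$co_localized])
  write_itol_binary_dataset(metadata$genome_id, anchor_pos,
                            "anchor_positive", "#1f77b4",
                            out("itol_anchor.txt"))
  write_itol_binary_dataset(metadata$genome_id, partner_pos,
                            "partner_positive", "#2ca02c",
                            out("itol_partner.txt"))
  write_itol_binary_dataset(metadata$genome_id, coloc_ind,
                            "co_localized", "#d62728",
                            out("itol_colocalized.txt"))

  tree_report <- NULL
  if (!is.null(config$tree)) {
    tree_report <- attach_tree(config$tree, metadata$genome_id)
    ape::write.tree(tree_report$tree, out("tree_pruned.nwk"))
    log_lines <- c(log_lines,
                   paste0("tree: ", length(tree_report$tree$tip.label),
                          " matched leaves, ",
                          length(tree_report$dropped_tips), " pruned"))
  }

  writeLines(log_lines, out("run_log.txt"))
  jsonlite::write_json(
    list(
      package = "profscreen",
      version = as.character(utils::packageVersion("profscreen")),
      seed = config$seed,
      anchor = config$anchor, partner = config$partner,
      max_evalue = config$policy$max_evalue,
      alpha = config$alpha, coloc_threshold = config$coloc_threshold,
      n_genomes = nrow(pa$m), n_families = ncol(pa$m)
    ),
    out("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    pa = pa, enrichment = enrichment, cooccurrence = cooc, pairs = pairs,
    colocalization = coloc, tree = tree_report, out_dir = config$out_dir,
    manifest = if (!is.null(config$scenario)) sim$manifest else NULL
  ))
}
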