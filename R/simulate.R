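#' Parameters for the synthetic genome-collection generator
#'
#' Defines the joint law of the generated collection: anchor-family
#' prevalence, partner prevalence conditional on anchor state, independent
#' background families, and — for dual-positive genomes — the probability of
#' a planted co-localized anchor-partner pair, the intergenic-distance laws
#' for near and far placements, and the orientation mixture.
#'
#' Defaults emulate the statistical regime of a strongly linked
#' anchor-partner pair in a desk-scale collection: a conditional partner
#' prevalence of 0.9 given anchor presence versus 0.05 in the anchor-negative
#' background, co-localization in 80% of dual-positive genomes with the gap
#' drawn uniformly below the 5 kb threshold, an orientation mixture dominated
#' by divergent (bidirectional) pairs with a small tandem minority, and an
#' archaeal:bacterial ratio of 573:178.
#'
#' @param n_genomes Number of genomes.
#' @param p_anchor Anchor-family prevalence.
#' @param p_partner_given_anchor,p_partner_given_no_anchor Conditional
#'   partner prevalences.
#' @param n_background_families Number of independent background families.
#' @param background_prevalence Per-family background prevalence (scalar or
#'   one value per family).
#' @param p_coloc_given_both Probability that a dual-positive genome carries
#'   a planted co-localized pair.
#' @param coloc_gap_range Integer range (inclusive) of planted co-localized
#'   gaps in bp; default uniform on \[0, 4999\].
#' @param far_gap_range Integer range of planted non-co-localized same-contig
#'   gaps; must start at or above the co-localization threshold.
#' @param p_far_second_contig Among non-co-localized dual-positive genomes,
#'   the probability that the partner sits on a second contig instead of far
#'   away on the same one.
#' @param orientation_mix Named probability vector over
#'   `c(divergent, convergent, tandem)`; must sum to 1.
#' @param contig_length Contig length in bp; checked upfront against the
#'   worst-case span of the placement scheme.
#' @param genes_per_genome Genes laid on the primary contig of each genome.
#' @param archaeal_fraction Probability that a genome is archaeal.
#' @param anchor_family,partner_family Accessions used in the emitted hits.
#' @param seed Integer seed; the collection is a deterministic function of
#'   the parameters and this seed.
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(n_genomes = 500,
                              p_anchor = 0.5,
                              p_partner_given_anchor = 0.9,
                              p_partner_given_no_anchor = 0.05,
                              n_background_families = 200,
                              background_prevalence = 0.3,
                              p_coloc_given_both = 0.8,
                              coloc_gap_range = c(0, 4999),
                              far_gap_range = c(5000, 40000),
                              p_far_second_contig = 0.2,
                              orientation_mix = c(divergent = 0.9,
                                                  convergent = 0.0,
                                                  tandem = 0.1),
                              contig_length = 200000,
                              genes_per_genome = 20,
                              archaeal_fraction = 573 / 751,
                              anchor_family = "PF09745",
                              partner_family = "PF18330",
                              seed = 1L) {
  probs <- c(p_anchor, p_partner_given_anchor, p_partner_given_no_anchor,
             background_prevalence, p_coloc_given_both, p_far_second_contig,
             archaeal_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(
    n_genomes >= 1, n_background_families >= 0, genes_per_genome >= 3,
    length(coloc_gap_range) == 2L, coloc_gap_range[1] >= 0,
    coloc_gap_range[2] >= coloc_gap_range[1],
    length(far_gap_range) == 2L, far_gap_range[2] >= far_gap_range[1],
    far_gap_range[1] > coloc_gap_range[2]
  )
  if (!(length(background_prevalence) %in% c(1L, max(1L, n_background_families)))) {
    stop("background_prevalence must be scalar or one value per family")
  }
  if (!setequal(names(orientation_mix),
                c("divergent", "convergent", "tandem")) ||
      abs(sum(orientation_mix) - 1) > 1e-8 || any(orientation_mix < 0)) {
    stop("orientation_mix must be a probability vector over divergent, convergent, tandem")
  }
  # worst-case primary-contig span: every gene at max length, every gap at the
  # truncation cap, plus one planted far gap
  worst <- genes_per_genome * MAX_GENE_LEN +
    genes_per_genome * (GAP_CAP + 1) + max(far_gap_range)
  if (worst > contig_length) {
    stop("contig_length ", contig_length,
         " too short for ", genes_per_genome,
         " genes (worst-case span ", worst, " bp)")
  }
  structure(
    list(
      n_genomes = as.integer(n_genomes), p_anchor = p_anchor,
      p_partner_given_anchor = p_partner_given_anchor,
      p_partner_given_no_anchor = p_partner_given_no_anchor,
      n_background_families = as.integer(n_background_families),
      background_prevalence = background_prevalence,
      p_coloc_given_both = p_coloc_given_both,
      coloc_gap_range = as.integer(coloc_gap_range),
      far_gap_range = as.integer(far_gap_range),
      p_far_second_contig = p_far_second_contig,
      orientation_mix = orientation_mix[c("divergent", "convergent", "tandem")],
      contig_length = as.integer(contig_length),
      genes_per_genome = as.integer(genes_per_genome),
      archaeal_fraction = archaeal_fraction,
      anchor_family = normalize_family_id(anchor_family),
      partner_family = normalize_family_id(partner_family),
      seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

MIN_GENE_LEN <- 300L
MAX_GENE_LEN <- 1500L
MEAN_GAP <- 500
GAP_CAP <- 5000L

# Presence states for the whole collection, drawn from the current RNG
# stream.  Shared by the matrix-only and full-collection simulators.
draw_presence <- function(params) {
  n <- params$n_genomes
  anchor <- stats::runif(n) < params$p_anchor
  p_part <- ifelse(anchor, params$p_partner_given_anchor,
                   params$p_partner_given_no_anchor)
  partner <- stats::runif(n) < p_part
  archaeal <- stats::runif(n) < params$archaeal_fraction
  bg <- matrix(
    stats::runif(n * params$n_background_families) <
      rep(params$background_prevalence, each = n),
    nrow = n
  )
  list(anchor = anchor, partner = partner, archaeal = archaeal, bg = bg)
}

simulated_metadata <- function(genome_ids, archaeal) {
  arch_phyla <- c("Halobacteriota", "Methanobacteriota", "Thermoproteota")
  bact_phyla <- c("Pseudomonadota", "Aquificota", "Nitrospirota")
  sources <- c("saltern", "hydrothermal vent", "thermal spring",
               "soda lake", "soil")
  phylum <- ifelse(
    archaeal,
    arch_phyla[1 + (seq_along(genome_ids) %% 3)],
    bact_phyla[1 + (seq_along(genome_ids) %% 3)]
  )
  tibble::tibble(
    genome_id = genome_ids,
    domain_of_life = ifelse(archaeal, "archaea", "bacteria"),
    phylum = phylum,
    order = paste0(phylum, "_order", 1 + (seq_along(genome_ids) %% 2)),
    genus = paste0(phylum, "_genus", 1 + (seq_along(genome_ids) %% 5)),
    isolation_source = sources[1 + (seq_along(genome_ids) %% 5)]
  )
}

#' Simulate only the presence/absence matrix
#'
#' Draws presence states (anchor, conditional partner, independent background
#' families) without placing genes or writing files; the fast path for
#' statistical calibration of the enrichment screen.
#'
#' @param params A [simulation_params()] object.
#' @param seed Overrides `params$seed` when given.
#' @return List with `pa` (a `presence_matrix`) and `truth` (per-genome
#'   tibble of planted states).
#' @export
simulate_presence_matrix <- function(params, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(if (is.null(seed)) params$seed else as.integer(seed))
  st <- draw_presence(params)
  genome_ids <- sprintf("G%05d", seq_len(params$n_genomes))
  fam_bg <- if (params$n_background_families > 0) {
    sprintf("BG%04d", seq_len(params$n_background_families))
  } else character(0)
  m <- cbind(
    matrix(as.integer(st$anchor), ncol = 1,
           dimnames = list(NULL, params$anchor_family)),
    matrix(as.integer(st$partner), ncol = 1,
           dimnames = list(NULL, params$partner_family)),
    matrix(as.integer(st$bg), nrow = params$n_genomes,
           dimnames = list(NULL, fam_bg))
  )
  rownames(m) <- genome_ids
  meta <- simulated_metadata(genome_ids, st$archaeal)
  list(
    pa = new_presence_matrix(m[, sort(colnames(m)), drop = FALSE], meta),
    truth = tibble::tibble(
      genome_id = genome_ids, anchor = st$anchor, partner = st$partner,
      domain_of_life = meta$domain_of_life
    )
  )
}

#' Simulate a full genome collection
#'
#' Generates per-genome gene coordinates (GFF3), a domain-hit table, genome
#' metadata and a ground-truth manifest.  Presence states follow
#' [simulation_params()]; in dual-positive genomes the anchor-partner pair is
#' planted adjacent with a gap drawn from the co-localized law (with
#' probability `p_coloc_given_both`), else far apart on the same contig or on
#' a second contig.  Background genes are laid left to right with
#' exponential-law gaps (mean 500 bp, capped at 5 kb) and lengths uniform on
#' \[300, 1500\] bp; planted pair gaps override the gap law.  Genes never
#' overlap.
#'
#' Each genome's placement uses a substream seeded deterministically from the
#' collection seed and the genome index, so the emitted files are a pure
#' function of `(params, seed)`: the same seed reproduces them byte for byte.
#'
#' @param params A [simulation_params()] object.
#' @param out_dir Output directory; when `NULL` nothing is written and the
#'   collection is returned in memory only.
#' @param seed Overrides `params$seed` when given.
#' @return List with `features`, `hits`, `metadata` tibbles, the `manifest`
#'   (per-genome truth + realized global counts), and `paths` when written.
#' @export
simulate_collection <- function(params, out_dir = NULL, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  set.seed(seed)
  n <- params$n_genomes
  st <- draw_presence(params)
  genome_ids <- sprintf("G%05d", seq_len(n))

  both <- st$anchor & st$partner
  coloc <- both & stats::runif(n) < params$p_coloc_given_both
  second_contig <- both & !coloc & stats::runif(n) < params$p_far_second_contig
  gap_planted <- ifelse(
    coloc,
    draw_int_range(n, params$coloc_gap_range),
    draw_int_range(n, params$far_gap_range)
  )
  orient <- sample(names(params$orientation_mix), n, replace = TRUE,
                   prob = params$orientation_mix)
  orient[!coloc] <- NA_character_
  gap_planted[!both | second_contig] <- NA_integer_

  feature_list <- vector("list", n)
  hit_list <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((seed %% 1000000L) * 2011L + i)
    g <- place_genome(
      genome_ids[i], params,
      anchor = st$anchor[i], partner = st$partner[i],
      paired = both[i] && !second_contig[i],
      second_contig = second_contig[i],
      gap = gap_planted[i],
      orientation = if (coloc[i]) orient[i] else NA_character_
    )
    feature_list[[i]] <- g$features
    hit_list[[i]] <- g$hits
    if (any(st$bg[i, ])) {
      fams <- sprintf("BG%04d", which(st$bg[i, ]))
      genes <- sample(g$features$gene_id, length(fams), replace = TRUE)
      hit_list[[i]] <- dplyr::bind_rows(
        hit_list[[i]],
        tibble::tibble(
          genome_id = genome_ids[i], gene_id = genes, family_id = fams,
          bit_score = round(stats::runif(length(fams), 50, 500), 1),
          e_value = signif(10^-stats::runif(length(fams), 10, 30), 3)
        )
      )
    }
  }
  features <- dplyr::bind_rows(feature_list)
  hits <- dplyr::bind_rows(hit_list)
  metadata <- simulated_metadata(genome_ids, st$archaeal)

  per_genome <- tibble::tibble(
    genome_id = genome_ids,
    domain_of_life = metadata$domain_of_life,
    anchor = st$anchor, partner = st$partner,
    co_localized = coloc,
    planted_distance = ifelse(coloc, gap_planted, NA_integer_),
    planted_orientation = orient,
    partner_on_second_contig = second_contig
  )
  manifest <- list(
    seed = seed,
    n_genomes = n,
    per_genome = per_genome,
    counts = manifest_counts(per_genome)
  )

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_collection(out_dir, genome_ids, features, hits, metadata,
                              manifest, params)
  }
  list(features = features, hits = hits, metadata = metadata,
       manifest = manifest, paths = paths)
}

manifest_counts <- function(pg) {
  tally <- function(p) {
    list(
      n_genomes = nrow(p),
      n_anchor_pos = sum(p$anchor),
      n_partner_pos = sum(p$partner),
      n_both = sum(p$anchor & p$partner),
      n_co_localized = sum(p$co_localized),
      orientation = as.list(table(factor(
        p$planted_orientation[p$co_localized],
        levels = c("divergent", "convergent", "tandem")
      )))
    )
  }
  list(
    all = tally(pg),
    archaea = tally(pg[pg$domain_of_life == "archaea", ]),
    bacteria = tally(pg[pg$domain_of_life == "bacteria", ])
  )
}

draw_int_range <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

# Lay one genome: genes_per_genome genes left-to-right on the primary contig,
# anchor/partner genes assigned per the planted design.
place_genome <- function(genome_id, params, anchor, partner, paired,
                         second_contig, gap, orientation) {
  n_g <- params$genes_per_genome
  lens <- draw_int_range(n_g, c(MIN_GENE_LEN, MAX_GENE_LEN))
  gaps <- pmin(as.integer(ceiling(stats::rexp(n_g, 1 / MEAN_GAP))), GAP_CAP)
  strands <- sample(c("forward", "reverse"), n_g, replace = TRUE)

  anchor_idx <- partner_idx <- NA_integer_
  if (anchor && partner && paired) {
    j <- sample.int(n_g - 1L, 1L)
    gaps[j + 1L] <- gap
    anchor_left <- stats::runif(1) < 0.5
    anchor_idx <- if (anchor_left) j else j + 1L
    partner_idx <- if (anchor_left) j + 1L else j
    if (!is.na(orientation)) {
      s <- switch(orientation,
        divergent = c("reverse", "forward"),
        convergent = c("forward", "reverse"),
        tandem = rep(sample(c("forward", "reverse"), 1), 2)
      )
      strands[c(j, j + 1L)] <- s
    }
  } else {
    if (anchor) anchor_idx <- sample.int(n_g, 1L)
    if (partner && !second_contig) {
      free <- setdiff(seq_len(n_g), anchor_idx)
      partner_idx <- free[sample.int(length(free), 1L)]
    }
  }

  starts <- integer(n_g)
  pos <- 0L
  for (i in seq_len(n_g)) {
    pos <- pos + gaps[i] + 1L
    starts[i] <- pos
    pos <- pos + lens[i] - 1L
  }
  stopifnot(pos <= params$contig_length)

  contig1 <- paste0(genome_id, "_c1")
  features <- tibble::tibble(
    genome_id = genome_id,
    contig_id = contig1,
    gene_id = sprintf("%s_g%03d", genome_id, seq_len(n_g)),
    start = starts,
    end = starts + lens - 1L,
    strand = strands
  )
  if (partner && second_contig) {
    plen <- draw_int_range(1, c(MIN_GENE_LEN, MAX_GENE_LEN))
    pstart <- draw_int_range(1, c(1000L, 20000L))
    features <- dplyr::bind_rows(features, tibble::tibble(
      genome_id = genome_id,
      contig_id = paste0(genome_id, "_c2"),
      gene_id = sprintf("%s_gp2", genome_id),
      start = pstart, end = pstart + plen - 1L,
      strand = sample(c("forward", "reverse"), 1)
    ))
    partner_idx <- nrow(features)
  }

  mk_hit <- function(idx, fam) {
    tibble::tibble(
      genome_id = genome_id,
      gene_id = features$gene_id[idx],
      family_id = fam,
      bit_score = round(stats::runif(1, 50, 500), 1),
      e_value = signif(10^-stats::runif(1, 10, 30), 3)
    )
  }
  hits <- empty_hits()
  if (anchor) hits <- dplyr::bind_rows(hits, mk_hit(anchor_idx,
                                                    params$anchor_family))
  if (partner) hits <- dplyr::bind_rows(hits, mk_hit(partner_idx,
                                                     params$partner_family))
  list(features = features, hits = hits)
}

write_collection <- function(out_dir, genome_ids, features, hits, metadata,
                             manifest, params) {
  gff_dir <- file.path(out_dir, "gff")
  dir.create(gff_dir, recursive = TRUE, showWarnings = FALSE)
  gff_paths <- character(length(genome_ids))
  for (i in seq_along(genome_ids)) {
    g <- genome_ids[i]
    f <- features[features$genome_id == g, ]
    lines <- c(
      "##gff-version 3",
      vapply(unique(f$contig_id), function(ct) {
        sprintf("##sequence-region %s 1 %d", ct, params$contig_length)
      }, character(1)),
      sprintf("%s\tprofscreen_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
              f$contig_id, f$start, f$end,
              ifelse(f$strand == "forward", "+", "-"), f$gene_id)
    )
    gff_paths[i] <- file.path(gff_dir, paste0(g, ".gff3"))
    writeLines(lines, gff_paths[i])
  }
  hits_path <- file.path(out_dir, "hits.tsv")
  readr::write_tsv(hits, hits_path)
  meta_path <- file.path(out_dir, "metadata.tsv")
  readr::write_tsv(metadata, meta_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(manifest["seed"], manifest["n_genomes"],
      list(per_genome = manifest$per_genome, counts = manifest$counts)),
    manifest_path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  list(gff_dir = gff_dir, gff = gff_paths, hits = hits_path,
       metadata = meta_path, manifest = manifest_path)
}

#' Deterministic fixture from printed counts
#'
#' Builds, without randomness, a presence/absence matrix, metadata table and
#' neighbor-pair list whose summaries equal the requested counts exactly —
#' the worked-example path for checking the summary arithmetic against
#' published counts.
#'
#' Dual-positive genomes get one anchor-partner pair each; the first
#' `n_coloc_*` pairs per domain sit 1,000 bp apart (below the 5 kb
#' threshold), the rest 10,000 bp apart.  Among the co-localized pairs the
#' first `n_tandem_*` are tandem, the remainder divergent.
#'
#' @param n_arch_both,n_bact_both Dual-positive genome counts per domain.
#' @param n_arch_anchor_only,n_bact_anchor_only Anchor-only counts.
#' @param n_negative Anchor-negative genomes (partner-negative background).
#' @param n_coloc_arch,n_coloc_bact Co-localized counts (at most the
#'   dual-positive counts).
#' @param n_tandem_arch,n_tandem_bact Tandem pairs among the co-localized
#'   ones.
#' @param anchor_family,partner_family Accessions used for the two columns.
#' @return List with `pa` (a `presence_matrix`), `metadata`, and `pairs`.
#' @export
fixture_from_counts <- function(n_arch_both, n_arch_anchor_only,
                                n_bact_both, n_bact_anchor_only,
                                n_negative = 0,
                                n_coloc_arch = 0, n_coloc_bact = 0,
                                n_tandem_arch = 0, n_tandem_bact = 0,
                                anchor_family = "PF09745",
                                partner_family = "RNL3") {
  counts <- c(n_arch_both, n_arch_anchor_only, n_bact_both,
              n_bact_anchor_only, n_negative, n_coloc_arch, n_coloc_bact,
              n_tandem_arch, n_tandem_bact)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all counts must be non-negative integers")
  }
  if (n_coloc_arch > n_arch_both || n_coloc_bact > n_bact_both) {
    stop("co-localized count cannot exceed the dual-positive count")
  }
  if (n_tandem_arch > n_coloc_arch || n_tandem_bact > n_coloc_bact) {
    stop("tandem count cannot exceed the co-localized count")
  }

  domain <- c(rep("archaea", n_arch_both + n_arch_anchor_only),
              rep("bacteria", n_bact_both + n_bact_anchor_only),
              rep(c("archaea", "bacteria"), length.out = n_negative))
  anchor <- c(rep(1L, n_arch_both + n_arch_anchor_only +
                    n_bact_both + n_bact_anchor_only),
              rep(0L, n_negative))
  partner <- c(rep(1L, n_arch_both), rep(0L, n_arch_anchor_only),
               rep(1L, n_bact_both), rep(0L, n_bact_anchor_only),
               rep(0L, n_negative))
  genome_ids <- sprintf("FX%05d", seq_along(domain))
  metadata <- simulated_metadata(genome_ids, domain == "archaea")

  m <- cbind(anchor, partner)
  colnames(m) <- normalize_family_id(c(anchor_family, partner_family))
  rownames(m) <- genome_ids
  pa <- new_presence_matrix(m[, sort(colnames(m)), drop = FALSE], metadata)

  pair_for <- function(id, coloc, tandem) {
    gap <- if (coloc) 1000L else 10000L
    a_start <- 1000L
    a_end <- 1900L
    p_start <- a_end + gap + 1L
    tibble::tibble(
      genome_id = id,
      anchor_gene_id = paste0(id, "_a"), anchor_contig = paste0(id, "_c1"),
      anchor_start = a_start, anchor_end = a_end,
      anchor_strand = if (tandem) "forward" else "reverse",
      partner_gene_id = paste0(id, "_p"), partner_contig = paste0(id, "_c1"),
      partner_start = p_start, partner_end = p_start + 899L,
      partner_strand = "forward",
      same_contig = TRUE, distance = as.numeric(gap),
      orientation = if (tandem) "tandem" else "divergent"
    )
  }
  dual_ids <- genome_ids[anchor == 1L & partner == 1L]
  dual_dom <- domain[anchor == 1L & partner == 1L]
  pairs <- empty_pairs()
  for (dom in c("archaea", "bacteria")) {
    ids <- dual_ids[dual_dom == dom]
    n_coloc <- if (dom == "archaea") n_coloc_arch else n_coloc_bact
    n_tandem <- if (dom == "archaea") n_tandem_arch else n_tandem_bact
    if (length(ids) == 0L) next
    pairs <- dplyr::bind_rows(pairs, dplyr::bind_rows(lapply(
      seq_along(ids),
      function(i) pair_for(ids[i], i <= n_coloc, i <= n_tandem)
    )))
  }
  list(pa = pa, metadata = metadata, pairs = pairs)
}
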