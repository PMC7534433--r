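#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic regulator-target world with planted, recoverable
#' structure: a sparse background of transcription factors drawing targets
#' uniformly from the gene universe (so two random TFs share almost nothing),
#' homeolog triads whose three members share a common "core" of targets sized
#' to hit a planted per-category mean shared ratio, and a designated causal
#' TF whose target set will overlap the simulated DEG sets at a planted rate.
#'
#' Defaults mirror the scale of the wheat GENIE3 validation study: a
#' 3,000-TF background, triad counts 44/530/52 for Stable/Mid 80/Dynamic
#' (one third of the 132/1,590/156 pairwise comparisons) plus 82 unlabelled
#' triads for 708 in all, planted category means 0.41/0.39/0.35, and a focal
#' regulator with 79 predicted targets.
#'
#' @param n_background_tfs number of non-triad transcription factors.
#' @param n_genes size of the target gene universe.
#' @param targets_per_tf integer range (min, max) of the per-TF target count.
#' @param triad_counts named integer vector: triads per movement category.
#' @param triad_overlap named numeric vector: planted mean pairwise shared
#'   ratio per category, in [0, 1]; names must match `triad_counts`.
#' @param genome_props length-3 probabilities for subgenomes A, B, D.
#' @param focal_targets target-set size of the designated causal TF.
#' @param families TF family labels assigned at random to background TFs and
#'   triads.
#' @param deg_q_shape Beta(shape1, shape2) parameters of the near-zero
#'   q-value component given to simulated DEGs; the background is
#'   Uniform(0, 1).
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_background_tfs = 3000,
                              n_genes = 20000,
                              targets_per_tf = c(20, 120),
                              triad_counts = c(Stable = 44, Mid80 = 530,
                                               Dynamic = 52,
                                               Unclassified = 82),
                              triad_overlap = c(Stable = 0.41, Mid80 = 0.39,
                                                Dynamic = 0.35,
                                                Unclassified = 0.40),
                              genome_props = c(A = 1, B = 1, D = 1) / 3,
                              focal_targets = 79,
                              families = c("NAC", "MYB", "WRKY", "bZIP",
                                           "C2C2_Dof", "HSF", "CCAAT_HAP3"),
                              deg_q_shape = c(0.5, 20)) {
  if (length(targets_per_tf) != 2 || targets_per_tf[1] > targets_per_tf[2] ||
      targets_per_tf[1] < 1) {
    grn_config_error("targets_per_tf must be an increasing positive range")
  }
  if (!setequal(names(triad_counts), names(triad_overlap))) {
    grn_config_error("triad_counts and triad_overlap must share names")
  }
  if (any(triad_overlap < 0 | triad_overlap > 1)) {
    grn_config_error("triad_overlap values must lie in [0, 1]")
  }
  if (any(triad_counts < 0) || n_background_tfs < 0 || n_genes < 1) {
    grn_config_error("counts must be non-negative (n_genes positive)")
  }
  if (focal_targets > n_genes) {
    grn_config_error("focal_targets cannot exceed n_genes")
  }
  structure(list(n_background_tfs = n_background_tfs, n_genes = n_genes,
                 targets_per_tf = as.integer(targets_per_tf),
                 triad_counts = triad_counts,
                 triad_overlap = triad_overlap[names(triad_counts)],
                 genome_props = genome_props / sum(genome_props),
                 focal_targets = focal_targets,
                 families = families,
                 deg_q_shape = deg_q_shape),
            class = "simulation_config")
}

#' Simulate a regulatory network with planted triad structure
#'
#' Background TFs draw their targets uniformly from the gene universe, so the
#' expected pairwise overlap between two random TFs is near zero at sparse
#' settings. Each triad's three members (assigned subgenomes A, B, D) share a
#' common core of `round(rho * t)` targets, where `t` is the triad's
#' target-set size and `rho` the category's planted overlap; the remaining
#' targets are drawn mutually disjoint, so every within-triad pairwise
#' shared ratio is exactly `round(rho * t) / t`. The first background TF
#' (`causal_tf`) receives exactly `focal_targets` targets for use as the
#' focal regulator in DEG simulations. Edge weights are Uniform(0.05, 1).
#'
#' @param config a `simulation_config`.
#' @param seed integer seed; output is fully determined by (config, seed).
#' @return List with `network` (a `regulatory_network`), `annotation`
#'   (a gene annotation table covering genes and TFs), `triads` (triad
#'   table with movement labels), `genes` (the target universe) and
#'   `causal_tf`.
#' @export
simulate_network <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  gene_genome <- sample(c("A", "B", "D"), config$n_genes, replace = TRUE,
                        prob = config$genome_props)
  lo <- config$targets_per_tf[1]; hi <- config$targets_per_tf[2]
  draw_t <- function(k) if (lo == hi) rep(lo, k) else
    sample(seq(lo, hi), k, replace = TRUE)

  regs <- list(); tgts <- list()
  # background TFs
  n_bg <- config$n_background_tfs
  bg_ids <- sprintf("TF%05d", seq_len(n_bg))
  if (n_bg > 0) {
    t_bg <- draw_t(n_bg)
    t_bg[1] <- config$focal_targets
    for (i in seq_len(n_bg)) {
      regs[[length(regs) + 1L]] <- rep(bg_ids[i], t_bg[i])
      tgts[[length(tgts) + 1L]] <- sample(genes, t_bg[i])
    }
  }
  bg_genome <- sample(c("A", "B", "D"), max(n_bg, 1), replace = TRUE,
                      prob = config$genome_props)[seq_len(n_bg)]
  bg_family <- sample(config$families, max(n_bg, 1),
                      replace = TRUE)[seq_len(n_bg)]

  # triads: shared core + mutually disjoint fill
  cats <- rep(names(config$triad_counts), config$triad_counts)
  n_tri <- length(cats)
  tri_rows <- vector("list", n_tri)
  tri_member <- character(0); tri_triad <- character(0)
  tri_family <- sample(config$families, max(n_tri, 1),
                       replace = TRUE)[seq_len(n_tri)]
  if (n_tri > 0) {
    t_tri <- draw_t(n_tri)
    for (i in seq_len(n_tri)) {
      t <- t_tri[i]
      core_n <- round(config$triad_overlap[[cats[i]]] * t)
      if (core_n > t) grn_config_error("core size exceeds target count")
      need <- core_n + 3L * (t - core_n)
      if (need > config$n_genes) {
        grn_config_error("n_genes too small for disjoint triad fills")
      }
      pool <- sample(genes, need)
      core <- pool[seq_len(core_n)]
      rest <- if (core_n > 0) pool[-seq_len(core_n)] else pool
      fills <- split(rest, rep(1:3, each = t - core_n)[seq_along(rest)])
      ids <- sprintf("TR%04d%s", i, c("A", "B", "D"))
      for (m in 1:3) {
        fill <- if (t > core_n) fills[[as.character(m)]] else character(0)
        regs[[length(regs) + 1L]] <- rep(ids[m], t)
        tgts[[length(tgts) + 1L]] <- c(core, fill)
      }
      tri_rows[[i]] <- data.frame(
        triad_id = sprintf("triad%04d", i),
        gene_a = ids[1], gene_b = ids[2], gene_d = ids[3],
        syntenic = TRUE, movement = cats[i], stringsAsFactors = FALSE)
      tri_member <- c(tri_member, ids)
      tri_triad <- c(tri_triad, rep(sprintf("triad%04d", i), 3))
    }
  }
  regulator <- unlist(regs, use.names = FALSE)
  target <- unlist(tgts, use.names = FALSE)
  net <- regulatory_network(data.frame(
    regulator = regulator, target = target,
    weight = stats::runif(length(regulator), 0.05, 1),
    stringsAsFactors = FALSE))

  tf_ids <- c(bg_ids, tri_member)
  annotation <- gene_annotation(data.frame(
    gene_id = c(genes, tf_ids),
    is_tf = c(rep(FALSE, length(genes)), rep(TRUE, length(tf_ids))),
    family = c(rep(NA_character_, length(genes)), bg_family,
               rep(tri_family, each = 3)[seq_along(tri_member)]),
    genome = c(gene_genome, bg_genome,
               rep(c("A", "B", "D"), length.out = length(tri_member))),
    triad_id = c(rep(NA_character_, length(genes) + n_bg), tri_triad),
    stringsAsFactors = FALSE))
  triads <- if (n_tri > 0) {
    triad_table(do.call(rbind, tri_rows))
  } else {
    triad_table(data.frame(triad_id = character(0), gene_a = character(0),
                           gene_b = character(0), gene_d = character(0),
                           syntenic = logical(0), movement = character(0),
                           stringsAsFactors = FALSE))
  }
  list(network = net, annotation = annotation, triads = triads,
       genes = genes, causal_tf = if (n_bg > 0) bg_ids[1] else NA_character_)
}

#' Simulate a differential-expression table with a planted causal overlap
#'
#' Builds one DEG set per timepoint: `round(r * |targets(causal_tf)|)` genes
#' drawn from the causal regulator's targets (the planted shared genes) plus
#' random non-target fill up to `n_deg`. DEG members receive q-values from
#' the near-zero Beta component, all other universe genes from Uniform(0, 1),
#' reproducing the DEG-enriched peak near q = 0 over a flat background.
#' Thresholding at q < 0.05 recovers the planted overlap up to the leakage
#' the q-model introduces.
#'
#' @param network a `regulatory_network`.
#' @param causal_tf regulator whose targets seed the DEG sets.
#' @param r planted overlap fraction(s), one per timepoint (recycled).
#' @param n_deg DEG-set size(s), one per timepoint (recycled).
#' @param universe gene universe of the simulated experiment.
#' @param timepoints character vector of timepoint labels.
#' @param seed integer seed.
#' @param q_shape Beta(shape1, shape2) parameters of the DEG q component.
#' @return A validated DEG table covering every universe gene at every
#'   timepoint, with attribute `planted` (per-timepoint list: `deg_set`,
#'   `planted_shared`, `r`, `n_deg`).
#' @export
simulate_deg_table <- function(network, causal_tf, r, n_deg, universe,
                               timepoints = "12DAA", seed,
                               q_shape = c(0.5, 20)) {
  targets <- suppressWarnings(targets_of(network, causal_tf))
  if (!length(targets)) {
    grn_config_error("causal TF '%s' has no targets", causal_tf)
  }
  r <- rep_len(r, length(timepoints))
  n_deg <- rep_len(n_deg, length(timepoints))
  set.seed(seed)
  non_targets <- setdiff(universe, targets)
  planted <- list()
  rows <- lapply(seq_along(timepoints), function(i) {
    k <- round(r[i] * length(targets))
    if (k > n_deg[i]) {
      grn_config_error("planted overlap (%d) exceeds n_deg (%d)", k, n_deg[i])
    }
    if (n_deg[i] - k > length(non_targets)) {
      grn_config_error("universe too small for %d non-target DEGs",
                       n_deg[i] - k)
    }
    planted_shared <- sample(targets, k)
    deg_set <- c(planted_shared, sample(non_targets, n_deg[i] - k))
    q <- stats::runif(length(universe))
    is_deg <- universe %in% deg_set
    q[is_deg] <- stats::rbeta(sum(is_deg), q_shape[1], q_shape[2])
    planted[[timepoints[i]]] <<- list(deg_set = deg_set,
                                      planted_shared = planted_shared,
                                      r = r[i], n_deg = n_deg[i])
    data.frame(gene_id = universe, q_value = q, timepoint = timepoints[i],
               stringsAsFactors = FALSE)
  })
  out <- deg_table(do.call(rbind, rows))
  attr(out, "planted") <- planted
  out
}

#' Simulate a TPM expression matrix with planted senescence upregulation
#'
#' Each gene gets a log-normal baseline TPM; senescent samples of genes in
#' `upregulated` are scaled by `fold`, and multiplicative log-normal noise of
#' standard deviation `noise_sd` (on the log scale) is applied throughout.
#' With `noise_sd = 0` the planted fold is recovered exactly by
#' [senescence_fold_change()] at `eps = 0`.
#'
#' @param genes gene ids (rows).
#' @param samples data.frame `sample_id`, `tissue`, `senescent`.
#' @param upregulated gene ids planted as senescence-upregulated.
#' @param fold planted fold change (> 0).
#' @param noise_sd log-scale noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @return An `expression_matrix`.
#' @export
simulate_expression <- function(genes, samples, upregulated = character(0),
                                fold = 2, noise_sd = 0.1, seed,
                                baseline_meanlog = log(10),
                                baseline_sdlog = 1) {
  if (fold <= 0) grn_config_error("`fold` must be positive")
  if (noise_sd < 0) grn_config_error("`noise_sd` must be non-negative")
  set.seed(seed)
  n_g <- length(genes); n_s <- nrow(samples)
  baseline <- stats::rlnorm(n_g, baseline_meanlog, baseline_sdlog)
  tpm <- matrix(baseline, nrow = n_g, ncol = n_s,
                dimnames = list(genes, samples$sample_id))
  up <- genes %in% upregulated
  tpm[up, samples$senescent] <- tpm[up, samples$senescent] * fold
  if (noise_sd > 0) {
    tpm <- tpm * exp(matrix(stats::rnorm(n_g * n_s, 0, noise_sd), n_g, n_s))
  }
  expression_matrix(tpm, samples)
}

#' Simulate the full input bundle
#'
#' Convenience wrapper chaining [simulate_network()], [simulate_deg_table()]
#' and [simulate_expression()] into one reproducible bundle mirroring the
#' study design: DEG sets at 12 and 22 days after anthesis whose overlap with
#' the causal TF's targets is planted at the focal geometry (12/79 and 4/79),
#' and a small expression matrix with senescing flag-leaf samples in which
#' the causal TF's planted shared genes are upregulated.
#'
#' @param config a `simulation_config`.
#' @param seed integer seed for the whole bundle.
#' @param r,n_deg,timepoints passed to [simulate_deg_table()].
#' @return List: `network`, `annotation`, `triads`, `genes`, `causal_tf`,
#'   `degs` (DEG table with `planted` attribute), `expression`.
#' @export
simulate_bundle <- function(config = simulation_config(), seed,
                            r = c(12, 4) / 79, n_deg = c(866, 130),
                            timepoints = c("12DAA", "22DAA")) {
  world <- simulate_network(config, seed = seed)
  degs <- simulate_deg_table(world$network, world$causal_tf, r = r,
                             n_deg = n_deg, universe = world$genes,
                             timepoints = timepoints, seed = seed + 1L,
                             q_shape = config$deg_q_shape)
  samples <- data.frame(
    sample_id = sprintf("S%02d", 1:12),
    tissue = rep(c("flag_leaf_senescing", "flag_leaf_green", "root",
                   "spike"), each = 3),
    senescent = rep(c(TRUE, FALSE, FALSE, FALSE), each = 3),
    stringsAsFactors = FALSE)
  up <- attr(degs, "planted")[[1]]$planted_shared
  tf_ids <- network_regulators(world$network)
  expr_genes <- Reduce(union, list(
    world$genes[seq_len(min(500, length(world$genes)))], up, tf_ids))
  expr <- simulate_expression(expr_genes, samples,
                              upregulated = up, fold = 2.5, noise_sd = 0.1,
                              seed = seed + 2L)
  c(world, list(degs = degs, expression = expr))
}

#' Write a simulated bundle to disk in the canonical dialects
#'
#' Writes the edge list, annotation, triad table, movement-category gene
#' lists, DEG table, expression matrix and sample metadata in the formats the
#' readers in this package consume, plus a plain-text ground-truth manifest
#' of the planted parameters.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(network = file.path(dir, "network.tsv"),
         annotation = file.path(dir, "annotation.tsv"),
         triads = file.path(dir, "triads.tsv"),
         degs = file.path(dir, "degs.tsv"),
         expression = file.path(dir, "expression.tsv"),
         samples = file.path(dir, "samples.tsv"),
         manifest = file.path(dir, "manifest.txt"))
  write_edge_list(bundle$network, p[["network"]])
  utils::write.table(bundle$annotation, p[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$triads[c("triad_id", "gene_a", "gene_b", "gene_d",
                                     "syntenic")],
                     p[["triads"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (cat in setdiff(unique(bundle$triads$movement), "Unclassified")) {
    rows <- bundle$triads$movement == cat
    f <- file.path(dir, sprintf("movement_%s.txt", cat))
    writeLines(c(bundle$triads$gene_a[rows], bundle$triads$gene_b[rows],
                 bundle$triads$gene_d[rows]), f)
    p[paste0("movement_", cat)] <- f
  }
  utils::write.table(
    data.frame(gene_id = bundle$degs$gene_id,
               q_value = sprintf("%.17g", bundle$degs$q_value),
               timepoint = bundle$degs$timepoint),
    p[["degs"]], sep = "\t", quote = FALSE, row.names = FALSE)
  expr_out <- data.frame(gene_id = rownames(bundle$expression$tpm),
                         bundle$expression$tpm, check.names = FALSE)
  utils::write.table(expr_out, p[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$expression$samples, p[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  planted <- attr(bundle$degs, "planted")
  manifest <- c(sprintf("causal_tf\t%s", bundle$causal_tf),
                unlist(lapply(names(planted), function(tp) {
                  sprintf("%s\t%s", paste0(tp, c("_r", "_n_deg")),
                          c(planted[[tp]]$r, planted[[tp]]$n_deg))
                })))
  writeLines(manifest, p[["manifest"]])
  invisible(p)
}
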