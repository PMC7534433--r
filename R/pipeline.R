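# Derived stage seeds: one run seed determines every stochastic draw, each
# sampling stage consuming a fixed documented offset so stages stay
# reproducible independently of which optional sections run.
stage_seed <- function(seed, offset) (seed + offset) %% .Machine$integer.max

#' Validate a focal regulator's predicted targets against DEG sets
#'
#' The core validation analysis: per timepoint, the focal regulator's shared
#' ratio against the DEG set, a resampling null of the same ratio over
#' randomly drawn regulators, and an exact sign test of whether the focal
#' ratio exceeds the null. One-sided ("greater") by default, matching the
#' directional question "does the focal TF overlap the DEGs more than a
#' random TF would?".
#'
#' @param network a `regulatory_network`.
#' @param degs DEG table (see [deg_table()]).
#' @param focal_tf focal regulator id.
#' @param annotation,genomes optional genome-of-origin filter applied to all
#'   target sets (e.g. `genomes = c("A", "B")` for tetraploid evidence).
#' @param timepoints timepoints to analyse; default all in `degs`.
#' @param q_threshold DEG threshold (strict), default 0.05.
#' @param n_null null-sample count per timepoint, default 1000.
#' @param seed run seed; timepoint `i` draws its null with seed `seed + i`.
#' @param alternative sign-test sidedness, default `"greater"`.
#' @param exclude_focal hold the focal TF out of its own null frame?
#'   Default `FALSE`.
#' @param replace sample the null frame with replacement? Default `FALSE`.
#' @return List of class `deg_validation`: per-timepoint results (`focal`
#'   record, `null_summary`, `p`, `n_deg`) plus the run parameters.
#' @export
run_deg_validation <- function(network, degs, focal_tf, annotation = NULL,
                               genomes = NULL, timepoints = NULL,
                               q_threshold = 0.05, n_null = 1000, seed,
                               alternative = "greater",
                               exclude_focal = FALSE, replace = FALSE) {
  timepoints <- timepoints %||% unique(degs$timepoint)
  focal_targets <- targets_of(network, focal_tf, genomes, annotation)
  if (!length(focal_targets)) {
    grn_config_error("focal regulator '%s' has an empty target set", focal_tf)
  }
  results <- lapply(seq_along(timepoints), function(i) {
    tp <- timepoints[i]
    deg_set <- filter_degs(degs, tp, q_threshold)
    focal <- shared_ratio(focal_targets, deg_set, id_a = focal_tf,
                          id_b = paste0("DEG_", tp))
    null <- null_ratio_distribution(
      network, deg_set, n_samples = n_null, seed = stage_seed(seed, i),
      exclude = if (exclude_focal) focal_tf else NULL,
      genomes = genomes, annotation = annotation, replace = replace)
    p <- sign_test_exceeds(focal$ratio, null$records$ratio, alternative)
    list(timepoint = tp, focal = focal, null_summary = null$summary,
         p = p, n_deg = length(deg_set))
  })
  names(results) <- timepoints
  structure(list(results = results,
                 params = list(focal_tf = focal_tf, genomes = genomes,
                               q_threshold = q_threshold, n_null = n_null,
                               seed = seed, alternative = alternative,
                               exclude_focal = exclude_focal,
                               replace = replace)),
            class = "deg_validation")
}

#' @export
print.deg_validation <- function(x, ...) {
  cat(sprintf("DEG validation of %s (sign test, %s)\n",
              x$params$focal_tf, x$params$alternative))
  for (res in x$results) {
    cat(sprintf(
      "  %s: %d/%d targets shared with %d DEGs (ratio %.3f, %.1f%%), p %s\n",
      res$timepoint, res$focal$intersection,
      min(res$focal$size_a, res$focal$size_b), res$n_deg, res$focal$ratio,
      100 * res$focal$ratio, format.pval(res$p, digits = 3, eps = 1e-300)))
    cat(sprintf("    null (n=%d): median %.3f, mean %.3f, max %.3f\n",
                res$null_summary$n, res$null_summary$median,
                res$null_summary$mean, res$null_summary$maximum))
  }
  invisible(x)
}

#' Run the full analysis suite
#'
#' Chains the package's analyses on one input bundle: the summary table of
#' shared-ratio distributions (all-TF random pairs, per-family pairs with the
#' unique-pair cap, homeolog pairwise comparisons, and per-movement-category
#' blocks), the movement-category rank-sum tests, the genome-of-origin KS
#' tests, the candidate-regulator scan, and the focal-TF DEG validation.
#' Sections whose inputs are absent are skipped with a warning.
#'
#' @param network a `regulatory_network`.
#' @param annotation gene annotation table.
#' @param degs optional DEG table (enables validation + candidate sections).
#' @param triads optional triad table (enables homeolog sections).
#' @param expression optional `expression_matrix` (adds senescence
#'   fold-change columns to the candidate table).
#' @param focal_tf optional focal regulator id.
#' @param genomes optional genome filter for the DEG-facing analyses (never
#'   applied to triad analyses, which need all three subgenomes).
#' @param q_threshold,n_null,alternative as in [run_deg_validation()].
#' @param n_pairs random-pair draws for the distribution table, default 1000
#'   (small families are capped at N(N-1)).
#' @param seed run seed governing every stochastic stage.
#' @return List of class `grn_suite` with elements `distribution_table`,
#'   `movement` (a `movement_comparison`), `genome_tests`, `candidates` (a
#'   `candidate_scan`), `validation` (a `deg_validation`), `params`; absent
#'   sections are `NULL`.
#' @export
run_full_suite <- function(network, annotation, degs = NULL, triads = NULL,
                           expression = NULL, focal_tf = NULL,
                           genomes = NULL, q_threshold = 0.05, n_null = 1000,
                           n_pairs = 1000, alternative = "greater", seed) {
  frame <- network_regulators(network, annotation)
  rows <- list()
  add_row <- function(label, summ) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(group = label, stringsAsFactors = FALSE),
      as.data.frame(summ))
  }

  # all-TF random pairs
  all_pairs <- sample_tf_pairs(frame, n_pairs, seed = stage_seed(seed, 100))
  add_row("All TFs", pairwise_ratio_distribution(network, all_pairs)$summary)

  # per-family pairs, capped at N(N-1) unique pairs
  fams <- annotation$family[match(frame, annotation$gene_id)]
  for (fam in sort(unique(stats::na.omit(fams)))) {
    members <- frame[!is.na(fams) & fams == fam]
    if (length(members) < 2) next
    fp <- sample_tf_pairs(members, n_pairs,
                          seed = stage_seed(seed, 200 + length(rows)))
    add_row(fam, pairwise_ratio_distribution(network, fp)$summary)
  }

  movement <- NULL; genome_tests <- NULL
  if (!is.null(triads) && nrow(triads)) {
    tri_rec <- triad_pairwise_ratios(network, triads)
    add_row("Homeologs", summarize_distribution(tri_rec$ratio))
    movement <- tryCatch(compare_movement_categories(tri_rec),
                         grn_error = function(e) {
                           warning(conditionMessage(e), call. = FALSE)
                           NULL
                         })
    if (!is.null(movement)) {
      for (i in seq_len(nrow(movement$summaries))) {
        add_row(movement$summaries$category[i], movement$summaries[i, -1])
      }
    }
    props <- suppressWarnings(target_genome_proportions(network, annotation))
    tri_of <- stats::setNames(
      rep(triads$movement, 3),
      c(triads$gene_a, triads$gene_b, triads$gene_d))
    props$movement <- unname(tri_of[props$tf_id])
    genome_tests <- genome_origin_association(props)
  } else {
    warning("no triad table: homeolog sections skipped", call. = FALSE)
  }

  candidates <- NULL; validation <- NULL
  if (!is.null(degs) && !is.null(focal_tf)) {
    validation <- run_deg_validation(
      network, degs, focal_tf, annotation = annotation, genomes = genomes,
      q_threshold = q_threshold, n_null = n_null, seed = seed,
      alternative = alternative)
    deg_sets <- lapply(stats::setNames(nm = unique(degs$timepoint)),
                       function(tp) filter_degs(degs, tp, q_threshold))
    candidates <- scan_candidate_regulators(network, deg_sets, focal_tf,
                                            genomes = genomes,
                                            annotation = annotation)
    if (!is.null(expression) && nrow(candidates$candidates)) {
      fc <- senescence_fold_change(expression, candidates$candidates$tf_id)
      candidates$candidates <- cbind(candidates$candidates, fc[-1])
    }
  } else {
    warning("no DEG table or focal TF: validation/candidate sections skipped",
            call. = FALSE)
  }

  distribution_table <- do.call(rbind, rows)
  rownames(distribution_table) <- NULL
  structure(list(distribution_table = distribution_table,
                 movement = movement, genome_tests = genome_tests,
                 candidates = candidates, validation = validation,
                 params = list(seed = seed, genomes = genomes,
                               q_threshold = q_threshold, n_null = n_null,
                               n_pairs = n_pairs, focal_tf = focal_tf,
                               alternative = alternative)),
            class = "grn_suite")
}

#' @export
print.grn_suite <- function(x, ...) {
  cat("shared-ratio distribution table\n")
  print(x$distribution_table, row.names = FALSE, digits = 3)
  if (!is.null(x$movement)) {
    cat("\nmovement-category rank-sum tests\n")
    print(x$movement$tests, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$genome_tests)) {
    cat(sprintf("\ngenome-of-origin KS tests: %d tests, min adjusted p %.3g\n",
                nrow(x$genome_tests), min(x$genome_tests$p_adjusted)))
  }
  if (!is.null(x$validation)) {
    cat("\n"); print(x$validation)
  }
  if (!is.null(x$candidates)) {
    cat("\n"); print(x$candidates)
  }
  invisible(x)
}

# Deterministic TSV writer with '#'-prefixed provenance header (no
# timestamps, so identical runs produce byte-identical files).
write_tsv_with_header <- function(tab, path, params) {
  hdr <- c(sprintf("# grnoverlap %s",
                   as.character(utils::packageVersion("grnoverlap"))),
           sprintf("# %s=%s", names(params),
                   vapply(params, function(v) {
                     paste(format(v, digits = 15), collapse = ",")
                   }, character(1))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full-suite report bundle as TSV files
#'
#' One TSV per section, each with a `#`-prefixed provenance header recording
#' the package version and the run parameters (including the seed). Output is
#' deterministic: re-running the same configuration and seed reproduces the
#' files byte for byte.
#'
#' @param suite a `grn_suite` from [run_full_suite()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- Filter(Negate(is.null), suite$params)
  paths <- character(0)
  w <- function(tab, name) {
    f <- file.path(dir, name)
    write_tsv_with_header(tab, f, params)
    paths[name] <<- f
  }
  w(suite$distribution_table, "distribution_table.tsv")
  if (!is.null(suite$movement)) {
    w(suite$movement$tests, "movement_tests.tsv")
  }
  if (!is.null(suite$genome_tests)) w(suite$genome_tests, "genome_tests.tsv")
  if (!is.null(suite$candidates)) {
    w(suite$candidates$candidates, "candidates.tsv")
  }
  if (!is.null(suite$validation)) {
    v <- do.call(rbind, lapply(suite$validation$results, function(res) {
      data.frame(timepoint = res$timepoint, n_targets = res$focal$size_a,
                 n_deg = res$n_deg, intersection = res$focal$intersection,
                 ratio = res$focal$ratio,
                 null_median = res$null_summary$median,
                 null_mean = res$null_summary$mean, p = res$p,
                 stringsAsFactors = FALSE)
    }))
    w(v, "deg_validation.tsv")
  }
  invisible(paths)
}
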