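#' Differentially expressed genes at a timepoint
#'
#' Genes whose FDR-adjusted q-value at `timepoint` is strictly below
#' `q_threshold` (the convention "q < 0.05").
#'
#' @param table a DEG table (see [deg_table()]).
#' @param timepoint timepoint label present in the table.
#' @param q_threshold threshold in (0, 1]; default 0.05.
#' @return Character vector of gene ids.
#' @export
filter_degs <- function(table, timepoint, q_threshold = 0.05) {
  if (length(q_threshold) != 1L || q_threshold <= 0 || q_threshold > 1) {
    grn_config_error("`q_threshold` must lie in (0, 1]")
  }
  rows <- table$timepoint == timepoint
  if (!any(rows)) {
    grn_config_error("timepoint '%s' not present in the DEG table (has: %s)",
                     timepoint,
                     paste(unique(table$timepoint), collapse = ", "))
  }
  table$gene_id[rows & table$q_value < q_threshold]
}

#' Quartile positions of a gene subset in the q-ranked DEG list
#'
#' Ranks the DEGs at a timepoint by ascending q-value (ties broken by gene id
#' for determinism), splits the ranked list into four equal-size bins (any
#' remainder going to the earlier bins) and counts where the members of
#' `subset` fall. Used to ask whether genes shared with an external list
#' concentrate among the most significant DEGs.
#'
#' @param table a DEG table.
#' @param timepoint timepoint label.
#' @param subset character vector of gene ids, all of which must be DEGs at
#'   the timepoint under `q_threshold`.
#' @param q_threshold DEG threshold, default 0.05.
#' @return List with `counts` (length-4 integer, top quartile first),
#'   `fractions`, and `n_deg`.
#' @export
ranked_quartile_positions <- function(table, timepoint, subset,
                                      q_threshold = 0.05) {
  degs_rows <- table[table$timepoint == timepoint &
                       table$q_value < q_threshold, , drop = FALSE]
  if (!nrow(degs_rows)) grn_empty_analysis_error("no DEG at this timepoint")
  ord <- order(degs_rows$q_value, degs_rows$gene_id)
  ranked <- degs_rows$gene_id[ord]
  subset <- unique(as.character(subset))
  missing_genes <- setdiff(subset, ranked)
  if (length(missing_genes)) {
    grn_config_error("subset member(s) not in the DEG list: %s",
                     paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  n <- length(ranked)
  base <- n %/% 4L
  rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= rem)
  bin <- rep.int(1:4, sizes)
  pos <- match(subset, ranked)
  counts <- tabulate(bin[pos], nbins = 4L)
  list(counts = counts,
       fractions = if (length(subset)) counts / length(subset) else rep(0, 4),
       n_deg = n)
}

#' Shared-target count between two regulators
#'
#' The number of predicted targets two regulators have in common, after an
#' optional genome-of-origin filter.
#'
#' @param network a `regulatory_network`.
#' @param tf_id,focal_tf regulator ids.
#' @param genomes,annotation optional genome filter, as in [targets_of()].
#' @return Non-negative integer; 0 with a warning when either regulator is
#'   absent from the network.
#' @export
shared_with_focal <- function(network, tf_id, focal_tf, genomes = NULL,
                              annotation = NULL) {
  t1 <- suppressWarnings(targets_of(network, tf_id, genomes, annotation))
  t2 <- suppressWarnings(targets_of(network, focal_tf, genomes, annotation))
  if (!length(t1) || !length(t2)) {
    warning("a regulator has no (filtered) target; shared count is 0",
            call. = FALSE)
    return(0L)
  }
  sum(t1 %in% t2)
}

#' Scan for regulators that out-share the focal regulator
#'
#' For every regulator in the network, computes the shared ratio of its
#' (optionally genome-filtered) target set against the DEG set of each
#' timepoint, and returns the regulators whose ratio strictly exceeds the
#' focal regulator's at one or more timepoints — the candidate-regulator set.
#' Each candidate is annotated with the timepoints at which it exceeds and
#' its shared-target count with the focal regulator. No multiple-testing
#' correction is applied: candidates are annotated, not re-tested.
#'
#' @param network a `regulatory_network`.
#' @param deg_sets named list of gene-id vectors, one per timepoint.
#' @param focal_tf the focal regulator id; must have a non-empty (filtered)
#'   target set.
#' @param genomes,annotation optional genome filter.
#' @return List of class `candidate_scan`: `candidates` (data.frame `tf_id`,
#'   `family` if annotation given, one `ratio_<tp>` and `exceeds_<tp>` column
#'   pair per timepoint, `shared_with_focal`), `focal_ratios` (named numeric),
#'   `n_tfs` (frame size), `n_candidates`, `pct_candidates` (percentage of
#'   the frame).
#' @export
scan_candidate_regulators <- function(network, deg_sets, focal_tf,
                                      genomes = NULL, annotation = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  if (is.null(names(deg_sets)) || any(names(deg_sets) == "")) {
    grn_config_error("`deg_sets` must be a named list (names = timepoints)")
  }
  idx <- target_set_index(network, genomes, annotation)
  focal_targets <- idx[[focal_tf]] %||% character(0)
  if (!length(focal_targets)) {
    grn_config_error("focal regulator '%s' has no (filtered) target set",
                     focal_tf)
  }
  tps <- names(deg_sets)
  frame <- sort(names(idx)[lengths(idx) > 0L])
  focal_ratios <- vapply(tps, function(tp) {
    shared_ratio(focal_targets, deg_sets[[tp]])$ratio
  }, numeric(1))
  ratio_mat <- vapply(tps, function(tp) {
    ref <- unique(as.character(deg_sets[[tp]]))
    vapply(frame, function(tf) {
      tg <- idx[[tf]]
      sum(tg %in% ref) / min(length(tg), length(ref))
    }, numeric(1))
  }, numeric(length(frame)))
  ratio_mat <- matrix(ratio_mat, nrow = length(frame),
                      dimnames = list(frame, tps))
  exceeds <- sweep(ratio_mat, 2, focal_ratios[tps], `>`)
  hit <- rownames(exceeds)[rowSums(exceeds) > 0L]
  cand <- data.frame(tf_id = hit, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    cand$family <- annotation$family[match(hit, annotation$gene_id)]
  }
  for (tp in tps) {
    cand[[paste0("ratio_", tp)]] <- ratio_mat[hit, tp]
    cand[[paste0("exceeds_", tp)]] <- exceeds[hit, tp]
  }
  cand$shared_with_focal <- vapply(hit, function(tf) {
    sum(idx[[tf]] %in% focal_targets)
  }, numeric(1))
  rownames(cand) <- NULL
  structure(list(candidates = cand, focal_ratios = focal_ratios,
                 n_tfs = length(frame), n_candidates = nrow(cand),
                 pct_candidates = 100 * nrow(cand) / length(frame)),
            class = "candidate_scan")
}

#' Senescence fold change from an expression matrix
#'
#' Fold change in mean expression between senescent and non-senescent samples
#' for each requested gene: `(mean TPM senescent + eps) / (mean TPM
#' non-senescent + eps)` with pseudocount `eps` (default 0.01 TPM). When
#' `average_tissues = TRUE`, samples are first averaged within
#' (tissue, senescent) groups so that unevenly replicated tissues weigh
#' equally. A gene is `upregulated` when fold > 1 and `twofold` when
#' fold > 2 (strict); genes absent from the matrix get `NA` fold and flags.
#'
#' @param expr an `expression_matrix`.
#' @param gene_ids genes to evaluate.
#' @param eps pseudocount in TPM.
#' @param average_tissues average replicates within tissue before the group
#'   means? Default `TRUE`.
#' @return data.frame `gene_id`, `fold_change`, `upregulated`, `twofold`.
#' @export
senescence_fold_change <- function(expr, gene_ids, eps = 0.01,
                                   average_tissues = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  sen <- expr$samples$senescent
  if (!any(sen) || all(sen)) {
    grn_config_error("need at least one senescent and one non-senescent sample")
  }
  vals <- expr$tpm
  if (average_tissues) {
    grp <- paste(expr$samples$tissue, sen, sep = "\r")
    cols <- split(seq_along(grp), grp)
    means <- vapply(cols, function(ix) {
      rowMeans(vals[, ix, drop = FALSE])
    }, numeric(nrow(vals)))
    means <- matrix(means, nrow = nrow(vals),
                    dimnames = list(rownames(vals), names(cols)))
    sen <- vapply(strsplit(names(cols), "\r"),
                  function(x) x[2] == "TRUE", logical(1))
    vals <- means
  }
  out <- do.call(rbind, lapply(gene_ids, function(g) {
    if (!g %in% rownames(vals)) {
      return(data.frame(gene_id = g, fold_change = NA_real_,
                        upregulated = NA, twofold = NA,
                        stringsAsFactors = FALSE))
    }
    fc <- (mean(vals[g, sen]) + eps) / (mean(vals[g, !sen]) + eps)
    data.frame(gene_id = g, fold_change = fc, upregulated = fc > 1,
               twofold = fc > 2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.candidate_scan <- function(x, ...) {
  cat(sprintf(
    "candidate regulators: %d of %d TFs (%.1f%%) exceed the focal ratio\n",
    x$n_candidates, x$n_tfs, x$pct_candidates))
  cat("focal shared ratios:",
      paste(sprintf("%s = %.3f", names(x$focal_ratios), x$focal_ratios),
            collapse = ", "), "\n")
  if (x$n_candidates) print(utils::head(x$candidates, 20), row.names = FALSE)
  invisible(x)
}
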