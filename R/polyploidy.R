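#' Pairwise shared ratios within homeolog triads
#'
#' For each syntenic 1:1:1 triad (one gene copy per subgenome A, B, D) whose
#' three members all have predicted targets in the network, computes the
#' shared ratio for the three pairwise comparisons A-B, A-D and B-D. Triads
#' with any member lacking targets are dropped with a count. No
#' genome-of-origin filter is applied here: all three subgenomes are needed.
#'
#' @param network a `regulatory_network`.
#' @param triads triad table (see [read_triads()] / [triad_table()]).
#' @param syntenic_only restrict to syntenic triads (default `TRUE`).
#' @return data.frame of class `triad_ratio_record`: `triad_id`, `pair` (one
#'   of "A-B", "A-D", "B-D"), `movement`, plus the shared-ratio columns.
#'   Exactly 3 rows per retained triad; `attr(, "n_dropped")` counts dropped
#'   triads.
#' @export
triad_pairwise_ratios <- function(network, triads, syntenic_only = TRUE) {
  stopifnot(inherits(network, "regulatory_network"))
  if (syntenic_only) triads <- triads[triads$syntenic, , drop = FALSE]
  idx <- target_set_index(network)
  sz <- function(g) length(idx[[g]] %||% character(0))
  ok <- vapply(triads$gene_a, sz, integer(1)) > 0L &
    vapply(triads$gene_b, sz, integer(1)) > 0L &
    vapply(triads$gene_d, sz, integer(1)) > 0L
  n_dropped <- sum(!ok)
  triads <- triads[ok, , drop = FALSE]
  if (!nrow(triads)) {
    grn_empty_analysis_error("no triad with three non-empty target sets")
  }
  pair_defs <- list(`A-B` = c("gene_a", "gene_b"),
                    `A-D` = c("gene_a", "gene_d"),
                    `B-D` = c("gene_b", "gene_d"))
  out <- do.call(rbind, lapply(names(pair_defs), function(p) {
    g1 <- triads[[pair_defs[[p]][1]]]
    g2 <- triads[[pair_defs[[p]][2]]]
    cbind(data.frame(triad_id = triads$triad_id, pair = p,
                     movement = triads$movement, stringsAsFactors = FALSE),
          as.data.frame(ratio_records(g1, g2, idx[g1], idx[g2])))
  }))
  # one A-B, A-D, B-D block per triad, in triad order
  out <- out[order(match(out$triad_id, triads$triad_id),
                   match(out$pair, names(pair_defs))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triad_ratio_record", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Compare homeolog overlap across expression-movement categories
#'
#' Rank-sum (Wilcoxon / Mann-Whitney) comparisons of the homeolog pairwise
#' shared ratios between movement categories (Stable vs Dynamic, Stable vs
#' Mid 80, Mid 80 vs Dynamic, for the conventional labels), plus a
#' six-number summary per category. `Unclassified` triads are excluded from
#' the tests. Two-sided by default.
#'
#' @param records `triad_ratio_record` from [triad_pairwise_ratios()].
#' @param alternative passed to [stats::wilcox.test()]; `"two.sided"`
#'   (default), `"less"` or `"greater"` (group1 vs group2).
#' @return List of class `movement_comparison`: `tests` (group1, group2, n1,
#'   n2, statistic, p) and `summaries` (category, six-number columns).
#' @export
compare_movement_categories <- function(records,
                                        alternative = "two.sided") {
  records <- records[records$movement != "Unclassified", , drop = FALSE]
  cats <- unique(records$movement)
  if (length(cats) < 2) {
    grn_config_error("need at least two movement categories with records")
  }
  # stable presentation order when the conventional labels are used
  pref <- c("Stable", "Mid80", "Dynamic")
  cats <- c(intersect(pref, cats), sort(setdiff(cats, pref)))
  ratios <- split(records$ratio, records$movement)
  summaries <- do.call(rbind, lapply(cats, function(cc) {
    cbind(data.frame(category = cc, stringsAsFactors = FALSE),
          as.data.frame(summarize_distribution(ratios[[cc]])))
  }))
  combos <- utils::combn(cats, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    x <- ratios[[g1]]; y <- ratios[[g2]]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("category %s vs %s skipped: fewer than 2 records",
                      g1, g2), call. = FALSE)
      return(NULL)
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative))
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(tests = tests, summaries = summaries),
            class = "movement_comparison")
}

#' Genome-of-origin composition of each regulator's target set
#'
#' For every regulator with at least one target of known subgenome, the
#' proportion of its targets annotated to the A, B and D subgenomes (targets
#' of unknown genome are excluded from the denominator). Used to ask whether
#' a transcription factor preferentially targets genes on its own subgenome.
#'
#' @param network a `regulatory_network`.
#' @param annotation annotation table giving each gene's `genome`; the
#'   regulator's own genome is read from the same table.
#' @return data.frame of class `genome_proportion_record`: `tf_id`,
#'   `tf_genome`, `prop_a`, `prop_b`, `prop_d`, `n_targets` (annotated
#'   targets only). TFs with no annotated target are dropped with a warning
#'   count.
#' @export
target_genome_proportions <- function(network, annotation) {
  stopifnot(inherits(network, "regulatory_network"))
  idx <- target_set_index(network)
  gmap <- stats::setNames(annotation$genome, annotation$gene_id)
  rows <- lapply(names(idx), function(tf) {
    g <- gmap[idx[[tf]]]
    g <- g[!is.na(g) & g %in% c("A", "B", "D")]
    n <- length(g)
    if (n == 0L) return(NULL)
    tfg <- unname(gmap[tf])
    data.frame(tf_id = tf,
               tf_genome = if (is.na(tfg)) "unknown" else tfg,
               prop_a = sum(g == "A") / n, prop_b = sum(g == "B") / n,
               prop_d = sum(g == "D") / n, n_targets = n,
               stringsAsFactors = FALSE)
  })
  n_dropped <- sum(vapply(rows, is.null, logical(1)))
  if (n_dropped) {
    warning(sprintf("%d regulator(s) dropped: no target of known genome",
                    n_dropped), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    grn_empty_analysis_error("no regulator with annotated targets")
  }
  rownames(out) <- NULL
  class(out) <- c("genome_proportion_record", "data.frame")
  out
}

#' Test association between regulator genome and target genome
#'
#' For each target-subgenome proportion (A, B, D), compares its distribution
#' between groups of regulators defined by the regulators' own genome of
#' origin using two-sample Kolmogorov-Smirnov tests, with Benjamini-Hochberg
#' adjustment across all tests run in the invocation. Under no association,
#' an A-genome transcription factor's targets are no more A-enriched than a
#' B- or D-genome factor's.
#'
#' @param proportions `genome_proportion_record` from
#'   [target_genome_proportions()]; may carry an optional `movement` column.
#' @param movement_stratify repeat the test suite within each movement
#'   category (requires a `movement` column)? The BH family is then
#'   per-stratum.
#' @return data.frame `stratum`, `target_genome`, `group1`, `group2`, `n1`,
#'   `n2`, `statistic` (KS D), `p`, `p_adjusted`.
#' @export
genome_origin_association <- function(proportions, movement_stratify = FALSE) {
  if (movement_stratify && is.null(proportions$movement)) {
    grn_config_error("movement_stratify requires a `movement` column")
  }
  strata <- if (movement_stratify) {
    split(proportions, proportions$movement)
  } else {
    list(all = proportions)
  }
  run_stratum <- function(name, dat) {
    dat <- dat[dat$tf_genome %in% c("A", "B", "D"), , drop = FALSE]
    groups <- split(dat, dat$tf_genome)
    gn <- names(groups)
    if (length(gn) < 2) return(NULL)
    combos <- utils::combn(gn, 2)
    props <- c(A = "prop_a", B = "prop_b", D = "prop_d")
    out <- list()
    for (tg in names(props)) {
      for (k in seq_len(ncol(combos))) {
        g1 <- combos[1, k]; g2 <- combos[2, k]
        x <- groups[[g1]][[props[[tg]]]]
        y <- groups[[g2]][[props[[tg]]]]
        if (length(x) < 2 || length(y) < 2) {
          warning(sprintf("KS %s vs %s (%s) skipped: group too small",
                          g1, g2, tg), call. = FALSE)
          next
        }
        ks <- suppressWarnings(stats::ks.test(x, y))
        out[[length(out) + 1L]] <- data.frame(
          stratum = name, target_genome = tg, group1 = g1, group2 = g2,
          n1 = length(x), n2 = length(y),
          statistic = unname(ks$statistic), p = ks$p.value,
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    if (!is.null(res)) res$p_adjusted <- stats::p.adjust(res$p, "BH")
    res
  }
  res <- do.call(rbind, Map(run_stratum, names(strata), strata))
  if (is.null(res)) grn_empty_analysis_error("no testable genome groups")
  rownames(res) <- NULL
  res
}

#' @export
print.movement_comparison <- function(x, ...) {
  cat("homeolog shared ratios by movement category\n")
  print(x$summaries, row.names = FALSE)
  cat("\npairwise rank-sum tests\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
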