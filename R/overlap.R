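#' Shared ratio between two gene sets
#'
#' The overlap statistic used throughout the package: for gene sets A and B,
#' the shared ratio is |A intersect B| / min(|A|, |B|) — the fraction of the
#' smaller set that is also in the larger. It is 1 when the smaller set is
#' contained in the larger and 0 when the sets are disjoint. When exactly one
#' set is empty the ratio is defined as 0 (there is nothing to share); when
#' both are empty it is undefined and an error is raised.
#'
#' @param set_a,set_b character vectors, treated as sets (duplicates removed).
#' @param id_a,id_b labels recorded in the result.
#' @return A one-row data.frame of class `shared_ratio_record` with columns
#'   `id_a`, `id_b`, `size_a`, `size_b`, `intersection`, `ratio`.
#' @examples
#' shared_ratio(paste0("g", 1:5), paste0("g", 4:13))$ratio  # 2/5 = 0.4
#' @export
shared_ratio <- function(set_a, set_b, id_a = "A", id_b = "B") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  na <- length(set_a)
  nb <- length(set_b)
  if (na == 0L && nb == 0L) {
    grn_degenerate_test_error("shared ratio is undefined for two empty sets")
  }
  ninter <- if (na == 0L || nb == 0L) 0L else sum(set_a %in% set_b)
  ratio <- if (min(na, nb) == 0L) 0 else ninter / min(na, nb)
  rec <- data.frame(id_a = id_a, id_b = id_b, size_a = na, size_b = nb,
                    intersection = ninter, ratio = ratio,
                    stringsAsFactors = FALSE)
  class(rec) <- c("shared_ratio_record", "data.frame")
  rec
}

# Vectorised construction of many shared-ratio records; sets_a/sets_b are
# lists of gene-id vectors (sets_b of length 1 is recycled, for the common
# one-reference-set case). All sets must be non-empty on at least one side,
# matching shared_ratio()'s contract (callers pre-drop empty sets).
ratio_records <- function(ids_a, ids_b, sets_a, sets_b) {
  n <- length(ids_a)
  if (length(sets_b) == 1L) sets_b <- rep(sets_b, n)
  size_a <- lengths(sets_a)
  size_b <- lengths(sets_b)
  inter <- mapply(function(a, b) sum(a %in% b), sets_a, sets_b,
                  USE.NAMES = FALSE)
  m <- pmin(size_a, size_b)
  rec <- data.frame(id_a = as.character(ids_a), id_b = as.character(ids_b),
                    size_a = size_a, size_b = size_b,
                    intersection = as.integer(inter),
                    ratio = ifelse(m > 0L, inter / pmax(m, 1L), 0),
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  class(rec) <- c("shared_ratio_record", "data.frame")
  rec
}

#' Six-number summary of a ratio distribution
#'
#' Summarises a collection of shared ratios as count, minimum, first quartile,
#' median, mean, third quartile and maximum — the shape in which resampling
#' distributions are reported. Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param ratios non-empty numeric vector of ratios in [0, 1].
#' @return One-row data.frame of class `distribution_summary` with columns
#'   `n`, `minimum`, `q1`, `median`, `mean`, `q3`, `maximum`.
#' @export
summarize_distribution <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (!length(ratios)) grn_config_error("cannot summarise an empty collection")
  if (any(!is.finite(ratios))) grn_config_error("ratios must be finite")
  qs <- stats::quantile(ratios, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- data.frame(n = length(ratios), minimum = min(ratios), q1 = qs[1],
                    median = qs[2], mean = mean(ratios), q3 = qs[3],
                    maximum = max(ratios))
  class(out) <- c("distribution_summary", "data.frame")
  out
}

#' Null distribution of shared ratios for randomly drawn regulators
#'
#' Draws `n_samples` transcription factors from the sampling frame and
#' computes each one's shared ratio against a fixed reference gene set
#' (typically the differentially expressed genes at one timepoint). The
#' resulting distribution is the resampling null against which an observed
#' focal-regulator ratio is judged with [sign_test_exceeds()].
#'
#' @param network a `regulatory_network`.
#' @param reference_set character vector of gene ids (e.g. a DEG set).
#' @param n_samples number of regulators to draw.
#' @param seed integer seed; the draw is fully reproducible.
#' @param tf_frame regulator ids to sample from; defaults to every regulator
#'   in the network (see [network_regulators()]).
#' @param exclude regulator ids removed from the frame before sampling (e.g.
#'   the focal regulator, if it is to be held out of its own null).
#' @param genomes,annotation optional genome-of-origin filter applied to every
#'   target set, as in [targets_of()].
#' @param replace sample with replacement? Default `FALSE`.
#' @return List of class `ratio_distribution` with elements `records` (one
#'   `shared_ratio_record` row per draw, in draw order), `summary` (a
#'   `distribution_summary`) and `n_dropped` (frame members dropped for empty
#'   target sets after filtering).
#' @export
null_ratio_distribution <- function(network, reference_set, n_samples, seed,
                                    tf_frame = NULL, exclude = NULL,
                                    genomes = NULL, annotation = NULL,
                                    replace = FALSE) {
  stopifnot(inherits(network, "regulatory_network"))
  if (n_samples < 1) grn_config_error("`n_samples` must be positive")
  reference_set <- unique(as.character(reference_set))
  frame <- tf_frame %||% network_regulators(network)
  frame <- setdiff(frame, exclude)
  idx <- target_set_index(network, genomes, annotation)
  frame <- frame[frame %in% names(idx)]
  sizes <- lengths(idx[frame])
  n_dropped <- sum(sizes == 0L)
  frame <- frame[sizes > 0L]
  if (!length(frame)) grn_empty_analysis_error("empty sampling frame")
  if (!replace && n_samples > length(frame)) {
    grn_config_error(
      "n_samples (%d) exceeds frame size (%d) without replacement",
      n_samples, length(frame))
  }
  set.seed(seed)
  drawn <- sample(frame, n_samples, replace = replace)
  records <- ratio_records(drawn, rep("reference", n_samples),
                           idx[drawn], list(reference_set))
  structure(list(records = records,
                 summary = summarize_distribution(records$ratio),
                 n_dropped = n_dropped),
            class = "ratio_distribution")
}

#' Exact binomial sign test of an observed value against a null sample
#'
#' Tests whether the null distribution's median differs from the observed
#' value: null samples tying the observed value are discarded, and the count
#' of samples above the observed value among the non-ties is referred to a
#' Binomial(n, 1/2). With `alternative = "greater"` the test asks whether the
#' observed value exceeds the null median (small p when nearly all null
#' samples fall below it).
#'
#' @param observed observed statistic (a shared ratio).
#' @param null_samples numeric vector of null statistics.
#' @param alternative one of `"greater"`, `"less"`, `"two_sided"`.
#' @return The p-value.
#' @export
sign_test_exceeds <- function(observed, null_samples,
                              alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!length(null_samples)) grn_config_error("null_samples is empty")
  n_above <- sum(null_samples > observed)
  n_below <- sum(null_samples < observed)
  n <- n_above + n_below
  if (n == 0L) {
    grn_degenerate_test_error(
      "all %d null samples tie with the observed value; sign test undefined",
      length(null_samples))
  }
  switch(alternative,
    greater = stats::pbinom(n_above, n, 0.5),
    less = stats::pbinom(n_below, n, 0.5),
    two_sided = min(1, 2 * min(stats::pbinom(n_above, n, 0.5),
                               stats::pbinom(n_below, n, 0.5))))
}

#' Sample unique ordered pairs of regulators
#'
#' Draws pairs of distinct transcription factors without replacement from the
#' N(N-1) possible ordered pairs. When the frame cannot supply `n_pairs`
#' unique pairs (small families), all available pairs are capped at N(N-1):
#' a 3-member family yields 6 pairs.
#'
#' @param tf_frame character vector of at least two regulator ids.
#' @param n_pairs requested number of pairs.
#' @param seed integer seed.
#' @return data.frame with columns `tf1`, `tf2`; `min(n_pairs, N(N-1))` rows,
#'   no duplicates, no self-pairs.
#' @export
sample_tf_pairs <- function(tf_frame, n_pairs, seed) {
  tf_frame <- unique(as.character(tf_frame))
  n <- length(tf_frame)
  if (n < 2) grn_config_error("need at least 2 regulators to form pairs")
  if (n_pairs < 1) grn_config_error("`n_pairs` must be positive")
  total <- as.double(n) * (n - 1)
  k <- min(n_pairs, total)
  set.seed(seed)
  # index the N(N-1) ordered non-self pairs without materialising them
  pick <- sample.int(total, k)
  i <- (pick - 1) %/% (n - 1) + 1
  j <- (pick - 1) %% (n - 1) + 1
  j <- ifelse(j >= i, j + 1, j)
  data.frame(tf1 = tf_frame[i], tf2 = tf_frame[j], stringsAsFactors = FALSE)
}

#' Shared-ratio distribution over regulator pairs
#'
#' Computes the shared ratio between the target sets of each supplied pair of
#' regulators. Pairs with a member whose (possibly genome-filtered) target set
#' is empty are dropped with a count.
#'
#' @param network a `regulatory_network`.
#' @param pairs data.frame with columns `tf1`, `tf2` (see
#'   [sample_tf_pairs()]).
#' @param genomes,annotation optional genome filter, as in [targets_of()].
#' @return `ratio_distribution` list: `records`, `summary`, `n_dropped`.
#' @export
pairwise_ratio_distribution <- function(network, pairs, genomes = NULL,
                                        annotation = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  idx <- target_set_index(network, genomes, annotation)
  sz <- function(tf) length(idx[[tf]] %||% character(0))
  ok <- vapply(pairs$tf1, sz, integer(1)) > 0L &
    vapply(pairs$tf2, sz, integer(1)) > 0L
  n_dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) {
    grn_empty_analysis_error("no pair with two non-empty target sets")
  }
  records <- ratio_records(pairs$tf1, pairs$tf2,
                           idx[pairs$tf1], idx[pairs$tf2])
  structure(list(records = records,
                 summary = summarize_distribution(records$ratio),
                 n_dropped = n_dropped),
            class = "ratio_distribution")
}

#' @export
print.ratio_distribution <- function(x, ...) {
  cat(sprintf("shared-ratio distribution over %d comparisons", x$summary$n))
  if (x$n_dropped) cat(sprintf(" (%d dropped for empty sets)", x$n_dropped))
  cat("\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
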