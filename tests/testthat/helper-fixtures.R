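# Small in-code fixtures shared across test files.

# Build a regulatory_network from a named list of target-id vectors; weights
# default to distinct descending values so trimming order is unambiguous.
net_from_targets <- function(target_sets, weights = NULL) {
  regulator <- rep(names(target_sets), lengths(target_sets))
  target <- unlist(target_sets, use.names = FALSE)
  if (is.null(weights)) weights <- seq(length(target), 1)
  regulatory_network(data.frame(regulator = regulator, target = target,
                                weight = weights, stringsAsFactors = FALSE))
}

# Minimal annotation covering the given genes; genome recycled.
make_annotation <- function(gene_id, genome = "A", is_tf = FALSE,
                            family = NA_character_,
                            triad_id = NA_character_) {
  gene_annotation(data.frame(
    gene_id = gene_id,
    is_tf = rep_len(is_tf, length(gene_id)),
    family = rep_len(family, length(gene_id)),
    genome = rep_len(genome, length(gene_id)),
    triad_id = rep_len(triad_id, length(gene_id)),
    stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent six-number oracle: sort + manual type-7 interpolation.
brute_six_number <- function(x) {
  s <- sort(x)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(n = n, minimum = s[1], q1 = interp(0.25), median = interp(0.5),
    mean = sum(s) / n, q3 = interp(0.75), maximum = s[n])
}

# A tiny three-regulator world used by several exhaustive-enumeration tests.
toy3 <- function() {
  net_from_targets(list(
    TFa = c("g1", "g2", "g3", "g4"),
    TFb = c("g3", "g4", "g5"),
    TFc = c("g6", "g7")))
}
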