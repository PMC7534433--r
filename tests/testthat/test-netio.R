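test_that("read_edge_list parses the canonical dialect and rejects bad input", {
  df <- data.frame(regulator = c("tf1", "tf1", "tf2"),
                   target = c("g1", "g2", "g1"),
                   weight = c(3, 2, 1))
  f <- write_tsv_fixture(df)
  net <- read_edge_list(f)
  expect_s3_class(net, "regulatory_network")
  expect_equal(nrow(net), 3L)
  expect_setequal(targets_of(net, "tf1"), c("g1", "g2"))

  # duplicate (regulator, target) is an error, never a silent merge
  f2 <- write_tsv_fixture(df[c(1, 1, 3), ])
  expect_error(read_edge_list(f2), class = "grn_validation_error")

  # non-numeric weight names the offending data row
  df$weight <- c("3", "NA", "1")
  f3 <- write_tsv_fixture(df)
  expect_error(read_edge_list(f3), "row 2", class = "grn_parse_error")

  # missing column under the configured dialect is a configuration error
  expect_error(read_edge_list(f, weight_col = "score"),
               class = "grn_config_error")

  # a non-canonical dialect maps columns and delimiter
  df4 <- data.frame(from = "tf1", to = "g1", score = 0.5)
  f4 <- tempfile(fileext = ".csv")
  utils::write.table(df4, f4, sep = ",", quote = FALSE, row.names = FALSE)
  net4 <- read_edge_list(f4, regulator_col = "from", target_col = "to",
                         weight_col = "score", sep = ",")
  expect_equal(net4$weight, 0.5)
})

test_that("edge lists round-trip bit-exactly through the canonical dialect", {
  set.seed(42)
  net <- net_from_targets(list(tfA = paste0("g", 1:7), tfB = paste0("g", 5:9)),
                          weights = runif(12))
  f <- tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_identical(back$regulator, net$regulator)
  expect_identical(back$target, net$target)
  expect_identical(back$weight, net$weight)
})

test_that("trim_top_edges keeps the highest weights with a deterministic tie rule", {
  net <- regulatory_network(data.frame(
    regulator = paste0("tf", 1:5), target = paste0("g", 1:5),
    weight = c(5, 4, 3, 2, 1)))
  expect_equal(trim_top_edges(net, 3)$weight, c(5, 4, 3))
  # n beyond the edge count is the identity
  expect_identical(as.data.frame(trim_top_edges(net, 99)),
                   as.data.frame(net))
  expect_error(trim_top_edges(net, 0), class = "grn_config_error")

  # tie at the cut: both one-of-the-weight-2-edges outcomes are admissible;
  # the documented rule picks the lexicographically first (regulator, target)
  tie <- regulatory_network(data.frame(
    regulator = c("tfA", "tfB", "tfA", "tfC"),
    target = c("g1", "g2", "g3", "g4"),
    weight = c(3, 2, 2, 1)))
  cut <- trim_top_edges(tie, 2)
  admissible <- list(c("tfA.g1", "tfA.g3"), c("tfA.g1", "tfB.g2"))
  got <- paste(cut$regulator, cut$target, sep = ".")
  expect_true(any(vapply(admissible, setequal, logical(1), y = got)))
  # deterministic under the lexicographic rule
  expect_equal(got, c("tfA.g1", "tfA.g3"))
  expect_identical(as.data.frame(trim_top_edges(cut, 2)),
                   as.data.frame(cut))  # idempotent
})

test_that("every retained weight is >= every discarded weight after trimming", {
  set.seed(11)
  for (rep in 1:5) {
    n_edges <- sample(5:40, 1)
    net <- regulatory_network(data.frame(
      regulator = sample(paste0("tf", 1:6), n_edges, replace = TRUE),
      target = paste0("g", seq_len(n_edges)),
      weight = sample(seq(0.5, 5, by = 0.5), n_edges, replace = TRUE)))
    n <- sample(seq_len(n_edges), 1)
    kept <- trim_top_edges(net, n)
    expect_equal(nrow(kept), min(n, n_edges))
    dropped_key <- setdiff(paste(net$regulator, net$target),
                           paste(kept$regulator, kept$target))
    dropped_w <- net$weight[paste(net$regulator, net$target) %in% dropped_key]
    if (length(dropped_w)) expect_gte(min(kept$weight), max(dropped_w))
  }
})

test_that("targets_of resolves and genome-filters target sets", {
  net <- net_from_targets(list(tf1 = c("g1", "g2", "g3")))
  ann <- make_annotation(c("g1", "g2", "g3", "tf1"),
                         genome = c("A", "B", "D", "A"),
                         is_tf = c(FALSE, FALSE, FALSE, TRUE))
  expect_setequal(targets_of(net, "tf1"), c("g1", "g2", "g3"))
  expect_setequal(targets_of(net, "tf1", genomes = c("A", "B"), ann),
                  c("g1", "g2"))
  # filter over all three genomes is a no-op when every target is annotated
  expect_setequal(targets_of(net, "tf1", genomes = c("A", "B", "D"), ann),
                  targets_of(net, "tf1"))
  expect_error(targets_of(net, "tf1", genomes = "A"),
               class = "grn_config_error")
  expect_warning(out <- targets_of(net, "absent"), "no edge")
  expect_length(out, 0)
})

test_that("annotation, DEG and triad validators enforce their invariants", {
  expect_error(make_annotation(c("g1", "g1")), class = "grn_validation_error")
  expect_error(
    gene_annotation(data.frame(gene_id = "g1", is_tf = FALSE, family = "NAC",
                               genome = "A", triad_id = NA)),
    class = "grn_validation_error")  # family only for TFs
  expect_error(
    deg_table(data.frame(gene_id = "g1", q_value = 1.2, timepoint = "t")),
    class = "grn_validation_error")
  expect_error(
    deg_table(data.frame(gene_id = c("g1", "g1"), q_value = 0.1,
                         timepoint = "t")),
    class = "grn_validation_error")
  expect_error(
    triad_table(data.frame(triad_id = "t1", gene_a = "x", gene_b = "x",
                           gene_d = "z", syntenic = TRUE)),
    class = "grn_validation_error")
  expect_error(
    triad_table(data.frame(triad_id = c("t1", "t2"),
                           gene_a = c("a1", "a1"), gene_b = c("b1", "b2"),
                           gene_d = c("d1", "d2"), syntenic = TRUE)),
    class = "grn_validation_error")  # one gene in two triads
})

test_that("movement categories are assigned from per-category gene lists", {
  tri <- data.frame(triad_id = c("t1", "t2", "t3"),
                    gene_a = c("a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3"),
                    gene_d = c("d1", "d2", "d3"), syntenic = TRUE)
  f_tri <- write_tsv_fixture(tri)
  f_dyn <- tempfile(); writeLines(c("a1"), f_dyn)
  f_sta <- tempfile(); writeLines(c("b3", "d3"), f_sta)
  got <- read_triads(f_tri, movement_files = list(Dynamic = f_dyn,
                                                  Stable = f_sta))
  expect_equal(got$movement, c("Dynamic", "Unclassified", "Stable"))

  # a gene listed in two categories is a validation error
  f_bad <- tempfile(); writeLines("a1", f_bad)
  expect_error(
    read_triads(f_tri, movement_files = list(Dynamic = f_dyn,
                                             Stable = f_bad)),
    class = "grn_validation_error")

  # members of one triad in conflicting categories is a validation error
  f_conf <- tempfile(); writeLines("b1", f_conf)
  expect_error(
    read_triads(f_tri, movement_files = list(Dynamic = f_dyn,
                                             Stable = f_conf)),
    class = "grn_validation_error")
})

test_that("expression matrices require complete metadata and valid TPM", {
  tpm <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), tissue = "leaf",
                     senescent = c(TRUE, FALSE))
  em <- expression_matrix(tpm, meta)
  expect_s3_class(em, "expression_matrix")
  expect_error(expression_matrix(tpm, meta[1, ]),
               class = "grn_validation_error")
  tpm[1, 1] <- -1
  expect_error(expression_matrix(tpm, meta), class = "grn_validation_error")
})
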