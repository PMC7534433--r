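#' Construct a regulatory network from an edge table
#'
#' A regulatory network is a weighted regulator -> target edge list, the form
#' in which GENIE3-style network predictions are distributed. The constructor
#' validates the invariants every downstream analysis relies on: no duplicate
#' (regulator, target) pair, and strictly positive finite weights.
#'
#' @param edges data.frame with character columns `regulator`, `target` and a
#'   numeric column `weight`.
#' @return An object of class `regulatory_network`: the validated edge
#'   data.frame, rows ordered by decreasing weight with ties broken
#'   lexicographically by (regulator, target).
#' @export
regulatory_network <- function(edges) {
  if (!is.data.frame(edges)) {
    grn_config_error("`edges` must be a data.frame")
  }
  need <- c("regulator", "target", "weight")
  missing_cols <- setdiff(need, names(edges))
  if (length(missing_cols)) {
    grn_config_error("edge table lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  edges <- edges[need]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (!is.numeric(edges$weight)) {
    bad <- which(is.na(suppressWarnings(as.numeric(edges$weight))))
    grn_parse_error("non-numeric weight at row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.finite(edges$weight) | edges$weight <= 0)
  if (length(bad)) {
    grn_parse_error("non-positive or non-finite weight at row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    grn_validation_error("duplicate (regulator, target) pair(s), e.g. (%s, %s)",
                         edges$regulator[which(dup)[1]],
                         edges$target[which(dup)[1]])
  }
  edges <- edges[order(-edges$weight, edges$regulator, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("regulatory_network", "data.frame")
  edges
}

#' Read a weighted edge list
#'
#' Reads a delimited regulator/target/weight file into a
#' [regulatory_network()]. Column names and the delimiter are configurable
#' because deposited networks do not share a canonical header; the canonical
#' dialect is tab-separated `regulator<TAB>target<TAB>weight`.
#'
#' @param path path to a delimited text file with a header row.
#' @param regulator_col,target_col,weight_col column names in the file.
#' @param sep field delimiter (default tab).
#' @return A `regulatory_network`.
#' @export
read_edge_list <- function(path, regulator_col = "regulator",
                           target_col = "target", weight_col = "weight",
                           sep = "\t") {
  if (!file.exists(path)) grn_config_error("no such file: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c(regulator_col, target_col, weight_col)) {
    if (!col %in% names(raw)) {
      grn_config_error("edge list %s has no column '%s' (found: %s)",
                       path, col, paste(names(raw), collapse = ", "))
    }
  }
  w <- suppressWarnings(as.numeric(raw[[weight_col]]))
  bad <- which(is.na(w))
  if (length(bad)) {
    grn_parse_error("non-numeric weight '%s' at data row %d of %s",
                    raw[[weight_col]][bad[1]], bad[1], path)
  }
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    grn_parse_error("non-positive weight %s at data row %d of %s",
                    format(w[bad[1]]), bad[1], path)
  }
  regulatory_network(data.frame(regulator = raw[[regulator_col]],
                                target = raw[[target_col]],
                                weight = w,
                                stringsAsFactors = FALSE))
}

#' Write an edge list in the canonical dialect
#'
#' Inverse of [read_edge_list()] for the canonical tab-separated dialect;
#' round-tripping preserves the edge multiset and weights exactly (weights are
#' written with full precision).
#'
#' @param network a `regulatory_network`.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  out <- data.frame(regulator = network$regulator,
                    target = network$target,
                    weight = sprintf("%.17g", network$weight),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim a network to its top-weighted edges
#'
#' Keeps the `n` highest-weight edges (all edges when the network is smaller),
#' mirroring the common practice of analysing only the top connections of a
#' genome-scale ranking. Ties at the cut weight are resolved by lexicographic
#' (regulator, target) order so the trim is deterministic.
#'
#' @param network a `regulatory_network`.
#' @param n positive integer number of edges to retain.
#' @return The trimmed `regulatory_network`.
#' @export
trim_top_edges <- function(network, n) {
  stopifnot(inherits(network, "regulatory_network"))
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    grn_config_error("`n` must be a positive integer")
  }
  # constructor ordering is (-weight, regulator, target), so head() is the rule
  out <- utils::head(as.data.frame(network), min(n, nrow(network)))
  regulatory_network(out)
}

#' Regulators present in a network
#'
#' The sampling frame for all resampling analyses: every regulator with at
#' least one retained edge. Regulators trimmed to zero edges drop out of the
#' frame by construction. Optionally restricted to genes flagged as
#' transcription factors in an annotation table.
#'
#' @param network a `regulatory_network`.
#' @param annotation optional annotation table (see [read_annotation()]);
#'   when given, only regulators with `is_tf = TRUE` are returned.
#' @return Character vector of regulator ids, sorted.
#' @export
network_regulators <- function(network, annotation = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  regs <- sort(unique(network$regulator))
  if (!is.null(annotation)) {
    tfs <- annotation$gene_id[annotation$is_tf]
    regs <- regs[regs %in% tfs]
  }
  regs
}

#' Predicted target set of a regulator
#'
#' Resolves the set of targets of `regulator` in the network, optionally
#' restricted to targets whose annotated genome of origin lies in `genomes`
#' (e.g. `c("A", "B")` when the validating expression data come from a
#' tetraploid and D-genome targets cannot be observed).
#'
#' @param network a `regulatory_network`.
#' @param regulator regulator gene id.
#' @param genomes optional character subset of `c("A","B","D")`.
#' @param annotation annotation table; required when `genomes` is given
#'   (genomes are looked up, never parsed out of gene ids).
#' @return Character vector (a set) of target gene ids; empty, with a warning,
#'   when the regulator has no edge in the network.
#' @export
targets_of <- function(network, regulator, genomes = NULL, annotation = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!is.null(genomes) && is.null(annotation)) {
    grn_config_error("`genomes` filter requires an `annotation` table")
  }
  tg <- unique(network$target[network$regulator == regulator])
  if (!length(tg)) {
    warning(sprintf("regulator '%s' has no edge in the network", regulator),
            call. = FALSE)
    return(character(0))
  }
  if (!is.null(genomes)) {
    tg <- filter_genomes(tg, genomes, annotation)
  }
  tg
}

# genome lookup used by targets_of() and the precomputed target-set index
filter_genomes <- function(genes, genomes, annotation) {
  gmap <- annotation$genome[match(genes, annotation$gene_id)]
  genes[!is.na(gmap) & gmap %in% genomes]
}

# Precompute every regulator's target set once; all resampling loops use this
# index instead of scanning the edge table per draw.
target_set_index <- function(network, genomes = NULL, annotation = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!is.null(genomes) && is.null(annotation)) {
    grn_config_error("`genomes` filter requires an `annotation` table")
  }
  idx <- split(network$target, network$regulator)
  idx <- lapply(idx, unique)
  if (!is.null(genomes)) {
    keep <- !is.na(annotation$genome) & annotation$genome %in% genomes
    allowed <- annotation$gene_id[keep]
    idx <- lapply(idx, function(tg) tg[tg %in% allowed])
  }
  idx
}

#' Read a gene annotation table
#'
#' Tab-separated columns `gene_id`, `is_tf`, `family`, `genome`, `triad_id`.
#' `family` applies only to transcription factors; `genome` is one of A/B/D or
#' `unknown`. Empty strings and "NA" in `family`/`triad_id` mean absent.
#'
#' @param path path to the TSV file.
#' @return data.frame with the five columns, validated.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) grn_config_error("no such file: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  gene_annotation(data.frame(
    gene_id = tab$gene_id,
    is_tf = toupper(tab$is_tf) %in% c("TRUE", "T", "1"),
    family = tab$family,
    genome = tab$genome,
    triad_id = tab$triad_id,
    stringsAsFactors = FALSE))
}

#' Validate a gene annotation table
#'
#' @param tab data.frame with columns `gene_id`, `is_tf` (logical), `family`,
#'   `genome`, `triad_id`; `family` and `triad_id` may be `NA`.
#' @return The validated data.frame.
#' @export
gene_annotation <- function(tab) {
  need <- c("gene_id", "is_tf", "family", "genome", "triad_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    grn_config_error("annotation lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  tab <- tab[need]
  tab$family[!is.na(tab$family) & tab$family == ""] <- NA_character_
  tab$triad_id[!is.na(tab$triad_id) & tab$triad_id == ""] <- NA_character_
  if (anyDuplicated(tab$gene_id)) {
    grn_validation_error("duplicate gene_id in annotation: %s",
                         tab$gene_id[anyDuplicated(tab$gene_id)])
  }
  bad <- !tab$genome %in% c("A", "B", "D", "unknown")
  if (any(bad)) {
    grn_validation_error("genome must be A/B/D/unknown; offender: %s",
                         tab$genome[which(bad)[1]])
  }
  if (any(!tab$is_tf & !is.na(tab$family))) {
    grn_validation_error("family set for non-TF gene: %s",
                         tab$gene_id[which(!tab$is_tf & !is.na(tab$family))[1]])
  }
  rownames(tab) <- NULL
  tab
}

#' Read a syntenic-triad table with movement-category gene lists
#'
#' The triad table is TSV with columns `triad_id`, `gene_a`, `gene_b`,
#' `gene_d`, `syntenic`. Expression-movement categories (Dynamic / Mid 80 /
#' Stable, i.e. high / middle / low variability of relative homeolog
#' expression across tissues) arrive as one plain-text gene-list file per
#' category; a triad is labelled by membership of any of its genes in a
#' category list, triads in no list are `Unclassified`, and conflicting
#' assignments are an error.
#'
#' @param path path to the triad TSV.
#' @param movement_files named list/vector of gene-list file paths; names are
#'   the category labels (conventionally `Dynamic`, `Mid80`, `Stable`).
#' @return data.frame `triad_id`, `gene_a`, `gene_b`, `gene_d`, `syntenic`
#'   (logical), `movement`.
#' @export
read_triads <- function(path, movement_files = NULL) {
  if (!file.exists(path)) grn_config_error("no such file: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  lists <- NULL
  if (!is.null(movement_files)) {
    if (is.null(names(movement_files)) || any(names(movement_files) == "")) {
      grn_config_error("movement_files must be named by category")
    }
    lists <- lapply(movement_files, function(f) {
      if (!file.exists(f)) grn_config_error("no such file: %s", f)
      scan(f, what = character(), quiet = TRUE)
    })
  }
  triad_table(data.frame(
    triad_id = tab$triad_id,
    gene_a = tab$gene_a, gene_b = tab$gene_b, gene_d = tab$gene_d,
    syntenic = toupper(tab$syntenic) %in% c("TRUE", "T", "1"),
    stringsAsFactors = FALSE), movement_lists = lists)
}

#' Validate a triad table and assign movement categories
#'
#' @param tab data.frame with `triad_id`, `gene_a`, `gene_b`, `gene_d`,
#'   `syntenic` (logical) and optionally `movement`.
#' @param movement_lists optional named list of character vectors of gene ids;
#'   overrides any `movement` column.
#' @return The validated triad data.frame with a `movement` column.
#' @export
triad_table <- function(tab, movement_lists = NULL) {
  need <- c("triad_id", "gene_a", "gene_b", "gene_d", "syntenic")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    grn_config_error("triad table lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$triad_id)) {
    grn_validation_error("duplicate triad_id: %s",
                         tab$triad_id[anyDuplicated(tab$triad_id)])
  }
  members <- c(tab$gene_a, tab$gene_b, tab$gene_d)
  same <- tab$gene_a == tab$gene_b | tab$gene_a == tab$gene_d |
    tab$gene_b == tab$gene_d
  if (any(same)) {
    grn_validation_error("triad %s has non-distinct members",
                         tab$triad_id[which(same)[1]])
  }
  if (anyDuplicated(members)) {
    grn_validation_error("gene %s belongs to more than one triad",
                         members[anyDuplicated(members)])
  }
  if (!is.null(movement_lists)) {
    all_listed <- unlist(movement_lists, use.names = FALSE)
    if (anyDuplicated(all_listed)) {
      grn_validation_error("gene %s appears in more than one movement list",
                           all_listed[anyDuplicated(all_listed)])
    }
    cat_of <- function(g) {
      hit <- vapply(movement_lists, function(l) g %in% l, logical(1))
      if (!any(hit)) NA_character_ else names(movement_lists)[which(hit)[1]]
    }
    movement <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      cats <- stats::na.omit(vapply(c(tab$gene_a[i], tab$gene_b[i],
                                      tab$gene_d[i]), cat_of, character(1)))
      ucats <- unique(cats)
      if (length(ucats) > 1) {
        grn_validation_error(
          "triad %s has members in conflicting movement categories (%s)",
          tab$triad_id[i], paste(ucats, collapse = ", "))
      }
      movement[i] <- if (length(ucats)) ucats else "Unclassified"
    }
    tab$movement <- movement
  } else if (is.null(tab$movement)) {
    tab$movement <- "Unclassified"
  }
  rownames(tab) <- NULL
  tab[c(need, "movement")]
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `q_value` (FDR-adjusted p-value in [0, 1]) and
#' `timepoint` (e.g. `"12DAA"`). One row per gene per timepoint.
#'
#' @param path path to the TSV file.
#' @return Validated data.frame `gene_id`, `q_value`, `timepoint`.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) grn_config_error("no such file: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  q <- suppressWarnings(as.numeric(tab$q_value))
  bad <- which(is.na(q))
  if (length(bad)) {
    grn_parse_error("non-numeric q_value at data row %d of %s", bad[1], path)
  }
  deg_table(data.frame(gene_id = tab$gene_id, q_value = q,
                       timepoint = tab$timepoint, stringsAsFactors = FALSE))
}

#' Validate a differential-expression table
#'
#' @param tab data.frame with `gene_id`, `q_value`, `timepoint`.
#' @return The validated data.frame.
#' @export
deg_table <- function(tab) {
  need <- c("gene_id", "q_value", "timepoint")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    grn_config_error("DEG table lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  tab <- tab[need]
  if (any(!is.finite(tab$q_value) | tab$q_value < 0 | tab$q_value > 1)) {
    grn_validation_error("q_value outside [0, 1]")
  }
  key <- paste(tab$gene_id, tab$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    grn_validation_error("duplicate (gene_id, timepoint) row: %s",
                         sub("\r", " @ ", key[anyDuplicated(key)]))
  }
  rownames(tab) <- NULL
  tab
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is TSV, first column `gene_id`, remaining columns one per
#' sample, values TPM. The metadata file is TSV with columns `sample_id`,
#' `tissue`, `senescent`.
#'
#' @param path path to the genes x samples TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return An `expression_matrix`: list with `tpm` (numeric matrix, genes x
#'   samples) and `samples` (metadata data.frame).
#' @export
read_expression <- function(path, metadata_path) {
  for (f in c(path, metadata_path)) {
    if (!file.exists(f)) grn_config_error("no such file: %s", f)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  tpm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(tpm) <- tab[[1]]
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            quote = "", colClasses = "character",
                            stringsAsFactors = FALSE, comment.char = "#")
  meta$senescent <- toupper(meta$senescent) %in% c("TRUE", "T", "1")
  expression_matrix(tpm, meta)
}

#' Construct a validated expression matrix
#'
#' @param tpm numeric genes x samples matrix of TPM (non-negative).
#' @param samples data.frame with `sample_id`, `tissue`, `senescent`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, samples) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    grn_config_error("`tpm` must be a numeric matrix")
  }
  if (any(!is.finite(tpm)) || any(tpm < 0)) {
    grn_validation_error("TPM values must be finite and non-negative")
  }
  need <- c("sample_id", "tissue", "senescent")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    grn_config_error("sample metadata lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  unmatched <- setdiff(colnames(tpm), samples$sample_id)
  if (length(unmatched)) {
    grn_validation_error("sample(s) without metadata: %s",
                         paste(unmatched, collapse = ", "))
  }
  samples <- samples[match(colnames(tpm), samples$sample_id), need]
  rownames(samples) <- NULL
  structure(list(tpm = tpm, samples = samples), class = "expression_matrix")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory network: %d edges, %d regulators, %d targets\n",
              nrow(x), length(unique(x$regulator)),
              length(unique(x$target))))
  if (nrow(x)) {
    cat(sprintf("weights in [%.4g, %.4g]\n", min(x$weight), max(x$weight)))
  }
  invisible(x)
}
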