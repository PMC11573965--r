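#' Spearman rank correlation between two value vectors
#'
#' Pearson correlation of average-tie ranks; symmetric, and invariant under
#' strictly monotone transforms of either input. Used row-wise on the ten
#' feature values of two meshes to quantify how similarly the two feature
#' profiles are ordered.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` when either vector is constant
#'   (undefined ranks).
#' @examples
#' spearman_cor(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Build the sample-similarity graph from a feature table
#'
#' Every table row becomes a node (keyed by `unique_id`); an undirected edge
#' connects two nodes when the Spearman correlation between their ten
#' feature values is at least `threshold` (inclusive, matching "equal or
#' above"). The unique ID and target columns are excluded from the
#' correlation. Edges are numbered 1..E in lexicographic (source, target)
#' order of unique IDs. Rows whose features are constant have undefined
#' correlations and contribute no edges (with a warning).
#'
#' @param table Feature table ([build_feature_table()]).
#' @param threshold Correlation threshold in \[-1, 1\], or -1 to connect
#'   every pair with a defined correlation. Default 0.7.
#' @param standardize Rank-irrelevant per-column standardization switch
#'   (z-score columns before the row-wise correlation). Default `FALSE`
#'   (raw feature values).
#' @return An object of class `sample_graph`: list with `nodes`
#'   (data.frame `unique_id`, `target`) and `edges` (data.frame
#'   `edge_number`, `source_node`, `target_node`, `correlation`), plus the
#'   construction `threshold`.
#' @examples
#' ds <- make_dataset(6, 4, seed = 1)
#' tab <- build_feature_table(ds$meshes, ds$labels)
#' g <- build_graph(tab, threshold = 0.7)
#' g
#' @export
build_graph <- function(table, threshold = 0.7, standardize = FALSE) {
  if (nrow(table) < 2L) stop("need at least 2 rows")
  x <- as.matrix(feature_columns(table))
  if (standardize) x <- scale(x)
  ids <- table$unique_id
  # Spearman between rows = Pearson between row-wise ranks
  cm <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  constant <- apply(x, 1L, function(r) stats::sd(r) == 0)
  if (any(constant)) {
    warning(sum(constant), " row(s) with constant features: no edges for them")
    cm[constant, ] <- NA
    cm[, constant] <- NA
  }
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[ut]
  keep <- !is.na(w) & w >= threshold
  src <- ut[keep, 1L]
  dst <- ut[keep, 2L]
  w <- w[keep]
  ord <- order(ids[src], ids[dst])
  edges <- data.frame(edge_number = seq_along(ord),
                      source_node = ids[src][ord],
                      target_node = ids[dst][ord],
                      correlation = w[ord])
  structure(list(nodes = data.frame(unique_id = ids, target = table$target),
                 edges = edges, threshold = threshold),
            class = "sample_graph")
}

#' @export
print.sample_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf(paste0("sample_graph: %d nodes, %d edges (threshold >= %g)\n",
                     "  intra-benign %d, intra-malignant %d, inter-class %d\n"),
              s$nodes, s$edges, x$threshold,
              s$intra_benign, s$intra_malignant, s$inter_class))
  invisible(x)
}

#' Edge composition statistics of a sample graph
#'
#' @param graph A [build_graph()] result.
#' @return List with `nodes`, `edges`, `intra_benign`, `intra_malignant`,
#'   `inter_class`; the three partition counts sum to `edges`.
#' @export
graph_stats <- function(graph) {
  lab <- stats::setNames(as.character(graph$nodes$target),
                         graph$nodes$unique_id)
  ls <- lab[as.character(graph$edges$source_node)]
  lt <- lab[as.character(graph$edges$target_node)]
  list(nodes = nrow(graph$nodes),
       edges = nrow(graph$edges),
       intra_benign = sum(ls == "benign" & lt == "benign"),
       intra_malignant = sum(ls == "malignant" & lt == "malignant"),
       inter_class = sum(ls != lt))
}

#' Export an edge list as CSV
#'
#' Writes `edge_number,source_node,target_node,correlation` with
#' correlations rounded to 2 decimals (full precision is retained in the
#' in-memory graph).
#'
#' @param graph A [build_graph()] result.
#' @param path CSV path.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  e$correlation <- round(e$correlation, 2L)
  utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sweep the correlation threshold
#'
#' Rebuilds the graph at each threshold and reports the edge count (always
#' non-increasing in the threshold); optionally trains the attention
#' classifier at each threshold with a fixed seed and split and reports its
#' test accuracy.
#'
#' @param table Feature table.
#' @param thresholds Ascending thresholds; use -1 for "no threshold"
#'   (all pairs with a defined correlation connected).
#' @param config A [gat_config()]; only used when `train = TRUE`.
#' @param train Also train and evaluate the classifier per threshold.
#' @param standardize Passed to [build_graph()].
#' @return Data.frame `threshold`, `edges` and, when training,
#'   `test_accuracy` (percent).
#' @export
threshold_sweep <- function(table, thresholds = c(-1, 0.5, 0.6, 0.7, 0.8, 0.9),
                            config = gat_config(), train = FALSE,
                            standardize = TRUE) {
  rows <- lapply(thresholds, function(th) {
    g <- build_graph(table, threshold = th, standardize = standardize)
    row <- data.frame(threshold = th, edges = nrow(g$edges))
    if (train) {
      fit <- train_gat(table, g, config)
      row$test_accuracy <- fit$report$metrics[["test_accuracy"]]
    }
    row
  })
  do.call(rbind, rows)
}
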