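feature_columns <- function(table) {
  miss <- setdiff(c(feature_names, "target"), names(table))
  if (length(miss)) stop("feature table is missing columns: ",
                         paste(miss, collapse = ", "))
  table[, feature_names, drop = FALSE]
}

#' One-way ANOVA F test per feature
#'
#' For each of the ten features, the one-way F statistic comparing the benign
#' and malignant groups (between-group mean square over within-group mean
#' square) and its p value from the F distribution with (1, N - 2) degrees
#' of freedom. For two groups this F is exactly the square of the pooled
#' two-sample t statistic.
#'
#' @param table Feature table ([build_feature_table()]).
#' @param alpha Significance threshold recorded in the output. Default 0.05.
#' @return Data.frame with columns `feature`, `F_value`, `p_value`,
#'   `significant`. Features with zero within-group variance but different
#'   group means get `F_value = Inf`, `p_value = 0`.
#' @examples
#' tab <- data.frame(unique_id = 1:6,
#'                   matrix(rnorm(60), 6, dimnames = list(NULL,
#'                     meshgat:::feature_names)),
#'                   target = rep(c("benign", "malignant"), each = 3))
#' anova_f(tab)
#' @export
anova_f <- function(table, alpha = 0.05) {
  g <- factor(table$target)
  if (nlevels(g) != 2L || any(tabulate(g) < 2L)) {
    stop("need both classes with at least 2 rows each")
  }
  x <- feature_columns(table)
  n <- nrow(x)
  res <- lapply(names(x), function(f) {
    v <- x[[f]]
    means <- tapply(v, g, mean)
    counts <- tabulate(g)
    grand <- mean(v)
    ssb <- sum(counts * (means - grand)^2)
    ssw <- sum((v - means[as.integer(g)])^2)
    dfb <- 1L
    dfw <- n - 2L
    if (ssw == 0) {
      if (ssb == 0) {
        data.frame(feature = f, F_value = 0, p_value = 1)
      } else {
        warning("feature '", f, "': zero within-group variance, F = Inf")
        data.frame(feature = f, F_value = Inf, p_value = 0)
      }
    } else {
      F_val <- (ssb / dfb) / (ssw / dfw)
      data.frame(feature = f, F_value = F_val,
                 p_value = stats::pf(F_val, dfb, dfw, lower.tail = FALSE))
    }
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha
  out
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features by the F-test-relevance / correlation-redundancy quotient
#' (FCQ) scheme: relevance of a feature is its one-way ANOVA F value against
#' the class label; redundancy is the mean absolute Pearson correlation with
#' the already-selected features. The first pick is the most relevant
#' feature; each subsequent pick maximizes relevance / redundancy. Scores
#' are min-max scaled to a 0-100 percent axis.
#'
#' @param table Feature table ([build_feature_table()]).
#' @return Data.frame `rank`, `feature`, `score` (percent), `raw_score`
#'   (the greedy quotient at selection time).
#' @export
mrmr_rank <- function(table) {
  x <- feature_columns(table)
  if (ncol(x) < 2L) stop("need at least 2 features")
  relevance <- anova_f(table)
  rel <- stats::setNames(relevance$F_value, relevance$feature)
  const <- vapply(x, function(v) stats::sd(v) == 0, TRUE)
  if (any(const)) {
    warning("constant feature column(s): ",
            paste(names(x)[const], collapse = ", "),
            " (relevance 0, ranked last)")
    rel[const] <- 0
  }
  cors <- abs(stats::cor(x))
  cors[is.na(cors)] <- 0
  selected <- character()
  scores <- numeric()
  remaining <- names(x)
  while (length(remaining)) {
    if (!length(selected)) {
      quotient <- rel[remaining]
    } else {
      red <- vapply(remaining, function(f) {
        mean(cors[f, selected])
      }, 1.0)
      quotient <- rel[remaining] / pmax(red, .Machine$double.eps)
    }
    # tie-break: lexicographic feature name
    best <- remaining[order(-quotient, remaining)][1L]
    selected <- c(selected, best)
    scores <- c(scores, quotient[[best]])
    remaining <- setdiff(remaining, best)
  }
  finite <- is.finite(scores)
  rng <- range(scores[finite])
  pct <- if (diff(rng) > 0) 100 * (scores - rng[1L]) / diff(rng)
         else rep(100, length(scores))
  pct[!finite] <- 100
  data.frame(rank = seq_along(selected), feature = selected,
             score = pct, raw_score = scores, row.names = NULL)
}

#' Class-wise feature means over random subsets
#'
#' For each class and each subset size, samples that many rows without
#' replacement (seeded) and reports the mean of every feature; the full-class
#' means are appended as size `"all"`. Stable subset means across sizes that
#' separate the two classes indicate a consistent feature pattern.
#'
#' @param table Feature table ([build_feature_table()]).
#' @param subset_sizes Integer vector of subset sizes.
#'   Default `c(70, 90, 110, 130, 150)`. Sizes larger than a class are
#'   capped at the class size with a warning.
#' @param seed Integer RNG seed.
#' @return Data.frame with columns `target`, `size` (character; `"all"` for
#'   the full class), `n_used`, then the ten feature means.
#' @export
pattern_summary <- function(table, subset_sizes = c(70, 90, 110, 130, 150),
                            seed = 1L) {
  set.seed(seed)
  x <- feature_columns(table)
  g <- factor(table$target)
  rows <- list()
  for (cls in levels(g)) {
    idx <- which(g == cls)
    for (s in subset_sizes) {
      n_used <- min(s, length(idx))
      if (n_used < s) {
        warning("class '", cls, "': subset size ", s,
                " capped at class size ", length(idx))
      }
      take <- sample(idx, n_used)
      rows[[length(rows) + 1L]] <- data.frame(
        target = cls, size = as.character(s), n_used = n_used,
        t(colMeans(x[take, , drop = FALSE])))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      target = cls, size = "all", n_used = length(idx),
      t(colMeans(x[idx, , drop = FALSE])))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
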