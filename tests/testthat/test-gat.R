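test_that("attention coefficients are a proper distribution per node and head", {
  set.seed(21)
  for (rep in 1:3) {
    tab <- random_feature_table(15, seed = rep)
    g <- build_graph(tab, threshold = 0.2, standardize = TRUE)
    X <- matrix(rnorm(15 * 6), 15, 6)
    res <- attention_layer(X, g, heads = 4L, out_dim = 5L, seed = rep)
    expect_true(all(res$alpha >= 0))
    sums <- rowsum(res$alpha, res$edges$src)
    expect_equal(unname(sums), matrix(1, nrow(sums), 4L), tolerance = 1e-6)
  }
})

test_that("equal scores give uniform attention; isolated nodes attend themselves", {
  # identical node features -> identical scores -> alpha = 1/neighborhood
  tab <- random_feature_table(6, seed = 2)
  g <- build_graph(tab, threshold = -1)
  X <- matrix(1, 6, 4)
  res <- attention_layer(X, g, heads = 2L, out_dim = 3L, seed = 1)
  expect_equal(res$alpha, matrix(1 / 6, nrow(res$alpha), 2L),
               tolerance = 1e-9)

  # a graph with no edges leaves only self-loops
  tab2 <- random_feature_table(4, seed = 3)
  g2 <- build_graph(tab2, threshold = 1.01)
  expect_identical(nrow(g2$edges), 0L)
  X2 <- matrix(rnorm(4 * 4), 4, 4)
  res2 <- attention_layer(X2, g2, heads = 3L, out_dim = 4L,
                          activation = "tanh", seed = 5)
  expect_equal(res2$alpha, matrix(1, 4, 3L), tolerance = 1e-9)
  # output = activation(W x_i) averaged over... concatenated heads
  W1 <- res2$params[[1]]$W
  expect_equal(res2$output[, 1:4], tanh(X2 %*% W1), tolerance = 1e-9)
})

test_that("model builds, forward pass yields row-stochastic probabilities", {
  tab <- random_feature_table(20, seed = 5)
  g <- build_graph(tab, threshold = 0, standardize = TRUE)
  cfg <- gat_config(epochs = 1L, seed = 3)
  params <- gat_init(cfg, 10L, 2L)
  adj <- meshgat:::graph_adjacency(g)
  X <- scale(as.matrix(tab[, 2:11]))
  fwd <- meshgat:::gat_forward(params, X, adj, cfg)
  expect_identical(dim(fwd$probs), c(20L, 2L))
  expect_equal(rowSums(fwd$probs), rep(1, 20), tolerance = 1e-9)
  # same seed, same initial outputs
  params2 <- gat_init(cfg, 10L, 2L)
  fwd2 <- meshgat:::gat_forward(params2, X, adj, cfg)
  expect_identical(fwd$probs, fwd2$probs)
  # single-head single-layer degenerate case still normalizes
  cfg1 <- gat_config(heads = 1L, attention_layers = 1L, seed = 3)
  p1 <- gat_init(cfg1, 10L, 2L)
  fwd1 <- meshgat:::gat_forward(p1, X, adj, cfg1)
  expect_equal(rowSums(fwd1$probs), rep(1, 20), tolerance = 1e-9)
  expect_error(gat_init(cfg, 0L), "feature_dim")
})

test_that("attention layers are permutation-equivariant", {
  tab <- random_feature_table(12, seed = 8)
  g <- build_graph(tab, threshold = 0.1, standardize = TRUE)
  X <- matrix(rnorm(12 * 5), 12, 5)
  res <- attention_layer(X, g, heads = 2L, out_dim = 4L, seed = 2)
  perm <- sample(12)
  tabp <- tab[perm, ]
  tabp$unique_id <- seq_len(12)  # relabel so node order matches row order
  gp <- build_graph(tabp, threshold = 0.1, standardize = TRUE)
  resp <- attention_layer(X[perm, , drop = FALSE], gp, heads = 2L,
                          out_dim = 4L, params = res$params)
  expect_equal(resp$output, res$output[perm, , drop = FALSE],
               tolerance = 1e-6)
})

test_that("training separates two well-separated synthetic classes", {
  ds <- make_dataset(40, 24, separation = 1, seed = 31)
  tab <- build_feature_table(ds$meshes, ds$labels)
  g <- build_graph(tab, 0.7, standardize = TRUE)
  cfg <- gat_config(attention_layers = 1L, heads = 4L, learning_rate = 5e-3,
                    batch_size = 32L, epochs = 120L, seed = 2)
  fit <- train_gat(tab, g, cfg)
  expect_gte(fit$report$metrics[["test_accuracy"]], 80)
  expect_gte(fit$report$metrics[["train_accuracy"]], 90)
  # loss decreases over training
  h <- fit$history
  expect_lt(mean(tail(h$loss, 10)), mean(head(h$loss, 10)))
  # prediction interface
  pr <- predict(fit, tab)
  expect_identical(nrow(pr), 64L)
  expect_true(all(pr$predicted %in% c("benign", "malignant")))
})

test_that("stratified split respects fractions and errors on single-class splits", {
  y <- rep(c("benign", "malignant"), c(70, 30))
  sa <- meshgat:::stratified_split(y, c(train = .7, validation = .15,
                                       test = .15), seed = 1)
  expect_identical(length(sa), 100L)
  expect_true(all(table(sa, y) > 0))
  expect_equal(sum(sa == "train"), 70, tolerance = 2)
  expect_error(meshgat:::stratified_split(rep("benign", 10),
                                          c(train = .7, validation = .15,
                                            test = .15), 1),
               "both classes")
})

test_that("evaluation metrics match their formulas and identities", {
  r <- evaluate_metrics(tp = 46, fp = 1, tn = 105, fn = 0)
  expect_equal(r$metrics[["precision"]], 100 * 46 / 47, tolerance = 1e-9)
  expect_equal(r$metrics[["sensitivity"]], 100)
  expect_equal(r$metrics[["fnr"]], 0)
  expect_equal(r$metrics[["npv"]], 100)

  perfect <- evaluate_metrics(tp = 10, tn = 20, fp = 0, fn = 0)
  expect_equal(perfect$metrics[["accuracy"]], 100)
  expect_equal(perfect$metrics[["f1"]], 100)
  expect_equal(perfect$metrics[["mcc"]], 100)

  # undefined ratios surface as NA, not silent zeros
  r0 <- evaluate_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(r0$metrics[["precision"]]))
  expect_true(r0$mcc_undefined)
  expect_identical(r0$metrics[["mcc"]], 0)

  set.seed(77)
  for (i in 1:1000) {
    cm <- sample.int(50, 4, replace = TRUE)  # strictly positive counts
    m <- evaluate_metrics(cm[1], cm[2], cm[3], cm[4])$metrics
    expect_equal(m[["sensitivity"]] + m[["fnr"]], 100, tolerance = 1e-9)
    expect_equal(m[["specificity"]] + m[["fpr"]], 100, tolerance = 1e-9)
    expect_equal(m[["precision"]] + m[["fdr"]], 100, tolerance = 1e-9)
    expect_true(m[["mcc"]] >= -100 - 1e-9 && m[["mcc"]] <= 100 + 1e-9)
  }
})

test_that("k-fold CV partitions nodes exactly and is seeded", {
  ds <- make_dataset(24, 12, separation = 1, seed = 41)
  tab <- build_feature_table(ds$meshes, ds$labels)
  g <- build_graph(tab, 0.7, standardize = TRUE)
  cfg <- gat_config(attention_layers = 1L, heads = 2L, hidden_units = 8L,
                    learning_rate = 5e-3, epochs = 30L, batch_size = 16L,
                    seed = 7)
  cv <- kfold_cv(tab, g, cfg, k = 3L)
  expect_length(cv$fold_accuracy, 3L)
  expect_identical(sort(unique(cv$folds)), 1:3)
  expect_identical(length(cv$folds), 36L)
  expect_equal(cv$mean, mean(cv$fold_accuracy))
  cv2 <- kfold_cv(tab, g, cfg, k = 3L)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(tab, g, cfg, k = 20L), "smallest class")
})

test_that("the ablation grid evaluates each axis and fixes the winner", {
  ds <- make_dataset(20, 12, separation = 1, seed = 51)
  tab <- build_feature_table(ds$meshes, ds$labels)
  g <- build_graph(tab, 0.7, standardize = TRUE)
  base <- gat_config(attention_layers = 1L, heads = 2L, hidden_units = 8L,
                     learning_rate = 5e-3, epochs = 20L, batch_size = 16L,
                     seed = 5)
  ab <- ablation_grid(tab, g, list(activation = c("relu", "tanh"),
                                   heads = c(2, 4)), base)
  expect_identical(nrow(ab$results), 4L)
  expect_identical(unique(ab$results$stage), c(1L, 2L))
  expect_true(ab$winner$activation %in% c("relu", "tanh"))
  best_act <- ab$results[ab$results$stage == 1, ]
  expect_identical(ab$winner$activation,
                   best_act$value[which.max(best_act$test_accuracy)])
  expect_warning(ablation_grid(tab, g, list(activation = character(0)), base),
                 "empty axis")
})
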