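test_that("parameter allocation follows the sparse architecture", {
  expect_identical(n_params(make_topology(1, 1)), 4L)
  expect_identical(n_params(make_topology(5, 2)), 10L)
  # published scale: 18,970 variants on 9,160 genes
  expect_identical(n_params(make_topology(18970, 9160)), 37291L)
  expect_error(build_gennet(make_topology(3, 2)[0, ]), "empty")
})

test_that("forward pass computes the gene-then-logistic composition", {
  net <- build_gennet(make_topology(1, 1), init_sd = 0)
  # all-zero parameters score 0.5 for everyone
  expect_equal(predict(net, matrix(c(0, 1, 2), ncol = 1)), rep(0.5, 3))

  # closed form: weights 1, biases 0, x = 2 -> logistic(2)
  net$par$w[] <- 1; net$par$u[] <- 1
  expect_equal(predict(net, matrix(2, 1, 1)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)

  # scores only depend on variants whose gene has nonzero output weight
  tp <- make_topology(4, 2)
  net2 <- build_gennet(tp, seed = 8)
  net2$par$u[2] <- 0
  x <- matrix(0, 3, 4)
  x2 <- x; x2[, which(tp$gene_node == 1L) ] <- 2
  expect_equal(predict(net2, x), predict(net2, x2))

  # monotone in a variant's code when its path weights are positive
  net3 <- build_gennet(make_topology(2, 1), init_sd = 0)
  net3$par$w[] <- 0.5; net3$par$u[] <- 1
  scores <- predict(net3, cbind(0:2, 0))
  expect_true(all(diff(scores) > 0))

  expect_error(predict(net2, matrix(0, 2, 3)), "expects")
})

test_that("training separates a separable toy cohort deterministically", {
  toy <- make_separable(10, 4)
  fit <- train_gennet(toy$x, toy$y, make_topology(4, 2), batch_size = 4,
                      max_epochs = 200, seed = 3)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  acc <- mean((predict(fit, toy$x) >= 0.5) == (toy$y == 1))
  expect_equal(acc, 1)

  # same seed, bit-identical loss history and weights
  fit2 <- train_gennet(toy$x, toy$y, make_topology(4, 2), batch_size = 4,
                       max_epochs = 200, seed = 3)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$par, fit2$par)

  # single-class input is rejected
  expect_error(train_gennet(toy$x, rep(1, 20), make_topology(4, 2)),
               "both classes")
})

test_that("training on permuted labels gives chance-level held-out AUC", {
  cfg <- cohort_config(n_cases = 250, n_controls = 250, n_variants = 50,
                       n_genes = 20, n_causal_genes = 8, effect_sd = 1,
                       seed = 17)
  co <- simulate_cohort(cfg)
  y_perm <- withr::with_seed(99, sample(co$truth$observed_label))
  idx_train <- 1:350
  idx_test <- 351:500
  fit <- train_gennet(co$genotypes[idx_train, ], y_perm[idx_train],
                      co$topology, max_epochs = 40, seed = 21)
  auc <- compute_auc(predict(fit, co$genotypes[idx_test, ]),
                     y_perm[idx_test])
  expect_lt(abs(auc - 0.5), 0.12)
})

test_that("early stopping on validation loss restores the best weights", {
  cfg <- cohort_config(n_cases = 120, n_controls = 120, n_variants = 40,
                       n_genes = 10, n_causal_genes = 5, effect_sd = 1,
                       seed = 23)
  co <- simulate_cohort(cfg)
  sp <- stratified_split(co$truth$observed_label, seed = 2)
  fit <- train_gennet(co$genotypes[sp$train, ],
                      co$truth$observed_label[sp$train], co$topology,
                      validation = list(
                        x = co$genotypes[sp$validation, ],
                        y = co$truth$observed_label[sp$validation]),
                      max_epochs = 200, patience = 5, seed = 2)
  h <- fit$history
  expect_lte(nrow(h), 200)
  # the restored weights reproduce the best recorded validation loss
  vl <- cohortsieve:::bce_loss(
    predict(fit, co$genotypes[sp$validation, ]),
    co$truth$observed_label[sp$validation])
  expect_equal(vl, min(h$val_loss, na.rm = TRUE), tolerance = 1e-10)
})

test_that("missing genotypes are resolved by the configured fill rule", {
  x <- matrix(c(NA, 1, 2, 0), 2, 2)
  tp <- make_topology(2, 1)
  net_zero <- build_gennet(tp, seed = 1)
  net_mean <- build_gennet(tp, missing_fill = "mean", seed = 1)
  x_zero <- x; x_zero[1, 1] <- 0
  x_mean <- x; x_mean[1, 1] <- 1
  expect_equal(predict(net_zero, x), predict(net_zero, x_zero))
  expect_equal(predict(net_mean, x), predict(net_mean, x_mean))
})

test_that("gene importances average ensemble output weights", {
  tp <- make_topology(4, 2)
  a <- build_gennet(tp, seed = 1)
  b <- build_gennet(tp, seed = 2)
  # a single model reports its own weights
  imp1 <- gene_importances(a)
  expect_equal(stats::setNames(imp1$mean_weight, imp1$gene)[names(a$par$u)],
               a$par$u)
  # opposite weights cancel under signed means ...
  b$par$u <- -a$par$u
  imp <- gene_importances(list(a, b))
  expect_equal(imp$mean_weight, c(0, 0))
  # ... but not under the magnitude option
  impm <- gene_importances(list(a, b), magnitude = TRUE)
  expect_equal(sort(impm$mean_weight, decreasing = TRUE),
               unname(sort(abs(a$par$u), decreasing = TRUE)))
  expect_error(gene_importances(list()), "empty")

  # mismatched topologies are rejected
  d <- build_gennet(make_topology(4, 3), seed = 1)
  expect_error(gene_importances(list(a, d)), "share one topology")
})

test_that("tidy and glance expose the fitted network", {
  toy <- make_separable(6, 4)
  fit <- train_gennet(toy$x, toy$y, make_topology(4, 2), batch_size = 4,
                      max_epochs = 10, seed = 5)
  td <- tidy(fit)
  expect_identical(nrow(td), n_params(fit))
  expect_setequal(unique(td$layer),
                  c("variant", "gene_bias", "gene_output", "output_bias"))
  gl <- glance(fit)
  expect_identical(gl$epochs, 10L)
  expect_identical(gl$n_params, 9L)
})
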