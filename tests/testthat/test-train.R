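# Cross-validation protocol, training contracts and hyperparameter search.

separable_source <- function(n = 300, g = 20, seed = 31) {
  set.seed(seed)
  X <- matrix(rnorm(n * g), n, g,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:g)))
  y <- rbinom(n, 1, 0.4)
  X[, 1:5] <- X[, 1:5] + 4 * y
  list(X = X, y = y)
}

test_that("cv splits partition, stratify and are seed-deterministic", {
  sp <- make_cv_splits(10, 5, seed = 1)
  held <- lapply(sp, `[[`, "heldout")
  expect_identical(sort(unlist(held)), 1:10)
  expect_true(all(lengths(held) == 2))
  for (f in sp) expect_length(intersect(f$train, f$heldout), 0)

  labels <- c(rep(1, 6), rep(0, 4))
  sp2 <- make_cv_splits(10, 5, labels = labels, seed = 2)
  for (f in sp2) {
    held_y <- labels[f$heldout]
    expect_lte(abs(sum(held_y == 1) - 6 / 5), 1)
    expect_lte(abs(sum(held_y == 0) - 4 / 5), 1)
  }
  expect_identical(make_cv_splits(30, 5, seed = 9),
                   make_cv_splits(30, 5, seed = 9))
})

test_that("lambda 0 reduces exactly to the baseline trainer", {
  st <- small_study()
  a <- adda(st$source, st$y_source, st$target, h_dim = 8, z_dim = 4,
            lambda = 0, epochs = 2, seed = 5)
  b <- adda_baseline(st$source, st$y_source, h_dim = 8, z_dim = 4,
                     epochs = 2, seed = 5)
  expect_identical(coef(a), coef(b))
  expect_null(a$discriminator)
})

test_that("source-validation AUC approaches 1 on separable data within 40 epochs", {
  d <- separable_source()
  val <- 251:300
  fit <- adda(d$X[-val, ], d$y[-val], NULL, h_dim = 64, z_dim = 32, lambda = 0,
              epochs = 40, learning_rate = 3e-3,
              validation = list(x = d$X[val, ], y = d$y[val]),
              seed = 4)
  expect_true(all(is.finite(fit$history$loss_bce)))
  expect_gte(tail(fit$history$val_auc, 1), 0.95)
})

test_that("target labels cannot influence training (leakage guard)", {
  st <- small_study()
  run <- function(y_target) {
    cross_validate(st$source, st$y_source, st$target, y_target,
                   cv_folds = 2, n_seeds = 1, seed = 77, return_models = TRUE,
                   h_dim = 8, z_dim = 4, epochs = 2)
  }
  r1 <- run(st$y_target)
  set.seed(1)
  r2 <- run(sample(st$y_target))
  m1 <- attr(r1, "models"); m2 <- attr(r2, "models")
  for (i in seq_along(m1)) expect_identical(coef(m1[[i]]), coef(m2[[i]]))
  # ... while the evaluation itself does change
  expect_false(isTRUE(all.equal(r1$cells$auc, r2$cells$auc)))
})

test_that("five folds by five seeds yield exactly 25 metric cells", {
  st <- small_study()
  rep <- cross_validate(st$source, st$y_source, st$target, st$y_target,
                        cv_folds = 5, n_seeds = 5, seed = 3,
                        h_dim = 6, z_dim = 3, epochs = 1)
  expect_identical(nrow(rep$cells), 25L)
  expect_true(all(rep$cells$auc >= 0 & rep$cells$auc <= 1, na.rm = TRUE))
  expect_equal(rep$summary$mean[1], mean(rep$cells$auc, na.rm = TRUE))
})

test_that("grid search picks the dominant configuration without target labels", {
  d <- separable_source(n = 240)
  tgt <- matrix(rnorm(40 * 20), 40, 20,
                dimnames = list(paste0("t", 1:40), paste0("g", 1:20)))
  # learning_rate 0 freezes training at random initialisation, so those
  # configurations produce random validation scores
  grid <- data.frame(h_dim = c(64, 64, 32), z_dim = c(32, 32, 16),
                     learning_rate = c(0, 3e-3, 0))
  gs <- grid_search(d$X, d$y, tgt, grid, cv_folds = 2, seed = 6,
                    lambda = 0, epochs = 40)
  expect_equal(gs$best$learning_rate, 3e-3)
  expect_identical(which.max(gs$results$val_auc), 2L)
  gs2 <- grid_search(d$X, d$y, tgt, grid, cv_folds = 2, seed = 6,
                     lambda = 0, epochs = 40)
  expect_identical(gs$results$val_auc, gs2$results$val_auc)
  one <- grid_search(d$X, d$y, tgt, data.frame(h_dim = 8, z_dim = 4),
                     cv_folds = 2, seed = 1, lambda = 0, epochs = 2)
  expect_equal(one$best$h_dim, 8)
})

test_that("training history is finite and recorded per epoch", {
  st <- small_study()
  h <- st$fit$history
  expect_identical(nrow(h), as.integer(st$fit$config$epochs))
  expect_true(all(is.finite(h$loss_bce)))
  expect_true(all(is.finite(h$loss_adv)))
})
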