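# Network construction, inference contracts and loss functions.

test_that("initialisation and eval-mode inference are deterministic, outputs in (0,1)", {
  st <- small_study()
  f1 <- adda(st$source, st$y_source, st$target, h_dim = 8, z_dim = 4,
             epochs = 2, seed = 33)
  f2 <- adda(st$source, st$y_source, st$target, h_dim = 8, z_dim = 4,
             epochs = 2, seed = 33)
  expect_identical(coef(f1), coef(f2))

  p1 <- predict(f1, st$target)
  p2 <- predict(f1, st$target)
  expect_identical(p1, p2)                       # dropout off at inference
  expect_true(all(p1 > 0 & p1 < 1))
  d <- predict(f1, st$target, type = "domain")
  expect_true(all(d > 0 & d < 1))
})

test_that("the extractor maps n x genes to n x z_dim and rejects mismatches", {
  st <- small_study()
  Z <- predict(st$fit, st$target, type = "latent")
  expect_identical(dim(Z), c(nrow(st$target), as.integer(st$fit$config$z_dim)))
  expect_true(all(is.finite(Z)))
  zero <- matrix(0, 1, ncol(st$target), dimnames = list("z", colnames(st$target)))
  expect_true(all(is.finite(predict(st$fit, zero, type = "latent"))))
  expect_error(predict(st$fit, st$target[, 1:5]), "genes")
})

test_that("bce loss matches closed forms and an elementwise oracle", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5), reduction = "sum"), 2 * log(2))
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  set.seed(4)
  y <- rbinom(50, 1, 0.4)
  p <- runif(50, 0.01, 0.99)
  manual <- -sum(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce_loss(y, p, reduction = "sum"), manual)
  expect_equal(bce_loss(y, p), manual / 50)
  w <- runif(50)
  manual_w <- -mean((w / mean(w)) * (y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(bce_loss(y, p, weights = w), manual_w)
})

test_that("adversarial loss closed forms and identity with domain-labelled bce", {
  ns <- 7; nt <- 5
  expect_lt(adv_loss(rep(1 - 1e-7, ns), rep(1e-7, nt), reduction = "sum"), 1e-5)
  expect_equal(adv_loss(rep(0.5, ns), rep(0.5, nt), reduction = "sum"),
               (ns + nt) * log(2))
  set.seed(8)
  ds <- runif(ns); dt <- runif(nt)
  expect_equal(adv_loss(ds, dt),
               bce_loss(c(rep(1, ns), rep(0, nt)), c(ds, dt)))
  expect_equal(adv_loss(ds, dt, flip = TRUE),
               bce_loss(c(rep(0, ns), rep(1, nt)), c(ds, dt)))
})

test_that("total loss is bce at lambda 0 and linear in lambda", {
  expect_equal(total_loss(1.3, 0.7, 0), 1.3)
  expect_equal(total_loss(1.3, 0, 1), 1.3)
  l1 <- total_loss(1, 2, 0.5); l2 <- total_loss(1, 2, 1.0)
  expect_equal(l2 - l1, 0.5 * 2)
  expect_error(total_loss(1, 1, -1), ">= 0")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(1)
  g <- 6; b <- 4
  M <- drugadda:::mlp_init(c(g, 5, 3))
  P <- drugadda:::mlp_init(c(3, 3, 1), head = "sigmoid")
  xs <- matrix(rnorm(b * g), b, g)
  ys <- c(1, 0, 1, 0)
  loss_of <- function(M) {
    p <- drugadda:::mlp_forward(P, drugadda:::mlp_forward(M, xs)$out)$out
    bce_loss(ys, as.numeric(p))
  }
  fm <- drugadda:::mlp_forward(M, xs)
  fp <- drugadda:::mlp_forward(P, fm$out)
  phat <- as.numeric(fp$out)
  gp <- drugadda:::mlp_backward(P, fp$caches, matrix((phat - ys) / b))
  gm <- drugadda:::mlp_backward(M, fm$caches, gp$dX)
  eps <- 1e-6
  for (i in 1:2) {
    for (j in sample(length(M$W[[i]]), 4)) {
      Mp <- M; Mp$W[[i]][j] <- Mp$W[[i]][j] + eps
      Mm <- M; Mm$W[[i]][j] <- Mm$W[[i]][j] - eps
      num <- (loss_of(Mp) - loss_of(Mm)) / (2 * eps)
      expect_equal(gm$gW[[i]][j], num, tolerance = 1e-5)
    }
  }
})

test_that("a model fitted on constant inputs converges to the class prior", {
  n <- 60
  X <- matrix(0, n, 3, dimnames = list(paste0("s", 1:n), c("a", "b", "c")))
  y <- c(rep(1, 18), rep(0, 42))        # prior 0.3
  fit <- adda(X, y, NULL, h_dim = 4, z_dim = 2, lambda = 0, epochs = 300,
              dropout = 0, sampling = "none", learning_rate = 1e-2, seed = 2)
  expect_equal(mean(predict(fit, X)), 0.3, tolerance = 0.05)
})

test_that("checkpoints reload to an identical model", {
  st <- small_study()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st$fit, path)
  back <- load_checkpoint(path)
  expect_identical(coef(back), coef(st$fit))
  expect_identical(predict(back, st$target), predict(st$fit, st$target))
})
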