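# Adversarial discriminative domain adaptation for drug-response transfer.
#
# Three networks are trained jointly:
#   * a feature extractor M (n_genes -> h_dim -> z_dim MLP) shared by both
#     domains,
#   * a drug-response predictor P (five affine layers of width z_dim, sigmoid
#     head) trained on labelled source samples only,
#   * a domain discriminator D (five affine layers of width h_dim on the
#     latent space, sigmoid head) trained to tell source from target.
# Updates alternate per mini-batch: D minimises the domain cross-entropy with
# extractor outputs detached; then M and P minimise the source classification
# loss plus lambda times the label-flipped domain loss, which pushes the
# latent representation towards domain invariance. With lambda = 0 the
# discriminator is never built or updated and the fit reduces exactly to a
# plain source-only classifier (the non-adapted baseline).

#' Fit an adversarial domain-adaptation drug-response model
#'
#' Trains a drug-sensitivity classifier on labelled source-domain (bulk)
#' expression and adapts its feature representation to an unlabelled
#' target-domain (single-cell) expression matrix through a domain
#' discriminator. Target labels are never an input: the target matrix is used
#' only unlabelled, so evaluation labels cannot leak into training.
#'
#' @param x_source Numeric samples x genes matrix of (z-scored) source
#'   expression.
#' @param y_source Binary response labels for the source rows: a 0/1 vector or
#'   a [response_labels()] table matched by sample id (1 = sensitive).
#' @param x_target Optional unlabelled target samples x genes matrix with the
#'   same gene columns; required when `lambda > 0`.
#' @param h_dim Width of the extractor hidden layer and the discriminator
#'   layers (default 128).
#' @param z_dim Latent dimension and predictor layer width (default 64).
#' @param lambda Non-negative weight of the adversarial term (default 0.3, a
#'   conservative weight that keeps the classification signal dominant;
#'   0 disables adaptation; tune per dataset with [grid_search()]).
#' @param epochs Training epochs (default 40).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param dropout Dropout rate between layers (default 0.5).
#' @param sampling Class-rebalancing mode for the imbalanced source labels:
#'   `"weight"` (inverse-frequency resampling per epoch, default), `"smote"`
#'   (synthetic minority oversampling of the training matrix), or `"none"`.
#' @param smote_k Nearest-neighbour count for SMOTE.
#' @param adv_mode Adversarial objective for the extractor: `"target"`
#'   (inverted-label objective over target batches only, default) or `"both"`
#'   (symmetric label-flipped objective over both domains).
#' @param d_dropout Dropout rate inside the discriminator (default 0; the
#'   adversarial gradient is cleaner without it).
#' @param d_lr_mult Learning-rate multiplier for the discriminator.
#' @param adv_batch_mult Integer factor enlarging the batches used for the
#'   adversarial passes (averages away adversarial gradient noise; default 1,
#'   matching the source batch size).
#' @param d_dim Discriminator hidden width; defaults to `h_dim`.
#' @param validation Optional list `list(x = , y = )` of held-out source
#'   samples; per-epoch validation AUC is recorded in the history.
#' @param seed Integer seed controlling initialisation, batching, dropout and
#'   SMOTE; fits are bit-reproducible under a fixed seed.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"adda"` with components `extractor`,
#'   `predictor`, `discriminator` (NULL when `lambda = 0`), `genes`, `config`
#'   and `history` (per-epoch data.frame of mean batch losses and validation
#'   AUC).
#' @seealso [predict.adda()], [cross_validate()], [integrated_gradients()]
#' @export
#' @examples
#' sim <- simulate_domain_pair(sim_config(n_genes = 60, n_source = 80,
#'                                        n_target = 60, seed = 7))
#' fit <- adda(sim$source$matrix, sim$source$labels,
#'             sim$target$matrix, h_dim = 16, z_dim = 8,
#'             epochs = 3, seed = 7)
#' head(predict(fit, sim$target$matrix))
adda <- function(x_source, y_source, x_target = NULL,
                 h_dim = 128L, z_dim = 64L, lambda = 0.3,
                 epochs = 40L, batch_size = 32L, learning_rate = 1e-3,
                 dropout = 0.5,
                 sampling = c("weight", "smote", "none"), smote_k = 5L,
                 adv_mode = c("target", "both"), d_dropout = 0,
                 d_lr_mult = 1, adv_batch_mult = 1L, d_dim = NULL,
                 validation = NULL, seed = 1L, verbose = FALSE) {
  adv_mode <- match.arg(adv_mode)
  sampling <- match.arg(sampling)
  stopifnot(h_dim >= 1, z_dim >= 1, lambda >= 0, epochs >= 1,
            batch_size >= 1, dropout >= 0, dropout < 1)
  x_source <- as.matrix(x_source)
  if (inherits(y_source, "response_labels")) {
    y <- align_labels(x_source, y_source)
  } else {
    y <- as.numeric(y_source)
  }
  if (length(y) != nrow(x_source)) stopf("y_source length must match rows")
  if (anyNA(y) || !all(y %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(y)) < 2) stopf("source labels must contain both classes")
  adapt <- lambda > 0
  if (adapt) {
    if (is.null(x_target)) stopf("x_target is required when lambda > 0")
    x_target <- as.matrix(x_target)
    if (!identical(colnames(x_source), colnames(x_target))) {
      stopf("source and target gene columns must match; run intersect_genes()")
    }
  }
  g <- ncol(x_source)

  with_seed(seed, {
    extractor <- mlp_init(c(g, h_dim, z_dim), head = "identity")
    predictor <- mlp_init(c(z_dim, rep(z_dim, 4L), 1L), head = "sigmoid")
    if (is.null(d_dim)) d_dim <- h_dim
    discriminator <- if (adapt) {
      mlp_init(c(z_dim, rep(d_dim, 4L), 1L), head = "sigmoid")
    }
    opt_m <- adam_init(extractor)
    opt_p <- adam_init(predictor)
    opt_d <- if (adapt) adam_init(discriminator)

    Xtr <- x_source
    ytr <- y
    if (sampling == "smote") {
      sm <- smote_oversample(Xtr, ytr, k = smote_k,
                             seed = sample.int(.Machine$integer.max - 1L, 1L))
      Xtr <- sm$X
      ytr <- sm$y
    }
    w <- if (sampling == "weight") balanced_sample_weights(ytr)
    n <- nrow(Xtr)
    n_batches <- ceiling(n / batch_size)

    history <- data.frame(epoch = seq_len(epochs), loss_bce = NA_real_,
                          loss_adv = NA_real_, val_auc = NA_real_)

    for (ep in seq_len(epochs)) {
      # warm-up ramp on the adversarial weight: the classification signal
      # shapes the representation first, then domain alignment phases in
      lambda_ep <- if (adapt) {
        lambda * (2 / (1 + exp(-10 * ep / epochs)) - 1)
      } else 0
      idx <- if (sampling == "weight") {
        sample.int(n, n, replace = TRUE, prob = w)
      } else {
        sample.int(n)
      }
      ep_bce <- ep_adv <- 0
      for (bi in seq_len(n_batches)) {
        rows <- idx[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
        xs <- Xtr[rows, , drop = FALSE]
        ys <- ytr[rows]
        b <- length(rows)

        if (adapt) {
          ba <- b * adv_batch_mult
          xt <- x_target[sample.int(nrow(x_target), ba, replace = TRUE), ,
                         drop = FALSE]
          xsa <- if (adv_batch_mult > 1L) {
            Xtr[sample.int(n, ba, replace = TRUE,
                           prob = if (sampling == "weight") w), , drop = FALSE]
          } else {
            xs
          }
          # -- discriminator step (extractor outputs detached) --
          fsa <- mlp_forward(extractor, xsa, 0, train = TRUE)
          ft <- mlp_forward(extractor, xt, 0, train = TRUE)
          Z <- rbind(fsa$out, ft$out)
          fd <- mlp_forward(discriminator, Z, d_dropout, train = TRUE)
          dhat <- as.numeric(fd$out)
          dom <- c(rep(1, ba), rep(0, ba))
          l_adv <- bce_loss(dom, dhat)
          gd <- mlp_backward(discriminator, fd$caches,
                             matrix((clip01(dhat) - dom) / length(dom)))
          st <- adam_step(discriminator, gd, opt_d, learning_rate * d_lr_mult)
          discriminator <- st$net
          opt_d <- st$state
        } else {
          l_adv <- NA_real_
        }

        # -- extractor + predictor step --
        fs <- mlp_forward(extractor, xs, dropout, train = TRUE)
        fp <- mlp_forward(predictor, fs$out, dropout, train = TRUE)
        phat <- as.numeric(fp$out)
        l_bce <- bce_loss(ys, phat)
        if (!is.finite(l_bce)) {
          stopf("non-finite classification loss at epoch %d, batch %d", ep, bi)
        }
        gp <- mlp_backward(predictor, fp$caches,
                           matrix((clip01(phat) - ys) / b))
        dZs <- gp$dX
        gm_t <- NULL
        ft <- NULL
        if (adapt) {
          # inverted-label adversarial objective: the extractor is updated so
          # that target latents look like source to D (-log D(M(x_t))); the
          # source mapping stays anchored by the classification loss only
          ft <- mlp_forward(extractor, xt, 0, train = TRUE)
          nt <- nrow(xt)
          if (adv_mode == "target") {
            fd <- mlp_forward(discriminator, ft$out, d_dropout, train = TRUE)
            dhat <- as.numeric(fd$out)
            gd <- mlp_backward(discriminator, fd$caches,
                               matrix((clip01(dhat) - 1) / nt))
            dZt <- lambda_ep * gd$dX
          } else {
            Z <- rbind(fs$out, ft$out)
            fd <- mlp_forward(discriminator, Z, d_dropout, train = TRUE)
            dhat <- as.numeric(fd$out)
            flipped <- c(rep(0, b), rep(1, nt))
            gd <- mlp_backward(discriminator, fd$caches,
                               matrix((clip01(dhat) - flipped) / length(flipped)))
            dZs <- dZs + lambda_ep * gd$dX[seq_len(b), , drop = FALSE]
            dZt <- lambda_ep * gd$dX[b + seq_len(nt), , drop = FALSE]
          }
          gm_t <- mlp_backward(extractor, ft$caches, dZt)
        }
        gm <- mlp_backward(extractor, fs$caches, dZs)
        if (!is.null(gm_t)) {
          for (i in seq_along(gm$gW)) {
            gm$gW[[i]] <- gm$gW[[i]] + gm_t$gW[[i]]
            gm$gb[[i]] <- gm$gb[[i]] + gm_t$gb[[i]]
          }
        }
        st <- adam_step(extractor, gm, opt_m, learning_rate)
        extractor <- st$net
        opt_m <- st$state
        st <- adam_step(predictor, gp, opt_p, learning_rate)
        predictor <- st$net
        opt_p <- st$state

        ep_bce <- ep_bce + l_bce
        ep_adv <- ep_adv + l_adv
      }
      history$loss_bce[ep] <- ep_bce / n_batches
      history$loss_adv[ep] <- ep_adv / n_batches
      if (!is.null(validation)) {
        pv <- eval_predict(extractor, predictor, as.matrix(validation$x))
        history$val_auc[ep] <- auc(validation$y, pv)
      }
      if (verbose) {
        message(sprintf("epoch %3d  bce %.4f  adv %s  val_auc %s", ep,
                        history$loss_bce[ep],
                        formatC(history$loss_adv[ep], format = "f", digits = 4),
                        formatC(history$val_auc[ep], format = "f", digits = 3)))
      }
    }

    structure(list(extractor = extractor, predictor = predictor,
                   discriminator = discriminator,
                   genes = colnames(x_source),
                   config = list(h_dim = h_dim, z_dim = z_dim, lambda = lambda,
                                 epochs = epochs, batch_size = batch_size,
                                 learning_rate = learning_rate,
                                 dropout = dropout, sampling = sampling,
                                 smote_k = smote_k, seed = seed),
                   history = history),
              class = "adda")
  })
}

#' Fit the non-adapted baseline classifier
#'
#' Identical pipeline with the discriminator and adversarial term disabled;
#' equivalent to `adda(..., lambda = 0)`.
#'
#' @inheritParams adda
#' @param ... Further arguments passed to [adda()].
#' @return An `"adda"` object with `lambda = 0` and no discriminator.
#' @export
adda_baseline <- function(x_source, y_source, ...) {
  adda(x_source, y_source, x_target = NULL, lambda = 0, ...)
}

# Deterministic inference-mode predictor probability (dropout disabled).
eval_predict <- function(extractor, predictor, X) {
  Z <- mlp_forward(extractor, X, train = FALSE)$out
  as.numeric(mlp_forward(predictor, Z, train = FALSE)$out)
}

#' Predict from a fitted adversarial domain-adaptation model
#'
#' Inference runs in evaluation mode (dropout disabled), so predictions are
#' deterministic.
#'
#' @param object An `"adda"` fit.
#' @param newdata Samples x genes matrix with the same gene columns used at
#'   training time.
#' @param type `"response"` (sensitivity probability, default), `"latent"`
#'   (the extracted representation, samples x z_dim), or `"domain"` (the
#'   discriminator's probability that a sample comes from the source domain).
#' @param ... Unused.
#' @return Named numeric vector, or a matrix for `type = "latent"`.
#' @export
predict.adda <- function(object, newdata,
                         type = c("response", "latent", "domain"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$genes)) {
    stopf("newdata has %d genes but the model was trained on %d",
          ncol(X), length(object$genes))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), object$genes)) {
    stopf("newdata gene columns differ from the training gene order")
  }
  Z <- mlp_forward(object$extractor, X, train = FALSE)$out
  out <- switch(type,
    latent = {
      rownames(Z) <- rownames(X)
      return(Z)
    },
    response = as.numeric(mlp_forward(object$predictor, Z,
                                      train = FALSE)$out),
    domain = {
      if (is.null(object$discriminator)) {
        stopf("model was fitted with lambda = 0; no discriminator available")
      }
      as.numeric(mlp_forward(object$discriminator, Z, train = FALSE)$out)
    })
  names(out) <- rownames(X)
  out
}

#' @export
print.adda <- function(x, ...) {
  cfg <- x$config
  cat("Adversarial domain-adaptation drug-response model\n")
  cat(sprintf("  genes: %d   latent dim: %d   hidden dim: %d\n",
              length(x$genes), cfg$z_dim, cfg$h_dim))
  cat(sprintf("  lambda: %g (%s)   sampling: %s   epochs: %d\n",
              cfg$lambda,
              if (cfg$lambda > 0) "adversarial" else "baseline, no adaptation",
              cfg$sampling, cfg$epochs))
  cat(sprintf("  final training loss (BCE): %.4f\n",
              utils::tail(x$history$loss_bce, 1)))
  invisible(x)
}

#' @export
summary.adda <- function(object, ...) {
  cfg <- object$config
  np <- n_params(object$extractor) + n_params(object$predictor) +
    if (!is.null(object$discriminator)) n_params(object$discriminator) else 0
  out <- list(
    n_genes = length(object$genes),
    n_parameters = np,
    config = cfg,
    final_loss_bce = utils::tail(object$history$loss_bce, 1),
    final_loss_adv = utils::tail(object$history$loss_adv, 1),
    final_val_auc = utils::tail(object$history$val_auc, 1)
  )
  class(out) <- "summary.adda"
  out
}

#' @export
print.summary.adda <- function(x, ...) {
  cat("Adversarial domain-adaptation model summary\n")
  cat(sprintf("  input genes          : %d\n", x$n_genes))
  cat(sprintf("  trainable parameters : %d\n", x$n_parameters))
  cat(sprintf("  adversarial weight   : %g\n", x$config$lambda))
  cat(sprintf("  final BCE loss       : %.4f\n", x$final_loss_bce))
  if (is.finite(x$final_loss_adv %||% NA)) {
    cat(sprintf("  final domain loss    : %.4f\n", x$final_loss_adv))
  }
  if (is.finite(x$final_val_auc %||% NA)) {
    cat(sprintf("  final validation AUC : %.3f\n", x$final_val_auc))
  }
  invisible(x)
}

#' Extract network weights from a fitted model
#'
#' @param object An `"adda"` fit.
#' @param ... Unused.
#' @return Named list of weight/bias lists for the extractor, predictor and
#'   (when present) discriminator.
#' @export
coef.adda <- function(object, ...) {
  out <- list(extractor = object$extractor[c("W", "b")],
              predictor = object$predictor[c("W", "b")])
  if (!is.null(object$discriminator)) {
    out$discriminator <- object$discriminator[c("W", "b")]
  }
  out
}

#' Plot training history of a fitted model
#'
#' Shows the per-epoch source classification loss, the domain-discriminator
#' loss, and the source-validation AUC when it was recorded.
#'
#' @param x An `"adda"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adda <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss_bce, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$loss_bce, h$loss_adv), na.rm = TRUE, finite = TRUE),
                 ...)
  if (any(is.finite(h$loss_adv))) {
    graphics::lines(h$epoch, h$loss_adv, lty = 2)
  }
  if (any(is.finite(h$val_auc))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_auc, type = "l", col = "steelblue",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4, col = "steelblue", col.axis = "steelblue")
  }
  legend_items <- c("classification loss", "domain loss", "validation AUC")
  keep <- c(TRUE, any(is.finite(h$loss_adv)), any(is.finite(h$val_auc)))
  graphics::legend("topright", legend = legend_items[keep],
                   lty = c(1, 2, 1)[keep],
                   col = c("black", "black", "steelblue")[keep], bty = "n")
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint embeds the configuration and gene order so a reload is
#' sufficient for prediction.
#'
#' @param model An `"adda"` fit.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `"adda"` object (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "adda"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "adda")) stopf("'%s' is not a model checkpoint", path)
  model
}
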