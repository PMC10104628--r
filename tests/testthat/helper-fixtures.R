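# Shared fixtures, built in code. Heavy objects are memoised so several test
# files can reuse one small trained model without refitting.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

toy_counts <- function(values, cells = NULL, genes = NULL) {
  m <- matrix(values, byrow = TRUE,
              nrow = length(values) / length(genes), ncol = length(genes))
  dimnames(m) <- list(cells %||% paste0("c", seq_len(nrow(m))), genes)
  expr_matrix(m, layer = "raw_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small paired study plus a fitted model, reused across test files.
small_study <- function() {
  memo("small_study", function() {
    cfg <- sim_config(n_genes = 100, n_signal_genes = 15, n_source = 120,
                      n_target = 90, seed = 42)
    sim <- simulate_domain_pair(cfg)
    src <- zscore_genes(sim$source$matrix)
    tgt <- preprocess_target(sim$target$matrix)$matrix
    shared <- intersect_genes(src, tgt)
    y_src <- drugadda:::align_labels(shared$source, sim$source$labels)
    y_tgt <- drugadda:::align_labels(shared$target, sim$target$labels)
    fit <- adda(shared$source, y_src, shared$target,
                h_dim = 24, z_dim = 12, epochs = 8, seed = 7)
    list(cfg = cfg, sim = sim, source = shared$source, target = shared$target,
         y_source = y_src, y_target = y_tgt, fit = fit)
  })
}

# Hand-built model realising F(x) = sigmoid(w . x) exactly: the first
# extractor layer splits x into (relu(x), relu(-x)) so every later ReLU acts
# on non-negative values and the network is linear end to end.
logistic_linear_model <- function(w) {
  g <- length(w)
  extractor <- drugadda:::mlp_init(c(g, 2 * g, 2 * g), head = "identity")
  extractor$W[[1]] <- cbind(diag(g), -diag(g))
  extractor$b[[1]] <- numeric(2 * g)
  extractor$W[[2]] <- diag(2 * g)
  extractor$b[[2]] <- numeric(2 * g)
  predictor <- drugadda:::mlp_init(c(2 * g, 2 * g, 1), head = "sigmoid")
  predictor$W[[1]] <- diag(2 * g)
  predictor$b[[1]] <- numeric(2 * g)
  predictor$W[[2]] <- matrix(c(w, -w), ncol = 1)
  predictor$b[[2]] <- 0
  structure(list(extractor = extractor, predictor = predictor,
                 discriminator = NULL, genes = paste0("g", seq_len(g)),
                 config = list(lambda = 0), history = data.frame()),
            class = "adda")
}

# Brute-force pair-counting AUC oracle (ties count 1/2).
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Average precision oracle for distinct scores: mean over positives of the
# precision at each positive's rank.
aupr_oracle_distinct <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  if (!sum(y)) return(NA_real_)
  ranks <- which(y == 1)
  mean(vapply(ranks, function(k) sum(y[1:k]) / k, numeric(1)))
}

# Exact two-sided Fisher p oracle: enumerate all tables with the observed
# margins, probabilities from the binomial-coefficient form.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_; N <- m + n2
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(N, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(N, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
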