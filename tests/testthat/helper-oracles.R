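# Independent brute-force oracles and tiny fixtures shared across tests.
# These deliberately avoid the package's own code paths wherever they act
# as the second route of a dual-route check.

random_dna <- function(len, with_n = FALSE) {
  ab <- c("A", "C", "G", "T")
  pr <- rep(0.25, 4)
  if (with_n) { ab <- c(ab, "N"); pr <- c(rep(0.24, 4), 0.04) }
  paste(sample(ab, len, replace = TRUE, prob = pr), collapse = "")
}

# O(N*F*K) sliding dot product, scalar loops only
bf_convolve <- function(X, W) {
  n <- nrow(X); f <- dim(W)[1]; k <- dim(W)[3]
  r <- n - f + 1L
  Y <- matrix(0, r, k)
  for (kk in seq_len(k))
    for (rr in seq_len(r))
      for (ii in seq_len(f))
        for (jj in 1:4)
          Y[rr, kk] <- Y[rr, kk] + W[ii, jj, kk] * X[rr + ii - 1L, jj]
  Y
}

# O(P*N) pair-counting AUC with ties counted 1/2
bf_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# brute-force recall at FDR: sweep every distinct score as threshold
bf_recall_at_fdr <- function(scores, labels, q) {
  P <- sum(labels == 1)
  best <- 0
  for (t in unique(scores)) {
    called <- scores >= t
    tp <- sum(labels[called] == 1)
    fp <- sum(called) - tp
    if (sum(called) > 0 && fp / sum(called) <= q)
      best <- max(best, tp / P)
  }
  best
}

# brute-force dinucleotide counts via substring extraction
bf_dinuc_counts <- function(seq) {
  n <- nchar(seq)
  di <- substring(seq, 1:(n - 1), 2:n)
  nm <- paste0(rep(c("A", "C", "G", "T"), each = 4), rep(c("A", "C", "G", "T"), 4))
  table(factor(di, levels = nm))
}

# exhaustive maximum coverage-preserving holdout size on a small combo set
bf_max_holdout <- function(combos) {
  n <- nrow(combos)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)   # base indices
    if (!length(keep)) next
    if (all(combos$tf %in% combos$tf[keep]) &&
        all(combos$cell %in% combos$cell[keep]))
      best <- max(best, n - length(keep))
  }
  best
}

# minimum Hamming distance of `motif` (or its reverse complement) to any
# window of seq, by direct string comparison
bf_min_hamming <- function(seq, motif) {
  L <- nchar(motif)
  n <- nchar(seq)
  best <- L
  for (m in c(motif, reverse_complement(motif))) {
    mm <- strsplit(m, "")[[1]]
    for (r in 1:(n - L + 1)) {
      w <- strsplit(substr(seq, r, r + L - 1), "")[[1]]
      best <- min(best, sum(w != mm))
    }
  }
  best
}

# a small generic model for forward-pass tests: randomized (not sd-0.01)
# parameters so degeneracies are unlikely
tiny_model <- function(tfs = c("T1", "T2"), cells = c("C1", "C2"),
                       seq_length = 30L, filter_length = 5L,
                       num_filters = 3L, pool_window = 10L, fc_size = 4L,
                       embed_dim = 3L, relu_mode = "literal", sd = 0.3) {
  cfg <- model_config(tfs, cells, seq_length = seq_length,
                      filter_length = filter_length,
                      num_filters = num_filters, pool_window = pool_window,
                      fc_size = fc_size, embed_dim = embed_dim,
                      relu_mode = relu_mode)
  p <- init_parameters(cfg)
  p <- lapply(p, function(x) { x[] <- rnorm(length(x), 0, sd); x })
  p$E_tf <- matrix(rnorm(length(tfs) * embed_dim, 0, sd), length(tfs),
                   dimnames = list(tfs, NULL))
  p$E_cell <- matrix(rnorm(length(cells) * embed_dim, 0, sd), length(cells),
                     dimnames = list(cells, NULL))
  p$b <- rnorm(num_filters, -1)
  class(p) <- "tfgate_params"
  list(params = p, config = cfg)
}

# numeric finite-difference gradient check for the main model; returns the
# worst relative error across all parameter groups
fd_gradient_check <- function(relu_mode, seed = 99L, B = 5L) {
  set.seed(seed)
  tm <- tiny_model(seq_length = 30L, filter_length = 5L, num_filters = 3L,
                   pool_window = 10L, fc_size = 4L, embed_dim = 3L,
                   relu_mode = relu_mode)
  p <- tm$params; cfg <- tm$config
  codes <- matrix(sample(0:4, B * 30L, TRUE, prob = c(.04, rep(.24, 4))), B, 30L)
  ti <- sample(1:2, B, TRUE); ci <- sample(1:2, B, TRUE)
  lab <- sample(0:1, B, TRUE)
  lossfn <- function(pp)
    tfgate:::bce_loss(tfgate:::forward_batch(codes, ti, ci, pp, cfg,
                                             want_cache = FALSE)$score, lab)$loss
  fw <- tfgate:::forward_batch(codes, ti, ci, p, cfg)
  gr <- tfgate:::backward_batch(tfgate:::bce_loss(fw$score, lab)$dscore,
                                fw, p, cfg)
  h <- 1e-6
  worst <- 0
  for (nm in names(gr)) {
    for (i in seq_along(p[[nm]])) {
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + h; f1 <- lossfn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h; f0 <- lossfn(pp)
      num <- (f1 - f0) / (2 * h)
      worst <- max(worst, abs(num - gr[[nm]][i]) /
                     max(abs(num), abs(gr[[nm]][i]), 1e-6))
    }
  }
  worst
}
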