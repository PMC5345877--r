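test_that("architecture geometry matches the published configurations", {
  dhs <- model_config(c("T1"), c("C1"))   # defaults: N=300, F=20, pool 100
  g <- model_geometry(dhs)
  expect_equal(g$conv_positions, 281L)
  expect_equal(g$num_windows, 3L)
  rb <- model_config(c("T1"), c("C1"), seq_length = 100L, num_filters = 600L)
  expect_equal(model_geometry(rb)$num_windows, 1L)
  expect_equal(length(embed_pair("T1", "C1", init_parameters(dhs))), 100L)
})

test_that("init_parameters follows the stated initialization", {
  set.seed(31)
  cfg <- model_config(c("T1", "T2"), c("C1"), seq_length = 60L,
                      filter_length = 20L, num_filters = 150L,
                      pool_window = 20L, fc_size = 10L)
  p <- init_parameters(cfg)
  expect_true(all(p$b == -4))
  expect_true(all(p$b1 == 0))
  expect_true(all(p$b2 == 0))
  expect_equal(dim(p$W), c(20L, 4L, 150L))
  # 150*20*4 = 12,000 draws: sample sd within 20% of 0.01
  expect_lt(abs(sd(p$W) - 0.01) / 0.01, 0.2)
  expect_lt(abs(mean(p$W)), 0.001)
})

test_that("convolve_onehot agrees with the brute-force oracle", {
  # hand example: X = one-hot("AC"), filter W[1,A]=1, W[2,C]=1 -> Y = [2]
  W <- array(0, c(2, 4, 1), dimnames = list(NULL, c("A", "C", "G", "T"), NULL))
  W[1, "A", 1] <- 1; W[2, "C", 1] <- 1
  expect_equal(convolve_onehot(one_hot_encode("AC"), W),
               matrix(2, 1, 1))
  # all-zero filter -> all-zero map
  expect_true(all(convolve_onehot(one_hot_encode("ACGTAC"),
                                  array(0, c(3, 4, 2))) == 0))
  expect_error(convolve_onehot(one_hot_encode("AC"), array(0, c(5, 4, 1))),
               "shorter")
  set.seed(32)
  for (i in 1:30) {
    n <- sample(6:40, 1); f <- sample(2:5, 1); k <- sample(1:4, 1)
    X <- one_hot_encode(random_dna(n, with_n = TRUE))
    W <- array(rnorm(f * 4 * k), c(f, 4, k))
    expect_lt(max(abs(convolve_onehot(X, W) - bf_convolve(X, W))), 1e-6)
  }
})

test_that("thresholded_relu implements both printed and shifted forms", {
  expect_equal(thresholded_relu(5, 2), 5)
  expect_equal(thresholded_relu(1, 2), 0)
  expect_equal(thresholded_relu(-3, -4), -3)     # literal passes negatives
  expect_equal(thresholded_relu(-3, -4, mode = "shifted"), 1)
  expect_equal(thresholded_relu(-5, -4, mode = "shifted"), 0)
})

test_that("max_pool partitions into non-overlapping windows", {
  Z <- matrix(seq_len(281 * 2), 281, 2)
  P <- max_pool(Z, 100)
  expect_equal(dim(P), c(3L, 2L))
  expect_equal(P[, 1], c(100, 200, 281))       # last window truncated
  expect_equal(dim(max_pool(matrix(0, 81, 5), 100)), c(1L, 5L))
  cst <- max_pool(matrix(7, 30, 3), 10)
  expect_true(all(cst == 7))
})

test_that("embedding lookup concatenates TF first and validates names", {
  set.seed(33)
  tm <- tiny_model(embed_dim = 4L)
  e <- embed_pair("T2", "C1", tm$params)
  expect_equal(e, c(tm$params$E_tf["T2", ], tm$params$E_cell["C1", ]))
  expect_error(embed_pair("T9", "C1", tm$params), "unknown TF")
  expect_error(embed_pair("T1", "HeLa", tm$params), "cell line")
  zp <- tm$params
  zp$E_tf[] <- 0; zp$E_cell[] <- 0
  expect_true(all(embed_pair("T1", "C2", zp) == 0))
})

test_that("compute_gates is the sigmoid of the affine map", {
  expect_equal(compute_gates(c(1, 2), matrix(0, 3, 2), rep(0, 3)),
               rep(0.5, 3))
  set.seed(34)
  W1 <- matrix(rnorm(4), 2, 2); b1 <- rnorm(2); e <- rnorm(2)
  g <- compute_gates(e, W1, b1)
  expect_equal(g, 1 / (1 + exp(-(W1 %*% e + b1)))[, 1])
  expect_true(all(g > 0 & g < 1))
})

test_that("strand_score equals an independently assembled pipeline", {
  set.seed(35)
  tm <- tiny_model(seq_length = 25L, filter_length = 4L, num_filters = 3L,
                   pool_window = 10L, fc_size = 2L, embed_dim = 2L)
  p <- tm$params; cfg <- tm$config
  s <- random_dna(25)
  # oracle: plain matrix arithmetic, no package internals
  X <- one_hot_encode(s)
  Y <- bf_convolve(X, p$W)
  Z <- Y * (Y > matrix(p$b, nrow(Y), 3, byrow = TRUE))
  P <- rbind(apply(Z[1:10, , drop = FALSE], 2, max),
             apply(Z[11:20, , drop = FALSE], 2, max),
             apply(Z[21:22, , drop = FALSE], 2, max))
  e <- c(p$E_tf["T1", ], p$E_cell["C2", ])
  G <- 1 / (1 + exp(-(p$W1 %*% e + p$b1)))[, 1]
  M <- sweep(P, 2, G, `*`)
  expected <- max(p$W2 %*% as.vector(t(M)) + p$b2)
  expect_equal(strand_score(s, "T1", "C2", p, cfg), expected)
  # all-zero parameters except b2 = c -> score c
  zp <- lapply(p, function(x) { x[] <- 0; x })
  class(zp) <- "tfgate_params"
  zp$b2 <- rep(1.7, 2)
  expect_equal(strand_score(s, "T1", "C1", zp, cfg), 1.7)
  expect_error(strand_score("ACGT", "T1", "C1", p, cfg), "length")
})

test_that("prediction is strand-symmetric and batched = single-instance", {
  set.seed(36)
  tm <- tiny_model()
  seqs <- replicate(20, random_dna(30, with_n = TRUE))
  tfs <- sample(c("T1", "T2"), 20, TRUE)
  cells <- sample(c("C1", "C2"), 20, TRUE)
  single <- mapply(function(s, t, c) predict_score(s, t, c, tm$params, tm$config),
                   seqs, tfs, cells, USE.NAMES = FALSE)
  batched <- predict_batch(seqs, tfs, cells, tm$params, tm$config,
                           type = "score")
  expect_equal(batched, single, tolerance = 1e-12)
  rc <- vapply(seqs, reverse_complement, "", USE.NAMES = FALSE)
  expect_identical(predict_batch(rc, tfs, cells, tm$params, tm$config,
                                 type = "score"), batched)
  probs <- predict_batch(seqs, tfs, cells, tm$params, tm$config)
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(probs[1], predict_prob(seqs[1], tfs[1], cells[1],
                                      tm$params, tm$config))
})

test_that("a closed gate makes the prediction ignore its filter", {
  set.seed(37)
  tm <- tiny_model(num_filters = 4L)
  p <- tm$params
  p$b1[2] <- -1e9                      # gate 2 -> sigmoid(-1e9) == 0 exactly
  p$W1[2, ] <- 0
  s <- random_dna(30)
  base <- predict_score(s, "T1", "C1", p, tm$config)
  p2 <- p
  p2$W[, , 2] <- rnorm(length(p2$W[, , 2]), 0, 5)   # perturb filter 2 wildly
  expect_identical(predict_score(s, "T1", "C1", p2, tm$config), base)
})

test_that("a log-odds filter separates planted motifs from shuffles", {
  set.seed(38)
  world <- make_world(num_tfs = 1L, num_cells = 1L, motif_length = 8L,
                      share_pwm = FALSE)
  pwm <- world$pwms[[1]]
  cfg <- model_config("TF1", "cell1", seq_length = 60L, filter_length = 8L,
                      num_filters = 1L, pool_window = 60L, fc_size = 1L,
                      embed_dim = 2L)
  p <- init_parameters(cfg)
  p$W[, , 1] <- log(pwm / matrix(world$base_probs, 8, 4, byrow = TRUE))
  p$b <- -1e6                           # pass everything
  p$W1[] <- 0; p$b1[] <- 10             # gates ~1
  p$W2[] <- 1; p$b2[] <- 0
  wins <- 0
  for (i in 1:200) {
    bg <- sample_background(1, 60, world)
    pos <- plant_motif(bg, world$consensus[[1]], sample.int(53, 1),
                       runif(1) < 0.5)
    neg <- dinucleotide_shuffle(pos)
    sp <- predict_score(pos, "TF1", "cell1", p, cfg)
    sn <- predict_score(neg, "TF1", "cell1", p, cfg)
    wins <- wins + (sp > sn)
  }
  expect_gte(wins / 200, 0.95)
})

test_that("model serialization round-trips exactly", {
  set.seed(39)
  tm <- tiny_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(tm$params, tm$config, f)
  m <- load_model(f)
  for (nm in names(tm$params))
    expect_equal(m$params[[nm]], tm$params[[nm]], tolerance = 1e-12)
  expect_equal(unclass(m$config), unclass(tm$config))
  s <- random_dna(30)
  expect_equal(predict_score(s, "T2", "C1", m$params, m$config),
               predict_score(s, "T2", "C1", tm$params, tm$config),
               tolerance = 1e-12)
})
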