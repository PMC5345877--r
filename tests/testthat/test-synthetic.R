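test_that("make_world satisfies its invariants", {
  w <- make_world(num_tfs = 8L, num_cells = 5L, motif_length = 8L,
                  activity_density = 0.7, seed = 71)
  expect_equal(length(w$pwms), 8L)
  for (pwm in w$pwms) {
    expect_equal(rowSums(pwm), rep(1, 8), tolerance = 1e-12)
    expect_true(all(apply(pwm, 1, max) >= 0.8))
  }
  expect_true(all(rowSums(w$activity) >= 1))
  expect_true(all(colSums(w$activity) >= 1))
  expect_identical(w$pwms[[1]], w$pwms[[2]])          # shared pair
  # average information content >= 1 bit per position
  ic <- vapply(w$pwms, function(pwm)
    mean(apply(pwm, 1, function(p) 2 + sum(p * log2(p)))), 0.0)
  expect_true(all(ic >= 1))
  # density 1 -> all-ones activity
  w1 <- make_world(num_tfs = 3L, num_cells = 3L, activity_density = 1,
                   seed = 72)
  expect_true(all(w1$activity == 1L))
  # reproducible bit-for-bit
  expect_identical(make_world(seed = 73), make_world(seed = 73))
})

test_that("generated positives carry the planted motif, negatives do not", {
  w <- make_world(num_tfs = 3L, num_cells = 2L, motif_length = 8L,
                  activity_density = 1, share_pwm = FALSE, seed = 74)
  set.seed(74)
  inst <- generate_instances(w, data.frame(tf = "TF1", cell = "cell1"),
                             100, 60)
  expect_equal(sum(inst$label), 50L)
  pos <- inst$seq[inst$label == 1]
  hd <- vapply(pos, bf_min_hamming, 0, motif = w$consensus[["TF1"]])
  expect_true(all(hd <= 2))
  expect_error(generate_instances(w, data.frame(tf = "TF1", cell = "cell1"),
                                  10, 6), "shorter")
  set.seed(9); a <- generate_instances(w, data.frame(tf = "TF1", cell = "cell1"), 20, 40)
  set.seed(9); b <- generate_instances(w, data.frame(tf = "TF1", cell = "cell1"), 20, 40)
  expect_identical(a, b)
})

test_that("the PWM-scan oracle calibrates active and inactive combos", {
  w <- make_world(num_tfs = 2L, num_cells = 2L, motif_length = 8L,
                  activity_density = 0.7, share_pwm = FALSE, seed = 75)
  w$activity[, ] <- matrix(c(1L, 0L, 1L, 1L), 2)     # TF2 inactive in cell1
  set.seed(75)
  scan_auc <- function(tf, cell, n) {
    inst <- generate_instances(w, data.frame(tf = tf, cell = cell), n, 60)
    s <- vapply(inst$seq, pwm_scan_score, 0.0, pwm = w$pwms[[tf]],
                base_probs = w$base_probs)
    roc_auc(data.frame(score = s, label = inst$label))
  }
  expect_gte(scan_auc("TF1", "cell1", 1000), 0.95)   # active: near-ceiling
  expect_lt(abs(scan_auc("TF2", "cell1", 1000) - 0.5), 0.05)  # inactive: chance
})

test_that("the genome fixture round-trips through the peak pipeline", {
  w <- make_world(num_tfs = 3L, num_cells = 2L, motif_length = 8L,
                  activity_density = 0.8, share_pwm = FALSE, seed = 76)
  set.seed(76)
  dir <- withr::local_tempdir()
  fx <- generate_genome_fixture(w, dir,
                                chrom_sizes = c(chr1 = 150000L,
                                                chr2 = 150000L),
                                peaks_per_experiment = 15L,
                                replicate_combos = 1L)
  meta <- read_metadata(fx$meta_file)
  expect_equal(nrow(meta), length(fx$peak_files))
  genome <- read_fasta_sequences(fx$fasta)
  expect_equal(nchar(genome), c(chr1 = 150000L, chr2 = 150000L))

  # peak counts per experiment and motif recovery at the summit
  for (e in seq_len(min(3, nrow(meta)))) {
    pk <- load_peaks(fx$peak_files[e])
    expect_equal(nrow(pk), 15L)
    top <- select_top_peaks(pk, 5, 60)
    seqs <- extract_sequences(top, genome)
    hd <- vapply(seqs, bf_min_hamming, 0,
                 motif = w$consensus[[meta$tf[e]]])
    expect_true(all(hd <= 2))
  }

  # union DHS + matched negatives devoid of the TF's consensus: exclude
  # every experiment of that TF (replicates plant the same motif)
  dnase <- load_peaks(fx$dnase_file)
  udhs <- build_union_dhs(list(dnase))
  tf1 <- meta$tf[1]
  same_tf <- which(meta$tf == tf1)
  tfpk <- do.call(rbind, lapply(fx$peak_files[same_tf], load_peaks))
  top <- select_top_peaks(tfpk, nrow(tfpk), 300)
  set.seed(77)
  neg <- build_dhs_negatives(udhs, top, 40, 60)
  nseq <- extract_sequences(neg, genome)
  hdn <- vapply(nseq, bf_min_hamming, 0, motif = w$consensus[[tf1]])
  expect_gte(mean(hdn >= 1), 0.99)
})

test_that("the reporter-assay fixture links activity to planted motifs", {
  w <- make_world(num_tfs = 4L, num_cells = 2L, activity_density = 0.8,
                  seed = 78)
  set.seed(78)
  mp0 <- generate_mpra_fixture(w, "cell1", n = 200, seq_length = 90,
                               noise_sd = 0)
  expect_true(all(mp0$activities == round(mp0$activities)))
  expect_true(all(mp0$activities %in% 0:3))
  mp <- generate_mpra_fixture(w, "cell1", n = 250, seq_length = 90,
                              noise_sd = 0.25)
  o <- order(mp$activities, decreasing = TRUE)
  expect_gt(mean(mp$motif_counts[o[1:100]]),
            mean(mp$motif_counts[o[151:250]]))
  expect_error(generate_mpra_fixture(w, "cell1", n = 100), "n >= 200")
})

test_that("SNP fixtures break the motif at one informative base", {
  w <- make_world(num_tfs = 3L, num_cells = 2L, share_pwm = FALSE, seed = 79)
  set.seed(79)
  snps <- generate_snp_fixture(w, "TF2", 60, n = 4)
  expect_equal(nrow(snps), 4L)
  for (i in 1:4) {
    fa <- snps$flank[i]
    fb <- fa
    substr(fb, snps$pos[i], snps$pos[i]) <- snps$allele_b[i]
    diffs <- which(strsplit(fa, "")[[1]] != strsplit(fb, "")[[1]])
    expect_equal(diffs, snps$pos[i])
    sa <- pwm_scan_score(fa, w$pwms[["TF2"]], w$base_probs)
    sb <- pwm_scan_score(fb, w$pwms[["TF2"]], w$base_probs)
    expect_gt(sa, sb)
  }
})
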