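test_that("load_peaks parses narrowPeak and BED dialects", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t400\t.\t0\t.\t5.0\t-1\t-1\t150",
               "chr1\t500\t700\t.\t0\t.\t2.5\t-1\t-1\t-1"), f)
  p <- load_peaks(f)
  expect_equal(p$start, c(100L, 500L))
  expect_equal(p$end, c(400L, 700L))
  expect_equal(p$summit_offset, c(150L, 100L))   # -1 summit -> midpoint
  expect_equal(p$score, c(5.0, 2.5))

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t10\t20\tpk1\t7", "chr2\t30\t41"), b)
  q <- load_peaks(b)
  expect_equal(q$summit_offset, c(5L, 5L))       # floor midpoint
  expect_equal(q$score, c(7, 0))

  e <- withr::local_tempfile()
  file.create(e)
  expect_equal(nrow(load_peaks(e)), 0L)

  m <- withr::local_tempfile()
  writeLines(c("chr1\t5\t50", "chr1\tfoo\t60"), m)
  expect_error(load_peaks(m), "line 2")
})

test_that("select_top_peaks ranks, centers and tie-breaks", {
  set.seed(21)
  pk <- data.frame(chrom = "chr1", start = seq(0, 900, by = 100),
                   end = seq(0, 900, by = 100) + 80,
                   summit_offset = 40L, score = c(5, 3, 9, 1, 7, 2, 8, 4, 6, 0))
  top <- select_top_peaks(pk, 5, 100)
  expect_equal(nrow(top), 5L)
  expect_true(all(top$end - top$start == 100L))
  expect_equal(top$score, sort(pk$score, decreasing = TRUE)[1:5])
  # summit at 1000, window 100 -> [950, 1050)
  one <- select_top_peaks(data.frame(chrom = "chr1", start = 900L, end = 1100L,
                                     summit_offset = 100L, score = 1),
                          1, 100)
  expect_equal(c(one$start, one$end), c(950L, 1050L))
  # equal scores -> ordered by (chrom, start)
  tie <- select_top_peaks(data.frame(chrom = c("chr2", "chr1"),
                                     start = c(0L, 0L), end = c(10L, 10L),
                                     summit_offset = 5L, score = 1),
                          2, 10)
  expect_equal(tie$chrom, c("chr1", "chr2"))
})

test_that("alternating_split sends odd ranks to training", {
  pk <- data.frame(rank = 1:6, x = letters[1:6])
  sp <- alternating_split(pk)
  expect_equal(sp$odd$rank, c(1L, 3L, 5L))
  expect_equal(sp$even$rank, c(2L, 4L, 6L))
  one <- alternating_split(data.frame(rank = 1L))
  expect_equal(nrow(one$odd), 1L)
  expect_equal(nrow(one$even), 0L)
  big <- alternating_split(data.frame(rank = 1:1000))
  expect_equal(c(nrow(big$odd), nrow(big$even)), c(500L, 500L))
})

test_that("build_shuffled_negatives matches dinucleotides pairwise", {
  set.seed(22)
  pos <- data.frame(label = 1L, tf = "T1", cell = "C1",
                    seq = replicate(20, random_dna(60)))
  neg <- build_shuffled_negatives(pos)
  expect_equal(nrow(neg), 20L)
  expect_true(all(neg$label == 0L))
  expect_equal(neg$tf, pos$tf)
  for (i in 1:20)
    expect_equal(as.vector(dinucleotide_counts(neg$seq[i])),
                 as.vector(bf_dinuc_counts(pos$seq[i])))
  hp <- data.frame(label = 1L, tf = "T1", cell = "C1",
                   seq = strrep("A", 30))
  expect_identical(build_shuffled_negatives(hp)$seq, hp$seq)
  set.seed(5); a <- build_shuffled_negatives(pos)$seq
  set.seed(5); b <- build_shuffled_negatives(pos)$seq
  expect_identical(a, b)
})

test_that("build_union_dhs trims to summit windows and merges", {
  pk <- function(chrom, start, end, summit)
    data.frame(chrom = chrom, start = start, end = end,
               summit_offset = summit, score = 1)
  # summit-centered 300bp windows [0,300) and [200,500) merge to [0,500)
  u <- build_union_dhs(list(pk("chr1", 100, 200, 50),   # summit 150 -> [0,300)
                            pk("chr1", 300, 400, 50)))  # summit 350 -> [200,500)
  expect_equal(u, data.frame(chrom = "chr1", start = 0L, end = 500L))
  # disjoint windows remain separate; total bp <= 300 * count
  set.seed(23)
  peaks <- pk("chr1", seq(0, 9000, by = 1000), seq(0, 9000, by = 1000) + 200, 100)
  u2 <- build_union_dhs(list(peaks))
  expect_equal(nrow(u2), 10L)
  expect_true(sum(u2$end - u2$start) <= 300 * 10)
})

test_that("build_dhs_negatives filters overlaps like a brute-force scan", {
  dhs <- data.frame(chrom = "chr1",
                    start = seq(0L, 9000L, by = 1000L),
                    end = seq(0L, 9000L, by = 1000L) + 300L)
  tfp <- data.frame(chrom = "chr1",
                    start = c(100L, 1100L, 2100L, 3299L),
                    end = c(150L, 1150L, 2150L, 3400L))
  # brute force: DHS regions with any bp overlap against any peak
  overl <- vapply(seq_len(nrow(dhs)), function(i)
    any(tfp$start < dhs$end[i] & tfp$end > dhs$start[i]), TRUE)
  expect_equal(sum(!overl), 6L)
  set.seed(24)
  neg <- build_dhs_negatives(dhs, tfp, 6, 100)
  expect_equal(nrow(neg), 6L)
  expect_true(all(neg$end - neg$start == 100L))
  # sampled centers must come from non-overlapping DHS regions
  centers <- neg$start + 50L
  expect_true(all(floor(centers / 1000) %in% (which(!overl) - 1L)))
  # pool too small -> warn and emit all
  expect_warning(few <- build_dhs_negatives(dhs, tfp, 8, 100), "pool")
  expect_equal(nrow(few), 6L)
  # no TF peaks -> pool is everything
  set.seed(25)
  expect_equal(nrow(build_dhs_negatives(dhs, tfp[0, ], 10, 100)), 10L)
  # peaks covering every region -> empty pool
  allpk <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  expect_warning(none <- build_dhs_negatives(dhs, allpk, 1, 100), "pool")
  expect_equal(nrow(none), 0L)
})

test_that("partition_combinations achieves the exhaustive holdout optimum", {
  grid3 <- expand.grid(tf = paste0("T", 1:3), cell = paste0("C", 1:3),
                       stringsAsFactors = FALSE)
  expect_equal(bf_max_holdout(grid3), 6L)
  set.seed(26)
  part <- partition_combinations(grid3, holdout_valid_size = 2L)
  expect_equal(nrow(part$validset2) + nrow(part$testset3), 6L)
  expect_equal(nrow(part$base), 3L)
  # coverage invariant
  held <- rbind(part$validset2, part$testset3)
  expect_true(all(held$tf %in% part$base$tf))
  expect_true(all(held$cell %in% part$base$cell))

  # single combination: removing it would orphan its TF
  solo <- partition_combinations(data.frame(tf = "T1", cell = "C1"),
                                 holdout_valid_size = 0L)
  expect_equal(nrow(solo$base), 1L)
  expect_equal(nrow(solo$testset3), 0L)

  # random small grids: exact algorithm matches exhaustive enumeration
  set.seed(27)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    combos <- unique(data.frame(tf = paste0("T", sample(1:4, n, TRUE)),
                                cell = paste0("C", sample(1:4, n, TRUE))))
    p <- partition_combinations(combos, holdout_valid_size = 0L)
    expect_equal(nrow(p$testset3), bf_max_holdout(combos),
                 info = paste("grid rep", rep))
    held <- p$testset3
    expect_true(all(held$tf %in% p$base$tf))
    expect_true(all(held$cell %in% p$base$cell))
  }

  # replicate-backed combinations form the replicate test set
  reps <- data.frame(tf = c("T1", "T1", "T2"), cell = c("C1", "C1", "C2"))
  p2 <- partition_combinations(data.frame(tf = c("T1", "T2"),
                                          cell = c("C1", "C2")),
                               replicates = reps, holdout_valid_size = 0L)
  expect_equal(p2$testset2, data.frame(tf = "T1", cell = "C1"))
  # oversized validation request errors
  expect_error(partition_combinations(grid3, holdout_valid_size = 7L),
               "holdout")
})

test_that("split_instances is a conserving uniform split", {
  set.seed(28)
  inst <- data.frame(label = rep(0:1, 50), tf = "T", cell = "C",
                     seq = replicate(100, random_dna(10)))
  sp <- split_instances(inst, c(70, 10, 20))
  expect_equal(nrow(sp$trainset), 70L)
  expect_equal(nrow(sp$validset1), 10L)
  expect_equal(nrow(sp$testset1), 20L)
  all_seqs <- sort(c(sp$trainset$seq, sp$validset1$seq, sp$testset1$seq))
  expect_equal(all_seqs, sort(inst$seq))
  set.seed(1); a <- split_instances(inst, c(NA, 10, 20))
  set.seed(1); b <- split_instances(inst, c(NA, 10, 20))
  expect_identical(a, b)
  expect_equal(nrow(a$trainset), 70L)    # NA absorbs the remainder
  expect_error(split_instances(inst, c(-1, 10, 20)), "negative")
  expect_error(split_instances(inst, c(90, 10, 20)), "available")
})

test_that("extract_sequences slices 0-based half-open and validates", {
  genome <- c(chr1 = "ACGTACGT")
  expect_identical(extract_sequences(data.frame(chrom = "chr1", start = 2L,
                                                end = 6L), genome), "GTAC")
  expect_error(extract_sequences(data.frame(chrom = "chr1", start = 3L,
                                            end = 3L), genome), "length")
  expect_error(extract_sequences(data.frame(chrom = "chr1", start = 4L,
                                            end = 12L), genome), "bounds")
  expect_error(extract_sequences(data.frame(chrom = "chrX", start = 0L,
                                            end = 4L), genome), "chromosome")
})

test_that("instance and partition round trips preserve content", {
  set.seed(29)
  inst <- data.frame(label = rep(0:1, 5), tf = "TF1", cell = "HepG2",
                     seq = replicate(10, random_dna(20)))
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  write_instances(inst, f)
  expect_equal(read_instances(f), inst)

  part <- partition_combinations(expand.grid(tf = paste0("T", 1:3),
                                             cell = paste0("C", 1:3),
                                             stringsAsFactors = FALSE),
                                 holdout_valid_size = 1L)
  pj <- withr::local_tempfile(fileext = ".json")
  write_partition(part, pj)
  rt <- read_partition(pj)
  for (nm in names(part))
    expect_equal(rt[[nm]], part[[nm]], ignore_attr = TRUE)
})

test_that("metadata reader enforces the documented header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("experiment_id\ttf\tcell_line\treplicate",
               "e1\tCTCF\tK562\trep1"), f)
  m <- read_metadata(f)
  expect_equal(m$tf, "CTCF")
  expect_equal(m$cell, "K562")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfactor", "e1\tCTCF"), bad)
  expect_error(read_metadata(bad), "columns")
})
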