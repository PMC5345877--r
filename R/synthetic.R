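#' Synthetic binding world
#'
#' Generates ground truth for testing every pipeline stage: one position
#' probability matrix (PWM) per TF with a sharp consensus, a binary
#' TF x cell-line activity matrix, and an order-1 Markov background model.
#' Binding in this world is motif-driven and cell-gated: a (TF, cell)
#' combination produces motif-bearing positive sequences only where the
#' activity matrix is 1.
#'
#' @param num_tfs,num_cells grid dimensions.
#' @param motif_length PWM length in bp.
#' @param activity_density Bernoulli rate of the activity matrix entries in
#'   (0, 1]; the matrix is repaired afterwards so every TF is active in at
#'   least one cell and every cell has at least one active TF.
#' @param gc background GC content (default 0.41, human-like).
#' @param markov_rho persistence of the order-1 background chain: the next
#'   base copies the previous one with probability `markov_rho`, else is
#'   drawn i.i.d.  Non-zero so that dinucleotide-preserving shuffling is a
#'   non-trivial control.
#' @param share_pwm when TRUE (default) the second TF shares the first TF's
#'   PWM, making embedding clustering testable.
#' @param seed optional seed applied via [set.seed()].
#' @return object of class `tfgate_world`: list with `pwms` (named list of
#'   L x 4 row-stochastic matrices), `consensus` (named character),
#'   `activity` (num_tfs x num_cells 0/1 matrix with dimnames), `gc`,
#'   `markov_rho`, `base_probs`, `seed`.
#' @export
make_world <- function(num_tfs = 8L, num_cells = 5L, motif_length = 8L,
                       activity_density = 0.7, gc = 0.41,
                       markov_rho = 0.1, share_pwm = TRUE, seed = NULL) {
  stopifnot(activity_density > 0, activity_density <= 1,
            num_tfs >= 1L, num_cells >= 1L, motif_length >= 2L)
  if (!is.null(seed)) set.seed(seed)
  tf_names <- paste0("TF", seq_len(num_tfs))
  cell_names <- paste0("cell", seq_len(num_cells))
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  make_pwm <- function() {
    cons <- sample.int(4L, motif_length, replace = TRUE)
    # sharp consensus: >= 0.8 per position, and strong enough that the
    # PWM-scan oracle separates active combinations at AUC >= 0.95
    alpha <- runif(motif_length, 0.85, 0.97)
    m <- matrix((1 - alpha) / 3, motif_length, 4L,
                dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_len(motif_length), cons)] <- alpha
    m
  }
  pwms <- lapply(seq_len(num_tfs), function(i) make_pwm())
  names(pwms) <- tf_names
  if (share_pwm && num_tfs >= 2L) pwms[[2L]] <- pwms[[1L]]
  consensus <- vapply(pwms, function(m)
    paste(DNA_BASES[max.col(m, ties.method = "first")], collapse = ""), "")

  activity <- matrix(rbinom(num_tfs * num_cells, 1L, activity_density),
                     num_tfs, num_cells,
                     dimnames = list(tf_names, cell_names))
  for (i in which(rowSums(activity) == 0))
    activity[i, sample.int(num_cells, 1L)] <- 1L
  for (j in which(colSums(activity) == 0))
    activity[sample.int(num_tfs, 1L), j] <- 1L

  structure(list(pwms = pwms, consensus = consensus, activity = activity,
                 gc = gc, markov_rho = markov_rho, base_probs = base_probs,
                 motif_length = motif_length, seed = seed),
            class = "tfgate_world")
}

#' Sample background sequences from the world's order-1 chain
#'
#' Vectorized: i.i.d. draws from the base composition plus forward-fill
#' over "copy the previous base" positions (persistence `markov_rho`).
#'
#' @param n number of sequences.
#' @param len sequence length (bp).
#' @param world a `tfgate_world`.
#' @return character vector of `n` sequences.
#' @export
sample_background <- function(n, len, world) {
  total <- n * len
  draws <- sample.int(4L, total, replace = TRUE, prob = world$base_probs)
  reset <- runif(total) >= world$markov_rho
  reset[seq(1L, total, by = len)] <- TRUE        # sequence starts
  src <- cummax(seq_len(total) * reset)          # index of governing draw
  codes <- draws[src]
  vapply(seq_len(n), function(i)
    codes_to_seq(codes[((i - 1L) * len + 1L):(i * len)]), "")
}

#' Draw one motif instance from a PWM
#'
#' Rejection-samples from the per-position distribution conditional on at
#' most `max_mismatch` deviations from the consensus, so every planted
#' instance stays within a bounded Hamming distance of the consensus (the
#' worlds use sharp PWMs, so acceptance is fast).
#'
#' @param pwm L x 4 position probability matrix (columns A,C,G,T).
#' @param max_mismatch maximum consensus mismatches tolerated (default 2;
#'   `Inf` for unconditioned draws).
#' @return character string of length L.
#' @export
sample_motif <- function(pwm, max_mismatch = 2L) {
  cons <- max.col(pwm, ties.method = "first")
  repeat {
    codes <- vapply(seq_len(nrow(pwm)), function(i)
      sample.int(4L, 1L, prob = pwm[i, ]), 0L)
    if (sum(codes != cons) <= max_mismatch) return(codes_to_seq(codes))
  }
}

#' Plant a motif instance into a sequence
#'
#' @param seq host sequence.
#' @param insert motif instance to plant.
#' @param pos 1-based start position.
#' @param revstrand plant the reverse complement instead.
#' @return the modified sequence.
#' @export
plant_motif <- function(seq, insert, pos, revstrand = FALSE) {
  if (revstrand) insert <- reverse_complement(insert)
  substr(seq, pos, pos + nchar(insert) - 1L) <- insert
  seq
}

#' PWM log-odds scan (generative oracle)
#'
#' Best log-odds score of a PWM against the background base composition,
#' maximized over all positions and both strands.  This is the Bayes-style
#' ceiling detector for the synthetic world: no trained model can
#' systematically beat it on world-generated data.
#'
#' @param seq character sequence.
#' @param pwm L x 4 position probability matrix (columns A,C,G,T).
#' @param base_probs background base probabilities (named, A,C,G,T).
#' @param pseudo numeric floor for PWM probabilities.
#' @return maximum log-odds score.
#' @export
pwm_scan_score <- function(seq, pwm, base_probs, pseudo = 1e-6) {
  lo <- log(pmax(pwm, pseudo)) -
    matrix(log(base_probs), nrow(pwm), 4L, byrow = TRUE)
  best <- -Inf
  for (codes in list(seq_to_codes(seq), revcomp_codes(seq_to_codes(seq)))) {
    L <- nrow(pwm)
    n <- length(codes)
    if (n < L) next
    for (r in 1:(n - L + 1L)) {
      w <- codes[r:(r + L - 1L)]
      if (any(w == 0L)) next
      s <- sum(lo[cbind(seq_len(L), w)])
      if (s > best) best <- s
    }
  }
  best
}

#' Generate labeled instances from the world
#'
#' For each requested (TF, cell) combination, emits `n_per_combo` instances
#' balanced 1:1.  For active combinations the positives are background
#' sequences with one PWM draw planted at a uniform position on a uniform
#' strand; negatives are pure background.  For inactive combinations the
#' "positives" are pure background too — binding is absent, so their labels
#' carry no sequence signal (by design).
#'
#' @param world a `tfgate_world`.
#' @param combos data.frame `tf`, `cell` (subset of the world grid).
#' @param n_per_combo instances per combination (positives = floor(n/2)).
#' @param seq_length instance sequence length; must be >= motif length.
#' @return instance table `label`, `tf`, `cell`, `seq`.
#' @export
generate_instances <- function(world, combos, n_per_combo, seq_length) {
  if (seq_length < world$motif_length)
    stop("seq_length shorter than motif length")
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    tf <- combos$tf[i]; cell <- combos$cell[i]
    if (!tf %in% rownames(world$activity) ||
        !cell %in% colnames(world$activity))
      stop(sprintf("combination (%s, %s) outside the world grid", tf, cell))
    npos <- n_per_combo %/% 2L
    nneg <- n_per_combo - npos
    pos <- sample_background(npos, seq_length, world)
    if (world$activity[tf, cell] == 1L) {
      L <- world$motif_length
      starts <- sample.int(seq_length - L + 1L, npos, replace = TRUE)
      strands <- runif(npos) < 0.5
      for (p in seq_len(npos))
        pos[p] <- plant_motif(pos[p], sample_motif(world$pwms[[tf]]),
                              starts[p], strands[p])
    }
    neg <- sample_background(nneg, seq_length, world)
    out[[i]] <- data.frame(
      label = c(rep(1L, npos), rep(0L, nneg)),
      tf = tf, cell = cell, seq = c(pos, neg))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate an on-disk genome fixture
#'
#' Builds a small multi-chromosome genome with planted binding sites, and
#' writes everything the dataset-construction pipeline ingests: a FASTA
#' genome, one narrowPeak file per ChIP-seq experiment (summit at the plant
#' site), DNase narrowPeak files covering all active regions plus extra
#' open background, a metadata TSV, and a ground-truth JSON.
#'
#' @param world a `tfgate_world`.
#' @param out_dir output directory (created).
#' @param chrom_sizes named vector of chromosome lengths (default four
#'   500 kb chromosomes, ~2 Mb total).
#' @param peaks_per_experiment planted sites per experiment.
#' @param replicate_combos number of active combinations that get a second
#'   (replicate) experiment.
#' @return invisibly, a list with file paths and the planted-site table.
#' @export
generate_genome_fixture <- function(world, out_dir,
                                    chrom_sizes = c(chr1 = 500000L,
                                                    chr2 = 500000L,
                                                    chr3 = 500000L,
                                                    chr4 = 500000L),
                                    peaks_per_experiment = 30L,
                                    replicate_combos = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  genome <- lapply(names(chrom_sizes), function(ch)
    sample_background(1L, chrom_sizes[[ch]], world))
  names(genome) <- names(chrom_sizes)

  act <- which(world$activity == 1L, arr.ind = TRUE)
  combos <- data.frame(tf = rownames(world$activity)[act[, 1]],
                       cell = colnames(world$activity)[act[, 2]])
  nrep <- min(replicate_combos, nrow(combos))
  rep_idx <- if (nrep > 0L) sample.int(nrow(combos), nrep) else integer(0)
  exp_tab <- rbind(
    data.frame(tf = combos$tf, cell = combos$cell, replicate = "rep1"),
    data.frame(tf = combos$tf[rep_idx], cell = combos$cell[rep_idx],
               replicate = "rep2"))
  exp_tab$experiment_id <- sprintf("exp%03d", seq_len(nrow(exp_tab)))

  # allocate non-overlapping 400 bp slots across the genome, then shuffle
  slot_w <- 400L
  slots <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(200L, chrom_sizes[[ch]] - slot_w - 200L, by = slot_w)
    data.frame(chrom = ch, pos = starts + slot_w %/% 2L)
  }))
  need <- nrow(exp_tab) * peaks_per_experiment
  extra_dnase <- 200L
  if (need + extra_dnase > nrow(slots))
    stop("genome too small for the requested number of peaks")
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]

  L <- world$motif_length
  sites <- vector("list", nrow(exp_tab))
  peak_files <- character(nrow(exp_tab))
  si <- 0L
  for (e in seq_len(nrow(exp_tab))) {
    take <- slots[si + seq_len(peaks_per_experiment), , drop = FALSE]
    si <- si + peaks_per_experiment
    tf <- exp_tab$tf[e]
    for (p in seq_len(nrow(take))) {
      ch <- take$chrom[p]; center <- take$pos[p]
      mstart <- center - L %/% 2L
      genome[[ch]] <- plant_motif(genome[[ch]],
                                  sample_motif(world$pwms[[tf]]),
                                  mstart, runif(1) < 0.5)
    }
    pk <- data.frame(chrom = take$chrom,
                     start = take$pos - 150L, end = take$pos + 150L,
                     name = sprintf("%s_peak%d", exp_tab$experiment_id[e],
                                    seq_len(nrow(take))),
                     score = 0L, strand = ".",
                     signal = round(runif(nrow(take), 1, 100), 2),
                     p = -1, q = -1,
                     summit = 150L)
    f <- file.path(out_dir, "peaks",
                   paste0(exp_tab$experiment_id[e], ".narrowPeak"))
    utils::write.table(pk, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    peak_files[e] <- f
    sites[[e]] <- data.frame(experiment_id = exp_tab$experiment_id[e],
                             tf = tf, cell = exp_tab$cell[e],
                             chrom = take$chrom, center = take$pos)
  }
  sites <- do.call(rbind, sites)

  # DNase: open chromatin over every planted site plus background regions
  open_pos <- rbind(sites[, c("chrom", "center")],
                    setNames(slots[si + seq_len(extra_dnase),
                                   c("chrom", "pos")], c("chrom", "center")))
  dn <- data.frame(chrom = open_pos$chrom,
                   start = open_pos$center - 200L,
                   end = open_pos$center + 200L,
                   name = sprintf("dhs%d", seq_len(nrow(open_pos))),
                   score = 0L, strand = ".",
                   signal = round(runif(nrow(open_pos), 1, 50), 2),
                   p = -1, q = -1, summit = 200L)
  dnase_file <- file.path(out_dir, "dnase.narrowPeak")
  utils::write.table(dn, dnase_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  fasta <- file.path(out_dir, "genome.fa")
  gset <- Biostrings::DNAStringSet(unlist(genome))
  names(gset) <- names(genome)
  Biostrings::writeXStringSet(gset, fasta)

  meta_file <- file.path(out_dir, "meta.tsv")
  utils::write.table(
    data.frame(experiment_id = exp_tab$experiment_id, tf = exp_tab$tf,
               cell_line = exp_tab$cell, replicate = exp_tab$replicate),
    meta_file, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_file <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(consensus = as.list(world$consensus),
                            activity = world$activity,
                            gc = world$gc),
                       truth_file, digits = NA, auto_unbox = TRUE)

  invisible(list(fasta = fasta, peak_files = peak_files,
                 dnase_file = dnase_file, meta_file = meta_file,
                 truth_file = truth_file, sites = sites,
                 experiments = exp_tab))
}

#' Generate a synthetic reporter-assay (MPRA-like) fixture
#'
#' Each of `n` sequences carries 0-3 planted motifs of TFs active in the
#' chosen cell line; measured activity is the planted-motif count plus
#' Gaussian noise.
#'
#' @param world a `tfgate_world`.
#' @param cell cell-line name.
#' @param n number of sequences (>= 200 so a top/bottom 100 exists).
#' @param seq_length sequence length.
#' @param noise_sd Gaussian noise standard deviation on the activity.
#' @return list with `seqs`, `activities`, `motif_counts`.
#' @export
generate_mpra_fixture <- function(world, cell, n = 300L, seq_length = 100L,
                                  noise_sd = 0.25) {
  stopifnot(n >= 200L)
  active_tfs <- rownames(world$activity)[world$activity[, cell] == 1L]
  L <- world$motif_length
  nslots <- 3L
  slot_w <- seq_length %/% nslots
  if (slot_w < L) stop("seq_length too short for 3 motif slots")
  seqs <- sample_background(n, seq_length, world)
  counts <- sample(0:3, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (counts[i] == 0L) next
    slots <- sample.int(nslots, counts[i])
    for (s in slots) {
      tf <- sample(active_tfs, 1L)
      pos <- (s - 1L) * slot_w + sample.int(slot_w - L + 1L, 1L)
      seqs[i] <- plant_motif(seqs[i], sample_motif(world$pwms[[tf]]),
                             pos, runif(1) < 0.5)
    }
  }
  list(seqs = seqs, activities = counts + rnorm(n, 0, noise_sd),
       motif_counts = counts)
}

#' Generate motif-destroying SNP fixtures
#'
#' Each fixture is a flank with the TF's motif planted at the center; the
#' variant position is the motif's most informative position, allele A the
#' consensus base (motif intact) and allele B the PWM's least likely base
#' there (motif broken).
#'
#' @param world a `tfgate_world`.
#' @param tf TF name.
#' @param seq_length flank length (model input length).
#' @param n number of fixtures.
#' @return data.frame `id`, `flank` (carrying allele A), `pos` (1-based),
#'   `allele_a`, `allele_b`.
#' @export
generate_snp_fixture <- function(world, tf, seq_length, n = 5L) {
  pwm <- world$pwms[[tf]]
  if (is.null(pwm)) stop("unknown TF: ", tf)
  L <- nrow(pwm)
  mpos <- which.max(apply(pwm, 1L, max))       # most informative position
  a <- DNA_BASES[which.max(pwm[mpos, ])]
  b <- DNA_BASES[which.min(pwm[mpos, ])]
  mstart <- (seq_length - L) %/% 2L + 1L
  out <- lapply(seq_len(n), function(i) {
    flank <- sample_background(1L, seq_length, world)
    inst <- world$consensus[[tf]]               # consensus: intact by design
    flank <- plant_motif(flank, inst, mstart, FALSE)
    pos <- mstart + mpos - 1L
    substr(flank, pos, pos) <- a
    data.frame(id = sprintf("%s_snp%d", tf, i), flank = flank,
               pos = pos, allele_a = a, allele_b = b)
  })
  do.call(rbind, out)
}
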