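#' Load peaks from a BED or narrowPeak file
#'
#' Coordinates are kept 0-based half-open.  For 10-column narrowPeak input
#' the summit offset (column 10) is used when >= 0, otherwise the region
#' midpoint; 3-6 column BED gets the midpoint convention and (when present)
#' the BED score as ranking statistic.  narrowPeak ranking uses column 7
#' (signalValue).
#'
#' @param path peak file (plain text, whitespace-delimited).
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `summit_offset`, `score`, `name`.
#' @export
load_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit_offset = integer(),
                      score = numeric(), name = character()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  parse_line <- function(f, i) {
    if (length(f) < 3L)
      stop(sprintf("malformed peak line %d: fewer than 3 columns", i))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0L || start >= end)
      stop(sprintf("malformed peak line %d: bad coordinates '%s' '%s'",
                   i, f[2], f[3]))
    if (length(f) >= 10L) {            # narrowPeak
      score <- suppressWarnings(as.numeric(f[7]))
      if (is.na(score))
        stop(sprintf("malformed peak line %d: bad signalValue '%s'", i, f[7]))
      summit <- suppressWarnings(as.integer(f[10]))
      if (is.na(summit))
        stop(sprintf("malformed peak line %d: bad summit '%s'", i, f[10]))
      if (summit < 0L) summit <- (end - start) %/% 2L
      if (summit >= end - start)
        stop(sprintf("malformed peak line %d: summit offset %d outside region",
                     i, summit))
    } else {                           # plain BED (3-6 columns)
      score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else 0
      if (is.na(score)) score <- 0
      summit <- (end - start) %/% 2L
    }
    nm <- if (length(f) >= 4L) f[4] else "."
    list(chrom = f[1], start = start, end = end,
         summit_offset = summit, score = score, name = nm)
  }
  rows <- Map(parse_line, fields, seq_along(fields))
  data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
             start = vapply(rows, `[[`, 0L, "start"),
             end = vapply(rows, `[[`, 0L, "end"),
             summit_offset = vapply(rows, `[[`, 0L, "summit_offset"),
             score = vapply(rows, `[[`, 0.0, "score"),
             name = vapply(rows, `[[`, "", "name"))
}

# 0-based half-open peak/region data.frame -> GRanges (1-based closed)
.regions_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

.granges_to_regions <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Select top-ranked peaks as fixed-width summit-centered windows
#'
#' Peaks are sorted by score descending (ties by chrom, then start), the
#' top `n` kept, and each converted to a window of exactly `window` bp
#' centered on its summit: `[summit - floor(w/2), summit - floor(w/2) + w)`.
#'
#' @param peaks data.frame from [load_peaks()].
#' @param n number of peaks to keep (all if fewer available).
#' @param window window width in bp.
#' @return data.frame `chrom`, `start`, `end`, `rank`, `score`.
#' @export
select_top_peaks <- function(peaks, n, window) {
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), rank = integer(), score = numeric()))
  o <- order(-peaks$score, peaks$chrom, peaks$start)
  keep <- o[seq_len(min(n, length(o)))]
  summit <- peaks$start[keep] + peaks$summit_offset[keep]
  start <- summit - window %/% 2L
  data.frame(chrom = peaks$chrom[keep],
             start = start, end = start + window,
             rank = seq_along(keep), score = peaks$score[keep])
}

#' Split rank-ordered peaks into odd and even ranks
#'
#' 1-based odd ranks feed the training pool, even ranks the test pool
#' (so 1,000 top peaks contribute 500 to each).
#'
#' @param top_peaks data.frame with a `rank` column (or taken as already
#'   ordered).
#' @return list `odd`, `even`.
#' @export
alternating_split <- function(top_peaks) {
  r <- if (!is.null(top_peaks$rank)) top_peaks$rank else seq_len(nrow(top_peaks))
  list(odd = top_peaks[r %% 2L == 1L, , drop = FALSE],
       even = top_peaks[r %% 2L == 0L, , drop = FALSE])
}

#' Dinucleotide-matched shuffled negatives
#'
#' One label-0 instance per positive instance, with the same TF and cell
#' line and a dinucleotide-preserving shuffle of the positive sequence.
#' Positives containing N must be dropped beforehand.
#'
#' @param positives instance table (`label`, `tf`, `cell`, `seq`), all
#'   label 1.
#' @return instance table of equal size with label 0.
#' @export
build_shuffled_negatives <- function(positives) {
  data.frame(label = 0L,
             tf = positives$tf, cell = positives$cell,
             seq = vapply(positives$seq, dinucleotide_shuffle, "",
                          USE.NAMES = FALSE))
}

#' Union of DNase I hypersensitive sites
#'
#' Every DNase peak is trimmed to a 300 bp window centered on its summit;
#' windows from all datasets are merged where overlapping (half-open
#' overlap) into a sorted, non-overlapping region set.
#'
#' @param dnase_peak_sets list of peak data.frames (each as from
#'   [load_peaks()]; summits required).
#' @param trim_width trimmed peak width in bp (default 300).
#' @return data.frame `chrom`, `start`, `end` of merged open regions.
#' @export
build_union_dhs <- function(dnase_peak_sets, trim_width = 300L) {
  wins <- lapply(dnase_peak_sets, function(p) {
    summit <- p$start + p$summit_offset
    start <- summit - trim_width %/% 2L
    data.frame(chrom = p$chrom, start = pmax(start, 0L),
               end = pmax(start, 0L) + trim_width)
  })
  all <- do.call(rbind, wins)
  gr <- GenomicRanges::reduce(.regions_to_granges(all))
  gr <- GenomicRanges::sort(gr)
  .granges_to_regions(gr)
}

#' Sample matched negatives from the union DHS
#'
#' The candidate pool is every union-DHS region with zero overlap against
#' any TF peak; `n` regions are sampled uniformly without replacement and
#' each is emitted as a fixed-width window centered in the region.
#'
#' @param union_dhs sorted non-overlapping region data.frame.
#' @param tf_peaks region data.frame of the TF's peaks.
#' @param n number of negatives wanted.
#' @param window emitted window width in bp.
#' @return data.frame `chrom`, `start`, `end`; fewer than `n` rows (with a
#'   warning) when the pool is too small.
#' @export
build_dhs_negatives <- function(union_dhs, tf_peaks, n, window) {
  pool <- union_dhs
  if (nrow(tf_peaks) > 0L && nrow(pool) > 0L) {
    hits <- GenomicRanges::findOverlaps(.regions_to_granges(pool),
                                        .regions_to_granges(tf_peaks))
    bad <- unique(S4Vectors::queryHits(hits))
    if (length(bad)) pool <- pool[-bad, , drop = FALSE]
  }
  if (nrow(pool) < n) {
    warning(sprintf("negative pool (%d) smaller than requested (%d); emitting all",
                    nrow(pool), n))
    take <- seq_len(nrow(pool))
  } else {
    take <- sample.int(nrow(pool), n)
  }
  sel <- pool[take, , drop = FALSE]
  center <- sel$start + (sel$end - sel$start) %/% 2L
  start <- center - window %/% 2L
  data.frame(chrom = sel$chrom, start = start, end = start + window)
}

#' Partition (TF, cell line) combinations for the imputation benchmark
#'
#' Finds the *largest* holdout H of combinations such that every TF and
#' every cell line occurring in H still occurs in the remaining base set.
#' This is solved exactly: the base must cover all TFs and cell lines, i.e.
#' be a minimum edge cover of the bipartite combination graph, computed via
#' maximum bipartite matching (Gallai: min cover = vertices - max matching).
#' `holdout_valid_size` members of H are then sampled as the
#' held-out-combination validation set, the rest form the imputation test
#' set; base combinations with at least `min_replicates` experiments form
#' the replicate test set (maximal by construction).
#'
#' @param combos data.frame with `tf`, `cell` columns (unique pairs).
#' @param replicates experiment metadata data.frame with `tf`, `cell` (one
#'   row per experiment), used to find replicated combinations.
#' @param holdout_valid_size size of the held-out validation subset
#'   (default 20).
#' @param min_replicates experiments needed for the replicate test set
#'   (default 2).
#' @return list of class `tfgate_partition` with data.frames `base`,
#'   `testset2`, `validset2`, `testset3`.
#' @export
partition_combinations <- function(combos, replicates = NULL,
                                   holdout_valid_size = 20L,
                                   min_replicates = 2L) {
  combos <- unique(combos[, c("tf", "cell")])
  rownames(combos) <- NULL
  tfs <- sort(unique(combos$tf))
  cells <- sort(unique(combos$cell))
  ti <- match(combos$tf, tfs)
  ci <- match(combos$cell, cells)

  # maximum bipartite matching (augmenting paths), TFs on the left
  adj_t <- lapply(seq_along(tfs), function(t) which(ti == t))
  match_cell <- rep(NA_integer_, length(cells))   # cell -> edge index
  try_augment <- function(t, env) {
    for (e in adj_t[[t]]) {
      cc <- ci[e]
      if (env$seen[cc]) next
      env$seen[cc] <- TRUE
      if (is.na(match_cell[cc]) || try_augment(ti[match_cell[cc]], env)) {
        match_cell[cc] <<- e
        return(TRUE)
      }
    }
    FALSE
  }
  for (t in seq_along(tfs)) {
    env <- new.env()
    env$seen <- rep(FALSE, length(cells))
    try_augment(t, env)
  }
  cover <- as.integer(stats::na.omit(match_cell))
  # add one incident edge (first by order) for every still-uncovered vertex
  for (t in setdiff(seq_along(tfs), unique(ti[cover])))
    cover <- c(cover, adj_t[[t]][1L])
  for (cc in setdiff(seq_along(cells), unique(ci[cover])))
    cover <- c(cover, which(ci == cc)[1L])
  cover <- sort(unique(cover))

  base <- combos[cover, , drop = FALSE]
  hold <- combos[-cover, , drop = FALSE]
  if (holdout_valid_size > nrow(hold))
    stop(sprintf("holdout has only %d combinations; cannot sample %d for validation",
                 nrow(hold), holdout_valid_size))
  vsel <- if (holdout_valid_size > 0L) sample.int(nrow(hold), holdout_valid_size)
          else integer(0)
  validset2 <- hold[vsel, , drop = FALSE]
  testset3 <- hold[setdiff(seq_len(nrow(hold)), vsel), , drop = FALSE]

  testset2 <- base[0L, , drop = FALSE]
  if (!is.null(replicates) && nrow(replicates) > 0L) {
    key <- paste(replicates$tf, replicates$cell, sep = "\r")
    cnt <- table(key)
    bkey <- paste(base$tf, base$cell, sep = "\r")
    testset2 <- base[bkey %in% names(cnt)[cnt >= min_replicates], , drop = FALSE]
  }
  out <- list(base = base, testset2 = testset2,
              validset2 = validset2, testset3 = testset3)
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  structure(out, class = "tfgate_partition")
}

#' Randomly split instances into train / validation / test sets
#'
#' Uniform random disjoint split; any remainder beyond the requested sizes
#' joins the training set.
#'
#' @param instances instance table.
#' @param sizes integer vector `c(train, valid1, test1)`; `train` may be NA
#'   to absorb the remainder.
#' @return list `trainset`, `validset1`, `testset1`.
#' @export
split_instances <- function(instances, sizes) {
  stopifnot(length(sizes) == 3L)
  n <- nrow(instances)
  s <- sizes
  if (is.na(s[1])) s[1] <- n - s[2] - s[3]
  if (any(s < 0)) stop("negative split sizes")
  if (sum(s) > n) stop(sprintf("requested %d instances but only %d available",
                               sum(s), n))
  ord <- sample.int(n)
  v1 <- ord[seq_len(s[2])]
  t1 <- ord[s[2] + seq_len(s[3])]
  tr <- ord[s[2] + s[3] + seq_len(n - s[2] - s[3])]
  list(trainset = instances[tr, , drop = FALSE],
       validset1 = instances[v1, , drop = FALSE],
       testset1 = instances[t1, , drop = FALSE])
}

#' Extract region sequences from a genome
#'
#' 0-based half-open slicing; output uppercased.  Regions beyond a
#' chromosome end (or of non-positive length) are an error naming the
#' region.
#'
#' @param regions data.frame `chrom`, `start`, `end`.
#' @param genome named character vector of chromosome sequences (e.g. from
#'   [read_fasta_sequences()]).
#' @return character vector of sequences.
#' @export
extract_sequences <- function(regions, genome) {
  vapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]; s <- regions$start[i]; e <- regions$end[i]
    if (!ch %in% names(genome))
      stop(sprintf("region %s:%d-%d: unknown chromosome", ch, s, e))
    if (e <= s)
      stop(sprintf("region %s:%d-%d has non-positive length", ch, s, e))
    if (s < 0L || e > nchar(genome[[ch]]))
      stop(sprintf("region %s:%d-%d outside chromosome bounds [0,%d)",
                   ch, s, e, nchar(genome[[ch]])))
    toupper(substr(genome[[ch]], s + 1L, e))
  }, "")
}

#' Write / read instance tables
#'
#' Instances are serialized as a (optionally gzipped) TSV with header
#' `label  tf  cell_line  sequence`.
#'
#' @param instances instance table (`label`, `tf`, `cell`, `seq`).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_instances <- function(instances, path) {
  df <- data.frame(label = instances$label, tf = instances$tf,
                   cell_line = instances$cell, sequence = instances$seq)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character",
                                         "character", "character"))
  data.frame(label = df$label, tf = df$tf, cell = df$cell_line,
             seq = df$sequence)
}

#' Write / read a combination partition as JSON
#'
#' @param partition a `tfgate_partition`.
#' @param path JSON file path.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(lapply(unclass(partition), function(d)
    data.frame(tf = d$tf, cell = d$cell)), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(obj, function(d)
    if (length(d)) data.frame(tf = d$tf, cell = d$cell)
    else data.frame(tf = character(), cell = character()))
  structure(out, class = "tfgate_partition")
}

#' Read experiment metadata
#'
#' TSV with header `experiment_id  tf  cell_line  replicate`.
#'
#' @param path metadata file.
#' @return data.frame `experiment_id`, `tf`, `cell`, `replicate`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("experiment_id", "tf", "cell_line", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  data.frame(experiment_id = df$experiment_id, tf = df$tf,
             cell = df$cell_line, replicate = df$replicate)
}
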