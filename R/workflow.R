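#' Build a labeled dataset from peak files and a genome
#'
#' End-to-end dataset construction: for every experiment in the metadata
#' table, load its peaks, keep the top `top_n` by signal as fixed-width
#' summit-centered windows, extract their sequences (positives; windows
#' containing N are dropped), and pair each positive with a matched
#' negative — either a dinucleotide-preserving shuffle of the positive
#' (`background = "shuffle"`) or a sequence sampled from the union of
#' DNase-accessible regions not overlapping any peak of the experiment
#' (`background = "dhs"`).  Also computes the combination partition over
#' the experiments' (TF, cell line) pairs.
#'
#' @param peaks_dir directory holding `<experiment_id>.narrowPeak` files.
#' @param meta_file metadata TSV (see [read_metadata()]).
#' @param genome_file genome FASTA.
#' @param background `"shuffle"` or `"dhs"`.
#' @param dnase_files character vector of DNase peak files (required for
#'   `background = "dhs"`).
#' @param top_n peaks kept per experiment.
#' @param window instance width in bp.
#' @param holdout_valid_size held-out validation combinations for the
#'   partition (0 for tiny toy datasets).
#' @return list: `instances` (table), `partition` (`tfgate_partition`),
#'   `meta`.
#' @export
build_dataset <- function(peaks_dir, meta_file, genome_file,
                          background = c("dhs", "shuffle"),
                          dnase_files = NULL, top_n = 5000L,
                          window = 300L, holdout_valid_size = 0L) {
  background <- match.arg(background)
  meta <- read_metadata(meta_file)
  genome <- read_fasta_sequences(genome_file)
  union_dhs <- NULL
  if (background == "dhs") {
    if (is.null(dnase_files) || !length(dnase_files))
      stop("background='dhs' requires dnase_files")
    union_dhs <- build_union_dhs(lapply(dnase_files, load_peaks))
  }
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pf <- file.path(peaks_dir, paste0(meta$experiment_id[i], ".narrowPeak"))
    peaks <- load_peaks(pf)
    top <- select_top_peaks(peaks, top_n, window)
    seqs <- extract_sequences(top, genome)
    keep <- !grepl("N", seqs, fixed = TRUE)
    seqs <- seqs[keep]
    pos <- data.frame(label = 1L, tf = meta$tf[i], cell = meta$cell[i],
                      seq = seqs)
    neg <- if (background == "shuffle") {
      build_shuffled_negatives(pos)
    } else {
      nr <- build_dhs_negatives(union_dhs, top, length(seqs), window)
      ns <- extract_sequences(nr, genome)
      data.frame(label = 0L, tf = meta$tf[i], cell = meta$cell[i],
                 seq = ns)
    }
    out[[i]] <- rbind(pos, neg)
  }
  instances <- do.call(rbind, out)
  rownames(instances) <- NULL
  combos <- unique(meta[, c("tf", "cell")])
  partition <- partition_combinations(combos, replicates = meta,
                                      holdout_valid_size = holdout_valid_size)
  list(instances = instances, partition = partition, meta = meta)
}

#' Subset instances to a set of combinations
#'
#' @param instances instance table.
#' @param combos data.frame `tf`, `cell`.
#' @return the matching instance rows.
#' @export
instances_for_combos <- function(instances, combos) {
  key <- paste(instances$tf, instances$cell, sep = "\r")
  want <- paste(combos$tf, combos$cell, sep = "\r")
  instances[key %in% want, , drop = FALSE]
}
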