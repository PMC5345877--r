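#' ROC AUC (rank / Mann-Whitney formulation)
#'
#' Probability that a uniformly chosen positive outscores a uniformly chosen
#' negative, with ties counted 1/2.
#'
#' @param records data.frame with numeric `score` and binary `label`
#'   columns (extra columns ignored).
#' @return AUC in [0,1], or `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(records) {
  score <- records$score
  label <- records$label
  stopifnot(length(score) == length(label), all(label %in% c(0, 1)))
  np <- sum(label == 1)
  nn <- sum(label == 0)
  if (np == 0L || nn == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-group AUC
#'
#' Computes one AUC per prediction group (by TF, or by TF x cell-line
#' combination) plus the mean over groups.  Single-class groups are dropped
#' with a warning.
#'
#' @param records data.frame with `score`, `label`, `tf` and (for
#'   `key = "tf_cell"`) `cell` columns.
#' @param key `"tf"` or `"tf_cell"`.
#' @return list with `table` (data.frame `group`, `auc`, `n`, ordered by
#'   group name) and `mean` (mean of the group AUCs).
#' @export
grouped_auc <- function(records, key = c("tf", "tf_cell")) {
  key <- match.arg(key)
  grp <- if (key == "tf") as.character(records$tf)
         else paste(records$tf, records$cell, sep = ":")
  pieces <- split(records, grp)
  aucs <- vapply(pieces, function(p) {
    if (length(unique(p$label)) < 2L) return(NA_real_)
    roc_auc(p)
  }, 0.0)
  if (anyNA(aucs))
    warning(sum(is.na(aucs)), " group(s) dropped (single-class)")
  tab <- data.frame(group = names(pieces),
                    auc = unname(aucs),
                    n = vapply(pieces, nrow, 0L))
  tab <- tab[order(tab$group), , drop = FALSE]
  rownames(tab) <- NULL
  keep <- !is.na(tab$auc)
  list(table = tab[keep, , drop = FALSE], mean = mean(tab$auc[keep]))
}

#' Recall at a fixed FDR cutoff
#'
#' Chooses the smallest score threshold t whose prediction set
#' `{score >= t}` has false discovery rate `FP/(FP+TP) <= q` and returns the
#' recall of that set; 0 when no threshold qualifies.  Following the
#' original protocol the threshold is chosen on the test data itself, which
#' is optimistic by construction but keeps the metric defined uniformly
#' across methods without a training set.
#'
#' @param records data.frame with `score` and binary `label`.
#' @param q FDR cutoff in [0,1].
#' @return recall in [0,1].
#' @export
recall_at_fdr <- function(records, q) {
  score <- records$score
  label <- records$label
  stopifnot(all(label %in% c(0, 1)), q >= 0, q <= 1)
  P <- sum(label == 1)
  if (P == 0L) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; l <- label[o]
  # candidate thresholds = distinct scores; set {score >= t} includes ties
  distinct_end <- which(diff(c(s, -Inf)) != 0)   # last index of each tie block
  tp <- cumsum(l)[distinct_end]
  n_called <- distinct_end
  fdr <- (n_called - tp) / n_called
  feasible <- which(fdr <= q)
  if (!length(feasible)) return(0)
  max(tp[feasible]) / P
}

#' Shuffle one metadata field (negative control)
#'
#' Permutes the values of the chosen field uniformly across records,
#' leaving everything else untouched.  Shuffling the TF column tests
#' whether predictions are sequence/TF-specific; shuffling the cell line
#' tests cell specificity.
#'
#' @param records data.frame (instances or prediction records).
#' @param field `"tf"` or `"cell"`.
#' @return a copy of `records` with the field permuted.
#' @export
shuffle_field <- function(records, field = c("tf", "cell")) {
  field <- match.arg(field)
  out <- records
  out[[field]] <- records[[field]][sample.int(nrow(records))]
  out
}

#' Bin a genome and label bins by peak centers
#'
#' Tiles every chromosome with consecutive non-overlapping bins of
#' `bin_length` bp (last bin truncated) and labels a bin 1 when at least one
#' peak center falls inside it under half-open `[start, end)` coordinates.
#' A peak's center is its summit when present, else the interval midpoint
#' (floor).
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param bin_length bin width in bp, >= 1.
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `summit_offset`.
#' @return data.frame `chrom`, `start`, `end`, `label`.
#' @export
bin_and_label <- function(chrom_sizes, bin_length, peaks) {
  stopifnot(bin_length >= 1L, length(names(chrom_sizes)) == length(chrom_sizes))
  centers <- peak_centers(peaks)
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0L, len - 1L, by = bin_length)
    ends <- pmin(starts + bin_length, len)
    lab <- integer(length(starts))
    cc <- centers[peaks$chrom == ch]
    cc <- cc[cc >= 0 & cc < len]
    if (length(cc)) {
      idx <- floor(cc / bin_length) + 1L
      lab[unique(idx)] <- 1L
    }
    data.frame(chrom = ch, start = starts, end = ends, label = lab)
  })
  do.call(rbind, out)
}

# absolute center coordinate of each peak (summit if present, else midpoint)
peak_centers <- function(peaks) {
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  if (!is.null(peaks$summit_offset)) {
    has <- !is.na(peaks$summit_offset) & peaks$summit_offset >= 0
    mid[has] <- peaks$start[has] + peaks$summit_offset[has]
  }
  mid
}

#' Paired comparison of grouped AUCs
#'
#' Wilcoxon signed-rank test between two methods' per-group AUC tables
#' (matched by group name).  Provided as the package's paired test; the
#' exact test used for the published grouped p-values is unstated.
#'
#' @param tab_a,tab_b data.frames as returned in `grouped_auc()$table`.
#' @return htest object.
#' @export
compare_grouped_auc <- function(tab_a, tab_b) {
  m <- merge(tab_a, tab_b, by = "group", suffixes = c("_a", "_b"))
  if (nrow(m) < 2L) stop("need at least 2 matched groups")
  stats::wilcox.test(m$auc_a, m$auc_b, paired = TRUE, exact = FALSE)
}
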