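#' Allele-effect (SNP delta) matrix
#'
#' For a variant specified as a flank with a marked position and two
#' alleles, computes `predict_prob(flank with allele A) - predict_prob(flank
#' with allele B)` for every requested (TF, cell line) pair.  Entries lie in
#' (-1, 1): +1 means strong binding under allele A and none under allele B,
#' 0 means no predicted difference.  Swapping the alleles negates the matrix
#' exactly.
#'
#' @param params,config trained model.
#' @param snp one-row data.frame (or list) with `flank`, `pos` (1-based),
#'   `allele_a`, `allele_b`; the flank must carry one of the two alleles at
#'   `pos` and have the model input length.
#' @param tf_set,cell_set entity names (default: full vocabularies).
#' @return numeric matrix, TFs in rows, cell lines in columns.
#' @export
snp_delta <- function(params, config, snp,
                      tf_set = config$tf_vocab,
                      cell_set = config$cell_vocab) {
  flank <- as.character(snp$flank)
  pos <- as.integer(snp$pos)
  a <- toupper(as.character(snp$allele_a))
  b <- toupper(as.character(snp$allele_b))
  if (nchar(flank) != config$seq_length)
    stop(sprintf("flank length %d does not match model input length %d",
                 nchar(flank), config$seq_length))
  cur <- substr(flank, pos, pos)
  if (!cur %in% c(a, b))
    stop(sprintf("flank base '%s' at position %d matches neither allele (%s/%s)",
                 cur, pos, a, b))
  seq_a <- flank; substr(seq_a, pos, pos) <- a
  seq_b <- flank; substr(seq_b, pos, pos) <- b
  grid <- expand.grid(tf = tf_set, cell = cell_set, stringsAsFactors = FALSE)
  pa <- predict_batch(rep(seq_a, nrow(grid)), grid$tf, grid$cell,
                      params, config, type = "prob")
  pb <- predict_batch(rep(seq_b, nrow(grid)), grid$tf, grid$cell,
                      params, config, type = "prob")
  matrix(pa - pb, nrow = length(tf_set),
         dimnames = list(tf_set, cell_set))
}

#' Predicted-binding affinity matrix
#'
#' Binding probabilities for every sequence against every TF in one fixed
#' cell line; the raw material of the enhancer signature.
#'
#' @param params,config trained model.
#' @param seqs character vector of sequences (model input length).
#' @param cell cell-line name.
#' @param tf_set TF names (default: full vocabulary).
#' @return numeric matrix, sequences x TFs, entries in (0,1).
#' @export
affinity_matrix <- function(params, config, seqs, cell,
                            tf_set = config$tf_vocab) {
  n <- length(seqs)
  out <- matrix(NA_real_, n, length(tf_set),
                dimnames = list(names(seqs), tf_set))
  for (j in seq_along(tf_set))
    out[, j] <- predict_batch(seqs, tf_set[j], cell, params, config,
                              type = "prob")
  out
}

#' Enhancer-activity signature (first principal component)
#'
#' Column-centers the sequences x TFs affinity matrix (no scaling) and
#' takes the first principal component scores as a per-sequence signature.
#' Because a principal component's sign is arbitrary — and genuinely flips
#' between cell lines in practice — the sign is fixed so the signature
#' correlates non-negatively with the per-sequence mean affinity.
#'
#' @param A affinity matrix (sequences x TFs), e.g. from
#'   [affinity_matrix()].
#' @return numeric vector of signature values, one per sequence.
#' @export
enhancer_signature <- function(A) {
  stopifnot(is.matrix(A), nrow(A) >= 2L, ncol(A) >= 2L)
  C <- scale(A, center = TRUE, scale = FALSE)
  if (max(abs(C)) == 0) stop("affinity matrix has rank 0 after centering")
  sv <- svd(C, nu = 1L, nv = 0L)
  sig <- drop(sv$u[, 1L]) * sv$d[1L]
  r <- suppressWarnings(cor(sig, rowMeans(A)))
  if (!is.na(r) && r < 0) sig <- -sig
  sig
}

#' Top-vs-bottom signature test
#'
#' Ranks sequences by measured activity and compares the signature of the
#' top k against the bottom k with Welch's two-sample t-test.
#'
#' @param signature numeric signature per sequence.
#' @param activities measured activities (same length).
#' @param k group size (default 100).
#' @return list `t` (statistic), `p` (p-value), `df`.
#' @export
top_bottom_test <- function(signature, activities, k = 100L) {
  n <- length(signature)
  stopifnot(length(activities) == n)
  if (n < 2L * k)
    stop(sprintf("need at least %d sequences for top/bottom %d", 2L * k, k))
  o <- order(activities, decreasing = TRUE)
  top <- signature[o[seq_len(k)]]
  bottom <- signature[o[(n - k + 1L):n]]
  ht <- t.test(top, bottom, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Spearman correlation between signature and activity
#'
#' Rank correlation with average ranks for ties; `NA` (with a warning) for
#' constant input.
#'
#' @param signature,activities numeric vectors (length >= 3).
#' @return rho in [-1, 1] or NA.
#' @export
spearman_signature <- function(signature, activities) {
  stopifnot(length(signature) == length(activities),
            length(signature) >= 3L)
  if (sd(signature) == 0 || sd(activities) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(signature, activities, method = "spearman")
}

#' Hierarchically cluster learned embeddings
#'
#' Agglomerative clustering (average linkage) of the embedding rows under
#' correlation distance (1 - Pearson).  Identical rows merge first at
#' distance 0; the tree has exactly n-1 merges.
#'
#' @param E embedding matrix with entity names as rownames.
#' @return an [stats::hclust] object with entity labels.
#' @export
cluster_embeddings <- function(E) {
  stopifnot(is.matrix(E), nrow(E) >= 2L)
  d <- 1 - cor(t(E))
  d[d < 0] <- 0                       # numerical guard
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Serialize an embedding cluster tree as Newick
#'
#' @param hc an hclust from [cluster_embeddings()].
#' @return single Newick string.
#' @export
embedding_tree_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
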