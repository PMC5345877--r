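#' @importFrom stats plogis rnorm runif rbinom setNames cor t.test sd
#' @importFrom utils read.table write.table head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib tfgate, .registration = TRUE
NULL

# Fixed column order for all one-hot matrices and serialized filters.
DNA_BASES <- c("A", "C", "G", "T")

# base -> integer code lookup indexed by raw byte value; A=1 C=2 G=3 T=4, N=0.
.base_code_table <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab[utf8ToInt("N")] <- 0L; tab[utf8ToInt("n")] <- 0L
  tab
})

#' Convert a DNA string to integer codes
#'
#' Internal workhorse: maps A/C/G/T to 1/2/3/4 and N to 0 (case-insensitive,
#' so soft-masked lowercase is accepted).  Any other character is an error
#' naming the offending position.
#'
#' @param seq single character string over A,C,G,T,N (any case).
#' @return integer vector of codes, one per base.
#' @keywords internal
#' @noRd
seq_to_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 1L) stop("sequence must be non-empty")
  codes <- .base_code_table[utf8ToInt(seq)]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("invalid character '%s' at position %d (alphabet is A,C,G,T,N)",
                 substr(seq, bad, bad), bad))
  }
  codes
}

codes_to_seq <- function(codes) {
  chars <- c("N", DNA_BASES)[codes + 1L]
  paste(chars, collapse = "")
}

# Reverse-complement on the integer code scale: A(1)<->T(4), C(2)<->G(3),
# N(0)->N(0), then reverse.
revcomp_codes <- function(codes) {
  comp <- ifelse(codes == 0L, 0L, 5L - codes)
  rev(comp)
}

#' One-hot encode a DNA sequence
#'
#' Represents a sequence of length N as an N x 4 binary matrix under the
#' fixed column order (A, C, G, T).  Row i carries a single 1 in the column
#' of base i; an ambiguous base N yields an all-zero row, which contributes
#' nothing under the linear convolution.
#'
#' @param seq character scalar over the alphabet A,C,G,T,N (case-insensitive).
#' @return integer matrix of dimension `nchar(seq)` x 4 with colnames
#'   `c("A","C","G","T")`.
#' @examples
#' one_hot_encode("ACGT")   # the 4x4 identity matrix
#' @export
one_hot_encode <- function(seq) {
  codes <- seq_to_codes(seq)
  m <- matrix(0L, nrow = length(codes), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  nz <- which(codes > 0L)
  m[cbind(nz, codes[nz])] <- 1L
  m
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; N maps to N.  Input is uppercased.
#'
#' @param seq character scalar over A,C,G,T,N.
#' @return character scalar.
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' @export
reverse_complement <- function(seq) {
  codes_to_seq(revcomp_codes(seq_to_codes(seq)))
}

#' Dinucleotide-preserving shuffle
#'
#' Returns a random permutation of `seq` with exactly the same multiset of
#' overlapping dinucleotides (hence identical mononucleotide counts and the
#' same first and last base).  Implemented as the Eulerian-path
#' (Altschul-Erickson) algorithm, which preserves counts exactly and samples
#' uniformly among valid shuffles.  Uses the R session RNG: call
#' [set.seed()] for reproducibility.
#'
#' @param seq character scalar over A,C,G,T of length >= 2.  N is not
#'   permitted; callers building shuffled negatives must drop N-containing
#'   positives first.
#' @return character scalar, a dinucleotide-preserving shuffle of `seq`.
#' @examples
#' set.seed(1)
#' dinucleotide_shuffle("ACGTACGT")
#' @export
dinucleotide_shuffle <- function(seq) {
  codes <- seq_to_codes(seq)
  n <- length(codes)
  if (n < 2L) stop("dinucleotide shuffle requires length >= 2")
  if (any(codes == 0L)) stop("dinucleotide shuffle is undefined over N bases")

  first <- codes[1L]
  last <- codes[n]
  # adjacency lists: edges[[v]] = multiset of successors of base v
  edges <- lapply(1:4, function(v) codes[which(codes[-n] == v) + 1L])
  verts <- which(vapply(edges, length, 1L) > 0L | seq_len(4L) == last)

  if (length(verts) == 1L) return(seq)  # homopolymer: unique shuffle

  # Altschul-Erickson: pick one random outgoing "last edge" per non-terminal
  # vertex; accept when those edges form paths all reaching the terminal
  # vertex; then randomly permute the remaining edges of every vertex.
  nonterm <- setdiff(verts, last)
  nonterm <- nonterm[vapply(edges[nonterm], length, 1L) > 0L]
  repeat {
    lastedge <- vapply(nonterm, function(v) {
      e <- edges[[v]]
      e[sample.int(length(e), 1L)]
    }, 0L)
    names(lastedge) <- nonterm
    ok <- TRUE
    for (v in nonterm) {
      # follow chosen last-edges from v; must reach `last` without a cycle
      seen <- integer(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || !(cur %in% nonterm)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastedge[[as.character(cur)]]
      }
      if (!ok) break
    }
    if (ok) break
  }

  shuffled <- lapply(1:4, function(v) {
    e <- edges[[v]]
    if (v %in% nonterm) {
      le <- lastedge[[as.character(v)]]
      # remove ONE occurrence of the chosen last edge, shuffle rest, append
      drop <- which(e == le)[1L]
      rest <- e[-drop]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      c(rest, le)
    } else {
      if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  })

  # walk the Eulerian path from `first`, consuming each adjacency list in order
  ptr <- rep(1L, 4L)
  out <- integer(n)
  out[1L] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  codes_to_seq(out)
}

#' Count overlapping dinucleotides
#'
#' @param seq character scalar over A,C,G,T.
#' @return named integer vector of length 16 (AA, AC, ..., TT).
#' @export
dinucleotide_counts <- function(seq) {
  codes <- seq_to_codes(seq)
  if (any(codes == 0L)) stop("dinucleotide counts are undefined over N bases")
  n <- length(codes)
  # first-base-major order: AA, AC, AG, AT, CA, ...
  nm <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, 4L))
  cnt <- setNames(integer(16L), nm)
  if (n >= 2L) {
    idx <- (codes[-n] - 1L) * 4L + codes[-1L]
    cnt[] <- tabulate(idx, nbins = 16L)
  }
  cnt
}

#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning uppercase
#' plain character strings (soft-masked lowercase accepted and uppercased).
#'
#' @param path FASTA file (single- or multi-record).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
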