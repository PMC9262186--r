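#' One-hot encode an RNA sequence
#'
#' Each position becomes an indicator row over the bases A, C, G, U (in that
#' column order). The ambiguous base N encodes as an all-zero row so genome
#' scans tolerate assembly gaps.
#'
#' @param seq RNA string over A, C, G, U, N.
#' @return L x 4 binary matrix with columns A, C, G, U.
#' @examples
#' one_hot_encode("ACGU")
#' @export
one_hot_encode <- function(seq) {
  assert_rna(seq, allow_n = TRUE)
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, RNA_BASES)
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, RNA_BASES))
  hit <- which(!is.na(idx))
  m[cbind(hit, idx[hit])] <- 1
  m
}

# 5x5 pairing weight lookup (A,C,G,U,N); N never pairs
pairing_weights <- function() {
  w <- matrix(0, 5, 5, dimnames = list(c(RNA_BASES, "N"),
                                       c(RNA_BASES, "N")))
  w["G", "C"] <- w["C", "G"] <- 1
  w["A", "U"] <- w["U", "A"] <- 0.66
  w["G", "U"] <- w["U", "G"] <- 0.33
  w
}

#' Base-pairing potential matrix encoding
#'
#' Encodes a sequence as the L x L matrix of pairwise pairing potentials:
#' G-C pairs weigh 1, A-U 0.66 and the G-U wobble pair 0.33; any other
#' combination (including pairs involving N) is 0. The matrix is symmetric
#' and depends only on the unordered base pair; the diagonal is zero since
#' no base pairs with itself.
#'
#' @param seq RNA string over A, C, G, U, N.
#' @return symmetric L x L numeric matrix.
#' @examples
#' pairing_matrix_encode("GCAU")
#' @export
pairing_matrix_encode <- function(seq) {
  assert_rna(seq, allow_n = TRUE)
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, c(RNA_BASES, "N"))
  idx[is.na(idx)] <- 5L
  w <- pairing_weights()
  m <- w[idx, idx, drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Encode a batch of equal-length sequences
#'
#' Stacks per-sequence encodings into one tensor with a leading batch
#' dimension: `B x L x 4` for one-hot inputs, `B x L x L` (single channel)
#' for pairing matrices.
#'
#' @param seqs character vector of equal-length sequences.
#' @param encoding `"onehot"` or `"matrix"`.
#' @return 3-dimensional numeric array.
#' @export
encode_batch <- function(seqs, encoding = c("onehot", "matrix")) {
  encoding <- match.arg(encoding)
  if (length(unique(nchar(seqs))) != 1L)
    stop("all sequences in a batch must have equal length", call. = FALSE)
  L <- nchar(seqs[1])
  flat <- input_matrix(seqs, encoding)
  d2 <- if (encoding == "onehot") 4L else L
  arr <- array(0, dim = c(length(seqs), L, d2))
  for (b in seq_along(seqs)) arr[b, , ] <- matrix(flat[, b], nrow = L)
  arr
}

# column-major (H*W) x B input for the C++ kernels; H = L, W = 4 or L
input_matrix <- function(seqs, encoding) {
  L <- nchar(seqs[1])
  if (encoding == "onehot") {
    out <- matrix(0, nrow = L * 4L, ncol = length(seqs))
    for (b in seq_along(seqs)) out[, b] <- one_hot_encode(seqs[b])
    out
  } else {
    out <- matrix(0, nrow = L * L, ncol = length(seqs))
    w <- pairing_weights()
    for (b in seq_along(seqs)) {
      idx <- match(strsplit(seqs[b], "")[[1]], c(RNA_BASES, "N"))
      idx[is.na(idx)] <- 5L
      out[, b] <- w[idx, idx]
    }
    out
  }
}
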