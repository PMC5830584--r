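# Internal helpers shared across modules.

# Column-wise Pearson correlation between two T x V matrices.
# Columns with zero variance in either input yield r = 0 and are flagged.
.cor_cols <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  sa <- sqrt(colSums(a^2))
  sb <- sqrt(colSums(b^2))
  num <- colSums(a * b)
  bad <- sa < .Machine$double.eps^0.5 | sb < .Machine$double.eps^0.5
  r <- ifelse(bad, 0, num / (sa * sb))
  attr(r, "zero_variance") <- bad
  r
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

# Average consecutive groups of `by` rows (anti-aliased downsampling).
.downsample_rows <- function(x, by) {
  if (by == 1L) return(x)
  n <- nrow(x)
  if (n %% by != 0L)
    .stopf("row count %d is not a multiple of the downsampling factor %d", n, by)
  grp <- rep(seq_len(n %/% by), each = by)
  rowsum(x, grp, reorder = FALSE) / by
}

# Causal discrete convolution of each column of x with kernel taps,
# truncated to the input length (zero initial state before the series).
.convolve_cols <- function(x, taps) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- length(taps)
  pad <- matrix(0, nrow = m - 1L, ncol = ncol(x))
  out <- stats::filter(rbind(pad, x), taps, method = "convolution", sides = 1L)
  out <- matrix(out, ncol = ncol(x))[m:(m + n - 1L), , drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}
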