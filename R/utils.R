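## Internal helpers shared across modules.

#' @noRd
.assertScalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s]", name, min, max), call. = FALSE)
  invisible(x)
}

## counts-per-10k log1p normalization; keeps sparsity for dgCMatrix input.
#' @noRd
.cp10kLog <- function(counts) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  if (inherits(counts, "sparseMatrix")) {
    norm <- counts %*% Matrix::Diagonal(x = 1e4 / cs)
    norm <- methods::as(norm, "CsparseMatrix")
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(counts)
    norm
  } else {
    log1p(sweep(as.matrix(counts), 2, cs, "/") * 1e4)
  }
}

## Deterministic per-stage seed derived from a global seed and a stage name.
## Simple polynomial string hash folded into the 31-bit positive range so the
## same (seed, stage) always maps to the same child seed.
#' @noRd
.deriveSeed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' @noRd
.asDense <- function(x) if (inherits(x, "Matrix")) as.matrix(x) else x
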