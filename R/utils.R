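# internal helpers shared across modules

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_mask <- function(x, arg = "mask") {
  if (inherits(x, "binary_vessel_map") || inherits(x, "skeleton_map")) x <- x$mask
  if (inherits(x, "faz_selection")) x <- x$mask
  if (!is.matrix(x) || !is.logical(x))
    stopf("`%s` must be a logical matrix (or an object carrying one)", arg)
  x
}

# 1-D convolution of `mat` with symmetric kernel `k` along the given margin,
# replicate padding at the borders
conv1d <- function(mat, k, margin = 1L) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(mat)[margin]
  acc <- matrix(0, nrow(mat), ncol(mat))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    acc <- acc + k[j] * (if (margin == 1L) mat[idx, , drop = FALSE]
                         else mat[, idx, drop = FALSE])
  }
  acc
}
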