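# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a parent seed
#'
#' Deterministic integer hash kept strictly below 2^31 so the result is a
#' valid R seed on all platforms.
#'
#' @param seed parent seed (integer-valued).
#' @param i stream index (integer-valued, >= 0).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  # two rounds of a multiplicative congruential mix, in double precision
  # (exact: products stay < 2^53)
  s <- (s * 48271) %% 2147483647
  s <- (s + as.numeric(i) * 69621) %% 2147483647
  s <- (s * 16807) %% 2147483647
  as.integer(s)
}

#' Run an expression with a locally-set RNG seed
#'
#' Saves and restores the global RNG state so callers' random streams are not
#' perturbed.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Bounding box of TRUE cells of a logical matrix, optionally padded; returns
# list(rows =, cols =) of index vectors, or NULL for an empty mask.
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(mask), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(mask), max(idx[, 2]) + pad)
  list(rows = r0:r1, cols = c0:c1)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Sample standard deviation that returns 0 for length-1 input.
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

# log2 with the 0 * log(0) = 0 convention applied by callers via xlog2x.
xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

msg <- function(...) message("[pcatomics] ", ...)
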