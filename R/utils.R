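# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generation does not disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Shift a matrix by (dr, dc), padding with `fill`
#'
#' Entry [r, c] of the result is m[r + dr, c + dc] when that index is in
#' range, otherwise `fill`.
#' @noRd
shift_matrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr)
  cs <- seq_len(nc)
  src_r <- rs + dr
  src_c <- cs + dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[rs[ok_r], cs[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# x * log2(x) with the 0 log 0 = 0 convention
xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# Entropy (bits) of a probability vector
entropy_bits <- function(p) {
  -sum(xlog2x(p))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
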