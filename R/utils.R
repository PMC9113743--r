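#' Wrap phase angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(6.0)       # 6 - 2*pi
#' wrap_phase(c(0, pi))  # pi maps to pi, not -pi
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% puts exact pi at -pi; keep the interval half-open at the top
  y[y == -pi] <- pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# unweighted centroid (x = column, y = row) of TRUE pixels in a mask
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}
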