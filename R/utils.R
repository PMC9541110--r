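`%||%` <- function(x, y) if (is.null(x)) y else x

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Report tables use conventional half-up rounding (printed-table style)
#' rather than banker's rounding.
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues formula; `axis` need not be normalized.
#' @param axis length-3 numeric axis.
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ax <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * ax + (1 - ct) * tcrossprod(a)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

# Run expr with a local RNG state seeded at `seed`; restores global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# skew-symmetric matrix -> axial vector
vee <- function(m) c(m[3, 2], m[1, 3], m[2, 1])

# Zero-phase filtering with odd-reflection end padding, so constants pass
# unchanged and edge transients do not leak into the series. The pad length
# is sized from the filter's slowest pole so the zero-initial-condition
# transient has decayed below ~1e-13 of the signal before the kept samples.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  r <- max(Mod(polyroot(rev(bf$a))))
  r <- min(max(r, 0.1), 0.999999)
  pad <- min(n - 1, max(50L, ceiling(log(1e-13) / log(r))))
  if (pad < 3) return(as.numeric(signal::filtfilt(bf, x)))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  as.numeric(y[(pad + 1):(pad + n)])
}
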