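# internal helpers shared across modules

# Evaluate code with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Number of residues in a closed residue interval
#'
#' Residue spans throughout the package are closed intervals `[from, to]`
#' on residue indices, so a span such as 74--99 contains `99 - 74 + 1 = 26`
#' residues. Used for loop spans and report bookkeeping.
#'
#' @param span integer vector of length 2, `c(from, to)` with `from <= to`.
#' @return integer: the inclusive residue count.
#' @examples
#' span_length(c(74, 99))
#' @export
span_length <- function(span) {
  if (length(span) != 2L || any(is.na(span)) || span[2] < span[1])
    stop("`span` must be c(from, to) with from <= to")
  as.integer(span[2] - span[1] + 1L)
}

# coerce a trace / matrix / data.frame to an n x 3 coordinate matrix
as_points <- function(x) {
  if (inherits(x, "catrace")) {
    if (isTRUE(x$broken))
      stop("trace is flagged broken; topology operations refuse broken traces",
           call. = FALSE)
    return(x$coords)
  }
  m <- as.matrix(x)
  if (ncol(m) != 3L || !is.numeric(m))
    stop("expected an n x 3 numeric coordinate matrix")
  storage.mode(m) <- "double"
  unname(m)
}

# uniform unit vectors (rows), consuming the current RNG stream
unit_dirs <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# random far-away closure points on a sphere centred on the chain's
# bounding box, radius 12 x its diagonal (spec of the closure scheme
# requires >= 10 x)
closure_points <- function(pts, n) {
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  ctr <- (lo + hi) / 2
  rad <- 12 * max(sqrt(sum((hi - lo)^2)), 1)
  d <- unit_dirs(n)
  sweep(d * rad, 2, ctr, "+")
}

# evaluate an integer-coefficient polynomial at integer t, |result|
eval_poly_abs <- function(coef, t) {
  if (length(coef) > 45L) return(NA_real_)  # keep double arithmetic exact
  abs(sum(coef * t^(seq_along(coef) - 1)))
}

# resample a polyline (open) to n points, evenly spaced by arc length
resample_polyline <- function(pts, n) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  tt <- seq(0, L, length.out = n)
  idx <- findInterval(tt, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(pts)] <- nrow(pts) - 1L
  w <- (tt - cum[idx]) / pmax(seg[idx], 1e-12)
  pts[idx, , drop = FALSE] * (1 - w) + pts[idx + 1L, , drop = FALSE] * w
}

# rotation matrix taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    # opposite: rotate pi about any axis perpendicular to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}
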