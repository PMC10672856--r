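#' KMT reduction of a polygonal chain
#'
#' Iteratively deletes a vertex whenever the triangle spanned by it and its
#' two neighbours is not crossed by any other segment of the chain, until no
#' vertex can be removed. The output is topologically equivalent to the
#' input (ambient isotopic with endpoints fixed for open chains); endpoints
#' are never deleted.
#'
#' @param x a [ca_trace()], or an `n x 3` coordinate matrix.
#' @param closed logical; treat the chain as a closed loop.
#' @return reduced `m x 3` matrix with attribute `kept`, the 1-based indices
#'   of the surviving input vertices.
#' @export
kmt_reduce <- function(x, closed = FALSE) {
  pts <- as_points(x)
  if (nrow(pts) < 3L) return(pts)
  cpp_kmt(pts, closed)
}

#' Close an open chain for knot classification
#'
#' An open chain has no knot type until its endpoints are joined. `direct`
#' closure joins them with a single segment; `random_sphere` joins both
#' endpoints to a random far-away point drawn uniformly on a sphere whose
#' radius is 12 times the chain's bounding-box diagonal (well beyond the
#' 10x lower bound needed for the closure to act "at infinity").
#'
#' @param x trace or `n x 3` matrix (open chain).
#' @param method `"random_sphere"` or `"direct"`.
#' @param n_closures number of random closures (ignored for `direct`).
#' @param seed integer seed; closures are deterministic given the seed.
#' @return list of closed loops, each an `m x 3` matrix whose rows are
#'   traversed cyclically.
#' @export
close_chain <- function(x, method = c("random_sphere", "direct"),
                        n_closures = 100, seed = NULL) {
  method <- match.arg(method)
  pts <- as_points(x)
  degenerate <- nrow(pts) < 3L || {
    sv <- svd(scale(pts, scale = FALSE))$d
    sv[2] < 1e-9 * max(sv[1], 1e-12)
  }
  if (degenerate)
    return(list(rbind(pts)))  # (near-)collinear chain: trivial unknot
  if (method == "direct") return(list(pts))
  if (is.null(seed)) stop("`seed` is required for random_sphere closures")
  stopifnot(n_closures >= 1)
  with_seed(seed, {
    far <- closure_points(pts, n_closures)
    lapply(seq_len(n_closures), function(k) rbind(pts, far[k, ]))
  })
}

#' Alexander polynomial value of a closed loop
#'
#' Projects the loop along a seeded random direction (retrying on degenerate
#' projections), builds the crossing diagram, and evaluates the Alexander
#' polynomial -- the determinant of the crossing-relation matrix with one
#' row and column deleted, normalised to integer coefficients with
#' `Delta(1) = 1` -- at integer `t`. The value is invariant under the
#' choice of projection.
#'
#' @param loop closed polygonal curve (`n x 3` matrix, rows cyclic).
#' @param t integer evaluation point (classification uses -1 and -2).
#' @param seed seed for the projection direction.
#' @return non-negative integer `|Delta(t)|`.
#' @examples
#' \donttest{
#' phi <- seq(0, 2 * pi, length.out = 200)[-200]
#' tre <- cbind((3 + 1.4 * cos(3 * phi)) * cos(2 * phi),
#'              (3 + 1.4 * cos(3 * phi)) * sin(2 * phi), 1.4 * sin(3 * phi))
#' alexander_value(tre, -1)  # 3
#' }
#' @export
alexander_value <- function(loop, t = -1, seed = 1) {
  pts <- as_points(loop)
  res <- with_seed(seed, cpp_loop_poly(pts, unit_dirs(256)))
  eval_poly_abs(res$coef, t)
}

# Internal single-chain classification consuming the current RNG stream.
classify_points <- function(pts, n_closures = 100,
                            method = c("random_sphere", "direct"),
                            early_stop = TRUE, max_reps = 3L) {
  method <- match.arg(method)
  n <- nrow(pts)
  if (n < 3L)
    return(list(notation = "0_1", probability = 1, d1 = 1, n_evaluated = 0L))
  closures <- if (method == "direct") matrix(0, 0, 3)
              else closure_points(pts, n_closures)
  dirs <- unit_dirs(12L * max(n_closures, 1L) + 128L)
  res <- cpp_classify_open(pts, closures, dirs, method == "direct",
                           ambiguous_d1(),
                           if (early_stop) min(30L, n_closures) else 0L,
                           max_reps)
  resolve_label(res)
}

# Turn per-closure |Delta(-1)| votes (plus representative polynomials for
# ambiguous values) into a consensus label.
resolve_label <- function(res) {
  d1s <- res$d1[!is.na(res$d1)]
  if (!length(d1s))
    return(list(notation = "unknown", probability = 0, d1 = NA_real_,
                n_evaluated = res$n_evaluated))
  tab <- sort(table(d1s), decreasing = TRUE)
  winner <- as.numeric(names(tab)[1])
  prob <- as.numeric(tab[1]) / length(res$d1)
  d2 <- NA_real_
  if (winner != 1 && winner %in% ambiguous_d1()) {
    reps <- which(res$rep_d1 == winner)
    if (length(reps)) {
      d2s <- vapply(res$polys[reps], eval_poly_abs, numeric(1), t = -2)
      d2s <- d2s[!is.na(d2s)]
      if (length(d2s)) {
        t2 <- sort(table(d2s), decreasing = TRUE)
        d2 <- as.numeric(names(t2)[1])
      }
    }
  }
  notation <- lookup_notation(winner, d2)
  structure(list(notation = notation, probability = prob, d1 = winner,
                 d2 = d2, n_evaluated = res$n_evaluated),
            class = "knot_label")
}

#' @export
print.knot_label <- function(x, ...) {
  cat(sprintf("<knot_label> %s  (probability %.2f over %d closures)\n",
              x$notation, x$probability, x$n_evaluated))
  invisible(x)
}

#' Determine the knot type of an open chain
#'
#' Classifies an open chain by consensus over stochastic closures: the
#' chain is KMT-reduced, each closure is joined through a random far-away
#' point, and the Alexander invariants `|Delta(-1)|` and (when needed to
#' break ties such as 4_1 vs 5_1 or 6_1 vs 3_1#3_1) `|Delta(-2)|` are
#' looked up in a built-in table covering the prime knots 0_1, 3_1, 4_1,
#' 5_1, 5_2, 6_1, 6_2, 6_3, 7_1 and their connected sums (pairwise, plus
#' trefoil sums up to 12 factors). The label is the majority vote and the
#' probability its vote fraction. Labels are achiral (the Alexander
#' polynomial cannot see chirality).
#'
#' @param x a [ca_trace()] (must not be broken) or `n x 3` matrix.
#' @param n_closures closures to attempt (default 100).
#' @param seed integer seed, required: results are deterministic given it.
#' @param method closure method, `"random_sphere"` (default) or `"direct"`.
#' @param early_stop stop early once the first `min(30, n_closures)`
#'   closures agree unanimously (the reported probability is then 1).
#' @return a `knot_label`: list with `notation` (e.g. `"3_1"`, `"0_1"`,
#'   `"3_1#3_1"`, or `"unknown"`) and `probability` in `[0, 1]`.
#' @export
classify_knot <- function(x, n_closures = 100, seed = NULL,
                          method = c("random_sphere", "direct"),
                          early_stop = TRUE) {
  if (is.null(seed)) stop("`seed` is required (classification is stochastic)")
  pts <- as_points(x)
  with_seed(seed, classify_points(pts, n_closures, match.arg(method),
                                  early_stop))
}
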