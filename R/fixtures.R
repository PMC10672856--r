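# Parametric generators of Calpha-like polylines with known topology.
# These stand in for predicted models: every topology operation is testable
# against construction ground truth, with no structure prediction run.

#' Recipe for a synthetic knotted chain
#'
#' Supported knots and their closed-curve parametrisations:
#' torus knots `T(2,q)` for 3_1, 5_1, 7_1; the standard figure-eight
#' space curve for 4_1; Lissajous curves for 5_2 (frequencies 2,3,7,
#' phases 0.3, 1.5, 0) and 6_1 (frequencies 2,3,5, phases 0.9, 0.9, 0);
#' a circle for 0_1. (6_3 has no convenient low-harmonic parametrisation
#' and is classification-table-only.) The curve is cut open at a seeded
#' location chosen (and verified) to preserve the knot type, short
#' straight escape tails are grown from the cut ends along
#' maximal-clearance directions (so the endpoints leave the globule, as
#' in a real open backbone), the polyline is resampled to `n_points` at
#' `spacing` angstrom mean consecutive distance, and Gaussian coordinate
#' noise is added.
#'
#' @param knot one of `"0_1"`, `"3_1"`, `"4_1"`, `"5_1"`, `"5_2"`,
#'   `"6_1"`, `"7_1"`.
#' @param n_points number of Calpha points (>= 30).
#' @param open_fraction fraction of the closed curve removed at the cut.
#' @param noise_sigma coordinate noise, angstrom.
#' @param seed integer seed.
#' @param spacing target mean consecutive spacing, angstrom (Calpha: 3.8).
#' @return object of class `knot_recipe`.
#' @export
knot_recipe <- function(knot = "3_1", n_points = 100, open_fraction = 0.05,
                        noise_sigma = 0, seed = 1, spacing = 3.8) {
  knots <- c("0_1", "3_1", "4_1", "5_1", "5_2", "6_1", "7_1")
  if (!knot %in% knots)
    stop("unsupported knot notation: ", knot,
         " (supported: ", paste(knots, collapse = ", "), ")")
  if (n_points < 30) stop("n_points must be >= 30")
  if (open_fraction <= 0 || open_fraction >= 0.5)
    stop("open_fraction must be in (0, 0.5)")
  structure(list(knot = knot, n_points = as.integer(n_points),
                 open_fraction = open_fraction, noise_sigma = noise_sigma,
                 seed = as.integer(seed), spacing = spacing),
            class = "knot_recipe")
}

closed_curve <- function(knot, n_fine = 1200) {
  tt <- seq(0, 2 * pi, length.out = n_fine + 1)[-(n_fine + 1)]
  torus <- function(q) {
    R <- 3; r <- 1.4
    cbind((R + r * cos(q * tt)) * cos(2 * tt),
          (R + r * cos(q * tt)) * sin(2 * tt),
          r * sin(q * tt))
  }
  liss <- function(fx, fy, fz, px, py)
    cbind(cos(fx * tt + px), cos(fy * tt + py), cos(fz * tt))
  switch(knot,
         "0_1" = cbind(cos(tt), sin(tt), 0 * tt),
         "3_1" = torus(3),
         "5_1" = torus(5),
         "7_1" = torus(7),
         "4_1" = cbind((2 + cos(2 * tt)) * cos(3 * tt),
                       (2 + cos(2 * tt)) * sin(3 * tt), sin(4 * tt)),
         "5_2" = liss(2, 3, 7, 0.3, 1.5),
         "6_1" = liss(2, 3, 5, 0.9, 0.9))
}

#' Generate an open chain of known knot type
#'
#' @param recipe a [knot_recipe()].
#' @return a [ca_trace()] with attribute `ground_truth` (the knot label).
#' @export
generate_knot <- function(recipe) {
  stopifnot(inherits(recipe, "knot_recipe"))
  with_seed(recipe$seed, {
    cur <- closed_curve(recipe$knot)
    nf <- nrow(cur)
    ncut <- max(1L, round(recipe$open_fraction * nf))
    # Seeded cut location, restricted to positions whose resulting endpoints
    # are well separated from the rest of the curve: a cut at a buried spot
    # (e.g. the inner equator of a torus knot) leaves endpoints whose
    # closure is ambiguous and can change the open-chain knot type.
    w <- max(3L, round(0.08 * nf))
    score <- vapply(seq_len(nf), function(i) {
      excl <- ((i - 1L + c(-(w:1), 0L, 1:w)) %% nf) + 1L
      min(sqrt(rowSums(sweep(cur[-excl, , drop = FALSE], 2, cur[i, ])^2)))
    }, numeric(1))
    cut_score <- score[((seq_len(nf) + ncut - 1L) %% nf) + 1L] +
      score[((seq_len(nf) - 2L) %% nf) + 1L]
    safe <- which(cut_score >= stats::quantile(cut_score, 0.6))
    safe <- safe[sample.int(length(safe))]  # seeded candidate order
    # straight escape tails at the cut ends; the direction is chosen for
    # maximal clearance from the rest of the chain so a tail cannot thread
    # a loop and change the topology
    grow_tails <- function(pts) {
      ctr <- colMeans(pts)
      ext <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
      tail_pts <- function(p) {
        # clearance is judged against chain points outside the endpoint's
        # own neighbourhood (the strand it grows from always starts close)
        other <- pts[sqrt(rowSums(sweep(pts, 2, p)^2)) > 0.15 * ext, ,
                     drop = FALSE]
        cands <- rbind((p - ctr) / max(sqrt(sum((p - ctr)^2)), 1e-9),
                       unit_dirs(60))
        steps <- seq_len(12) * (0.09 * ext)
        best <- NULL; best_clear <- -Inf
        for (ci in seq_len(nrow(cands))) {
          tp <- sweep(outer(steps, cands[ci, ]), 2, p, "+")
          clear <- min(apply(tp, 1, function(q)
            min(sqrt(rowSums(sweep(other, 2, q)^2)))))
          if (clear > best_clear) { best_clear <- clear; best <- tp }
          if (best_clear > 0.45 * ext) break  # ample clearance
        }
        best
      }
      m0 <- nrow(pts)
      rbind(tail_pts(pts[1, ])[rev(seq_len(12)), , drop = FALSE], pts,
            tail_pts(pts[m0, ]))
    }
    # The knot type of an open chain depends on where the closed curve is
    # cut (cutting inside a clasp region unties part of the knot), so each
    # candidate cut is assembled (cut + tails + resampling) and verified;
    # cuts that fail to preserve the requested type are rejected.
    pts <- NULL
    for (cut in utils::head(safe, 30L)) {
      keep <- ((cut + seq_len(nf - ncut) - 1L) %% nf) + 1L
      cand <- resample_polyline(grow_tails(cur[keep, , drop = FALSE]),
                                recipe$n_points)
      msp <- mean(sqrt(rowSums((cand[-1, , drop = FALSE] -
                                  cand[-nrow(cand), , drop = FALSE])^2)))
      cand <- cand * (recipe$spacing / msp)
      if (recipe$knot == "0_1") { pts <- cand; break }
      chk <- classify_points(cand, n_closures = 50)
      if (chk$notation == recipe$knot && chk$probability >= 0.9) {
        pts <- cand
        break
      }
    }
    if (is.null(pts))
      stop("could not find a type-preserving cut for ", recipe$knot,
           " with seed ", recipe$seed)
    if (recipe$noise_sigma > 0)
      pts <- pts + matrix(rnorm(length(pts), sd = recipe$noise_sigma),
                          ncol = 3)
    tr <- ca_trace(pts, source = "synthetic")
    attr(tr, "ground_truth") <- recipe$knot
    tr
  })
}

#' Concatenate knotted units into a composite chain
#'
#' Units are rotated so their end-to-end vector lies along +x, placed
#' consecutively along x with non-overlapping bounding boxes, and joined
#' by straight linkers of `linker_points` vertices at the unit spacing
#' (lightly jittered, as real linkers are never perfectly collinear) --
#' the synthetic analogue of a tandem-repeat fusion whose every domain
#' folds back on itself. The true factor list is recorded.
#'
#' @param units list of [knot_recipe()]s (N- to C-terminal order).
#' @param linker_points vertices per straight linker (default 9).
#' @return a [ca_trace()] with attribute `ground_truth`, a data frame of
#'   the units' labels and point spans in the assembled chain.
#' @export
concat_knots <- function(units, linker_points = 9) {
  stopifnot(length(units) >= 1)
  traces <- lapply(units, generate_knot)
  spacing <- units[[1]]$spacing
  gap <- (linker_points + 1) * spacing
  placed <- list(); gt <- list(); offset <- 0
  prev_end <- NULL
  for (k in seq_along(traces)) {
    p <- traces[[k]]$coords
    ee <- p[nrow(p), ] - p[1, ]
    if (sqrt(sum(ee^2)) > 1e-9) {
      Rm <- rotation_between(ee, c(1, 0, 0))
      p <- p %*% t(Rm)
    }
    p <- sweep(p, 2, p[1, ])  # start at origin
    if (k > 1) {
      # place after the previous unit: start = prev end + gap along x,
      # pushed further until bounding boxes are disjoint
      shift <- prev_end + c(gap, 0, 0)
      p2 <- sweep(p, 2, shift, "+")
      while (min(p2[, 1]) <= prev_max_x + spacing) {
        shift[1] <- shift[1] + spacing
        p2 <- sweep(p, 2, shift, "+")
      }
      # straight linker from the previous end to this start, with a small
      # seeded jitter: real linkers are never perfectly collinear, and
      # exact collinearity creates degenerate subchain geometry
      lk_n <- max(linker_points, ceiling(sqrt(sum((p2[1, ] - prev_end)^2)) /
                                           spacing) - 1L)
      w <- seq_len(lk_n) / (lk_n + 1)
      linker <- outer(1 - w, prev_end) + outer(w, p2[1, ])
      linker <- linker + with_seed(units[[k]]$seed + 131L,
                                   matrix(rnorm(3 * lk_n, sd = 0.15),
                                          ncol = 3))
      placed[[length(placed) + 1L]] <- linker
      p <- p2
    }
    start_idx <- sum(vapply(placed, nrow, integer(1))) + 1L
    placed[[length(placed) + 1L]] <- p
    gt[[k]] <- data.frame(unit = k, label = attr(traces[[k]], "ground_truth"),
                          start = start_idx, end = start_idx + nrow(p) - 1L)
    prev_end <- p[nrow(p), ]
    prev_max_x <- max(p[, 1])
  }
  tr <- ca_trace(do.call(rbind, placed), source = "synthetic")
  attr(tr, "ground_truth") <- do.call(rbind, gt)
  tr
}

#' Generate a slipknot chain
#'
#' Builds an open trefoil and then pulls its threaded end back out along
#' its own path (a parallel retrace at a small offset, then an escape),
#' so the full chain closes to the unknot while the prefix subchain still
#' closes to a trefoil -- the signature a correctly folded tandem repeat
#' of a shallowly knotted domain is expected to show.
#'
#' @param n_points total points of the final chain.
#' @param seed integer seed.
#' @param noise_sigma coordinate noise, angstrom.
#' @return a [ca_trace()] with attribute `ground_truth`, a list with the
#'   knotted prefix interval and its label.
#' @export
generate_slipknot <- function(n_points = 120, seed = 1, noise_sigma = 0) {
  stopifnot(n_points >= 60)
  n_unit <- floor(n_points * 0.55)
  base <- generate_knot(knot_recipe("3_1", n_points = n_unit,
                                    open_fraction = 0.12, noise_sigma = 0,
                                    seed = seed))
  with_seed(seed + 1L, {
    p <- base$coords
    m <- nrow(p)
    ctr <- colMeans(p)
    # constant offset perpendicular to the end-to-end vector
    ee <- p[m, ] - p[1, ]
    ax <- if (abs(ee[1]) < 0.9 * sqrt(sum(ee^2))) c(1, 0, 0) else c(0, 0, 1)
    off <- ee / sqrt(sum(ee^2))
    off <- ax - sum(ax * off) * off
    off <- 1.6 * off / sqrt(sum(off^2))
    n_back <- n_points - m - 6L
    back_idx <- round(seq(m - 1, 2, length.out = n_back))
    retrace <- sweep(p[back_idx, , drop = FALSE], 2, off, "+")
    # escape beyond the start, away from the body
    d <- p[1, ] - ctr; d <- d / sqrt(sum(d^2))
    esc <- sweep(outer(seq_len(6) * 3.8, d), 2,
                 p[2, ] + off + 3.8 * d, "+")
    pts <- rbind(p, retrace, esc)
    if (noise_sigma > 0)
      pts <- pts + matrix(rnorm(length(pts), sd = noise_sigma), ncol = 3)
    tr <- ca_trace(pts, source = "synthetic")
    attr(tr, "ground_truth") <- list(full = "0_1", prefix = c(1L, m),
                                     prefix_label = "3_1")
    tr
  })
}

#' Write a synthetic ring-and-thread full-atom fixture
#'
#' Writes a PDB with a circular loop of pseudo-residues (single carbon
#' pseudo-atoms at ~3.8 angstrom spacing) in the xy-plane and a straight
#' threading strand along z, either piercing the ring centre or passing
#' outside it -- the geometry probed by [loop_occlusion()].
#'
#' @param path output PDB path.
#' @param ring_radius ring radius, angstrom.
#' @param pierce logical; thread through the ring (TRUE) or outside it.
#' @return invisibly, a list with the loop and thread residue spans.
#' @export
generate_ring_and_thread <- function(path, ring_radius = 12, pierce = TRUE) {
  m <- max(8L, round(2 * pi * ring_radius / 3.8))
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  ring <- cbind(ring_radius * cos(th), ring_radius * sin(th), 0)
  zs <- seq(-15, 15, by = 3.8)
  xoff <- if (pierce) 0 else 2.5 * ring_radius
  thread <- cbind(xoff, 0, zs)
  xyz <- rbind(ring, thread)
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = seq_len(n), resid = rep("ALA", n),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep("A", n), o = rep(1, n), b = rep(0, n))
  invisible(list(loop_span = c(1L, m),
                 thread_span = c(m + 1L, n), path = path))
}
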