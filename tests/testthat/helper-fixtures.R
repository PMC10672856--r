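# shared fixture builders (everything generated in code; no data files)

closed_torus_knot <- function(q, n = 400, R = 3, r = 1.4) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((R + r * cos(q * phi)) * cos(2 * phi),
        (R + r * cos(q * phi)) * sin(2 * phi),
        r * sin(q * phi))
}

closed_figure_eight <- function(n = 500) {
  s <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((2 + cos(2 * s)) * cos(3 * s), (2 + cos(2 * s)) * sin(3 * s),
        sin(4 * s))
}

# connected sum of k trefoils as one closed loop: open trefoil units placed
# along x and the far ends joined by a wide rectangular return path
closed_trefoil_sum <- function(k, seed = 1) {
  tr <- concat_knots(lapply(seq_len(k), function(i)
    knot_recipe("3_1", n_points = 90, noise_sigma = 0, seed = seed + i)))
  p <- tr$coords
  lo <- apply(p, 2, min); hi <- apply(p, 2, max)
  span <- max(hi - lo)
  ret_y <- lo[2] - 0.7 * span
  way <- rbind(c(hi[1] + 0.25 * span, p[nrow(p), 2], p[nrow(p), 3]),
               c(hi[1] + 0.25 * span, ret_y, p[nrow(p), 3]),
               c(lo[1] - 0.25 * span, ret_y, p[1, 3]),
               c(lo[1] - 0.25 * span, p[1, 2], p[1, 3]))
  rbind(p, way)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal hand-written PDB fixture text
mini_pdb_lines <- function() {
  xyz <- cbind(seq(0, 15.2, by = 3.8), 0, 0)
  b <- c(81.3, 79.0, 85.2, 90.1, 77.7)
  vapply(1:5, function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, b[i])
  }, character(1))
}
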