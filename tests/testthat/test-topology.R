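# KMT reduction, chain closure and Alexander-invariant classification

test_that("KMT reduction collapses unknotted geometry and keeps endpoints", {
  arc <- cbind(cos(seq(0, pi, length.out = 50)),
               sin(seq(0, pi, length.out = 50)), 0)
  red <- kmt_reduce(arc)
  expect_lte(nrow(red), 3)
  expect_equal(red[1, ], arc[1, ])
  expect_equal(red[nrow(red), ], arc[50, ])

  three <- rbind(c(0, 0, 0), c(1, 2, 0), c(2, 0, 1))
  expect_equal(kmt_reduce(three), three, ignore_attr = TRUE)
})

test_that("KMT reduction preserves knot type", {
  tre <- closed_torus_knot(3, 200)
  red <- kmt_reduce(tre, closed = TRUE)
  expect_lt(nrow(red), nrow(tre))
  expect_equal(alexander_value(red, -1), 3)
  expect_equal(alexander_value(tre, -1), 3)
})

test_that("Alexander matrix of the standard trefoil diagram matches the pipeline", {
  # Independent oracle: the 3-crossing trefoil diagram has Wirtinger
  # relations whose crossing matrix rows are (t at incoming underpass,
  # -1 at outgoing underpass, 1-t at overpass), cyclically.  Deleting one
  # row and column and evaluating the determinant by base R:
  alex_row <- function(m, t, i, j, o) {
    r <- numeric(3); r[i] <- t; r[j] <- -1; r[o] <- 1 - t
    r
  }
  det_at <- function(t) {
    M <- rbind(alex_row(3, t, 1, 2, 3),
               alex_row(3, t, 2, 3, 1),
               alex_row(3, t, 3, 1, 2))
    det(M[1:2, 1:2])
  }
  expect_equal(abs(det_at(-1)), 3)   # |t^2 - t + 1| at -1
  expect_equal(abs(det_at(-2)), 7)
  # pipeline on a geometric trefoil agrees with the hand diagram
  tre <- closed_torus_knot(3)
  expect_equal(alexander_value(tre, -1), 3)
  expect_equal(alexander_value(tre, -2), 7)
})

test_that("Alexander values match closed forms for torus and figure-eight knots", {
  # T(2,q): Delta(t) = (t^q + 1)/(t + 1), so |Delta(-1)| = q and
  # |Delta(-2)| = 2^q - 1
  for (q in c(3, 5, 7)) {
    tk <- closed_torus_knot(q)
    expect_equal(alexander_value(tk, -1), q)
    expect_equal(alexander_value(tk, -2), 2^q - 1)
  }
  f8 <- closed_figure_eight()
  expect_equal(alexander_value(f8, -1), 5)
  expect_equal(alexander_value(f8, -2), 11)
  # unknot: planar polygon
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  expect_equal(alexander_value(cbind(cos(th), sin(th), 0), -1), 1)
})

test_that("Alexander value is multiplicative over connected sums of trefoils", {
  for (k in 1:3) {
    loop <- closed_trefoil_sum(k, seed = 10 * k)
    expect_equal(alexander_value(loop, -1), 3^k)
    expect_equal(alexander_value(loop, -2), 7^k)
  }
})

test_that("classification recovers generator ground truth", {
  tre <- generate_knot(knot_recipe("3_1", n_points = 100, seed = 4))
  lab <- classify_knot(tre, seed = 11)
  expect_equal(lab$notation, "3_1")
  expect_gte(lab$probability, 0.9)

  ext <- cbind(seq(0, 380, by = 3.8), 0, 0) +
    matrix(rnorm(303, sd = 0.3), ncol = 3)
  lab0 <- classify_knot(ext, seed = 12)
  expect_equal(lab0$notation, "0_1")
  expect_gte(lab0$probability, 0.99)

  g61 <- generate_knot(knot_recipe("6_1", n_points = 110, seed = 5))
  lab61 <- classify_knot(g61, seed = 13)
  expect_equal(lab61$notation, "6_1")
  expect_gte(lab61$probability, 0.8)
})

test_that("random closures of an open trefoil overwhelmingly classify 3_1", {
  tre <- generate_knot(knot_recipe("3_1", n_points = 100, seed = 2))
  loops <- close_chain(tre, "random_sphere", n_closures = 100, seed = 3)
  expect_length(loops, 100)
  labs <- vapply(loops, function(l) alexander_value(l, -1, seed = 5),
                 numeric(1))
  expect_gte(sum(labs == 3), 90)
})

test_that("closures are deterministic given the seed", {
  tre <- generate_knot(knot_recipe("3_1", n_points = 80, seed = 1))
  l1 <- close_chain(tre, n_closures = 5, seed = 42)
  l2 <- close_chain(tre, n_closures = 5, seed = 42)
  expect_identical(l1, l2)
  c1 <- classify_knot(tre, seed = 7)
  c2 <- classify_knot(tre, seed = 7)
  expect_identical(c1, c2)
})

test_that("degenerate chains close to the trivial unknot", {
  straight <- cbind(seq(0, 34.2, by = 3.8), 0, 0)
  loops <- close_chain(straight, "direct")
  expect_length(loops, 1)
  lab <- classify_knot(straight, seed = 1)
  expect_equal(lab$notation, "0_1")
})

test_that("classification is invariant under rigid motion and reversal", {
  tre <- generate_knot(knot_recipe("3_1", n_points = 90, seed = 6))
  base <- classify_knot(tre, seed = 21)
  set.seed(99)
  for (i in 1:5) {
    q <- random_rotation()
    moved <- sweep(tre$coords %*% q, 2, rnorm(3, sd = 40), "+")
    lab <- classify_knot(moved, seed = 21)
    expect_equal(lab$notation, base$notation)
    expect_lte(abs(lab$probability - base$probability), 0.05)
  }
  rev_lab <- classify_knot(tre$coords[nrow(tre$coords):1, ], seed = 21)
  expect_equal(rev_lab$notation, base$notation)
})

test_that("classification refuses broken traces", {
  tr <- ca_trace(cbind(seq(0, 38, by = 3.8), 0, 0))
  tr$broken <- TRUE
  expect_error(classify_knot(tr, seed = 1), "broken")
})

test_that("the invariant lookup table is collision-free", {
  tab <- knotscope:::build_knot_table()
  expect_false(any(duplicated(paste(tab$d1, tab$d2))))
  expect_true(all(c("3_1", "6_1", "3_1#3_1", "7_1", "5_2") %in% tab$notation))
  # 12-fold trefoil sums are resolvable
  expect_true(paste(rep("3_1", 12), collapse = "#") %in% tab$notation)
  expect_equal(knot_factor_count(c("0_1", "3_1", "3_1#3_1#6_1", "unknown")),
               c(0L, 1L, 3L, NA_integer_))
})
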