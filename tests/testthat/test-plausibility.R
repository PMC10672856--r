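# feasibility rules, loop occlusion, domain overlap, confidence profile

# consecutive factors with the terminal cores anchored near the chain ends
# (as find_cores produces for real tandem constructs)
fake_factors <- function(classes, n = 400, labels = NULL) {
  k <- length(classes)
  if (is.null(labels)) labels <- rep("3_1", max(k, 0L))
  if (k == 0) {
    df <- data.frame(label = character(0), probability = numeric(0),
                     core_start = integer(0), core_end = integer(0),
                     depth_n = integer(0), depth_c = integer(0),
                     depth_class = character(0), stringsAsFactors = FALSE)
  } else {
    bounds <- round(seq(25, n - 25, length.out = k + 1))
    core_start <- head(bounds, -1) + c(0, rep(5, k - 1))
    core_end <- tail(bounds, -1) - c(rep(5, k - 1), 0)
    df <- data.frame(label = labels, probability = rep(1, k),
                     core_start = core_start, core_end = core_end,
                     depth_n = NA_integer_, depth_c = NA_integer_,
                     depth_class = classes, stringsAsFactors = FALSE)
  }
  structure(df, class = c("knot_factors", "data.frame"), slipknot = FALSE,
            full_label = if (k) paste(labels, collapse = "#") else "0_1",
            n = n, unresolved = FALSE)
}

test_that("zero or one factor is plausible; ten consecutive knots are not", {
  v0 <- assess_feasibility(fake_factors(character(0)))
  expect_equal(v0$verdict, "plausible")

  v1 <- assess_feasibility(fake_factors("shallow", n = 120))
  expect_equal(v1$verdict, "plausible")
  expect_equal(nrow(v1$triggered_rules), 0)

  v10 <- assess_feasibility(fake_factors(rep("shallow", 10), n = 1000))
  expect_equal(v10$verdict, "implausible")
  expect_true("R1" %in% v10$triggered_rules$id)
})

test_that("three factors need a central deep knot; that layout is at the limit", {
  ok <- assess_feasibility(fake_factors(c("shallow", "deep", "shallow")))
  expect_equal(ok$verdict, "plausible")
  expect_true("at_mechanism_limit" %in% ok$flags)

  bad <- assess_feasibility(fake_factors(c("deep", "shallow", "shallow")))
  expect_equal(bad$verdict, "implausible")
  expect_true("R3" %in% bad$triggered_rules$id)

  allsh <- assess_feasibility(fake_factors(rep("shallow", 3)))
  expect_equal(allsh$verdict, "implausible")
})

test_that("more than one deep factor triggers R2", {
  v <- assess_feasibility(fake_factors(c("deep", "deep")))
  expect_equal(v$verdict, "implausible")
  expect_true("R2" %in% v$triggered_rules$id)
})

test_that("two factors buried away from both termini trigger R4", {
  f <- fake_factors(c("shallow", "shallow"), n = 600)
  # push both cores far from the ends
  f$core_start <- c(200, 350); f$core_end <- c(260, 410)
  v <- assess_feasibility(f)
  expect_equal(v$verdict, "implausible")
  expect_true("R4" %in% v$triggered_rules$id)
})

test_that("appending factors never rescues an implausible verdict", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    cls <- sample(c("shallow", "deep"), k, replace = TRUE)
    base <- assess_feasibility(fake_factors(cls, n = 150 * (k + 1)))
    more <- assess_feasibility(fake_factors(c(cls, "shallow"),
                                            n = 150 * (k + 2)))
    if (base$verdict == "implausible")
      expect_equal(more$verdict, "implausible")
  }
})

test_that("rule order and output are deterministic", {
  f <- fake_factors(rep("deep", 4), n = 900)
  v1 <- assess_feasibility(f)
  v2 <- assess_feasibility(f)
  expect_identical(v1$triggered_rules, v2$triggered_rules)
})

test_that("unresolved factors give an ambiguous verdict", {
  f <- fake_factors("shallow", labels = "unresolved")
  attr(f, "unresolved") <- TRUE
  expect_equal(assess_feasibility(f)$verdict, "ambiguous")
})

test_that("ring fixtures pass from open to blocked as geometry tightens", {
  wide <- withr::local_tempfile(fileext = ".pdb")
  generate_ring_and_thread(wide, ring_radius = 12, pierce = TRUE)
  spans <- generate_ring_and_thread(withr::local_tempfile(fileext = ".pdb"),
                                    ring_radius = 12)
  rep_open <- loop_occlusion(wide, spans$loop_span, spans$thread_span,
                             atom_radius = 1.7)
  expect_equal(rep_open$verdict, "open")
  expect_gt(rep_open$clearance, 2.8)

  narrow <- withr::local_tempfile(fileext = ".pdb")
  sp2 <- generate_ring_and_thread(narrow, ring_radius = 4.5, pierce = TRUE)
  rep_block <- loop_occlusion(narrow, sp2$loop_span, sp2$thread_span,
                              atom_radius = 3.6)  # tryptophan-bulky
  expect_equal(rep_block$verdict, "blocked")

  # clearance decreases monotonically with pseudo-atom radius, and the
  # verdict passes open -> tight -> blocked in that order
  mid <- withr::local_tempfile(fileext = ".pdb")
  sp3 <- generate_ring_and_thread(mid, ring_radius = 6, pierce = TRUE)
  radii <- c(1.0, 2.0, 3.0, 4.0, 5.2)
  reps <- lapply(radii, function(r)
    loop_occlusion(mid, sp3$loop_span, sp3$thread_span, atom_radius = r))
  clear <- vapply(reps, `[[`, numeric(1), "clearance")
  expect_true(all(diff(clear) < 0))
  verd <- vapply(reps, `[[`, character(1), "verdict")
  expect_equal(rle(verd)$values, c("open", "tight", "blocked"))
})

test_that("a thread outside the ring raises a piercing error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  sp <- generate_ring_and_thread(f, ring_radius = 10, pierce = FALSE)
  expect_error(loop_occlusion(f, sp$loop_span, sp$thread_span),
               "does not pierce")
})

test_that("domain overlap flags superimposed copies but not separated ones", {
  dom <- generate_knot(knot_recipe("3_1", n_points = 60, seed = 2))$coords
  set.seed(7)
  apart <- rbind(dom, sweep(dom, 2, c(150, 0, 0), "+"))
  tr1 <- ca_trace(apart)
  ov1 <- domain_overlap(tr1, list(c(1, 60), c(61, 120)))
  expect_gt(ov1$overlap_score, 2)
  expect_false(ov1$overlaid)

  jitter <- dom + matrix(rnorm(length(dom), sd = 1), ncol = 3)
  tr2 <- ca_trace(rbind(dom, jitter))
  ov2 <- domain_overlap(tr2, list(c(1, 60), c(61, 120)))
  expect_lt(ov2$overlap_score, 0.2)
  expect_true(ov2$overlaid)

  # symmetric in pair order
  ov2b <- domain_overlap(tr2, list(c(61, 120), c(1, 60)))
  expect_equal(ov2$overlaid, ov2b$overlaid)
  expect_equal(ov2$overlap_score, ov2b$overlap_score)

  # invariant under global rigid motion
  q <- random_rotation()
  tr3 <- ca_trace(sweep(rbind(dom, jitter) %*% q, 2, c(30, -20, 5), "+"))
  ov3 <- domain_overlap(tr3, list(c(1, 60), c(61, 120)))
  expect_equal(ov3$overlap_score, ov2$overlap_score, tolerance = 1e-8)

  expect_error(domain_overlap(tr2, list(c(1, 60), c(100, 150))), "span")
})

test_that("confidence profile bands segments and flags masking", {
  n <- 60
  tr <- ca_trace(cbind(seq_len(n) * 3.8, 0, 0), plddt = rep(80, n))
  pr <- confidence_profile(tr, data.frame(label = "unit1", start = 1,
                                          end = n))
  expect_equal(pr$table$mean_plddt[1], 80)
  expect_equal(pr$table$class[1], "good")

  # two segments (92, 65) -> global 78.5, implausible topology -> masking
  tr2 <- ca_trace(cbind(seq_len(n) * 3.8, 0, 0),
                  plddt = c(rep(92, n / 2), rep(65, n / 2)))
  segs <- data.frame(label = c("core", "linker"),
                     start = c(1, n / 2 + 1), end = c(n / 2, n))
  verdict <- assess_feasibility(fake_factors(rep("shallow", 10), n = 1000))
  pr2 <- confidence_profile(tr2, segs, verdict)
  expect_equal(pr2$global_mean, 78.5)
  expect_equal(pr2$table$class, c("high", "low", "good"))
  expect_true(pr2$masking)

  # empty segment list: global row only
  pr3 <- confidence_profile(tr)
  expect_equal(nrow(pr3$table), 1)
  expect_equal(pr3$table$segment, "global")
})
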