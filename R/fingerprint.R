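#' Subchain knot fingerprint
#'
#' Classifies every subchain `[i, j]` whose endpoints lie on a regular
#' index grid of stride `step` (the exact chain ends are always included),
#' producing the matrix of labels that underlies knotted-core location,
#' slipknot detection and composite-knot decomposition.
#'
#' Positions are 1-based point indices along the trace (for structure
#' traces these correspond to residues in trace order; author numbering is
#' kept separately for reporting).
#'
#' @inheritParams classify_knot
#' @param step grid stride in residues (default 5).
#' @return data frame of class `knot_fingerprint` with columns `start`,
#'   `end`, `notation`, `probability`; attributes `n` (chain length),
#'   `step`, `seed`, `n_closures`.
#' @export
knot_fingerprint <- function(x, step = 5, n_closures = 100, seed = NULL,
                             early_stop = TRUE) {
  if (is.null(seed)) stop("`seed` is required")
  stopifnot(step >= 1)
  pts <- as_points(x)
  n <- nrow(pts)
  grid <- sort(unique(c(seq(1L, n, by = as.integer(step)), n)))
  iv <- which(outer(grid, grid, "<"), arr.ind = TRUE)
  starts <- grid[iv[, 1]]; ends <- grid[iv[, 2]]
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  res <- with_seed(seed, {
    lapply(seq_along(starts), function(k) {
      sub <- pts[starts[k]:ends[k], , drop = FALSE]
      if (nrow(sub) < 4L) return(list(notation = "0_1", probability = 1))
      classify_points(sub, n_closures, "random_sphere", early_stop)
    })
  })
  out <- data.frame(
    start = starts, end = ends,
    notation = vapply(res, `[[`, character(1), "notation"),
    probability = vapply(res, `[[`, numeric(1), "probability"),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("knot_fingerprint", "data.frame"),
            n = n, step = step, seed = seed, n_closures = n_closures)
}

fp_label <- function(fp, i, j) {
  hit <- fp$start == i & fp$end == j
  if (!any(hit)) return(NULL)
  list(notation = fp$notation[hit][1], probability = fp$probability[hit][1])
}

#' Classify knot depth
#'
#' A knot is deep when its core lies further than `deep_threshold`
#' (default 20) residues from the nearest chain terminus (or neighbouring
#' factor boundary); otherwise it is shallow.
#'
#' @param depth_n,depth_c distances (residues) from the core to the
#'   N-/C-side boundary.
#' @param deep_threshold depth cutoff in residues.
#' @return character vector, `"deep"` or `"shallow"`.
#' @export
classify_depth <- function(depth_n, depth_c, deep_threshold = 20) {
  ifelse(pmin(depth_n, depth_c) > deep_threshold, "deep", "shallow")
}

#' Decompose a fingerprint into consecutive prime-knot factors
#'
#' Greedy left-to-right scan: the next factor's core is the shortest grid
#' interval (ties broken leftmost) classified as a prime knot with
#' probability at least `core_prob_min` whose removal -- trimming the chain
#' to the remaining right part -- lowers the composite factor count of the
#' remainder by exactly one. Depths are measured to the chain ends for
#' terminal factors and to the neighbouring core boundary for internal
#' ones, and classified by [classify_depth()].
#'
#' @param fp a [knot_fingerprint()].
#' @param core_prob_min minimum closure-consensus probability for a core.
#' @param deep_threshold residues; see [classify_depth()].
#' @return data frame of class `knot_factors` with one row per factor
#'   (`label`, `probability`, `core_start`, `core_end`, `depth_n`,
#'   `depth_c`, `depth_class`), possibly a final `"unresolved"` row when
#'   the fingerprint is inconsistent. Attributes: `slipknot` (logical),
#'   `full_label`, `n`.
#' @export
find_cores <- function(fp, core_prob_min = 0.5, deep_threshold = 20) {
  stopifnot(inherits(fp, "knot_fingerprint"))
  n <- attr(fp, "n")
  full <- fp_label(fp, min(fp$start), n)
  full_count <- knot_factor_count(full$notation)
  knotted_rows <- fp$notation != "0_1" & !fp$notation %in% c("unknown") &
    fp$probability >= core_prob_min
  slip <- identical(full$notation, "0_1") && any(knotted_rows)

  empty <- data.frame(label = character(0), probability = numeric(0),
                      core_start = integer(0), core_end = integer(0),
                      depth_n = integer(0), depth_c = integer(0),
                      depth_class = character(0), stringsAsFactors = FALSE)
  mk <- function(df, unresolved = FALSE)
    structure(df, class = c("knot_factors", "data.frame"), slipknot = slip,
              full_label = full$notation, n = n, unresolved = unresolved)

  if (identical(full$notation, "0_1")) return(mk(empty))
  if (is.na(full_count)) {
    out <- rbind(empty, data.frame(label = "unresolved", probability = NA_real_,
                                   core_start = NA_integer_, core_end = NA_integer_,
                                   depth_n = NA_integer_, depth_c = NA_integer_,
                                   depth_class = NA_character_))
    return(mk(out, unresolved = TRUE))
  }

  prime <- !grepl("#", fp$notation, fixed = TRUE) & fp$notation != "0_1" &
    fp$notation != "unknown"
  a <- min(fp$start)
  cores <- empty
  remaining <- full_count
  repeat {
    if (remaining <= 0L) break
    rem_after <- function(j) {
      if (j >= n) return(0L)
      lab <- fp_label(fp, j, n)
      if (is.null(lab)) return(NA_integer_)
      knot_factor_count(lab$notation)
    }
    cand <- which(prime & fp$probability >= core_prob_min & fp$start >= a)
    if (length(cand)) {
      after <- vapply(fp$end[cand], rem_after, integer(1))
      cand <- cand[!is.na(after) & after == remaining - 1L]
    }
    if (!length(cand)) {
      cores <- rbind(cores,
                     data.frame(label = "unresolved", probability = NA_real_,
                                core_start = NA_integer_, core_end = NA_integer_,
                                depth_n = NA_integer_, depth_c = NA_integer_,
                                depth_class = NA_character_))
      return(mk(cores, unresolved = TRUE))
    }
    len <- fp$end[cand] - fp$start[cand]
    pick <- cand[order(len, fp$start[cand])][1]
    # +/- step local refinement: among grid neighbours of the chosen core
    # that satisfy the same conditions, keep the most confident one (a
    # minimal interval can clip the core boundary and dilute the closure
    # consensus of an otherwise solid factor)
    step <- attr(fp, "step")
    nb <- cand[abs(fp$start[cand] - fp$start[pick]) <= step &
                 abs(fp$end[cand] - fp$end[pick]) <= step]
    if (length(nb) > 1) {
      nlen <- fp$end[nb] - fp$start[nb]
      pick <- nb[order(-fp$probability[nb], nlen, fp$start[nb])][1]
    }
    cores <- rbind(cores,
                   data.frame(label = fp$notation[pick],
                              probability = fp$probability[pick],
                              core_start = fp$start[pick],
                              core_end = fp$end[pick],
                              depth_n = NA_integer_, depth_c = NA_integer_,
                              depth_class = NA_character_))
    a <- fp$end[pick]
    remaining <- remaining - 1L
  }
  if (nrow(cores)) {
    k <- nrow(cores)
    for (i in seq_len(k)) {
      lb <- if (i == 1L) 1L else cores$core_end[i - 1L]
      rb <- if (i == k) n else cores$core_start[i + 1L]
      cores$depth_n[i] <- cores$core_start[i] - lb
      cores$depth_c[i] <- rb - cores$core_end[i]
    }
    cores$depth_class <- classify_depth(cores$depth_n, cores$depth_c,
                                        deep_threshold)
  }
  mk(cores)
}

#' Detect slipknots in a fingerprint
#'
#' A slipknot is a knotted subchain of a chain whose full-length closure is
#' unknotted: the threaded end doubles back out, so extending the subchain
#' to the whole chain unties it. Returns the maximal knotted subchains of
#' such a chain; for a chain whose full closure is knotted the result is
#' empty (those subchains are cores, not slipknots).
#'
#' @param fp a [knot_fingerprint()].
#' @param prob_min minimum consensus probability for a knotted interval.
#' @return data frame with columns `start`, `end`, `notation`,
#'   `probability` (zero rows when there is no slipknot).
#' @export
detect_slipknots <- function(fp, prob_min = 0.5) {
  stopifnot(inherits(fp, "knot_fingerprint"))
  n <- attr(fp, "n")
  full <- fp_label(fp, min(fp$start), n)
  out <- fp[0, c("start", "end", "notation", "probability")]
  if (!identical(full$notation, "0_1")) return(out)
  kn <- fp[fp$notation != "0_1" & fp$notation != "unknown" &
             fp$probability >= prob_min, , drop = FALSE]
  if (!nrow(kn)) return(out)
  # maximal intervals: not strictly contained in another knotted interval
  keep <- vapply(seq_len(nrow(kn)), function(i) {
    !any(kn$start <= kn$start[i] & kn$end >= kn$end[i] &
           (kn$start < kn$start[i] | kn$end > kn$end[i]))
  }, logical(1))
  res <- kn[keep, c("start", "end", "notation", "probability"), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a fingerprint as TSV
#'
#' @param fp a [knot_fingerprint()].
#' @param path output file.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  utils::write.table(as.data.frame(fp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
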