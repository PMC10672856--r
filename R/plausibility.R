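#' Judge whether a factor decomposition is mechanistically feasible
#'
#' Encodes the known mechanisms of protein knot formation as hard rules on
#' a consecutive-factor decomposition. Tail threading can knot the two
#' termini (shallowly); on-ribosome co-translational folding can form one
#' deep knot (one twisted loop can sit around the exit tunnel); domain
#' swapping likewise yields a single knot. Their combination tops out at
#' three consecutive knots -- two shallow terminal knots around one deep
#' central knot. Beyond that, a predicted geometry is not reachable by any
#' known folding mechanism.
#'
#' Hard rules (any triggered rule makes the verdict `implausible`):
#' \describe{
#'   \item{R1}{more than `max_factors` (default 3) consecutive factors.}
#'   \item{R2}{more than one deep factor.}
#'   \item{R3}{with exactly three factors, a single deep factor flanked by
#'     the two others is required (deep must be central).}
#'   \item{R4}{more than one factor lies internal to the chain (outer core
#'     boundary further than `terminal_margin` from the nearest end):
#'     only the single deep-mechanism knot may sit away from the termini.}
#' }
#' Soft rule S1 flags the three-factor central-deep arrangement as
#' `at_mechanism_limit`. Zero or one factor is plausible. Unresolved or
#' unknown factors give an `ambiguous` verdict.
#'
#' @param factors a `knot_factors` frame from [find_cores()] (ordered
#'   N to C), or a data frame with the same columns.
#' @param max_factors maximum consecutive knots formable (3).
#' @param terminal_margin residues within which a core boundary counts as
#'   terminal (the main free parameter of the rule set; default 40).
#' @return object of class `plausibility_verdict`: list with `verdict`
#'   (`plausible` / `implausible` / `ambiguous`), `triggered_rules`
#'   (data frame `id`, `text`), `flags`, and the input `factors`.
#' @export
assess_feasibility <- function(factors, max_factors = 3,
                               terminal_margin = 40) {
  rules <- data.frame(id = character(0), text = character(0),
                      stringsAsFactors = FALSE)
  flags <- character(0)
  trig <- function(id, text) rules <<- rbind(rules, data.frame(id = id,
                                                               text = text))
  n_chain <- attr(factors, "n")
  unresolved <- isTRUE(attr(factors, "unresolved")) ||
    any(factors$label %in% c("unresolved", "unknown"))
  if (isTRUE(attr(factors, "slipknot"))) flags <- c(flags, "slipknot_expected")
  verdict <- "plausible"
  k <- nrow(factors)
  if (unresolved) {
    verdict <- "ambiguous"
  } else if (k > 0) {
    deep <- factors$depth_class == "deep"
    if (k > max_factors)
      trig("R1", sprintf(
        "%d consecutive knots exceed the maximum of %d reachable by combining tail threading with one deep-knot mechanism",
        k, max_factors))
    if (sum(deep) > 1)
      trig("R2", sprintf(
        "%d deep knots, but only one twisted loop can be held at the ribosome exit tunnel (or arise by domain swapping)",
        sum(deep)))
    if (k == 3 && !identical(which(deep), 2L))
      trig("R3",
           "three consecutive knots are only reachable as two terminal shallow knots around one central deep knot")
    if (!is.null(n_chain) && k <= max_factors) {
      internal <- !((factors$core_start - 1) <= terminal_margin |
                      (n_chain - factors$core_end) <= terminal_margin)
      if (sum(internal) > 1)
        trig("R4", sprintf(
          "%d factors lie away from both termini; at most one non-terminal knot is mechanistically reachable",
          sum(internal)))
    }
    if (nrow(rules)) verdict <- "implausible"
    if (k == 3 && verdict == "plausible") flags <- c(flags, "at_mechanism_limit")
  }
  structure(list(verdict = verdict, triggered_rules = rules, flags = flags,
                 factors = factors),
            class = "plausibility_verdict")
}

#' @export
print.plausibility_verdict <- function(x, ...) {
  cat(sprintf("<plausibility_verdict> %s (%d factor%s)\n", x$verdict,
              nrow(x$factors), if (nrow(x$factors) == 1) "" else "s"))
  if (nrow(x$triggered_rules))
    cat(paste0("  ", x$triggered_rules$id, ": ", x$triggered_rules$text,
               collapse = "\n"), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# single published vdW set (angstrom)
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Loop-occlusion test
#'
#' Measures whether the twisted loop that a knotted chain's tail must
#' thread is sterically open. The loop's Calpha ring defines a best-fit
#' plane polygon; the thread segment piercing that polygon defines the
#' threading axis; the clearance is the smallest distance from the axis to
#' any loop heavy atom minus that atom's van der Waals radius. Verdicts:
#' `open` above 2.8 angstrom (a water diameter), `tight` between 1.0 and
#' 2.8, `blocked` below 1.0.
#'
#' @param path full-atom PDB/mmCIF file.
#' @param loop_span,thread_span closed residue-number intervals `c(from, to)`.
#' @param chain chain identifier (default first chain).
#' @param atom_radius optional uniform pseudo-atom radius overriding the
#'   per-element van der Waals table (used by synthetic ring fixtures).
#' @return object of class `occlusion_report`: `loop_span`,
#'   `piercing_residue`, `clearance` (angstrom), `verdict`, `loop_n_residues`.
#' @export
loop_occlusion <- function(path, loop_span, thread_span, chain = NULL,
                           atom_radius = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(chain)) chain <- sort(unique(at$chain))[1]
  at <- at[at$chain == chain & !is.na(at$resno), , drop = FALSE]
  at <- at[!(at$elesy %in% c("H", "D")) | is.na(at$elesy), , drop = FALSE]
  loop_at <- at[at$resno >= loop_span[1] & at$resno <= loop_span[2], ,
                drop = FALSE]
  ring <- loop_at[loop_at$elety == "CA", , drop = FALSE]
  ring <- ring[order(ring$resno), , drop = FALSE]
  if (nrow(ring) < 3) stop("loop span has fewer than 3 CA atoms")
  thr <- at[at$resno >= thread_span[1] & at$resno <= thread_span[2] &
              at$elety == "CA", , drop = FALSE]
  thr <- thr[order(thr$resno), , drop = FALSE]
  if (nrow(thr) < 2) stop("thread span has fewer than 2 CA atoms")

  ringxyz <- cbind(ring$x, ring$y, ring$z)
  ctr <- colMeans(ringxyz)
  sv <- svd(sweep(ringxyz, 2, ctr))
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  poly <- cbind((sweep(ringxyz, 2, ctr)) %*% e1,
                (sweep(ringxyz, 2, ctr)) %*% e2)
  pip <- function(p) {  # point-in-polygon, ray casting
    x <- p[1]; y <- p[2]; np <- nrow(poly); inside <- FALSE
    j <- np
    for (i in seq_len(np)) {
      if ((poly[i, 2] > y) != (poly[j, 2] > y) &&
          x < (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
      j <- i
    }
    inside
  }
  thrxyz <- cbind(thr$x, thr$y, thr$z)
  hdist <- (sweep(thrxyz, 2, ctr)) %*% nrm
  pierce <- NULL
  for (i in seq_len(nrow(thrxyz) - 1)) {
    if (sign(hdist[i]) != sign(hdist[i + 1]) && hdist[i] != hdist[i + 1]) {
      w <- hdist[i] / (hdist[i] - hdist[i + 1])
      hit <- (1 - w) * thrxyz[i, ] + w * thrxyz[i + 1, ]
      uv <- c(sum((hit - ctr) * e1), sum((hit - ctr) * e2))
      if (pip(uv)) {
        pierce <- list(i = i, point = hit,
                       dir = thrxyz[i + 1, ] - thrxyz[i, ])
        break
      }
    }
  }
  if (is.null(pierce)) stop("thread does not pierce loop")
  axis_dir <- pierce$dir / sqrt(sum(pierce$dir^2))
  # clearance to loop heavy atoms
  lxyz <- cbind(loop_at$x, loop_at$y, loop_at$z)
  rel <- sweep(lxyz, 2, pierce$point)
  proj <- rel - outer(as.numeric(rel %*% axis_dir), axis_dir)
  dists <- sqrt(rowSums(proj^2))
  radii <- if (!is.null(atom_radius)) rep(atom_radius, nrow(loop_at))
           else {
             r <- vdw_radii[loop_at$elesy]
             r[is.na(r)] <- vdw_radii["C"]
             r
           }
  clearance <- max(min(dists - radii), 0)
  verdict <- if (clearance > 2.8) "open" else if (clearance >= 1.0) "tight"
             else "blocked"
  structure(list(loop_span = loop_span,
                 loop_n_residues = span_length(loop_span),
                 piercing_residue = thr$resno[pierce$i],
                 clearance = clearance, verdict = verdict),
            class = "occlusion_report")
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf(
    "<occlusion_report> loop %d-%d (%d residues), pierced at %d: clearance %.2f A -> %s\n",
    x$loop_span[1], x$loop_span[2], x$loop_n_residues, x$piercing_residue,
    x$clearance, x$verdict))
  invisible(x)
}

#' Detect overlaid domains
#'
#' Deep-learning predictors that allow chain passing can place sequence
#' copies of a domain on top of each other. For each pair of domain spans
#' the overlap score is the centroid distance divided by the sum of the two
#' radii of gyration; a pair is flagged overlaid when the score drops below
#' 0.5 and more than `0.1 x min(domain length)` inter-domain Calpha pairs
#' clash (closer than 4 angstrom).
#'
#' @param trace a [ca_trace()].
#' @param domain_spans list of closed position intervals `c(from, to)`,
#'   non-overlapping in sequence.
#' @return data frame with one row per pair: `i`, `j`, `overlap_score`,
#'   `clash_count`, `overlaid`.
#' @export
domain_overlap <- function(trace, domain_spans) {
  stopifnot(inherits(trace, "catrace"), length(domain_spans) >= 2)
  n <- length(trace)
  doms <- lapply(domain_spans, function(s) {
    if (s[1] < 1 || s[2] > n || s[1] >= s[2]) stop("span outside trace")
    trace$coords[s[1]:s[2], , drop = FALSE]
  })
  cent <- lapply(doms, colMeans)
  rg <- vapply(doms, function(d)
    sqrt(mean(rowSums(sweep(d, 2, colMeans(d))^2))), numeric(1))
  prs <- utils::combn(length(doms), 2)
  out <- lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    sc <- sqrt(sum((cent[[i]] - cent[[j]])^2)) / (rg[i] + rg[j])
    dd <- as.matrix(stats::dist(rbind(doms[[i]], doms[[j]])))
    ni <- nrow(doms[[i]])
    clash <- sum(dd[seq_len(ni), -seq_len(ni), drop = FALSE] < 4.0)
    data.frame(i = i, j = j, overlap_score = sc, clash_count = clash,
               overlaid = sc < 0.5 &&
                 clash > 0.1 * min(ni, nrow(doms[[j]])))
  })
  do.call(rbind, out)
}

#' Per-segment confidence (pLDDT) profile
#'
#' Summarises per-residue pLDDT over labeled segments plus a global row,
#' with the standard bands: `high` (>= 90, modeled to high accuracy),
#' `good` (>= 70, generally good backbone), `low` (< 70). A high global
#' mean can mask a topologically impossible arrangement -- each knotted
#' core resembles its native template locally, so averaging hides the
#' error; the `masking` flag is set when the global mean is >= 70 yet the
#' topology verdict is implausible.
#'
#' @param trace a [ca_trace()] with pLDDT present.
#' @param segments optional data frame with columns `label`, `start`,
#'   `end` (positions along the trace), e.g. from [span_report()].
#' @param verdict optional [assess_feasibility()] result for the masking
#'   flag.
#' @return list with `table` (segment, n, mean_plddt, min_plddt, class),
#'   `global_mean`, `masking`.
#' @export
confidence_profile <- function(trace, segments = NULL, verdict = NULL) {
  stopifnot(inherits(trace, "catrace"))
  if (is.null(trace$plddt))
    stop("trace has no pLDDT (B-factors outside [0,100] or absent)")
  band <- function(m) if (m >= 90) "high" else if (m >= 70) "good" else "low"
  rows <- list()
  if (!is.null(segments) && nrow(segments)) {
    for (i in seq_len(nrow(segments))) {
      v <- trace$plddt[segments$start[i]:segments$end[i]]
      rows[[i]] <- data.frame(segment = segments$label[i],
                              n = length(v), mean_plddt = mean(v),
                              min_plddt = min(v), class = band(mean(v)))
    }
  }
  gm <- mean(trace$plddt)
  rows[[length(rows) + 1L]] <- data.frame(segment = "global",
                                          n = length(trace$plddt),
                                          mean_plddt = gm,
                                          min_plddt = min(trace$plddt),
                                          class = band(gm))
  masking <- !is.null(verdict) && gm >= 70 &&
    identical(verdict$verdict, "implausible")
  list(table = do.call(rbind, rows), global_mean = gm, masking = masking)
}
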