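#' Construct a Calpha trace
#'
#' The package's central container: the ordered Calpha coordinates of one
#' chain, with residue numbers, optional per-residue pLDDT, and a broken
#' flag set when the chain has unbridged gaps or non-physical consecutive
#' Calpha-Calpha distances (outside 2.0--4.5 angstrom). Topology operations
#' refuse broken traces.
#'
#' @param coords `n x 3` numeric matrix of coordinates in angstrom.
#' @param residue_numbers strictly increasing integers (default `1:n`).
#' @param chain_id chain identifier.
#' @param plddt optional per-residue confidence in `[0, 100]`.
#' @param source file of origin, or `"synthetic"`.
#' @param check_geometry validate consecutive-distance bounds.
#' @return object of class `catrace`.
#' @export
ca_trace <- function(coords, residue_numbers = NULL, chain_id = "A",
                     plddt = NULL, source = "synthetic",
                     check_geometry = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (ncol(coords) != 3L || n < 1L) stop("coords must be an n x 3 matrix")
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  residue_numbers <- as.integer(residue_numbers)
  if (length(residue_numbers) != n) stop("residue_numbers length mismatch")
  if (any(diff(residue_numbers) <= 0L))
    stop("residue_numbers must be strictly increasing")
  if (!is.null(plddt)) {
    if (length(plddt) != n) stop("plddt length mismatch")
    if (any(!is.na(plddt) & (plddt < 0 | plddt > 100)))
      stop("plddt values must lie in [0, 100]")
  }
  broken <- FALSE
  if (any(diff(residue_numbers) != 1L)) broken <- TRUE
  if (check_geometry && n > 1L) {
    d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-n, , drop = FALSE])^2))
    if (any(d < 2.0 | d > 4.5)) broken <- TRUE
  }
  structure(list(chain_id = chain_id, residue_numbers = residue_numbers,
                 coords = unname(coords), plddt = plddt, source = source,
                 broken = broken),
            class = "catrace")
}

#' @export
print.catrace <- function(x, ...) {
  cat(sprintf("<catrace> chain %s: %d residues (%d-%d)%s%s, source: %s\n",
              x$chain_id, length(x$residue_numbers),
              min(x$residue_numbers), max(x$residue_numbers),
              if (!is.null(x$plddt)) ", pLDDT" else "",
              if (isTRUE(x$broken)) ", BROKEN" else "", x$source))
  invisible(x)
}

#' @export
length.catrace <- function(x) length(x$residue_numbers)

#' Extract a subchain of a trace by position
#'
#' @param trace a `catrace`.
#' @param from,to 1-based positions along the trace (closed interval).
#' @return a `catrace` for the subchain.
#' @export
trace_subchain <- function(trace, from, to) {
  stopifnot(inherits(trace, "catrace"), from >= 1, to <= length(trace),
            from < to)
  idx <- from:to
  ca_trace(trace$coords[idx, , drop = FALSE], trace$residue_numbers[idx],
           trace$chain_id, trace$plddt[idx], trace$source)
}
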