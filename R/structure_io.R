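#' Read Calpha traces from a PDB or mmCIF file
#'
#' Extracts one [ca_trace()] per selected chain from a structure file.
#' Only polymer `ATOM` records contribute (hetero-residues and waters are
#' ignored); alternate locations are resolved to the highest occupancy,
#' ties to the first encountered. The B-factor column is interpreted as
#' AlphaFold-style per-residue pLDDT only when every value lies in
#' `[0, 100]`; otherwise confidence operations are disabled for the trace
#' (crystallographic B-factors must not masquerade as confidence).
#' Residue-number gaps of up to `max_bridge` residues are bridged by
#' linear interpolation via [bridge_gaps()]; longer gaps flag the trace
#' broken.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param chain optional chain identifier(s); default all chains.
#' @param max_bridge largest residue gap bridged by interpolation.
#' @return list of `catrace`, one per chain, in sorted chain order.
#' @export
read_structure <- function(path, chain = NULL, max_bridge = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  # bio3d warns about altloc records and about read.cif being beta; altlocs
  # are resolved below and the cif fields used here are stable
  pdb <- tryCatch(
    suppressWarnings(
      if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
      else bio3d::read.pdb(path, rm.alt = FALSE)),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA" & !is.na(at$resno), ,
           drop = FALSE]
  if (!nrow(ca)) stop("no polymer CA atoms in ", path)
  chains <- sort(unique(ca$chain))
  if (!is.null(chain)) {
    missing <- setdiff(chain, chains)
    if (length(missing))
      stop("chain(s) not present: ", paste(missing, collapse = ", "))
    chains <- sort(chain)
  }
  lapply(chains, function(ch) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    if (!nrow(cc)) stop("empty chain: ", ch)
    # altloc: highest occupancy, then first
    occ <- ifelse(is.na(cc$o), 1, cc$o)
    ord <- order(cc$resno, -occ, seq_len(nrow(cc)))
    cc <- cc[ord, , drop = FALSE]
    cc <- cc[!duplicated(cc$resno), , drop = FALSE]
    b <- cc$b
    plddt <- if (all(!is.na(b)) && all(b >= 0 & b <= 100)) b else NULL
    tr <- ca_trace(cbind(cc$x, cc$y, cc$z), cc$resno, ch, plddt,
                   source = path)
    bridge_gaps(tr, max_bridge = max_bridge)
  })
}

#' Bridge short residue gaps in a trace
#'
#' Missing residues (jumps in residue numbering) of up to `max_bridge`
#' residues are filled by linear interpolation of coordinates (and pLDDT);
#' longer gaps are left in place and flag the trace broken, since
#' interpolating across them could silently change the topology the tool
#' is meant to audit. After bridging, consecutive Calpha distances outside
#' 2.0--4.5 angstrom also flag the trace broken.
#'
#' @param trace a [ca_trace()].
#' @param max_bridge maximum gap length (missing residues) to interpolate.
#' @return a `catrace` with gaps bridged and its `broken` flag updated.
#' @export
bridge_gaps <- function(trace, max_bridge = 3) {
  stopifnot(inherits(trace, "catrace"), max_bridge >= 0)
  rn <- trace$residue_numbers
  gaps <- diff(rn) - 1L
  broken <- FALSE
  coords <- list(); resno <- list(); plddt <- list()
  has_p <- !is.null(trace$plddt)
  for (i in seq_along(rn)) {
    coords[[length(coords) + 1L]] <- trace$coords[i, , drop = FALSE]
    resno[[length(resno) + 1L]] <- rn[i]
    if (has_p) plddt[[length(plddt) + 1L]] <- trace$plddt[i]
    if (i < length(rn) && gaps[i] > 0L) {
      if (gaps[i] <= max_bridge) {
        w <- seq_len(gaps[i]) / (gaps[i] + 1)
        interp <- outer(1 - w, trace$coords[i, ]) +
          outer(w, trace$coords[i + 1L, ])
        coords[[length(coords) + 1L]] <- interp
        resno[[length(resno) + 1L]] <- rn[i] + seq_len(gaps[i])
        if (has_p)
          plddt[[length(plddt) + 1L]] <-
            (1 - w) * trace$plddt[i] + w * trace$plddt[i + 1L]
      } else {
        broken <- TRUE
      }
    }
  }
  out <- ca_trace(do.call(rbind, coords), unlist(resno), trace$chain_id,
                  if (has_p) unlist(plddt) else NULL, trace$source)
  d <- sqrt(rowSums((out$coords[-1, , drop = FALSE] -
                       out$coords[-nrow(out$coords), , drop = FALSE])^2))
  # distances across unbridged gaps are judged by the broken flag already
  contig <- diff(out$residue_numbers) == 1L
  if (any(contig & (d < 2.0 | d > 4.5))) broken <- TRUE
  out$broken <- broken || out$broken
  out
}

#' Write a trace as a PDB file
#'
#' Emits a standard PDB with one poly-alanine CA atom per residue; pLDDT
#' (when present) goes to the B-factor column. Round-trips coordinates at
#' PDB precision (1e-3 angstrom).
#'
#' @param trace a [ca_trace()].
#' @param path output file.
#' @export
write_trace_pdb <- function(trace, path) {
  stopifnot(inherits(trace, "catrace"))
  n <- length(trace)
  b <- if (!is.null(trace$plddt)) trace$plddt else rep(0, n)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(trace$coords)),
                   resno = trace$residue_numbers, resid = rep("ALA", n),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep(trace$chain_id, n), o = rep(1, n), b = b)
  invisible(path)
}

#' Read a raw xyz polyline
#'
#' One point per line, whitespace-separated coordinates in angstrom --
#' the minimal interchange format for synthetic chains. Returns a
#' coordinate matrix accepted by every topology operation.
#'
#' @param path text file with three numeric columns.
#' @return `n x 3` numeric matrix.
#' @export
read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 3L || !is.numeric(m)) stop("expected three numeric columns")
  unname(m)
}

#' @param points `n x 3` matrix.
#' @rdname read_xyz
#' @export
write_xyz <- function(points, path) {
  utils::write.table(as_points(points), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

aa1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
         "Q", "R", "S", "T", "V", "W", "Y")

#' Read / write amino-acid FASTA
#'
#' Thin validated wrappers around seqinr's FASTA I/O. Sequences must use
#' the canonical 20-letter alphabet; anything else (including `X`) is
#' rejected with an alphabet error.
#'
#' @param path FASTA file.
#' @return `read_fasta`: data frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!length(recs)) stop("no records in ", path)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  bad <- !grepl(paste0("^[", paste(aa1, collapse = ""), "]+$"), seqs)
  if (any(bad))
    stop("non-canonical amino-acid letters in record(s): ",
         paste(names(recs)[bad], collapse = ", "))
  data.frame(id = names(recs), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' @param records data frame with columns `id`, `sequence`.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  seqinr::write.fasta(as.list(records$sequence), names = records$id,
                      file.out = path, as.string = TRUE)
  invisible(path)
}
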