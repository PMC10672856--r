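#' Audit one structure or trace end to end
#'
#' Runs the full pipeline: subchain fingerprint, core decomposition,
#' feasibility rules, slipknot detection, and (when pLDDT is present)
#' the confidence profile with the masking flag.
#'
#' @param x a [ca_trace()], or a structure file path (first chain used
#'   unless `chain` given).
#' @param chain chain identifier when `x` is a path.
#' @param step,n_closures,seed fingerprint parameters (see
#'   [knot_fingerprint()]).
#' @param segments optional segment table for [confidence_profile()].
#' @param ... passed to [assess_feasibility()].
#' @return object of class `knot_audit`: list with `trace`, `knot`
#'   (full-chain label), `fingerprint`, `factors`, `slipknots`, `verdict`,
#'   `confidence` (or NULL), `red_flags`, and `config`.
#' @export
audit_structure <- function(x, chain = NULL, step = 5, n_closures = 100,
                            seed = 42, segments = NULL, ...) {
  trace <- if (inherits(x, "catrace")) x
           else read_structure(x, chain = chain)[[1]]
  red_flags <- character(0)
  if (isTRUE(trace$broken)) {
    red_flags <- "broken_chain"
    verdict <- structure(list(verdict = "ambiguous",
                              triggered_rules = data.frame(id = character(0),
                                                           text = character(0)),
                              flags = red_flags, factors = NULL),
                         class = "plausibility_verdict")
    return(structure(list(trace = trace, knot = NULL, fingerprint = NULL,
                          factors = NULL, slipknots = NULL, verdict = verdict,
                          confidence = NULL, red_flags = red_flags,
                          config = list(step = step, n_closures = n_closures,
                                        seed = seed)),
                     class = "knot_audit"))
  }
  fp <- knot_fingerprint(trace, step = step, n_closures = n_closures,
                         seed = seed)
  factors <- find_cores(fp)
  slip <- detect_slipknots(fp)
  verdict <- assess_feasibility(factors, ...)
  if (isTRUE(attr(factors, "slipknot"))) red_flags <- c(red_flags,
                                                        "slipknot_expected")
  conf <- NULL
  if (!is.null(trace$plddt)) {
    conf <- confidence_profile(trace, segments, verdict)
    if (conf$masking) red_flags <- c(red_flags, "plddt_masking")
  }
  full <- fp_label(fp, 1L, attr(fp, "n"))
  structure(list(trace = trace, knot = full, fingerprint = fp,
                 factors = factors, slipknots = slip, verdict = verdict,
                 confidence = conf, red_flags = red_flags,
                 config = list(step = step, n_closures = n_closures,
                               seed = seed)),
            class = "knot_audit")
}

#' @export
print.knot_audit <- function(x, ...) {
  cat("<knot_audit>", if (!is.null(x$knot))
    sprintf("full chain %s (p=%.2f);", x$knot$notation, x$knot$probability)
    else "no classification;",
    sprintf("%d factor(s); verdict: %s\n",
            if (is.null(x$factors)) 0L else nrow(x$factors),
            x$verdict$verdict))
  if (length(x$red_flags)) cat("  red flags:",
                               paste(x$red_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write an audit as a JSON report
#'
#' @param audit a [audit_structure()] result.
#' @param path output JSON file.
#' @export
write_audit_json <- function(audit, path) {
  stopifnot(inherits(audit, "knot_audit"))
  rep <- list(
    file = audit$trace$source,
    chain = audit$trace$chain_id,
    n_residues = length(audit$trace),
    knot_label = if (!is.null(audit$knot)) audit$knot$notation else NA,
    probability = if (!is.null(audit$knot)) audit$knot$probability else NA,
    factors = if (!is.null(audit$factors)) as.data.frame(audit$factors)
              else list(),
    verdict = audit$verdict$verdict,
    triggered_rules = audit$verdict$triggered_rules,
    red_flags = audit$red_flags,
    confidence = if (!is.null(audit$confidence))
      list(table = audit$confidence$table,
           global_mean = audit$confidence$global_mean,
           masking = audit$confidence$masking) else NULL,
    config = audit$config
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Summarise audits as a TSV table
#'
#' @param audits list of [audit_structure()] results.
#' @param path output TSV file.
#' @export
write_audit_tsv <- function(audits, path) {
  rows <- lapply(audits, function(a)
    data.frame(file = a$trace$source, chain = a$trace$chain_id,
               n_residues = length(a$trace),
               knot = if (!is.null(a$knot)) a$knot$notation else NA,
               probability = if (!is.null(a$knot)) a$knot$probability else NA,
               n_factors = if (is.null(a$factors)) NA_integer_
                           else nrow(a$factors),
               verdict = a$verdict$verdict,
               red_flags = paste(a$red_flags, collapse = ","),
               seed = a$config$seed))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
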