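# In-silico fragment size selection and the tMAD detection statistic.

#' In-silico fragment size selection
#'
#' Retains exactly the fragments whose length (`end - start`) lies in the
#' inclusive window `[lower, upper]`, preserving input order.  The default
#' 90-150 bp window sits below the mononucleosomal ~167 bp mode and so
#' enriches the shorter tumor-derived fragments relative to cfDNA from
#' normal cells.
#'
#' @param fragments a fragment table.
#' @param lower,upper inclusive bounds in bp; `0 < lower <= upper`.
#' @return the retained `fragment_table`, with attributes `n_retained` and
#'   `n_dropped`.
#' @export
size_select <- function(fragments, lower = 90, upper = 150) {
  stopifnot_scalar_number(lower, "lower", min = 1)
  stopifnot_scalar_number(upper, "upper", min = lower)
  fragments <- as_fragment_table(as.data.frame(fragments))
  len <- fragment_lengths(fragments)
  keep <- len >= lower & len <= upper
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_table", "data.frame")
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Trimmed median absolute deviation from copy-number neutrality (tMAD)
#'
#' Genome-wide SCNA burden summarized as a single number: absolute
#' deviations `|r_i|` of the usable bin log2 ratios from 0 (copy-number
#' neutrality) are computed, the `ceiling(q * n)` largest are discarded
#' (one-sided trim, so a few extreme bins cannot dominate), and the median
#' of the rest is returned.  A sample is flagged as ctDNA-positive when the
#' statistic strictly exceeds `threshold` (default 0.015).
#'
#' @param profile a `cn_profile`, or a bare numeric vector of log2 ratios.
#' @param q trim fraction in \[0, 0.5); `q = 0` is the plain median
#'   absolute deviation from zero.
#' @param threshold detection threshold on the tMAD scale (no 1.4826
#'   normal-consistency factor is applied).
#' @param min_bins minimum number of usable bins required; below this the
#'   statistic is refused (default 10; lower it only for toy inputs).
#' @return a `tmad_result`: list with `tmad`, `q`, `n_bins`, `n_trimmed`,
#'   `threshold`, `detected`.
#' @export
tmad <- function(profile, q = 0.05, threshold = 0.015, min_bins = 10L) {
  stopifnot_scalar_number(q, "q", min = 0)
  if (q >= 0.5) abort("`q` must be below 0.5")
  stopifnot_scalar_number(threshold, "threshold", min = 0)
  r <- if (is.numeric(profile)) profile
       else {
         stopifnot(inherits(profile, "cn_profile"))
         profile$log2ratio[profile$usable]
       }
  stopifnot_scalar_number(min_bins, "min_bins", min = 1, integer = TRUE)
  r <- r[is.finite(r)]
  n <- length(r)
  if (n < min_bins)
    abort("tMAD needs >= ", min_bins, " usable bins, have ", n)
  d <- sort(abs(r))
  k <- ceiling(q * n)
  retained <- if (k > 0L) d[seq_len(n - k)] else d
  value <- median(retained)
  structure(
    list(tmad = value, q = q, n_bins = n, n_trimmed = k,
         threshold = threshold, detected = value > threshold),
    class = "tmad_result"
  )
}

#' @export
print.tmad_result <- function(x, ...) {
  cat("<tmad_result> tMAD = ", signif(x$tmad, 4), " (", x$n_bins,
      " bins, trimmed ", x$n_trimmed, ", q = ", x$q, ")\n", sep = "")
  cat("  ctDNA ", if (x$detected) "DETECTED" else "not detected",
      " at threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' ctDNA detection decision from a tMAD value
#'
#' Detection is strict: `tmad > threshold`; a value exactly at the
#' threshold is not detected.
#'
#' @param result a `tmad_result` or a bare non-negative tMAD value.
#' @param threshold detection threshold (default 0.015).
#' @return for a `tmad_result`, the result with `detected` and `threshold`
#'   updated; for a bare value, a logical flag.
#' @export
detect_ctdna <- function(result, threshold = 0.015) {
  stopifnot_scalar_number(threshold, "threshold", min = 0)
  if (inherits(result, "tmad_result")) {
    result$threshold <- threshold
    result$detected <- result$tmad > threshold
    return(result)
  }
  stopifnot_scalar_number(result, "result", min = 0)
  result > threshold
}

#' Read-depth quality control
#'
#' Flags samples below the minimum fragment count required for reliable
#' copy-number evaluation (default 5 million).  Failure is a flag, not a
#' hard stop: under-sequenced samples remain processable but carry the
#' flag into every downstream report.
#'
#' @param fragments a fragment table.
#' @param min_fragments required count (default `5e6`).
#' @return a `qc_result`: list with `n_fragments`, `min_fragments`, `pass`.
#' @export
qc_depth <- function(fragments, min_fragments = 5e6) {
  stopifnot_scalar_number(min_fragments, "min_fragments", min = 0)
  n <- nrow(as.data.frame(fragments))
  structure(
    list(n_fragments = n, min_fragments = min_fragments,
         pass = n >= min_fragments),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", x$n_fragments, " fragments; depth QC ",
      if (x$pass) "PASS" else "FAIL", " (minimum ", x$min_fragments,
      ")\n", sep = "")
  invisible(x)
}

#' Run the detection pipeline with and without size selection
#'
#' The paired comparison behind the sensitivity gain of size selection:
#' the same fragment table is taken through
#' count -> GC-correct -> log2 profile -> {tMAD, SCNA calls}
#' twice, once on all fragments and once on the 90-150 bp subset, and both
#' arms are reported side by side.
#'
#' @param fragments a fragment table.
#' @param bins a `bin_set`.
#' @param lower,upper size-selection window in bp.
#' @param q,threshold tMAD trim fraction and detection threshold.
#' @param gain_thresh,loss_thresh,min_bins SCNA-calling parameters.
#' @param gc_span loess span for GC correction.
#' @param min_fragments depth-QC minimum.
#' @param gc_correction set `FALSE` to skip GC correction in both arms
#'   (e.g. for bias-free simulations with few bins).
#' @return a `pipeline_comparison`: list with `qc` and per-arm lists
#'   (`unselected`, `selected`) each holding `n_fragments`, `tmad`
#'   (a `tmad_result`), and `calls`.
#' @export
compare_pipelines <- function(fragments, bins, lower = 90, upper = 150,
                              q = 0.05, threshold = 0.015,
                              gain_thresh = 0.15, loss_thresh = -0.15,
                              min_bins = 10L, gc_span = 0.3,
                              min_fragments = 5e6, gc_correction = TRUE) {
  fragments <- as_fragment_table(as.data.frame(fragments))
  run_arm <- function(frags) {
    counts <- count_fragments(frags, bins)
    if (gc_correction) counts <- gc_correct(counts, span = gc_span)
    profile <- to_log2_profile(counts)
    list(
      n_fragments = nrow(frags),
      tmad = tmad(profile, q = q, threshold = threshold),
      calls = call_scnas(profile, gain_thresh = gain_thresh,
                         loss_thresh = loss_thresh, min_bins = min_bins)
    )
  }
  selected <- size_select(fragments, lower = lower, upper = upper)
  structure(
    list(
      qc = qc_depth(fragments, min_fragments = min_fragments),
      size_window = c(lower = lower, upper = upper),
      unselected = run_arm(fragments),
      selected = run_arm(selected)
    ),
    class = "pipeline_comparison"
  )
}

#' @export
print.pipeline_comparison <- function(x, ...) {
  fmt <- function(arm, label) {
    cat(sprintf("  %-11s %9d fragments  tMAD %.4f  %s  %d SCNA call(s)\n",
                label, arm$n_fragments, arm$tmad$tmad,
                if (arm$tmad$detected) "DETECTED    " else "not detected",
                nrow(arm$calls)))
  }
  cat("<pipeline_comparison> size window [", x$size_window["lower"], ", ",
      x$size_window["upper"], "] bp; depth QC ",
      if (x$qc$pass) "PASS" else "FAIL", "\n", sep = "")
  fmt(x$unselected, "unselected")
  fmt(x$selected, "selected")
  invisible(x)
}
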