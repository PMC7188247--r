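# Bin counting, GC correction, log2 copy-number profiles and run-length
# SCNA calling from fragment tables.

#' Count fragments per genome bin
#'
#' Each fragment is assigned to exactly one bin by its midpoint
#' `floor((start + end) / 2)` — unambiguous and length-unbiased for
#' fragments straddling a bin boundary.  Fragments whose midpoint falls
#' outside every bin are dropped and reported.
#'
#' @param fragments a fragment table (`chrom`, `start`, `end`).
#' @param bins a `bin_set`; bins must be sorted and non-overlapping within
#'   each chromosome.
#' @return a `bin_counts`: data frame parallel to `bins` with columns
#'   `chrom`, `start`, `end`, `gc`, `usable`, `raw`, `corrected`
#'   (`corrected` is `NA` until [gc_correct()] runs) and attributes
#'   `n_dropped`, `n_fragments`.
#' @export
count_fragments <- function(fragments, bins) {
  fragments <- as_fragment_table(as.data.frame(fragments))
  bin_chroms <- unique(bins$chrom)
  raw <- integer(nrow(bins))
  n_dropped <- 0L
  if (nrow(fragments)) {
    foreign <- !(fragments$chrom %in% bin_chroms)
    if (any(foreign)) {
      i <- which(foreign)[1L]
      abort("fragment record ", i, " is on chromosome '",
            fragments$chrom[i], "', which is not in the bin set (",
            paste(bin_chroms, collapse = ", "),
            "); mixed chromosome namespaces?")
    }
    mid <- floor((fragments$start + fragments$end) / 2)
    for (chr in bin_chroms) {
      b <- which(bins$chrom == chr)
      f <- which(fragments$chrom == chr)
      if (!length(f)) next
      # half-open bins: midpoint == start of bin i+1 belongs to bin i+1
      idx <- findInterval(mid[f], bins$start[b])
      inside <- idx >= 1L & mid[f] < bins$end[b][pmax(idx, 1L)]
      n_dropped <- n_dropped + sum(!inside)
      hits <- tabulate(idx[inside], nbins = length(b))
      raw[b] <- raw[b] + hits
    }
  }
  counts <- data.frame(bins[, c("chrom", "start", "end", "gc", "usable")],
                       raw = raw, corrected = NA_real_,
                       stringsAsFactors = FALSE)
  class(counts) <- c("bin_counts", "data.frame")
  attr(counts, "n_fragments") <- nrow(fragments)
  attr(counts, "n_dropped") <- n_dropped
  counts
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("<bin_counts> ", nrow(x), " bins; ",
      attr(x, "n_fragments") %||% NA, " fragments counted, ",
      attr(x, "n_dropped") %||% NA, " dropped\n", sep = "")
  if (any(!is.na(x$corrected))) cat("  GC-corrected\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct bin counts for GC-content bias
#'
#' Fits a smooth local-regression curve `f(gc)` of raw count on GC fraction
#' over usable, nonzero bins (robust `"symmetric"` fitting so altered
#' segments do not drag the curve) and rescales every usable bin by
#' `corrected = raw / f(gc) * median(f)`, which removes the GC trend while
#' preserving the overall count level.  Bins where the fitted curve
#' collapses (below `1e-6` of its median) are masked instead of divided.
#'
#' @param counts a `bin_counts` from [count_fragments()].
#' @param span loess smoothing span over the GC axis.
#' @param min_fit_bins minimum number of usable nonzero bins required to
#'   attempt a fit (refused below this; rerun without correction instead).
#' @return the `bin_counts` with `corrected` filled in on usable bins and
#'   `usable` switched off where the fit is degenerate.
#' @export
gc_correct <- function(counts, span = 0.3, min_fit_bins = 20L) {
  stopifnot(inherits(counts, "bin_counts"))
  stopifnot_scalar_number(span, "span", min = 0.05, max = 1)
  fit_on <- counts$usable & counts$raw > 0
  if (sum(fit_on) < min_fit_bins)
    abort("GC correction needs >= ", min_fit_bins,
          " usable bins with nonzero counts (have ", sum(fit_on),
          "); skip correction and use raw counts instead")
  gc <- counts$gc
  usable <- counts$usable

  if (diff(range(gc[fit_on])) < 1e-9) {
    # degenerate covariate: the fit is a constant, correction is identity
    counts$corrected <- ifelse(usable, as.numeric(counts$raw), NA_real_)
    return(counts)
  }

  fit <- loess(raw ~ gc, data = counts[fit_on, , drop = FALSE],
               span = span, degree = 2, family = "symmetric",
               control = stats::loess.control(surface = "direct"))
  f <- rep(NA_real_, nrow(counts))
  f[usable] <- predict(fit, newdata = data.frame(gc = gc[usable]))
  f_med <- median(f[fit_on])
  ok <- usable & is.finite(f) & f > 1e-6 * f_med
  counts$corrected <- ifelse(ok, counts$raw / f * f_med, NA_real_)
  counts$usable <- counts$usable & ok
  counts
}

#' Convert corrected bin counts to a log2 copy-number profile
#'
#' `r_i = log2(corrected_i / m)` with `m` the median corrected count over
#' usable nonzero bins, so a copy-neutral genome sits at 0 by construction.
#' Zero-count bins cannot carry a finite ratio and are masked.
#'
#' @param counts a `bin_counts`; if [gc_correct()] has not been run the raw
#'   counts are used as-is.
#' @return a `cn_profile`: data frame with bin coordinates, `log2ratio` and
#'   a `usable` mask; attribute `median_count` records `m`.
#' @export
to_log2_profile <- function(counts) {
  stopifnot(inherits(counts, "bin_counts"))
  value <- if (all(is.na(counts$corrected))) as.numeric(counts$raw)
           else counts$corrected
  ok <- counts$usable & !is.na(value) & value > 0
  if (!any(ok))
    abort("profile is all zero/masked; cannot normalize")
  m <- median(value[ok])
  profile <- data.frame(
    counts[, c("chrom", "start", "end", "gc")],
    log2ratio = ifelse(ok, log2(value / m), NA_real_),
    usable = ok,
    stringsAsFactors = FALSE
  )
  class(profile) <- c("cn_profile", "data.frame")
  attr(profile, "median_count") <- m
  profile
}

#' @export
print.cn_profile <- function(x, ...) {
  r <- x$log2ratio[x$usable]
  cat("<cn_profile> ", nrow(x), " bins (", sum(x$usable), " usable)\n",
      sep = "")
  cat("  log2 ratio: median ", signif(median(r), 3), ", MAD-from-0 ",
      signif(median(abs(r)), 3), "\n", sep = "")
  invisible(x)
}

#' Call gained and lost regions from a log2 profile
#'
#' Scans the usable bins in coordinate order and reports every maximal run
#' of at least `min_bins` consecutive usable bins whose log2 ratio is at or
#' above `gain_thresh` (gain) or at or below `loss_thresh` (loss).  No
#' segmentation model is imposed: this is direct bin-level thresholding
#' with a minimum-run requirement to suppress isolated noise bins.
#'
#' @param profile a `cn_profile`.
#' @param gain_thresh log2 units, > 0 (default +0.15).
#' @param loss_thresh log2 units, < 0 (default -0.15).
#' @param min_bins minimum run length in bins (>= 1).
#' @return data frame of calls: `chrom`, `start`, `end`, `bin_from`,
#'   `bin_to` (1-based indices into the profile), `n_bins`, `direction`
#'   (`"gain"`/`"loss"`), `mean_log2`.  Zero rows when nothing is called.
#' @export
call_scnas <- function(profile, gain_thresh = 0.15, loss_thresh = -0.15,
                       min_bins = 10L) {
  stopifnot(inherits(profile, "cn_profile"))
  if (!(gain_thresh > 0 && loss_thresh < 0))
    abort("need gain_thresh > 0 > loss_thresh")
  stopifnot_scalar_number(min_bins, "min_bins", min = 1, integer = TRUE)

  idx <- which(profile$usable)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), bin_from = integer(),
                      bin_to = integer(), n_bins = integer(),
                      direction = character(), mean_log2 = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  r <- profile$log2ratio[idx]
  state <- ifelse(r >= gain_thresh, 1L, ifelse(r <= loss_thresh, -1L, 0L))
  # chromosome changes break runs even if states agree
  chrom_id <- cumsum(c(TRUE, profile$chrom[idx][-1] !=
                               profile$chrom[idx][-length(idx)]))
  runs <- rle(state + 10L * chrom_id)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$lengths >= min_bins & (runs$values %% 10L) != 0L)
  if (!length(keep)) return(empty)
  calls <- lapply(keep, function(k) {
    i <- idx[starts[k]:ends[k]]
    data.frame(
      chrom = profile$chrom[i[1L]],
      start = profile$start[i[1L]],
      end = profile$end[i[length(i)]],
      bin_from = i[1L],
      bin_to = i[length(i)],
      n_bins = length(i),
      direction = if (state[starts[k]] == 1L) "gain" else "loss",
      mean_log2 = mean(profile$log2ratio[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$start), , drop = FALSE]
}
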