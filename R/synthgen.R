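# Synthetic cfDNA data generation: genome bins, copy-number ground truth,
# fragment tables and longitudinal concentration series.  All generators are
# deterministic given `seed` and leave the global RNG stream untouched.

#' Partition a synthetic chromosome into fixed-size bins
#'
#' Builds a contiguous, non-overlapping set of 0-based half-open bins on a
#' single synthetic chromosome, with a smoothly varying (autocorrelated) GC
#' fraction per bin.  The GC track is an AR(1) latent Gaussian mapped through
#' its CDF onto `gc_range`, which gives the slowly drifting composition real
#' genomes show at megabase scale.
#'
#' @param n_bins number of bins (>= 1).
#' @param bin_size bin width in bp (>= 1).
#' @param gc_range length-2 numeric within \[0, 1\]; a degenerate range such as
#'   `c(0.5, 0.5)` yields a constant GC track.
#' @param seed integer seed; the same seed reproduces the bin set exactly.
#' @param chrom chromosome name used for every bin.
#' @param gc_autocor lag-1 autocorrelation of the latent GC process.
#' @return a `bin_set`: data frame with columns `chrom`, `start`, `end`,
#'   `gc`, `usable`.
#' @export
make_bins <- function(n_bins, bin_size, gc_range = c(0.3, 0.6), seed = 1L,
                      chrom = "chrS", gc_autocor = 0.95) {
  stopifnot_scalar_number(n_bins, "n_bins", min = 1, integer = TRUE)
  stopifnot_scalar_number(bin_size, "bin_size", min = 1)
  if (!is.numeric(gc_range) || length(gc_range) != 2L ||
      any(gc_range < 0) || any(gc_range > 1) || gc_range[1] > gc_range[2])
    abort("`gc_range` must be an interval within [0, 1]")
  stopifnot_scalar_number(gc_autocor, "gc_autocor", min = 0, max = 0.999)

  gc <- withr::with_seed(seed, {
    z <- numeric(n_bins)
    z[1L] <- rnorm(1L)
    if (n_bins > 1L) {
      eps <- rnorm(n_bins - 1L)
      for (i in 2:n_bins)
        z[i] <- gc_autocor * z[i - 1L] + sqrt(1 - gc_autocor^2) * eps[i - 1L]
    }
    gc_range[1] + (gc_range[2] - gc_range[1]) * pnorm(z)
  })

  bins <- data.frame(
    chrom  = rep(chrom, n_bins),
    start  = as.numeric(0:(n_bins - 1L)) * bin_size,
    end    = as.numeric(1:n_bins) * bin_size,
    gc     = gc,
    usable = rep(TRUE, n_bins),
    stringsAsFactors = FALSE
  )
  class(bins) <- c("bin_set", "data.frame")
  bins
}

#' @export
print.bin_set <- function(x, ...) {
  cat("<bin_set> ", nrow(x), " bins on ", length(unique(x$chrom)),
      " chromosome(s), ", sum(x$usable), " usable\n", sep = "")
  cat("  gc: [", round(min(x$gc), 3), ", ", round(max(x$gc), 3), "]\n",
      sep = "")
  invisible(x)
}

#' Define somatic copy-number ground truth over a bin set
#'
#' Segments assign an integer tumor copy number to contiguous bin-index
#' ranges that must partition the bins; normal cells are diploid throughout.
#' At tumor fraction `tf` the expected relative coverage weight of bin i is
#' `w_i = (1 - tf) * 2 + tf * c_i`, the mixture of the two genomes.
#'
#' @param bins a `bin_set` from [make_bins()].
#' @param segments data frame with columns `from`, `to` (1-based inclusive
#'   bin indices) and `cn` (integer tumor copy number >= 0), or `NULL` for a
#'   fully copy-neutral genome (`cn = 2` everywhere).
#' @param tf tumor fraction in \[0, 1\].
#' @return an `scna_truth`: list with per-bin `cn`, per-bin mixture weight
#'   `w`, `tf` and the validated `segments` table.
#' @export
make_truth <- function(bins, segments = NULL, tf = 0) {
  stopifnot(inherits(bins, "data.frame"))
  stopifnot_scalar_number(tf, "tf", min = 0, max = 1)
  n <- nrow(bins)
  if (is.null(segments))
    segments <- data.frame(from = 1L, to = n, cn = 2L)
  req <- c("from", "to", "cn")
  if (!all(req %in% names(segments)))
    abort("`segments` needs columns from, to, cn")
  segments <- segments[order(segments$from), , drop = FALSE]
  if (any(segments$cn < 0) || any(segments$cn != round(segments$cn)))
    abort("tumor copy numbers must be non-negative integers")
  if (any(segments$to < segments$from))
    abort("segment with to < from")
  # ranges must tile 1..n with no gap or overlap
  expected_from <- c(1L, segments$to[-nrow(segments)] + 1L)
  if (segments$from[1L] != 1L || segments$to[nrow(segments)] != n ||
      any(segments$from != expected_from))
    abort("segment ranges must partition bins 1..", n,
          " without gaps or overlaps")

  cn <- rep(segments$cn, segments$to - segments$from + 1L)
  truth <- list(
    cn = cn,
    w = (1 - tf) * 2 + tf * cn,
    tf = tf,
    segments = segments,
    n_bins = n
  )
  class(truth) <- "scna_truth"
  truth
}

#' @export
print.scna_truth <- function(x, ...) {
  alt <- x$segments[x$segments$cn != 2L, , drop = FALSE]
  cat("<scna_truth> tf = ", x$tf, ", ", x$n_bins, " bins, ",
      nrow(alt), " altered segment(s)\n", sep = "")
  invisible(x)
}

#' Fragment-length model for one cfDNA compartment
#'
#' Plasma cfDNA from healthy tissue is dominated by mononucleosomal
#' fragments with a mode near 167 bp; tumor-derived cfDNA is shifted
#' shorter (mode near 145 bp here).  Lengths are drawn from a normal
#' distribution rounded to integer bp and clamped at 1.
#'
#' @param component `"normal"` or `"tumor"`; sets the default mode.
#' @param mode modal fragment length in bp (default 167 normal / 145 tumor).
#' @param sd standard deviation of the length distribution in bp.
#' @return a `size_model` list.
#' @export
size_model <- function(component = c("normal", "tumor"), mode = NULL,
                       sd = 20) {
  component <- match.arg(component)
  if (is.null(mode)) mode <- if (component == "tumor") 145 else 167
  stopifnot_scalar_number(mode, "mode", min = 1)
  stopifnot_scalar_number(sd, "sd", min = 0)
  structure(list(component = component, mode = mode, sd = sd),
            class = "size_model")
}

# internal: draw n integer fragment lengths from a size model
draw_lengths <- function(model, n) {
  if (n == 0L) return(integer(0))
  pmax(1L, as.integer(round(rnorm(n, model$mode, model$sd))))
}

#' Probability mass of a size model inside a length window
#'
#' Exact mass the discretized (rounded-normal) model places on integer
#' lengths in `[lower, upper]`; used as the analytic oracle for
#' size-selection enrichment.
#'
#' @param model a [size_model()].
#' @param lower,upper inclusive bounds in bp.
#' @return probability in \[0, 1\].
#' @export
size_model_mass <- function(model, lower, upper) {
  pnorm(upper + 0.5, model$mode, model$sd) -
    pnorm(lower - 0.5, model$mode, model$sd)
}

#' Multiplicative GC bias curve
#'
#' Returns the unimodal factor `exp(-k * (gc - center)^2)` as a function of
#' GC fraction; `k = 0` gives no bias.  This is the smooth coverage-GC
#' dependence that GC correction is expected to remove.
#'
#' @param k curvature (>= 0); larger means stronger bias.
#' @param center GC fraction with maximal representation.
#' @return function mapping GC fractions to positive factors.
#' @export
gc_bias_factor <- function(k = 8, center = 0.45) {
  stopifnot_scalar_number(k, "k", min = 0)
  force(center)
  function(gc) exp(-k * (gc - center)^2)
}

#' Simulate a cfDNA fragment table under copy-number and GC structure
#'
#' Each fragment falls in bin i with probability proportional to
#' `w_i * gc_bias(gc_i)` (multinomial counts), is tumor-derived with
#' probability `tf * c_i / w_i` inside that bin, draws its length from the
#' compartment's size model, and starts uniformly within the bin.  The true
#' origin is kept in an `origin` column that downstream stages must ignore;
#' it exists only so enrichment can be asserted in tests.
#'
#' @param truth an `scna_truth` from [make_truth()].
#' @param bins the matching `bin_set`.
#' @param n_fragments number of fragments to draw (>= 1).
#' @param size_normal,size_tumor [size_model()]s for the two compartments.
#' @param gc_bias function of GC fraction returning strictly positive
#'   multiplicative factors, e.g. [gc_bias_factor()]; `NULL` disables bias.
#' @param overdispersion extra-multinomial count noise: each bin's
#'   sampling weight is jittered by a mean-1 gamma factor with variance
#'   `overdispersion` (0 = pure multinomial, the default).
#' @param seed integer seed (bit-reproducible output).
#' @return a `fragment_table` with columns `chrom`, `start`, `end`, `origin`.
#' @export
simulate_fragments <- function(truth, bins, n_fragments,
                               size_normal = size_model("normal"),
                               size_tumor = size_model("tumor"),
                               gc_bias = gc_bias_factor(),
                               overdispersion = 0,
                               seed = 1L) {
  stopifnot(inherits(truth, "scna_truth"), nrow(bins) == truth$n_bins)
  stopifnot_scalar_number(n_fragments, "n_fragments", min = 1,
                          integer = TRUE)
  bias <- if (is.null(gc_bias)) rep(1, nrow(bins)) else gc_bias(bins$gc)
  if (any(!is.finite(bias)) || any(bias <= 0))
    abort("`gc_bias` must return strictly positive finite factors")
  stopifnot_scalar_number(overdispersion, "overdispersion", min = 0)
  prob <- truth$w * bias
  if (all(prob == 0)) abort("all bin weights are zero; nothing to simulate")
  p_tumor_bin <- ifelse(truth$w > 0, truth$tf * truth$cn / truth$w, 0)

  withr::with_seed(seed, {
    if (overdispersion > 0)
      prob <- prob * stats::rgamma(nrow(bins), shape = 1 / overdispersion,
                                   rate = 1 / overdispersion)
    bin_of <- sample.int(nrow(bins), n_fragments, replace = TRUE,
                         prob = prob)
    tumor <- rbinom(n_fragments, 1L, p_tumor_bin[bin_of]) == 1L
    len <- integer(n_fragments)
    len[!tumor] <- draw_lengths(size_normal, sum(!tumor))
    len[tumor] <- draw_lengths(size_tumor, sum(tumor))
    start <- floor(runif(n_fragments, bins$start[bin_of], bins$end[bin_of]))
    frags <- data.frame(
      chrom = bins$chrom[bin_of],
      start = start,
      end = start + len,
      origin = ifelse(tumor, "tumor", "normal"),
      stringsAsFactors = FALSE
    )
    as_fragment_table(frags)
  })
}

#' Blood-sampling schedules for the two study parts
#'
#' Part 1 follows short-term kinetics around single treatment events: a
#' baseline test/retest pair, then samples 30/60/120 minutes after the first
#' chemotherapy infusion and after the first 2-Gy radiotherapy fraction
#' (eight samples).  Part 2 follows the whole course: baseline, after the
#' first chemotherapy cycle at the planning PET/CT, and after radiotherapy
#' fractions 1, 11, 22 and 33 (six samples).
#'
#' @param part `"part1"` or `"part2"`.
#' @return ordered character vector of unique timepoint labels.
#' @export
schedule_timepoints <- function(part = c("part1", "part2")) {
  part <- match.arg(part)
  if (part == "part1")
    c("baseline_test", "baseline_retest",
      "chemo_30min", "chemo_60min", "chemo_120min",
      "rt_30min", "rt_60min", "rt_120min")
  else
    c("baseline", "post_c1_pet", "rt_fx1", "rt_fx11", "rt_fx22", "rt_fx33")
}

#' Simulate longitudinal cfDNA concentration series
#'
#' Every patient is measured at every schedule timepoint:
#' `concentration = max(0, baseline + trend(timepoint) + noise)` with
#' independent mean-zero Gaussian measurement noise of SD `sd_meas`.  The
#' default `sd_meas = 1` ng/ml makes the single-measurement 95% band
#' `1.96 * SD` approximately +/- 2 ng/ml, the repeatability scale of Qubit
#' cfDNA quantification.
#'
#' @param schedule ordered timepoint labels, e.g. [schedule_timepoints()].
#' @param patients data frame with columns `patient`, `histology`
#'   (`"AC"`/`"SCC"`), `baseline` (mean ng/ml).
#' @param sd_meas measurement SD in ng/ml (>= 0).
#' @param trend named numeric vector of per-timepoint offsets in ng/ml
#'   (missing labels get 0), or `NULL` for no trend.
#' @param seed integer seed.
#' @return a `concentration_series`: data frame with columns `patient`,
#'   `histology`, `timepoint`, `ng_per_ml`.
#' @export
simulate_concentrations <- function(schedule, patients, sd_meas = 1,
                                    trend = NULL, seed = 1L) {
  if (anyDuplicated(schedule)) abort("schedule labels must be unique")
  stopifnot_scalar_number(sd_meas, "sd_meas", min = 0)
  req <- c("patient", "histology", "baseline")
  if (!all(req %in% names(patients)))
    abort("`patients` needs columns patient, histology, baseline")
  offsets <- stats::setNames(rep(0, length(schedule)), schedule)
  if (!is.null(trend)) {
    unknown <- setdiff(names(trend), schedule)
    if (length(unknown))
      abort("trend names not in schedule: ", paste(unknown, collapse = ", "))
    offsets[names(trend)] <- trend
  }
  grid <- expand.grid(timepoint = schedule, patient = patients$patient,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$histology <- patients$histology[match(grid$patient, patients$patient)]
  grid$baseline <- patients$baseline[match(grid$patient, patients$patient)]
  noise <- withr::with_seed(seed, rnorm(nrow(grid), 0, sd_meas))
  grid$ng_per_ml <- pmax(0, grid$baseline + offsets[grid$timepoint] + noise)
  series <- grid[, c("patient", "histology", "timepoint", "ng_per_ml")]
  series$timepoint <- factor(series$timepoint, levels = schedule)
  rownames(series) <- NULL
  class(series) <- c("concentration_series", "data.frame")
  series
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series> ", length(unique(x$patient)), " patient(s) x ",
      length(unique(x$timepoint)), " timepoint(s), ", nrow(x),
      " measurements\n", sep = "")
  cat("  ng/ml: median ", round(stats::median(x$ng_per_ml), 2), ", range [",
      round(min(x$ng_per_ml), 2), ", ", round(max(x$ng_per_ml), 2), "]\n",
      sep = "")
  invisible(x)
}
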