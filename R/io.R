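# File formats (BED fragments, TSV profiles, CSV concentration tables,
# JSON reports/configs), the bundled cohort baseline table, and the
# end-to-end driver.

#' Read a fragment table from a BED3(+) file
#'
#' Tab-separated, 0-based half-open records `chrom start end [origin]`.
#' Lines starting with `#` or `track` are skipped.  Malformed records are
#' reported with their line numbers.
#'
#' @param path file path.
#' @return a `fragment_table`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") &
    nzchar(trimws(lines))
  line_no <- which(keep)
  if (!length(line_no))
    return(as_fragment_table(data.frame(chrom = character(),
                                        start = numeric(), end = numeric(),
                                        stringsAsFactors = FALSE)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    abort("line ", line_no[which(nf < 3L)[1L]],
          ": expected >= 3 tab-separated fields (chrom, start, end)")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    abort("line ", line_no[bad[1L]], ": non-numeric start/end")
  bad <- which(end <= start)
  if (length(bad))
    abort("line ", line_no[bad[1L]], ": end <= start (",
          lines[keep][bad[1L]], ")")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$origin <- vapply(parts, `[[`, "", 4L)
  as_fragment_table(df)
}

#' Write a fragment table as BED
#'
#' @param fragments a fragment table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  df <- as.data.frame(fragments)
  cols <- intersect(c("chrom", "start", "end", "origin"), names(df))
  data.table::fwrite(df[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a copy-number profile as TSV
#'
#' One row per bin with header
#' `chrom start end gc raw corrected log2ratio usable`; masked bins carry
#' the literal `NA` sentinel in `corrected`/`log2ratio`.
#'
#' @param profile a `cn_profile`.
#' @param counts the matching `bin_counts` (raw/corrected columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, counts, path) {
  stopifnot(inherits(profile, "cn_profile"), inherits(counts, "bin_counts"),
            nrow(profile) == nrow(counts))
  out <- data.frame(
    chrom = profile$chrom, start = profile$start, end = profile$end,
    gc = profile$gc, raw = counts$raw, corrected = counts$corrected,
    log2ratio = profile$log2ratio, usable = profile$usable,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a copy-number profile TSV written by [write_profile()]
#'
#' @param path file path.
#' @return list with `profile` (a `cn_profile`) and `counts`
#'   (a `bin_counts`).
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  req <- c("chrom", "start", "end", "gc", "raw", "corrected", "log2ratio",
           "usable")
  missing <- setdiff(req, names(df))
  if (length(missing))
    abort("profile file lacks column(s): ", paste(missing, collapse = ", "))
  counts <- data.frame(df[, c("chrom", "start", "end", "gc", "usable")],
                       raw = df$raw, corrected = df$corrected,
                       stringsAsFactors = FALSE)
  class(counts) <- c("bin_counts", "data.frame")
  profile <- data.frame(df[, c("chrom", "start", "end", "gc")],
                        log2ratio = df$log2ratio, usable = df$usable,
                        stringsAsFactors = FALSE)
  class(profile) <- c("cn_profile", "data.frame")
  list(profile = profile, counts = counts)
}

#' Read a concentration series from CSV
#'
#' Header `patient,histology,timepoint,ng_per_ml`.
#'
#' @param path file path.
#' @return a `concentration_series`.
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  req <- c("patient", "histology", "timepoint", "ng_per_ml")
  missing <- setdiff(req, names(df))
  if (length(missing))
    abort("concentration file lacks column(s): ",
          paste(missing, collapse = ", "))
  if (any(df$ng_per_ml < 0)) abort("negative concentration in ", path)
  class(df) <- c("concentration_series", "data.frame")
  df
}

#' Write a concentration series as CSV
#'
#' @param series a concentration series.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(series, path) {
  df <- as.data.frame(series)
  df$timepoint <- as.character(df$timepoint)
  data.table::fwrite(df[, c("patient", "histology", "timepoint",
                            "ng_per_ml")], path)
  invisible(path)
}

#' Baseline cfDNA concentrations of the ten-patient NSCLC cohort
#'
#' The bundled per-patient baseline table of the chemo-radiotherapy cohort
#' the package's dynamics statistics were designed around: patient id,
#' histology (AC/SCC), study part, and baseline plasma cfDNA in ng/ml
#' (patients 1-4 are the mean of their baseline test/retest pair).
#'
#' @param as_series return a `concentration_series` (one `"baseline"`
#'   timepoint per patient) instead of the raw table.
#' @return data frame or `concentration_series`.
#' @export
cohort_baseline <- function(as_series = FALSE) {
  path <- system.file("extdata", "cohort_baseline_cfdna.csv",
                      package = "plasmaSCNA", mustWork = TRUE)
  df <- as.data.frame(data.table::fread(path))
  if (!as_series) return(df)
  series <- data.frame(patient = df$patient, histology = df$histology,
                       timepoint = "baseline",
                       ng_per_ml = df$baseline_ng_per_ml,
                       stringsAsFactors = FALSE)
  class(series) <- c("concentration_series", "data.frame")
  series
}

#' Build a run configuration with documented defaults
#'
#' Collects every tunable of the pipeline.  Defaults put a 5-million
#' fragment sample at about 5000 fragments per bin (1000 bins of 1 Mb),
#' the regime where a copy-neutral profile's tMAD stays below the 0.015
#' detection threshold.
#'
#' @param n_bins,bin_size,gc_range,gc_autocor bin-set parameters.
#' @param n_fragments fragments per simulated sample.
#' @param tf tumor fraction of the simulated sample.
#' @param segments SCNA truth segments (see [make_truth()]).
#' @param gc_bias_k curvature of the simulated GC bias.
#' @param size_lower,size_upper in-silico size-selection window (bp).
#' @param tmad_q,tmad_threshold tMAD trim fraction and detection threshold.
#' @param gain_thresh,loss_thresh,min_bins SCNA-calling parameters.
#' @param gc_span loess span of the GC correction.
#' @param min_fragments depth-QC minimum.
#' @param seed master seed; all stage seeds derive from it.
#' @param schedule `"part1"` or `"part2"`.
#' @param fragments_path optional BED file to analyze instead of simulating.
#' @param concentrations_path optional CSV of concentrations for the
#'   dynamics summaries.
#' @return a `run_config` list.
#' @export
run_config <- function(n_bins = 1000L, bin_size = 1e6,
                       gc_range = c(0.3, 0.6), gc_autocor = 0.95,
                       n_fragments = 5e6, tf = 0, segments = NULL,
                       gc_bias_k = 8, size_lower = 90, size_upper = 150,
                       tmad_q = 0.05, tmad_threshold = 0.015,
                       gain_thresh = 0.15, loss_thresh = -0.15,
                       min_bins = 10L, gc_span = 0.3, min_fragments = 5e6,
                       seed = 1L, schedule = "part2",
                       fragments_path = NULL, concentrations_path = NULL) {
  cfg <- list(
    n_bins = as.integer(n_bins), bin_size = as.numeric(bin_size),
    gc_range = as.numeric(gc_range), gc_autocor = as.numeric(gc_autocor),
    n_fragments = as.numeric(n_fragments), tf = as.numeric(tf),
    segments = segments, gc_bias_k = as.numeric(gc_bias_k),
    size_lower = as.numeric(size_lower),
    size_upper = as.numeric(size_upper), tmad_q = as.numeric(tmad_q),
    tmad_threshold = as.numeric(tmad_threshold),
    gain_thresh = as.numeric(gain_thresh),
    loss_thresh = as.numeric(loss_thresh),
    min_bins = as.integer(min_bins), gc_span = as.numeric(gc_span),
    min_fragments = as.numeric(min_fragments),
    seed = as.integer(seed), schedule = as.character(schedule),
    fragments_path = fragments_path,
    concentrations_path = concentrations_path
  )
  stopifnot_scalar_number(cfg$tf, "tf", min = 0, max = 1)
  stopifnot_scalar_number(cfg$seed, "seed", integer = TRUE)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (JSON)
#'
#' Configurations round-trip losslessly.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$segments)) raw$segments <- as.data.frame(raw$segments)
  do.call(run_config, raw)
}

#' Run the full pipeline from a configuration
#'
#' Simulates (or ingests) a fragment sample, runs the paired
#' detection pipeline with and without size selection, and, when a
#' concentration table is supplied, attaches the dynamics summaries.
#' The entire run is a pure function of the configuration: the same
#' config and seed reproduce the report exactly.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `config`, `bins` summary, `qc`, both
#'   pipeline arms, and optional `dynamics`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$fragments_path) &&
      !file.exists(config$fragments_path))
    abort("fragments_path does not exist: ", config$fragments_path)
  if (!is.null(config$concentrations_path) &&
      !file.exists(config$concentrations_path))
    abort("concentrations_path does not exist: ",
          config$concentrations_path)

  bins <- make_bins(config$n_bins, config$bin_size,
                    gc_range = config$gc_range, seed = config$seed,
                    gc_autocor = config$gc_autocor)
  if (is.null(config$fragments_path)) {
    truth <- make_truth(bins, segments = config$segments, tf = config$tf)
    fragments <- simulate_fragments(
      truth, bins, n_fragments = config$n_fragments,
      gc_bias = gc_bias_factor(config$gc_bias_k),
      seed = config$seed + 1L
    )
  } else {
    fragments <- read_fragments(config$fragments_path)
  }

  comparison <- compare_pipelines(
    fragments, bins,
    lower = config$size_lower, upper = config$size_upper,
    q = config$tmad_q, threshold = config$tmad_threshold,
    gain_thresh = config$gain_thresh, loss_thresh = config$loss_thresh,
    min_bins = config$min_bins, gc_span = config$gc_span,
    min_fragments = config$min_fragments
  )

  dynamics <- NULL
  if (!is.null(config$concentrations_path)) {
    series <- read_concentrations(config$concentrations_path)
    baseline <- summarize_baseline(series)
    later <- setdiff(unique(as.character(series$timepoint)),
                     baseline_labels(as_series(series)))
    deltas <- lapply(later, function(tp)
      change_from_baseline(series, tp))
    names(deltas) <- later
    dynamics <- list(baseline = baseline, change_from_baseline = deltas)
  }

  report <- list(
    package_version = as.character(packageVersion("plasmaSCNA")),
    config = unclass(config),
    n_bins = nrow(bins),
    qc = unclass(comparison$qc),
    unselected = serialize_arm(comparison$unselected),
    selected = serialize_arm(comparison$selected),
    dynamics = dynamics
  )
  class(report) <- "run_report"
  report
}

# internal: flatten one pipeline arm into plain lists for JSON
serialize_arm <- function(arm) {
  list(
    n_fragments = arm$n_fragments,
    tmad = arm$tmad$tmad,
    detected = arm$tmad$detected,
    n_tmad_bins = arm$tmad$n_bins,
    calls = arm$calls
  )
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> plasmaSCNA ", x$package_version, ", seed ",
      x$config$seed, "\n", sep = "")
  cat("  depth QC: ", if (x$qc$pass) "PASS" else "FAIL", " (",
      x$qc$n_fragments, " fragments)\n", sep = "")
  cat(sprintf("  unselected: tMAD %.4f (%s), %d call(s)\n",
              x$unselected$tmad,
              if (x$unselected$detected) "detected" else "not detected",
              nrow(x$unselected$calls)))
  cat(sprintf("  selected:   tMAD %.4f (%s), %d call(s)\n",
              x$selected$tmad,
              if (x$selected$detected) "detected" else "not detected",
              nrow(x$selected$calls)))
  if (!is.null(x$dynamics))
    cat("  dynamics: baseline median ",
        round(x$dynamics$baseline$median, 2), " ng/ml over ",
        x$dynamics$baseline$n, " patients\n", sep = "")
  invisible(x)
}
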