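# Longitudinal cfDNA concentration statistics: Bland-Altman agreement,
# baseline summaries, change from baseline by histology, an exact
# rank-sum test with midranks, and Spearman correlation.

# internal: coerce to a concentration series data frame and validate
as_series <- function(series) {
  df <- as.data.frame(series)
  req <- c("patient", "timepoint", "ng_per_ml")
  missing <- setdiff(req, names(df))
  if (length(missing))
    abort("concentration series lacks column(s): ",
          paste(missing, collapse = ", "))
  df$timepoint <- as.character(df$timepoint)
  df
}

# internal: default baseline labels are any timepoint starting "baseline"
baseline_labels <- function(series) {
  labs <- unique(series$timepoint)
  hit <- labs[startsWith(labs, "baseline")]
  if (!length(hit)) abort("no baseline timepoint found in series")
  hit
}

#' Bland-Altman limits of agreement for clustered repeat measurements
#'
#' For each patient and each cluster of timepoints (e.g. the baseline
#' test/retest pair, the three post-chemotherapy draws, the three
#' post-radiotherapy draws), every measurement's difference from its own
#' cluster mean is computed.  The pooled differences give the mean
#' difference and the 95% limits of agreement
#' `mean +/- 1.96 * SD` (sample SD, n-1 denominator).
#'
#' @param series a concentration series (`patient`, `timepoint`,
#'   `ng_per_ml`).
#' @param grouping named list of character vectors; each element is one
#'   cluster of timepoint labels.  Defaults to the part-1 clusters
#'   (baseline pair, chemo triplet, RT triplet).
#' @return a `bland_altman_result`: list with the per-measurement
#'   `differences` table, `mean_diff`, `sd_diff`, `lower`, `upper`
#'   (all ng/ml) and `n`.
#' @export
bland_altman <- function(series, grouping = NULL) {
  df <- as_series(series)
  if (is.null(grouping)) {
    tp <- schedule_timepoints("part1")
    grouping <- list(baseline = tp[1:2], chemo = tp[3:5], rt = tp[6:8])
  }
  if (is.null(names(grouping)) || any(!nzchar(names(grouping))))
    names(grouping) <- paste0("cluster", seq_along(grouping))

  rows <- list()
  for (pat in unique(df$patient)) {
    for (cl in names(grouping)) {
      sub <- df[df$patient == pat & df$timepoint %in% grouping[[cl]], ,
                drop = FALSE]
      if (nrow(sub) == 0L) next
      if (nrow(sub) == 1L)
        abort("cluster '", cl, "' has a single measurement for patient ",
              pat, "; agreement needs >= 2 per cluster")
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pat, cluster = cl, timepoint = sub$timepoint,
        ng_per_ml = sub$ng_per_ml,
        diff = sub$ng_per_ml - mean(sub$ng_per_ml),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) abort("no cluster had any measurements")
  differences <- do.call(rbind, rows)
  d <- differences$diff
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(differences = differences, mean_diff = mean_diff,
         sd_diff = sd_diff,
         lower = mean_diff - 1.96 * sd_diff,
         upper = mean_diff + 1.96 * sd_diff,
         n = length(d)),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat("<bland_altman_result> n = ", x$n, " measurements\n", sep = "")
  cat(sprintf("  mean difference %.3f ng/ml, SD %.3f\n",
              x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% limits of agreement [%.3f, %.3f] ng/ml\n",
              x$lower, x$upper))
  invisible(x)
}

#' Baseline cfDNA summary across a cohort
#'
#' Baseline test/retest measurements are averaged within patient before
#' any summary, then the cohort median and range are reported, together
#' with per-histology mean baselines (optionally over a declared patient
#' subset, e.g. the part-2 patients).
#'
#' @param series a concentration series with a `histology` column.
#' @param baseline_timepoints labels counted as baseline; defaults to all
#'   labels starting with `"baseline"`.
#' @param group_subset patient ids over which the per-histology means are
#'   taken; `NULL` uses all patients.
#' @return a `baseline_summary`: list with `per_patient` table, `median`,
#'   `min`, `max` (ng/ml), `group_means` and `group_n` keyed by histology.
#' @export
summarize_baseline <- function(series, baseline_timepoints = NULL,
                               group_subset = NULL) {
  df <- as_series(series)
  if (is.null(baseline_timepoints))
    baseline_timepoints <- baseline_labels(df)
  base <- df[df$timepoint %in% baseline_timepoints, , drop = FALSE]
  if (!nrow(base)) abort("no baseline measurements in series")
  agg <- stats::aggregate(ng_per_ml ~ patient, data = base, FUN = mean)
  if (!is.null(df$histology))
    agg$histology <- df$histology[match(agg$patient, df$patient)]
  agg <- agg[order(match(agg$patient, unique(df$patient))), , drop = FALSE]
  rownames(agg) <- NULL

  grp <- if (is.null(group_subset)) agg
         else agg[agg$patient %in% group_subset, , drop = FALSE]
  group_means <- group_n <- NULL
  if (!is.null(grp$histology) && nrow(grp)) {
    group_means <- tapply(grp$ng_per_ml, grp$histology, mean)
    group_n <- tapply(grp$ng_per_ml, grp$histology, length)
  }
  structure(
    list(per_patient = agg,
         median = median(agg$ng_per_ml),
         min = min(agg$ng_per_ml),
         max = max(agg$ng_per_ml),
         n = nrow(agg),
         group_means = group_means,
         group_n = group_n),
    class = "baseline_summary"
  )
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat("<baseline_summary> ", x$n, " patient(s)\n", sep = "")
  cat(sprintf("  median %.2f ng/ml, range [%.2f, %.2f]\n",
              x$median, x$min, x$max))
  if (!is.null(x$group_means))
    for (h in names(x$group_means))
      cat(sprintf("  %s: mean %.2f ng/ml (n = %d)\n", h,
                  x$group_means[[h]], x$group_n[[h]]))
  invisible(x)
}

#' Change in cfDNA concentration from baseline, by histology
#'
#' Per patient, `delta = value(timepoint) - value(baseline)` with baseline
#' test/retest averaged first.  Patients missing the target timepoint are
#' excluded pairwise (never imputed) and listed in the result; a patient
#' with no baseline is an error.
#'
#' @param series a concentration series with a `histology` column.
#' @param timepoint target timepoint label.
#' @param baseline_timepoints labels counted as baseline; default as in
#'   [summarize_baseline()].
#' @return a `delta_summary`: list with per-patient `deltas` table, group
#'   `mean`, `min`, `max` per histology, `excluded` patient ids and
#'   `n_included` / `n_total`.
#' @export
change_from_baseline <- function(series, timepoint,
                                 baseline_timepoints = NULL) {
  df <- as_series(series)
  if (is.null(baseline_timepoints))
    baseline_timepoints <- baseline_labels(df)
  patients <- unique(df$patient)
  rows <- list()
  excluded <- character()
  for (pat in patients) {
    sub <- df[df$patient == pat, , drop = FALSE]
    base <- sub$ng_per_ml[sub$timepoint %in% baseline_timepoints]
    if (!length(base))
      abort("patient ", pat, " has no baseline measurement")
    target <- sub$ng_per_ml[sub$timepoint == timepoint]
    if (!length(target)) {
      excluded <- c(excluded, as.character(pat))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient = pat,
      histology = if (is.null(sub$histology)) NA_character_
                  else as.character(sub$histology[1L]),
      delta = mean(target) - mean(base),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    abort("no patient has a measurement at timepoint '", timepoint, "'")
  deltas <- do.call(rbind, rows)
  groups <- NULL
  if (!all(is.na(deltas$histology))) {
    groups <- do.call(rbind, lapply(split(deltas, deltas$histology),
      function(g) data.frame(histology = g$histology[1L],
                             mean = mean(g$delta), min = min(g$delta),
                             max = max(g$delta), n = nrow(g),
                             stringsAsFactors = FALSE)))
    rownames(groups) <- NULL
  }
  structure(
    list(timepoint = timepoint, deltas = deltas, groups = groups,
         excluded = excluded, n_included = nrow(deltas),
         n_total = length(patients)),
    class = "delta_summary"
  )
}

#' @export
print.delta_summary <- function(x, ...) {
  cat("<delta_summary> change from baseline at '", x$timepoint, "' (",
      x$n_included, " of ", x$n_total, " patients)\n", sep = "")
  if (!is.null(x$groups))
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("  %s: mean %+.2f ng/ml, range [%.2f, %.2f] (n = %d)\n",
                  x$groups$histology[i], x$groups$mean[i], x$groups$min[i],
                  x$groups$max[i], x$groups$n[i]))
  if (length(x$excluded))
    cat("  excluded (missing timepoint): ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Exact two-sided Wilcoxon rank-sum test with midranks
#'
#' The two-sided p-value is the null probability, over all
#' `choose(n_a + n_b, n_a)` equally likely assignments of the pooled
#' midranks to group labels, that the rank sum deviates from its null mean
#' at least as much as observed.  Ties are handled by midranks; the exact
#' distribution is computed by a generating-function recursion over the
#' doubled midranks (integers), so no assignment is ever materialized.
#' Above `exact_max` per group a normal approximation with tie correction
#' is used instead.
#'
#' @param a,b numeric vectors of measurements (both non-empty).
#' @param exact_max largest per-group size for which the exact
#'   distribution is enumerated (default 12).
#' @return a `rank_sum_result`: list with `p_value`, `statistic` (rank sum
#'   of `a`), `null_mean`, `n_a`, `n_b`, `exact`.
#' @export
rank_sum_exact <- function(a, b, exact_max = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) abort("missing values not allowed")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))                 # midranks
  w_obs <- sum(r[seq_len(n_a)])
  e_w <- n_a * (n + 1) / 2
  dev_obs <- abs(w_obs - e_w)

  exact <- max(n_a, n_b) <= exact_max
  if (exact) {
    # doubled midranks are integers; count subsets of size n_a by sum
    r2 <- as.integer(round(2 * r))
    s_max <- sum(sort(r2, decreasing = TRUE)[seq_len(n_a)])
    # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
    counts <- matrix(0, nrow = n_a + 1L, ncol = s_max + 1L)
    counts[1L, 1L] <- 1
    for (x in r2) {
      kmax <- n_a
      for (k in kmax:1) {
        from <- which(counts[k, ] > 0)
        from <- from[from + x <= s_max + 1L]
        if (length(from))
          counts[k + 1L, from + x] <- counts[k + 1L, from + x] +
            counts[k, from]
      }
    }
    sums2 <- which(counts[n_a + 1L, ] > 0) - 1L
    freq <- counts[n_a + 1L, sums2 + 1L]
    w_vals <- sums2 / 2
    p <- sum(freq[abs(w_vals - e_w) >= dev_obs - 1e-9]) / choose(n, n_a)
  } else {
    # normal approximation with tie correction on the variance
    ties <- table(r)
    v_w <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- if (v_w > 0) dev_obs / sqrt(v_w) else 0
    p <- min(1, 2 * pnorm(-z))
  }
  structure(
    list(p_value = p, statistic = w_obs, null_mean = e_w,
         n_a = n_a, n_b = n_b, exact = exact),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat("<rank_sum_result> W = ", x$statistic, " (null mean ", x$null_mean,
      "), n = ", x$n_a, " vs ", x$n_b, "\n", sep = "")
  cat("  two-sided p = ", signif(x$p_value, 4),
      if (x$exact) " (exact)" else " (normal approximation)", "\n",
      sep = "")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Product-moment correlation of midranks.  Returns `NA` with a warning
#' when either vector is constant (the correlation is undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Spearman's rho, or `NA_real_` if undefined.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("Spearman correlation undefined for a constant vector",
            call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
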