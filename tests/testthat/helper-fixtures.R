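# Shared fixtures and independent oracles used across test files.
# All fixtures are generated in code; nothing is read from disk except the
# bundled cohort table.

# Small neutral simulation: bins + fragments at a chosen per-bin depth.
sim_neutral <- function(n_bins = 100, depth = 2000, seed = 1,
                        gc_bias = NULL, tf = 0, segments = NULL) {
  bins <- make_bins(n_bins, 1e6, seed = seed)
  truth <- make_truth(bins, segments = segments, tf = tf)
  frags <- simulate_fragments(truth, bins, n_bins * depth,
                              gc_bias = gc_bias, seed = seed + 1000L)
  list(bins = bins, truth = truth, fragments = frags)
}

# Profile straight from a fragment table (optionally skipping GC fit).
profile_of <- function(fragments, bins, correct = TRUE) {
  counts <- count_fragments(fragments, bins)
  if (correct) counts <- gc_correct(counts)
  to_log2_profile(counts)
}

# Build a cn_profile directly from a log2-ratio vector (toy profiles for
# the calling logic; NA marks masked bins).
profile_from_r <- function(r, chrom = "chrS", bin_size = 1e6) {
  n <- length(r)
  p <- data.frame(
    chrom = rep(chrom, n),
    start = as.numeric(0:(n - 1)) * bin_size,
    end = as.numeric(1:n) * bin_size,
    gc = rep(0.45, n),
    log2ratio = r,
    usable = !is.na(r),
    stringsAsFactors = FALSE
  )
  class(p) <- c("cn_profile", "data.frame")
  p
}

# Build a bin_counts object with prescribed raw counts.
counts_from_raw <- function(raw, gc = NULL, seed = 1) {
  n <- length(raw)
  bins <- make_bins(n, 1e6, seed = seed)
  if (!is.null(gc)) bins$gc <- gc
  counts <- data.frame(bins[, c("chrom", "start", "end", "gc", "usable")],
                       raw = raw, corrected = NA_real_,
                       stringsAsFactors = FALSE)
  class(counts) <- c("bin_counts", "data.frame")
  attr(counts, "n_fragments") <- sum(raw)
  attr(counts, "n_dropped") <- 0L
  counts
}

# Independent brute-force oracle for the exact two-sided rank-sum p-value:
# materializes every label assignment with combn() and recomputes the rank
# sum per assignment, unlike the package's generating-function recursion.
brute_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  e <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - e)
  sets <- utils::combn(n, n1)
  w <- apply(sets, 2, function(i) sum(r[i]))
  mean(abs(w - e) >= obs - 1e-9)
}

# Concentration series for a hand-built cohort: one row per patient and
# timepoint, values supplied as a patient x timepoint matrix.
series_from_matrix <- function(values, patients, histology, timepoints) {
  df <- do.call(rbind, lapply(seq_along(patients), function(i) {
    data.frame(patient = patients[i], histology = histology[i],
               timepoint = timepoints, ng_per_ml = values[i, ],
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("concentration_series", "data.frame")
  df
}
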