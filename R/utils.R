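#' @importFrom stats cor loess mad median pnorm predict rbinom rnorm runif sd
#' @importFrom utils combn packageVersion
NULL

# internal: stop with a consistent prefix and no call noise
abort <- function(...) stop(..., call. = FALSE)

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("`", name, "` must be a single finite number")
  if (x < min || x > max)
    abort("`", name, "` must be in [", min, ", ", max, "], got ", x)
  if (integer && x != round(x))
    abort("`", name, "` must be a whole number, got ", x)
  invisible(x)
}

# columns required of a fragment table (BED3-like, 0-based half-open)
FRAGMENT_COLS <- c("chrom", "start", "end")

as_fragment_table <- function(df) {
  missing <- setdiff(FRAGMENT_COLS, names(df))
  if (length(missing))
    abort("fragment table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad))
    abort("fragment record ", bad[1L], " has end <= start (",
          df$chrom[bad[1L]], ":", df$start[bad[1L]], "-", df$end[bad[1L]], ")")
  class(df) <- c("fragment_table", "data.frame")
  df
}

#' Fragment lengths of a fragment table
#'
#' Lengths follow the 0-based half-open convention: `end - start`.
#'
#' @param fragments a fragment table (data frame with `chrom`, `start`, `end`).
#' @return integer-valued vector of fragment lengths in bp.
#' @export
fragment_lengths <- function(fragments) {
  fragments$end - fragments$start
}

#' @export
print.fragment_table <- function(x, ...) {
  cat("<fragment_table> ", nrow(x), " fragments on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  if (nrow(x)) {
    len <- fragment_lengths(x)
    cat("  length: median ", stats::median(len), " bp, range [",
        min(len), ", ", max(len), "]\n", sep = "")
    if (!is.null(x$origin))
      cat("  origin labels: ",
          paste(sprintf("%s=%d", names(table(x$origin)), table(x$origin)),
                collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
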