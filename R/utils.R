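# Interval arithmetic on half-open [start, end) intervals in megabases.
# All QTL coordinates in the package follow this convention, so union,
# intersection and length computations are exact for abutting intervals.

#' Merge overlapping or abutting half-open intervals
#'
#' @param df data frame with numeric `start` and `end` columns (Mb).
#' @return tibble with columns `start`, `end`, sorted, disjoint,
#'   non-abutting.
#' @keywords internal
#' @noRd
merge_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  stopifnot(all(df$end > df$start))
  o <- order(df$start, df$end)
  s <- df$start[o]
  e <- df$end[o]
  out_s <- s[1]
  out_e <- e[1]
  k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e[k]) {
      # overlap or abutment: [a,b) and [b,c) merge to [a,c)
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_s[k] <- s[i]
      out_e[k] <- e[i]
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# Intersection of two merged (sorted, disjoint) interval sets.
intersect_intervals <- function(a, b) {
  i <- 1L
  j <- 1L
  s <- numeric(0)
  e <- numeric(0)
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (hi > lo) {
      s <- c(s, lo)
      e <- c(e, hi)
    }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  tibble::tibble(start = s, end = e)
}

# Accept either start/end or ci_start/ci_end column pairs on a QTL table.
interval_cols <- function(df) {
  nm <- names(df)
  if (all(c("start", "end") %in% nm)) {
    dplyr::rename(df, .start = "start", .end = "end")
  } else if (all(c("ci_start", "ci_end") %in% nm)) {
    dplyr::rename(df, .start = "ci_start", .end = "ci_end")
  } else {
    stop("interval table needs start/end or ci_start/ci_end columns",
         call. = FALSE)
  }
}

# Merge a per-chromosome interval table; returns tibble(chrom, start, end).
merge_by_chrom <- function(df) {
  df <- interval_cols(df)
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(~ merge_intervals(
      tibble::tibble(start = .x$.start, end = .x$.end))) |>
    dplyr::ungroup()
}

# Stage-offset seeding: every stochastic stage derives its stream from the
# config seed plus a small fixed offset, so stages are individually
# reproducible and jointly non-overlapping for the seed ranges in use.
seed_offset <- c(
  mosaic = 0L, effects = 101L, phenotype = 202L, panel = 303L,
  genotype = 404L, rmip = 505L, pipeline = 606L
)

with_stage_seed <- function(seed, stage) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed) + seed_offset[[stage]])
  }
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
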