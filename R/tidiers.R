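#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise a genome scan
#'
#' @param x an `hs_scan` tibble.
#' @param ... unused.
#' @return one-row tibble: phenotype, number of markers, sample size,
#'   peak logP and its location.
#' @export
glance.hs_scan <- function(x, ...) {
  i <- which.max(x$logP)
  tibble::tibble(
    phenotype = attr(x, "phenotype"),
    conditioned_on = attr(x, "conditioned_on") %||% NA_character_,
    n = attr(x, "n"),
    n_markers = nrow(x),
    max_logP = x$logP[i],
    peak_chrom = x$chrom[i],
    peak_pos = x$pos[i]
  )
}

#' Summarise an RMIP profile
#'
#' @param x an `hs_rmip` tibble.
#' @param ... unused.
#' @return one-row tibble with the number of resamples, windows, and the
#'   top window.
#' @export
glance.hs_rmip <- function(x, ...) {
  i <- which.max(x$rmip)
  tibble::tibble(
    phenotype = attr(x, "phenotype"),
    B = attr(x, "B"),
    n_windows = nrow(x),
    max_rmip = x$rmip[i],
    top_chrom = x$chrom[i],
    top_window_start = x$window_start[i]
  )
}

#' Tidy a similarity matrix into long form
#'
#' @param x an `hs_simmat`.
#' @param ... unused.
#' @return tibble with columns `item1`, `item2`, `similarity` (upper
#'   triangle only).
#' @export
tidy.hs_simmat <- function(x, ...) {
  S <- unclass(x)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(S)[idx[, 1]],
                 item2 = colnames(S)[idx[, 2]],
                 similarity = S[idx])
}

#' Tidy a dosage tensor into long form
#'
#' @param x a `dosage_tensor`.
#' @param ... unused.
#' @return tibble with columns `individual`, `marker`, `founder`,
#'   `dosage`.
#' @export
tidy.dosage_tensor <- function(x, ...) {
  map <- attr(x, "map")
  d <- dim(x)
  tibble::tibble(
    individual = rep(dimnames(x)[[1]] %||% as.character(seq_len(d[1])),
                     times = d[2] * d[3]),
    marker = rep(rep(map$marker, each = d[1]), times = d[3]),
    founder = rep(seq_len(d[3]), each = d[1] * d[2]),
    dosage = as.vector(unclass(x))
  )
}
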