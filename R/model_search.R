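# Default entry threshold for forward selection (logP).  Calibrated once
# at the package's reference null scale (one 100 Mb chromosome, markers
# every 2 Mb, n = 400, B = 50) so that QTL calls at RMIP >= 0.25 occur at
# about one false positive per four null genome scans
# (scripts/tune_entry_threshold.R reproduces the calibration).
hs_entry_logp_default <- 2.5

#' Greedy forward selection of a multilocus QTL model
#'
#' Repeatedly adds the marker with the highest conditional logP (given
#' the already-selected markers' founder dosages as covariates) while
#' that logP reaches the entry threshold.  Markers within
#' `merge_window_mb` of a selected marker become ineligible, so one QTL
#' cannot enter twice.
#'
#' @inheritParams genome_scan
#' @param entry_logp logP required to enter the model (default 3, the
#'   package's calibrated null operating point).
#' @param merge_window_mb eligibility-suppression radius around selected
#'   markers, Mb (default 5).
#' @param max_steps safety cap on model size (default 25).
#' @return tibble: one row per selected marker (`marker`, `chrom`, `pos`,
#'   `logP` at entry, `step`), zero rows if nothing qualifies.
#' @export
forward_select <- function(phenotypes, dosage, phenotype,
                           entry_logp = hs_entry_logp_default,
                           merge_window_mb = 5, max_steps = 25,
                           max_logp = 320) {
  map <- attr(dosage, "map")
  y <- phenotypes[[phenotype]]
  ok <- stats::complete.cases(y)
  forward_select_core(y[ok], dosage[ok, , , drop = FALSE], map,
                      entry_logp, merge_window_mb, max_steps, max_logp)
}

forward_select_core <- function(y, D, map, entry_logp, merge_window_mb,
                                max_steps, max_logp = 320) {
  n <- length(y)
  M <- dim(D)[2]
  K <- dim(D)[3]
  eligible <- rep(TRUE, M)
  sel <- integer(0)
  sel_logp <- numeric(0)
  repeat {
    C <- matrix(1, n, 1)
    if (length(sel)) {
      extra <- do.call(cbind, lapply(sel, function(m)
        matrix(D[, m, ], n, K)[, -K, drop = FALSE]))
      C <- cbind(C, extra)
    }
    if (n <= ncol(C) + K) break
    sc <- scan_core(y, D, C, max_logp, effects = FALSE)
    sc$logP[!eligible] <- -Inf
    best <- which.max(sc$logP)
    if (!length(best) || sc$logP[best] < entry_logp) break
    sel <- c(sel, best)
    sel_logp <- c(sel_logp, sc$logP[best])
    eligible[map$chrom == map$chrom[best] &
               abs(map$pos - map$pos[best]) <= merge_window_mb] <- FALSE
    if (length(sel) >= max_steps) break
  }
  tibble::tibble(marker = map$marker[sel], chrom = map$chrom[sel],
                 pos = map$pos[sel], logP = sel_logp,
                 step = seq_along(sel))
}

#' Resample model inclusion probabilities (RMIP)
#'
#' Draws `B` subsamples of the individuals (80% without replacement by
#' default), runs [forward_select()] on each, and reports for each
#' genomic window the fraction of resampled multilocus models that
#' include a marker in the window.  An RMIP of 1 means the locus enters
#' every resampled model; 0.5 means half of them.
#'
#' @inheritParams forward_select
#' @param B number of resamples (default 100).
#' @param resample_fraction fraction of individuals per resample, in
#'   (0, 1] (default 0.8).
#' @param window_mb window size tiling the genome for inclusion
#'   accounting (default 1.5 Mb).
#' @param seed optional integer seed for the resampling stream.
#' @return tibble of class `hs_rmip`: `chrom`, `window_start`,
#'   `window_end`, `count`, `rmip`, covering every window of the genome.
#'   Attributes: `B`, `peaks` (tibble of per-resample selected marker
#'   positions), `params`, `phenotype`.
#' @export
rmip <- function(phenotypes, dosage, phenotype, B = 100,
                 resample_fraction = 0.8,
                 entry_logp = hs_entry_logp_default,
                 window_mb = 1.5, merge_window_mb = 5, seed = NULL,
                 max_logp = 320) {
  stopifnot(B >= 2, resample_fraction > 0, resample_fraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  map <- attr(dosage, "map")
  chroms <- attr(dosage, "chromosomes")
  y <- phenotypes[[phenotype]]
  ok <- which(stats::complete.cases(y))
  K <- dim(dosage)[3]
  m_sub <- floor(resample_fraction * length(ok))
  if (m_sub < K + 2) {
    stop("resample smaller than the minimum fit size", call. = FALSE)
  }
  peaks <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- ok[sample.int(length(ok), m_sub)]
    fs <- forward_select_core(y[idx], dosage[idx, , , drop = FALSE], map,
                              entry_logp, merge_window_mb, 25, max_logp)
    if (nrow(fs)) {
      peaks[[b]] <- dplyr::mutate(fs, resample = b)
    }
  }
  peaks <- dplyr::bind_rows(peaks)
  windows <- purrr::pmap_dfr(chroms, function(chrom, length) {
    widx <- 0:(ceiling(length / window_mb) - 1)
    tibble::tibble(chrom = chrom, widx = widx,
                   window_start = widx * window_mb,
                   window_end = pmin((widx + 1) * window_mb, length))
  })
  if (nrow(peaks)) {
    hits <- peaks |>
      dplyr::mutate(widx = floor(.data$pos / window_mb + 1e-9)) |>
      dplyr::distinct(.data$resample, .data$chrom, .data$widx) |>
      dplyr::count(.data$chrom, .data$widx, name = "count")
    windows <- dplyr::left_join(windows, hits, by = c("chrom", "widx"))
    windows$count[is.na(windows$count)] <- 0L
  } else {
    windows$count <- 0L
    peaks <- tibble::tibble(marker = character(0), chrom = character(0),
                            pos = numeric(0), logP = numeric(0),
                            step = integer(0), resample = integer(0))
  }
  windows$rmip <- windows$count / B
  spacing <- stats::median(unlist(tapply(map$pos, map$chrom,
                                         function(p) diff(sort(p)))))
  structure(windows, class = c("hs_rmip", class(windows)),
            B = B, peaks = peaks, phenotype = phenotype,
            params = list(resample_fraction = resample_fraction,
                          entry_logp = entry_logp, window_mb = window_mb,
                          merge_window_mb = merge_window_mb,
                          marker_spacing = spacing),
            chromosomes = chroms)
}

#' Call QTLs from an RMIP profile
#'
#' Windows at or above the RMIP threshold become QTLs; adjacent
#' qualifying windows merge.  The 95% positional confidence interval of
#' each QTL is the 2.5th-97.5th percentile of the per-resample selected
#' peak positions attributed to it (peaks within the merged window span,
#' padded by the merge window), widened to at least one window.
#'
#' @param profile an `hs_rmip` tibble from [rmip()].
#' @param rmip_threshold minimum RMIP for a call, in (0, 1] (default
#'   0.25, the operating point at which about one false positive QTL
#'   occurs every four null genome scans).
#' @return tibble of class `hs_qtlset`: `phenotype`, `chrom`, `ci_start`,
#'   `ci_end`, `peak`, `rmip`, `n_peaks`.
#' @export
call_qtls <- function(profile, rmip_threshold = 0.25) {
  stopifnot(rmip_threshold > 0, rmip_threshold <= 1)
  peaks <- attr(profile, "peaks")
  params <- attr(profile, "params")
  chroms <- attr(profile, "chromosomes")
  phen <- attr(profile, "phenotype") %||% NA_character_
  qual <- profile[profile$rmip >= rmip_threshold, , drop = FALSE]
  empty <- tibble::tibble(phenotype = character(0), chrom = character(0),
                          ci_start = numeric(0), ci_end = numeric(0),
                          peak = numeric(0), rmip = numeric(0),
                          n_peaks = integer(0))
  if (nrow(qual) == 0) {
    return(structure(empty, class = c("hs_qtlset", class(empty))))
  }
  qual <- dplyr::arrange(qual, .data$chrom, .data$window_start)
  # merge runs of adjacent qualifying windows
  newrun <- c(TRUE, qual$chrom[-1] != qual$chrom[-nrow(qual)] |
                qual$widx[-1] != qual$widx[-nrow(qual)] + 1L)
  run <- cumsum(newrun)
  out <- lapply(split(seq_len(nrow(qual)), run), function(i) {
    chrom <- qual$chrom[i[1]]
    span <- c(qual$window_start[i[1]], qual$window_end[i[length(i)]])
    pad <- params$merge_window_mb
    pk <- peaks$pos[peaks$chrom == chrom &
                      peaks$pos >= span[1] - pad &
                      peaks$pos < span[2] + pad]
    clen <- chroms$length[match(chrom, chroms$chrom)]
    if (length(pk) == 0) {
      ci <- span
      centre <- mean(span)
    } else {
      # m-out-of-n subsampling calibration: peak scatter across
      # fraction-f subsamples understates full-sample peak sampling
      # variation by sqrt((1-f)/f), so quantile deviations from the
      # median are rescaled by sqrt(f/(1-f)); the half-marker-spacing
      # pad reflects the granularity of peak localisation on the grid.
      centre <- stats::median(pk)
      qs <- unname(stats::quantile(pk, c(0.025, 0.975)))
      f <- params$resample_fraction
      scl <- if (f < 1) sqrt(f / (1 - f)) else 1
      pad <- (params$marker_spacing %||% 0) / 2
      ci <- centre + scl * (qs - centre) + c(-pad, pad)
      ci <- pmin(pmax(ci, 0), clen)
    }
    if (diff(ci) < params$window_mb) {
      mid <- mean(ci)
      ci <- mid + c(-0.5, 0.5) * params$window_mb
      ci <- pmin(pmax(ci, 0), clen)
    }
    centre <- min(max(centre, ci[1]), ci[2])
    tibble::tibble(phenotype = phen, chrom = chrom,
                   ci_start = ci[1], ci_end = ci[2], peak = centre,
                   rmip = max(qual$rmip[i]), n_peaks = length(pk))
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("hs_qtlset", class(out)))
}
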