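#' Phenome-wide correlation screen
#'
#' Correlates a focal phenotype against every other phenotype column of
#' the table (pairwise-complete observations), Spearman rank correlation
#' by default.  Results are sorted by logP; the screen is read against a
#' conservative Bonferroni threshold from [conservative_threshold()].
#'
#' @param table an `hs_pheno` tibble (or any data frame whose non-id
#'   columns are phenotypes).
#' @param focal name of the focal phenotype column.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param id_cols columns to ignore (default `"individual"`).
#' @return tibble of class `hs_screen`: `phenotype`, `method`, `r`, `p`,
#'   `logP`, `variance_explained` (percent, `100 r^2`), `n`, `degenerate`
#'   (flag for constant phenotypes, excluded from threshold tests).
#'   Attribute `focal` records the focal phenotype.
#' @export
correlation_screen <- function(table, focal,
                               method = c("spearman", "pearson"),
                               id_cols = "individual") {
  method <- match.arg(method)
  x <- table[[focal]]
  if (is.null(x)) stop("focal phenotype not found", call. = FALSE)
  others <- setdiff(names(table), c(id_cols, focal))
  others <- others[vapply(table[others], is.numeric, logical(1))]
  out <- purrr::map_dfr(others, function(nm) {
    res <- pair_correlation(x, table[[nm]], method)
    dplyr::bind_cols(tibble::tibble(phenotype = nm), res)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$logP))
  structure(out, class = c("hs_screen", class(out)),
            focal = focal, method = method)
}

# Correlation of one pair with the package's p-value conventions:
# Spearman = Pearson on average ranks, p from the t approximation for
# n >= 10 and from the exact permutation distribution below that.
pair_correlation <- function(x, y, method) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  base <- tibble::tibble(method = method, r = NA_real_, p = NA_real_,
                         logP = NA_real_, variance_explained = NA_real_,
                         n = n, degenerate = FALSE)
  if (n < 4) {
    base$degenerate <- TRUE
    return(base)
  }
  xs <- x[ok]
  ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    base$degenerate <- TRUE
    return(base)
  }
  if (method == "spearman") {
    xs <- rank(xs)
    ys <- rank(ys)
  }
  r <- stats::cor(xs, ys)
  if (abs(r) >= 1) {
    p <- if (n < 10 && method == "spearman") 2 / factorial(n) else 0
    p <- max(p, 1e-320)
  } else if (n < 10 && method == "spearman") {
    # exact permutation distribution of the rank correlation
    perms <- permute_all(n)
    robs <- abs(r)
    rs <- apply(perms, 1, function(pp) stats::cor(xs, ys[pp]))
    p <- mean(abs(rs) >= robs - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  base$r <- r
  base$p <- p
  base$logP <- -log10(max(p, 1e-320))
  base$variance_explained <- 100 * r^2
  base
}

permute_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permute_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Conservative multiple-testing threshold for the screen
#'
#' Bonferroni across the number of screened phenotypes:
#' `logP threshold = -log10(alpha / n_phenotypes)`.
#'
#' @param n_phenotypes number of phenotypes screened (>= 1).
#' @param alpha family-wise error rate, in (0, 1) (default 0.05).
#' @return the logP threshold (a number).
#' @export
conservative_threshold <- function(n_phenotypes, alpha = 0.05) {
  if (n_phenotypes < 1) stop("n_phenotypes must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  -log10(alpha / n_phenotypes)
}

#' Correlation between two phenotypes in a strain panel
#'
#' Computes the correlation either across individual animals or across
#' strain means (replicates averaged first), together with the
#' least-squares regression line used for panel scatter plots.
#'
#' @param panel an `hs_panel` tibble with a `strain` (or `line`) column.
#' @param x,y phenotype column names.
#' @param level `"animal"` or `"strain_mean"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return one-row tibble: `level`, `method`, `r`, `p`, `logP`,
#'   `variance_explained`, `n`, `slope`, `intercept`.
#' @export
strain_panel_correlation <- function(panel, x, y,
                                     level = c("animal", "strain_mean"),
                                     method = c("pearson", "spearman")) {
  level <- match.arg(level)
  method <- match.arg(method)
  strain_col <- intersect(c("strain", "line"), names(panel))[1]
  if (is.na(strain_col)) stop("panel needs a strain or line column",
                              call. = FALSE)
  df <- tibble::tibble(strain = panel[[strain_col]],
                       x = panel[[x]], y = panel[[y]])
  if (level == "strain_mean") {
    df <- df |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(x = mean(.data$x, na.rm = TRUE),
                       y = mean(.data$y, na.rm = TRUE))
    if (nrow(df) < 3) {
      stop("fewer than 3 strains for strain-mean correlation",
           call. = FALSE)
    }
  }
  res <- pair_correlation(df$x, df$y, method)
  fit <- stats::lm(y ~ x, data = df)
  dplyr::bind_cols(tibble::tibble(level = level), res,
                   tibble::tibble(slope = unname(stats::coef(fit)[2]),
                                  intercept = unname(stats::coef(fit)[1])))
}
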