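#' Haplotype-dosage association test at one locus
#'
#' Partial F-test comparing the linear model
#' \{intercept + covariates + founder-dosage contrasts\} against
#' \{intercept + covariates\}.  Because dosage rows sum to 2, one founder
#' (the last) serves as reference and its column is dropped; collinear
#' contrasts are dropped with reduced numerator degrees of freedom.
#'
#' @param dosage_at_locus numeric matrix individuals x founders.
#' @param phenotype_values numeric vector.
#' @param covariates optional numeric matrix/data frame of covariates
#'   (no intercept column).
#' @param max_logp cap on logP so perfect fits stay finite (default 320).
#' @return one-row tibble: `logP`, `df` (numerator d.f. actually used),
#'   `rdf`, `n`, and `eff_1` .. `eff_K` mean-centred founder effects.
#' @export
locus_test <- function(dosage_at_locus, phenotype_values, covariates = NULL,
                       max_logp = 320) {
  X <- as.matrix(dosage_at_locus)
  y <- as.numeric(phenotype_values)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- stats::complete.cases(y, C)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  C <- if (is.null(C)) matrix(1, length(y), 1) else cbind(1, C[ok, , drop = FALSE])
  K <- ncol(X)
  if (length(y) < K + ncol(C) + 1) {
    stop("insufficient complete observations for the locus test",
         call. = FALSE)
  }
  res <- locus_fit(y, X, C, max_logp)
  tibble::tibble(logP = res$logP, df = res$df, rdf = res$rdf,
                 n = length(y),
                 !!!stats::setNames(as.list(res$eff),
                                    paste0("eff_", seq_len(K))))
}

# Core fit shared by locus_test and genome_scan.  C must include the
# intercept.  Returns logP, numerator df, residual df, K-vector of
# mean-centred founder effects.
locus_fit <- function(y, X, C, max_logp = 320, qc = NULL, yr = NULL,
                      rss0 = NULL) {
  K <- ncol(X)
  if (is.null(qc)) qc <- qr(C)
  if (is.null(yr)) yr <- qr.resid(qc, y)
  if (is.null(rss0)) rss0 <- sum(yr^2)
  Xc <- X[, -K, drop = FALSE]               # reference founder dropped
  Xr <- qr.resid(qc, Xc)
  qx <- qr(Xr)
  r <- qx$rank
  n <- length(y)
  rdf <- n - qc$rank - r
  eff <- numeric(K)
  if (r == 0 || rdf <= 0 || rss0 <= 0) {
    return(list(logP = 0, df = r, rdf = max(rdf, 0), eff = eff))
  }
  beta <- qr.coef(qx, yr)
  rss1 <- sum(qr.resid(qx, yr)^2)
  beta[is.na(beta)] <- 0
  eff[-K] <- beta
  eff <- eff - mean(eff)
  Fstat <- ((rss0 - rss1) / r) / (rss1 / rdf)
  if (!is.finite(Fstat) || rss1 <= rss0 * 1e-14) {
    logP <- max_logp
  } else {
    logP <- -stats::pf(Fstat, r, rdf, lower.tail = FALSE, log.p = TRUE) /
      log(10)
    logP <- min(max(logP, 0), max_logp)
  }
  list(logP = logP, df = r, rdf = rdf, eff = eff)
}

# Internal fast scan: y (n), D (n x M x K), C (n x c incl. intercept).
# The covariate projection is applied to all marker contrasts in one
# LAPACK call; per-marker fits then reduce to a 7x7 Cholesky solve, with
# a QR fallback for rank-deficient (degenerate-dosage) loci.
scan_core <- function(y, D, C, max_logp = 320, effects = TRUE) {
  n <- length(y)
  M <- dim(D)[2]
  K <- dim(D)[3]
  qc <- qr(C)
  yr <- qr.resid(qc, y)
  rss0 <- sum(yr^2)
  logP <- numeric(M)
  df <- integer(M)
  eff <- matrix(0, M, K)
  # columns m + (k-1)*M of the flattened tensor hold founder k at marker m
  Dm <- matrix(D, n, M * K)
  keep <- as.vector(outer(seq_len(M), (seq_len(K - 1) - 1L) * M, `+`))
  Dr <- qr.resid(qc, Dm[, keep, drop = FALSE])
  r_full <- K - 1L
  rdf_full <- n - qc$rank - r_full
  for (m in seq_len(M)) {
    X <- Dr[, m + (seq_len(K - 1) - 1L) * M, drop = FALSE]
    W <- crossprod(X)
    ch <- tryCatch(chol(W), error = function(e) NULL)
    ok <- FALSE
    if (!is.null(ch) && rdf_full > 0 && rss0 > 0) {
      b <- crossprod(X, yr)
      u <- backsolve(ch, b, transpose = TRUE)
      rss1 <- rss0 - sum(u^2)
      if (rss1 > -1e-8 * rss0) {
        ok <- TRUE
        rss1 <- max(rss1, 0)
        Fstat <- ((rss0 - rss1) / r_full) / (rss1 / rdf_full)
        if (!is.finite(Fstat) || rss1 <= rss0 * 1e-14) {
          logP[m] <- max_logp
        } else {
          logP[m] <- min(max(
            -stats::pf(Fstat, r_full, rdf_full, lower.tail = FALSE,
                       log.p = TRUE) / log(10), 0), max_logp)
        }
        df[m] <- r_full
        if (effects) {
          beta <- backsolve(ch, u)
          e <- c(beta, 0)
          eff[m, ] <- e - mean(e)
        }
      }
    }
    if (!ok) {
      X0 <- matrix(D[, m, ], n, K)
      res <- locus_fit(y, X0, C, max_logp, qc = qc, yr = yr, rss0 = rss0)
      logP[m] <- res$logP
      df[m] <- res$df
      eff[m, ] <- res$eff
    }
  }
  list(logP = logP, df = df, eff = eff)
}

#' Genome scan by founder-haplotype regression
#'
#' Applies [locus_test()] at every marker of a dosage tensor.  Missing
#' phenotype or covariate values are dropped listwise for the whole scan.
#'
#' @param phenotypes an `hs_pheno` tibble (or any data frame with an
#'   `individual` column and phenotype columns).
#' @param dosage a `dosage_tensor` over the same individuals.
#' @param phenotype name of the phenotype column to scan.
#' @param covariates optional character vector of covariate column names
#'   in `phenotypes`.
#' @param max_logp logP cap (default 320).
#' @return tibble of class `hs_scan`: `marker`, `chrom`, `pos`, `logP`,
#'   `df`, `eff_1` .. `eff_K`.  Attributes: `phenotype`, `covariates`,
#'   `n`, `chromosomes`.
#' @export
genome_scan <- function(phenotypes, dosage, phenotype, covariates = NULL,
                        max_logp = 320) {
  stopifnot(inherits(dosage, "dosage_tensor"))
  map <- attr(dosage, "map")
  y <- phenotypes[[phenotype]]
  if (is.null(y)) stop("phenotype '", phenotype, "' not found", call. = FALSE)
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(phenotypes[covariates])
  }
  ok <- stats::complete.cases(y, C)
  n_ok <- sum(ok)
  K <- dim(dosage)[3]
  if (n_ok < K + length(covariates) + 2) {
    stop("insufficient complete observations for the genome scan",
         call. = FALSE)
  }
  Cfull <- if (is.null(C)) matrix(1, n_ok, 1) else cbind(1, C[ok, , drop = FALSE])
  res <- scan_core(y[ok], dosage[ok, , , drop = FALSE], Cfull, max_logp)
  out <- dplyr::bind_cols(
    map,
    tibble::tibble(logP = res$logP, df = res$df),
    tibble::as_tibble(stats::setNames(as.data.frame(res$eff),
                                      paste0("eff_", seq_len(K))))
  )
  structure(out, class = c("hs_scan", class(out)),
            phenotype = phenotype, covariates = covariates, n = n_ok,
            chromosomes = attr(dosage, "chromosomes"))
}

#' Conditional genome scan on covariate residuals
#'
#' Regresses the phenotype on a conditioning phenotype by ordinary least
#' squares (complete cases), then scans the residuals.  Shared genetic
#' control shows as attenuation of the conditioned peaks.
#'
#' @inheritParams genome_scan
#' @param condition_on name of the conditioning phenotype column.
#' @return an `hs_scan` tibble (see [genome_scan()]); attribute
#'   `conditioned_on` records the conditioning phenotype.
#' @export
conditional_scan <- function(phenotypes, dosage, phenotype, condition_on,
                             max_logp = 320) {
  y <- phenotypes[[phenotype]]
  z <- phenotypes[[condition_on]]
  if (is.null(y) || is.null(z)) {
    stop("phenotype column not found", call. = FALSE)
  }
  ok <- stats::complete.cases(y, z)
  if (stats::sd(z[ok]) == 0) {
    stop("conditioning phenotype is constant (degenerate covariate)",
         call. = FALSE)
  }
  resid <- rep(NA_real_, length(y))
  fit <- stats::lm.fit(cbind(1, z[ok]), y[ok])
  r_ok <- fit$residuals
  # residuals that are pure floating-point noise (phenotype an exact
  # linear function of the conditioner) are a genuinely empty signal
  if (stats::sd(r_ok) < 1e-10 * stats::sd(y[ok])) r_ok[] <- 0
  resid[ok] <- r_ok
  ph2 <- phenotypes
  ph2[[".cond_resid"]] <- resid
  out <- genome_scan(ph2, dosage, ".cond_resid", max_logp = max_logp)
  attr(out, "phenotype") <- phenotype
  attr(out, "conditioned_on") <- condition_on
  out
}
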