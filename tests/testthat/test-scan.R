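# One fixed dosage fixture reused across blocks
scan_fix <- local({
  cfg <- hs_config(n_individuals = 500, chromosomes = c(`1` = 100),
                   marker_spacing = 2, qtl_spec = list(),
                   null_phenotypes = "y", polygenic_h2 = 0, seed = 21)
  st <- simulate_hs_study(cfg)
  st
})

test_that("null locus tests are uniform: mean logP near log10(e)", {
  set.seed(22)
  n <- 500
  D1 <- matrix(scan_fix$dosage[, 10, ], n, 8)
  reps <- 1000
  logp <- numeric(reps)
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    y <- rnorm(n)
    r <- locus_test(D1, y)
    logp[i] <- r$logP
    p[i] <- 10^(-r$logP)
  }
  # mean of -log10 U(0,1) is log10(e) = 0.4343
  expect_lt(abs(mean(logp) - log10(exp(1))), 4 * sd(logp) / sqrt(reps))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("F-test p-value agrees with a permutation oracle", {
  set.seed(23)
  n <- 120
  D1 <- matrix(scan_fix$dosage[1:n, 25, ], n, 8)
  # phenotype with a modest true signal so p is away from 0 and 1
  y <- D1 %*% c(0.3, 0, 0, -0.3, 0, 0, 0, 0) + rnorm(n)
  p_f <- 10^(-locus_test(D1, y)$logP)
  # permutation distribution of the F statistic, vectorised
  X <- D1[, 1:7]
  Q <- qr.Q(qr(cbind(1, X)))
  n_perm <- 10000
  fstat <- function(yy) {
    rss0 <- sum((yy - mean(yy))^2)
    fit <- Q %*% crossprod(Q, yy)
    rss1 <- sum((yy - fit)^2)
    ((rss0 - rss1) / 7) / (rss1 / (n - 8))
  }
  f_obs <- fstat(y)
  f_perm <- replicate(n_perm, fstat(sample(y)))
  p_perm <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  tol <- 4 * sqrt(p_f * (1 - p_f) / n_perm) + 2 / n_perm
  expect_lt(abs(p_f - p_perm), tol)
})

test_that("perfect fits cap at max_logp and degenerate columns drop", {
  n <- 200
  D1 <- matrix(scan_fix$dosage[1:n, 30, ], n, 8)
  y <- D1 %*% rnorm(8)  # noise-free function of the dosage
  r <- locus_test(D1, y)
  expect_equal(r$logP, 320)
  r2 <- locus_test(D1, y, max_logp = 50)
  expect_equal(r2$logP, 50)
  # constant dosage column: contrast dropped, finite result
  D_const <- D1
  D_const[, 2] <- 0
  D_const[, 1] <- 2 - rowSums(D_const[, 3:8])
  r3 <- locus_test(D_const, rnorm(n))
  expect_true(is.finite(r3$logP))
  expect_lte(r3$df, 6)
  # effects are mean-centred
  expect_equal(sum(r3[paste0("eff_", 1:8)]), 0, tolerance = 1e-10)
  expect_error(locus_test(D1[1:8, ], rnorm(8)), "insufficient")
})

test_that("genome scan finds the causal locus and handles missingness", {
  st <- tiny_study(n = 400, frac = 0.2, seed = 24, spacing = 2)
  sc <- genome_scan(st$phenotypes, st$dosage, "y")
  expect_s3_class(sc, "hs_scan")
  expect_equal(nrow(sc), 50)
  expect_true(all(sc$logP >= 0 & is.finite(sc$logP)))
  truth <- attr(st$phenotypes, "truth")
  expect_lt(abs(sc$pos[which.max(sc$logP)] - truth$marker_pos[1]), 3.1)
  g <- glance(sc)
  expect_equal(g$n, 400)
  # listwise deletion: inject missing values, scan still runs
  ph <- st$phenotypes
  ph$y[1:40] <- NA
  sc2 <- genome_scan(ph, st$dosage, "y")
  expect_equal(attr(sc2, "n"), 360)
})

test_that("noise-free scan is globally maximal at the causal marker", {
  st <- tiny_study(n = 300, frac = 0.5, seed = 25, spacing = 2)
  truth <- attr(st$phenotypes, "truth")
  mk <- truth$marker[1]
  y_pure <- as.vector(st$dosage[, mk, ] %*% c(2, -1, 0.5, 0, -2, 1, 0, -0.5))
  ph <- st$phenotypes
  ph$y <- y_pure
  sc <- genome_scan(ph, st$dosage, "y")
  expect_equal(sc$marker[which.max(sc$logP)], mk)
  expect_equal(max(sc$logP), 320)
})

test_that("conditioning a phenotype on itself nullifies the scan", {
  st <- tiny_study(n = 300, frac = 0.3, seed = 26, spacing = 4)
  ph <- st$phenotypes
  ph$y2 <- ph$y
  cs <- conditional_scan(ph, st$dosage, "y", "y2")
  expect_true(all(cs$logP == 0))
  ph$flat <- 1
  expect_error(conditional_scan(ph, st$dosage, "y", "flat"), "constant")
})

test_that("conditioning attenuates shared peaks in both directions", {
  # strongly genetically coupled pair: five shared loci at effect
  # correlation 1 explaining 0.75 of each trait
  ratios_ab <- c()
  ratios_ba <- c()
  for (r in 1:4) {
    qs <- lapply(1:5, function(i) hs_qtl(as.character(i), 50, 0.15,
                                         c("a", "b")))
    cfg <- hs_config(n_individuals = 700,
                     chromosomes = stats::setNames(rep(100, 5), 1:5),
                     marker_spacing = 2, qtl_spec = qs,
                     effect_correlation = 1, polygenic_h2 = 0,
                     seed = 900 + r)
    st <- simulate_hs_study(cfg)
    sa <- genome_scan(st$phenotypes, st$dosage, "a")
    ca <- conditional_scan(st$phenotypes, st$dosage, "a", "b")
    sb <- genome_scan(st$phenotypes, st$dosage, "b")
    cb <- conditional_scan(st$phenotypes, st$dosage, "b", "a")
    pk <- function(s, ch) max(s$logP[s$chrom == ch & abs(s$pos - 50) <= 5])
    for (ch in as.character(1:5)) {
      ratios_ab <- c(ratios_ab, pk(ca, ch) / pk(sa, ch))
      ratios_ba <- c(ratios_ba, pk(cb, ch) / pk(sb, ch))
    }
  }
  # >= 80% reduction of the shared peaks, on average, both directions
  expect_lt(mean(ratios_ab), 0.2)
  expect_lt(mean(ratios_ba), 0.2)
})

test_that("conditioning leaves private loci essentially untouched", {
  # Fig-2-like asymmetric pair: the conditioning trait is well
  # determined by the shared loci (0.65 of its variance) while they
  # explain only 0.1 of the scanned trait, which keeps a private locus;
  # the overall correlation (~0.25) stays moderate so private peaks
  # move little
  ratios_private <- c()
  for (r in 1:3) {
    qs <- c(
      lapply(1:5, function(i)
        hs_qtl(as.character(i), 40, c(a = 0.02, b = 0.13), c("a", "b"))),
      list(hs_qtl("3", 85, 0.08, "a")))
    cfg <- hs_config(n_individuals = 700,
                     chromosomes = stats::setNames(rep(100, 5), 1:5),
                     marker_spacing = 2, qtl_spec = qs,
                     effect_correlation = 1, polygenic_h2 = 0,
                     seed = 950 + r)
    st <- simulate_hs_study(cfg)
    sa <- genome_scan(st$phenotypes, st$dosage, "a")
    ca <- conditional_scan(st$phenotypes, st$dosage, "a", "b")
    truth <- attr(st$phenotypes, "truth")
    mk <- truth$marker[truth$phenotype == "a" & truth$chrom == "3" &
                         truth$pos == 85]
    ratios_private <- c(ratios_private,
                        ca$logP[ca$marker == mk] / sa$logP[sa$marker == mk])
  }
  expect_gt(mean(ratios_private), 0.8)
  expect_lt(mean(ratios_private), 1.2)
})
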