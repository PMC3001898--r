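test_that("mosaic segments tile chromosomes with the expected density", {
  cfg <- hs_config(n_individuals = 500, chromosomes = c(`1` = 100),
                   generations = 50, qtl_spec = list(),
                   null_phenotypes = "y", polygenic_h2 = 0, seed = 1)
  mos <- simulate_mosaics(cfg)
  # exact tiling per track
  by_track <- split(seq_len(nrow(mos)),
                    paste(mos$individual, mos$chrom, mos$track))
  for (g in by_track[1:50]) {
    expect_equal(mos$start[g[1]], 0)
    expect_equal(mos$end[g[length(g)]], 100)
    if (length(g) > 1) {
      expect_equal(mos$start[g[-1]], mos$end[g[-length(g)]])
    }
  }
  expect_true(all(mos$founder %in% 1:8))
  # mean segment count per track: length / (100/gen cM at 0.5 cM/Mb)
  # = 100 Mb / 4 Mb = 25 segments, i.e. 24 breakpoints + 1; tracks here
  # number 1,000, so the mean is tight
  n_seg <- lengths(by_track)
  expect_lt(abs(mean(n_seg) - 26) / 26, 0.05)  # 25 breakpoint intervals + 1
})

test_that("degenerate mosaic configs behave", {
  cfg0 <- hs_config(n_individuals = 0, chromosomes = c(`1` = 50),
                    qtl_spec = list(), seed = 1)
  expect_equal(nrow(simulate_mosaics(cfg0)), 0)
  expect_error(hs_config(chromosomes = c(`1` = -5)), "positive")
  # very many generations: dosage approaches uniform 2/8 per founder
  cfg_hot <- hs_config(n_individuals = 300, chromosomes = c(`1` = 20),
                       generations = 5000, marker_spacing = 5,
                       qtl_spec = list(), seed = 2)
  st_map <- make_marker_map(cfg_hot)
  D <- mosaics_to_dosage(simulate_mosaics(cfg_hot), st_map)
  expect_equal(unname(colMeans(D[, 1, ])), rep(2 / 8, 8), tolerance = 0.15)
})

test_that("dosage tensor counts founder tracks and conserves rows", {
  cfg <- hs_config(n_individuals = 20, chromosomes = c(`1` = 30),
                   marker_spacing = 2, qtl_spec = list(),
                   null_phenotypes = "y", seed = 3)
  mos <- simulate_mosaics(cfg)
  map <- make_marker_map(cfg)
  D <- mosaics_to_dosage(mos, map)
  expect_equal(dim(D), c(20, 15, 8))
  # conservation: every row sums to exactly 2
  expect_true(all(apply(D, c(1, 2), sum) == 2))
  expect_true(all(D %in% 0:2))
  # spot-check one individual at one marker against the mosaic
  pos <- map$pos[4]
  seg <- mos[mos$individual == 7 & mos$start <= pos & mos$end > pos, ]
  expect_equal(nrow(seg), 2)
  expected <- tabulate(seg$founder, 8)
  expect_equal(unname(D[7, 4, ]), expected)
  # marker outside bounds errors
  bad <- tibble::tibble(marker = "x", chrom = "1", pos = 31)
  expect_error(mosaics_to_dosage(mos, bad), "outside")
  # true_dosages is the same bypass
  expect_identical(unclass(true_dosages(mos, map)), unclass(D))
})

test_that("simulation is bitwise reproducible from the seed", {
  cfg <- hs_config(n_individuals = 30, chromosomes = c(`1` = 40),
                   qtl_spec = list(hs_qtl("1", 20, 0.1, "y")),
                   seed = 99)
  s1 <- simulate_hs_study(cfg)
  s2 <- simulate_hs_study(cfg)
  expect_identical(s1$mosaics, s2$mosaics)
  expect_identical(unclass(s1$dosage), unclass(s2$dosage))
  expect_identical(as.data.frame(s1$phenotypes),
                   as.data.frame(s2$phenotypes))
})

test_that("each simulated QTL explains its stated variance fraction", {
  # oracle: regress the phenotype on the true dosage at the causal
  # marker and average realised R^2 over replicates
  frac <- 0.05
  reps <- 200
  r2 <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- hs_config(n_individuals = 400, chromosomes = c(`1` = 20),
                     marker_spacing = 4,
                     qtl_spec = list(hs_qtl("1", 10, frac, "y")),
                     polygenic_h2 = 0, seed = 5000 + i)
    st <- simulate_hs_study(cfg)
    mk <- attr(st$phenotypes, "truth")$marker[1]
    X <- st$dosage[, mk, 1:7]
    r2[i] <- summary(lm(st$phenotypes$y ~ X))$r.squared
  }
  se <- sd(r2) / sqrt(reps)
  # fitting 7 founder contrasts inflates R^2 by ~ d/n under the null part
  bias_allowance <- 7 / 400
  expect_lt(abs(mean(r2) - frac), 3 * se + bias_allowance)
})

test_that("shared loci induce positive phenotypic correlation", {
  rs <- numeric(60)
  for (i in seq_along(rs)) {
    qs <- lapply(c(10, 30, 50, 70, 90), function(p)
      hs_qtl("1", p, 0.05, c("a", "b")))
    cfg <- hs_config(n_individuals = 300, chromosomes = c(`1` = 100),
                     marker_spacing = 2, qtl_spec = qs,
                     effect_correlation = 0.9, polygenic_h2 = 0,
                     seed = 6000 + i)
    st <- simulate_hs_study(cfg)
    rs[i] <- cor(st$phenotypes$a, st$phenotypes$b)
  }
  expect_gt(mean(rs > 0), 0.95)
  expect_gt(mean(rs), 0.1)
})

test_that("missing-value injection respects the configured rate", {
  cfg <- hs_config(n_individuals = 500, chromosomes = c(`1` = 20),
                   marker_spacing = 4, qtl_spec = list(),
                   null_phenotypes = c("a", "b"), missing_rate = 0.1,
                   polygenic_h2 = 0, seed = 8)
  st <- simulate_hs_study(cfg)
  vals <- as.matrix(st$phenotypes[, c("a", "b")])
  expect_lt(abs(mean(is.na(vals)) - 0.1), 0.03)
})

test_that("progenitor panel has the right design and noise behaviour", {
  cfg <- hs_config(n_individuals = 10, chromosomes = c(`1` = 100),
                   qtl_spec = list(hs_qtl("1", 50, 0.3, "y")),
                   polygenic_h2 = 0, seed = 10)
  pan <- simulate_strain_panel(cfg, "progenitor", replicates = 5)
  expect_equal(nrow(pan), 40)  # 8 strains x 5 animals
  expect_equal(length(unique(pan$strain)), 8)
  # zero within-strain noise: replicates identical within strain
  pan0 <- simulate_strain_panel(cfg, "progenitor", replicates = 3,
                                within_strain_sd = 0)
  spread <- tapply(pan0$y, pan0$strain, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("recombinant inbred lines are homozygous two-founder mosaics", {
  cfg <- hs_config(n_individuals = 10, chromosomes = c(`1` = 100),
                   marker_spacing = 5,
                   qtl_spec = list(hs_qtl("1", 50, 0.3, "y")),
                   polygenic_h2 = 0, seed = 11)
  ri <- simulate_strain_panel(cfg, "recombinant_inbred", n_lines = 30,
                              ri_founders = c(5, 7))
  expect_equal(nrow(ri), 30)
  D <- attr(ri, "dosage")
  # support on at most the two RI founders, homozygous at every marker
  expect_true(all(D[, , -c(5, 7)] == 0))
  expect_true(all(D %in% c(0, 2)))
  expect_true(all(apply(D, c(1, 2), sum) == 2))
})

test_that("invalid QTL architectures are rejected", {
  expect_error(hs_qtl("1", 10, 0, "y"), "variance_fraction")
  expect_error(
    hs_config(chromosomes = c(`1` = 100),
              qtl_spec = list(hs_qtl("1", 50, 0.6, "y"),
                              hs_qtl("1", 70, 0.5, "y")),
              polygenic_h2 = 0),
    "reach 1")
  expect_error(
    hs_config(chromosomes = c(`1` = 100),
              qtl_spec = list(hs_qtl("1", 150, 0.1, "y"))),
    "outside")
})
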