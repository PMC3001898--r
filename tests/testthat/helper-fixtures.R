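# Shared fixtures and independent oracles used across the suite.

# Small single-QTL study
tiny_study <- function(n = 200, frac = 0.08, seed = 1, spacing = 1,
                       chrom_len = 100, polygenic = 0) {
  cfg <- hs_config(
    n_individuals = n, chromosomes = c(`1` = chrom_len),
    marker_spacing = spacing,
    qtl_spec = list(hs_qtl("1", chrom_len / 2, frac, "y")),
    polygenic_h2 = polygenic, seed = seed)
  simulate_hs_study(cfg)
}

# Rasterised Sorensen oracle: grid of 0.1 Mb cells, set membership by
# cell, similarity from cell counts.  Independent of the package's
# interval arithmetic.
raster_sorensen <- function(a, b, cell = 0.1) {
  norm <- function(df) {
    if ("ci_start" %in% names(df)) {
      df$start <- df$ci_start
      df$end <- df$ci_end
    }
    df
  }
  a <- norm(a); b <- norm(b)
  cells <- function(df) {
    if (nrow(df) == 0) return(character(0))
    unlist(lapply(seq_len(nrow(df)), function(i) {
      lo <- round(df$start[i] / cell)
      hi <- round(df$end[i] / cell) - 1
      if (hi < lo) return(character(0))
      paste(df$chrom[i], lo:hi)
    }))
  }
  ca <- unique(cells(a))
  cb <- unique(cells(b))
  if (length(ca) + length(cb) == 0) return(0)
  2 * length(intersect(ca, cb)) / (length(ca) + length(cb))
}

# Random interval set on a 0.1 Mb lattice (so the raster oracle is exact)
random_qtlset <- function(n_int, chroms = as.character(1:3), len = 100) {
  ch <- sample(chroms, n_int, replace = TRUE)
  s <- round(runif(n_int, 0, len - 10), 1)
  w <- round(runif(n_int, 0.2, 8), 1)
  tibble::tibble(chrom = ch, start = s, end = pmin(s + w, len))
}

# Exhaustive-enumeration oracle for the ancestry HMM posterior: sums the
# joint probability over every ordered founder-pair path.
enumerate_posterior <- function(g, H, s, eps, K) {
  M <- length(g)
  emis <- hsqtl:::genotype_emission(eps)
  states <- expand.grid(a = 1:K, b = 1:K)
  nS <- nrow(states)
  trans1 <- function(sm) {
    # per-track transition matrix
    (1 - sm) * diag(K) + sm / K
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(nS)), M)))
  post <- array(0, c(K, K, M))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- 1 / K^2
    for (m in seq_len(M)) {
      st <- paths[r, m]
      a <- states$a[st]; b <- states$b[st]
      if (m > 1) {
        st0 <- paths[r, m - 1]
        a0 <- states$a[st0]; b0 <- states$b[st0]
        Tm <- trans1(s[m - 1])
        pr <- pr * Tm[a0, a] * Tm[b0, b]
      }
      if (!is.na(g[m])) {
        tg <- H[m, a] + H[m, b]
        pr <- pr * emis[g[m] + 1, tg + 1]
      }
    }
    total <- total + pr
    for (m in seq_len(M)) {
      st <- paths[r, m]
      post[states$a[st], states$b[st], m] <-
        post[states$a[st], states$b[st], m] + pr
    }
  }
  post / total
}
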