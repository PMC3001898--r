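#' Marker map for a simulated genome
#'
#' Places markers on a regular grid (offset half a spacing from the
#' chromosome start) along each chromosome of the configured genome.
#'
#' @param config an [hs_config()] object.
#' @return tibble with columns `marker`, `chrom`, `pos` (Mb).
#' @export
make_marker_map <- function(config) {
  purrr::pmap_dfr(config$chromosomes, function(chrom, length) {
    pos <- seq(config$marker_spacing / 2, length,
               by = config$marker_spacing)
    tibble::tibble(
      marker = sprintf("m%s_%03d", chrom, seq_along(pos)),
      chrom = chrom,
      pos = pos
    )
  })
}

#' Simulate founder mosaics for an outbred HS population
#'
#' Each individual carries two haplotype tracks per chromosome.  Ancestral
#' recombination breakpoints are laid down by a memoryless (Poisson)
#' process with mean segment length `100/generations` cM converted at
#' `cm_per_mb`; founder identity at each segment is i.i.d. uniform over
#' the founders.  This reproduces the fine founder mosaic of a stock
#' intercrossed for many generations without simulating pedigrees.
#'
#' @param config an [hs_config()] object.
#' @return tibble of class `hs_mosaic` with columns `individual`, `chrom`,
#'   `track` (1 or 2), `start`, `end` (Mb, half-open), `founder`
#'   (1..n_founders).  Segments tile each chromosome exactly.
#' @export
simulate_mosaics <- function(config) {
  stopifnot(inherits(config, "hs_config"))
  with_stage_seed(config$seed, "mosaic")
  rate <- config$generations * config$cm_per_mb / 100  # breakpoints per Mb
  K <- config$n_founders
  n <- config$n_individuals
  if (n == 0) {
    out <- tibble::tibble(individual = integer(0), chrom = character(0),
                          track = integer(0), start = numeric(0),
                          end = numeric(0), founder = integer(0))
    return(structure(out, class = c("hs_mosaic", class(out)),
                     chromosomes = config$chromosomes,
                     n_founders = K))
  }
  ind_v <- list(); chrom_v <- list(); track_v <- list()
  start_v <- list(); end_v <- list(); founder_v <- list()
  k <- 0L
  for (ci in seq_len(nrow(config$chromosomes))) {
    chrom <- config$chromosomes$chrom[ci]
    len <- config$chromosomes$length[ci]
    for (tr in 1:2) {
      for (ind in seq_len(n)) {
        bp <- simulate_breakpoints(len, rate)
        ns <- length(bp) + 1L
        k <- k + 1L
        ind_v[[k]] <- rep.int(ind, ns)
        chrom_v[[k]] <- rep.int(chrom, ns)
        track_v[[k]] <- rep.int(tr, ns)
        start_v[[k]] <- c(0, bp)
        end_v[[k]] <- c(bp, len)
        founder_v[[k]] <- sample.int(K, ns, replace = TRUE)
      }
    }
  }
  out <- tibble::tibble(
    individual = unlist(ind_v), chrom = unlist(chrom_v),
    track = unlist(track_v), start = unlist(start_v),
    end = unlist(end_v), founder = unlist(founder_v))
  out <- dplyr::arrange(out, .data$individual, .data$chrom, .data$track,
                        .data$start)
  structure(out, class = c("hs_mosaic", class(out)),
            chromosomes = config$chromosomes, n_founders = K)
}

simulate_breakpoints <- function(len, rate) {
  if (rate <= 0) return(numeric(0))
  bp <- numeric(0)
  at <- 0
  # draw in blocks to keep the loop short
  repeat {
    block <- stats::rexp(max(8L, ceiling(len * rate * 1.5)), rate)
    pos <- at + cumsum(block)
    bp <- c(bp, pos[pos < len])
    at <- pos[length(pos)]
    if (at >= len) break
  }
  bp
}

#' Convert founder mosaics to an expected founder-dosage tensor
#'
#' At each marker the dosage of founder f is the number of haplotype
#' tracks (0, 1, or 2) assigned to f, so every individual x marker row
#' sums to exactly 2.
#'
#' @param mosaics an `hs_mosaic` tibble from [simulate_mosaics()].
#' @param marker_map tibble with `marker`, `chrom`, `pos`.
#' @return a `dosage_tensor`: numeric array individuals x markers x
#'   founders with the marker map attached as attribute `map`.
#' @export
mosaics_to_dosage <- function(mosaics, marker_map) {
  chroms <- attr(mosaics, "chromosomes")
  K <- attr(mosaics, "n_founders") %||% max(mosaics$founder)
  lens <- stats::setNames(chroms$length, chroms$chrom)
  if (any(!marker_map$chrom %in% chroms$chrom) ||
      any(marker_map$pos < 0 | marker_map$pos >= lens[marker_map$chrom])) {
    stop("marker outside chromosome bounds", call. = FALSE)
  }
  inds <- sort(unique(mosaics$individual))
  n <- length(inds)
  M <- nrow(marker_map)
  D <- array(0, dim = c(n, M, K),
             dimnames = list(individual = as.character(inds),
                             marker = marker_map$marker,
                             founder = NULL))
  key <- paste(mosaics$individual, mosaics$chrom, mosaics$track, sep = "\r")
  segs <- split(seq_len(nrow(mosaics)), key)
  mcol <- split(seq_len(M), marker_map$chrom)
  for (g in segs) {
    chrom <- mosaics$chrom[g[1]]
    cols <- mcol[[chrom]]
    if (is.null(cols)) next
    ind <- match(mosaics$individual[g[1]], inds)
    idx <- findInterval(marker_map$pos[cols], mosaics$start[g])
    f <- mosaics$founder[g][idx]
    for (k in seq_along(cols)) {
      D[ind, cols[k], f[k]] <- D[ind, cols[k], f[k]] + 1
    }
  }
  structure(D, class = "dosage_tensor", map = marker_map,
            chromosomes = chroms)
}

#' True founder dosages from known descent
#'
#' Known-descent bypass for the ancestry reconstruction: delegates to
#' [mosaics_to_dosage()].
#'
#' @inheritParams mosaics_to_dosage
#' @return a `dosage_tensor`.
#' @export
true_dosages <- function(mosaics, marker_map) {
  mosaics_to_dosage(mosaics, marker_map)
}

# Per-QTL, per-phenotype founder-effect vectors.  Shared loci get one
# vector per phenotype, correlated at config$effect_correlation; vectors
# are mean-centred (dosage rows sum to 2, so the mean is an intercept).
qtl_effect_vectors <- function(config) {
  with_stage_seed(config$seed, "effects")
  K <- config$n_founders
  rho <- config$effect_correlation
  lapply(config$qtl_spec, function(q) {
    base <- q$founder_effects %||% stats::rnorm(K)
    base <- base - mean(base)
    if (stats::sd(base) > 0) base <- base / stats::sd(base)
    eff <- lapply(q$phenotypes, function(p) {
      if (length(q$phenotypes) == 1) return(base)
      z <- stats::rnorm(K)
      z <- z - mean(z)
      if (stats::sd(z) > 0) z <- z / stats::sd(z)
      v <- rho * base + sqrt(max(0, 1 - rho^2)) * z
      v - mean(v)
    })
    names(eff) <- q$phenotypes
    eff
  })
}

#' Simulate phenotypes on a founder-dosage tensor
#'
#' Each phenotype is the sum of its QTL contributions (founder-effect
#' vectors applied to the dosage at the marker nearest the specified QTL
#' position), a diffuse polygenic term spread over all markers, and
#' Gaussian noise.  Effect vectors are rescaled so that each locus
#' explains its stated variance fraction in the simulated sample; total
#' phenotypic variance is approximately 1.
#'
#' @param dosage a `dosage_tensor`.
#' @param config the [hs_config()] that generated it.
#' @param trait_sets optional tibble (`phenotype`, `trait_set`) attached to
#'   the result for downstream grouping.
#' @return tibble of class `hs_pheno`: one row per individual, one column
#'   per phenotype, plus an `individual` column.  Attributes: `trait_sets`
#'   and `truth` (per-phenotype tibble of simulated QTLs: chromosome,
#'   position, assigned marker, variance fraction).
#' @export
simulate_phenotypes <- function(dosage, config, trait_sets = NULL) {
  stopifnot(inherits(dosage, "dosage_tensor"))
  validate_qtl_spec(config)
  map <- attr(dosage, "map")
  n <- dim(dosage)[1]
  M <- dim(dosage)[2]
  K <- dim(dosage)[3]
  effects <- qtl_effect_vectors(config)
  with_stage_seed(config$seed, "phenotype")
  phenos <- unique(c(unlist(lapply(config$qtl_spec, `[[`, "phenotypes")),
                     config$null_phenotypes))
  vals <- matrix(0, n, length(phenos), dimnames = list(NULL, phenos))
  truth <- list()
  for (qi in seq_along(config$qtl_spec)) {
    q <- config$qtl_spec[[qi]]
    on_chrom <- which(map$chrom == q$chrom)
    mk <- on_chrom[which.min(abs(map$pos[on_chrom] - q$position))]
    Dm <- dosage[, mk, , drop = TRUE]
    dim(Dm) <- c(n, K)
    for (p in q$phenotypes) {
      g <- Dm %*% effects[[qi]][[p]]
      sg <- stats::sd(g)
      if (sg > 0) {
        vals[, p] <- vals[, p] + g * sqrt(q$variance_fraction[[p]]) / sg
      } else {
        warning("QTL on ", q$chrom, " at ", q$position,
                " has constant dosage; no effect simulated")
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        phenotype = p, chrom = q$chrom, pos = q$position,
        marker = map$marker[mk], marker_pos = map$pos[mk],
        variance_fraction = q$variance_fraction,
        n_phenotypes_sharing = length(q$phenotypes)
      )
    }
  }
  fr <- qtl_fractions_by_phenotype(config)
  Dflat <- matrix(aperm(dosage, c(1, 3, 2)), nrow = n)  # n x (K*M)
  for (p in phenos) {
    if (config$polygenic_h2 > 0) {
      b <- stats::rnorm(K * M)
      gp <- Dflat %*% b
      sgp <- stats::sd(gp)
      if (sgp > 0) {
        vals[, p] <- vals[, p] + gp * sqrt(config$polygenic_h2) / sgp
      }
    }
    fr_p <- if (p %in% names(fr)) fr[[p]] else 0
    nv <- config$noise_var %||% max(1 - fr_p - config$polygenic_h2, 0)
    if (nv > 0) vals[, p] <- vals[, p] + stats::rnorm(n, sd = sqrt(nv))
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(vals)) < config$missing_rate
    vals[miss] <- NA_real_
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(
    tibble::tibble(individual = as.integer(dimnames(dosage)[[1]] %||%
                                             seq_len(n))), out)
  truth <- dplyr::bind_rows(truth)
  ts <- trait_sets %||%
    tibble::tibble(phenotype = phenos, trait_set = phenos)
  structure(out, class = c("hs_pheno", class(out)),
            trait_sets = ts, truth = truth)
}

#' Simulate a full synthetic HS study
#'
#' Convenience wrapper: mosaics, marker map, dosage tensor and phenotype
#' table in one call, all driven by the seed in `config`.
#'
#' @inheritParams simulate_phenotypes
#' @param config an [hs_config()] object.
#' @return list of class `hs_study` with elements `config`, `map`,
#'   `mosaics`, `dosage`, `phenotypes`.
#' @export
simulate_hs_study <- function(config, trait_sets = NULL) {
  map <- make_marker_map(config)
  mosaics <- simulate_mosaics(config)
  dosage <- mosaics_to_dosage(mosaics, map)
  phenotypes <- simulate_phenotypes(dosage, config, trait_sets = trait_sets)
  structure(list(config = config, map = map, mosaics = mosaics,
                 dosage = dosage, phenotypes = phenotypes),
            class = "hs_study")
}

#' Simulate an inbred strain panel
#'
#' Two panel kinds mirror the replication designs used alongside an HS
#' study: a progenitor panel (the eight founder strains, several replicate
#' animals each, sharing the HS architecture's strain-level genetic
#' values) and a recombinant-inbred panel (fully homozygous mosaic lines
#' derived from two founders, one value per line).
#'
#' @param config an [hs_config()] object (its `qtl_spec` defines the
#'   genetic values).
#' @param panel_kind `"progenitor"` or `"recombinant_inbred"`.
#' @param replicates animals per progenitor strain (default 5).
#' @param n_lines number of recombinant-inbred lines (default 30).
#' @param ri_founders the two founder indices an RI panel descends from
#'   (default 5 and 7, the classic B6 x DBA/2 pairing).
#' @param within_strain_sd residual SD among replicate animals of one
#'   strain (default `sqrt(1 - h2)` where h2 is the architecture's total
#'   genetic fraction).
#' @return tibble of class `hs_panel`: columns `strain` (or `line`),
#'   `animal`, one column per phenotype.  For RI panels the line dosage
#'   tensor is attached as attribute `dosage`.
#' @export
simulate_strain_panel <- function(config,
                                  panel_kind = c("progenitor",
                                                 "recombinant_inbred"),
                                  replicates = 5,
                                  n_lines = 30,
                                  ri_founders = c(5, 7),
                                  within_strain_sd = NULL) {
  panel_kind <- match.arg(panel_kind)
  validate_qtl_spec(config)
  K <- config$n_founders
  effects <- qtl_effect_vectors(config)
  with_stage_seed(config$seed, "panel")
  phenos <- unique(unlist(lapply(config$qtl_spec, `[[`, "phenotypes")))
  fr <- qtl_fractions_by_phenotype(config)

  if (panel_kind == "progenitor") {
    # strain s is homozygous for founder s: dosage 2 at its own founder
    vals <- matrix(0, K, length(phenos), dimnames = list(NULL, phenos))
    for (qi in seq_along(config$qtl_spec)) {
      q <- config$qtl_spec[[qi]]
      for (p in q$phenotypes) {
        g <- 2 * effects[[qi]][[p]]
        sg <- stats::sd(g)
        if (sg > 0) vals[, p] <- vals[, p] + g * sqrt(q$variance_fraction[[p]]) / sg
      }
    }
    out <- list()
    for (p in phenos) {
      h2 <- min(fr[[p]] + config$polygenic_h2, 0.99)
      sdw <- within_strain_sd %||% sqrt(1 - h2)
      strain_val <- vals[, p]
      if (config$polygenic_h2 > 0) {
        poly <- stats::rnorm(K)
        strain_val <- strain_val +
          sqrt(config$polygenic_h2) * poly / stats::sd(poly)
      }
      out[[p]] <- rep(strain_val, each = replicates) +
        stats::rnorm(K * replicates, sd = sdw)
    }
    res <- dplyr::bind_cols(
      tibble::tibble(
        strain = rep(config$founder_names, each = replicates),
        animal = rep(seq_len(replicates), times = K)),
      tibble::as_tibble(out))
    return(structure(res, class = c("hs_panel", class(res)),
                     panel_kind = "progenitor"))
  }

  # recombinant-inbred: one homozygous mosaic track per line, two founders
  ri_cfg <- config
  ri_cfg$n_individuals <- as.integer(n_lines)
  ri_cfg$seed <- NULL  # stream already positioned
  mos <- simulate_mosaics(ri_cfg)
  # restrict founders to the two RI progenitors, duplicate onto both tracks
  mos$founder <- ri_founders[1 + (mos$founder %% 2)]
  mos <- dplyr::filter(mos, .data$track == 1)
  mos2 <- dplyr::mutate(mos, track = 2L)
  mos <- structure(dplyr::bind_rows(mos, mos2),
                   class = c("hs_mosaic", class(mos)),
                   chromosomes = config$chromosomes, n_founders = K)
  map <- make_marker_map(config)
  D <- mosaics_to_dosage(mos, map)
  vals <- matrix(0, n_lines, length(phenos), dimnames = list(NULL, phenos))
  for (qi in seq_along(config$qtl_spec)) {
    q <- config$qtl_spec[[qi]]
    on_chrom <- which(map$chrom == q$chrom)
    mk <- on_chrom[which.min(abs(map$pos[on_chrom] - q$position))]
    Dm <- matrix(D[, mk, ], ncol = K)
    for (p in q$phenotypes) {
      g <- Dm %*% effects[[qi]][[p]]
      sg <- stats::sd(g)
      if (sg > 0) vals[, p] <- vals[, p] + g * sqrt(q$variance_fraction[[p]]) / sg
    }
  }
  for (p in phenos) {
    h2 <- min(fr[[p]] + config$polygenic_h2, 0.99)
    sdw <- within_strain_sd %||% sqrt(1 - h2)
    vals[, p] <- vals[, p] + stats::rnorm(n_lines, sd = sdw)
  }
  res <- dplyr::bind_cols(
    tibble::tibble(line = sprintf("RI%02d", seq_len(n_lines)),
                   animal = 1L),
    tibble::as_tibble(as.data.frame(vals)))
  structure(res, class = c("hs_panel", class(res)),
            panel_kind = "recombinant_inbred", dosage = D)
}
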