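#' Simulation configuration for a synthetic heterogeneous stock
#'
#' Defines the study conditions for the synthetic HS population: sample
#' size, number of intercross generations (which sets the density of
#' ancestral recombination breakpoints), the genome, marker spacing, and
#' the QTL architecture.
#'
#' The breakpoint process is memoryless: inter-breakpoint distances on each
#' haplotype track are exponential with mean `100 / generations` cM,
#' converted to Mb at `cm_per_mb` (default 0.5 cM/Mb), so 50 generations
#' give a mean founder-segment length of 4 Mb.  Founder identity at each
#' segment is drawn uniformly from the eight founders.
#'
#' @param n_individuals number of outbred individuals (default 700, the
#'   scale of an HS mapping population).
#' @param generations number of intercross generations since the founding
#'   of the stock; acts as a breakpoint-density proxy (default 50).
#' @param chromosomes tibble with columns `chrom` (character) and `length`
#'   (Mb), or a named numeric vector of lengths.
#' @param marker_spacing marker grid spacing in Mb (default 1).
#' @param cm_per_mb genome-wide genetic-to-physical conversion (default 0.5).
#' @param qtl_spec list of QTL specifications from [hs_qtl()].
#' @param effect_correlation correlation between the founder-effect vectors
#'   of two phenotypes at a shared locus (default 0.9).
#' @param polygenic_h2 fraction of phenotypic variance from a diffuse
#'   polygenic background spread over all markers (default 0.1).
#' @param noise_var residual environmental variance; `NULL` (default) sets
#'   it per phenotype so the total variance is 1.
#' @param missing_rate fraction of phenotype values set missing at random
#'   (default 0).
#' @param null_phenotypes names of phenotypes with no QTLs (polygenic
#'   background plus noise only; pure noise when `polygenic_h2 = 0`).
#' @param n_founders number of founder strains (default 8).
#' @param founder_names character vector of founder strain names.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#'
#' @return an object of class `hs_config` (a list).
#' @export
#' @examples
#' cfg <- hs_config(n_individuals = 50, chromosomes = c(`1` = 100),
#'                  qtl_spec = list(hs_qtl("1", 50, 0.05, "trait")),
#'                  seed = 1)
hs_config <- function(n_individuals = 700,
                      generations = 50,
                      chromosomes = c(`1` = 100, `2` = 100, `3` = 100,
                                      `4` = 100, `5` = 100),
                      marker_spacing = 1,
                      cm_per_mb = 0.5,
                      qtl_spec = list(),
                      effect_correlation = 0.9,
                      polygenic_h2 = 0.1,
                      noise_var = NULL,
                      missing_rate = 0,
                      null_phenotypes = character(0),
                      n_founders = 8,
                      founder_names = NULL,
                      seed = NULL) {
  if (is.numeric(chromosomes)) {
    chromosomes <- tibble::tibble(
      chrom = names(chromosomes) %||% as.character(seq_along(chromosomes)),
      length = unname(chromosomes)
    )
  }
  chromosomes <- tibble::as_tibble(chromosomes)
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (marker_spacing <= 0) stop("marker_spacing must be positive", call. = FALSE)
  if (generations <= 0) stop("generations must be positive", call. = FALSE)
  if (n_individuals < 0) stop("n_individuals must be non-negative", call. = FALSE)
  if (polygenic_h2 < 0 || polygenic_h2 >= 1) {
    stop("polygenic_h2 must be in [0, 1)", call. = FALSE)
  }
  founder_names <- founder_names %||%
    c("AJ", "AKR", "BALBc", "C3H", "B6", "CBA", "DBA2", "LP")[seq_len(n_founders)]
  if (length(founder_names) != n_founders) {
    founder_names <- paste0("F", seq_len(n_founders))
  }

  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    generations = generations,
    chromosomes = chromosomes,
    marker_spacing = marker_spacing,
    cm_per_mb = cm_per_mb,
    qtl_spec = qtl_spec,
    effect_correlation = effect_correlation,
    polygenic_h2 = polygenic_h2,
    noise_var = noise_var,
    missing_rate = missing_rate,
    null_phenotypes = null_phenotypes,
    n_founders = as.integer(n_founders),
    founder_names = founder_names,
    seed = seed
  ), class = "hs_config")
  validate_qtl_spec(cfg)
  cfg
}

#' Specify one simulated QTL
#'
#' @param chrom chromosome name (character).
#' @param position position in Mb.
#' @param variance_fraction fraction of phenotypic variance explained by
#'   this locus, in (0, 1); either a single value for all phenotypes
#'   sharing the locus or one value per phenotype (a shared locus may be
#'   strong in one trait and weak in another).
#' @param phenotypes character vector of phenotype names influenced by the
#'   locus; more than one name makes it a shared (pleiotropic) locus, whose
#'   per-phenotype founder-effect vectors are correlated at the level set
#'   by `effect_correlation` in [hs_config()].
#' @param founder_effects optional base 8-vector of founder effects; drawn
#'   standard normal when `NULL`.
#' @return a `qtl_spec` list.
#' @export
hs_qtl <- function(chrom, position, variance_fraction, phenotypes,
                   founder_effects = NULL) {
  phenotypes <- as.character(phenotypes)
  if (any(variance_fraction <= 0) || any(variance_fraction >= 1)) {
    stop("variance_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!length(variance_fraction) %in% c(1L, length(phenotypes))) {
    stop("variance_fraction must have length 1 or one value per phenotype",
         call. = FALSE)
  }
  vf <- rep_len(variance_fraction, length(phenotypes))
  names(vf) <- phenotypes
  structure(list(
    chrom = as.character(chrom),
    position = position,
    variance_fraction = vf,
    phenotypes = phenotypes,
    founder_effects = founder_effects
  ), class = "qtl_spec")
}

validate_qtl_spec <- function(config) {
  for (q in config$qtl_spec) {
    len <- config$chromosomes$length[match(q$chrom, config$chromosomes$chrom)]
    if (is.na(len)) {
      stop("QTL chromosome '", q$chrom, "' not in the genome", call. = FALSE)
    }
    if (q$position < 0 || q$position >= len) {
      stop("QTL position ", q$position, " outside chromosome ", q$chrom,
           call. = FALSE)
    }
  }
  fr <- qtl_fractions_by_phenotype(config)
  bad <- names(fr)[fr + config$polygenic_h2 >= 1]
  if (length(bad)) {
    stop("QTL variance fractions + polygenic_h2 reach 1 for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

qtl_fractions_by_phenotype <- function(config) {
  ph <- unique(unlist(lapply(config$qtl_spec, `[[`, "phenotypes")))
  out <- stats::setNames(numeric(length(ph)), ph)
  for (q in config$qtl_spec) {
    out[q$phenotypes] <- out[q$phenotypes] + q$variance_fraction[q$phenotypes]
  }
  out
}

#' Default two-focal-phenotype QTL architecture
#'
#' Builds the package's reference architecture: two focal phenotypes
#' (hippocampal proliferation, `ki67`, and the T-cell subset measure,
#' `cd8_in_cd3`) share five loci, one per chromosome; `ki67` carries four
#' private loci, `cd8_in_cd3` eight private loci of which one is a
#' large-effect (15% variance) major-histocompatibility analogue that is
#' completely absent from `ki67`.  Additional phenotypes each get three
#' private loci, giving a phenome of `n_phenotypes` traits grouped into
#' trait sets.
#'
#' @param n_phenotypes total number of phenotypes (default 16; minimum 2).
#' @param shared_fraction variance fraction of each shared locus (default
#'   0.04).
#' @param private_fraction variance fraction of ordinary private loci
#'   (default 0.03).
#' @param major_fraction variance fraction of the large-effect locus
#'   private to `cd8_in_cd3` (default 0.15).
#' @param other_loci `"fixed"` for deterministic positions of the
#'   non-focal phenotypes' loci, `"random"` to draw them uniformly (uses
#'   the current RNG stream).
#' @param chromosomes tibble (`chrom`, `length`) of the genome the
#'   architecture is laid onto; the canonical layout (five 100 Mb
#'   chromosomes) is rescaled and wrapped onto it.
#' @return list with elements `qtl_spec` (for [hs_config()]) and
#'   `trait_sets` (tibble mapping phenotype to trait set).
#' @export
default_architecture <- function(n_phenotypes = 16,
                                 shared_fraction = 0.04,
                                 private_fraction = 0.03,
                                 major_fraction = 0.15,
                                 other_loci = c("fixed", "random"),
                                 chromosomes = NULL) {
  other_loci <- match.arg(other_loci)
  stopifnot(n_phenotypes >= 2)
  chroms <- as.character(1:5)
  spec <- list()
  # five shared loci, one per chromosome (echoing shared QTLs on five
  # chromosomes between the focal traits)
  shared_pos <- c(25, 45, 65, 30, 55)
  for (i in 1:5) {
    spec <- c(spec, list(hs_qtl(chroms[i], shared_pos[i], shared_fraction,
                                c("ki67", "cd8_in_cd3"))))
  }
  # ki67-private loci
  ki67_pos <- list(c("1", 80), c("2", 10), c("3", 90), c("4", 70))
  for (p in ki67_pos) {
    spec <- c(spec, list(hs_qtl(p[1], as.numeric(p[2]), private_fraction,
                                "ki67")))
  }
  # cd8-private loci, incl. one major-effect MHC analogue
  cd8_pos <- list(c("1", 55), c("2", 65), c("2", 90), c("3", 15),
                  c("4", 5), c("4", 92), c("5", 10))
  for (p in cd8_pos) {
    spec <- c(spec, list(hs_qtl(p[1], as.numeric(p[2]), private_fraction,
                                "cd8_in_cd3")))
  }
  spec <- c(spec, list(hs_qtl("5", 85, major_fraction, "cd8_in_cd3")))

  other <- character(0)
  if (n_phenotypes > 2) {
    other <- sprintf("pheno%02d", seq_len(n_phenotypes - 2) + 2)
    for (k in seq_along(other)) {
      for (j in 1:3) {
        if (other_loci == "random") {
          ch <- sample(chroms, 1)
          pos <- stats::runif(1, 0, 100)
        } else {
          # deterministic spread over the genome
          ch <- chroms[((k + j) %% 5) + 1]
          pos <- ((k * 17 + j * 37) %% 95) + 2.5
        }
        spec <- c(spec, list(hs_qtl(ch, pos, private_fraction, other[k])))
      }
    }
  }
  set_names <- c("hippocampal function", "T cell",
                 rep(c("anxiety", "activity", "startle", "metabolism",
                       "immunology", "haematology", "biochemistry",
                       "anatomy"), length.out = length(other)))
  trait_sets <- tibble::tibble(
    phenotype = c("ki67", "cd8_in_cd3", other),
    trait_set = set_names[seq_len(n_phenotypes)]
  )
  if (!is.null(chromosomes)) {
    chromosomes <- tibble::as_tibble(chromosomes)
    nc <- nrow(chromosomes)
    spec <- lapply(spec, function(q) {
      i <- match(q$chrom, chroms)
      j <- (i - 1) %% nc + 1
      q$chrom <- as.character(chromosomes$chrom[j])
      q$position <- q$position / 100 * chromosomes$length[j]
      q
    })
  }
  list(qtl_spec = spec, trait_sets = trait_sets)
}

#' @export
print.hs_config <- function(x, ...) {
  cat("<hs_config>\n")
  cat("  individuals:", x$n_individuals,
      "| generations:", x$generations,
      "| founders:", x$n_founders, "\n")
  cat("  genome:", nrow(x$chromosomes), "chromosomes,",
      sum(x$chromosomes$length), "Mb; markers every",
      x$marker_spacing, "Mb\n")
  cat("  QTLs:", length(x$qtl_spec),
      "| polygenic h2:", x$polygenic_h2, "\n")
  invisible(x)
}
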