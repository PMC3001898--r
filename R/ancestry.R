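#' Simulate a biallelic founder haplotype panel
#'
#' Draws a 0/1 allele for each founder at each marker, i.i.d. with allele
#' frequency `p1`.  Used to generate genotype data whose founder ancestry
#' the HMM must reconstruct.
#'
#' @param marker_map tibble with `marker`, `chrom`, `pos`.
#' @param n_founders number of founder strains (default 8).
#' @param p1 probability of the "1" allele (default 0.5).
#' @param founder_names optional founder names.
#' @return a `founder_panel`: integer matrix markers x founders with the
#'   map attached as attribute `map`.
#' @export
simulate_founder_panel <- function(marker_map, n_founders = 8, p1 = 0.5,
                                   founder_names = NULL) {
  M <- nrow(marker_map)
  H <- matrix(stats::rbinom(M * n_founders, 1, p1), M, n_founders)
  rownames(H) <- marker_map$marker
  colnames(H) <- founder_names %||% paste0("F", seq_len(n_founders))
  structure(H, class = "founder_panel", map = marker_map)
}

#' Genotypes implied by founder mosaics
#'
#' Reads each individual's biallelic genotype (0/1/2 allele count) off its
#' founder mosaic and the founder haplotype panel, optionally flipping
#' each allele with probability `error_rate`.
#'
#' @param mosaics an `hs_mosaic`.
#' @param founder_panel a `founder_panel`.
#' @param error_rate per-allele genotyping error probability (default 0).
#' @return integer matrix individuals x markers of allele counts.
#' @export
mosaic_genotypes <- function(mosaics, founder_panel, error_rate = 0) {
  map <- attr(founder_panel, "map")
  D <- mosaics_to_dosage(mosaics, map)
  n <- dim(D)[1]; M <- dim(D)[2]; K <- dim(D)[3]
  G <- matrix(0L, n, M, dimnames = list(dimnames(D)[[1]], map$marker))
  for (f in seq_len(K)) {
    G <- G + matrix(D[, , f], n, M) * rep(founder_panel[, f], each = n)
  }
  G <- round(G)
  if (error_rate > 0) {
    # flip each of the two allele reads independently
    for (read in 1:2) {
      flip <- matrix(stats::runif(n * M) < error_rate, n, M)
      has1 <- G >= read  # whether this read was a "1"
      G <- G + ifelse(flip, ifelse(has1, -1L, 1L), 0L)
      G <- pmin(pmax(G, 0L), 2L)
    }
  }
  storage.mode(G) <- "integer"
  G
}

# Genotype emission probabilities.  Each of the two allele reads is
# correct with probability 1-eps.  Returns a 3 x 3 matrix
# P(observed count | true count).
genotype_emission <- function(eps) {
  p <- matrix(0, 3, 3)
  for (true in 0:2) {
    # true count = number of "1" alleles; each read flips independently
    for (obs in 0:2) {
      pr <- 0
      for (flips1 in 0:true) {           # 1-alleles read as 0
        flips0 <- obs - (true - flips1)  # 0-alleles read as 1
        if (flips0 < 0 || flips0 > 2 - true) next
        pr <- pr + choose(true, flips1) * eps^flips1 * (1 - eps)^(true - flips1) *
          choose(2 - true, flips0) * eps^flips0 * (1 - eps)^(2 - true - flips0)
      }
      p[obs + 1, true + 1] <- pr
    }
  }
  p
}

#' Reconstruct expected founder dosages from genotypes
#'
#' Runs a forward-backward pass over founder-pair hidden states, per
#' individual and chromosome.  Each haplotype track switches ancestry
#' between adjacent markers with probability `1 - exp(-switch_rate * d)`
#' over distance `d` Mb, landing uniformly on any founder; genotype
#' emissions use a symmetric per-allele error `error_rate`.  The expected
#' dosage of founder f at a marker is the posterior probability mass of
#' states carrying f, counted with multiplicity, so rows sum to 2.
#'
#' @param genotypes integer matrix individuals x markers (0/1/2).
#' @param founder_panel a `founder_panel` on the same markers.
#' @param marker_map tibble with `marker`, `chrom`, `pos`; positions must
#'   be strictly increasing within chromosome.
#' @param switch_rate ancestry transitions per Mb per track.  Default
#'   matches the simulator's breakpoint density for 50 generations at
#'   0.5 cM/Mb (1/4 per Mb).
#' @param error_rate symmetric genotyping error (default 0.01).
#' @param chromosomes optional tibble(`chrom`, `length`) attached to the
#'   result.
#' @return a `dosage_tensor` (individuals x markers x founders).
#' @export
infer_dosages <- function(genotypes, founder_panel, marker_map,
                          switch_rate = 0.25, error_rate = 0.01,
                          chromosomes = NULL) {
  stopifnot(switch_rate > 0, error_rate >= 0, error_rate < 1)
  n <- nrow(genotypes)
  M <- nrow(marker_map)
  stopifnot(ncol(genotypes) == M, nrow(founder_panel) == M)
  K <- ncol(founder_panel)
  emis <- genotype_emission(error_rate)
  D <- array(0, dim = c(n, M, K),
             dimnames = list(individual = rownames(genotypes),
                             marker = marker_map$marker, founder = NULL))
  for (chrom in unique(marker_map$chrom)) {
    cols <- which(marker_map$chrom == chrom)
    pos <- marker_map$pos[cols]
    if (any(diff(pos) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome",
           call. = FALSE)
    }
    # per-step, per-state-pair emission likelihood lookup:
    # true genotype of state (a,b) at marker m is H[m,a] + H[m,b]
    H <- founder_panel[cols, , drop = FALSE]
    d <- diff(pos)
    s <- 1 - exp(-switch_rate * d)
    for (ind in seq_len(n)) {
      g <- genotypes[ind, cols]
      post <- pair_forward_backward(g, H, s, emis, K)
      if (is.null(post)) {
        stop("genotype incompatible with all ancestry states ",
             "(individual ", ind, ", chromosome ", chrom,
             ") with error rate 0", call. = FALSE)
      }
      # dosage: multiplicity of founder f over ordered pairs
      for (m in seq_along(cols)) {
        P <- post[, , m]
        D[ind, cols[m], ] <- rowSums(P) + colSums(P)
      }
    }
  }
  structure(D, class = "dosage_tensor", map = marker_map,
            chromosomes = chromosomes %||% attr(founder_panel, "chromosomes"))
}

# Forward-backward over ordered founder pairs, represented as K x K
# matrices.  Transitions factorise per track:  A' = t(T) %*% A %*% T with
# T = (1-s) I + (s/K) J.  Applying T to a vector v is
# (1-s) v + (s/K) sum(v), done row- and column-wise.
pair_forward_backward <- function(g, H, s, emis, K) {
  Tm <- length(g)
  miss <- is.na(g)
  Emat <- function(m) {
    if (miss[m]) return(matrix(1, K, K))
    tg <- outer(H[m, ], H[m, ], `+`)       # true genotype per state
    matrix(emis[g[m] + 1, tg + 1], K, K)
  }
  apply_T <- function(A, sm) {
    # one-track transition applied to rows then columns
    A1 <- (1 - sm) * A + (sm / K) * matrix(colSums(A), K, K, byrow = TRUE)
    (1 - sm) * A1 + (sm / K) * matrix(rowSums(A1), K, K)
  }
  alpha <- array(0, c(K, K, Tm))
  scale <- numeric(Tm)
  A <- matrix(1 / K^2, K, K) * Emat(1)
  scale[1] <- sum(A)
  if (scale[1] == 0) return(NULL)
  alpha[, , 1] <- A / scale[1]
  for (m in seq_len(Tm)[-1]) {
    A <- apply_T(alpha[, , m - 1], s[m - 1]) * Emat(m)
    scale[m] <- sum(A)
    if (scale[m] == 0) return(NULL)
    alpha[, , m] <- A / scale[m]
  }
  beta <- matrix(1, K, K)
  post <- array(0, c(K, K, Tm))
  post[, , Tm] <- alpha[, , Tm]
  if (Tm > 1) {
    for (m in rev(seq_len(Tm - 1))) {
      # T is symmetric, so the backward recursion reuses apply_T;
      # rescale by the forward scale factors to avoid underflow
      beta <- apply_T(beta * Emat(m + 1), s[m]) / scale[m + 1]
      P <- alpha[, , m] * beta
      post[, , m] <- P / sum(P)
    }
  }
  post
}
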