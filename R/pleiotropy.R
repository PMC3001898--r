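#' Total merged length of a QTL interval set
#'
#' Sums interval lengths per phenotype after merging any within-phenotype
#' overlaps (and abutments) on the same chromosome.  Intervals are
#' half-open `[start, end)` in Mb.
#'
#' @param qtls tibble with columns `chrom`, `start`/`end` (or
#'   `ci_start`/`ci_end`) and optionally `phenotype`.
#' @return tibble with `phenotype` (if present) and `total_mb`.
#' @export
qtl_total_length <- function(qtls) {
  if ("phenotype" %in% names(qtls)) {
    qtls |>
      dplyr::group_by(.data$phenotype) |>
      dplyr::group_modify(~ tibble::tibble(total_mb = total_length_one(.x))) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(total_mb = total_length_one(qtls))
  }
}

total_length_one <- function(df) {
  if (nrow(df) == 0) return(0)
  m <- merge_by_chrom(df)
  sum(m$end - m$start)
}

#' Overlap length between two QTL interval sets
#'
#' Intersects the merged interval unions of two phenotypes' QTL sets,
#' chromosome by chromosome (half-open arithmetic).
#'
#' @param a,b interval tibbles (`chrom` + `start`/`end` or
#'   `ci_start`/`ci_end`).
#' @return tibble with one row per chromosome with nonzero overlap:
#'   `chrom`, `overlap_mb`; total overlap is `sum(overlap_mb)`.
#' @export
qtl_overlap_length <- function(a, b) {
  ma <- merge_by_chrom(a)
  mb <- merge_by_chrom(b)
  shared <- intersect(unique(ma$chrom), unique(mb$chrom))
  out <- purrr::map_dfr(shared, function(ch) {
    ia <- ma[ma$chrom == ch, c("start", "end")]
    ib <- mb[mb$chrom == ch, c("start", "end")]
    ov <- intersect_intervals(ia, ib)
    tibble::tibble(chrom = ch, overlap_mb = sum(ov$end - ov$start))
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(0), overlap_mb = numeric(0)))
  }
  out[out$overlap_mb > 0, , drop = FALSE]
}

#' Sorensen similarity between two QTL interval sets
#'
#' Length-based Sorensen coefficient
#' `S = 2 |A intersect B| / (|A| + |B|)` with `|.|` the merged total
#' megabase length of a set (the count-based variant, using numbers of
#' overlapping merged intervals, is available with `method = "count"`).
#' Two empty sets are maximally distant (`S = 0`, with a warning), so
#' phenotypes with no detected QTLs do not silently collapse the tree.
#'
#' @inheritParams qtl_overlap_length
#' @param method `"length"` (default) or `"count"`.
#' @return a number in `[0, 1]`.
#' @export
sorensen <- function(a, b, method = c("length", "count")) {
  method <- match.arg(method)
  ma <- merge_by_chrom(a)
  mb <- merge_by_chrom(b)
  if (method == "length") {
    ta <- sum(ma$end - ma$start)
    tb <- sum(mb$end - mb$start)
    if (ta + tb == 0) {
      warning("both QTL sets empty; Sorensen similarity set to 0")
      return(0)
    }
    ov <- qtl_overlap_length(ma, mb)
    return(2 * sum(ov$overlap_mb) / (ta + tb))
  }
  # count-based: overlapping merged-interval pairs
  na <- nrow(ma)
  nb <- nrow(mb)
  if (na + nb == 0) {
    warning("both QTL sets empty; Sorensen similarity set to 0")
    return(0)
  }
  hits_a <- sum(vapply(seq_len(na), function(i) {
    any(mb$chrom == ma$chrom[i] & mb$start < ma$end[i] &
          mb$end > ma$start[i])
  }, logical(1)))
  hits_b <- sum(vapply(seq_len(nb), function(i) {
    any(ma$chrom == mb$chrom[i] & ma$start < mb$end[i] &
          ma$end > mb$start[i])
  }, logical(1)))
  (hits_a + hits_b) / (na + nb)
}

#' Pairwise Sorensen similarity matrix
#'
#' @param qtls tibble of QTL intervals for several phenotypes (must have
#'   a `phenotype` column).
#' @param method passed to [sorensen()].
#' @param phenotypes optional character vector fixing the row order and
#'   including phenotypes with no intervals (similarity 0 to everything).
#' @return symmetric matrix of class `hs_simmat` with values in `[0, 1]`;
#'   diagonal is 1 for phenotypes with at least one interval.
#' @export
similarity_matrix <- function(qtls, method = c("length", "count"),
                              phenotypes = NULL) {
  method <- match.arg(method)
  ph <- phenotypes %||% unique(qtls$phenotype)
  S <- matrix(0, length(ph), length(ph), dimnames = list(ph, ph))
  sets <- lapply(ph, function(p) qtls[qtls$phenotype == p, , drop = FALSE])
  for (i in seq_along(ph)) {
    for (j in seq_len(i)) {
      S[i, j] <- S[j, i] <- suppressWarnings(
        sorensen(sets[[i]], sets[[j]], method = method))
    }
  }
  structure(S, class = c("hs_simmat", "matrix"), method = method)
}

#' Merge QTL sets into trait sets
#'
#' Replaces per-phenotype QTL sets by the merged union of intervals over
#' all member phenotypes of each trait set.
#'
#' @param qtls tibble of QTL intervals with a `phenotype` column.
#' @param trait_sets tibble with columns `phenotype`, `trait_set`
#'   labelling every phenotype present in `qtls`.
#' @return tibble with columns `phenotype` (the trait-set label),
#'   `chrom`, `ci_start`, `ci_end`.
#' @export
group_trait_sets <- function(qtls, trait_sets) {
  missing_lab <- setdiff(unique(qtls$phenotype), trait_sets$phenotype)
  if (length(missing_lab)) {
    stop("unlabelled phenotypes: ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  }
  qtls |>
    interval_cols() |>
    dplyr::inner_join(trait_sets, by = "phenotype") |>
    dplyr::group_by(phenotype = .data$trait_set, .data$chrom) |>
    dplyr::group_modify(~ merge_intervals(
      tibble::tibble(start = .x$.start, end = .x$.end))) |>
    dplyr::ungroup() |>
    dplyr::rename(ci_start = "start", ci_end = "end")
}

#' Agglomerative phenotype tree from a similarity matrix
#'
#' Clusters phenotypes on the distance `d = 1 - S` (not a metric; no
#' metricity is assumed by the agglomeration) and returns a rooted tree
#' with cophenetic branch lengths.
#'
#' @param similarity an `hs_simmat` (or plain symmetric matrix in
#'   `[0, 1]`).
#' @param linkage agglomeration method for [stats::hclust()]; default
#'   `"average"` (UPGMA).
#' @return an [ape::as.phylo()] tree of class `phylo`, with attributes
#'   `linkage` and `hclust`.
#' @export
cluster_tree <- function(similarity, linkage = "average") {
  S <- unclass(similarity)
  if (any(is.na(S))) stop("similarity matrix contains NA", call. = FALSE)
  stopifnot(isSymmetric(unname(S)), all(S >= 0 - 1e-12), all(S <= 1 + 1e-12))
  d <- stats::as.dist(1 - S)
  hc <- stats::hclust(d, method = linkage)
  tr <- ape::as.phylo(hc)
  attr(tr, "linkage") <- linkage
  attr(tr, "hclust") <- hc
  tr
}

#' Write a phenotype tree as Newick
#'
#' @param tree a `phylo` tree from [cluster_tree()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pheno_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
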