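test_that("published interval sets give the known totals and overlaps", {
  q <- hs_published_qtls()
  tot <- qtl_total_length(q)
  expect_equal(tot$total_mb[tot$phenotype == "ki67"], 46.1, tolerance = 1e-9)
  expect_equal(tot$total_mb[tot$phenotype == "cd8_in_cd3"], 39.9,
               tolerance = 1e-9)

  a <- q[q$phenotype == "ki67", ]
  b <- q[q$phenotype == "cd8_in_cd3", ]
  ov <- qtl_overlap_length(a, b)
  expect_setequal(ov$chrom, c("5", "6", "10", "13", "16"))
  expect_equal(ov$overlap_mb[ov$chrom == "5"], 5.6, tolerance = 1e-9)
  expect_equal(sum(ov$overlap_mb), 15.0, tolerance = 1e-9)

  s <- sorensen(a, b)
  expect_equal(s, 2 * 15.0 / (46.1 + 39.9), tolerance = 1e-9)
})

test_that("sorensen identities: self-similarity 1, disjoint 0, empty 0", {
  a <- tibble::tibble(chrom = "1", start = c(10, 30), end = c(20, 35))
  b <- tibble::tibble(chrom = "1", start = 50, end = 60)
  e <- tibble::tibble(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  expect_equal(sorensen(a, a), 1)
  expect_equal(sorensen(a, b), 0)
  expect_warning(s0 <- sorensen(e, e), "empty")
  expect_equal(s0, 0)
  expect_equal(qtl_total_length(e)$total_mb, 0)
  expect_equal(sorensen(a, a, method = "count"), 1)
  expect_equal(sorensen(a, b, method = "count"), 0)
})

test_that("sorensen matches the 0.1 Mb rasterised oracle and is symmetric", {
  set.seed(42)
  for (i in 1:300) {
    a <- random_qtlset(sample(0:6, 1))
    b <- random_qtlset(sample(1:6, 1))
    s_ab <- suppressWarnings(sorensen(a, b))
    s_ba <- suppressWarnings(sorensen(b, a))
    expect_equal(s_ab, s_ba, tolerance = 1e-12)
    expect_equal(s_ab, raster_sorensen(a, b), tolerance = 1e-9)
  }
})

test_that("lengths are invariant under splitting intervals into pieces", {
  set.seed(7)
  a <- random_qtlset(5)
  split_one <- function(df) {
    i <- sample(nrow(df), 1)
    mid <- round(mean(c(df$start[i], df$end[i])), 2)
    if (mid <= df$start[i] || mid >= df$end[i]) return(df)
    dplyr::bind_rows(
      df[-i, ],
      tibble::tibble(chrom = df$chrom[i], start = df$start[i], end = mid),
      tibble::tibble(chrom = df$chrom[i], start = mid, end = df$end[i]))
  }
  a_split <- split_one(split_one(a))
  expect_equal(qtl_total_length(a)$total_mb,
               qtl_total_length(a_split)$total_mb)
  b <- random_qtlset(4)
  expect_equal(sum(qtl_overlap_length(a, b)$overlap_mb),
               sum(qtl_overlap_length(a_split, b)$overlap_mb))
})

test_that("trait-set grouping merges member intervals", {
  q <- tibble::tibble(
    phenotype = c("p1", "p2", "p2", "p3"),
    chrom = c("1", "1", "1", "2"),
    start = c(10, 10, 20, 5),
    end = c(20, 20, 30, 8))
  labs <- tibble::tibble(phenotype = c("p1", "p2", "p3"),
                         trait_set = c("s1", "s1", "s2"))
  g <- group_trait_sets(q, labs)
  s1 <- g[g$phenotype == "s1", ]
  # abutting [10,20) and [20,30) merge to [10,30)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$ci_start, 10)
  expect_equal(s1$ci_end, 30)
  # identical intervals union to either member
  g_ident <- group_trait_sets(q[1:2, ], labs)
  expect_equal(g_ident$ci_start, 10)
  expect_equal(g_ident$ci_end, 20)
  # one phenotype per set is the identity (up to within-set merging)
  labs_id <- tibble::tibble(phenotype = c("p1", "p2", "p3"),
                            trait_set = c("p1", "p2", "p3"))
  g_id <- group_trait_sets(q, labs_id)
  expect_equal(qtl_total_length(g_id)$total_mb,
               qtl_total_length(q)$total_mb)
  expect_error(group_trait_sets(q, labs[-1, ]), "unlabelled")
})

test_that("similarity matrix is symmetric with unit diagonal", {
  set.seed(11)
  q <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(p)
    dplyr::mutate(random_qtlset(4), phenotype = p)))
  S <- similarity_matrix(q)
  expect_true(isSymmetric(unname(unclass(S))))
  expect_equal(unname(diag(unclass(S))), rep(1, 3))
  expect_true(all(unclass(S) >= 0 & unclass(S) <= 1))
  long <- tidy(S)
  expect_equal(nrow(long), 3)
})

test_that("cluster_tree joins the most similar pair first", {
  S <- matrix(c(1, 1, 0,
                1, 1, 0,
                0, 0, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- cluster_tree(S)
  # A and B coalesce at distance 0; cophenetic distance 0 between them
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd["A", "B"], 0)
  expect_gt(cd["A", "C"], 0.5)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})

test_that("tree topology is invariant to input order", {
  set.seed(13)
  q <- dplyr::bind_rows(lapply(letters[1:6], function(p)
    dplyr::mutate(random_qtlset(5), phenotype = p)))
  S1 <- similarity_matrix(q, phenotypes = letters[1:6])
  perm <- c(4, 2, 6, 1, 3, 5)
  S2 <- unclass(S1)[perm, perm]
  t1 <- cluster_tree(S1)
  t2 <- cluster_tree(structure(S2, class = c("hs_simmat", "matrix")))
  expect_equal(ape::cophenetic.phylo(t1)[letters[1:6], letters[1:6]],
               ape::cophenetic.phylo(t2)[letters[1:6], letters[1:6]],
               tolerance = 1e-12)
})

test_that("cluster_tree rejects NA similarities", {
  S <- matrix(c(1, NA, NA, 1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(cluster_tree(S), "NA")
})
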