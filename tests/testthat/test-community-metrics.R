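test_that("CLR transform matches hand-computed values and sums to zero", {
  tab <- make_counts(matrix(c(1L, 1L, 1L, 1L), 1))
  expect_equal(unclass(clr_transform(tab, 1))[1, ], rep(0, 4),
               ignore_attr = TRUE)

  tab2 <- make_counts(matrix(c(8L, 2L), 1))
  v <- unclass(clr_transform(tab2, 1))[1, ]
  expect_equal(unname(v), c(log(9) - log(sqrt(27)), log(3) - log(sqrt(27))),
               tolerance = 1e-12)
  expect_equal(unname(v), c(0.5493, -0.5493), tolerance = 1e-4)

  set.seed(11)
  tab3 <- make_counts(matrix(rpois(60, 20), 6, 10))
  expect_true(all(abs(rowSums(clr_transform(tab3, 1))) < 1e-9))
  expect_error(clr_transform(tab3, 0), class = "parameter_error")
})

test_that("CLR is scale-invariant and agrees with the brute-force oracle", {
  set.seed(7)
  for (i in 1:20) {
    row <- rpois(8, 15)
    expect_equal(unname(unclass(clr_transform(matrix(row, 1), 1))[1, ]),
                 brute_clr(row, 1), tolerance = 1e-10)
    ## scaling composition and pseudocount by a constant leaves CLR fixed
    expect_equal(unclass(clr_transform(matrix(row * 7, 1), 7))[1, ],
                 unclass(clr_transform(matrix(row, 1), 1))[1, ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("richness counts strictly positive taxa", {
  expect_equal(observed_richness(c(0, 5, 2, 0)), 2)
  expect_equal(observed_richness(c(0, 0, 0)), 0)
  expect_equal(observed_richness(c(1, 1, 1)), 3)
})

test_that("Shannon diversity matches closed forms and vegan", {
  expect_equal(shannon_diversity(rep(5, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(0, 9, 0)), 0)
  expect_equal(shannon_diversity(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(3, 1)), 0.5623, tolerance = 1e-4)
  expect_error(shannon_diversity(c(0, 0)),
               class = "undefined_diversity_error")

  ## independent oracle: vegan's Shannon index
  set.seed(3)
  for (i in 1:10) {
    row <- rpois(12, 8)
    if (sum(row) == 0) next
    expect_equal(shannon_diversity(row),
                 unname(vegan::diversity(matrix(row, 1), "shannon")),
                 tolerance = 1e-10)
  }
})

test_that("Aitchison distance matches hand computation and is a metric", {
  a <- unclass(clr_transform(matrix(c(8L, 2L), 1), 1))[1, ]
  b <- unclass(clr_transform(matrix(c(2L, 8L), 1), 1))[1, ]
  expect_equal(aitchison_distance(a, a), 0)
  expect_equal(aitchison_distance(a, b), sqrt(2 * log(3)^2),
               tolerance = 1e-12)
  expect_equal(aitchison_distance(a, b), 1.5537, tolerance = 1e-4)
  expect_error(aitchison_distance(a, c(a, 0)), class = "alignment_error")

  set.seed(21)
  for (i in 1:25) {
    x <- brute_clr(rpois(10, 12)); y <- brute_clr(rpois(10, 12))
    z <- brute_clr(rpois(10, 12))
    ## permutation invariance
    perm <- sample(10)
    expect_equal(aitchison_distance(x[perm], y[perm]),
                 aitchison_distance(x, y), tolerance = 1e-12)
    ## triangle inequality
    expect_lte(aitchison_distance(x, z),
               aitchison_distance(x, y) + aitchison_distance(y, z) + 1e-12)
  }
})

test_that("prevalence filter keeps the >= boundary and never edits counts", {
  set.seed(5)
  m <- matrix(0L, 100, 3)
  m[1:14, 1] <- 1L   # 14% prevalence
  m[1:15, 2] <- 2L   # 15% prevalence
  m[, 3] <- 5L
  tab <- make_counts(m)
  filt <- suppressMessages(prevalence_filter(tab, 0.15))
  expect_identical(colnames(filt$counts), c("g02", "g03"))
  expect_equal(attr(filt, "n_removed"), 1)
  expect_identical(filt$counts, tab$counts[, c("g02", "g03")])

  ident <- suppressMessages(prevalence_filter(tab, 0))
  expect_identical(ident$counts, tab$counts)
  sparse <- make_counts(matrix(c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L), 4))
  expect_warning(suppressMessages(prevalence_filter(sparse, 1)),
                 "every taxon")
})

test_that("PCA ordination reconstructs the centred CLR matrix and orders variance", {
  set.seed(9)
  tab <- make_counts(matrix(rpois(80, 30), 8, 10))
  clr <- clr_transform(tab, 1)
  ord <- pca_ordination(clr, n_components = 8)
  expect_true(all(diff(ord$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(ord$explained_variance_fraction), 1 + 1e-12)
  recon <- ord$scores %*% t(ord$rotation)
  centred <- scale(unclass(clr), center = TRUE, scale = FALSE)
  expect_equal(recon, unclass(centred), tolerance = 1e-8,
               ignore_attr = TRUE)

  ## rank-1 data: one component explains everything
  base <- rpois(10, 20)
  m <- rbind(base, base * 2L, base * 4L, base * 8L)
  rownames(m) <- paste0("S", 1:4)
  clr1 <- clr_transform(make_counts(m, samples = rownames(m)), 1e-9)
  ord1 <- pca_ordination(clr1, 2)
  expect_gt(ord1$explained_variance_fraction[1], 1 - 1e-6)

  ## two identical samples: no variance to explain, equal scores
  two <- make_counts(matrix(c(5L, 1L, 5L, 1L), 2, byrow = TRUE))
  ord2 <- pca_ordination(clr_transform(two, 1), 1)
  expect_equal(ord2$explained_variance_fraction[1], 0)
  expect_equal(ord2$scores[1, ], ord2$scores[2, ])
  expect_error(pca_ordination(clr, 20), class = "parameter_error")
})

test_that("log2 abundance is the documented elementwise transform", {
  tab <- make_counts(matrix(c(0L, 7L, 3L, 1L), 2))
  l2 <- log2_abundance(tab, 1)
  expect_equal(l2[1, 1], 0)
  expect_equal(l2[2, 1], 3)
  expect_true(all(diff(log2_abundance(matrix(0:10, 1), 1)[1, ]) > 0))
})
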