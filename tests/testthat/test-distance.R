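# shared fixture: one fitted OTU and its subject mixtures
fixture_mixtures <- function(I = 40L, seed = 10L) {
  set.seed(seed)
  counts <- simulate_from_mixture(c(0.35, 0.35, 0.3), shapes = c(1, 7),
                                  rates = c(1, 1), I = I)
  t <- runif(I, 0.7, 1.3)
  fit <- fit_otu_mixture(counts, t, B = 3L, seed = seed)
  subject_mixtures(fit)
}

test_that("discrete L2 PDF distance equals the brute-force category sum", {
  sm <- fixture_mixtures()
  D <- as.matrix(l2_discrete_pdf(sm))
  P <- sm$category_pdf
  for (i in c(1L, 5L)) for (j in c(2L, 17L)) {
    expect_equal(D[i, j], sqrt(sum((P[i, ] - P[j, ])^2)), tolerance = 1e-10)
  }
  # quadratic-form route through the shared component matrix
  G <- crossprod(sm$category_matrix)      # P^T P over components
  dw <- sm$posterior[3L, ] - sm$posterior[9L, ]
  expect_equal(D[3L, 9L], sqrt(drop(t(dw) %*% G %*% dw)), tolerance = 1e-10)
  expect_equal(D[4L, 4L], 0)
})

test_that("point masses at z and h sit at the analytic distances", {
  comps <- rbind(comp_row("zero_mass"), comp_row("gamma", 1, 1),
                 comp_row("high_mass"))
  C <- 7L
  fit <- manual_fit(comps, cutoff = C, weights = c(0.5, 0, 0.5),
                    counts = c(0L, 100L), t = c(1, 1))
  sm <- subject_mixtures(fit)
  expect_equal(as.matrix(l2_discrete_pdf(sm))[1L, 2L], sqrt(2),
               tolerance = 1e-12)
  # CDFs differ by one on every category except the last of C+3
  expect_equal(as.matrix(l2_discrete_cdf(sm))[1L, 2L], sqrt(C + 2),
               tolerance = 1e-12)
  # continuous CDFs differ by one on all of [0, C)
  expect_equal(as.matrix(l2_continuous_cdf(sm))[1L, 2L], sqrt(C),
               tolerance = 1e-9)
})

test_that("continuous CDF distance matches a dense quadrature oracle", {
  sm <- fixture_mixtures(I = 12L, seed = 11L)
  D <- as.matrix(l2_continuous_cdf(sm))
  C <- sm$grid$cutoff
  Pc <- apply(sm$category_matrix, 2L, cumsum)
  # dense quadrature over [0, C] with >= 4096 nodes, stratified so every
  # unit interval of the step functions is covered evenly
  per <- ceiling(4096 / C)
  grid_k <- rep(seq_len(C) - 1L, each = per) + (seq_len(per) - 0.5) / per
  Fi <- function(i, k) {
    idx <- pmin(floor(k) + 2L, nrow(Pc))
    as.vector(sm$posterior[i, ] %*% t(Pc))[idx]
  }
  for (pair in list(c(1L, 2L), c(3L, 10L))) {
    f1 <- Fi(pair[1L], grid_k); f2 <- Fi(pair[2L], grid_k)
    oracle <- sqrt(sum((f1 - f2)^2) / per)
    expect_equal(D[pair[1L], pair[2L]], oracle, tolerance = 1e-6)
  }
  # Gram matrix is symmetric PSD
  G <- cdf_gram(sm)
  expect_equal(G, t(G))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * max(abs(G)))
})

test_that("every metric satisfies the distance axioms on a shared fixture", {
  set.seed(12)
  mat <- matrix(rpois(10 * 6, 4), 10, 6,
                dimnames = list(paste0("s", 1:10), paste0("o", 1:6)))
  mat[1, ] <- 0   # a fully empty sample must not break anything
  ra <- suppressWarnings(to_relative_abundance(mat))
  tree <- simulate_tree(paste0("o", 1:6), seed = 12)
  sm <- fixture_mixtures(I = 10L, seed = 12L)
  dms <- list(
    dist_manhattan(ra), dist_euclidean(ra), dist_bray_curtis(ra),
    dist_weighted_unifrac(ra, tree), dist_generalized_unifrac(ra, tree),
    dist_manhattan(log_transform(ra)),
    l2_discrete_pdf(sm), l2_discrete_cdf(sm), l2_continuous_cdf(sm))
  for (dm in dms) {
    D <- as.matrix(dm)
    expect_equal(D, t(D), tolerance = 1e-10)
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    expect_true(all(D >= 0))
  }
})

test_that("Manhattan and Euclidean match a naive double loop", {
  set.seed(13)
  mat <- matrix(runif(8 * 5), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("o", 1:5)))
  DM <- as.matrix(dist_manhattan(mat))
  DE <- as.matrix(dist_euclidean(mat))
  for (i in 1:8) for (j in 1:8) {
    expect_equal(DM[i, j], sum(abs(mat[i, ] - mat[j, ])), tolerance = 1e-12)
    expect_equal(DE[i, j], sqrt(sum((mat[i, ] - mat[j, ])^2)),
                 tolerance = 1e-12)
  }
  expect_equal(as.matrix(dist_manhattan(rbind(a = c(1, 0), b = c(0, 1))))[1, 2], 2)
  expect_equal(as.matrix(dist_euclidean(rbind(a = c(1, 0), b = c(0, 1))))[1, 2],
               sqrt(2))
  # cross-check against vegan on the same data
  expect_equal(unname(DM), unname(as.matrix(vegan::vegdist(mat, "manhattan"))),
               tolerance = 1e-12)
})

test_that("Bray-Curtis handles disjoint, identical and empty pairs", {
  mat <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0), d = c(0, 0), e = c(0, 0))
  D <- as.matrix(dist_bray_curtis(mat))
  expect_equal(D["a", "b"], 2 / (2 + 1e-8))
  expect_equal(D["a", "c"], 0)
  expect_equal(D["d", "e"], 0)   # 0/(0+eps), not NaN
  expect_true(all(D <= 1 + 1e-7))
  # agrees with vegan where supports overlap
  set.seed(14)
  m2 <- matrix(rpois(6 * 4, 5) + 1, 6, 4)
  rownames(m2) <- paste0("s", 1:6)
  expect_equal(unname(as.matrix(dist_bray_curtis(m2))),
               unname(as.matrix(vegan::vegdist(m2, "bray"))),
               tolerance = 1e-6)
})

test_that("weighted UniFrac matches hand and enumeration oracles", {
  # star tree with unit branches: per-branch abundances are the leaf values
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  mat <- rbind(s1 = c(A = 0.5, B = 0.3, C = 0.2),
               s2 = c(A = 0.2, B = 0.2, C = 0.6))
  D <- as.matrix(dist_weighted_unifrac(mat, star))
  hand <- sum(abs(mat[1, ] - mat[2, ])) / (sum(mat[1, ] + mat[2, ]) + 1e-8)
  expect_equal(D[1, 2], hand, tolerance = 1e-10)

  # 4-leaf tree, disjoint supports: naive per-branch enumeration
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:1):0.25);")
  ab <- rbind(s1 = c(A = 0.7, B = 0.3, C = 0, D = 0),
              s2 = c(A = 0, B = 0, C = 0.4, D = 0.6))
  D2 <- as.matrix(dist_weighted_unifrac(ab, tree))
  # branch abundance sums per sample (A, B, AB, C, D, CD)
  b <- c(1, 2, 0.5, 3, 1, 0.25)
  x1 <- c(0.7, 0.3, 1, 0, 0, 0); x2 <- c(0, 0, 0, 0.4, 0.6, 1)
  expect_equal(D2[1, 2],
               sum(b * abs(x1 - x2)) / (sum(b * (x1 + x2)) + 1e-8),
               tolerance = 1e-10)
  expect_equal(D2[1, 1], 0)
  expect_true(all(D2 <= 1 + 1e-7))
})

test_that("generalized UniFrac interpolates to the weighted form at alpha 1", {
  set.seed(15)
  mat <- matrix(rpois(6 * 5, 4), 6, 5,
                dimnames = list(paste0("s", 1:6), paste0("o", 1:5)))
  ra <- suppressWarnings(to_relative_abundance(mat))
  tree <- simulate_tree(paste0("o", 1:5), seed = 15)
  Dg1 <- as.matrix(dist_generalized_unifrac(ra, tree, alpha = 1))
  Dw <- as.matrix(dist_weighted_unifrac(ra, tree))
  expect_equal(Dg1, Dw, tolerance = 1e-10)

  # 3-leaf hand computation at alpha 0.5
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  m <- rbind(s1 = c(A = 1, B = 0, C = 0), s2 = c(A = 0.5, B = 0.5, C = 0))
  sx <- m[1, ] + m[2, ]; dx <- abs(m[1, ] - m[2, ])
  pos <- sx > 0
  hand <- sum(sqrt(sx[pos]) * dx[pos] / sx[pos]) / (sum(sqrt(sx[pos])) + 1e-8)
  expect_equal(as.matrix(dist_generalized_unifrac(m, star))[1, 2], hand,
               tolerance = 1e-10)
})

test_that("log transform is monotone and feeds metrics unchanged", {
  mat <- rbind(s1 = c(0, 0.4, 0.6), s2 = c(0.1, 0.2, 0.7))
  lt <- count_matrix(log_transform(mat))
  expect_equal(lt["s1", 1], log(1e-8))
  expect_true(all((mat[1, ] < mat[2, ]) == (lt["s1", ] < lt["s2", ])))
  same <- rbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  expect_equal(as.matrix(dist_manhattan(log_transform(same)))[1, 2], 0)
})

test_that("per-OTU combination rules preserve structure", {
  D1 <- new_micro_dist(blob_dist(3, 3, within = 3, between = 3), "l2_d_pdf")
  D2 <- new_micro_dist(blob_dist(3, 3, within = 4, between = 4), "l2_d_pdf")
  comb <- combine_distances(list(D1, D2), "l2")
  off <- as.matrix(comb)[1, 2]
  expect_equal(off, 5)   # 3-4-5
  expect_equal(as.matrix(combine_distances(list(D1), "l2")), as.matrix(D1))
  expect_equal(as.matrix(combine_distances(list(D1, D1), "mean")),
               as.matrix(D1))
  expect_equal(as.matrix(combine_distances(list(D1, D1), "sum")),
               2 * as.matrix(D1))
  D3 <- new_micro_dist(matrix(0, 2, 2), "x")
  expect_error(combine_distances(list(D1, D3)), "mismatched")
})

test_that("tidy view of a distance matrix is the upper triangle", {
  D <- random_points_dist(4, seed = 16)
  td <- tidy(new_micro_dist(D, "euclidean"))
  expect_equal(nrow(td), 6L)
  expect_equal(td$distance[td$item1 == "s1" & td$item2 == "s2"], D[1, 2])
})
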