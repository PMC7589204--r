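test_that("relative resolution scales totals to mean one", {
  mat <- rbind(s1 = c(60, 40), s2 = c(100, 0), s3 = c(50, 50))
  colnames(mat) <- c("a", "b")
  t <- compute_relative_resolution(mat)
  expect_equal(unname(t), c(1, 1, 1))
  mat2 <- rbind(s1 = c(25, 25), s2 = c(100, 50))
  colnames(mat2) <- c("a", "b")
  expect_equal(unname(compute_relative_resolution(mat2)), c(0.5, 1.5))
  mat2["s1", ] <- 0
  expect_error(compute_relative_resolution(mat2), "undefined")
  guarded <- compute_relative_resolution(mat2, zero_totals = "guard")
  expect_true(all(guarded > 0))
  expect_equal(mean(guarded), 1)
})

test_that("component grid spans zero mass, low/mid/high gammas and high mass", {
  counts <- c(rep(0, 50), rep(2, 30), rep(30, 10), 200)
  grid <- build_component_grid(counts, cutoff = 150L, c_mid = 10L,
                               high_knots = 5L)
  comps <- grid$components
  expect_equal(comps$kind[1L], "zero_mass")
  expect_equal(comps$kind[nrow(comps)], "high_mass")
  # rounded exponentials of the even log grid between c_mid and the cutoff:
  # knots 10, 20, 39, 76, 150 give shapes 11, 21, 40, 77, 151 (the first
  # merges with the last small-count component)
  expect_true(all(c(11, 21, 40, 77, 151) %in% comps$shape))
  expect_equal(max(comps$shape, na.rm = TRUE), 151)
  # gamma means strictly increasing after dedup
  means <- comps$mean[comps$kind == "gamma"]
  expect_true(all(diff(means) > 0))

  expect_error(build_component_grid(rep(0, 10)), "no positive")
  expect_error(build_component_grid(counts, cutoff = 10L, c_mid = 10L),
               "strictly below")
})

test_that("component count pmf matches negative-binomial closed forms", {
  g11 <- comp_row("gamma", 1, 1)
  expect_equal(component_count_pmf(g11, 0L, t = 1), 0.5)
  expect_equal(component_count_pmf(g11, 0:3, t = 1), 0.5^(1:4))
  g21 <- comp_row("gamma", 2, 1)
  expect_equal(component_count_pmf(g21, 0L, t = 1), 0.25)
  z <- comp_row("zero_mass")
  expect_equal(component_count_pmf(z, c(0L, 3L)), c(1, 0))
  h <- comp_row("high_mass")
  expect_equal(component_count_pmf(h, c(2L, Inf)), c(0, 1))
  # thinning: t enters as NB(shape, rate/(t+rate))
  expect_equal(component_count_pmf(g11, 4L, t = 0.5),
               dnbinom(4, size = 1, prob = 1 / 1.5))
})

test_that("expected aggregated counts reproduce geometric masses and conserve I", {
  comps <- rbind(comp_row("zero_mass"), comp_row("gamma", 1, 1),
                 comp_row("high_mass"))
  grid <- microclust:::new_component_grid(comps, cutoff = 2L, c_mid = 1L,
                                          high_knots = 0L)
  yhat <- expected_aggregated_counts(grid, c(0, 1, 0), t = 1)
  expect_equal(yhat, c(0.5, 0.25, 0.125, 0.125))
  expect_equal(expected_aggregated_counts(grid, c(1, 0, 0), t = rep(1, 7)),
               c(7, 0, 0, 0))
  set.seed(1)
  for (rep in 1:5) {
    w <- rgamma(3, 1); w <- w / sum(w)
    t <- runif(11, 0.5, 1.5)
    expect_equal(sum(expected_aggregated_counts(grid, w, t)), 11,
                 tolerance = 1e-6)
  }
})

test_that("weight estimation is exact on pure components and optimal", {
  counts <- rep(0L, 100)
  grid <- build_component_grid(c(rep(0L, 99), 5L), cutoff = 10L, c_mid = 3L)
  y <- aggregate_counts(counts, grid$cutoff)
  fit <- estimate_weights(grid, y, t = rep(1, 100))
  expect_equal(fit$weights[1L], 1, tolerance = 1e-6)

  # optimality: no random simplex point beats the solution
  set.seed(2)
  counts <- simulate_from_mixture(c(0.4, 0.3, 0.3), shapes = c(1, 6),
                                  rates = c(1, 1), I = 300)
  grid <- build_component_grid(counts, cutoff = max(counts) + 2L, c_mid = 8L)
  t <- rep(1, 300)
  y <- aggregate_counts(counts, grid$cutoff)
  fit <- estimate_weights(grid, y, t)
  B <- microclust:::avg_fit_matrix(microclust:::design_tensor(grid, t))
  obj <- function(w) sum((y - 300 * as.vector(B %*% w))^2)
  expect_equal(fit$objective, obj(fit$weights), tolerance = 1e-6)
  M <- length(fit$weights)
  for (i in 1:100) {
    w <- rgamma(M, 1); w <- w / sum(w)
    expect_gte(obj(w), fit$objective - 1e-8)
  }
})

test_that("qp and penalised-nnls routes agree and are permutation invariant", {
  # a well-conditioned grid (distinct component means, no near-duplicate
  # columns) where the exact QP and the penalised NNLS must coincide
  set.seed(3)
  counts <- simulate_from_mixture(c(0.5, 0.25, 0.25), shapes = c(2, 8),
                                  rates = c(2, 1), I = 400,
                                  t = runif(400, 0.7, 1.3))
  t <- runif(400, 0.7, 1.3)
  grid <- build_component_grid(counts, cutoff = max(max(counts), 12L),
                               c_mid = 2L, high_knots = 2L,
                               low_means = NULL)
  y <- aggregate_counts(counts, grid$cutoff)
  f1 <- estimate_weights(grid, y, t, method = "qp")
  f2 <- estimate_weights(grid, y, t, method = "nnls")
  expect_equal(f1$weights, f2$weights, tolerance = 1e-4)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-4)
  expect_equal(sum(f1$weights), 1, tolerance = 1e-8)
  expect_true(all(f1$weights >= 0))

  perm <- sample(length(counts))
  f3 <- estimate_weights(grid, aggregate_counts(counts[perm], grid$cutoff),
                         t[perm])
  expect_lt(max(abs(f3$weights - f1$weights)), 1e-10)

  # on an ill-conditioned grid the two routes may distribute weight across
  # near-duplicate components differently but reach the same objective
  grid2 <- build_component_grid(counts, cutoff = max(max(counts), 12L),
                                c_mid = 6L)
  y2 <- aggregate_counts(counts, grid2$cutoff)
  g1 <- estimate_weights(grid2, y2, t, method = "qp")
  g2 <- estimate_weights(grid2, y2, t, method = "nnls")
  expect_equal(g1$objective, g2$objective, tolerance = 0.02)
})

test_that("weights recover a known generating mixture at large I", {
  # truth: 40% structural zero, 35% Gamma(1,1), 25% Gamma(6,1); the grid is
  # built without the near-zero-mean block so the structural zero weight is
  # cleanly identified
  recover <- function(I, seed) {
    set.seed(seed)
    counts <- simulate_from_mixture(c(0.4, 0.35, 0.25), shapes = c(1, 6),
                                    rates = c(1, 1), I = I)
    grid <- build_component_grid(counts, cutoff = max(counts) + 2L,
                                 c_mid = 8L, low_means = NULL)
    fit <- fit_otu_mixture(counts, rep(1, I), grids = list(grid), B = 10L,
                           seed = seed)
    abs(fit$weights[1L] - 0.4)
  }
  errs <- vapply(1:3, function(s) recover(2000L, s), numeric(1))
  expect_lt(max(errs), 0.05)
  # Monte-Carlo error shrinks with I
  small <- vapply(1:3, function(s) recover(200L, s), numeric(1))
  expect_lt(mean(errs), mean(small) + 0.05)
})

test_that("bootstrap selection reduces to a plain fit and prefers the truth", {
  set.seed(5)
  counts <- simulate_from_mixture(c(0.5, 0.3, 0.2), shapes = c(1, 5),
                                  rates = c(1, 1), I = 300)
  t <- rep(1, 300)
  grid <- build_component_grid(counts, cutoff = max(counts) + 2L, c_mid = 6L)
  plain <- estimate_weights(grid, aggregate_counts(counts, grid$cutoff), t)
  boot <- fit_otu_mixture(counts, t, grids = list(grid), B = 1L,
                          resample = FALSE)
  expect_equal(boot$weights, plain$weights, tolerance = 1e-10)
  expect_equal(boot$objective, plain$objective, tolerance = 1e-8)

  # a grid containing the generating components should usually win against a
  # deliberately impoverished one
  wins <- 0L
  for (s in 1:10) {
    counts <- simulate_from_mixture(c(0.3, 0.3, 0.4), shapes = c(1, 9),
                                    rates = c(1, 1), I = 2000)
    cutoff <- max(counts) + 2L
    good <- build_component_grid(counts, cutoff = cutoff, c_mid = 10L)
    poor <- build_component_grid(counts, cutoff = cutoff, c_mid = 1L,
                                 high_knots = 2L, low_means = c(0.1))
    fit <- fit_otu_mixture(counts, rep(1, 2000), grids = list(poor, good),
                           B = 5L, seed = 100 + s)
    wins <- wins + (fit$selected == 2L)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
    expect_true(all(fit$weights >= 0))
  }
  expect_gt(wins / 10, 0.5)
})

test_that("subject posteriors follow Bayes rule and categories sum to one", {
  # two gammas G(1,1) and G(10,1) with equal population weight, n = 0:
  # posterior on G(1,1) is (1/2) / ((1/2) + (1/2)^10) in closed form
  comps <- rbind(comp_row("zero_mass"), comp_row("gamma", 1, 1),
                 comp_row("gamma", 10, 1), comp_row("high_mass"))
  fit <- manual_fit(comps, cutoff = 30L, weights = c(0, 0.5, 0.5, 0),
                    counts = c(0, 40), t = c(1, 1))
  sm <- subject_mixtures(fit)
  expect_equal(unname(sm$posterior[1L, 2L]), 0.5 / (0.5 + 0.5^10),
               tolerance = 1e-12)
  # count above the cutoff with zero high-mass weight still resolves through
  # the gamma tails
  expect_gt(sm$posterior[2L, 3L], 0.99)

  # pure zero-mass population, n = 0 -> category z carries everything
  fitz <- manual_fit(rbind(comp_row("zero_mass"), comp_row("gamma", 1, 1),
                           comp_row("high_mass")),
                     cutoff = 5L, weights = c(1, 0, 0),
                     counts = 0L, t = 1)
  smz <- subject_mixtures(fitz)
  expect_equal(unname(smz$category_pdf[1L, "z"]), 1)

  # high mass and n > C
  fith <- manual_fit(rbind(comp_row("zero_mass"), comp_row("gamma", 1, 1),
                           comp_row("high_mass")),
                     cutoff = 5L, weights = c(0.2, 0.3, 0.5),
                     counts = 99L, t = 1)
  smh <- subject_mixtures(fith)
  expect_gt(unname(smh$category_pdf[1L, "h"]), 0.99)

  # invariants on a realistic fitted OTU
  set.seed(6)
  counts <- simulate_from_mixture(c(0.4, 0.3, 0.3), shapes = c(1, 6),
                                  rates = c(1, 1), I = 150)
  t <- runif(150, 0.7, 1.3)
  fit <- fit_otu_mixture(counts, t, B = 5L, seed = 1)
  sm <- subject_mixtures(fit)
  expect_equal(unname(rowSums(sm$category_pdf)), rep(1, 150),
               tolerance = 1e-8)
  expect_equal(unname(sm$category_cdf[, ncol(sm$category_cdf)]),
               rep(1, 150), tolerance = 1e-8)
  expect_true(all(apply(sm$category_cdf, 1L, function(x) all(diff(x) >= -1e-12))))
  expect_error(
    subject_mixtures(manual_fit(rbind(comp_row("zero_mass"),
                                      comp_row("gamma", 1, 1),
                                      comp_row("high_mass")),
                                cutoff = 5L, weights = c(1, 0, 0),
                                counts = 3L, t = 1)),
    "no compatible")
})

test_that("tidiers expose weights and fit summary", {
  set.seed(7)
  counts <- simulate_from_mixture(c(0.3, 0.4, 0.3), shapes = c(1, 4),
                                  rates = c(1, 1), I = 120)
  fit <- fit_otu_mixture(counts, rep(1, 120), B = 3L, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$n_components, nrow(td))
  expect_equal(gl$zero_weight, td$weight[1L])
})
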