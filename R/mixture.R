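#' Relative sequencing resolution
#'
#' Each sample's total read count scaled by the cohort average,
#' `t_i = N_i / mean(N)`. The resolution thins the latent per-OTU Poisson
#' rate, so deeper-sequenced samples are expected to show proportionally
#' larger counts; by construction `mean(t) == 1`.
#'
#' Samples with zero total reads have no defined resolution; the default is
#' to refuse them, but under very sparse designs a sample can legitimately
#' show zero counts on every retained OTU, so `zero_totals = "guard"`
#' assigns such samples half the smallest positive total before scaling
#' (their mixture likelihood at count zero is insensitive to the exact
#' value).
#'
#' @param table Count tibble or matrix (all OTUs, before any filtering).
#' @param zero_totals `"error"` (default) or `"guard"`.
#' @return Named numeric vector of per-sample resolutions, mean exactly 1.
#' @export
compute_relative_resolution <- function(table,
                                        zero_totals = c("error", "guard")) {
  zero_totals <- match.arg(zero_totals)
  tot <- sample_totals(table)
  if (all(tot == 0)) stop("all sample totals are zero", call. = FALSE)
  if (any(tot == 0)) {
    if (zero_totals == "error") {
      stop("samples with zero total reads have undefined resolution: ",
           paste(names(tot)[tot == 0], collapse = ", "), call. = FALSE)
    }
    tot[tot == 0] <- min(tot[tot > 0]) / 2
  }
  tot / mean(tot)
}

# component grid --------------------------------------------------------------

new_component_grid <- function(components, cutoff, c_mid, high_knots) {
  stopifnot(is.data.frame(components),
            components$kind[1L] == "zero_mass",
            components$kind[nrow(components)] == "high_mass")
  structure(list(components = components, cutoff = as.integer(cutoff),
                 c_mid = as.integer(c_mid), high_knots = as.integer(high_knots)),
            class = "component_grid")
}

#' @export
print.component_grid <- function(x, ...) {
  cat(sprintf("<component_grid> %d components, cutoff C = %d\n",
              nrow(x$components), x$cutoff))
  print(x$components, n = Inf)
  invisible(x)
}

n_components <- function(grid) nrow(grid$components)

#' Build the per-OTU mixture component grid
#'
#' The population rate distribution of one OTU is approximated by an ordered
#' set of fixed components: a structural-zero point mass; a few left-skewed
#' low-rate Gamma components (sub-unit means, shape below 1); Gamma
#' components `Gamma(n + 1, 1)` for small counts `n = 0..c_mid` (the
#' posterior of a Poisson rate given an observed count `n` under a flat
#' prior); sparser high-range Gamma components whose shapes come from an even
#' grid on the log scale between `c_mid` and the cutoff `C`; and a high point
#' mass absorbing every count above `C`. Only the component weights are
#' estimated; the component parameters are fixed by this construction.
#'
#' @param counts Integer count vector for one OTU (one entry per sample).
#' @param cutoff High cutoff `C`; defaults to the 99th percentile of the
#'   counts, rounded up, floored at 10.
#' @param c_mid Largest small count given its own `Gamma(n+1, 1)` component;
#'   default `min(10, cutoff - 1)`.
#' @param high_knots Number of log-spaced high-range components, default 5.
#' @param low_means Means of the left-skewed low-rate components (shape 0.5),
#'   default `c(0.1, 0.3, 0.6)`.
#' @return A `component_grid` object.
#' @export
build_component_grid <- function(counts, cutoff = NULL, c_mid = NULL,
                                 high_knots = 5L,
                                 low_means = c(0.1, 0.3, 0.6)) {
  counts <- as.numeric(counts)
  validate_counts(counts)
  if (all(counts == 0)) {
    stop("grid undefined: OTU has no positive counts", call. = FALSE)
  }
  if (is.null(cutoff)) {
    cutoff <- max(10, ceiling(stats::quantile(counts, 0.99, names = FALSE)))
  }
  if (is.null(c_mid)) c_mid <- min(10L, cutoff - 1L)
  if (c_mid >= cutoff) {
    stop("c_mid must be strictly below the cutoff", call. = FALSE)
  }
  low <- if (length(low_means) == 0L) {
    tibble::tibble(kind = character(), shape = numeric(), rate = numeric())
  } else {
    tibble::tibble(kind = "gamma", shape = 0.5, rate = 0.5 / low_means)
  }
  mid <- tibble::tibble(kind = "gamma", shape = seq(0L, c_mid) + 1, rate = 1)
  knots <- unique(round(exp(seq(log(c_mid), log(cutoff),
                                length.out = high_knots))))
  high <- tibble::tibble(kind = "gamma", shape = knots + 1, rate = 1)
  gam <- rbind(low, mid, high)
  gam <- gam[!duplicated(gam[, c("shape", "rate")]), ]
  gam <- gam[order(gam$shape / gam$rate), ]
  comps <- rbind(tibble::tibble(kind = "zero_mass", shape = NA_real_,
                                rate = NA_real_),
                 gam,
                 tibble::tibble(kind = "high_mass", shape = NA_real_,
                                rate = NA_real_))
  comps$mean <- ifelse(comps$kind == "gamma", comps$shape / comps$rate, NA)
  new_component_grid(comps, cutoff, c_mid, high_knots)
}

#' Candidate grid family for bootstrap model selection
#'
#' @param counts Integer count vector for one OTU.
#' @param c_mid,high_knots Vectors of settings crossed into candidates; the
#'   cutoff is shared so objectives are comparable.
#' @param cutoff Shared cutoff, defaulting as in [build_component_grid()].
#' @return List of `component_grid` objects.
#' @export
candidate_grids <- function(counts, c_mid = c(5L, 10L),
                            high_knots = c(3L, 5L), cutoff = NULL) {
  if (is.null(cutoff)) {
    cutoff <- max(10, ceiling(stats::quantile(as.numeric(counts), 0.99,
                                              names = FALSE)))
  }
  settings <- expand.grid(c_mid = pmin(c_mid, cutoff - 1L),
                          high_knots = high_knots)
  settings <- unique(settings)
  purrr::pmap(settings, function(c_mid, high_knots) {
    build_component_grid(counts, cutoff = cutoff, c_mid = c_mid,
                         high_knots = high_knots)
  })
}

#' Count probability of a single mixture component
#'
#' A Gamma rate component `Gamma(shape, rate)` observed through
#' `Poisson(rate * t)` sampling gives negative-binomial counts:
#' \deqn{P(K=k) = \binom{k+\alpha-1}{k}
#'   \left(\frac{\beta}{t+\beta}\right)^\alpha
#'   \left(\frac{t}{t+\beta}\right)^k.}
#' The structural-zero point mass puts probability 1 on `k = 0`; the
#' high point mass puts probability 1 on the tail bin, encoded as `k = Inf`.
#'
#' @param component List or one-row data frame with `kind` and, for Gamma
#'   components, `shape` and `rate`.
#' @param k Non-negative integer count(s); `Inf` denotes the above-cutoff
#'   tail bin.
#' @param t Relative resolution, positive scalar.
#' @return Probability vector along `k`.
#' @export
component_count_pmf <- function(component, k, t = 1) {
  stopifnot(t > 0)
  kind <- component$kind[1L]
  if (kind == "zero_mass") return(as.numeric(k == 0))
  if (kind == "high_mass") return(as.numeric(is.infinite(k)))
  shape <- component$shape[1L]; rate <- component$rate[1L]
  stopifnot(shape > 0, rate > 0)
  out <- numeric(length(k))
  fin <- is.finite(k)
  out[fin] <- stats::dnbinom(k[fin], size = shape, prob = rate / (t + rate))
  out[!fin] <- NA_real_   # tail mass depends on the cutoff; see design tensor
  out
}

# design tensor ---------------------------------------------------------------
# Per-subject component count probabilities over the observable bins
# (0, 1, ..., C, >C), computed by the stable NB recurrence
#   p_0 = (beta/(t+beta))^alpha,  p_{k+1} = p_k (k+alpha)/(k+1) * t/(t+beta).
# Stored as a (nbins x M) x I matrix so a bootstrap reweighting is one
# matrix-vector product.
design_tensor <- function(grid, t) {
  C <- grid$cutoff
  nbins <- C + 2L
  I <- length(t)
  M <- n_components(grid)
  big <- matrix(0, nbins * M, I)
  for (m in seq_len(M)) {
    rows <- (m - 1L) * nbins + seq_len(nbins)
    comp <- grid$components[m, ]
    if (comp$kind == "zero_mass") {
      big[rows[1L], ] <- 1
    } else if (comp$kind == "high_mass") {
      big[rows[nbins], ] <- 1
    } else {
      a <- comp$shape; b <- comp$rate
      pk <- exp(a * log(b / (t + b)))          # p_0 per subject
      ratio <- t / (t + b)
      pm <- matrix(0, nbins, I)
      pm[1L, ] <- pk
      for (k in seq_len(C)) {
        pk <- pk * ((k - 1 + a) / k) * ratio
        pm[k + 1L, ] <- pk
      }
      pm[nbins, ] <- pmax(0, 1 - colSums(pm[seq_len(C + 1L), , drop = FALSE]))
      big[rows, ] <- pm
    }
  }
  structure(list(big = big, nbins = nbins, M = M, I = I, grid = grid, t = t),
            class = "design_tensor")
}

# Subject-averaged component bin probabilities, optionally under bootstrap
# subject weights (counts of how often each subject was resampled).
avg_fit_matrix <- function(tensor, subject_weights = NULL) {
  if (is.null(subject_weights)) subject_weights <- rep(1, tensor$I)
  p <- as.vector(tensor$big %*% subject_weights) / sum(subject_weights)
  matrix(p, tensor$nbins, tensor$M)
}

#' Aggregate counts into the model's observation bins
#'
#' `y_k` is the number of samples in which the OTU was observed exactly `k`
#' times, for `k = 0..C`, with one extra bin for counts above the cutoff.
#'
#' @param counts Integer count vector for one OTU.
#' @param cutoff The grid cutoff `C`.
#' @return Integer vector of length `cutoff + 2`; sums to `length(counts)`.
#' @export
aggregate_counts <- function(counts, cutoff) {
  validate_counts(counts)
  k <- pmin(counts, cutoff + 1L)
  tabulate(k + 1L, nbins = cutoff + 2L)
}

#' Expected aggregated counts under mixture weights
#'
#' \deqn{\hat y_k = \sum_m w_m \bar p_{km} I} where \eqn{\bar p_{km}} is the
#' component bin probability averaged over the subjects' relative
#' resolutions. Total mass is conserved: `sum(yhat) == I` for any simplex
#' weights.
#'
#' @param grid A `component_grid`.
#' @param weights Simplex weight vector, one entry per component.
#' @param t Relative resolution vector (one entry per subject).
#' @return Numeric vector of expected bin counts (length `cutoff + 2`).
#' @export
expected_aggregated_counts <- function(grid, weights, t) {
  stopifnot(length(weights) == n_components(grid),
            all(weights >= -1e-12), abs(sum(weights) - 1) < 1e-8)
  B <- avg_fit_matrix(design_tensor(grid, t))
  as.vector(B %*% weights) * length(t)
}

# solvers ---------------------------------------------------------------------

# Lawson-Hanson non-negative least squares, argmin ||A x - b|| s.t. x >= 0.
nnls_solve <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, b)))
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- as.vector(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > 0)) break
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  x
}

#' Estimate population mixture weights
#'
#' Solves the simplex-constrained least-squares problem
#' \deqn{\hat w = \arg\min_w \sum_k \big(y_k - I \sum_m w_m \bar p_{km}\big)^2
#'  \quad \text{s.t. } \sum_m w_m = 1,\; w_m \ge 0}
#' matching the observed to the expected aggregated counts. Two routes are
#' provided: an exact active-set quadratic program (`"qp"`, the default, via
#' \pkg{quadprog}) and a Lawson-Hanson non-negative least squares with a
#' heavily weighted sum-to-one row followed by renormalisation (`"nnls"`).
#' The two agree to ~1e-4 and the second serves as an internal cross-check.
#'
#' @param grid A `component_grid`.
#' @param observed Aggregated count vector from [aggregate_counts()] (length
#'   `cutoff + 2`).
#' @param t Relative resolution vector.
#' @param method `"qp"` or `"nnls"`.
#' @param tensor Optional precomputed design tensor (internal reuse).
#' @param subject_weights Optional bootstrap multiplicities per subject.
#' @return Object of class `population_mixture`: list with `grid`, `weights`
#'   (simplex), `objective` (achieved residual sum of squares), `method`.
#' @export
estimate_weights <- function(grid, observed, t, method = c("qp", "nnls"),
                             tensor = NULL, subject_weights = NULL) {
  method <- match.arg(method)
  stopifnot(length(observed) == grid$cutoff + 2L)
  if (is.null(tensor)) tensor <- design_tensor(grid, t)
  B <- avg_fit_matrix(tensor, subject_weights)
  I <- sum(observed)
  w <- solve_simplex_ls(B, observed / I, method)
  resid <- observed - I * as.vector(B %*% w)
  structure(list(grid = grid, weights = w, objective = sum(resid^2),
                 method = method, n_samples = I),
            class = "population_mixture")
}

solve_simplex_ls <- function(B, yn, method) {
  M <- ncol(B)
  if (method == "qp") {
    D <- crossprod(B)
    D <- D + diag(1e-10 * max(diag(D)), M)
    sol <- quadprog::solve.QP(
      Dmat = D, dvec = as.vector(crossprod(B, yn)),
      Amat = cbind(rep(1, M), diag(M)),
      bvec = c(1, rep(0, M)), meq = 1L)
    w <- pmax(sol$solution, 0)
  } else {
    lam <- 1e3 * max(yn)
    A <- rbind(B, rep(lam, M))
    w <- nnls_solve(A, c(yn, lam))
  }
  w / sum(w)
}

#' @export
print.population_mixture <- function(x, ...) {
  cat(sprintf("<population_mixture> %d components, objective %.4g\n",
              length(x$weights), x$objective))
  invisible(x)
}

# bootstrap model selection ----------------------------------------------------

#' Fit an OTU mixture with bootstrap model selection
#'
#' Implements the per-OTU estimation step of the clustering algorithm: over
#' `B` bootstrap resamples of subjects, every candidate component grid is fit
#' by [estimate_weights()] and its residual objective recorded; the grid with
#' the smallest mean bootstrap objective wins (ties broken toward fewer
#' components), and the final population weights are the renormalised mean of
#' the winning grid's bootstrap weight vectors.
#'
#' @param counts Integer count vector for one OTU.
#' @param t Relative resolution vector, same length.
#' @param grids List of candidate `component_grid`s sharing one cutoff;
#'   default [candidate_grids()] family.
#' @param B Number of bootstrap replicates, default 50.
#' @param seed Optional integer seed for the resampling.
#' @param resample Set `FALSE` to fit the full data `B` times (no
#'   resampling); with `B = 1` this reduces exactly to [estimate_weights()].
#' @param method Solver passed through to [estimate_weights()].
#' @return Object of class `otu_mixture_fit`: winning `grid`, final
#'   `weights`, full-data `objective`, the per-replicate selection table
#'   `boot`, the design `tensor`, plus `counts` and `t`.
#' @export
fit_otu_mixture <- function(counts, t, grids = NULL, B = 50L, seed = NULL,
                            resample = TRUE, method = "qp") {
  sample_ids <- names(counts)
  counts <- as.numeric(counts)
  validate_counts(counts)
  stopifnot(length(counts) == length(t), B >= 1L)
  if (is.null(grids)) grids <- candidate_grids(counts)
  cutoffs <- vapply(grids, function(g) g$cutoff, integer(1L))
  stopifnot(length(unique(cutoffs)) == 1L)
  cutoff <- cutoffs[1L]
  if (!is.null(seed)) set.seed(seed)
  I <- length(counts)
  tensors <- lapply(grids, design_tensor, t = t)
  L <- length(grids)
  obj <- matrix(NA_real_, B, L)
  wlist <- lapply(seq_len(L), function(l) {
    matrix(NA_real_, B, n_components(grids[[l]]))
  })
  for (b in seq_len(B)) {
    idx <- if (resample) sample.int(I, replace = TRUE) else seq_len(I)
    sw <- tabulate(idx, nbins = I)
    yb <- aggregate_counts(counts[idx], cutoff)
    for (l in seq_len(L)) {
      fit <- estimate_weights(grids[[l]], yb, t, method = method,
                              tensor = tensors[[l]], subject_weights = sw)
      obj[b, l] <- fit$objective
      wlist[[l]][b, ] <- fit$weights
    }
  }
  mean_obj <- colMeans(obj)
  ncomp <- vapply(grids, n_components, integer(1L))
  best <- order(mean_obj, ncomp)[1L]
  w <- colMeans(wlist[[best]])
  w <- pmax(w, 0); w <- w / sum(w)
  y <- aggregate_counts(counts, cutoff)
  resid <- y - I * as.vector(avg_fit_matrix(tensors[[best]]) %*% w)
  boot <- tibble::tibble(
    replicate = rep(seq_len(B), times = L),
    grid = rep(seq_len(L), each = B),
    objective = as.vector(obj))
  structure(list(grid = grids[[best]], weights = w, objective = sum(resid^2),
                 boot = boot, selected = best, mean_objective = mean_obj,
                 B = B, seed = seed, tensor = tensors[[best]],
                 counts = counts, t = t, sample_ids = sample_ids),
            class = "otu_mixture_fit")
}

#' @export
print.otu_mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<otu_mixture_fit> grid %d/%d selected (C = %d, %d ",
                     "components), B = %d, objective %.4g\n"),
              x$selected, length(x$mean_objective), x$grid$cutoff,
              length(x$weights), x$B, x$objective))
  invisible(x)
}

# subject mixtures -------------------------------------------------------------

# Category bookkeeping: categories are ordered (z, 0, 1, ..., C, h). The
# structural-zero point mass occupies its own category distinct from an
# observed count of zero, which is what lets the L2 distances tell structural
# and sampling zeros apart.
category_matrix <- function(fit) {
  grid <- fit$grid
  C <- grid$cutoff
  M <- n_components(grid)
  Bavg <- avg_fit_matrix(fit$tensor)          # (C+2) x M over observable bins
  P <- matrix(0, C + 3L, M)
  for (m in seq_len(M)) {
    kind <- grid$components$kind[m]
    if (kind == "zero_mass") {
      P[1L, m] <- 1
    } else if (kind == "high_mass") {
      P[C + 3L, m] <- 1
    } else {
      P[2L:(C + 2L), m] <- Bavg[seq_len(C + 1L), m]
      P[C + 3L, m] <- Bavg[C + 2L, m]
    }
  }
  rownames(P) <- c("z", as.character(0:C), "h")
  P
}

#' Subject-specific posterior mixtures
#'
#' Conditions the fitted population mixture on each subject's observed count
#' and resolution. Posterior component weights follow Bayes' rule,
#' `w_im proportional to w_m * p_m(n_i | t_i)`, where the structural-zero
#' mass is compatible only with `n_i = 0` and the high mass only with counts
#' above the cutoff. Each subject's category distribution over
#' `(z, 0, ..., C, h)` is the posterior-weight combination of the shared
#' component category probabilities, so `P_i(z)` is exactly the subject's
#' posterior structural-zero weight.
#'
#' @param fit An `otu_mixture_fit`.
#' @return Object of class `subject_mixtures`: list with `posterior` (I x M
#'   matrix), `category_pdf` and `category_cdf` (I x (C+3) matrices over the
#'   ordered categories), and the shared `category_matrix`.
#' @export
subject_mixtures <- function(fit) {
  grid <- fit$grid
  C <- grid$cutoff
  M <- n_components(grid)
  I <- length(fit$counts)
  nbins <- C + 2L
  bins <- pmin(fit$counts, C + 1L) + 1L       # observable bin per subject
  lik <- matrix(0, I, M)
  for (m in seq_len(M)) {
    rows <- (m - 1L) * nbins + bins
    lik[, m] <- fit$tensor$big[cbind(rows, seq_len(I))]
  }
  post <- lik * rep(fit$weights, each = I)
  tot <- rowSums(post)
  if (any(tot <= 0)) {
    bad <- which(tot <= 0)[1L]
    stop(sprintf("no compatible mixture component for subject %d (count %g)",
                 bad, fit$counts[bad]), call. = FALSE)
  }
  post <- post / tot
  P <- category_matrix(fit)
  pdf <- post %*% t(P)
  cdf <- t(apply(pdf, 1L, cumsum))
  colnames(pdf) <- colnames(cdf) <- rownames(P)
  rownames(post) <- rownames(pdf) <- rownames(cdf) <- fit$sample_ids
  structure(list(posterior = post, category_pdf = pdf, category_cdf = cdf,
                 category_matrix = P, grid = grid, t = fit$t),
            class = "subject_mixtures")
}

#' @export
print.subject_mixtures <- function(x, ...) {
  cat(sprintf("<subject_mixtures> %d subjects, %d components, %d categories\n",
              nrow(x$posterior), ncol(x$posterior), ncol(x$category_pdf)))
  invisible(x)
}

#' @rdname tidy.micro_dist
#' @method tidy otu_mixture_fit
#' @export
tidy.otu_mixture_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$weights),
                 kind = x$grid$components$kind,
                 shape = x$grid$components$shape,
                 rate = x$grid$components$rate,
                 weight = x$weights)
}

#' @rdname tidy.micro_dist
#' @method glance otu_mixture_fit
#' @export
glance.otu_mixture_fit <- function(x, ...) {
  tibble::tibble(n_components = length(x$weights),
                 cutoff = x$grid$cutoff,
                 objective = x$objective,
                 zero_weight = x$weights[1L],
                 high_weight = x$weights[length(x$weights)],
                 B = x$B,
                 selected_grid = x$selected)
}
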