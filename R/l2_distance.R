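#' L2-norm distances between subject mixtures
#'
#' Pairwise sample distances for one OTU, computed from the subject-specific
#' posterior mixtures. Three variants:
#' * `l2_discrete_pdf()`: L2 norm of the difference of category
#'   probability vectors over `(z, 0, ..., C, h)`.
#' * `l2_discrete_cdf()`: the same on the running-sum (CDF) vectors in
#'   category order.
#' * `l2_continuous_cdf()`: the continuous norm
#'   \eqn{\sqrt{\int_0^C [F_i(k) - F_j(k)]^2 dk}}, evaluated exactly through
#'   the Gram matrix of the component CDF step functions (see [cdf_gram()]),
#'   as the quadratic form \eqn{(w_i - w_j)^T G (w_i - w_j)} in the posterior
#'   weights.
#'
#' Keeping the structural zero `z` as its own category distinct from an
#' observed zero count is what gives these metrics their sensitivity to
#' presence/absence structure in sparse data.
#'
#' @param sm A `subject_mixtures` object (one OTU).
#' @return A `micro_dist` of pairwise subject distances.
#' @export
l2_discrete_pdf <- function(sm) {
  stopifnot(inherits(sm, "subject_mixtures"))
  dist_to_micro(stats::dist(sm$category_pdf), mixture_ids(sm), "l2_d_pdf")
}

#' @rdname l2_discrete_pdf
#' @export
l2_discrete_cdf <- function(sm) {
  stopifnot(inherits(sm, "subject_mixtures"))
  dist_to_micro(stats::dist(sm$category_cdf), mixture_ids(sm), "l2_d_cdf")
}

#' @rdname l2_discrete_pdf
#' @param gram Optional precomputed [cdf_gram()] matrix.
#' @export
l2_continuous_cdf <- function(sm, gram = NULL) {
  stopifnot(inherits(sm, "subject_mixtures"))
  if (is.null(gram)) gram <- cdf_gram(sm)
  # factor G = R'R so the quadratic form becomes a plain Euclidean distance
  eg <- eigen(gram, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(ev)) {
    stop("CDF Gram matrix is not positive semidefinite", call. = FALSE)
  }
  R <- diag(sqrt(ev)) %*% t(eg$vectors)
  S <- sm$posterior %*% t(R)
  dist_to_micro(stats::dist(S), mixture_ids(sm), "l2_c_cdf")
}

mixture_ids <- function(sm) {
  ids <- rownames(sm$posterior)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(sm$posterior)))
  ids
}

#' Gram matrix of component CDF step functions
#'
#' Each mixture component's count CDF, placed on the real line, is a step
#' function constant on unit intervals: the structural-zero mass has CDF 1
#' on all of `[0, C]`, the high mass has CDF 0 below `C`, and a Gamma
#' component steps through its (subject-averaged) negative-binomial CDF.
#' Hence \eqn{G_{q_1 q_2} = \int_0^C F_{q_1} F_{q_2}\,dk =
#' \sum_{k=0}^{C-1} F_{q_1}(k) F_{q_2}(k)} exactly — no quadrature is
#' needed.
#'
#' @param sm A `subject_mixtures` object.
#' @return Symmetric positive semidefinite M x M matrix.
#' @export
cdf_gram <- function(sm) {
  Pc <- apply(sm$category_matrix, 2L, cumsum)   # CDF over category order
  C <- sm$grid$cutoff
  FF <- Pc[2L:(C + 1L), , drop = FALSE]         # F_m(k), k = 0..C-1
  crossprod(FF)
}

#' Mixture-model beta diversity across OTUs
#'
#' Fits (or reuses) one mixture per OTU and returns the combined L2 distance
#' over all OTUs.
#'
#' @param table Count tibble or matrix.
#' @param metric One of `"l2_d_pdf"`, `"l2_d_cdf"`, `"l2_c_cdf"`.
#' @param fits Optional list of `otu_mixture_fit`s (one per OTU column of
#'   `table`), e.g. from [fit_all_otus()]; fitted here when missing.
#' @param combine Cross-OTU aggregation rule, see [combine_distances()].
#' @param ... Passed to [fit_all_otus()] when `fits` is missing.
#' @return A `micro_dist`.
#' @export
mixture_distance <- function(table,
                             metric = c("l2_d_pdf", "l2_d_cdf", "l2_c_cdf"),
                             fits = NULL, combine = "l2", ...) {
  metric <- match.arg(metric)
  if (is.null(fits)) fits <- fit_all_otus(table, ...)
  per_otu <- lapply(fits, function(fit) {
    sm <- subject_mixtures(fit)
    switch(metric,
           l2_d_pdf = l2_discrete_pdf(sm),
           l2_d_cdf = l2_discrete_cdf(sm),
           l2_c_cdf = l2_continuous_cdf(sm))
  })
  out <- combine_distances(per_otu, combine)
  out$metric <- metric
  out
}

#' Fit mixtures for every OTU of a table
#'
#' @param table Count tibble or matrix.
#' @param t Optional externally supplied relative resolutions; computed from
#'   the table by default.
#' @param B Bootstrap replicates per OTU.
#' @param c_mid,high_knots Candidate-grid family settings, see
#'   [candidate_grids()].
#' @param seed Optional seed; per-OTU seeds are derived from it.
#' @return Named list of `otu_mixture_fit` objects (skipping all-zero OTUs
#'   with a warning).
#' @export
fit_all_otus <- function(table, t = NULL, B = 50L, c_mid = c(5L, 10L),
                         high_knots = c(3L, 5L), seed = NULL) {
  mat <- count_matrix(table)
  if (is.null(t)) t <- compute_relative_resolution(mat, zero_totals = "guard")
  otus <- colnames(mat)
  keep <- colSums(mat) > 0
  if (!all(keep)) {
    warning("skipping all-zero OTUs: ", paste(otus[!keep], collapse = ", "),
            call. = FALSE)
  }
  fits <- lapply(which(keep), function(j) {
    counts <- mat[, j]
    grids <- candidate_grids(counts, c_mid = c_mid, high_knots = high_knots)
    fit_otu_mixture(counts, t, grids = grids, B = B,
                    seed = if (is.null(seed)) NULL else seed + j)
  })
  names(fits) <- otus[keep]
  fits
}
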