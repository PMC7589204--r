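#' Distance matrix container
#'
#' A `micro_dist` is a symmetric, zero-diagonal, non-negative matrix of
#' pairwise sample distances tagged with the metric that produced it. It is
#' the common currency between the distance functions, [pam_cluster()], and
#' the validation indices.
#'
#' @param values Square numeric matrix with sample identifiers as dimnames.
#' @param metric Short metric name, e.g. `"bray_curtis"`.
#' @return A `micro_dist` object.
#' @export
new_micro_dist <- function(values, metric = "unknown") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("s", seq_len(nrow(values)))
  }
  values <- (values + t(values)) / 2   # kill round-off asymmetry
  diag(values) <- 0
  if (any(values < 0)) {
    if (min(values) < -1e-10) stop("negative distances", call. = FALSE)
    values[values < 0] <- 0
  }
  structure(list(values = values, metric = metric), class = "micro_dist")
}

#' @export
as.matrix.micro_dist <- function(x, ...) x$values

#' @export
as.dist.micro_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' @export
print.micro_dist <- function(x, ...) {
  cat(sprintf("<micro_dist> %s: %d samples\n", x$metric, nrow(x$values)))
  print(utils::head(x$values[, seq_len(min(6L, ncol(x$values))), drop = FALSE]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance matrix into long form
#'
#' @param x A `micro_dist`.
#' @param ... Unused.
#' @return Tibble with columns `item1`, `item2`, `distance` (upper triangle).
#' @method tidy micro_dist
#' @export
tidy.micro_dist <- function(x, ...) {
  m <- x$values
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(m)[idx[, 1L]],
                 item2 = colnames(m)[idx[, 2L]],
                 distance = m[idx])
}

dist_to_micro <- function(d, ids, metric) {
  m <- as.matrix(d)
  rownames(m) <- colnames(m) <- ids
  new_micro_dist(m, metric)
}

# classical metrics ----------------------------------------------------------

#' Manhattan and Euclidean sample distances
#'
#' Straight city-block / L2 distances between sample rows, usually applied to
#' relative abundances (see [to_relative_abundance()]) or their log
#' transform.
#'
#' @param table Abundance tibble or matrix, samples in rows.
#' @return A `micro_dist`.
#' @export
dist_manhattan <- function(table) {
  mat <- count_matrix(table)
  dist_to_micro(stats::dist(mat, method = "manhattan"), rownames(mat),
                "manhattan")
}

#' @rdname dist_manhattan
#' @export
dist_euclidean <- function(table) {
  mat <- count_matrix(table)
  dist_to_micro(stats::dist(mat, method = "euclidean"), rownames(mat),
                "euclidean")
}

#' Bray-Curtis dissimilarity with a zero-guard
#'
#' \deqn{D(j,k) = \sum_i |x_{ij} - x_{ik}| / (\sum_i (x_{ij} + x_{ik}) + \epsilon)}
#' The small `epsilon` in the denominator keeps the value defined (0) when
#' both samples are entirely empty; it is far below any abundance scale of
#' interest, so non-degenerate values are unchanged to ~1e-8.
#'
#' @param table Abundance tibble or matrix.
#' @param epsilon Denominator guard, default `1e-8`.
#' @return A `micro_dist` with values in \[0, 1\].
#' @export
dist_bray_curtis <- function(table, epsilon = 1e-8) {
  stopifnot(epsilon > 0)
  mat <- count_matrix(table)
  # numerator is a Manhattan distance; denominator depends only on row sums
  num <- as.matrix(stats::dist(mat, method = "manhattan"))
  tot <- rowSums(mat)
  den <- outer(tot, tot, `+`) + epsilon
  out <- num / den
  dimnames(out) <- list(rownames(mat), rownames(mat))
  new_micro_dist(out, "bray_curtis")
}

# UniFrac --------------------------------------------------------------------

# Per-branch abundance: for each edge of the rooted tree, the summed relative
# abundance of all leaves descending through that edge, per sample.
branch_abundances <- function(table, tree) {
  mat <- count_matrix(table)
  check_tree(tree, colnames(mat))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nrow(mat), nnode)
  acc[, seq_len(ntip)] <- mat[, tree$tip.label, drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {      # postorder: children first
    acc[, tree$edge[e, 1L]] <- acc[, tree$edge[e, 1L]] + acc[, tree$edge[e, 2L]]
  }
  list(x = acc[, tree$edge[, 2L], drop = FALSE],  # samples x edges
       b = tree$edge.length)
}

#' Weighted and generalized UniFrac distances
#'
#' Phylogeny-aware beta diversity. With \eqn{x_{ij}} the summed relative
#' abundance below branch \eqn{i} in sample \eqn{j} and \eqn{b_i} the branch
#' length, the weighted form is
#' \deqn{D_w(j,k) = \sum_i b_i |x_{ij}-x_{ik}| / (\sum_i b_i (x_{ij}+x_{ik}) + \epsilon)}
#' and the generalized form moderates the abundance weight with an exponent
#' `alpha` (default 0.5):
#' \deqn{D_g(j,k) = \sum_i b_i (x_{ij}+x_{ik})^\alpha
#'   \frac{|x_{ij}-x_{ik}|}{x_{ij}+x_{ik}} /
#'   (\sum_i b_i (x_{ij}+x_{ik})^\alpha + \epsilon).}
#' Branches carrying no abundance in either sample contribute 0 (the limit of
#' the summand); `alpha = 1` recovers the weighted form.
#'
#' @param table Relative abundance tibble or matrix; every OTU column must be
#'   a leaf of `tree`.
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param epsilon Denominator guard, default `1e-8`.
#' @param alpha Abundance exponent for the generalized form.
#' @return A `micro_dist`.
#' @export
dist_weighted_unifrac <- function(table, tree, epsilon = 1e-8) {
  ba <- branch_abundances(table, tree)
  ids <- rownames(count_matrix(table))
  # branch-length-weighted Manhattan over branch abundances; the denominator
  # only involves per-sample branch totals
  xs <- ba$x %*% diag(ba$b, length(ba$b))
  num <- as.matrix(stats::dist(xs, method = "manhattan"))
  tot <- as.vector(ba$x %*% ba$b)
  out <- num / (outer(tot, tot, `+`) + epsilon)
  dimnames(out) <- list(ids, ids)
  new_micro_dist(out, "weighted_unifrac")
}

#' @rdname dist_weighted_unifrac
#' @export
dist_generalized_unifrac <- function(table, tree, alpha = 0.5,
                                     epsilon = 1e-8) {
  ba <- branch_abundances(table, tree)
  n <- nrow(ba$x)
  ids <- rownames(count_matrix(table))
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      sx <- ba$x[j, ] + ba$x[k, ]
      dx <- abs(ba$x[j, ] - ba$x[k, ])
      pos <- sx > 0
      num <- sum(ba$b[pos] * sx[pos]^alpha * dx[pos] / sx[pos])
      den <- sum(ba$b[pos] * sx[pos]^alpha) + epsilon
      out[j, k] <- out[k, j] <- num / den
    }
  }
  new_micro_dist(out, "generalized_unifrac")
}

#' Log-transform an abundance table
#'
#' Entrywise `log(x + pseudo)`; the transformed table feeds the Manhattan,
#' Euclidean and Bray-Curtis metrics unchanged. The pseudo-count defaults to
#' `1e-8`, the same guard used in the denominator of the ratio metrics; it
#' sets the floor value `log(1e-8)` for absent taxa and is worth varying in a
#' sensitivity check since no canonical value exists.
#'
#' @param table Abundance tibble or matrix.
#' @param pseudo Positive pseudo-count added before the log.
#' @return Tibble of the same shape.
#' @export
log_transform <- function(table, pseudo = 1e-8) {
  stopifnot(pseudo > 0)
  count_tbl(log(count_matrix(table) + pseudo))
}

#' Combine per-OTU distance matrices
#'
#' The mixture-model L2 metrics produce one matrix per OTU; this collapses
#' them into a single sample distance. The default `"l2"` rule treats the
#' per-OTU distances as orthogonal coordinates (root of the sum of squared
#' distances); `"sum"` and `"mean"` are plain elementwise aggregates. All
#' rules preserve symmetry and the zero diagonal.
#'
#' @param dms List of `micro_dist` objects over identical sample sets.
#' @param rule `"l2"` (default), `"sum"`, or `"mean"`.
#' @return A single `micro_dist`.
#' @export
combine_distances <- function(dms, rule = c("l2", "sum", "mean")) {
  rule <- match.arg(rule)
  stopifnot(length(dms) >= 1L)
  mats <- lapply(dms, as.matrix)
  ids <- rownames(mats[[1L]])
  for (m in mats) {
    if (!identical(rownames(m), ids)) {
      stop("mismatched sample sets across per-OTU distance matrices",
           call. = FALSE)
    }
  }
  out <- switch(rule,
    l2   = sqrt(Reduce(`+`, lapply(mats, function(m) m^2))),
    sum  = Reduce(`+`, mats),
    mean = Reduce(`+`, mats) / length(mats))
  new_micro_dist(out, paste0(dms[[1L]]$metric, "_", rule))
}
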