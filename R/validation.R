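#' Internal cluster validation indices
#'
#' Index functions scoring a partition on its distance matrix alone, used to
#' choose the number of clusters:
#' * `dunn_index()` — minimum single-linkage inter-cluster distance divided
#'   by the maximum cluster diameter (maximise).
#' * `silhouette_index()` — mean over points of `(b - a) / max(a, b)` with
#'   `a` the mean within-cluster distance and `b` the smallest mean distance
#'   to another cluster; singleton clusters contribute 0 (maximise).
#' * `xie_beni_index()` — summed squared distances to the cluster medoids
#'   over `n` times the smallest squared medoid separation (minimise).
#' * `wemmert_gancarski_index()` — size-weighted mean of
#'   `max(0, 1 - mean_i d(i, own medoid)/d(i, nearest other medoid))`
#'   (maximise).
#'
#' The medoid-based indices take a full `pam_clustering`; the others only
#' need the assignment vector.
#'
#' @param dm A `micro_dist` or square distance matrix.
#' @param assignment Integer cluster ids per sample.
#' @param result A `pam_clustering` (for the medoid-based indices).
#' @return A single numeric score.
#' @export
dunn_index <- function(dm, assignment) {
  D <- as.matrix(dm)
  cl <- split(seq_along(assignment), assignment)
  if (length(cl) < 2L) stop("need at least 2 clusters", call. = FALSE)
  diam <- vapply(cl, function(idx) {
    if (length(idx) < 2L) 0 else max(D[idx, idx])
  }, numeric(1L))
  if (max(diam) == 0) {
    stop("all clusters are singletons or zero-diameter; Dunn undefined",
         call. = FALSE)
  }
  pairs <- utils::combn(length(cl), 2L)
  delta <- apply(pairs, 2L, function(p) {
    min(D[cl[[p[1L]]], cl[[p[2L]]], drop = FALSE])
  })
  min(delta) / max(diam)
}

#' @rdname dunn_index
#' @export
silhouette_index <- function(dm, assignment) {
  D <- as.matrix(dm)
  n <- length(assignment)
  ids <- sort(unique(assignment))
  if (length(ids) < 2L) stop("need at least 2 clusters", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    if (sum(own) == 1L) { s[i] <- 0; next }   # singleton convention
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(ids[ids != assignment[i]], function(g) {
      mean(D[i, assignment == g])
    }, numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' @rdname dunn_index
#' @export
xie_beni_index <- function(dm, result) {
  D <- as.matrix(dm)
  med <- result$medoids
  n <- length(result$assignment)
  sep <- D[med, med, drop = FALSE]
  minsep <- min(sep[upper.tri(sep)])
  if (minsep == 0) stop("coincident medoids; Xie-Beni undefined",
                        call. = FALSE)
  within <- sum(D[cbind(seq_len(n), med[result$assignment])]^2)
  within / (n * minsep^2)
}

#' @rdname dunn_index
#' @export
wemmert_gancarski_index <- function(dm, result) {
  D <- as.matrix(dm)
  med <- result$medoids
  n <- length(result$assignment)
  total <- 0
  for (g in seq_along(med)) {
    idx <- which(result$assignment == g)
    down <- D[idx, med[g]]
    others <- D[idx, med[-g], drop = FALSE]
    nearest <- apply(others, 1L, min)
    ratio <- ifelse(nearest == 0, Inf, down / nearest)
    total <- total + length(idx) * max(0, 1 - mean(ratio))
  }
  total / n
}

index_direction <- function(index_name) {
  switch(index_name,
         dunn = , silhouette = , wemmert_gancarski = "max",
         xie_beni = "min",
         stop("unknown index: ", index_name, call. = FALSE))
}

score_index <- function(dm, result, index_name) {
  switch(index_name,
         dunn = dunn_index(dm, result$assignment),
         silhouette = silhouette_index(dm, result$assignment),
         xie_beni = xie_beni_index(dm, result),
         wemmert_gancarski = wemmert_gancarski_index(dm, result))
}

#' Select the number of clusters with an internal index
#'
#' Scores each candidate clustering with the chosen internal index and
#' returns the one attaining the extremum in the index's direction (maximum
#' for Dunn/Silhouette/Wemmert-Gancarski, minimum for Xie-Beni). Ties break
#' toward the smaller number of clusters; candidates whose index is
#' undefined (e.g. coincident medoids) are dropped.
#'
#' @param dm The distance matrix the clusterings were built on.
#' @param results List of `pam_clustering`s, e.g. from [pam_sweep()].
#' @param index_name One of `"dunn"`, `"silhouette"`, `"xie_beni"`,
#'   `"wemmert_gancarski"`.
#' @return List with `best` (the selected `pam_clustering`) and `scores`
#'   (tibble of k, score, selected).
#' @export
select_k <- function(dm, results, index_name = "dunn") {
  stopifnot(length(results) >= 1L)
  dir <- index_direction(index_name)
  scores <- vapply(results, function(r) {
    tryCatch(score_index(dm, r, index_name), error = function(e) NA_real_)
  }, numeric(1L))
  ks <- vapply(results, function(r) r$k, integer(1L))
  ord <- order(if (dir == "max") -scores else scores, ks, na.last = TRUE)
  best <- ord[1L]
  if (is.na(scores[best])) {
    stop("index '", index_name, "' undefined for every candidate",
         call. = FALSE)
  }
  list(best = results[[best]],
       scores = tibble::tibble(k = ks, index = index_name, score = scores,
                               selected = seq_along(results) == best))
}

# external validation ----------------------------------------------------------

# All injective mappings from the smaller side (clusters or classes) into the
# larger, scored on the confusion matrix by depth-first enumeration.
best_injective_matching <- function(conf, max_mappings = 1e6) {
  small_in_rows <- nrow(conf) <= ncol(conf)
  A <- if (small_in_rows) conf else t(conf)
  ns <- nrow(A); nl <- ncol(A)
  n_maps <- prod(nl - seq_len(ns) + 1)
  if (n_maps > max_mappings) {
    stop(sprintf("exhaustive matching refused: %d x %d needs %g mappings",
                 nrow(conf), ncol(conf), n_maps), call. = FALSE)
  }
  best <- list(hits = -1, map = integer(0))
  recurse <- function(level, used, map, hits) {
    if (level > ns) {
      if (hits > best$hits) best <<- list(hits = hits, map = map)
      return()
    }
    for (tgt in seq_len(nl)) {
      if (used[tgt]) next
      used[tgt] <- TRUE
      recurse(level + 1L, used, c(map, tgt), hits + A[level, tgt])
      used[tgt] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nl), integer(0), 0)
  if (small_in_rows) {
    cbind(row = seq_len(ns), col = best$map)
  } else {
    cbind(row = best$map, col = seq_len(ns))
  }
}

#' Matched accuracy and Jaccard index against known labels
#'
#' External validation of a clustering. The predicted clusters are matched to
#' the true classes by the injective mapping that maximises the number of
#' correctly placed samples: when there are fewer clusters than classes every
#' cluster is mapped to some class, when there are more, the best subset of
#' clusters is matched and samples in unmatched clusters count as errors.
#' `accuracy` is the maximised fraction of correct samples. `jaccard` is the
#' unweighted mean over matched (cluster, class) pairs of
#' `|intersection| / |union|`; under balanced two-class symmetric errors it
#' equals `a / (2 - a)` for accuracy `a`.
#'
#' @param predicted Integer cluster assignment (or a `pam_clustering`).
#' @param truth Integer class labels, same length/samples, or a label tibble
#'   from [read_labels()].
#' @param max_mappings Cap on the exhaustive matching enumeration.
#' @return A one-row tibble with `accuracy`, `jaccard`, `n_clusters`,
#'   `n_classes`, and the `matching` as a list column (tibble of cluster,
#'   class).
#' @export
external_scores <- function(predicted, truth, max_mappings = 1e6) {
  if (inherits(predicted, "pam_clustering")) predicted <- predicted$assignment
  if (is.data.frame(truth)) truth <- truth$label
  stopifnot(length(predicted) == length(truth))
  pc <- as.integer(factor(predicted)); tc <- as.integer(factor(truth))
  conf <- as.matrix(table(pc, tc))
  m <- best_injective_matching(conf, max_mappings)
  hits <- sum(conf[m])
  jac <- apply(m, 1L, function(pr) {
    inter <- conf[pr[1L], pr[2L]]
    uni <- sum(conf[pr[1L], ]) + sum(conf[, pr[2L]]) - inter
    if (uni == 0) 0 else inter / uni
  })
  tibble::tibble(
    accuracy = hits / length(predicted),
    jaccard = mean(jac),
    n_clusters = nrow(conf),
    n_classes = ncol(conf),
    matching = list(tibble::tibble(
      cluster = sort(unique(predicted))[m[, 1L]],
      class = sort(unique(truth))[m[, 2L]])))
}

#' @rdname external_scores
#' @export
matched_accuracy <- function(predicted, truth, max_mappings = 1e6) {
  external_scores(predicted, truth, max_mappings)$accuracy
}

#' @rdname external_scores
#' @export
jaccard_score <- function(predicted, truth, max_mappings = 1e6) {
  external_scores(predicted, truth, max_mappings)$jaccard
}
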