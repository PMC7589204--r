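#' Partitioning Around Medoids on a precomputed distance matrix
#'
#' Picks `k` samples as medoids minimising the sum of distances from every
#' sample to its nearest medoid, by the classical two-phase procedure: an
#' initialisation followed by a steepest-descent swap phase that evaluates
#' every (medoid, non-medoid) exchange and applies the single most
#' cost-reducing one per iteration until no strict improvement exists. Ties
#' — nearest-medoid assignment and equal-cost swaps alike — break toward the
#' lowest index.
#'
#' The swap phase is a hill climber, so a single start can stall in a local
#' optimum. With `init = "build"` (default) the deterministic greedy BUILD
#' start is supplemented by `restarts` seeded random starts and the
#' lowest-cost local optimum is returned; `init = "random"` uses random
#' starts only, as in the classical description. The whole procedure is
#' deterministic given `seed` (a `NULL` seed behaves as seed 0 for the
#' restart draws, leaving the caller's RNG state untouched).
#'
#' @param dm A `micro_dist` or square distance matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @param init `"build"` (default) or `"random"`.
#' @param seed Integer seed for the random starts.
#' @param restarts Number of random starts added to the initialisation,
#'   default 5.
#' @param max_iter Safety bound on swap iterations per start.
#' @return Object of class `pam_clustering`: `k`, `medoids` (sample
#'   indices), `assignment` (cluster ids 1..k, named by sample), `total_cost`,
#'   `iterations`, `init`, `seed`.
#' @export
pam_cluster <- function(dm, k, init = c("build", "random"), seed = NULL,
                        restarts = 5L, max_iter = 200L) {
  D <- as.matrix(dm)
  n <- nrow(D)
  init <- match.arg(init)
  if (k < 2L || k >= n) stop("need 2 <= k < n", call. = FALSE)
  seed <- seed %||% 0L
  starts <- list()
  if (init == "build") starts[[1L]] <- pam_build(D, k)
  n_random <- restarts + as.integer(init == "random")
  if (n_random > 0L) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    for (r in seq_len(n_random)) {
      starts[[length(starts) + 1L]] <- sort(sample.int(n, k))
    }
  }
  best <- NULL
  for (medoids in starts) {
    res <- pam_swap(D, medoids, max_iter)
    if (is.null(best) || res$cost < best$cost - 1e-12) best <- res
  }
  Dm <- D[, best$medoids, drop = FALSE]
  assignment <- max.col(-Dm, ties.method = "first")
  names(assignment) <- rownames(D)
  structure(list(k = as.integer(k), medoids = best$medoids,
                 assignment = assignment,
                 total_cost = sum(Dm[cbind(seq_len(n), assignment)]),
                 iterations = best$iterations, init = init, seed = seed,
                 metric = if (inherits(dm, "micro_dist")) dm$metric else NA),
            class = "pam_clustering")
}

# steepest-descent swap phase from a fixed set of starting medoids
pam_swap <- function(D, medoids, max_iter = 200L) {
  n <- nrow(D)
  cost <- pam_cost(D, medoids)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Dm <- D[, medoids, drop = FALSE]
    near <- max.col(-Dm, ties.method = "first")
    d1 <- Dm[cbind(seq_len(n), near)]
    d2 <- apply(Dm, 1L, function(r) sort(r, partial = 2L)[2L])
    best <- list(cost = cost, m = NA_integer_, j = NA_integer_)
    others <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      base <- ifelse(near == mi, d2, d1)
      cand_cost <- colSums(pmin(D[, others, drop = FALSE], base))
      b <- which.min(cand_cost)          # first minimum = lowest index
      if (cand_cost[b] < best$cost - 1e-12) {
        best <- list(cost = cand_cost[b], m = mi, j = others[b])
      }
    }
    if (is.na(best$m) || iter > max_iter) break
    stopifnot(best$cost <= cost + 1e-12)  # swap phase never increases cost
    medoids[best$m] <- best$j
    medoids <- sort(medoids)
    cost <- pam_cost(D, medoids)
  }
  list(medoids = medoids, cost = cost, iterations = iter)
}

pam_cost <- function(D, medoids) {
  sum(apply(D[, medoids, drop = FALSE], 1L, min))
}

# Greedy BUILD initialisation: start from the most central point, then add
# the medoid giving the largest cost reduction, ties toward the lowest index.
pam_build <- function(D, k) {
  n <- nrow(D)
  medoids <- which.min(colSums(D))
  dnear <- D[, medoids]
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(0, dnear - D[, j]))
    }, numeric(1L))
    j <- which.max(gain)
    medoids <- c(medoids, j)
    dnear <- pmin(dnear, D[, j])
  }
  sort(medoids)
}

#' Run PAM over a range of cluster counts
#'
#' @param dm A `micro_dist` or square distance matrix.
#' @param k_range Integer vector of cluster counts, default `2:10`.
#' @inheritParams pam_cluster
#' @return Named list of `pam_clustering` results, one per `k`.
#' @export
pam_sweep <- function(dm, k_range = 2:10, init = "build", seed = NULL,
                      restarts = 2L) {
  n <- nrow(as.matrix(dm))
  k_range <- k_range[k_range >= 2L & k_range < n]
  stopifnot(length(k_range) >= 1L)
  res <- lapply(k_range, function(k) {
    pam_cluster(dm, k, init = init, restarts = restarts,
                seed = if (is.null(seed)) NULL else seed + k)
  })
  names(res) <- paste0("k", k_range)
  res
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat(sprintf("<pam_clustering> k = %d, total cost %.4g, %d iterations\n",
              x$k, x$total_cost, x$iterations))
  cat("cluster sizes:", table(x$assignment), "\n")
  invisible(x)
}

#' @rdname tidy.micro_dist
#' @method tidy pam_clustering
#' @export
tidy.pam_clustering <- function(x, ...) {
  tibble::tibble(sample_id = names(x$assignment) %||%
                   as.character(seq_along(x$assignment)),
                 cluster = unname(x$assignment),
                 is_medoid = seq_along(x$assignment) %in% x$medoids)
}

#' @rdname tidy.micro_dist
#' @method glance pam_clustering
#' @export
glance.pam_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, total_cost = x$total_cost,
                 iterations = x$iterations, init = x$init,
                 metric = x$metric)
}
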