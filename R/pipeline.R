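metric_registry <- c("l2_d_pdf", "l2_d_cdf", "l2_c_cdf",
                     "manhattan", "euclidean", "bray_curtis",
                     "wunifrac", "gunifrac",
                     "manhattan_log", "euclidean_log", "bray_curtis_log")

parse_metric <- function(metric) {
  metric <- match.arg(metric, metric_registry)
  list(base = sub("_log$", "", metric),
       log = grepl("_log$", metric),
       mixture = grepl("^l2_", metric),
       name = metric)
}

#' Compute a sample distance matrix under any supported metric
#'
#' Dispatcher covering the three mixture-model L2 norms, the classical
#' metrics on relative abundances (optionally log-transformed), and the two
#' UniFrac variants.
#'
#' @param table Count tibble or matrix.
#' @param metric One of `r paste0('"', c("l2_d_pdf", "l2_d_cdf", "l2_c_cdf",
#'   "manhattan", "euclidean", "bray_curtis", "wunifrac", "gunifrac",
#'   "manhattan_log", "euclidean_log", "bray_curtis_log"), '"', collapse = ", ")`.
#' @param tree Rooted phylogeny, required for the UniFrac metrics.
#' @param fits Optional per-OTU mixture fits (reused for the L2 metrics).
#' @param combine Cross-OTU rule for the L2 metrics.
#' @param epsilon Denominator guard for ratio metrics.
#' @param pseudo Pseudo-count for the log transform.
#' @param ... Passed to [fit_all_otus()] when mixtures must be fitted.
#' @return A `micro_dist`.
#' @export
compute_distance <- function(table, metric, tree = NULL, fits = NULL,
                             combine = "l2", epsilon = 1e-8, pseudo = 1e-8,
                             ...) {
  spec <- parse_metric(metric)
  if (spec$mixture) {
    return(mixture_distance(table, spec$base, fits = fits,
                            combine = combine, ...))
  }
  ra <- suppressWarnings(to_relative_abundance(table))
  if (spec$base %in% c("wunifrac", "gunifrac")) {
    if (is.null(tree)) stop("tree required for UniFrac metrics", call. = FALSE)
    return(switch(spec$base,
                  wunifrac = dist_weighted_unifrac(ra, tree, epsilon),
                  gunifrac = dist_generalized_unifrac(ra, tree,
                                                      epsilon = epsilon)))
  }
  if (spec$log) ra <- log_transform(ra, pseudo)
  out <- switch(spec$base,
                manhattan = dist_manhattan(ra),
                euclidean = dist_euclidean(ra),
                bray_curtis = dist_bray_curtis(ra, epsilon))
  out$metric <- spec$name
  out
}

#' Cluster a count table end to end
#'
#' The full pipeline for one metric: (for mixture metrics) per-OTU bootstrap
#' model selection and weight estimation, subject-specific mixtures and L2
#' distances combined across OTUs — or the requested baseline distance —
#' followed by a PAM sweep over `k_range` and internal-index selection of
#' the number of clusters. Deterministic given `seed`.
#'
#' @inheritParams compute_distance
#' @param k_range Candidate cluster counts, default `2:10`.
#' @param index Internal index used to pick `k`, default `"dunn"`.
#' @param restarts Random PAM restarts added to the deterministic BUILD
#'   start; 0 (default) keeps the sweep fully deterministic and fast on
#'   hundreds of samples.
#' @param truth Optional known labels (vector or tibble) for external
#'   scoring.
#' @param B Bootstrap replicates per OTU for mixture metrics.
#' @param seed Optional seed driving mixture fitting.
#' @param ... Passed to [fit_all_otus()].
#' @return Object of class `clustering_run`: `best` (`pam_clustering`),
#'   `scores` (per-k index tibble), `distance`, `metric`, and `external`
#'   (one-row score tibble, when `truth` was given).
#' @export
run_clustering <- function(table, metric = "l2_d_pdf", tree = NULL,
                           k_range = 2:10, index = "dunn", truth = NULL,
                           fits = NULL, B = 10L, combine = "l2",
                           epsilon = 1e-8, pseudo = 1e-8, seed = NULL,
                           restarts = 0L, ...) {
  dm <- compute_distance(table, metric, tree = tree, fits = fits,
                         combine = combine, epsilon = epsilon,
                         pseudo = pseudo, B = B, seed = seed, ...)
  sweep <- pam_sweep(dm, k_range, restarts = restarts)
  sel <- select_k(dm, sweep, index)
  external <- if (!is.null(truth)) external_scores(sel$best, truth)
  structure(list(best = sel$best, scores = sel$scores, distance = dm,
                 metric = metric, index = index, external = external),
            class = "clustering_run")
}

#' @export
print.clustering_run <- function(x, ...) {
  cat(sprintf("<clustering_run> metric %s, %s-selected k = %d\n",
              x$metric, x$index, x$best$k))
  if (!is.null(x$external)) {
    cat(sprintf("  external: accuracy %.3f, jaccard %.3f\n",
                x$external$accuracy, x$external$jaccard))
  }
  invisible(x)
}

#' @rdname tidy.micro_dist
#' @method tidy clustering_run
#' @export
tidy.clustering_run <- function(x, ...) tidy(x$best)

#' @rdname tidy.micro_dist
#' @method glance clustering_run
#' @export
glance.clustering_run <- function(x, ...) {
  out <- tibble::tibble(metric = x$metric, index = x$index, k = x$best$k,
                        total_cost = x$best$total_cost)
  if (!is.null(x$external)) {
    out$accuracy <- x$external$accuracy
    out$jaccard <- x$external$jaccard
  }
  out
}

#' Replicated simulation study
#'
#' Repeats: simulate a dataset under one scenario, run every requested
#' metric on the same dataset (mixture fits are shared across the L2
#' metrics), select k by the internal index, and score against the true
#' subclass labels. Summaries are the per-metric mean accuracy (MA), mean
#' Jaccard index (MJI) and mean selected k over completed replicates.
#'
#' @param n_subclasses,subclass_size,n_otus,tier,subclass_mode Scenario
#'   definition, see [simulate_dataset()].
#' @param metrics Character vector of metric names (see
#'   [compute_distance()]).
#' @param n_replicates Number of replicate datasets.
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`.
#' @param B,c_mid,high_knots Mixture fitting configuration.
#' @param k_range,index Clustering sweep configuration.
#' @param sim_args Named list of further arguments to [simulate_dataset()]
#'   (e.g. `mean_range`, `shape_values`).
#' @return Object of class `simulation_study`: `replicates` (one row per
#'   replicate x metric) and `summary` (per-metric MA/MJI/mean k).
#' @export
run_simulation_study <- function(n_subclasses = 2L, tier = "high",
                                 metrics = c("l2_d_pdf", "manhattan"),
                                 n_replicates = 20L, base_seed = 1L,
                                 subclass_size = 200L, n_otus = 25L,
                                 subclass_mode = "shared",
                                 B = 10L, c_mid = c(5L, 10L),
                                 high_knots = 5L,
                                 k_range = 2:10, index = "dunn",
                                 sim_args = list()) {
  metrics <- vapply(metrics, function(m) parse_metric(m)$name, character(1L))
  need_fits <- any(grepl("^l2_", metrics))
  need_tree <- any(metrics %in% c("wunifrac", "gunifrac"))
  rows <- list()
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      ds <- do.call(simulate_dataset,
                    c(list(n_subclasses = n_subclasses,
                           subclass_size = subclass_size, n_otus = n_otus,
                           tier = tier, seed = base_seed + r,
                           subclass_mode = subclass_mode), sim_args))
      tree <- if (need_tree) {
        simulate_tree(colnames(count_matrix(ds$table)),
                      seed = base_seed + r)
      }
      fits <- if (need_fits) {
        fit_all_otus(ds$table, B = B, c_mid = c_mid,
                     high_knots = high_knots, seed = base_seed + r)
      }
      purrr::map_dfr(metrics, function(m) {
        run <- run_clustering(ds$table, m, tree = tree, fits = fits,
                              k_range = k_range, index = index,
                              truth = ds$truth)
        tibble::tibble(replicate = r, metric = m, k = run$best$k,
                       accuracy = run$external$accuracy,
                       jaccard = run$external$jaccard,
                       mean_zp = mean(ds$realized_zp))
      })
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    stop("every replicate failed; see warnings", call. = FALSE)
  }
  replicates <- dplyr::bind_rows(rows)
  summary <- replicates |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_accuracy = mean(.data$accuracy),
                     mean_jaccard = mean(.data$jaccard),
                     mean_k = mean(.data$k),
                     .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 scenario = list(n_subclasses = n_subclasses, tier = tier,
                                 subclass_size = subclass_size,
                                 n_otus = n_otus, index = index, B = B,
                                 base_seed = base_seed,
                                 n_replicates = n_replicates,
                                 failures = failures)),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("<simulation_study> %d subclasses, %s ZP, %d replicates\n",
              x$scenario$n_subclasses, x$scenario$tier,
              x$scenario$n_replicates))
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.micro_dist
#' @method tidy simulation_study
#' @export
tidy.simulation_study <- function(x, ...) x$replicates

#' @rdname tidy.micro_dist
#' @method glance simulation_study
#' @export
glance.simulation_study <- function(x, ...) x$summary

#' Rank OTUs by between-cluster difference
#'
#' Two-sample Wilcoxon rank-sum tests (Kruskal-Wallis for more than two
#' clusters) on relative abundances per OTU, Benjamini-Hochberg adjusted
#' and ranked, with per-cluster location/spread summaries in the customary
#' mean (sd) / median (min, max) layout.
#'
#' @param table Count tibble or matrix.
#' @param assignment Cluster ids per sample (or a `pam_clustering`).
#' @return Tibble, one row per OTU, ordered by adjusted p-value.
#' @export
differential_otus <- function(table, assignment) {
  if (inherits(assignment, "pam_clustering")) assignment <- assignment$assignment
  ra <- count_matrix(suppressWarnings(to_relative_abundance(table)))
  cl <- sort(unique(assignment))
  if (min(table(assignment)) < 2L) {
    stop("every cluster needs at least 2 samples", call. = FALSE)
  }
  res <- purrr::map_dfr(colnames(ra), function(otu) {
    x <- ra[, otu]
    p <- if (length(cl) == 2L) {
      suppressWarnings(stats::wilcox.test(x[assignment == cl[1L]],
                                          x[assignment == cl[2L]]))$p.value
    } else {
      stats::kruskal.test(x, factor(assignment))$p.value
    }
    row <- tibble::tibble(otu = otu, p_value = p)
    for (g in cl) {
      xg <- x[assignment == g]
      row[[sprintf("cluster%s_mean_sd", g)]] <-
        sprintf("%.4g (%.4g)", mean(xg), stats::sd(xg))
      row[[sprintf("cluster%s_median_range", g)]] <-
        sprintf("%.4g (%.4g, %.4g)", stats::median(xg), min(xg), max(xg))
    }
    row
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  dplyr::arrange(res, .data$p_adjusted, .data$p_value)
}
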