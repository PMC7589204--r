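#' Zero-proportion tier definitions
#'
#' The simulator targets three sparsity regimes, defined by the realized
#' fraction of zero entries per OTU (structural zeros plus sampling zeros
#' from low-rate components): low 13-27%, medium 39-61%, high 84-93%.
#' Sparsity is also the sub-class signal: within a tier each subclass draws
#' its per-OTU structural-zero weight from its own Beta distribution, whose
#' mean places that subclass at an evenly spaced realized-ZP level inside
#' the tier interval (see [subclass_z_params()]). Rejection-resampling then
#' enforces the interval on every OTU's realized zero proportion.
#'
#' @param tier `"low"`, `"medium"` or `"high"`.
#' @return List with `interval`, the target realized-ZP interval.
#' @export
zp_tier <- function(tier = c("high", "medium", "low")) {
  tier <- match.arg(tier)
  switch(tier,
    high   = list(interval = c(0.84, 0.93)),
    medium = list(interval = c(0.39, 0.61)),
    low    = list(interval = c(0.13, 0.27)))
}

#' Per-subclass Beta parameters for the structural-zero weight
#'
#' The subclass realized-ZP targets are spread evenly across the tier
#' interval including its endpoints (`lo` and `lo + width` for two
#' subclasses), reading the printed tier ranges as the between-subclass
#' sparsity spread — sparsity is the sub-class signal.
#' The structural-zero mean is back-computed by discounting the average
#' sampling-zero probability of the positive mixture part (0.081 under the
#' default component distribution, measured once by Monte Carlo at design
#' time), and the Beta standard deviation is an eighth of the interval
#' width so per-OTU draws stay inside the tier.
#'
#' @param tier Tier name or [zp_tier()] list.
#' @param n_subclasses Number of subclasses.
#' @param sampling_zero Mean sampling-zero probability of the positive
#'   mixture part.
#' @param spread Interval-width-to-sd divisor, default 8.
#' @return List of length `n_subclasses`, each with `alpha` and `beta`.
#' @export
subclass_z_params <- function(tier, n_subclasses, sampling_zero = 0.081,
                              spread = 8) {
  if (is.character(tier)) tier <- zp_tier(tier)
  lo <- tier$interval[1L]; width <- diff(tier$interval)
  lapply(seq_len(n_subclasses), function(c_id) {
    target <- if (n_subclasses == 1L) lo + width / 2 else
      lo + width * (c_id - 1) / (n_subclasses - 1)
    m <- (target - sampling_zero) / (1 - sampling_zero)
    stopifnot(m > 0, m < 1)
    s <- (width / spread) / (1 - sampling_zero)
    conc <- max(m * (1 - m) / s^2 - 1, 2)
    list(alpha = m * conc, beta = (1 - m) * conc)
  })
}

# Draw a random Gamma-component family for one OTU: M - 1 components with
# means log-uniform over mean_range and small integer shapes, plus Dirichlet
# relative weights. These are the population rate components the mixture
# model later approximates.
draw_components <- function(M, mean_range = c(2, 20), shape_values = 1:5) {
  means <- exp(stats::runif(M - 1L, log(mean_range[1L]), log(mean_range[2L])))
  shapes <- if (length(shape_values) == 1L) rep(shape_values, M - 1L) else
    sample(shape_values, M - 1L, replace = TRUE)
  u <- stats::rgamma(M - 1L, 1)
  list(means = means, shapes = shapes, rates = shapes / means, u = u / sum(u))
}

#' Simulate one OTU across labelled subclasses
#'
#' One OTU's counts for all subjects: per subclass the structural-zero
#' weight `z_c` is drawn from the tier's Beta distribution; subjects are
#' allocated by a multinomial draw over the mixture weights
#' `(z_c, (1 - z_c) * u)`; non-zero subjects draw a rate from their Gamma
#' component and an observed count from `Poisson(rate * t_i)`.
#'
#' By default (`subclass_mode = "shared"`) the Gamma components and their
#' relative weights `u` are drawn once and shared by all subclasses, so the
#' only systematic between-subclass signal is the difference in
#' structural-zero weights — the sparsity-driven regime the mixture
#' distances are designed to detect. `"independent"` redraws the entire
#' mixture per subclass, giving strongly separated subclasses.
#'
#' @param labels Integer subclass label per subject.
#' @param t Relative resolution per subject.
#' @param z_params Per-subclass Beta parameters for the structural-zero
#'   weight, see [subclass_z_params()].
#' @param subclass_mode `"shared"` or `"independent"`.
#' @param n_components_range Range for the mixture size `M` (uniform draw),
#'   default 5..15.
#' @param mean_range,shape_values Component parameter pools, see
#'   [draw_components()].
#' @return List with `counts` (integer vector) and `record` (the generating
#'   mixture: per-subclass `z`, shared or per-subclass components, `M`).
#' @export
simulate_otu <- function(labels, t, z_params,
                         subclass_mode = c("shared", "independent"),
                         n_components_range = c(5L, 15L),
                         mean_range = c(2, 20), shape_values = 1:5) {
  subclass_mode <- match.arg(subclass_mode)
  stopifnot(length(labels) == length(t))
  classes <- sort(unique(labels))
  stopifnot(length(z_params) >= length(classes))
  M_pool <- seq(n_components_range[1L], n_components_range[2L])
  M <- if (length(M_pool) == 1L) M_pool else sample(M_pool, 1L)
  shared <- if (subclass_mode == "shared") {
    draw_components(M, mean_range, shape_values)
  }
  counts <- integer(length(labels))
  rec <- list(M = M, subclass_mode = subclass_mode, subclasses = list())
  for (c_id in classes) {
    idx <- which(labels == c_id)
    comp <- shared %||% draw_components(M, mean_range, shape_values)
    zp_c <- z_params[[match(c_id, classes)]]
    z <- stats::rbeta(1L, zp_c$alpha, zp_c$beta)
    w <- c(z, (1 - z) * comp$u)
    alloc <- sample.int(M, length(idx), replace = TRUE, prob = w)
    r <- numeric(length(idx))
    pos <- alloc > 1L
    if (any(pos)) {
      g <- alloc[pos] - 1L
      r[pos] <- stats::rgamma(sum(pos), shape = comp$shapes[g],
                              rate = comp$rates[g])
    }
    counts[idx] <- stats::rpois(length(idx), r * t[idx])
    rec$subclasses[[as.character(c_id)]] <-
      list(z = z, weights = w, components = comp, allocation = alloc)
  }
  list(counts = counts, record = rec)
}

#' Simulate a sub-class structured OTU count dataset
#'
#' Generates `n_otus` independent OTUs over balanced subclasses under the
#' chosen zero-proportion tier, with per-subject relative resolutions drawn
#' from `Uniform(2/3, 4/3)` and rejection-resampling of each OTU (up to
#' `max_attempts` draws) until its realized zero proportion falls inside the
#' tier interval.
#'
#' @param n_subclasses Number of subclasses (2 or 3 in the reference study).
#' @param subclass_size Subjects per subclass, default 200.
#' @param n_otus Number of OTUs, default 25.
#' @param tier Zero-proportion tier: `"high"`, `"medium"`, `"low"`.
#' @param seed Optional integer seed.
#' @param resolution_range Range of the Uniform resolution draw.
#' @param max_attempts Rejection cap per OTU.
#' @inheritParams simulate_otu
#' @return Object of class `simulated_dataset`: `table` (count tibble),
#'   `truth` (tibble of `sample_id`, `label`), `t` (true resolutions),
#'   `mixtures` (per-OTU generating records), `realized_zp`, `tier`.
#' @export
simulate_dataset <- function(n_subclasses = 2L, subclass_size = 200L,
                             n_otus = 25L, tier = "high", seed = NULL,
                             subclass_mode = c("shared", "independent"),
                             n_components_range = c(5L, 15L),
                             mean_range = c(2, 20), shape_values = 1:5,
                             resolution_range = c(2 / 3, 4 / 3),
                             max_attempts = 100L) {
  subclass_mode <- match.arg(subclass_mode)
  if (!is.null(seed)) set.seed(seed)
  tier_name <- if (is.character(tier)) match.arg(tier, c("high", "medium", "low")) else "custom"
  tier_def <- if (is.character(tier)) zp_tier(tier) else tier
  z_params <- subclass_z_params(tier_def, n_subclasses)
  n <- n_subclasses * subclass_size
  labels <- rep(seq_len(n_subclasses), each = subclass_size)
  t <- stats::runif(n, resolution_range[1L], resolution_range[2L])
  counts <- matrix(0L, n, n_otus)
  mixtures <- vector("list", n_otus)
  zp <- numeric(n_otus)
  for (j in seq_len(n_otus)) {
    for (attempt in seq_len(max_attempts)) {
      sim <- simulate_otu(labels, t, z_params, subclass_mode,
                          n_components_range, mean_range, shape_values)
      realized <- mean(sim$counts == 0)
      if (realized >= tier_def$interval[1L] &&
          realized <= tier_def$interval[2L]) break
      if (attempt == max_attempts) {
        stop("rejection cap exceeded for OTU ", j,
             "; recalibrate the tier's Beta parameters", call. = FALSE)
      }
    }
    counts[, j] <- sim$counts
    mixtures[[j]] <- sim$record
    zp[j] <- realized
  }
  ids <- sprintf("s%03d", seq_len(n))
  rownames(counts) <- ids
  colnames(counts) <- sprintf("OTU%02d", seq_len(n_otus))
  structure(list(table = count_tbl(counts),
                 truth = tibble::tibble(sample_id = ids, label = labels),
                 t = stats::setNames(t, ids),
                 mixtures = mixtures, realized_zp = zp,
                 tier = tier_name, seed = seed,
                 subclass_mode = subclass_mode),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("<simulated_dataset> %d samples x %d OTUs, %d ",
                     "subclasses, %s ZP (realized %.2f-%.2f)\n"),
              nrow(x$truth), length(x$realized_zp),
              length(unique(x$truth$label)), x$tier,
              min(x$realized_zp), max(x$realized_zp)))
  invisible(x)
}

#' Simulate a random rooted phylogeny over OTUs
#'
#' Random bifurcating topology (sequential random joins via [ape::rtree()])
#' with exponential branch lengths of mean one; used to exercise the UniFrac
#' baselines, which need a tree the simulation itself has no biology for.
#'
#' @param otu_ids Character vector of leaf names (length >= 2).
#' @param seed Optional seed.
#' @return A rooted [ape::phylo] with `length(otu_ids)` leaves.
#' @export
simulate_tree <- function(otu_ids, seed = NULL) {
  stopifnot(length(otu_ids) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(length(otu_ids), rooted = TRUE, br = stats::rexp)
  tree$tip.label <- sample(otu_ids)
  tree
}
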