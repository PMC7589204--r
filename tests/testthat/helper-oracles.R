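# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities from first principles rather
# than calling package internals.

# random Euclidean point cloud -> distance matrix (guaranteed metric)
random_points_dist <- function(n, seed, dim = 2L) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n, dim)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", seq_len(n))
  D
}

# all permutations of a vector (small n only)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# exhaustive PAM: minimum total cost over all medoid subsets of size k
pam_exhaustive_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1L, min))
    best <- min(best, cost)
  }
  best
}

dunn_oracle <- function(D, cl) {
  ids <- unique(cl)
  diam <- 0
  for (g in ids) {
    idx <- which(cl == g)
    if (length(idx) > 1L) diam <- max(diam, max(D[idx, idx]))
  }
  sep <- Inf
  for (g1 in ids) for (g2 in ids) {
    if (g1 < g2) sep <- min(sep, min(D[cl == g1, cl == g2]))
  }
  sep / diam
}

silhouette_oracle <- function(D, cl) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(cl == cl[i] & seq_len(n) != i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) b <- min(b, mean(D[i, cl == g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

xie_beni_oracle <- function(D, cl, medoids) {
  n <- length(cl)
  within <- 0
  for (i in seq_len(n)) within <- within + D[i, medoids[cl[i]]]^2
  minsep <- Inf
  for (g1 in seq_along(medoids)) for (g2 in seq_along(medoids)) {
    if (g1 < g2) minsep <- min(minsep, D[medoids[g1], medoids[g2]])
  }
  within / (n * minsep^2)
}

wg_oracle <- function(D, cl, medoids) {
  n <- length(cl)
  total <- 0
  for (g in seq_along(medoids)) {
    idx <- which(cl == g)
    ratios <- vapply(idx, function(i) {
      D[i, medoids[g]] / min(D[i, medoids[-g]])
    }, numeric(1L))
    total <- total + length(idx) * max(0, 1 - mean(ratios))
  }
  total / n
}

# best matched accuracy by enumerating injective maps of the smaller side
accuracy_oracle <- function(pred, truth) {
  conf <- as.matrix(table(pred, truth))
  if (nrow(conf) <= ncol(conf)) {
    targets <- utils::combn(ncol(conf), nrow(conf), simplify = FALSE)
    best <- 0
    for (tg in targets) for (p in perms(tg)) {
      best <- max(best, sum(conf[cbind(seq_len(nrow(conf)), p)]))
    }
  } else {
    targets <- utils::combn(nrow(conf), ncol(conf), simplify = FALSE)
    best <- 0
    for (tg in targets) for (p in perms(tg)) {
      best <- max(best, sum(conf[cbind(p, seq_len(ncol(conf)))]))
    }
  }
  best / length(pred)
}

# fixture: a fitted-mixture-like object built from an explicit grid so that
# closed-form posterior checks are possible
manual_fit <- function(components, cutoff, weights, counts, t) {
  grid <- microclust:::new_component_grid(components, cutoff,
                                          c_mid = 1L, high_knots = 0L)
  structure(list(grid = grid, weights = weights,
                 tensor = microclust:::design_tensor(grid, t),
                 counts = counts, t = t,
                 sample_ids = paste0("s", seq_along(counts))),
            class = "otu_mixture_fit")
}

comp_row <- function(kind, shape = NA_real_, rate = NA_real_) {
  tibble::tibble(kind = kind, shape = shape, rate = rate,
                 mean = ifelse(kind == "gamma", shape / rate, NA_real_))
}

# simulate counts from an explicit (zero, gammas, high-free) mixture
simulate_from_mixture <- function(weights, shapes, rates, I, t = rep(1, I)) {
  comp <- sample(seq_along(weights), I, replace = TRUE, prob = weights)
  r <- numeric(I)
  pos <- comp > 1L
  r[pos] <- rgamma(sum(pos), shape = shapes[comp[pos] - 1L],
                   rate = rates[comp[pos] - 1L])
  rpois(I, r * t)
}

# two well-separated blob distance matrix
blob_dist <- function(n1 = 5L, n2 = 5L, within = 0.1, between = 10) {
  n <- n1 + n2
  D <- matrix(between, n, n)
  D[seq_len(n1), seq_len(n1)] <- within
  D[(n1 + 1L):n, (n1 + 1L):n] <- within
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("s", seq_len(n))
  D
}
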