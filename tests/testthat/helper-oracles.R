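# Independent oracles and fixture builders.  Everything here recomputes
# quantities from first principles (enumeration, literal definitions,
# pure-R re-tracing) so the implementation under test is never checking
# itself.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two-sided Fisher p by literal hypergeometric enumeration over all
# outcomes with fixed margins, summing those no more probable than the
# observed table.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Literal step-up definition of Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, m * ps[i:m] / (i:m)),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Re-trace one serialized tree for one encoded row, in pure R.
oracle_tree_leaf <- function(tree, xrow, ncat) {
  node <- 1L
  while (tree$var[node] >= 0) {
    v <- tree$var[node] + 1L
    go_left <- if (ncat[v] > 0) {
      bitwAnd(tree$mask[node], bitwShiftL(1L, as.integer(xrow[v]) - 1L)) > 0
    } else {
      xrow[v] <= tree$thr[node]
    }
    node <- (if (go_left) tree$left[node] else tree$right[node]) + 1L
  }
  node - 1L
}

# Proximity by independently re-tracing every row through every tree.
oracle_proximity <- function(forest) {
  n0 <- forest$n_original
  X <- forest$encoding$x[seq_len(n0), , drop = FALSE]
  ncat <- forest$encoding$ncat
  ntree <- length(forest$trees)
  P <- matrix(0, n0, n0)
  for (t in seq_len(ntree)) {
    lf <- vapply(seq_len(n0),
                 function(i) oracle_tree_leaf(forest$trees[[t]], X[i, ], ncat),
                 integer(1))
    P <- P + outer(lf, lf, "==")
  }
  P / ntree
}

# Exhaustive best Gini split over all (variable, midpoint cutpoint)
# candidates on continuous features, same tie-break as the grower
# (lowest variable index, lowest threshold; strict improvement 1e-12).
oracle_best_split <- function(X, y) {
  y <- as.integer(as.factor(y))
  m <- nrow(X)
  gini <- function(yy) {
    if (!length(yy)) return(0)
    p <- tabulate(yy, max(y)) / length(yy)
    1 - sum(p^2)
  }
  parent <- gini(y)
  best <- list(var = NA_integer_, thr = NA_real_, gain = -Inf)
  for (v in seq_len(ncol(X))) {
    xs <- sort(unique(X[, v]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- xs[i] + (xs[i + 1] - xs[i]) / 2
      l <- y[X[, v] <= thr]
      r <- y[X[, v] > thr]
      gain <- parent - (length(l) / m) * gini(l) - (length(r) / m) * gini(r)
      if (gain > best$gain + 1e-12)
        best <- list(var = v, thr = thr, gain = gain)
    }
  }
  best
}

pam_cost <- function(D, meds) sum(apply(D[, meds, drop = FALSE], 1, min))

absdiff_D <- function(pts) abs(outer(pts, pts, "-"))

# Random tiny instance with latent cluster structure (centers well
# separated relative to within-cluster spread), the regime the pipeline
# feeds PAM.
random_clusterable_instance <- function() {
  k <- sample(2:3, 1)
  n <- sample((k + 2):9, 1)
  centers <- matrix(rnorm(k * 2, sd = 4), k)
  pts <- centers[sample(k, n, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(n * 2), n)
  list(D = as.matrix(dist(pts)), k = k, n = n)
}

# Exhaustive optimal k-medoid cost.
oracle_pam_opt <- function(D, k) {
  min(combn(nrow(D), k, function(meds) pam_cost(D, meds)))
}

# TRUE iff some single (medoid, non-medoid) exchange strictly reduces
# cost.
has_improving_swap <- function(D, meds) {
  cur <- pam_cost(D, meds)
  for (m in meds)
    for (h in setdiff(seq_len(nrow(D)), meds))
      if (pam_cost(D, c(setdiff(meds, m), h)) < cur - 1e-12) return(TRUE)
  FALSE
}

tree_depth <- function(tree, node = 1L) {
  if (tree$var[node] < 0) return(0L)
  1L + max(tree_depth(tree, tree$left[node] + 1L),
           tree_depth(tree, tree$right[node] + 1L))
}

# A small deterministic, schema-complete cohort.
toy_cohort <- function(n = 8, seed = 1) {
  cfg <- preset("null_one_class", seed = seed)
  cfg$n_subjects <- as.integer(n)
  simulate_cohort(cfg)$cohort
}

# Two Gaussian blobs in 2-D.
make_blobs <- function(n_per = 50, centers = c(0, 10), sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    x <- data.frame(
      x1 = rnorm(2 * n_per, rep(centers, each = n_per), sd),
      x2 = rnorm(2 * n_per, rep(centers, each = n_per), sd))
    rownames(x) <- sprintf("r%03d", seq_len(2 * n_per))
    list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
  })
}
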