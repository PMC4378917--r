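#' Dissimilarity from a proximity matrix
#'
#' `D = 1 - P`: co-occurrence in terminal nodes turned into a
#' dissimilarity for medoid clustering and scaling.
#'
#' @param P proximity matrix (symmetric, unit diagonal, entries in
#'   \[0, 1\]).
#' @return Symmetric zero-diagonal dissimilarity matrix.
#' @export
as_dissimilarity <- function(P) {
  P <- unclass(P)
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  D <- 1 - P
  check_dissimilarity(D)
  D
}

check_dissimilarity <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D),
            isTRUE(all.equal(D, t(D), tolerance = 1e-8)),
            all(abs(diag(D)) < 1e-12))
  if (any(D < -1e-12)) stop("dissimilarities must be non-negative")
  invisible(D)
}

#' PAM BUILD phase
#'
#' Greedy seeding: the first medoid minimises total dissimilarity to all
#' rows; each subsequent medoid maximises the decrease in total cost.
#' Ties go to the lowest row index.
#'
#' @param D dissimilarity matrix.
#' @param k number of medoids, `1 <= k <= n`.
#' @return Integer vector of medoid row indices (selection order).
#' @export
pam_build <- function(D, k) {
  check_dissimilarity(D)
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must be in [1, n]")
  meds <- which.min(colSums(D))
  dmin <- D[, meds]
  while (length(meds) < k) {
    gains <- colSums(pmax(dmin - D, 0))
    gains[meds] <- -Inf
    h <- which.max(gains)
    meds <- c(meds, h)
    dmin <- pmin(dmin, D[, h])
  }
  as.integer(meds)
}

#' PAM SWAP phase
#'
#' Steepest descent: repeatedly applies the single (medoid, non-medoid)
#' exchange with the greatest cost reduction until no exchange strictly
#' reduces total cost.  Ties toward the lowest medoid index, then the
#' lowest candidate index.
#'
#' @param D dissimilarity matrix.
#' @param medoids starting medoid row indices.
#' @return An `rf_pam` clustering (local optimum), see [pam_cluster()].
#' @export
pam_swap <- function(D, medoids) {
  check_dissimilarity(D)
  n <- nrow(D)
  medoids <- as.integer(medoids)
  stopifnot(all(medoids >= 1), all(medoids <= n), !anyDuplicated(medoids))
  cost <- function(meds) sum(do.call(pmin, as.data.frame(D[, meds, drop = FALSE])))
  cur <- cost(medoids)
  repeat {
    best_delta <- 0
    best <- NULL
    for (m in sort(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- c(setdiff(medoids, m), h)
        delta <- cost(cand) - cur
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best <- c(m, h)
        }
      }
    }
    if (is.null(best)) break
    medoids <- c(setdiff(medoids, best[1]), best[2])
    cur <- cur + best_delta
  }
  finalize_pam(D, sort(medoids))
}

finalize_pam <- function(D, medoids) {
  n <- nrow(D)
  k <- length(medoids)
  Dm <- D[, medoids, drop = FALSE]
  assignment <- max.col(-Dm, ties.method = "first")
  assignment[medoids] <- seq_len(k)  # each medoid represents itself
  total_cost <- sum(Dm[cbind(seq_len(n), assignment)])
  structure(list(k = k, medoids = medoids, clustering = assignment,
                 total_cost = total_cost),
            class = "rf_pam")
}

#' Partitioning Around Medoids
#'
#' BUILD then SWAP on a precomputed dissimilarity matrix; fully
#' deterministic (all ties broken toward the lowest index), so repeated
#' runs agree without a seed.  Cluster indices are reported in order of
#' medoid row index.
#'
#' @param D dissimilarity matrix (e.g. `1 - proximity`).
#' @param k number of clusters, >= 1.
#' @return An `rf_pam` list: `k`, `medoids` (sorted row indices),
#'   `clustering` (per-row cluster index, nearest medoid, ties to the
#'   lowest medoid index) and `total_cost`.
#' @export
pam_cluster <- function(D, k) {
  pam_swap(D, pam_build(D, k))
}

#' @export
print.rf_pam <- function(x, ...) {
  cat("PAM clustering: k =", x$k, " medoids =", paste(x$medoids, collapse = ", "),
      sprintf(" total cost = %.4f\n", x$total_cost))
  print(table(cluster = x$clustering))
  invisible(x)
}
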