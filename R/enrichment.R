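#' Two-sided Fisher exact test on a 2x2 table
#'
#' The p-value sums, under the hypergeometric distribution with fixed
#' margins, the probabilities of all outcomes no more probable than the
#' observed one (within a small relative slack for floating-point ties).
#' The odds-ratio estimate is the conditional maximum-likelihood
#' estimate (0 when `a = 0`, `Inf` when `b = 0` or `c = 0` with the
#' complementary cells positive); the sample odds ratio `ad / bc` is
#' also returned for transparency.
#'
#' @param a,b,c,d cell counts: `a` in-class & trait present, `b`
#'   in-class & absent, `c` out-of-class & present, `d` out-of-class &
#'   absent.  Alternatively pass a 2x2 matrix as `a`.
#' @return List with `p`, `or_cmle`, `or_sample`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("empty table")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = "two.sided")
  or_sample <- (a * d) / (b * c)
  list(p = ft$p.value, or_cmle = unname(ft$estimate), or_sample = or_sample)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction:
#' `adjusted_(i) = min_{j >= i} (m * p_(j) / j)` on the sorted p-values,
#' capped at 1 and mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Class-versus-rest trait enrichment
#'
#' For every (class, trait) pair — including requested combination
#' traits — builds the in-class vs out-of-class 2x2 table, runs the
#' two-sided Fisher exact test, and adjusts all p-values in the run by
#' Benjamini-Hochberg.  The adjustment family is configurable: the
#' whole run (default, the widest defensible family) or per trait
#' across classes.
#'
#' @param cohort a `cf_cohort` (or a data frame of 0/1 trait columns).
#' @param clustering factor/vector of class labels per subject.
#' @param traits names of 0/1 trait variables to test.
#' @param combos optional list of length-2 character vectors; each pair
#'   is tested as its logical AND (named `"x_and_y"`).
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param family `"per_run"` (default) or `"per_trait"` BH family.
#' @return Data frame with one row per (class, trait): counts `a, b, c,
#'   d`, `or_cmle`, `or_sample`, `p_raw`, `p_bh`, `significant`, `note`.
#' @export
class_trait_enrichment <- function(cohort, clustering, traits,
                                   combos = NULL, alpha = 0.05,
                                   family = c("per_run", "per_trait")) {
  family <- match.arg(family)
  d <- if (inherits(cohort, "cf_cohort")) cohort$data else cohort
  clustering <- as.factor(clustering)
  stopifnot(length(clustering) == nrow(d))
  flags <- list()
  for (tr in traits) {
    if (!tr %in% names(d)) stop("trait '", tr, "' not in cohort")
    v <- as.numeric(d[[tr]])
    if (!all(v %in% c(0, 1))) stop("trait '", tr, "' is not a 0/1 flag")
    flags[[tr]] <- v
  }
  for (cb in combos) {
    stopifnot(length(cb) == 2, all(cb %in% names(flags)))
    flags[[paste(cb, collapse = "_and_")]] <-
      combo_trait(flags[[cb[1]]], flags[[cb[2]]])
  }
  rows <- list()
  for (cl in levels(clustering)) {
    inc <- clustering == cl
    for (tr in names(flags)) {
      f <- flags[[tr]]
      a <- sum(inc & f == 1); b <- sum(inc & f == 0)
      cc <- sum(!inc & f == 1); dd <- sum(!inc & f == 0)
      if (length(unique(f)) == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, trait = tr, a = a, b = b, c = cc, d = dd,
          or_cmle = 1, or_sample = NA_real_, p_raw = 1,
          note = "trait constant across cohort",
          stringsAsFactors = FALSE)
      } else {
        ft <- fisher_exact(a, b, cc, dd)
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, trait = tr, a = a, b = b, c = cc, d = dd,
          or_cmle = ft$or_cmle, or_sample = ft$or_sample, p_raw = ft$p,
          note = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- if (family == "per_run") bh_adjust(out$p_raw) else
    stats::ave(out$p_raw, out$trait, FUN = bh_adjust)
  out$significant <- out$p_bh < alpha
  out
}

#' Write an enrichment table (machine-readable class-vs-rest report)
#'
#' @param enr result of [class_trait_enrichment()].
#' @param path output CSV path.
#' @param k number of classes in the run (recorded in the table).
#' @export
write_enrichment <- function(enr, path, k = length(unique(enr$class))) {
  out <- cbind(k = k, enr)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
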