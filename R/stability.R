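# all permutations of 1..k in lexicographic order
permutations <- function(k) {
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in gen(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  gen(seq_len(as.integer(k)))
}

#' Match class labels between two clusterings of shared subjects
#'
#' Finds the one-to-one assignment of time-0 classes to time-1 classes
#' maximizing total overlap on the shared subjects, solved exactly by
#' enumerating all k! permutations (k is small here; ties go to the
#' lexicographically smallest permutation).  Clusterings done
#' independently at two time points carry arbitrary labels; matching
#' them by overlap is the reproducible analogue of matching phenotypes
#' by interpretation.
#'
#' @param clust0,clust1 named vectors/factors of class labels (names =
#'   subject ids) at the two time points.
#' @param shared_ids subject ids present in both; defaults to the
#'   intersection of the names.
#' @return An `rf_matching` list: `mapping` (named character, time-0
#'   class -> time-1 class), `overlap` (k x k contingency on shared
#'   subjects), `n_shared`.
#' @export
match_classes <- function(clust0, clust1,
                          shared_ids = intersect(names(clust0), names(clust1))) {
  stopifnot(!is.null(names(clust0)), !is.null(names(clust1)),
            length(shared_ids) > 0,
            all(shared_ids %in% names(clust0)),
            all(shared_ids %in% names(clust1)))
  a0 <- factor(as.character(clust0[shared_ids]))
  a1 <- factor(as.character(clust1[shared_ids]))
  k0 <- nlevels(a0); k1 <- nlevels(a1)
  if (k0 != k1)
    stop("clusterings have different numbers of classes (", k0, " vs ", k1,
         "); rerun both at equal k before matching")
  if (k0 > 8) stop("exhaustive matching supports k <= 8")
  ov <- table(a0, a1)
  best <- NULL; best_val <- -1
  for (p in permutations(k0)) {
    val <- sum(ov[cbind(seq_len(k0), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  mapping <- setNames(levels(a1)[best], levels(a0))
  structure(list(mapping = mapping, overlap = ov, n_shared = length(shared_ids),
                 total_overlap = best_val),
            class = "rf_matching")
}

#' Cross-cohort transition report
#'
#' Counts class transitions among subjects present at both time points
#' under matched labels, and summarises per-class stability: `p_transitions`
#' (fraction of a class's subjects that left it) and `f_transitions`
#' (fraction of all transitions arriving into a class).  Subjects with a
#' death/transplant event are excluded from transition counts and
#' reported only in per-class event tallies.
#'
#' @param clust0,clust1 named class-label vectors at the two time points.
#' @param matching an `rf_matching` from [match_classes()]; computed if
#'   `NULL`.
#' @param events optional data frame with columns `id`, `event`
#'   (`death`/`transplant`); subjects are tallied by their time-0 class.
#' @return An `rf_transitions` list: `shared_ids`, `counts` (origin x
#'   destination, time-0 label space), `p_transitions`, `f_transitions`,
#'   `events` (per-class death/transplant counts), `n_transitions`.
#' @export
transition_report <- function(clust0, clust1, matching = NULL, events = NULL) {
  shared <- intersect(names(clust0), names(clust1))
  ev_ids <- character()
  ev_tab <- NULL
  lev0 <- sort(unique(as.character(clust0)))
  if (!is.null(events) && nrow(events)) {
    stopifnot(all(c("id", "event") %in% names(events)))
    ev <- events[events$event %in% c("death", "transplant"), , drop = FALSE]
    ev_ids <- as.character(ev$id)
    cls0 <- factor(as.character(clust0[ev_ids]), levels = lev0)
    ev_tab <- table(class = cls0, event = factor(ev$event,
                                                 c("death", "transplant")))
  }
  shared <- setdiff(shared, ev_ids)
  if (is.null(matching)) matching <- match_classes(clust0, clust1, shared)
  a0 <- as.character(clust0[shared])
  a1 <- as.character(clust1[shared])
  # express destinations in the time-0 label space via the inverse map
  inv <- setNames(names(matching$mapping), matching$mapping)
  dest <- unname(inv[a1])
  lev <- names(matching$mapping)
  counts <- table(origin = factor(a0, lev), destination = factor(dest, lev))
  stay <- diag(counts)
  origin_n <- rowSums(counts)
  p_trans <- ifelse(origin_n > 0, 1 - stay / origin_n, NA)
  n_moves <- sum(counts) - sum(stay)
  arrive <- colSums(counts) - stay
  f_trans <- if (n_moves > 0) arrive / n_moves else rep(NA_real_, length(lev))
  structure(list(shared_ids = shared, counts = counts,
                 p_transitions = setNames(as.numeric(p_trans), lev),
                 f_transitions = setNames(as.numeric(f_trans), lev),
                 events = ev_tab, n_transitions = n_moves,
                 matching = matching),
            class = "rf_transitions")
}

#' @export
print.rf_transitions <- function(x, ...) {
  cat("transition report:", length(x$shared_ids), "shared subjects,",
      x$n_transitions, "transitions\n")
  print(x$counts)
  cat("p_transitions (leaving):\n"); print(round(x$p_transitions, 3))
  cat("f_transitions (arriving):\n"); print(round(x$f_transitions, 3))
  if (!is.null(x$events)) { cat("events:\n"); print(x$events) }
  invisible(x)
}

#' Write transition report CSVs
#'
#' Emits the counts matrix and a per-class summary of leaving
#' proportions, arrival fractions and event tallies.
#'
#' @param x an `rf_transitions`.
#' @param counts_path,summary_path output CSV paths.
#' @export
write_transitions <- function(x, counts_path, summary_path) {
  write.csv(as.data.frame.matrix(x$counts), counts_path)
  lev <- names(x$p_transitions)
  deaths <- transplants <- rep(0L, length(lev))
  if (!is.null(x$events)) {
    deaths <- as.integer(x$events[, "death"])
    transplants <- as.integer(x$events[, "transplant"])
  }
  write.csv(data.frame(class = lev, p_transitions = x$p_transitions,
                       f_transitions = x$f_transitions,
                       deaths = deaths, transplants = transplants,
                       row.names = NULL),
            summary_path, row.names = FALSE)
  invisible(x)
}
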