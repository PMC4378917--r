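#' Random forest configuration
#'
#' @param n_trees number of trees (default 1500, the setting used for
#'   clinical phenotyping; smaller ensembles are adequate for
#'   simulation studies).
#' @param mtry variables tried per split; default `floor(sqrt(p))`,
#'   resolved at fit time.
#' @param min_node_size minimum node size below which splitting stops
#'   (default 1: grow to purity, unpruned).
#' @param seed integer seed for the forest's internal random stream.
#'   Per-tree substreams are a fixed function of (seed, tree index), so
#'   changing `n_trees` never reshuffles earlier trees.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 1500, mtry = NULL, min_node_size = 1,
                          seed = 1) {
  stopifnot(n_trees >= 1, min_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.numeric(seed)),
            class = "forest_config")
}

# Encode a mixed-type data frame as the numeric matrix + level-count
# vector the C++ tree grower expects.  `template` reuses the factor
# levels of a previous encoding so train/apply stay consistent.
encode_features <- function(df, template = NULL) {
  stopifnot(is.data.frame(df), nrow(df) >= 1)
  p <- ncol(df)
  ncat <- integer(p)
  levs <- vector("list", p)
  M <- matrix(0, nrow(df), p, dimnames = list(NULL, names(df)))
  for (j in seq_len(p)) {
    v <- df[[j]]
    if (is.character(v)) v <- factor(v)
    if (is.logical(v)) v <- as.numeric(v)
    if (is.factor(v)) {
      if (!is.null(template)) {
        tl <- template$levels[[j]]
        if (is.null(tl) || !all(levels(v) %in% tl))
          stop("factor levels of '", names(df)[j],
               "' do not match the training encoding")
        v <- factor(as.character(v), levels = tl)
      }
      ncat[j] <- nlevels(v)
      levs[[j]] <- levels(v)
      M[, j] <- as.numeric(as.integer(v))
    } else {
      M[, j] <- as.numeric(v)
    }
    if (anyNA(M[, j])) stop("missing values in feature '", names(df)[j], "'")
  }
  list(x = M, ncat = ncat, levels = levs, names = names(df))
}

#' Fit a supervised classification random forest
#'
#' Unpruned CART trees on independent bootstrap samples, best splits by
#' Gini impurity decrease over `mtry` randomly drawn candidate
#' variables.  Categorical variables are split natively by exhaustive
#' level-subset search; no dummy coding.  Deterministic given
#' `config$seed`.
#'
#' @param features data frame of mixed-type features (factors for
#'   categorical variables).
#' @param labels factor (or coercible) of class labels; at least two
#'   classes must be present.
#' @param config a [forest_config()].
#' @return An `rf_forest` object.
#' @export
fit_supervised_forest <- function(features, labels, config = forest_config()) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    stop("need at least two classes for a classification forest")
  if (length(labels) != nrow(features))
    stop("labels and features disagree in length")
  enc <- encode_features(features)
  p <- ncol(enc$x)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(p))) else config$mtry
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, p]")
  fit <- rf_grow_forest(enc$x, as.integer(enc$ncat),
                        as.integer(labels) - 1L, nlevels(labels),
                        config$n_trees, as.integer(mtry),
                        config$min_node_size, config$seed)
  never_oob <- sum(rowSums(fit$inbag == 0) == 0)
  if (never_oob > 0)
    warning(never_oob, " row(s) in-bag for every tree; they are excluded ",
            "from OOB statistics")
  structure(list(trees = fit$trees, inbag = fit$inbag, encoding = enc,
                 y = labels, class_labels = levels(labels),
                 config = config, mtry = mtry, n = nrow(enc$x),
                 n_original = nrow(enc$x), unsupervised = FALSE),
            class = "rf_forest")
}

#' @export
print.rf_forest <- function(x, ...) {
  cat("rf_forest:", length(x$trees), "trees,", x$n, "rows,",
      ncol(x$encoding$x), "variables, mtry", x$mtry,
      if (x$unsupervised) "(unsupervised real-vs-synthetic contrast)", "\n")
  invisible(x)
}

#' Grow a single unpruned CART tree
#'
#' Grows one tree on the rows exactly as given (no bootstrap): the
#' building block of the forest, exposed for inspection and testing.
#' The serialized tree uses 0-based node references; `var = -1` marks a
#' leaf.
#'
#' @param features data frame of mixed-type features.
#' @param labels class labels.
#' @param mtry candidate variables per split (default all).
#' @param min_node_size minimum node size for splitting.
#' @param seed seed for the candidate-variable draws.
#' @return An `rf_tree` list: the serialized tree (`var`, `thr`,
#'   `mask`, `left`, `right`, `cls`) plus the feature `encoding` and
#'   `class_labels`.
#' @export
grow_tree <- function(features, labels, mtry = NULL, min_node_size = 1,
                      seed = 1) {
  labels <- droplevels(as.factor(labels))
  enc <- encode_features(features)
  p <- ncol(enc$x)
  if (is.null(mtry)) mtry <- p
  stopifnot(mtry >= 1, mtry <= p)
  tr <- rf_grow_single_tree(enc$x, as.integer(enc$ncat),
                            as.integer(labels) - 1L, nlevels(labels),
                            as.integer(mtry), as.integer(min_node_size),
                            seed)
  structure(c(tr, list(encoding = enc, class_labels = levels(labels))),
            class = "rf_tree")
}

#' Predict classes with a single tree
#'
#' @param object an `rf_tree`.
#' @param newdata data frame of features (same columns as training).
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.rf_tree <- function(object, newdata, ...) {
  enc <- encode_features(newdata, template = object$encoding)
  tl <- list(object[c("var", "thr", "mask", "left", "right", "cls")])
  leaves <- rf_leaf_ids(tl, enc$x, as.integer(enc$ncat))
  factor(object$class_labels[object$cls[leaves[, 1] + 1L] + 1L],
         levels = object$class_labels)
}

#' Augment data with a marginally-sampled synthetic contrast class
#'
#' Implements the two-class device behind unsupervised random forests:
#' the observed rows are labelled `observed` and an equal number of
#' synthetic rows, each variable drawn independently with replacement
#' from its own empirical marginal distribution, are labelled
#' `synthetic`.  The synthetic class preserves every marginal but
#' destroys the joint dependence structure, so a classifier that
#' separates the two has learned the dependence among variables.
#'
#' @param features data frame of observed features (n >= 2 rows).
#' @param seed integer seed.
#' @return List with `features` (2n rows, observed first) and `labels`
#'   (factor `observed`/`synthetic`).
#' @export
make_synthetic_contrast <- function(features, seed = 1) {
  stopifnot(is.data.frame(features), nrow(features) >= 2)
  n <- nrow(features)
  synth <- features
  with_seed(seed, {
    for (j in seq_len(ncol(features)))
      synth[[j]] <- features[[j]][sample.int(n, n, replace = TRUE)]
  })
  rownames(synth) <- paste0("synth_", seq_len(n))
  list(features = rbind(features, synth),
       labels = factor(rep(c("observed", "synthetic"), each = n),
                       levels = c("observed", "synthetic")))
}

#' Fit an unsupervised random forest
#'
#' Applies [make_synthetic_contrast()] and fits a supervised forest to
#' the resulting two-class problem.  The returned forest remembers the
#' original rows (always the first `n`), so proximities are reported
#' over the observed subjects only.
#'
#' @param features data frame of observed features.
#' @param config a [forest_config()]; its seed also drives the
#'   synthetic-class sampling.
#' @return An `rf_forest` with `unsupervised = TRUE`.
#' @export
fit_unsupervised_forest <- function(features, config = forest_config()) {
  stopifnot(nrow(features) >= 2)
  contrast <- make_synthetic_contrast(features,
                                      seed = derive_seed(config$seed, 1))
  f <- fit_supervised_forest(contrast$features, contrast$labels, config)
  f$unsupervised <- TRUE
  f$n_original <- nrow(features)
  f$original_ids <- rownames(features)
  f
}

#' Random forest proximity matrix
#'
#' `P[i, j]` is the fraction of trees in which subjects i and j land in
#' the same terminal node, every row run down every tree (all-tree
#' convention).  With `oob_only = TRUE`, only trees where both rows are
#' out-of-bag are counted and the denominator is the number of such
#' trees.  For an unsupervised forest the matrix covers the original
#' rows only.
#'
#' @param forest an `rf_forest`.
#' @param oob_only count OOB pairs only (default `FALSE`).
#' @return An n x n symmetric matrix with unit diagonal, entries in
#'   \[0, 1\], dimnames = subject ids.
#' @export
compute_proximity <- function(forest, oob_only = FALSE) {
  stopifnot(inherits(forest, "rf_forest"))
  n0 <- forest$n_original
  X <- forest$encoding$x[seq_len(n0), , drop = FALSE]
  leaves <- rf_leaf_ids(forest$trees, X, as.integer(forest$encoding$ncat))
  inbag <- forest$inbag[seq_len(n0), , drop = FALSE]
  P <- rf_proximity_from_leaves(leaves, inbag, oob_only)
  ids <- if (!is.null(forest$original_ids)) forest$original_ids
         else as.character(seq_len(n0))
  dimnames(P) <- list(ids, ids)
  stopifnot(isTRUE(all.equal(P, t(P), tolerance = 1e-12)),
            all(diag(P) == 1), all(P >= 0), all(P <= 1))
  structure(P, class = c("rf_proximity", class(P)))
}

#' Out-of-bag error and confusion matrix
#'
#' Each row is predicted by majority vote over the trees for which it is
#' out of bag (ties broken toward the lowest class index); the
#' misclassification rate and the true-by-predicted confusion matrix
#' are computed over OOB-covered rows.
#'
#' @param forest an `rf_forest`.
#' @return An `rf_oob` list: `error_rate`, `confusion`, `predicted`,
#'   `n_never_oob`.
#' @export
oob_evaluate <- function(forest) {
  stopifnot(inherits(forest, "rf_forest"))
  votes <- rf_oob_votes(forest$trees, forest$inbag, forest$encoding$x,
                        as.integer(forest$encoding$ncat),
                        length(forest$class_labels))
  covered <- rowSums(votes) > 0
  if (!any(covered))
    stop("no row is out of bag for any tree; grow more trees")
  pred <- rep(NA_character_, forest$n)
  pred[covered] <- forest$class_labels[max.col(votes[covered, , drop = FALSE],
                                               ties.method = "first")]
  truth <- as.character(forest$y)
  confusion <- table(true = factor(truth[covered], forest$class_labels),
                     predicted = factor(pred[covered], forest$class_labels))
  err <- mean(pred[covered] != truth[covered])
  structure(list(error_rate = err, confusion = confusion,
                 predicted = factor(pred, forest$class_labels),
                 n_never_oob = sum(!covered)),
            class = "rf_oob")
}

#' @export
print.rf_oob <- function(x, ...) {
  cat(sprintf("OOB error rate: %.2f%% (%d rows never OOB)\n",
              100 * x$error_rate, x$n_never_oob))
  print(x$confusion)
  invisible(x)
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' For every tree and variable, the tree's OOB accuracy is computed
#' before and after randomly permuting that variable's values among the
#' tree's OOB rows; the per-tree decreases are averaged and their
#' standard error across trees reported.  A variable that is constant,
#' or never used, has importance exactly zero.
#'
#' @param forest an `rf_forest`.
#' @return An `rf_importance` data frame: `variable`,
#'   `mean_decrease_accuracy`, `se`, `rank` (ties toward the lower
#'   variable index).
#' @export
permutation_importance <- function(forest) {
  stopifnot(inherits(forest, "rf_forest"))
  D <- rf_perm_importance_cpp(forest$trees, forest$inbag, forest$encoding$x,
                              as.integer(forest$encoding$ncat),
                              as.integer(forest$y) - 1L, forest$config$seed)
  m <- colMeans(D, na.rm = TRUE)
  ntree_used <- colSums(!is.na(D))
  se <- apply(D, 2, sd, na.rm = TRUE) / sqrt(pmax(ntree_used, 1))
  ord <- order(-m, seq_along(m))
  rank <- integer(length(m))
  rank[ord] <- seq_along(m)
  structure(data.frame(variable = forest$encoding$names,
                       mean_decrease_accuracy = m, se = se, rank = rank,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("rf_importance", "data.frame"))
}
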