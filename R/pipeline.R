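#' Two-stage phenotyping pipeline configuration
#'
#' @param k number of phenotype classes (>= 2).
#' @param n_top_variables how many variables the importance-based
#'   dimension reduction keeps (default 8).
#' @param forest a [forest_config()].
#' @param include,exclude optional variable include/exclude lists
#'   applied to the cohort schema before stage 1.
#' @param mds_dims embedding dimensions for the final visualization
#'   coordinates.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k, n_top_variables = 8,
                            forest = forest_config(), include = NULL,
                            exclude = NULL, mds_dims = 2) {
  stopifnot(k >= 2, n_top_variables >= 1)
  structure(list(k = as.integer(k),
                 n_top_variables = as.integer(n_top_variables),
                 forest = forest, include = include, exclude = exclude,
                 mds_dims = as.integer(mds_dims)),
            class = "pipeline_config")
}

#' Select the most important variables
#'
#' Top `m` variables by mean decrease in accuracy; ties already resolve
#' toward the lower variable index in the importance ranking.
#'
#' @param report an `rf_importance` from [permutation_importance()].
#' @param m number of variables to keep (`m <= p`).
#' @return Character vector of variable names in rank order.
#' @export
select_top_variables <- function(report, m) {
  stopifnot(inherits(report, "rf_importance"), m <= nrow(report))
  report$variable[order(report$rank)][seq_len(m)]
}

#' Per-class clinical profiles
#'
#' Arithmetic means of the six profile variables (FEV1\%, FVC\%,
#' Brasfield, age, age-by-FEV1\% product, BMI), the fraction of male
#' subjects, and the prevalence of every binary trait, per class.
#' Classes are lettered A, B, C, ... in ascending order of mean
#' age-by-FEV1\% product (A = lowest accrued lung health), a
#' deterministic convention for human-facing labels.
#'
#' @param cohort a `cf_cohort`.
#' @param clustering integer/factor class assignment covering the
#'   cohort.
#' @return A `class_profiles` data frame (one row per class) with
#'   attribute `assignment`: the per-subject lettered factor.
#' @export
profile_classes <- function(cohort, clustering) {
  d <- cohort$data
  stopifnot(length(clustering) == nrow(d))
  cl <- as.factor(clustering)
  if (any(table(cl) == 0)) stop("empty class in clustering")
  prof_vars <- intersect(c("fev1_pct", "fvc_pct", "brasfield", "age",
                           "age_fev1_product", "bmi"), names(d))
  traits <- cohort$schema$name[cohort$schema$role == "binary"]
  key <- if ("age_fev1_product" %in% names(d)) "age_fev1_product"
         else prof_vars[1]
  cl_means <- tapply(d[[key]], cl, mean)
  ord <- order(cl_means, seq_along(cl_means))
  letter_of <- setNames(class_letters(nlevels(cl))[order(ord)], levels(cl))
  assignment <- factor(letter_of[as.character(cl)],
                       levels = class_letters(nlevels(cl)))
  rows <- lapply(levels(assignment), function(L) {
    idx <- assignment == L
    row <- data.frame(class = L, n = sum(idx))
    for (v in prof_vars) row[[paste0("mean_", v)]] <- mean(d[[v]][idx])
    row$fraction_male <- if ("gender" %in% names(d))
      mean(d$gender[idx] == "male") else NA_real_
    for (tr in traits) row[[paste0("prev_", tr)]] <- mean(d[[tr]][idx])
    row
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$n) == nrow(d),
            all(out$fraction_male >= 0 & out$fraction_male <= 1, na.rm = TRUE))
  attr(out, "assignment") <- assignment
  class(out) <- c("class_profiles", "data.frame")
  out
}

#' Run the two-stage unsupervised phenotyping procedure
#'
#' The six steps: (1) an unsupervised random forest over all variables
#' yields a proximity matrix; (2) PAM on `1 - proximity` forms initial
#' classes; (3) a supervised forest on those classes gives the OOB
#' error and permutation variable importance; (4) the unsupervised
#' forest is repeated on the top `n_top_variables` variables; (5) PAM on
#' the second proximity forms the final classes; (6) a supervised
#' forest on the final classes gives the final OOB error/confusion
#' matrix, and classical MDS of the second dissimilarity provides
#' visualization coordinates.  Deterministic given `config$forest$seed`
#' (stage-specific forests use fixed derived seeds).
#'
#' @param cohort a `cf_cohort`.
#' @param config a [pipeline_config()].
#' @param verbose log per-stage progress.
#' @return An `rf_phenotypes` list: `stage1` (proximity, clustering,
#'   oob, importance), `selected_variables`, `stage2` (proximity,
#'   clustering, oob), `embedding`, `profiles`, `assignment` (lettered
#'   factor, A = lowest mean age-by-FEV1\% product), `config`.
#' @export
run_two_stage <- function(cohort, config, verbose = FALSE) {
  stopifnot(inherits(cohort, "cf_cohort"), inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  vars <- cohort$schema$name
  if (!is.null(config$include)) vars <- intersect(vars, config$include)
  if (!is.null(config$exclude)) vars <- setdiff(vars, config$exclude)
  if (config$n_top_variables > length(vars))
    stop("n_top_variables exceeds the number of variables")
  x <- cohort_features(cohort, vars)
  fc <- config$forest

  say("stage 1: unsupervised forest on ", length(vars), " variables")
  f1 <- fit_unsupervised_forest(x, fc)
  P1 <- compute_proximity(f1)
  c1 <- pam_cluster(as_dissimilarity(P1), config$k)

  say("stage 1: supervised forest on initial classes")
  fc3 <- fc; fc3$seed <- derive_seed(fc$seed, 3)
  sf1 <- fit_supervised_forest(x, factor(c1$clustering), fc3)
  oob1 <- oob_evaluate(sf1)
  imp <- permutation_importance(sf1)
  sel <- select_top_variables(imp, config$n_top_variables)
  say("selected: ", paste(sel, collapse = ", "))

  say("stage 2: unsupervised forest on selected variables")
  fc4 <- fc; fc4$seed <- derive_seed(fc$seed, 4)
  f2 <- fit_unsupervised_forest(x[, sel, drop = FALSE], fc4)
  P2 <- compute_proximity(f2)
  D2 <- as_dissimilarity(P2)
  c2 <- pam_cluster(D2, config$k)

  say("stage 2: supervised forest on final classes")
  fc5 <- fc; fc5$seed <- derive_seed(fc$seed, 5)
  sf2 <- fit_supervised_forest(x, factor(c2$clustering), fc5)
  oob2 <- oob_evaluate(sf2)
  emb <- classical_mds(D2, config$mds_dims)
  say(sprintf("OOB error: stage 1 %.1f%%, stage 2 %.1f%%; negative-eigenvalue mass %.3f",
              100 * oob1$error_rate, 100 * oob2$error_rate,
              emb$negative_eigenvalue_mass))
  profiles <- profile_classes(cohort, c2$clustering)
  structure(list(stage1 = list(proximity = P1, clustering = c1, oob = oob1,
                               importance = imp),
                 selected_variables = sel,
                 stage2 = list(proximity = P2, clustering = c2, oob = oob2),
                 embedding = emb, profiles = profiles,
                 assignment = setNames(attr(profiles, "assignment"),
                                       cohort$data$id),
                 config = config),
            class = "rf_phenotypes")
}

#' @export
print.rf_phenotypes <- function(x, ...) {
  cat("two-stage phenotyping: k =", x$config$k, "\n")
  cat(sprintf("stage 1 OOB error %.2f%% -> stage 2 OOB error %.2f%%\n",
              100 * x$stage1$oob$error_rate, 100 * x$stage2$oob$error_rate))
  cat("selected variables:", paste(x$selected_variables, collapse = ", "),
      "\n\nclass profiles:\n")
  print(as.data.frame(x$profiles), digits = 3)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits clustering, importance, confusion, proximity, embedding and
#' profile CSVs plus a JSON run manifest (configuration, seed, package
#' version).
#'
#' @param result an `rf_phenotypes`.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_phenotypes <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  ids <- names(result$assignment)
  meds <- result$stage2$clustering$medoids
  write.csv(data.frame(subject_id = ids,
                       class_letter = as.character(result$assignment),
                       medoid_id = ids[meds][result$stage2$clustering$clustering]),
            fp("clustering.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$stage1$importance), fp("importance.csv"),
            row.names = FALSE)
  write.csv(as.data.frame.matrix(result$stage2$oob$confusion),
            fp("confusion.csv"))
  write.csv(as.data.frame(unclass(result$stage2$proximity)),
            fp("proximity.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = ids, result$embedding$coordinates),
            fp("embedding.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$profiles), fp("profiles.csv"),
            row.names = FALSE)
  manifest <- list(
    k = result$config$k,
    n_top_variables = result$config$n_top_variables,
    n_trees = result$config$forest$n_trees,
    mtry = result$config$forest$mtry,
    seed = result$config$forest$seed,
    selected_variables = result$selected_variables,
    stage1_oob_error = result$stage1$oob$error_rate,
    stage2_oob_error = result$stage2$oob$error_rate,
    negative_eigenvalue_mass = result$embedding$negative_eigenvalue_mass,
    package_version = as.character(utils::packageVersion("phenoforest")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  } else {
    dput(manifest, fp("manifest.json"))
  }
  invisible(list.files(outdir, full.names = TRUE))
}
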