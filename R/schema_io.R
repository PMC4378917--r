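#' Controlled vocabulary of sputum-culture organisms
#'
#' Organism groups tracked as per-subject presence flags: *Pseudomonas*
#' spp. (PA), methicillin-resistant and -sensitive *S. aureus*,
#' *Achromobacter*, *Burkholderia*, *Stenotrophomonas*, *Candida*,
#' *Aspergillus*, *Scedosporium* and mycobacteria.
#'
#' @return Character vector of organism flag names.
#' @export
cf_organisms <- function() {
  c("pa", "mrsa", "mssa", "achromobacter", "burkholderia",
    "stenotrophomonas", "candida", "aspergillus", "scedosporium",
    "mycobacteria")
}

cftr_levels <- function() c("two_class_I_II_III", "any_class_IV_V_VI", "unknown")

#' Default clinical variable schema
#'
#' One row per clinical variable with its measurement role
#' (`continuous`, `binary` or `categorical`), units, and the allowed
#' levels for categorical variables.  Covers demographics (age, gender),
#' CFTR mutation class grouping, spirometry (FEV1\% and FVC\% predicted),
#' anthropometry (height, weight, BMI), the Brasfield chest-radiograph
#' score, pancreatic sufficiency, the accrued lung-health score (age
#' multiplied by FEV1\% predicted) and the organism presence flags.
#'
#' @param extra_continuous optional character vector of additional
#'   continuous variable names (e.g. simulated noise variables).
#' @return A data frame with columns `name`, `role`, `units` and a list
#'   column `levels`.
#' @export
cf_schema <- function(extra_continuous = character()) {
  base <- data.frame(
    name = c("age", "gender", "cftr_group", "fev1_pct", "fvc_pct",
             "height", "weight", "bmi", "brasfield",
             "pancreatic_sufficient", "age_fev1_product", cf_organisms()),
    role = c("continuous", "categorical", "categorical", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "binary", "continuous",
             rep("binary", length(cf_organisms()))),
    units = c("years", "", "", "percent", "percent", "m", "kg", "kg/m2",
              "score", "flag", "years.percent",
              rep("flag", length(cf_organisms()))),
    stringsAsFactors = FALSE
  )
  base$levels <- vector("list", nrow(base))
  base$levels[[which(base$name == "gender")]] <- c("female", "male")
  base$levels[[which(base$name == "cftr_group")]] <- cftr_levels()
  if (length(extra_continuous)) {
    extra <- data.frame(name = extra_continuous, role = "continuous",
                        units = "", stringsAsFactors = FALSE)
    extra$levels <- vector("list", nrow(extra))
    base <- rbind(base, extra)
  }
  if (anyDuplicated(base$name)) stop("schema variable names must be unique")
  structure(base, class = c("cf_schema", "data.frame"))
}

#' Construct a cohort object
#'
#' Bundles a per-subject feature table with its variable schema.  Only
#' complete cases are admitted: every schema variable must be present and
#' non-missing for every subject.
#'
#' @param data data frame with an `id` column, one column per schema
#'   variable, and optionally an `event` column
#'   (`none`/`death`/`transplant`).
#' @param schema variable schema, see [cf_schema()].
#' @param label free-text cohort label (e.g. `"2011"`).
#' @return An object of class `cf_cohort`.
#' @export
cohort <- function(data, schema = cf_schema(), label = "") {
  stopifnot(is.data.frame(data))
  if (!"id" %in% names(data)) stop("cohort data must have an 'id' column")
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols))
    stop("missing schema columns: ", paste(missing_cols, collapse = ", "))
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) stop("subject ids must be unique")
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    if (anyNA(data[[v]]))
      stop("missing values in '", v, "': cohorts are complete-case only")
    if (schema$role[i] == "categorical") {
      lev <- schema$levels[[i]]
      bad <- setdiff(unique(as.character(data[[v]])), lev)
      if (length(bad))
        stop("variable '", v, "' has levels outside schema: ",
             paste(bad, collapse = ", "))
      data[[v]] <- factor(as.character(data[[v]]), levels = lev)
    } else {
      data[[v]] <- as.numeric(data[[v]])
      if (schema$role[i] == "binary" && !all(data[[v]] %in% c(0, 1)))
        stop("binary variable '", v, "' must be coded 0/1")
    }
  }
  obj <- structure(list(data = data, schema = schema, label = label),
                   class = "cf_cohort")
  obj
}

#' @export
print.cf_cohort <- function(x, ...) {
  cat("cf_cohort", if (nzchar(x$label)) paste0("'", x$label, "'"), ":",
      nrow(x$data), "subjects,", nrow(x$schema), "variables\n")
  invisible(x)
}

#' Check cohort invariants
#'
#' Verifies subject-level invariants: unique ids, completeness, BMI
#' consistent with height and weight (1e-6 relative tolerance, with a
#' validation warning past 1\%), Brasfield score in \[0, 25\],
#' age-by-FEV1\% product consistent with its factors, finite spirometry,
#' and 0/1 coding of flags.
#'
#' @param x a `cf_cohort`.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cf_cohort"))
  d <- x$data
  out <- character()
  if (anyDuplicated(d$id)) out <- c(out, "duplicate subject ids")
  for (v in x$schema$name)
    if (anyNA(d[[v]])) out <- c(out, paste0("missing values in ", v))
  if (all(c("bmi", "height", "weight") %in% names(d))) {
    rel <- abs(d$bmi - d$weight / d$height^2) / pmax(d$bmi, 1e-12)
    if (any(rel > 0.01))
      out <- c(out, sprintf("%d subjects with bmi != weight/height^2 (>1%%)",
                            sum(rel > 0.01)))
  }
  if ("brasfield" %in% names(d) &&
      any(d$brasfield < 0 | d$brasfield > 25))
    out <- c(out, "brasfield score outside [0, 25]")
  if (all(c("age_fev1_product", "age", "fev1_pct") %in% names(d))) {
    rel <- abs(d$age_fev1_product - d$age * d$fev1_pct) /
      pmax(abs(d$age_fev1_product), 1e-12)
    if (any(rel > 1e-9))
      out <- c(out, "age_fev1_product inconsistent with age * fev1_pct")
  }
  for (v in intersect(c("fev1_pct", "fvc_pct"), names(d)))
    if (any(!is.finite(d[[v]]))) out <- c(out, paste0(v, " not finite"))
  out
}

#' Read a cohort table from a delimited file
#'
#' Expects a header row with an `id` column and one column per schema
#' variable; booleans coded 0/1.  Rows with any missing or unparseable
#' required value are rejected and reported (complete-case policy, no
#' imputation), mirroring clinic datasets where incomplete subjects are
#' excluded rather than imputed.
#'
#' @param path file path (CSV by default).
#' @param schema variable schema, see [cf_schema()].
#' @param label cohort label.
#' @param sep field separator.
#' @param height_unit `"m"` (default) or `"cm"`; heights in cm are
#'   converted to metres on load.
#' @return A `cf_cohort`; rejected rows are attached as a data frame
#'   (`line`, `reason`) in `$rejections`.
#' @export
load_cohort <- function(path, schema = cf_schema(), label = "", sep = ",",
                        height_unit = c("m", "cm")) {
  height_unit <- match.arg(height_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c("id", schema$name), names(raw))
  if (length(missing_cols))
    stop("schema error: missing columns ", paste(missing_cols, collapse = ", "))
  keep <- rep(TRUE, nrow(raw))
  reasons <- character(nrow(raw))
  parsed <- raw
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    val <- trimws(raw[[v]])
    blank <- is.na(val) | val == ""
    if (schema$role[i] == "categorical") {
      bad <- !blank & !(val %in% schema$levels[[i]])
      parsed[[v]] <- ifelse(blank | bad, NA, val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      bad <- !blank & is.na(num)
      parsed[[v]] <- num
    }
    prob <- blank | bad
    newly <- prob & keep
    reasons[newly] <- paste0(ifelse(blank[newly], "missing ", "unparseable "),
                             "value in '", v, "'")
    keep <- keep & !prob
  }
  if (height_unit == "cm") parsed$height <- parsed$height / 100
  rejections <- data.frame(line = which(!keep) + 1L,  # +1 for header row
                           reason = reasons[!keep],
                           stringsAsFactors = FALSE)
  co <- cohort(parsed[keep, , drop = FALSE], schema = schema, label = label)
  co$rejections <- rejections
  co
}

#' Write a cohort table
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces the cohort exactly.
#'
#' @param x a `cf_cohort`.
#' @param path output file path.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cf_cohort"))
  d <- x$data
  for (v in names(d)) {
    if (is.numeric(d[[v]])) d[[v]] <- sprintf("%.17g", d[[v]])
    if (is.factor(d[[v]])) d[[v]] <- as.character(d[[v]])
  }
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute derived clinical variables
#'
#' Populates BMI (weight / height^2, kg/m2) and the accrued lung-health
#' score (age times FEV1\% predicted).  Pre-existing stored values are
#' validated against the recomputation; discrepancies beyond 1\% raise a
#' validation warning and are replaced by the recomputed value.
#'
#' @param x a `cf_cohort` with age, fev1_pct, height and weight.
#' @return The cohort with `bmi` and `age_fev1_product` populated.
#' @export
derive_features <- function(x) {
  stopifnot(inherits(x, "cf_cohort"))
  d <- x$data
  for (v in c("age", "fev1_pct", "height", "weight"))
    if (!v %in% names(d)) stop("derive_features needs '", v, "'")
  if (any(d$height == 0)) stop("height must be positive")
  bmi <- d$weight / d$height^2
  prod <- d$age * d$fev1_pct
  if ("bmi" %in% names(d) && !all(is.na(d$bmi))) {
    rel <- abs(d$bmi - bmi) / pmax(bmi, 1e-12)
    if (any(rel > 0.01, na.rm = TRUE))
      warning(sum(rel > 0.01, na.rm = TRUE),
              " stored bmi value(s) differ from weight/height^2 by >1%;",
              " recomputed")
  }
  if ("age_fev1_product" %in% names(d) && !all(is.na(d$age_fev1_product))) {
    rel <- abs(d$age_fev1_product - prod) / pmax(abs(prod), 1e-12)
    if (any(rel > 0.01, na.rm = TRUE))
      warning("stored age_fev1_product inconsistent with age * fev1_pct;",
              " recomputed")
  }
  d$bmi <- bmi
  d$age_fev1_product <- prod
  x$data <- d
  x
}

#' Severity band of the accrued lung-health score
#'
#' The age-by-FEV1\% product separates severe, moderate and mild disease
#' at approximately 1000 and 1600; the exact boundary convention here is
#' severe < 1000, 1000 <= moderate <= 1600, mild > 1600.
#'
#' @param product numeric vector of age-by-FEV1\% products (>= 0).
#' @param cutoffs length-2 numeric, the severe/moderate and
#'   moderate/mild boundaries.
#' @return Factor with levels `severe`, `moderate`, `mild`.
#' @export
severity_band <- function(product, cutoffs = c(1000, 1600)) {
  if (any(product < 0, na.rm = TRUE)) stop("product must be non-negative")
  stopifnot(length(cutoffs) == 2, cutoffs[1] <= cutoffs[2])
  out <- ifelse(product < cutoffs[1], "severe",
                ifelse(product <= cutoffs[2], "moderate", "mild"))
  factor(out, levels = c("severe", "moderate", "mild"))
}

#' Aggregate raw culture records into presence flags
#'
#' An organism is called present for a subject iff at least two positive
#' sputum cultures for that organism fall within the 365 days up to and
#' including the subject's reference date.
#'
#' @param records data frame with columns `subject_id`, `date`
#'   (ISO-8601), `organism`, `positive` (0/1 or logical).
#' @param reference_date a single date (cohort snapshot) or a data frame
#'   with columns `subject_id`, `reference_date` for per-subject
#'   most-recent-encounter dates.
#' @param organisms controlled vocabulary; defaults to [cf_organisms()].
#' @return Data frame: `subject_id` plus one 0/1 column per organism.
#' @export
aggregate_microbiology <- function(records, reference_date,
                                   organisms = cf_organisms()) {
  stopifnot(all(c("subject_id", "date", "organism", "positive") %in%
                  names(records)))
  bad <- setdiff(unique(records$organism), organisms)
  if (length(bad))
    stop("unknown organism(s): ", paste(bad, collapse = ", "))
  dates <- as.Date(records$date)
  if (anyNA(dates)) stop("unparseable culture date(s)")
  ids <- sort(unique(as.character(records$subject_id)))
  if (is.data.frame(reference_date)) {
    ref <- setNames(as.Date(reference_date$reference_date),
                    as.character(reference_date$subject_id))
    if (!all(ids %in% names(ref)))
      stop("reference_date missing for some subjects")
    refs <- ref[ids]
  } else {
    refs <- setNames(rep(as.Date(reference_date), length(ids)), ids)
  }
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  pos <- if (is.logical(records$positive)) records$positive
         else records$positive == 1
  for (org in organisms) {
    flag <- vapply(ids, function(s) {
      in_win <- records$subject_id == s & records$organism == org & pos &
        dates > refs[s] - 365 & dates <= refs[s]
      sum(in_win) >= 2
    }, logical(1))
    out[[org]] <- as.integer(flag)
  }
  out
}

#' Combine two presence flags into a combination trait
#'
#' Logical AND of two per-subject flags, e.g. PA/Candida co-presence.
#'
#' @param flag_a,flag_b 0/1 vectors of equal length.
#' @return 0/1 vector.
#' @export
combo_trait <- function(flag_a, flag_b) {
  stopifnot(length(flag_a) == length(flag_b),
            all(flag_a %in% c(0, 1)), all(flag_b %in% c(0, 1)))
  as.integer(flag_a == 1 & flag_b == 1)
}

#' Extract the clustering feature table from a cohort
#'
#' Returns the schema variables (optionally filtered) as a data frame
#' with categorical variables as factors, ready for the forest.
#'
#' @param x a `cf_cohort`.
#' @param variables variable names to keep; default all schema variables.
#' @return Data frame of features, row names = subject ids.
#' @export
cohort_features <- function(x, variables = NULL) {
  stopifnot(inherits(x, "cf_cohort"))
  if (is.null(variables)) variables <- x$schema$name
  bad <- setdiff(variables, x$schema$name)
  if (length(bad)) stop("not in schema: ", paste(bad, collapse = ", "))
  out <- x$data[, variables, drop = FALSE]
  rownames(out) <- x$data$id
  out
}
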