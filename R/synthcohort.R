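# Physiologic truncation bounds for generated adults (synthetic design
# choices, not measurements): age 18-80 y, FEV1% 15-140, FVC% 15-150,
# height 1.40-2.00 m, weight 35-120 kg, Brasfield 3-25 (integer).
sim_bounds <- function() {
  list(age = c(18, 80), fev1_pct = c(15, 140), fvc_pct = c(15, 150),
       height = c(1.40, 2.00), weight = c(35, 120), brasfield = c(3, 25))
}

# exact inverse-CDF truncated normal
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Specification of one latent clinical class
#'
#' Per-class generative parameters for the synthetic cohort: normal
#' means/SDs for the continuous clinical variables (truncated at
#' physiologic bounds at draw time), the male probability, pancreatic
#' sufficiency and organism-presence prevalences, and CFTR group
#' probabilities.
#'
#' @param name class name (e.g. `"A"`).
#' @param weight mixing weight in (0, 1]; weights must sum to 1 across
#'   a configuration.
#' @param age,fev1_pct,fvc_pct,height,weight_kg,brasfield length-2
#'   numeric `c(mean, sd)` in years, percent, percent, m, kg, score.
#' @param male_p probability of male gender.
#' @param ps_p pancreatic sufficiency prevalence.
#' @param cftr_p length-3 probabilities for the CFTR groups
#'   (two class I-III / any class IV-VI / unknown), summing to 1.
#' @param traits named numeric prevalences for organism flags; missing
#'   organisms default to 0.05.
#' @return A `class_spec` list.
#' @export
class_spec <- function(name, weight, age, fev1_pct, fvc_pct, height,
                       weight_kg, brasfield, male_p = 0.5, ps_p = 0.15,
                       cftr_p = c(0.8, 0.1, 0.1), traits = NULL) {
  tr <- setNames(rep(0.05, length(cf_organisms())), cf_organisms())
  if (!is.null(traits)) {
    bad <- setdiff(names(traits), cf_organisms())
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    tr[names(traits)] <- traits
  }
  spec <- list(name = name, weight = weight,
               cont = list(age = age, fev1_pct = fev1_pct, fvc_pct = fvc_pct,
                           height = height, weight = weight_kg,
                           brasfield = brasfield),
               male_p = male_p, ps_p = ps_p, cftr_p = cftr_p, traits = tr)
  b <- sim_bounds()
  for (v in names(spec$cont)) {
    mv <- spec$cont[[v]]
    stopifnot(length(mv) == 2)
    if (mv[2] <= 0) stop("SD of '", v, "' must be positive")
    if (mv[1] < b[[v]][1] || mv[1] > b[[v]][2])
      stop("mean of '", v, "' outside physiologic bounds [",
           b[[v]][1], ", ", b[[v]][2], "]")
  }
  probs <- c(male_p, ps_p, cftr_p, tr)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cftr_p) - 1) > 1e-8) stop("cftr_p must sum to 1")
  structure(spec, class = "class_spec")
}

#' Simulation configuration
#'
#' @param n_subjects cohort size (>= number of classes).
#' @param class_specs list of [class_spec()]s; mixing weights must sum
#'   to 1.
#' @param n_noise_variables number of iid standard-normal noise columns
#'   appended (named `noise_01`, ...).
#' @param noise_sd SD of the noise columns.
#' @param seed integer seed; the whole simulation is reproducible from
#'   it.
#' @param followup list of follow-up parameters: `persistence` (per
#'   class, named, or a scalar), `hazard` (per-class death/transplant
#'   probability over the gap), `drift_sd` (additive drift SD on
#'   FEV1\%/FVC\%/weight for persisting subjects, native units),
#'   `years_gap`, `n_new` (new subjects appended at follow-up).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects, class_specs, n_noise_variables = 0,
                       noise_sd = 1, seed = 1,
                       followup = list(persistence = 0.8, hazard = 0,
                                       drift_sd = 3, years_gap = 3,
                                       n_new = 0)) {
  w <- vapply(class_specs, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("mixing weights must sum to 1")
  if (n_subjects < length(class_specs))
    stop("n_subjects must be at least the number of classes")
  fu <- utils::modifyList(list(persistence = 0.8, hazard = 0, drift_sd = 3,
                               years_gap = 3, n_new = 0), followup)
  structure(list(n_subjects = as.integer(n_subjects),
                 class_specs = class_specs,
                 n_noise_variables = as.integer(n_noise_variables),
                 noise_sd = noise_sd, seed = as.numeric(seed),
                 followup = fu),
            class = "sim_config")
}

draw_class_rows <- function(spec, n, ids) {
  b <- sim_bounds()
  dr <- function(v) rtrunc_norm(n, spec$cont[[v]][1], spec$cont[[v]][2],
                                b[[v]][1], b[[v]][2])
  age <- dr("age"); fev1 <- dr("fev1_pct"); height <- dr("height")
  wt <- dr("weight")
  fvc <- pmax(dr("fvc_pct"), 0.9 * fev1)
  fvc <- pmin(pmax(fvc, b$fvc_pct[1]), b$fvc_pct[2])
  bras <- pmin(pmax(round(dr("brasfield")), b$brasfield[1]), b$brasfield[2])
  d <- data.frame(
    id = ids,
    age = age,
    gender = ifelse(runif(n) < spec$male_p, "male", "female"),
    cftr_group = sample(cftr_levels(), n, replace = TRUE, prob = spec$cftr_p),
    fev1_pct = fev1, fvc_pct = fvc, height = height, weight = wt,
    bmi = wt / height^2, brasfield = bras,
    pancreatic_sufficient = rbinom(n, 1, spec$ps_p),
    age_fev1_product = age * fev1,
    stringsAsFactors = FALSE)
  for (org in cf_organisms()) d[[org]] <- rbinom(n, 1, spec$traits[[org]])
  d
}

#' Simulate a synthetic CF-like cohort with known latent classes
#'
#' Draws each subject's class from the mixing weights, continuous
#' variables from per-class truncated normals, BMI and the
#' age-by-FEV1\% product deterministically from their factors, traits as
#' per-class Bernoulli flags, and optional iid normal noise columns.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param label cohort label.
#' @return List with `cohort` (a `cf_cohort`) and `labels` (factor of
#'   true class names).
#' @export
simulate_cohort <- function(config, label = "baseline") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  k <- length(config$class_specs)
  nm <- vapply(config$class_specs, function(s) s$name, character(1))
  w <- vapply(config$class_specs, function(s) s$weight, numeric(1))
  with_seed(config$seed, {
    cls <- sample(k, n, replace = TRUE, prob = w)
    ids <- sprintf("S%04d", seq_len(n))
    rows <- vector("list", k)
    for (c in seq_len(k)) {
      idx <- which(cls == c)
      if (length(idx))
        rows[[c]] <- cbind(draw_class_rows(config$class_specs[[c]],
                                           length(idx), ids[idx]),
                           .row = idx)
    }
    d <- do.call(rbind, rows)
    d <- d[order(d$.row), setdiff(names(d), ".row"), drop = FALSE]
    noise_names <- character()
    if (config$n_noise_variables > 0) {
      noise_names <- sprintf("noise_%02d", seq_len(config$n_noise_variables))
      for (v in noise_names) d[[v]] <- rnorm(n, 0, config$noise_sd)
    }
    co <- cohort(d, schema = cf_schema(extra_continuous = noise_names),
                 label = label)
    list(cohort = co, labels = factor(nm[cls], levels = nm))
  })
}

#' Simulate a paired follow-up cohort
#'
#' Emulates a second snapshot of the same clinic some years later: each
#' baseline subject either suffers a death/transplant event (per-class
#' hazard; removed from the follow-up cohort and listed in `events`),
#' persists in class (ages advance by the gap, FEV1\%/FVC\%/weight
#' drift), or transitions to a uniformly-chosen other class with all
#' class-conditional variables redrawn.  New subjects are appended from
#' the mixing weights to emulate clinic growth.
#'
#' @param baseline result of [simulate_cohort()] (list with `cohort`,
#'   `labels`).
#' @param config the [sim_config()] used at baseline (its `followup`
#'   entry drives this function).
#' @return List with `cohort`, `labels` (follow-up classes of surviving
#'   + new subjects) and `events` (data frame `id`, `class0`, `event`).
#' @export
simulate_followup <- function(baseline, config) {
  stopifnot(inherits(config, "sim_config"))
  fu <- config$followup
  specs <- config$class_specs
  k <- length(specs)
  nm <- vapply(specs, function(s) s$name, character(1))
  w <- vapply(specs, function(s) s$weight, numeric(1))
  per <- if (length(fu$persistence) == 1)
    setNames(rep(fu$persistence, k), nm) else fu$persistence[nm]
  haz <- if (length(fu$hazard) == 1)
    setNames(rep(fu$hazard, k), nm) else fu$hazard[nm]
  d0 <- baseline$cohort$data
  lab0 <- as.character(baseline$labels)
  n <- nrow(d0)
  b <- sim_bounds()
  with_seed(derive_seed(config$seed, 2), {
    u_ev <- runif(n); u_per <- runif(n)
    has_event <- u_ev < haz[lab0]
    events <- data.frame(id = d0$id[has_event], class0 = lab0[has_event],
                         event = sample(c("death", "transplant"),
                                        sum(has_event), replace = TRUE),
                         stringsAsFactors = FALSE)
    alive <- which(!has_event)
    moves <- alive[u_per[alive] >= per[lab0[alive]]]
    stays <- setdiff(alive, moves)
    out <- vector("list", 3)
    lab1 <- character(0)
    # persisting subjects: age the record forward with mild drift
    ds <- d0[stays, , drop = FALSE]
    ds$age <- pmin(ds$age + fu$years_gap, b$age[2])
    ds$fev1_pct <- pmin(pmax(ds$fev1_pct + rnorm(nrow(ds), 0, fu$drift_sd),
                             b$fev1_pct[1]), b$fev1_pct[2])
    ds$fvc_pct <- pmin(pmax(pmax(ds$fvc_pct + rnorm(nrow(ds), 0, fu$drift_sd),
                                 0.9 * ds$fev1_pct),
                            b$fvc_pct[1]), b$fvc_pct[2])
    ds$weight <- pmin(pmax(ds$weight + rnorm(nrow(ds), 0, fu$drift_sd / 2),
                           b$weight[1]), b$weight[2])
    ds$bmi <- ds$weight / ds$height^2
    ds$age_fev1_product <- ds$age * ds$fev1_pct
    out[[1]] <- ds; lab1 <- c(lab1, lab0[stays])
    # movers: redrawn from the destination class
    if (length(moves)) {
      dest <- vapply(lab0[moves], function(cl) {
        sample(setdiff(nm, cl), 1)
      }, character(1))
      mrows <- vector("list", length(moves))
      for (i in seq_along(moves)) {
        sp <- specs[[match(dest[i], nm)]]
        mrows[[i]] <- draw_class_rows(sp, 1, d0$id[moves[i]])
      }
      dm <- do.call(rbind, mrows)
      dm$age <- pmin(pmax(d0$age[moves] + fu$years_gap, b$age[1]), b$age[2])
      dm$age_fev1_product <- dm$age * dm$fev1_pct
      out[[2]] <- dm; lab1 <- c(lab1, dest)
    }
    if (fu$n_new > 0) {
      cls_new <- sample(k, fu$n_new, replace = TRUE, prob = w)
      ids_new <- sprintf("N%04d", seq_len(fu$n_new))
      nrows <- vector("list", k)
      for (c in seq_len(k)) {
        idx <- which(cls_new == c)
        if (length(idx))
          nrows[[c]] <- draw_class_rows(specs[[c]], length(idx), ids_new[idx])
      }
      dn <- do.call(rbind, nrows)
      out[[3]] <- dn
      lab1 <- c(lab1, nm[sort(rep(seq_len(k), times = tabulate(cls_new, k)))])
    }
    d1 <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    noise_names <- grep("^noise_", baseline$cohort$schema$name, value = TRUE)
    if (length(noise_names))
      for (v in noise_names) d1[[v]] <- rnorm(nrow(d1), 0, config$noise_sd)
    co <- cohort(d1, schema = baseline$cohort$schema, label = "followup")
    list(cohort = co, labels = factor(lab1, levels = nm), events = events)
  })
}

#' Shipped simulation presets
#'
#' Documented synthetic configurations (parameter values are design
#' choices of this package, not measurements):
#' \describe{
#'   \item{`fig4_like_k5`}{Five classes qualitatively echoing published
#'     adult-CF phenotypes: a low lung-health low-BMI class (A), an
#'     older male class with low product (B), a median-product
#'     female-dominated class (C), a high-product well-nourished
#'     male-dominated class with frequent pancreatic sufficiency and
#'     residual-function CFTR mutations (D), and a young
#'     female-dominated class with modest lung function (E).  n = 211.}
#'   \item{`separable_k3`}{Three widely separated classes (about 3
#'     within-class SDs apart on age and FEV1\%); n = 150.}
#'   \item{`noise_heavy`}{Four classes informative only through the
#'     eight clinical variables age, FEV1\%, FVC\%, height, weight, BMI,
#'     Brasfield and the age-by-FEV1\% product, plus 10 pure-noise
#'     columns; traits and gender carry no class signal.  n = 200.}
#'   \item{`null_one_class`}{A single class: no structure to recover.
#'     n = 150.}
#' }
#'
#' @param name preset name.
#' @param seed seed stored in the returned configuration.
#' @return A [sim_config()].
#' @export
preset <- function(name, seed = 1) {
  presets <- c("fig4_like_k5", "separable_k3", "noise_heavy", "null_one_class")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  if (name == "fig4_like_k5") {
    cs <- list(
      class_spec("A", 0.20, age = c(28, 3), fev1_pct = c(32, 5),
                 fvc_pct = c(48, 7), height = c(1.63, 0.04),
                 weight_kg = c(48, 3.5), brasfield = c(8, 1.5),
                 male_p = 0.5, ps_p = 0.05, cftr_p = c(0.90, 0.02, 0.08),
                 traits = c(pa = 0.85, candida = 0.65, mssa = 0.20,
                            mrsa = 0.20, aspergillus = 0.20)),
      class_spec("B", 0.20, age = c(42, 3), fev1_pct = c(34, 5),
                 fvc_pct = c(52, 7), height = c(1.76, 0.04),
                 weight_kg = c(68, 3.5), brasfield = c(11, 1.5),
                 male_p = 0.85, ps_p = 0.10, cftr_p = c(0.85, 0.05, 0.10),
                 traits = c(pa = 0.75, candida = 0.30, mssa = 0.25)),
      class_spec("C", 0.20, age = c(34, 3), fev1_pct = c(52, 5),
                 fvc_pct = c(70, 7), height = c(1.60, 0.04),
                 weight_kg = c(55, 3.5), brasfield = c(14, 1.5),
                 male_p = 0.15, ps_p = 0.15, cftr_p = c(0.80, 0.10, 0.10),
                 traits = c(pa = 0.25, mssa = 0.50, aspergillus = 0.45,
                            candida = 0.25)),
      class_spec("D", 0.20, age = c(38, 3), fev1_pct = c(78, 5),
                 fvc_pct = c(92, 7), height = c(1.78, 0.04),
                 weight_kg = c(80, 3.5), brasfield = c(19, 1.5),
                 male_p = 0.85, ps_p = 0.50, cftr_p = c(0.35, 0.45, 0.20),
                 traits = c(pa = 0.20, candida = 0.10)),
      class_spec("E", 0.20, age = c(24, 3), fev1_pct = c(48, 5),
                 fvc_pct = c(64, 7), height = c(1.62, 0.04),
                 weight_kg = c(52, 3.5), brasfield = c(12, 1.5),
                 male_p = 0.15, ps_p = 0.15, cftr_p = c(0.80, 0.10, 0.10),
                 traits = c(pa = 0.50, candida = 0.30)))
    return(sim_config(211, cs, seed = seed,
                      followup = list(
                        persistence = c(A = 0.78, B = 0.94, C = 0.78,
                                        D = 0.94, E = 0.85),
                        hazard = c(A = 0.06, B = 0.05, C = 0.01,
                                   D = 0.01, E = 0.02),
                        drift_sd = 3, years_gap = 3, n_new = 92)))
  }
  if (name == "separable_k3") {
    cs <- list(
      class_spec("A", 1 / 3, age = c(25, 3), fev1_pct = c(35, 5),
                 fvc_pct = c(50, 6), height = c(1.60, 0.04),
                 weight_kg = c(48, 3.5), brasfield = c(7, 1.5)),
      class_spec("B", 1 / 3, age = c(35, 3), fev1_pct = c(65, 5),
                 fvc_pct = c(80, 6), height = c(1.70, 0.04),
                 weight_kg = c(60, 3.5), brasfield = c(14, 1.5)),
      class_spec("C", 1 / 3, age = c(50, 3), fev1_pct = c(95, 5),
                 fvc_pct = c(108, 6), height = c(1.78, 0.04),
                 weight_kg = c(75, 3.5), brasfield = c(21, 1.5)))
    return(sim_config(150, cs, seed = seed))
  }
  if (name == "noise_heavy") {
    mk <- function(nm, w, a, f, fv, h, wt, br)
      class_spec(nm, w, age = c(a, 3), fev1_pct = c(f, 5),
                 fvc_pct = c(fv, 6), height = c(h, 0.04),
                 weight_kg = c(wt, 3.5), brasfield = c(br, 1.5),
                 male_p = 0.5, ps_p = 0.2, cftr_p = c(0.8, 0.1, 0.1),
                 traits = c(pa = 0.3, candida = 0.2))
    cs <- list(mk("A", 0.25, 25, 35, 50, 1.60, 48, 7),
               mk("B", 0.25, 32, 55, 70, 1.68, 58, 12),
               mk("C", 0.25, 40, 75, 88, 1.74, 70, 17),
               mk("D", 0.25, 50, 95, 105, 1.80, 82, 22))
    return(sim_config(200, cs, n_noise_variables = 10, seed = seed))
  }
  # null_one_class
  cs <- list(class_spec("A", 1, age = c(32, 6), fev1_pct = c(60, 15),
                        fvc_pct = c(75, 15), height = c(1.70, 0.08),
                        weight_kg = c(62, 8), brasfield = c(14, 3)))
  sim_config(150, cs, seed = seed)
}
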