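test_that("simulation is reproducible and structurally valid", {
  cfg <- preset("fig4_like_k5", seed = 4)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$data, s2$cohort$data)
  expect_identical(s1$labels, s2$labels)
  for (nm in c("fig4_like_k5", "separable_k3", "noise_heavy",
               "null_one_class")) {
    sim <- simulate_cohort(preset(nm, seed = 8))
    expect_length(validate_cohort(sim$cohort), 0)
    d <- sim$cohort$data
    expect_equal(d$bmi, d$weight / d$height^2, tolerance = 1e-12)
    expect_equal(d$age_fev1_product, d$age * d$fev1_pct, tolerance = 1e-12)
    expect_true(all(d$brasfield == round(d$brasfield) &
                      d$brasfield >= 3 & d$brasfield <= 25))
  }
  expect_error(preset("nope"), "fig4_like_k5")
  expect_error(class_spec("X", 1, age = c(150, 5), fev1_pct = c(60, 10),
                          fvc_pct = c(70, 10), height = c(1.7, 0.05),
                          weight_kg = c(60, 5), brasfield = c(12, 2)),
               "bounds")
})

test_that("generator moments match the class specification", {
  spec <- class_spec("only", 1, age = c(35, 4), fev1_pct = c(60, 8),
                     fvc_pct = c(75, 8), height = c(1.70, 0.05),
                     weight_kg = c(62, 5), brasfield = c(14, 2),
                     male_p = 0.6, ps_p = 0.3, traits = c(pa = 0.4))
  sim <- simulate_cohort(sim_config(2000, list(spec), seed = 21))
  d <- sim$cohort$data
  for (v in c("age", "fev1_pct", "height", "weight")) {
    mu <- spec$cont[[if (v == "weight") "weight" else v]][1]
    sdv <- spec$cont[[if (v == "weight") "weight" else v]][2]
    expect_lt(abs(mean(d[[v]]) - mu), 3 * sdv / sqrt(2000))
  }
  expect_lt(abs(mean(d$gender == "male") - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
  expect_lt(abs(mean(d$pancreatic_sufficient) - 0.3),
            3 * sqrt(0.3 * 0.7 / 2000))
  expect_lt(abs(mean(d$pa) - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
  # fvc stays plausible relative to fev1
  expect_true(all(d$fvc_pct >= 0.9 * d$fev1_pct - 1e-9))
})

test_that("follow-up with full persistence and no hazard is a fixed point", {
  cfg <- preset("separable_k3", seed = 31)
  cfg$followup <- list(persistence = 1, hazard = 0, drift_sd = 0,
                       years_gap = 3, n_new = 0)
  base <- simulate_cohort(cfg)
  fu <- simulate_followup(base, cfg)
  expect_equal(nrow(fu$events), 0)
  expect_identical(as.character(fu$labels), as.character(base$labels))
  expect_equal(fu$cohort$data$age, base$cohort$data$age + 3)
  expect_equal(fu$cohort$data$fev1_pct, base$cohort$data$fev1_pct)
})

test_that("events concentrate in the high-hazard class", {
  cfg <- preset("fig4_like_k5", seed = 51)
  cfg$followup$hazard <- c(A = 0.5, B = 0.02, C = 0.005, D = 0.005, E = 0.005)
  base <- simulate_cohort(cfg)
  fu <- simulate_followup(base, cfg)
  expect_gt(nrow(fu$events), 0)
  expect_gte(mean(fu$events$class0 == "A"), 0.8)
})

test_that("the one-class preset has no recoverable structure", {
  sim <- simulate_cohort(preset("null_one_class", seed = 61))
  res <- run_two_stage(sim$cohort,
                       pipeline_config(k = 3,
                                       forest = forest_config(n_trees = 80,
                                                              seed = 61)))
  arbitrary <- rep_len(1:3, nrow(sim$cohort$data))
  expect_lt(abs(ari(res$assignment, arbitrary)), 0.05)
})
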