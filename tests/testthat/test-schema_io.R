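test_that("cohort tables round-trip exactly through write and load", {
  co <- toy_cohort(n = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- load_cohort(path, schema = co$schema, label = co$label)
  expect_equal(nrow(co2$data), 5)
  expect_equal(nrow(co2$rejections), 0)
  for (v in c("id", co$schema$name))
    expect_identical(unname(co2$data[[v]]), unname(co$data[[v]]))
  # second round trip is also exact
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("rows with missing or bad values are rejected with line numbers", {
  co <- toy_cohort(n = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path)
  header <- strsplit(lines[1], ",")[[1]]
  fev_col <- which(header == "fev1_pct")
  row2 <- strsplit(lines[3], ",")[[1]]
  row2[fev_col] <- ""
  lines[3] <- paste(row2, collapse = ",")
  writeLines(lines, path)
  co2 <- load_cohort(path, schema = co$schema)
  expect_equal(nrow(co2$data), 2)
  expect_equal(co2$rejections$line, 3L)
  expect_match(co2$rejections$reason, "fev1_pct")
  # unparseable value is reported distinctly
  row4 <- strsplit(lines[4], ",")[[1]]
  row4[fev_col] <- "not-a-number"
  lines[4] <- paste(row4, collapse = ",")
  writeLines(lines, path)
  co3 <- load_cohort(path, schema = co$schema)
  expect_equal(nrow(co3$data), 1)
  expect_match(co3$rejections$reason[2], "unparseable")
  # a missing column is a schema error, not a row rejection
  writeLines(gsub("fev1_pct", "wrong_name", readLines(path)), path)
  expect_error(load_cohort(path, schema = co$schema), "fev1_pct")
})

test_that("derive_features computes BMI and the lung-health product and is idempotent", {
  co <- toy_cohort(n = 6, seed = 2)
  co$data$age[1] <- 40; co$data$fev1_pct[1] <- 50
  co$data$height[2] <- 1.70; co$data$weight[2] <- 57.8
  # keep stored derived values consistent with the edited raw fields
  co$data$bmi <- co$data$weight / co$data$height^2
  co$data$age_fev1_product <- co$data$age * co$data$fev1_pct
  d1 <- derive_features(co)
  expect_equal(d1$data$age_fev1_product[1], 2000)
  expect_equal(d1$data$bmi[2], 20.0, tolerance = 0.01 / 20)
  d2 <- derive_features(d1)
  expect_identical(d1$data, d2$data)
  # stored values inconsistent by > 1% trigger a validation warning
  co$data$bmi[3] <- co$data$bmi[3] * 1.10
  expect_warning(derive_features(co), "bmi")
  co$data$height[4] <- 0
  expect_error(derive_features(co), "height")
})

test_that("severity bands partition the product axis at 1000 and 1600", {
  expect_equal(as.character(severity_band(c(900, 1300, 1700))),
               c("severe", "moderate", "mild"))
  grid <- c(0, 500, 999.999, 1000, 1200, 1600, 1600.001, 5000)
  bands <- severity_band(grid)
  expect_false(anyNA(bands))          # every product maps to exactly one band
  expect_equal(as.character(bands[grid < 1000]),
               rep("severe", sum(grid < 1000)))
  expect_equal(as.character(bands[grid >= 1000 & grid <= 1600]),
               rep("moderate", sum(grid >= 1000 & grid <= 1600)))
  expect_error(severity_band(-1), "non-negative")
})

test_that("microbiology presence needs two positives inside the 12-month window", {
  recs <- data.frame(
    subject_id = c("s1", "s1", "s2", "s3", "s3"),
    date = c("2014-01-15", "2014-04-15",   # two PA, 3 months apart
             "2014-05-01",                 # one PA only
             "2013-05-28", "2014-05-01"),  # one of the two is 400 days old
    organism = "pa",
    positive = 1)
  flags <- aggregate_microbiology(recs, reference_date = "2014-07-01")
  expect_equal(flags$pa, c(1, 0, 0))
  # negative cultures never count
  recs$positive[2] <- 0
  expect_equal(aggregate_microbiology(recs, "2014-07-01")$pa, c(0, 0, 0))
  expect_error(aggregate_microbiology(transform(recs, organism = "ecoli"),
                                      "2014-07-01"), "unknown organism")
})

test_that("adding a positive culture is monotone for presence flags", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- 20
      recs <- data.frame(
        subject_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
        date = as.character(as.Date("2014-07-01") - sample(0:500, n, TRUE)),
        organism = sample(c("pa", "mssa", "candida"), n, TRUE),
        positive = rbinom(n, 1, 0.7))
      before <- aggregate_microbiology(recs, "2014-07-01")
      extra <- data.frame(subject_id = sample(c("s1", "s2", "s3"), 1),
                          date = "2014-06-01", organism = "pa", positive = 1)
      after <- aggregate_microbiology(rbind(recs, extra), "2014-07-01")
      for (org in cf_organisms())
        expect_true(all(after[[org]] >= before[[org]]))
    }
  })
})

test_that("combination traits are the commutative AND of their parts", {
  expect_equal(combo_trait(c(1, 1, 0, 0), c(1, 0, 1, 0)), c(1, 0, 0, 0))
  co <- toy_cohort(n = 30, seed = 9)
  expect_identical(combo_trait(co$data$pa, co$data$candida),
                   combo_trait(co$data$candida, co$data$pa))
})
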