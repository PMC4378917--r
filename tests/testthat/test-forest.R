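test_that("a single tree separates separable data and stops at purity", {
  tr <- grow_tree(data.frame(x = c(1, 2, 9, 10)),
                  c("A", "A", "B", "B"))
  expect_true(tr$thr[1] > 2 && tr$thr[1] < 9)
  pred <- predict(tr, data.frame(x = c(1, 2, 9, 10)))
  expect_equal(as.character(pred), c("A", "A", "B", "B"))
  # all labels identical: a single leaf
  leaf <- grow_tree(data.frame(x = c(1, 2, 3)), c("A", "A", "A"))
  expect_equal(leaf$var, -1L)
  # XOR needs depth >= 2 and is solved exactly (zero-gain root split)
  xor_x <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  xor_y <- c("A", "B", "B", "A")
  tr2 <- grow_tree(xor_x, xor_y, mtry = 2)
  expect_gte(tree_depth(tr2), 2L)
  expect_equal(as.character(predict(tr2, xor_x)), xor_y)
})

test_that("the Gini split finder matches exhaustive enumeration", {
  withr::with_seed(11, {
    for (case in 1:20) {
      m <- sample(5:30, 1)
      X <- matrix(round(rnorm(m * 3), 2), m, 3,
                  dimnames = list(NULL, c("v1", "v2", "v3")))
      y <- sample(c("A", "B", if (case %% 2) "C"), m, replace = TRUE)
      if (length(unique(y)) < 2) next
      tr <- grow_tree(as.data.frame(X), y, mtry = 3, seed = case)
      orc <- oracle_best_split(X, y)
      if (is.na(orc$var)) {
        expect_equal(tr$var[1], -1L)
      } else {
        expect_equal(tr$var[1] + 1L, orc$var)
        expect_equal(tr$thr[1], orc$thr, tolerance = 1e-12)
      }
    }
  })
})

test_that("forests are deterministic given the seed", {
  b <- make_blobs(n_per = 20, sd = 1, seed = 2)
  cfg <- forest_config(n_trees = 25, seed = 99)
  f1 <- fit_supervised_forest(b$x, b$y, cfg)
  f2 <- fit_supervised_forest(b$x, b$y, cfg)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(oob_evaluate(f1)$predicted, oob_evaluate(f2)$predicted)
  expect_identical(permutation_importance(f1), permutation_importance(f2))
  # growing more trees leaves earlier trees untouched
  f3 <- fit_supervised_forest(b$x, b$y, forest_config(n_trees = 40, seed = 99))
  expect_identical(f3$trees[1:25], f1$trees)
})

test_that("OOB error is small on separated classes and ~50% under a label null", {
  b <- make_blobs(n_per = 50, centers = c(0, 10), sd = 0.1, seed = 4)
  f <- fit_supervised_forest(b$x, b$y, forest_config(n_trees = 100, seed = 1))
  expect_lt(oob_evaluate(f)$error_rate, 0.02)
  # permuted labels, balanced binary
  withr::with_seed(8, {
    xn <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
    yn <- factor(rep(c("a", "b"), 100))
  })
  fn <- fit_supervised_forest(xn, yn, forest_config(n_trees = 150, seed = 2))
  err <- oob_evaluate(fn)$error_rate
  expect_gte(err, 0.4)
  expect_lte(err, 0.6)
  expect_error(fit_supervised_forest(xn, factor(rep("a", 200))), "two classes")
})

test_that("OOB bookkeeping matches the bootstrap complement", {
  b <- make_blobs(n_per = 15, sd = 1, seed = 6)
  f <- suppressWarnings(  # a 1-tree forest leaves in-bag rows uncovered
    fit_supervised_forest(b$x, b$y, forest_config(n_trees = 1, seed = 3)))
  ev <- oob_evaluate(f)
  oob_rows <- which(f$inbag[, 1] == 0)
  expect_equal(which(!is.na(ev$predicted)), oob_rows)
  expect_equal(ev$n_never_oob, nrow(b$x) - length(oob_rows))
  # confusion row sums equal class counts among OOB-covered rows
  f2 <- fit_supervised_forest(b$x, b$y, forest_config(n_trees = 60, seed = 3))
  ev2 <- oob_evaluate(f2)
  covered <- !is.na(ev2$predicted)
  expect_equal(as.vector(rowSums(ev2$confusion)),
               as.vector(table(b$y[covered])))
})

test_that("synthetic contrast resamples marginals and breaks dependence", {
  withr::with_seed(10, {
    x <- data.frame(u = rnorm(1000))
    x$v <- x$u                       # perfectly correlated pair
    x$w <- 5                         # constant column
    x$g <- factor(sample(c("p", "q"), 1000, TRUE))
  })
  ctr <- make_synthetic_contrast(x, seed = 42)
  expect_equal(nrow(ctr$features), 2000)
  expect_equal(as.character(unique(ctr$labels)), c("observed", "synthetic"))
  synth <- ctr$features[1001:2000, ]
  for (col in c("u", "v", "w"))
    expect_true(all(synth[[col]] %in% x[[col]]))
  expect_true(all(synth$w == 5))
  expect_lt(abs(cor(synth$u, synth$v)), 0.1)
  expect_gt(abs(cor(x$u, x$v)), 0.99)
})

test_that("unsupervised forests separate structured data from its marginals", {
  # two tight blobs described redundantly by six coordinates: the
  # marginal-product synthetic class rarely reproduces a consistent
  # combination, so the real class is easy to recognise
  withr::with_seed(5, {
    g <- rep(c(0, 10), each = 30)
    x <- as.data.frame(lapply(1:6, function(j) g + rnorm(60, 0, 0.1)))
    names(x) <- paste0("x", 1:6)
  })
  f <- fit_unsupervised_forest(x, forest_config(n_trees = 100, seed = 11))
  expect_true(f$unsupervised)
  expect_lt(oob_evaluate(f)$error_rate, 0.20)
  P <- compute_proximity(f)
  expect_equal(dim(P), c(60, 60))    # proximity covers original rows only
})

test_that("proximity matches the brute-force pair-trace oracle", {
  withr::with_seed(21, {
    x <- data.frame(a = rnorm(30), b = rnorm(30),
                    g = factor(sample(c("u", "v", "w"), 30, TRUE)))
    y <- factor(sample(c("A", "B"), 30, TRUE))
  })
  rownames(x) <- sprintf("r%02d", 1:30)
  f <- suppressWarnings(
    fit_supervised_forest(x, y, forest_config(n_trees = 10, seed = 7)))
  P <- compute_proximity(f)
  expect_equal(unclass(P), oracle_proximity(f), ignore_attr = TRUE,
               tolerance = 1e-12)
  fu <- suppressWarnings(
    fit_unsupervised_forest(x, forest_config(n_trees = 10, seed = 7)))
  Pu <- compute_proximity(fu)
  expect_equal(unclass(Pu), oracle_proximity(fu), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("proximity is a unit-diagonal similarity that tracks cluster structure", {
  b <- make_blobs(n_per = 20, centers = c(0, 8), sd = 0.2, seed = 9)
  x <- b$x
  x[11, ] <- x[10, ]  # duplicated row pair
  f <- fit_unsupervised_forest(x, forest_config(n_trees = 60, seed = 13))
  P <- compute_proximity(f)
  expect_equal(unclass(P), t(unclass(P)))
  expect_true(all(diag(P) == 1))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(P[10, 11], 1)  # identical rows share every leaf
  within <- c(P[1:20, 1:20][upper.tri(diag(20))],
              P[21:40, 21:40][upper.tri(diag(20))])
  between <- P[1:20, 21:40]
  expect_gt(mean(within), mean(between))
})

test_that("permutation importance finds signal and calibrates at zero on noise", {
  withr::with_seed(33, {
    n <- 120
    x <- data.frame(signal = rep(c(0, 6), each = n / 2) + rnorm(n, 0, 0.5),
                    noise = rnorm(n),
                    const = rep(1.5, n))
    y <- factor(rep(c("A", "B"), each = n / 2))
  })
  f <- fit_supervised_forest(x, y, forest_config(n_trees = 120, seed = 17))
  imp <- permutation_importance(f)
  expect_equal(imp$variable[imp$rank == 1], "signal")
  expect_identical(imp$mean_decrease_accuracy[imp$variable == "const"], 0)
  noise_row <- imp[imp$variable == "noise", ]
  expect_lt(abs(noise_row$mean_decrease_accuracy), 2 * noise_row$se)
})

test_that("OOB error agrees with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  withr::with_seed(9, {
    x <- data.frame(a = rep(c(0, 1.5), each = 60) + rnorm(120),
                    b = rep(c(0, 1.5), each = 60) + rnorm(120))
    y <- factor(rep(c("A", "B"), each = 60))
  })
  f <- fit_supervised_forest(x, y, forest_config(n_trees = 300, seed = 2))
  ours <- oob_evaluate(f)$error_rate
  theirs <- withr::with_seed(2, {
    randomForest::randomForest(x, y, ntree = 300)$err.rate[300, "OOB"]
  })
  expect_lt(abs(ours - theirs), 0.06)
})

test_that("importance is centred at zero under the label null", {
  # A single permuted-label dataset still contains real chance
  # associations that trees legitimately learn, so calibration must be
  # checked across replicate datasets, not across trees of one forest.
  means <- withr::with_seed(55, vapply(1:30, function(r) {
    x <- data.frame(a = rnorm(120), b = rnorm(120),
                    g = factor(sample(c("m", "f"), 120, TRUE)))
    y <- factor(sample(rep(c("A", "B"), 60)))
    f <- fit_supervised_forest(x, y, forest_config(n_trees = 60, seed = r))
    permutation_importance(f)$mean_decrease_accuracy
  }, numeric(3)))
  grand <- rowMeans(means)
  se <- apply(means, 1, sd) / sqrt(ncol(means))
  expect_true(all(abs(grand) <= 3 * se))
})
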