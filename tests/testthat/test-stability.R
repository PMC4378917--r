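test_that("class matching recovers a planted permutation", {
  withr::with_seed(41, {
    a0 <- setNames(sample(LETTERS[1:4], 60, TRUE), sprintf("s%02d", 1:60))
  })
  perm <- c(A = "C", B = "D", C = "A", D = "B")
  a1 <- setNames(perm[a0], names(a0))
  m <- match_classes(a0, a1)
  expect_equal(m$mapping, perm)
  expect_equal(m$total_overlap, 60)
  # symmetry: matching the other way is the inverse mapping
  m_rev <- match_classes(a1, a0)
  expect_equal(m_rev$mapping[m$mapping], setNames(names(m$mapping), m$mapping))
  expect_error(match_classes(a0, setNames(rep("X", 60), names(a0))),
               "equal k")
})

test_that("matching equals the brute-force optimum on random overlaps", {
  withr::with_seed(43, {
    for (i in 1:15) {
      k <- sample(2:4, 1)
      n <- 30
      ids <- sprintf("s%02d", 1:n)
      a0 <- setNames(sample(LETTERS[1:k], n, TRUE), ids)
      a1 <- setNames(sample(letters[1:k], n, TRUE), ids)
      if (length(unique(a0)) < k || length(unique(a1)) < k) next
      m <- match_classes(a0, a1)
      ov <- table(a0, a1)
      brute <- max(vapply(phenoforest:::permutations(k), function(p)
        sum(ov[cbind(seq_len(k), p)]), numeric(1)))
      expect_equal(m$total_overlap, brute)
    }
  })
})

test_that("transition counts, p and f statistics follow their definitions", {
  ids <- sprintf("s%02d", 1:20)
  a0 <- setNames(rep(c("A", "B"), each = 10), ids)
  a1 <- a0
  tr0 <- transition_report(a0, a1)
  expect_equal(sum(tr0$counts) - sum(diag(tr0$counts)), 0)
  expect_equal(unname(tr0$p_transitions), c(0, 0))
  # move 2 of the 10 A subjects to B
  a1[c("s01", "s02")] <- "B"
  tr <- transition_report(a0, a1)
  expect_equal(unname(tr$p_transitions["A"]), 0.2)
  expect_equal(unname(tr$f_transitions["B"]), 1)
  expect_equal(sum(tr$f_transitions), 1)
  # conservation: margins equal class sizes at each time point
  expect_equal(as.vector(rowSums(tr$counts)), as.vector(table(a0)))
  expect_equal(as.vector(colSums(tr$counts)), as.vector(table(a1)))
  expect_equal(sum(tr$counts), 20)
})

test_that("relabeling both clusterings together leaves the report invariant", {
  withr::with_seed(47, {
    ids <- sprintf("s%03d", 1:80)
    a0 <- setNames(sample(LETTERS[1:3], 80, TRUE), ids)
    a1 <- a0
    movers <- sample(ids, 20)
    a1[movers] <- vapply(a0[movers], function(cl)
      sample(setdiff(LETTERS[1:3], cl), 1), character(1))
  })
  relab <- c(A = "B", B = "C", C = "A")
  tr1 <- transition_report(a0, a1)
  tr2 <- transition_report(setNames(relab[a0], ids), setNames(relab[a1], ids))
  expect_equal(sort(unname(tr1$p_transitions)), sort(unname(tr2$p_transitions)))
  expect_equal(sort(unname(tr1$f_transitions)), sort(unname(tr2$f_transitions)))
  expect_equal(tr1$n_transitions, tr2$n_transitions)
})

test_that("death/transplant subjects are tallied, not counted as transitions", {
  ids <- sprintf("s%02d", 1:12)
  a0 <- setNames(rep(c("A", "B"), each = 6), ids)
  a1 <- a0[1:10]  # two subjects gone by follow-up
  ev <- data.frame(id = c("s11", "s12"), event = c("death", "transplant"))
  tr <- transition_report(a0, a1, events = ev)
  expect_equal(length(tr$shared_ids), 10)
  expect_equal(sum(tr$counts), 10)
  expect_equal(as.vector(tr$events["B", ]), c(1, 1))
})

test_that("simulated follow-up transition fractions track the persistence rate", {
  cfg <- preset("separable_k3", seed = 77)
  cfg$followup$persistence <- 0.8
  cfg$followup$hazard <- 0
  base <- simulate_cohort(cfg)
  fracs <- vapply(1:30, function(r) {
    cfg2 <- cfg
    cfg2$seed <- phenoforest:::derive_seed(77, 100 + r)
    b <- simulate_cohort(cfg2)
    fu <- simulate_followup(b, cfg2)
    a0 <- setNames(as.character(b$labels), b$cohort$data$id)
    a1 <- setNames(as.character(fu$labels), fu$cohort$data$id)
    shared <- intersect(names(a0), names(a1))
    mean(a0[shared] != a1[shared])
  }, numeric(1))
  se <- sqrt(0.2 * 0.8 / (150 * 30))
  expect_lt(abs(mean(fracs) - 0.2), 4 * se)
})
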