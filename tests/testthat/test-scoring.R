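# Charge pools, survival scoring matrices, paired sets, lookups.

test_that("charge pool aggregates and partitions corpus charges", {
  bps <- list(fake_blueprint(c(0.1, -0.2, 0.3), c("C", "O", "C")),
              fake_blueprint(c(0, 0.5, -0.5, 0.2), c("C", "C", "N", "O")))
  pool <- build_charge_pool(bps)
  expect_length(pool$charges, 7L)
  expect_equal(pool$n_molecules, 2L)
  expect_equal(sum(lengths(pool$per_element)), length(pool$charges))
  expect_setequal(names(pool$per_element), c("C", "N", "O"))
  expect_equal(sort(pool$per_element$O), sort(c(-0.2, 0.2)))
  expect_error(build_charge_pool(list()), "empty corpus")
})

test_that("pairwise differences cover i<j pairs or the full cross product", {
  expect_setequal(round(pairwise_abs_differences(c(0, 0.1, 0.3)), 10),
                  c(0.1, 0.3, 0.2))
  expect_length(pairwise_abs_differences(0.5), 0L)
  expect_setequal(pairwise_abs_differences(0, c(0.2, 0.5)), c(0.2, 0.5))
  expect_length(pairwise_abs_differences(c(1, 2), c(1, 2, 3)), 6L)
  expect_error(pairwise_abs_differences(numeric(0)), "empty")
})

test_that("toy matrix reproduces hand-enumerated survival scores", {
  m <- build_scoring_matrix(c(0.1, 0.2, 0.3))
  expect_equal(m$raw_scores[1], 0)              # P(d >= 0) = 1
  expect_equal(m$raw_scores[2], log2(3 / 3))
  expect_equal(m$raw_scores[3], log2(2 / 3))
  expect_equal(m$raw_scores[4], log2(1 / 3))
  # mean = 0.2 sits in bin 2 (0-based): that bin scores exactly 0,
  # smaller-difference bins positive, larger negative
  expect_equal(m$mean_diff, 0.2)
  expect_equal(m$mean_bin, 3L)
  expect_equal(m$scores[3], 0)
  expect_equal(m$scores[1], -log2(2 / 3))
  expect_equal(m$scores[4], -1)
  expect_equal(m$floor, min(m$scores))
  expect_error(build_scoring_matrix(numeric(0)), "no differences")
})

test_that("matrix entries equal a brute-force survival recount on small pools", {
  set.seed(7)
  for (rep in 1:5) {
    diffs <- round(runif(sample(3:10, 1), 0, 3.5), 3)
    m <- build_scoring_matrix(diffs)
    for (k in seq_len(30)) {
      s <- brute_survival(diffs, (k - 1) / 10)
      expected <- if (s == 0) log2(1 / length(diffs)) else log2(s)
      expect_equal(m$raw_scores[k], expected)
    }
    expect_equal(m$raw_scores[1], 0)
    expect_true(all(diff(m$raw_scores) <= 1e-12))
  }
})

test_that("identical charges give a zero bin and a floor plateau", {
  m <- build_scoring_matrix(rep(0, 10))  # 5 molecules of one identical atom
  expect_equal(m$scores[1], 0)
  expect_true(all(m$scores[-1] == m$floor))
  expect_equal(m$raw_scores[2], log2(1 / 10))  # empty-tail pseudo-count
})

test_that("normalization shifts sign exactly at the mean bin", {
  set.seed(11)
  for (rep in 1:10) {
    diffs <- abs(rnorm(200, 0, 0.6))
    m <- build_scoring_matrix(diffs)
    expect_equal(m$scores[m$mean_bin], 0)
    if (m$mean_bin > 1) expect_true(all(m$scores[1:(m$mean_bin - 1)] >= 0))
    if (m$mean_bin < 30) expect_true(all(m$scores[(m$mean_bin + 1):30] <= 0))
  }
})

test_that("all-vs-all composition matches the direct construction", {
  bps <- list(fake_blueprint(c(0.0, 0.1)), fake_blueprint(0.3))
  m <- build_all_vs_all(bps)
  direct <- build_scoring_matrix(pairwise_abs_differences(c(0, 0.1, 0.3)))
  expect_equal(m$raw_scores, direct$raw_scores)
  expect_equal(m$scores, direct$scores)
})

test_that("paired set stores observed pairs and falls back elsewhere", {
  carbons <- list(fake_blueprint(c(0.0, 0.1, 0.25)),
                  fake_blueprint(c(0.05, -0.1)))
  pset <- build_paired(carbons, min_pair_observations = 5)
  expect_named(pset$matrices, "C|C")
  # a pair never observed resolves through the fallback
  expect_equal(score_lookup(pset, "C", 0.1, "O", 0.1),
               score_lookup(pset$fallback, "C", 0.1, "O", 0.1))
  # the C-C matrix equals the direct build on the pooled carbon differences
  direct <- build_scoring_matrix(
    pairwise_abs_differences(c(0, 0.1, 0.25, 0.05, -0.1)))
  expect_equal(pset$matrices[["C|C"]]$scores, direct$scores)

  # below-threshold pairs are not stored
  tiny <- build_paired(carbons, min_pair_observations = 1000)
  expect_length(tiny$matrices, 0L)
})

test_that("within-molecule pooling restricts pairing to each molecule", {
  bps <- list(fake_blueprint(c(0.0, 0.1)), fake_blueprint(c(1.0, 1.4)))
  pset <- build_paired(bps, min_pair_observations = 1, within_molecules = TRUE)
  # only the two intra-molecule differences 0.1 and 0.4 contribute
  expect_equal(pset$matrices[["C|C"]]$n_observations, 2L)
  expect_equal(pset$matrices[["C|C"]]$mean_diff, mean(c(0.1, 0.4)))
})

test_that("score lookup bins, clamps and is symmetric", {
  m <- fake_matrix(seq(0, -29))  # bin k scores -(k-1): easy to read off
  expect_equal(score_lookup(m, "C", 0.5, "C", 0.5), 0)
  expect_equal(score_lookup(m, "C", 5, "C", 0), -29)   # |d|=5 clamps
  expect_equal(score_lookup(m, "C", 0.1, "O", -0.25), -3)  # bin 3 (0-based)
  set.seed(3)
  for (rep in 1:20) {
    qa <- rnorm(1); qb <- rnorm(1)
    expect_equal(score_lookup(m, "C", qa, "O", qb),
                 score_lookup(m, "O", qb, "C", qa))
  }
})

test_that("matrices and paired sets survive a serialization round trip", {
  bps <- list(fake_blueprint(c(0.1, -0.3), c("C", "O")),
              fake_blueprint(c(0.2, 0.05, -0.15), c("C", "C", "O")))
  m <- build_all_vs_all(bps)
  pre <- file.path(tempdir(), "avsa")
  write_scoring_matrix(m, pre)
  m2 <- read_scoring_matrix(pre)
  expect_equal(m2$scores, m$scores)
  expect_equal(m2$raw_scores, m$raw_scores)
  expect_equal(m2$mean_diff, m$mean_diff)
  expect_equal(m2$n_observations, m$n_observations)

  pset <- build_paired(bps, min_pair_observations = 1)
  dir <- file.path(tempdir(), "paired")
  write_paired_set(pset, dir)
  p2 <- read_paired_set(dir)
  expect_setequal(names(p2$matrices), names(pset$matrices))
  for (key in names(pset$matrices))
    expect_equal(p2$matrices[[key]]$scores, pset$matrices[[key]]$scores)
  expect_equal(p2$fallback$scores, pset$fallback$scores)
  unlink(c(paste0(pre, c(".csv", ".json")), dir), recursive = TRUE)
})
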