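# Affine-gap dynamic program: fill, traceback, whole-molecule alignment.

test_that("single-pair and all-gap boundary scores follow the recurrences", {
  m <- toy_scorer()
  a <- fake_blueprint(0.05); b <- fake_blueprint(0.05)
  st <- align_fill(a, b, m, gap_penalties(2, 1))
  expect_equal(st$F[2, 2], m$scores[1])

  # length-k molecule against an empty one: one opened, k-1 extended
  for (k in c(1, 3, 5)) {
    bp <- fake_blueprint(seq_len(k) / 10)
    empty <- compute_blueprint("")
    for (pen in list(c(2, 1), c(0, 0), c(-3, 1), c(4, -2))) {
      st <- align_fill(bp, empty, m, gap_penalties(pen[1], pen[2]))
      expect_equal(max(st$M[k + 1, 1], st$X[k + 1, 1], st$Y[k + 1, 1]),
                   -pen[1] - (k - 1) * pen[2])
    }
  }
})

test_that("optimal scores equal exhaustive alignment enumeration", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    S <- matrix(rnorm(n * m, 0, 3), n, m)
    a <- fake_blueprint(rnorm(n)); b <- fake_blueprint(rnorm(m))
    for (p in 1:4) {
      pen <- runif(2, -3, 5)
      st <- align_fill(a, b, toy_scorer(), gap_penalties(pen[1], pen[2]),
                       S = S)
      got <- max(st$M[n + 1, m + 1], st$X[n + 1, m + 1], st$Y[n + 1, m + 1])
      expect_equal(got, oracle_align_score(S, n, m, pen[1], pen[2]),
                   tolerance = 1e-10)
    }
  }
})

test_that("traceback rescoring reproduces the lattice optimum", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(1:7, 1); m <- sample(1:7, 1)
    S <- matrix(rnorm(n * m, 0, 3), n, m)
    pen <- gap_penalties(runif(1, -2, 4), runif(1, -2, 4))
    st <- align_fill(fake_blueprint(rnorm(n)), fake_blueprint(rnorm(m)),
                     toy_scorer(), pen, S = S)
    tb <- align_traceback(st)
    # structural invariants of the emitted alignment
    expect_gte(length(tb$a_idx), max(n, m))
    expect_false(any(is.na(tb$a_idx) & is.na(tb$b_idx)))
    expect_equal(tb$a_idx[!is.na(tb$a_idx)], seq_len(n))
    expect_equal(tb$b_idx[!is.na(tb$b_idx)], seq_len(m))
    # independent column-wise rescoring equals F(n, m)
    expect_equal(rescore_alignment(tb$a_idx, tb$b_idx, S,
                                   pen$g_open, pen$g_extend),
                 max(st$M[n + 1, m + 1], st$X[n + 1, m + 1],
                     st$Y[n + 1, m + 1]),
                 tolerance = 1e-10)
  }
})

test_that("self-alignment is gap-free with score n * scores[0]", {
  corp <- builtin_corpus("demo")
  bps <- compute_blueprints(corp$smiles, corp$id)
  mat <- build_all_vs_all(bps)
  for (k in c(2, 4, 7)) {
    al <- align_molecules(bps[[k]], bps[[k]], mat, gap_penalties(1, 1))
    expect_false(any(is.na(al$aligned_a)))
    expect_false(any(is.na(al$aligned_b)))
    expect_equal(al$score, length(bps[[k]]$charges) * mat$scores[1])
    expect_identical(al$aligned_smiles_a, bps[[k]]$canonical_smiles)
  }
})

test_that("alignment against an empty molecule is a single gap block", {
  mat <- toy_scorer()
  al <- align_molecules("C", "", mat, gap_penalties(2, 1))
  expect_equal(length(al$aligned_a), 1L)
  expect_true(is.na(al$aligned_b))
  expect_equal(al$score, -2)
  expect_identical(al$aligned_smiles_b, "-")
})

test_that("the optimal score is invariant under argument swap", {
  corp <- builtin_corpus("krebs")
  bps <- compute_blueprints(corp$smiles, corp$id)
  mat <- build_all_vs_all(bps)
  for (pair in list(c(1, 2), c(3, 5), c(6, 7))) {
    ab <- align_molecules(bps[[pair[1]]], bps[[pair[2]]], mat,
                          gap_penalties(1, 0))
    ba <- align_molecules(bps[[pair[2]]], bps[[pair[1]]], mat,
                          gap_penalties(1, 0))
    expect_equal(ab$score, ba$score)
    # and gaps removed always recover the inputs
    expect_identical(ab$aligned_a[!is.na(ab$aligned_a)],
                     bps[[pair[1]]]$tokens$symbol)
    expect_identical(ab$aligned_b[!is.na(ab$aligned_b)],
                     bps[[pair[2]]]$tokens$symbol)
  }
})

test_that("a more penalizing gap open never increases the optimum", {
  set.seed(99)
  for (rep in 1:15) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    S <- matrix(rnorm(n * m, 0, 3), n, m)
    a <- fake_blueprint(rnorm(n)); b <- fake_blueprint(rnorm(m))
    ge <- runif(1, -1, 2)
    opens <- sort(runif(4, -3, 5))
    scores <- vapply(opens, function(go) {
      st <- align_fill(a, b, toy_scorer(), gap_penalties(go, ge), S = S)
      max(st$M[n + 1, m + 1], st$X[n + 1, m + 1], st$Y[n + 1, m + 1])
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-10))
  }
})

test_that("independent blocks add under a forced-diagonal matrix", {
  # two identical sequences, huge diagonal reward: the optimum is the
  # gap-free diagonal, so scores add when blocks are concatenated
  diag_scorer <- fake_matrix(c(10, rep(-50, 29)))
  q1 <- c(0.0, 0.5, 1.0); q2 <- c(2.0, 2.5)
  s1 <- align_molecules(fake_blueprint(q1), fake_blueprint(q1),
                        diag_scorer, gap_penalties(3, 2))$score
  s2 <- align_molecules(fake_blueprint(q2), fake_blueprint(q2),
                        diag_scorer, gap_penalties(3, 2))$score
  s12 <- align_molecules(fake_blueprint(c(q1, q2)),
                         fake_blueprint(c(q1, q2)),
                         diag_scorer, gap_penalties(3, 2))$score
  expect_equal(s12, s1 + s2)
})

test_that("paired mode selects pair matrices inside the alignment", {
  bps <- list(fake_blueprint(c(0.1, -0.2, 0.15, -0.25), c("C", "O", "C", "O")),
              fake_blueprint(c(0.12, -0.22, 0.4), c("C", "O", "N")))
  pset <- build_paired(bps, min_pair_observations = 1)
  a <- bps[[1]]; b <- bps[[2]]
  S <- smialign:::.substitution_matrix(pset, a, b)
  for (i in seq_along(a$charges)) for (j in seq_along(b$charges)) {
    expect_equal(S[i, j],
                 score_lookup(pset, a$tokens$element[i], a$charges[i],
                              b$tokens$element[j], b$charges[j]))
  }
})
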