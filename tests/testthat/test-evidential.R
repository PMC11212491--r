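test_that("evidence maps to a normalised Dirichlet opinion", {
  op <- opinion_from_evidence(rbind(c(4, 0), c(9, 9), c(0, 0)))
  # row (4,0): alpha = (5,1), S = 6 -> p = (2/3, 0), u = 2/6
  expect_equal(op$P[1, ], c(4 / 6, 0), tolerance = 1e-12)
  expect_equal(op$U[1], 2 / 6, tolerance = 1e-12)
  # row (9,9): S = 20 -> p = (0.45, 0.45), u = 0.10
  expect_equal(op$P[2, ], c(0.45, 0.45), tolerance = 1e-12)
  expect_equal(op$U[2], 0.10, tolerance = 1e-12)
  # zero evidence: vacuous opinion
  expect_equal(op$P[3, ], c(0, 0))
  expect_equal(op$U[3], 1)
  expect_equal(op$alpha, rbind(c(5, 1), c(10, 10), c(1, 1)))

  op3 <- opinion_from_evidence(matrix(0, 2, 3))
  expect_equal(op3$U, c(1, 1))

  expect_error(opinion_from_evidence(rbind(c(-1, 2))), "non-negative")
  expect_error(dirichlet_opinion(rbind(c(0.9, 0.2)), 0.2), "sum\\(p\\)")
})

test_that("opinion normalisation holds for many random evidence rows", {
  set.seed(41)
  for (b in 2:4) {
    FE <- matrix(rexp(1000 * b, rate = 0.2), 1000, b)
    op <- opinion_from_evidence(FE)
    expect_lt(max(abs(rowSums(op$P) + op$U - 1)), 1e-6)
    expect_true(all(op$U > 0))
  }
})

test_that("pairwise combination reproduces the worked example", {
  op1 <- dirichlet_opinion(rbind(c(0.6, 0.2)), 0.2)
  op2 <- dirichlet_opinion(rbind(c(0.3, 0.3)), 0.4)
  out <- ds_combine_pair(op1, op2)
  # conflict C = 0.6*0.3 + 0.2*0.3 = 0.24, 1 - C = 0.76
  expect_equal(out$P[1, ], c(0.48, 0.20) / 0.76, tolerance = 1e-4)
  expect_equal(out$P[1, ], c(0.6316, 0.2632), tolerance = 5e-4)
  expect_equal(out$U[1], 0.08 / 0.76, tolerance = 1e-4)
  expect_equal(out$U[1], 0.1053, tolerance = 5e-4)
  expect_lt(abs(sum(out$P[1, ]) + out$U[1] - 1), 1e-12)
})

test_that("combination is commutative with the vacuous neutral element", {
  set.seed(42)
  n <- 1000; b <- 3
  a <- random_opinion(n, b)
  v <- opinion_from_evidence(matrix(0, n, b))
  # vacuous neutrality, exactly
  out <- ds_combine_pair(a, v)
  expect_equal(out$P, a$P, tolerance = 1e-12)
  expect_equal(out$U, a$U, tolerance = 1e-12)
  # commutativity on random opinion pairs
  c2 <- random_opinion(n, b)
  ab <- ds_combine_pair(a, c2)
  ba <- ds_combine_pair(c2, a)
  expect_equal(ab$P, ba$P, tolerance = 1e-10)
  expect_equal(ab$U, ba$U, tolerance = 1e-10)
})

test_that("self-combination never increases uncertainty", {
  set.seed(43)
  op <- random_opinion(500, 3)
  out <- ds_combine_pair(op, op)
  expect_true(all(out$U <= op$U + 1e-12))
})

test_that("sequential fold and fused-alpha recovery invert the evidence map", {
  set.seed(44)
  FE <- matrix(rexp(40 * 3), 40, 3)
  op <- opinion_from_evidence(FE)
  # single opinion: fold identity, and alpha recovery returns F + 1
  one <- ds_combine_all(list(op))
  expect_equal(one$P, op$P)
  expect_equal(one$alpha, FE + 1, tolerance = 1e-8)

  # three vacuous opinions stay vacuous with all-ones alpha
  v <- opinion_from_evidence(matrix(0, 5, 3))
  fv <- ds_combine_all(list(v, v, v))
  expect_equal(fv$U, rep(1, 5))
  expect_equal(fv$alpha, matrix(1, 5, 3))

  # fold of several sources still satisfies the normalisation invariant
  ops <- replicate(4, random_opinion(40, 3), simplify = FALSE)
  fused <- ds_combine_all(ops)
  expect_lt(max(abs(rowSums(fused$P) + fused$U - 1)), 1e-6)
})

test_that("total conflict raises an error naming the sample", {
  op1 <- dirichlet_opinion(rbind(c(1 - 1e-14, 0)), 1e-14)
  op2 <- dirichlet_opinion(rbind(c(0, 1 - 1e-14)), 1e-14)
  expect_error(ds_combine_pair(op1, op2), "sample 1")
})

test_that("Dirichlet cross-entropy matches digamma identities", {
  # alpha = (1,1): psi(2) - psi(1) = 1 exactly
  y2 <- rbind(c(1, 0))
  expect_equal(dirichlet_ce_loss(rbind(c(1, 1)), y2), 1, tolerance = 1e-12)
  expect_equal(dirichlet_ce_loss(rbind(c(1, 1)), rbind(c(0, 1))), 1,
               tolerance = 1e-12)
  # alpha = (1,1,1): psi(3) - psi(1) = 1.5
  expect_equal(dirichlet_ce_loss(rbind(c(1, 1, 1)), rbind(c(1, 0, 0))), 1.5,
               tolerance = 1e-12)
  # monotone decreasing in true-class evidence, towards 0
  ts <- c(0, 1, 10, 100, 1e4)
  losses <- sapply(ts, function(t) {
    dirichlet_ce_loss(rbind(c(1 + t, 1)), y2)
  })
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[length(losses)], 1e-3)
  expect_error(dirichlet_ce_loss(rbind(c(0, 1)), y2), "alpha > 0")
})

test_that("wrong-evidence penalty is zero iff no misplaced evidence", {
  y <- rbind(c(1, 0))
  expect_equal(wrong_evidence_penalty(rbind(c(5, 1)), y), 0, tolerance = 1e-12)
  expect_gt(wrong_evidence_penalty(rbind(c(5, 3)), y), 0)
  # strictly increasing in non-target alpha
  ks <- c(1, 1.5, 2, 4, 8)
  pen <- sapply(ks, function(k) wrong_evidence_penalty(rbind(c(5, k)), y))
  expect_true(all(diff(pen) > 0))
  # multiclass, masked mean
  y3 <- rbind(c(1, 0, 0), c(0, 1, 0))
  a3 <- rbind(c(2, 1, 1), c(3, 2, 5))
  expect_equal(wrong_evidence_penalty(a3, y3, 1L), 0, tolerance = 1e-12)
  expect_gt(wrong_evidence_penalty(a3, y3, 2L), 0)
})

test_that("annealing ramps the penalty weight linearly into [0,1]", {
  expect_equal(trustomics:::annealing_lambda(0, 50), 0)
  expect_equal(trustomics:::annealing_lambda(25, 50), 0.5)
  expect_equal(trustomics:::annealing_lambda(50, 50), 1)
  expect_equal(trustomics:::annealing_lambda(500, 50), 1)
  a <- rbind(c(2, 3))
  y <- rbind(c(1, 0))
  l0 <- tmo_loss(a, y, 1L, epoch = 0, annealing_step = 50L)
  expect_equal(l0, dirichlet_ce_loss(a, y), tolerance = 1e-12)
  lh <- tmo_loss(a, y, 1L, epoch = 25, annealing_step = 50L)
  expect_equal(lh, dirichlet_ce_loss(a, y) + 0.5 * wrong_evidence_penalty(a, y),
               tolerance = 1e-12)
})

test_that("overall loss is additive over omics and finite", {
  set.seed(45)
  b <- 3
  alpha1 <- matrix(rexp(30), 10, b) + 1
  alpha2 <- matrix(rexp(30), 10, b) + 1
  fused <- matrix(rexp(30), 10, b) + 1
  y <- trustomics:::one_hot(sample(0:2, 10, TRUE), b)
  l1 <- overall_loss(list(alpha1), fused, y, epoch = 10, annealing_step = 50L)
  l2 <- overall_loss(list(alpha1, alpha2), fused, y,
                     epoch = 10, annealing_step = 50L)
  expect_equal(l2 - l1, tmo_loss(alpha2, y, epoch = 10, annealing_step = 50L),
               tolerance = 1e-12)
  # degenerate one-omics case where fused == the single source
  ld <- overall_loss(list(alpha1), alpha1, y, epoch = 10, annealing_step = 50L)
  expect_equal(ld, 2 * tmo_loss(alpha1, y, epoch = 10, annealing_step = 50L),
               tolerance = 1e-12)
  expect_true(is.finite(l2) && l2 >= 0)
})
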