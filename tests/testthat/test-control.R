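test_that("product-control two-type attractor criterion matches its spectrum", {
  # gamma < -a3 b1 b2 / (a1 a2) stabilizes the missing-type direction
  m <- unit_model(control = control_product(0.1, 0.1, -2))
  expect_true(predict_e2ij_attractor_product(m)$attractor)
  expect_true(all(Re(eig_at(m, c(1, 1, 0, 0))) < 0))
  # gamma = 0 leaves the third eigenvalue at a3 > 0
  m0 <- unit_model(control = control_product(0.1, 0.1, 0))
  expect_false(predict_e2ij_attractor_product(m0)$attractor)
  # viral condition fails when p4 exceeds the joint clearance at capacity
  m5 <- unit_model(p4 = 3, control = control_product(0.1, 0.1, -2))
  expect_false(predict_e2ij_attractor_product(m5)$attractor)
})

test_that("controlled boundary eigenvalues match the closed forms", {
  mp <- unit_model(control = control_product(0.1, 0.1, 0.1))
  expect_equal(sort(boundary_eigenvalues(mp, "E0")), c(0.5, 1, 1, 1))
  mw <- unit_model(control = control_pairwise_sum(0, -2, -2))
  expect_equal(sort(boundary_eigenvalues(mw, "E11")), c(-1, -1, -1, -0.5))
  # eigensolver agreement at every label with a printed spectrum
  draws <- sample_params(20, seed = 41, control_kind = "product")
  co_of <- function(m, lab) {
    eq <- equilibria(immune_model(m$a, m$b, m$c, m$p, m$p4))
    equilibrium_coords(eq[eq$label == lab, ], m)[1, ]
  }
  for (m in draws$model) {
    for (lab in c("E0", "E11", "E12", "E13", "E212", "E213", "E223")) {
      num <- sort(Re(eig_at(m, co_of(m, lab))))
      ana <- sort(boundary_eigenvalues(m, lab))
      expect_lt(max(abs(num - ana)) / max(1, max(abs(num))), 1e-9)
    }
  }
  draws_w <- sample_params(20, seed = 43, control_kind = "pairwise_sum")
  for (m in draws_w$model) {
    for (lab in c("E0", "E11", "E12", "E13")) {
      num <- sort(Re(eig_at(m, co_of(m, lab))))
      ana <- sort(boundary_eigenvalues(m, lab))
      expect_lt(max(abs(num - ana)) / max(1, max(abs(num))), 1e-9)
    }
  }
})

test_that("pairwise-control single-type attractor criterion matches", {
  m <- unit_model(control = control_pairwise_sum(0, -2, -2))
  expect_true(predict_e11_attractor_pairwise(m)$attractor)
  expect_true(all(Re(eig_at(m, c(1, 0, 0, 0))) < 0))
  # one transverse combination at zero margin: indeterminate-free strict FALSE
  m0 <- unit_model(control = control_pairwise_sum(0, -2, 0))
  expect_false(predict_e11_attractor_pairwise(m0)$attractor)
  m2 <- unit_model(p4 = 2, control = control_pairwise_sum(0, -2, -2))
  expect_false(predict_e11_attractor_pairwise(m2)$attractor)
})

test_that("pairwise-control two-type criterion follows the factorization", {
  m <- unit_model(control = control_pairwise_sum(0.1, 0.1, -2))
  r <- predict_e212_attractor_pairwise(m)
  expect_true(r$exists)
  cf <- e212_closed_form(m)
  expect_equal(r$attractor, all(Re(eig_at(m, cf$coords)) < 0))
  # zero alpha, beta collapse to the product-control sum condition
  mz <- unit_model(control = control_pairwise_sum(0, 0, -2))
  rz <- predict_e212_attractor_pairwise(mz)
  mprod <- unit_model(control = control_product(0, 0, -2))
  expect_equal(rz$attractor, predict_e2ij_attractor_product(mprod)$attractor)
  # inverted denominator with negative numerators: admissible but saddle
  ms <- unit_model(p4 = 0.3, control = control_pairwise_sum(-3, -3, -5))
  cfs <- e212_closed_form(ms)
  expect_true(all(cfs$coords[1:2] > 0))
  expect_true(all(cfs$coords[1:2] < 1))  # below the carrying capacities
  expect_false(predict_e212_attractor_pairwise(ms)$attractor)
  lam <- Re(eig_at(ms, cfs$coords))
  expect_true(any(lam > 0) && any(lam < 0))  # saddle
  # nonexistence when b1 b2 = alpha beta
  mn <- unit_model(control = control_pairwise_sum(1, 1, 0))
  expect_false(predict_e212_attractor_pairwise(mn)$exists)
})

test_that("the E212 characteristic-polynomial factorization is exact", {
  draws <- sample_params(50, seed = 47, control_kind = "pairwise_sum")
  for (m in draws$model) {
    cf <- e212_closed_form(m)
    if (!cf$exists) next
    fac <- e212_charpoly_factors(m)
    num <- charpoly_from_eigenvalues(eig_at(m, cf$coords))
    expect_charpoly_match(fac$charpoly, num)
  }
})

test_that("attractor predicates agree with the eigensolver across draws", {
  check_agreement <- function(draws, coords_fn, predicate_fn) {
    for (m in draws$model) {
      r <- predicate_fn(m)
      if (isFALSE(r$exists)) next
      if (any(abs(r$conditions$margin) < 1e-6)) next  # boundary band
      lam <- Re(eig_at(m, coords_fn(m)))
      if (min(abs(lam)) < 1e-6 * max(1, max(abs(lam)))) next
      expect_equal(r$attractor, all(lam < 0))
    }
  }
  check_agreement(sample_params(50, seed = 53, control_kind = "product"),
                  function(m) c(m$a[1] / m$b[1], m$a[2] / m$b[2], 0, 0),
                  predict_e2ij_attractor_product)
  check_agreement(sample_params(50, seed = 59, control_kind = "pairwise_sum"),
                  function(m) c(m$a[1] / m$b[1], 0, 0, 0),
                  predict_e11_attractor_pairwise)
  check_agreement(sample_params(50, seed = 61, control_kind = "pairwise_sum"),
                  function(m) e212_closed_form(m)$coords,
                  predict_e212_attractor_pairwise)
})

test_that("zero controls reduce every predicate to the uncontrolled verdicts", {
  # with no control, E212 and E11 are always saddles (a positive transverse
  # eigenvalue survives), so the attractor predicates must say FALSE
  mp <- unit_model(control = control_product(0, 0, 0))
  expect_false(predict_e2ij_attractor_product(mp)$attractor)
  mw <- unit_model(control = control_pairwise_sum(0, 0, 0))
  expect_false(predict_e11_attractor_pairwise(mw)$attractor)
  expect_false(predict_e212_attractor_pairwise(mw)$attractor)
  v <- theorem_verdicts(unit_model())
  expect_equal(v$predicted[v$label == "E212"], "saddle")
  expect_equal(v$predicted[v$label == "E11"], "saddle")
})

test_that("boundary equality margins are reported indeterminate", {
  m0 <- unit_model(control = control_product(0.1, 0.1, -1))  # a3 b1 b2 + g a1 a2 = 0
  expect_true(is.na(predict_e2ij_attractor_product(m0, boundary_tol = 1e-12)$attractor))
})
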