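test_that("eigenvalue classification matches the explicit spectra", {
  m <- unit_model()
  st <- classify_stability(m)
  e0 <- st[st$label == "E0", ]
  expect_equal(sort(Re(e0$eigenvalues[[1]])), c(0.5, 1, 1, 1))
  expect_equal(e0$classification, "repeller")
  e3 <- st[st$label == "E3", ]
  expect_equal(sort(Re(e3$eigenvalues[[1]])), c(-2.5, -1, -1, -1))
  expect_equal(e3$classification, "attractor_node")
  expect_equal(st[st$label == "E41", ]$classification, "saddle")
})

test_that("Routh-Hurwitz quartic criterion matches the printed inequalities", {
  expect_true(routh_hurwitz_quartic(4, 6, 4, 1))    # (X+1)^4
  expect_false(routh_hurwitz_quartic(2, 0, -2, -1)) # (X-1)(X+1)^3
  # boundary: (X^2+1)(X+1)^2 zeroes the third Hurwitz expression
  expect_false(routh_hurwitz_quartic(2, 2, 2, 1))
  # accepts a charpoly object
  expect_true(routh_hurwitz_quartic(charpoly_from_eigenvalues(
    c(-1, -2, -0.5 + 3i, -0.5 - 3i))))
})

test_that("Routh-Hurwitz agrees with direct root computation", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 300) {
    co <- runif(4, -5, 5)
    mre <- max_re_root(co[1], co[2], co[3], co[4])
    h <- c(co[1], co[2] * co[1] - co[3],
           co[3] * co[2] * co[1] - co[4] * co[1]^2 - co[3]^2, co[4])
    if (abs(mre) < 1e-9 || any(abs(h) < 1e-9)) next  # boundary band
    expect_equal(routh_hurwitz_quartic(co[1], co[2], co[3], co[4]), mre < 0)
    n_checked <- n_checked + 1
  }
})

test_that("analytic charpoly at the two-type virus-on point matches", {
  m <- unit_model()
  cp <- charpoly_e512(m)
  expect_equal(cp$A3, 0.25)
  expect_equal(cp$A2, -0.4375)
  num <- charpoly_from_eigenvalues(eig_at(m, c(0.25, 0.25, 0, 0.75)))
  expect_charpoly_match(cp, num)
  # deflation identities of the cubic factor
  d <- cp$deflation
  expect_equal(d$B2, cp$A3 + d$lambda1)
  expect_equal(d$B1, cp$A2 + d$lambda1 * d$B2)
  expect_equal(d$B0, cp$A1 + d$lambda1 * d$B1)
  expect_equal(cp$A0, -d$lambda1 * d$B0)
})

test_that("charpoly constant term vanishes when the viral load hits a3/c3", {
  # unit rates give v512 = 0.75; put the third type's kill threshold there
  m <- immune_model(c(1, 1, 0.75), rep(1, 3), rep(1, 3), rep(1, 3), 0.5)
  cp <- charpoly_e512(m)
  expect_equal(cp$A0, 0)
  expect_equal(cp$deflation$lambda1, 0)
})

test_that("analytic charpolys match numeric oracles over random draws", {
  draws <- sample_params(20, seed = 13)
  for (m in draws$model) {
    eq <- equilibria(m)
    co512 <- equilibrium_coords(eq[eq$label == "E512", ], m)[1, ]
    co6 <- equilibrium_coords(eq[eq$label == "E6", ], m)[1, ]
    suppressWarnings({
      expect_charpoly_match(charpoly_e512(m),
                            charpoly_from_eigenvalues(eig_at(m, co512)))
      expect_charpoly_match(charpoly_e6(m),
                            charpoly_from_eigenvalues(eig_at(m, co6)))
    })
  }
})

test_that("interior-point charpoly certifies the saddle when admissible", {
  m <- unit_model()
  cp <- charpoly_e6(m)
  expect_equal(cp$A3, 0.5)  # sum of b_i x_i at (1/6, 1/6, 1/6)
  expect_lt(cp$A0, 0)
})

test_that("explicit single-type virus-on eigenvalues match the eigensolver", {
  m <- unit_model()
  ev <- e41_eigenvalues(m, 1)
  expect_equal(attr(ev, "Delta"), 1.25)
  expect_equal(ev[1:2], c(0.5, 0.5))  # transverse pair a_j - c_j(...)
  expect_equal(ev[3:4], (-0.5 + c(1, -1) * sqrt(1.25)) / 2)
  draws <- sample_params(30, seed = 23)
  for (m in draws$model) {
    for (i in 1:3) {
      if (m$p[i] * m$a[i] / m$b[i] <= m$p4) next  # inadmissible
      ev <- e41_eigenvalues(m, i)
      co <- numeric(4)
      co[i] <- m$p4 / m$p[i]
      co[4] <- (m$a[i] - m$b[i] * m$p4 / m$p[i]) / m$c[i]
      num <- sort(Re(eig_at(m, co)))
      expect_lt(max(abs(sort(ev) - num)) / max(1, max(abs(num))), 1e-9)
      # admissible single-type point: the in-plane pair has opposite signs
      expect_lt(ev[4], 0)
      expect_gt(ev[3], 0)
    }
  }
})

test_that("analytic verdicts follow the attractor threshold on p4", {
  m <- unit_model()  # p4 = 0.5 < 3
  v <- theorem_verdicts(m)
  expect_equal(v$predicted[v$label == "E3"], "attractor_node")
  expect_equal(v$predicted[v$label == "E0"], "repeller")
  expect_true(all(v$predicted[!v$label %in% c("E0", "E3")] == "saddle"))
  v5 <- theorem_verdicts(unit_model(p4 = 5))
  expect_equal(v5$predicted[v5$label == "E3"], "saddle")
  # inadmissible virus-on points get no verdict at p4 = 5
  expect_true(all(is.na(v5$predicted[grepl("^E[456]", v5$label)])))
})

test_that("admissible boundary equilibria up to E4i have real spectra", {
  # virus-free points have triangular Jacobians; at an admissible E4i the
  # discriminant of the in-plane pair is positive (an inadmissible E4i,
  # with negative viral load, can carry a complex pair)
  draws <- sample_params(30, seed = 29)
  for (m in draws$model) {
    st <- classify_stability(m)
    for (i in seq_len(nrow(st))) {
      if (grepl("^E5|^E6", st$label[i])) next
      if (grepl("^E4", st$label[i]) && !st$in_sigma_plus[i]) next
      lam <- st$eigenvalues[[i]]
      expect_lt(max(abs(Im(lam))), 1e-9 * max(1, max(Mod(lam))))
    }
  }
})

test_that("nonhyperbolic points are flagged rather than classified", {
  # on the collision surface E3 and E6 merge and carry a zero eigenvalue
  m <- unit_model(p4 = 3)
  st <- classify_stability(m)
  expect_equal(st$classification[st$label == "E3"], "nonhyperbolic")
  expect_false(st$hyperbolic[st$label == "E3"])
})
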