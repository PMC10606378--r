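test_that("closed-form enumeration returns the canonical 15-point catalogue", {
  m <- unit_model()
  eq <- equilibria(m)
  expect_equal(nrow(eq), 15)
  expect_setequal(eq$label,
                  c("E0", "E11", "E12", "E13", "E212", "E213", "E223", "E3",
                    "E41", "E42", "E43", "E512", "E513", "E523", "E6"))
  co <- equilibrium_coords(eq, m)
  expect_equal(unname(co["E512", ]), c(0.25, 0.25, 0, 0.75))
  expect_equal(unname(co["E6", ]), c(1/6, 1/6, 1/6, 5/6))
  expect_equal(unname(co["E41", ]), c(0.5, 0, 0, 0.5))
  expect_equal(unname(co["E3", ]), c(1, 1, 1, 0))
  # at unit parameters every point is admissible; only E6 is interior
  expect_true(all(eq$in_sigma_plus))
  interior <- apply(co, 1, function(r) all(r > 0))
  expect_equal(sum(interior), 1)
  expect_true(interior["E6"])
})

test_that("every catalogued point annihilates the vector field", {
  draws <- sample_params(20, seed = 3)
  for (m in draws$model) {
    co <- equilibrium_coords(equilibria(m), m)
    res <- apply(co, 1, function(r) max(abs(vector_field(m, r))))
    expect_lt(max(res), 1e-10 * max(1, max(abs(co))))
  }
})

test_that("generic support enumeration counts 2^(n+1) - 1 equilibria", {
  for (n in 1:5) {
    m <- unit_model(n = n)
    expect_equal(nrow(equilibria(m)), 2^(n + 1) - 1)
  }
})

test_that("one immunity type gives the three hand-derived equilibria", {
  m <- immune_model(1, 1, 1, 1, 0.5)
  co <- equilibrium_coords(equilibria(m), m)
  expect_equal(unname(co[order(co[, 1], co[, 2]), ]),
               rbind(c(0, 0), c(0.5, 0.5), c(1, 0)))
})

test_that("generic enumeration at n = 3 reproduces the canonical formulas", {
  draws <- sample_params(10, seed = 7)
  for (m in draws$model) {
    eq <- equilibria(m)
    # recompute from first principles per support pattern
    for (i in seq_len(nrow(eq))) {
      supp <- eq$support[[i]]
      co <- equilibrium_coords(eq[i, ], m)[1, ]
      if (!eq$virus_on[i]) {
        expect_equal(unname(co[supp]), m$a[supp] / m$b[supp], tolerance = 1e-12)
        expect_identical(unname(co[4]), 0)
      } else {
        v <- (sum(m$p[supp] * m$a[supp] / m$b[supp]) - m$p4) /
          sum(m$p[supp] * m$c[supp] / m$b[supp])
        expect_equal(unname(co[4]), v, tolerance = 1e-12)
        expect_equal(unname(co[supp]), (m$a[supp] - m$c[supp] * v) / m$b[supp],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("admissibility flags match the analytic positivity conditions", {
  draws <- sample_params(40, seed = 19)
  for (m in draws$model) {
    eq <- equilibria(m)
    cap <- m$p * m$a / m$b
    for (i in 1:3) {
      e4 <- eq[eq$label == paste0("E4", i), ]
      expect_equal(e4$in_sigma_plus, cap[i] > m$p4)
    }
    e6 <- eq[eq$label == "E6", ]
    v6 <- e6$v
    expect_equal(e6$in_sigma_plus, v6 > 0 && v6 < min(m$a / m$c))
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (ij in pairs) {
      lab <- paste0("E5", paste(ij, collapse = ""))
      e5 <- eq[eq$label == lab, ]
      expect_equal(e5$in_sigma_plus,
                   e5$v > 0 && e5$v < min(m$a[ij] / m$c[ij]))
    }
  }
})

test_that("numeric solver with zero controls reproduces the catalogue", {
  m0 <- unit_model(control = control_product(0, 0, 0))
  sol <- solve_equilibria(m0, seed = 5)
  expect_equal(nrow(sol), 15)
  ref <- equilibrium_coords(equilibria(unit_model()), unit_model())
  got <- equilibrium_coords(sol, m0)
  for (lab in rownames(ref)) {
    expect_lt(max(abs(got[lab, ] - ref[lab, ])), 1e-9)
  }
})

test_that("pairwise-sum control shifts the two-type point to its closed form", {
  m <- unit_model(control = control_pairwise_sum(0.1, 0.1, 0))
  cf <- e212_closed_form(m)
  # (a1 b2 + a2 alpha) / (b1 b2 - alpha beta) at unit rates
  expect_equal(cf$x1, 1.1 / 0.99)
  expect_equal(cf$x2, 1.1 / 0.99)
  sol <- solve_equilibria(m, supports = list(c(1, 2)), seed = 2)
  vf_off <- sol[!sol$virus_on, ]
  expect_equal(nrow(vf_off), 1)
  expect_lt(max(abs(equilibrium_coords(vf_off, m)[1, ] - cf$coords)), 1e-9)
})

test_that("solver residuals stay below the acceptance threshold", {
  m <- unit_model(control = control_pairwise_sum(0.3, -0.2, 0.4))
  sol <- solve_equilibria(m, seed = 9)
  expect_true(all(sol$residual < 1e-9))
})

test_that("coexistence-uniqueness determinant matches hand evaluations", {
  mk <- function(b, al, be, ga) {
    immune_model(rep(1, 3), b, rep(1, 3), rep(1, 3), 0.5,
                 control = control_pairwise_sum(al, be, ga))
  }
  expect_equal(e3_uniqueness_determinant(mk(rep(1, 3), 0, 0, 0)), 1)
  expect_equal(e3_uniqueness_determinant(mk(rep(1, 3), 1, 1, 1)), -4)
  expect_equal(e3_uniqueness_determinant(mk(c(2, 3, 4), 1, 0, 0)), 24)
  expect_error(e3_uniqueness_determinant(unit_model()), "pairwise_sum")
})

test_that("coincident support patterns are kept and flagged", {
  # p4 = p1 a1 / b1 makes the type-1 virus-on point collide with E11
  m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), 1)
  eq <- distinct_equilibria(equilibria(m), m)
  expect_equal(nrow(eq), 15)
  expect_true(all(eq$coincident[eq$label %in% c("E11", "E41")]))
})
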