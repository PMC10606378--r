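# shared fixtures and oracles, built in code

unit_model <- function(p4 = 0.5, control = control_none(), n = 3L) {
  immune_model(rep(1, n), rep(1, n), rep(1, n), rep(1, n), p4, control = control)
}

# central-difference Jacobian oracle (independent of model_jacobian)
fd_jacobian <- function(model, state, h = 1e-5) {
  n <- length(state)
  sapply(seq_len(n), function(j) {
    hj <- h * max(1, abs(state[j]))
    e <- numeric(n); e[j] <- hj
    (vector_field(model, state + e) - vector_field(model, state - e)) / (2 * hj)
  })
}

eig_at <- function(model, coords) {
  eigen(model_jacobian(model, coords), only.values = TRUE)$values
}

# largest real part of the roots of X^4 + A3 X^3 + A2 X^2 + A1 X + A0
max_re_root <- function(A3, A2, A1, A0) {
  max(Re(polyroot(c(A0, A1, A2, A3, 1))))
}

expect_charpoly_match <- function(analytic, numeric_cp, rel_tol = 1e-8) {
  a <- unlist(analytic[c("A3", "A2", "A1", "A0")])
  b <- unlist(numeric_cp[c("A3", "A2", "A1", "A0")])
  expect_lt(max(abs(a - b) / pmax(1, abs(a))), rel_tol)
}
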