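#' Specify an immune-pathogen interaction model
#'
#' Builds the deterministic model coupling `n_types` immunity compartments
#' to a single replicating pathogen. Each immunity level grows logistically
#' (intrinsic rate `a[i]`, self-limitation `b[i]`, carrying capacity
#' `a[i]/b[i]`) and is killed by the pathogen at rate `c[i]`; the viral load
#' proliferates at rate `p4` and is cleared by immunity type `i` at rate
#' `p[i]`:
#'
#' \deqn{\dot x_i = a_i x_i - b_i x_i^2 - c_i x_i v, \qquad
#'       \dot v = p_4 v - \sum_i p_i x_i v.}
#'
#' An optional control term (see [control_product()] and
#' [control_pairwise_sum()]) is added to the immunity equations only; the
#' viral equation is never controlled, reflecting interventions that boost
#' immunity rather than attack the pathogen directly. Controls are defined
#' only for three immunity types.
#'
#' @param a Numeric vector of intrinsic immunity growth rates (1/time),
#'   one per immunity type; all strictly positive.
#' @param b Numeric vector of self-limitation coefficients
#'   (1/(level x time)); all strictly positive.
#' @param c Numeric vector of kill-by-virus rates (1/(load x time));
#'   all strictly positive.
#' @param p Numeric vector of per-type virus clearance rates
#'   (1/(level x time)); all strictly positive.
#' @param p4 Viral proliferation rate (1/time), strictly positive scalar.
#' @param control A control specification from [control_none()],
#'   [control_product()] or [control_pairwise_sum()].
#'
#' @return An object of class `immune_model`: a list with fields `n_types`,
#'   `a`, `b`, `c`, `p`, `p4` and `control`.
#'
#' @examples
#' m <- immune_model(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1),
#'                   p = c(1, 1, 1), p4 = 0.5)
#' vector_field(m, c(1, 1, 1, 0))  # the virus-free coexistence point
#' @export
immune_model <- function(a, b, c, p, p4, control = control_none()) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); p <- as.numeric(p); p4 <- as.numeric(p4)
  n <- length(a)
  if (n < 1L) abort("at least one immunity type is required")
  if (length(b) != n || length(c) != n || length(p) != n) {
    abort("`a`, `b`, `c` and `p` must all have the same length")
  }
  if (length(p4) != 1L) abort("`p4` must be a scalar")
  vals <- c(a, b, c, p, p4)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("all rate parameters must be strictly positive and finite")
  }
  if (!inherits(control, "immune_control")) {
    abort("`control` must be created with control_none(), control_product() or control_pairwise_sum()")
  }
  if (control$kind != "none" && n != 3L) {
    abort("control terms are defined only for three immunity types")
  }
  structure(
    list(n_types = n, a = a, b = b, c = c, p = p, p4 = p4, control = control),
    class = "immune_model"
  )
}

#' Control specifications for the immunity equations
#'
#' `control_none()` selects the uncontrolled system. `control_product()` adds
#' the triple-product terms \eqn{\alpha x_1 x_2 x_3}, \eqn{\beta x_1 x_2 x_3},
#' \eqn{\gamma x_1 x_2 x_3} to the three immunity equations; the boost to each
#' compartment requires all three to be present. `control_pairwise_sum()` adds
#' \eqn{\alpha x_1 (x_2 + x_3)}, \eqn{\beta x_2 (x_3 + x_1)},
#' \eqn{\gamma x_3 (x_1 + x_2)}: each compartment is boosted (or damped, for
#' negative constants) in proportion to the sum of the other two.
#'
#' @param alpha,beta,gamma Finite real control constants (any sign), acting on
#'   the first, second and third immunity equation respectively.
#' @return An object of class `immune_control` with fields `kind`, `alpha`,
#'   `beta`, `gamma`.
#' @export
control_none <- function() {
  structure(list(kind = "none", alpha = 0, beta = 0, gamma = 0),
            class = "immune_control")
}

#' @rdname control_none
#' @export
control_product <- function(alpha, beta, gamma) {
  new_control("product", alpha, beta, gamma)
}

#' @rdname control_none
#' @export
control_pairwise_sum <- function(alpha, beta, gamma) {
  new_control("pairwise_sum", alpha, beta, gamma)
}

new_control <- function(kind, alpha, beta, gamma) {
  vals <- c(alpha, beta, gamma)
  if (length(vals) != 3L || !all(is.finite(vals))) {
    abort("`alpha`, `beta`, `gamma` must be finite scalars")
  }
  structure(list(kind = kind, alpha = as.numeric(alpha),
                 beta = as.numeric(beta), gamma = as.numeric(gamma)),
            class = "immune_control")
}

#' @export
print.immune_model <- function(x, ...) {
  cat("<immune_model> ", x$n_types, " immunity type(s) + viral load\n", sep = "")
  cat("  a  =", format(x$a), "\n")
  cat("  b  =", format(x$b), "\n")
  cat("  c  =", format(x$c), "\n")
  cat("  p  =", format(x$p), "\n")
  cat("  p4 =", format(x$p4), "\n")
  if (x$control$kind != "none") {
    cat("  control:", x$control$kind,
        sprintf("(alpha=%g, beta=%g, gamma=%g)",
                x$control$alpha, x$control$beta, x$control$gamma), "\n")
  }
  invisible(x)
}

check_state <- function(model, state) {
  state <- as.numeric(state)
  if (length(state) != model$n_types + 1L) {
    abort(sprintf("state must have length %d (immunity levels + viral load)",
                  model$n_types + 1L))
  }
  if (!all(is.finite(state))) abort("state components must be finite")
  state
}

# control contribution to the immunity equations (length n vector, zeros
# when kind == "none"); viral equation is never controlled
control_terms <- function(model, x) {
  ctl <- model$control
  if (ctl$kind == "none") return(numeric(model$n_types))
  k <- c(ctl$alpha, ctl$beta, ctl$gamma)
  if (ctl$kind == "product") {
    k * prod(x)
  } else {
    k * x * (sum(x) - x)
  }
}

#' Evaluate the model vector field
#'
#' Returns the instantaneous rates of change
#' \eqn{(\dot x_1, \dots, \dot x_n, \dot v)} of the selected system
#' (uncontrolled, product control, or pairwise-sum control) at a state.
#'
#' @param model An [immune_model()].
#' @param state Numeric vector of length `n_types + 1`: immunity levels
#'   followed by the viral load.
#' @return Numeric vector of length `n_types + 1`.
#' @examples
#' m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 0.5)
#' vector_field(m, c(0, 0, 0, 1))  # pure viral growth at rate p4
#' @export
vector_field <- function(model, state) {
  state <- check_state(model, state)
  n <- model$n_types
  x <- state[seq_len(n)]
  v <- state[n + 1L]
  dx <- model$a * x - model$b * x^2 - model$c * x * v + control_terms(model, x)
  dv <- model$p4 * v - sum(model$p * x) * v
  c(dx, dv)
}

#' Jacobian matrix of the model vector field
#'
#' Analytic matrix of partial derivatives of [vector_field()] with respect to
#' the state, for the uncontrolled system and both control variants.
#'
#' @inheritParams vector_field
#' @return A `(n_types + 1) x (n_types + 1)` numeric matrix.
#' @export
model_jacobian <- function(model, state) {
  state <- check_state(model, state)
  n <- model$n_types
  x <- state[seq_len(n)]
  v <- state[n + 1L]
  J <- matrix(0, n + 1L, n + 1L)
  ctl <- model$control
  for (i in seq_len(n)) {
    J[i, i] <- model$a[i] - 2 * model$b[i] * x[i] - model$c[i] * v
    J[i, n + 1L] <- -model$c[i] * x[i]
  }
  if (ctl$kind != "none") {
    k <- c(ctl$alpha, ctl$beta, ctl$gamma)
    if (ctl$kind == "product") {
      # d/dx_j (k_i * x1 x2 x3)
      for (i in 1:3) for (j in 1:3) {
        J[i, j] <- J[i, j] + k[i] * prod(x[-j])
      }
    } else {
      # d/dx_j (k_i * x_i * (sum(x) - x_i))
      for (i in 1:3) for (j in 1:3) {
        J[i, j] <- J[i, j] +
          if (i == j) k[i] * (sum(x) - x[i]) else k[i] * x[i]
      }
    }
  }
  J[n + 1L, seq_len(n)] <- -model$p * v
  J[n + 1L, n + 1L] <- model$p4 - sum(model$p * x)
  J
}

#' Closed-form solution of the logistic immunity equation
#'
#' In the absence of the pathogen each immunity level follows the logistic
#' law \eqn{\dot x = a x - b x^2}, whose solution from \eqn{x(0) = x_0} is
#' \deqn{x(t) = \frac{a x_0 e^{a t}}{a + b x_0 (e^{a t} - 1)},}
#' approaching the carrying capacity \eqn{a/b} as \eqn{t \to \infty} for any
#' positive start.
#'
#' @param a Intrinsic growth rate, positive scalar.
#' @param b Self-limitation coefficient, positive scalar.
#' @param x0 Initial level, nonnegative.
#' @param t Time (scalar or vector), nonnegative.
#' @return Numeric vector of levels, same length as `t`.
#' @examples
#' logistic_solution(1, 1, 0.5, c(0, 1, 10))
#' @export
logistic_solution <- function(a, b, x0, t) {
  if (a <= 0 || b <= 0) abort("`a` and `b` must be strictly positive")
  if (x0 < 0) abort("`x0` must be nonnegative")
  if (any(t < 0)) abort("`t` must be nonnegative")
  # rescaled form avoids overflow of exp(a t) for large t
  e <- exp(-a * t)
  a * x0 / (a * e + b * x0 * (1 - e))
}

#' @export
tidy.immune_model <- function(x, ...) {
  n <- x$n_types
  dplyr::bind_rows(
    tibble(term = paste0("a", seq_len(n)), value = x$a),
    tibble(term = paste0("b", seq_len(n)), value = x$b),
    tibble(term = paste0("c", seq_len(n)), value = x$c),
    tibble(term = paste0("p", seq_len(n)), value = x$p),
    tibble(term = "p4", value = x$p4),
    if (x$control$kind != "none") {
      tibble(term = c("alpha", "beta", "gamma"),
             value = c(x$control$alpha, x$control$beta, x$control$gamma))
    }
  )
}

#' @export
glance.immune_model <- function(x, ...) {
  tibble(
    n_types = x$n_types,
    control = x$control$kind,
    p4 = x$p4,
    clearance_at_capacity = sum(x$p * x$a / x$b),
    n_equilibria = 2^(x$n_types + 1L) - 1L
  )
}
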