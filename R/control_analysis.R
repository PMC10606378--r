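#' Attractor predicates for controlled boundary equilibria
#'
#' Evaluates the closed-form attractor criteria for the boundary equilibria
#' whose eigenvalues are known explicitly under the two control variants.
#'
#' Under the product control, the two-type virus-free point `E2ij` (both
#' supported types at carrying capacity) is an attractor iff
#' \eqn{p_4 < p_i a_i/b_i + p_j a_j/b_j} and
#' \eqn{a_k b_i b_j + g_k a_i a_j < 0}, where \eqn{g_k} is the control
#' constant of the missing type's equation. Under the pairwise-sum control,
#' the single-type point `E1i` is an attractor iff \eqn{p_4 < p_i a_i/b_i}
#' and both transverse combinations \eqn{a_j b_i + g_j a_i} are negative;
#' the two-type point `E212` (closed form in [e212_closed_form()]) is an
#' attractor iff the viral eigenvalue \eqn{p_4 - p_1 x_1^* - p_2 x_2^*}, the
#' third-type eigenvalue \eqn{a_3 + \gamma (x_1^* + x_2^*)} are negative and
#' the quadratic factor of the characteristic polynomial passes
#' Routh-Hurwitz (\eqn{b_1 x_1^* + b_2 x_2^* > 0} and
#' \eqn{x_1^* x_2^* (b_1 b_2 - \alpha\beta) > 0}).
#'
#' Boundary equality cases are reported as `NA` (indeterminate): the
#' criteria are strict and linearization is silent on the threshold.
#'
#' @param model A controlled [immune_model()] of the matching kind.
#' @param boundary_tol Conditions within this distance of equality give `NA`.
#' @return A list with `attractor` (`TRUE`/`FALSE`/`NA`), `exists` (for
#'   `predict_e212_attractor` under pairwise-sum control) and `conditions`
#'   (tibble of the individual inequality margins; a condition holds when
#'   its margin is positive).
#' @name control_predicates
NULL

#' @rdname control_predicates
#' @param i,j Supported immunity types of the two-type point (product
#'   control); the missing type is the remaining index.
#' @export
predict_e2ij_attractor_product <- function(model, i = 1L, j = 2L,
                                           boundary_tol = 0) {
  stopifnot_kind(model, "product")
  k <- setdiff(1:3, c(i, j))
  g <- c(model$control$alpha, model$control$beta, model$control$gamma)[k]
  margins <- c(
    viral = sum(model$p[c(i, j)] * model$a[c(i, j)] / model$b[c(i, j)]) - model$p4,
    third_type = -(model$a[k] * model$b[i] * model$b[j] + g * model$a[i] * model$a[j])
  )
  predicate_result(margins, boundary_tol)
}

#' @rdname control_predicates
#' @export
predict_e11_attractor_pairwise <- function(model, i = 1L, boundary_tol = 0) {
  stopifnot_kind(model, "pairwise_sum")
  g <- c(model$control$alpha, model$control$beta, model$control$gamma)
  js <- setdiff(1:3, i)
  margins <- c(
    viral = model$p[i] * model$a[i] / model$b[i] - model$p4,
    setNames(-(model$a[js] * model$b[i] + g[js] * model$a[i]),
             paste0("transverse", js))
  )
  predicate_result(margins, boundary_tol)
}

#' @rdname control_predicates
#' @export
predict_e212_attractor_pairwise <- function(model, boundary_tol = 0) {
  stopifnot_kind(model, "pairwise_sum")
  cf <- e212_closed_form(model)
  if (!cf$exists) {
    return(list(attractor = NA, exists = FALSE, conditions = NULL))
  }
  fac <- e212_charpoly_factors(model)
  margins <- c(
    viral = -fac$lambda_viral,
    third_type = -fac$lambda_third,
    quad_linear = fac$q1,
    quad_constant = fac$q0
  )
  out <- predicate_result(margins, boundary_tol)
  out$exists <- TRUE
  out
}

predicate_result <- function(margins, boundary_tol) {
  on_boundary <- abs(margins) <= boundary_tol
  attractor <- if (any(on_boundary)) NA else all(margins > 0)
  list(attractor = attractor,
       conditions = tibble(condition = names(margins), margin = unname(margins)))
}

#' Characteristic-polynomial factorization at the controlled two-type point
#'
#' Under the pairwise-sum control the characteristic polynomial at the
#' two-type virus-free point factors as
#' \deqn{(X - \lambda_{3}) (X - \lambda_{v})
#'       (X^2 + q_1 X + q_0),}
#' with \eqn{\lambda_{3} = a_3 + \gamma (x_1^* + x_2^*)} (the missing type's
#' transverse eigenvalue), \eqn{\lambda_{v} = p_4 - p_1 x_1^* - p_2 x_2^*}
#' (the viral eigenvalue), \eqn{q_1 = b_1 x_1^* + b_2 x_2^*} and
#' \eqn{q_0 = x_1^* x_2^* (b_1 b_2 - \alpha\beta)}.
#'
#' @param model An [immune_model()] with pairwise-sum control and
#'   \eqn{b_1 b_2 \neq \alpha\beta}.
#' @return A list with `lambda_third`, `lambda_viral`, `q1`, `q0`, the
#'   expanded quartic as a `charpoly`, and the coordinates `x1`, `x2`.
#' @export
e212_charpoly_factors <- function(model) {
  stopifnot_kind(model, "pairwise_sum")
  cf <- e212_closed_form(model)
  if (!cf$exists) abort("E212 does not exist: b1*b2 == alpha*beta")
  x1 <- cf$x1; x2 <- cf$x2
  ga <- model$control$gamma
  al <- model$control$alpha; be <- model$control$beta
  lambda_third <- model$a[3] + ga * (x1 + x2)
  lambda_viral <- model$p4 - model$p[1] * x1 - model$p[2] * x2
  q1 <- model$b[1] * x1 + model$b[2] * x2
  q0 <- x1 * x2 * (model$b[1] * model$b[2] - al * be)
  # expand (X - l3)(X - lv)(X^2 + q1 X + q0)
  quad1 <- c(1, -(lambda_third + lambda_viral), lambda_third * lambda_viral)
  quad2 <- c(1, q1, q0)
  quartic <- convolve_poly(quad1, quad2)
  list(lambda_third = lambda_third, lambda_viral = lambda_viral,
       q1 = q1, q0 = q0, x1 = x1, x2 = x2,
       charpoly = new_charpoly(quartic[2], quartic[3], quartic[4], quartic[5]))
}

convolve_poly <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) for (j in seq_along(q)) {
    out[i + j - 1L] <- out[i + j - 1L] + p[i] * q[j]
  }
  out
}

#' Closed-form eigenvalues at controlled boundary equilibria
#'
#' Returns the printed-form eigenvalues at the boundary equilibria whose
#' spectra are explicit under each control kind. For the uncontrolled system
#' and the product control, the single- and two-type virus-free points keep
#' the uncontrolled coordinates; under the product control the two-type
#' point `E2ij` picks up the shifted transverse eigenvalue
#' \eqn{(a_k b_i b_j + g_k a_i a_j)/(b_i b_j)}. Under the pairwise-sum
#' control the single-type point `E1i` has eigenvalues \eqn{-a_i},
#' \eqn{(a_j b_i + g_j a_i)/b_i} for the two missing types, and
#' \eqn{p_4 - p_i a_i/b_i}; the two-type point `E212` gets the roots of the
#' factorization in [e212_charpoly_factors()].
#'
#' @param model An [immune_model()] (any control kind).
#' @param label One of `"E0"`, `"E11"`, `"E12"`, `"E13"`, `"E212"`,
#'   `"E213"`, `"E223"` (the last two for product control only; `"E212"`
#'   only, beyond product, for pairwise-sum).
#' @return Numeric (or complex, for the pairwise `E212` quadratic factor)
#'   vector of 4 eigenvalues.
#' @export
boundary_eigenvalues <- function(model, label) {
  a <- model$a; b <- model$b; p <- model$p; p4 <- model$p4
  kind <- model$control$kind
  g <- c(model$control$alpha, model$control$beta, model$control$gamma)
  if (label == "E0") return(c(a, p4))
  if (grepl("^E1[123]$", label)) {
    i <- as.integer(substr(label, 3, 3))
    js <- setdiff(1:3, i)
    trans <- switch(kind,
      none = a[js],
      product = a[js],
      pairwise_sum = (a[js] * b[i] + g[js] * a[i]) / b[i]
    )
    return(c(-a[i], trans, p4 - p[i] * a[i] / b[i]))
  }
  if (grepl("^E2[123]{2}$", label)) {
    ij <- as.integer(strsplit(substr(label, 3, 4), "")[[1]])
    i <- ij[1]; j <- ij[2]; k <- setdiff(1:3, ij)
    if (kind %in% c("none", "product")) {
      trans_k <- if (kind == "none") a[k] else
        (a[k] * b[i] * b[j] + g[k] * a[i] * a[j]) / (b[i] * b[j])
      return(c(-a[i], -a[j], trans_k,
               p4 - p[i] * a[i] / b[i] - p[j] * a[j] / b[j]))
    }
    if (label != "E212") {
      abort("no printed eigenvalue formulas for this label under pairwise-sum control")
    }
    fac <- e212_charpoly_factors(model)
    disc <- as.complex(fac$q1^2 - 4 * fac$q0)
    quad_roots <- (-fac$q1 + c(1, -1) * sqrt(disc)) / 2
    return(c(fac$lambda_third, fac$lambda_viral, quad_roots))
  }
  abort(sprintf("no closed-form eigenvalues for label %s", label))
}
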