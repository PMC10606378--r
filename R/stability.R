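#' Classify the local stability of equilibria
#'
#' Computes the Jacobian eigenvalues at each equilibrium of a catalogue and
#' classifies the point from the sign pattern of the real parts: all negative
#' gives an attractor (node when all eigenvalues are real, focus otherwise),
#' all positive a repeller, mixed signs a saddle. A point is flagged
#' nonhyperbolic when some eigenvalue's real part falls below a scale-free
#' threshold `tol * max(1, spectral radius)`; linearization is inconclusive
#' there and no classification is forced.
#'
#' @param model An [immune_model()].
#' @param eq_tbl An equilibrium catalogue from [equilibria()] or
#'   [solve_equilibria()]; defaults to the closed-form catalogue.
#' @param tol Relative threshold for treating a real part as zero.
#' @return The catalogue with added columns `eigenvalues` (list of complex
#'   vectors), `hyperbolic` and `classification` (one of `attractor_node`,
#'   `attractor_focus`, `repeller`, `saddle`, `nonhyperbolic`).
#' @examples
#' m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 0.5)
#' classify_stability(m)[, c("label", "classification")]
#' @export
classify_stability <- function(model, eq_tbl = equilibria(model), tol = 1e-9) {
  n <- model$n_types
  ev <- purrr::map(seq_len(nrow(eq_tbl)), function(i) {
    J <- model_jacobian(model, coords_of(eq_tbl[i, ], n))
    if (!all(is.finite(J))) abort("non-finite Jacobian entries")
    eigen(J, only.values = TRUE)$values
  })
  eq_tbl$eigenvalues <- purrr::map(ev, as.complex)
  cls <- purrr::map_chr(ev, classify_eigenvalues, tol = tol)
  eq_tbl$hyperbolic <- cls != "nonhyperbolic"
  eq_tbl$classification <- cls
  class(eq_tbl) <- c("immune_stability", class(eq_tbl))
  eq_tbl
}

classify_eigenvalues <- function(lambda, tol = 1e-9) {
  re <- Re(lambda)
  scale <- max(1, max(Mod(lambda)))
  if (any(abs(re) < tol * scale)) return("nonhyperbolic")
  if (all(re < 0)) {
    if (all(abs(Im(lambda)) < tol * scale)) "attractor_node" else "attractor_focus"
  } else if (all(re > 0)) {
    "repeller"
  } else {
    "saddle"
  }
}

#' Routh-Hurwitz criterion for a monic quartic
#'
#' For \eqn{X^4 + A_3 X^3 + A_2 X^2 + A_1 X + A_0}, all roots lie in the
#' open left half-plane if and only if
#' \eqn{A_3 > 0}, \eqn{A_2 A_3 - A_1 > 0},
#' \eqn{A_1 A_2 A_3 - A_0 A_3^2 - A_1^2 > 0} and \eqn{A_0 > 0}.
#'
#' @param A3,A2,A1,A0 Quartic coefficients, or a `charpoly` object (from
#'   [charpoly_e512()] / [charpoly_e6()]) as the first argument.
#' @return `TRUE` iff all four inequalities hold strictly.
#' @examples
#' routh_hurwitz_quartic(4, 6, 4, 1)   # (X + 1)^4 -> stable
#' routh_hurwitz_quartic(2, 0, -2, -1) # root at +1 -> not stable
#' @export
routh_hurwitz_quartic <- function(A3, A2 = NULL, A1 = NULL, A0 = NULL) {
  if (inherits(A3, "charpoly")) {
    co <- A3; A3 <- co$A3; A2 <- co$A2; A1 <- co$A1; A0 <- co$A0
  }
  stopifnot(all(is.finite(c(A3, A2, A1, A0))))
  A3 > 0 && (A2 * A3 - A1) > 0 &&
    (A1 * A2 * A3 - A0 * A3^2 - A1^2) > 0 && A0 > 0
}

new_charpoly <- function(A3, A2, A1, A0, deflation = NULL, at = NULL) {
  structure(list(A3 = A3, A2 = A2, A1 = A1, A0 = A0,
                 deflation = deflation, at = at),
            class = "charpoly")
}

#' @export
print.charpoly <- function(x, ...) {
  cat(sprintf("X^4 + (%g) X^3 + (%g) X^2 + (%g) X + (%g)\n",
              x$A3, x$A2, x$A1, x$A0))
  invisible(x)
}

#' @export
tidy.charpoly <- function(x, ...) {
  tibble(term = c("A3", "A2", "A1", "A0"),
         value = c(x$A3, x$A2, x$A1, x$A0))
}

#' Analytic characteristic polynomial at the two-type virus-on equilibrium
#'
#' Closed-form coefficients of the monic quartic characteristic polynomial of
#' the Jacobian at the equilibrium supported on immunity types 1 and 2 with
#' the virus on (`E512`), expressed through its coordinates
#' \eqn{(x_1, x_2, 0, x_4)}. The constant term factorizes as
#' \eqn{A_0 = x_1 x_2 x_4 (a_3 - c_3 x_4)(b_1 p_2 c_2 + p_1 c_1 b_2)}, so
#' its sign - hence the saddle verdict via the product of eigenvalues -
#' is controlled by the position of the viral load relative to
#' \eqn{a_3/c_3}. Also returns the deflated cubic obtained by dividing out
#' the explicit transverse eigenvalue \eqn{\lambda_1 = a_3 - c_3 x_4}, with
#' \eqn{B_2 = A_3 + \lambda_1}, \eqn{B_1 = A_2 + \lambda_1 B_2},
#' \eqn{B_0 = A_1 + \lambda_1 B_1} (so that \eqn{A_0 = -\lambda_1 B_0}).
#'
#' @param model An uncontrolled [immune_model()] with three types.
#' @return A `charpoly` object with fields `A3..A0`, `deflation`
#'   (`lambda1`, `B2`, `B1`, `B0`) and `at` (the coordinates used).
#' @export
charpoly_e512 <- function(model) {
  ab <- model; a <- ab$a; b <- ab$b; cc <- ab$c; p <- ab$p; p4 <- ab$p4
  d <- p[1] * cc[1] / b[1] + p[2] * cc[2] / b[2]
  v <- (p[1] * a[1] / b[1] + p[2] * a[2] / b[2] - p4) / d
  x1 <- (a[1] - cc[1] * v) / b[1]
  x2 <- (a[2] - cc[2] * v) / b[2]
  x4 <- v
  if (x1 <= 0 || x2 <= 0 || x4 <= 0) {
    warn("E512 has nonpositive coordinates; coefficient formulas are still evaluated")
  }
  A3 <- b[1] * x1 + b[2] * x2 + cc[3] * x4 - a[3]
  A2 <- b[1] * x1 * cc[3] * x4 + b[2] * x2 * cc[3] * x4 -
    p[1] * x4 * cc[1] * x1 - p[2] * x4 * cc[2] * x2 +
    b[1] * x1 * b[2] * x2 - b[2] * x2 * a[3] - b[1] * x1 * a[3]
  A1 <- -b[1] * x1 * b[2] * x2 * a[3] + b[1] * x1 * b[2] * x2 * cc[3] * x4 -
    b[1] * x1 * p[2] * x4 * cc[2] * x2 + p[2] * x4 * cc[2] * x2 * a[3] -
    p[2] * x4^2 * cc[2] * x2 * cc[3] - p[1] * x4 * cc[1] * x1 * b[2] * x2 +
    p[1] * x4 * cc[1] * x1 * a[3] - p[1] * x4^2 * cc[1] * x1 * cc[3]
  A0 <- x2 * x1 * x4 * (a[3] - cc[3] * x4) * (b[1] * p[2] * cc[2] + p[1] * cc[1] * b[2])
  lambda1 <- a[3] - cc[3] * x4
  B2 <- A3 + lambda1
  B1 <- A2 + lambda1 * B2
  B0 <- A1 + lambda1 * B1
  new_charpoly(A3, A2, A1, A0,
               deflation = list(lambda1 = lambda1, B2 = B2, B1 = B1, B0 = B0),
               at = c(x1 = x1, x2 = x2, x3 = 0, v = x4))
}

#' Analytic characteristic polynomial at the interior equilibrium
#'
#' Closed-form coefficients at the full-support virus-on point `E6` with
#' coordinates \eqn{(x_1, x_2, x_3, x_4)}:
#' \eqn{A_3 = b_1 x_1 + b_2 x_2 + b_3 x_3} and
#' \eqn{A_0 = -x_1 x_2 x_3 x_4 (p_3 b_1 b_2 c_3 + p_1 b_2 b_3 c_1 +
#' b_1 p_2 b_3 c_2)}. When the point is biologically admissible, \eqn{A_3 > 0}
#' and \eqn{A_0 < 0}, which forces a saddle and rules out two pure-imaginary
#' eigenvalue pairs.
#'
#' @inheritParams charpoly_e512
#' @return A `charpoly` object (no deflation field).
#' @export
charpoly_e6 <- function(model) {
  a <- model$a; b <- model$b; cc <- model$c; p <- model$p; p4 <- model$p4
  d <- sum(p * cc / b)
  v <- (sum(p * a / b) - p4) / d
  x <- (a - cc * v) / b
  x4 <- v
  if (any(x <= 0) || x4 <= 0) {
    warn("E6 has nonpositive coordinates; coefficient formulas are still evaluated")
  }
  A3 <- sum(b * x)
  A2 <- b[1] * x[1] * b[2] * x[2] + b[1] * x[1] * b[3] * x[3] +
    b[2] * x[2] * b[3] * x[3] -
    (p[1] * cc[1] * x[1] + p[2] * cc[2] * x[2] + p[3] * cc[3] * x[3]) * x4
  A1 <- x[1] * x[2] * x[3] * b[1] * b[2] * b[3] -
    x[2] * x[3] * x4 * (p[2] * b[3] * cc[2] + p[3] * b[2] * cc[3]) -
    x[1] * x[2] * x4 * (p[1] * b[2] * cc[1] + p[2] * b[1] * cc[2]) -
    x[1] * x[3] * x4 * (p[3] * b[1] * cc[3] + p[1] * b[3] * cc[1])
  A0 <- -x[1] * x[2] * x[3] * x4 *
    (p[3] * b[1] * b[2] * cc[3] + p[1] * b[2] * b[3] * cc[1] + b[1] * p[2] * b[3] * cc[2])
  new_charpoly(A3, A2, A1, A0, at = c(x1 = x[1], x2 = x[2], x3 = x[3], v = x4))
}

#' Monic characteristic polynomial coefficients from eigenvalues
#'
#' Expands \eqn{\prod_i (X - \lambda_i)} for a 4x4 spectrum and returns the
#' real parts of the coefficients (imaginary parts vanish for a real matrix).
#' Used as the numeric oracle against the analytic coefficient formulas.
#'
#' @param lambda Complex vector of 4 eigenvalues.
#' @return A `charpoly` object.
#' @export
charpoly_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 4L)
  co <- c(1 + 0i)
  for (l in lambda) co <- c(co, 0) - c(0, l * co)
  co <- Re(co)
  new_charpoly(A3 = co[2], A2 = co[3], A1 = co[4], A0 = co[5])
}

#' Explicit eigenvalues at a single-type virus-on equilibrium
#'
#' At the equilibrium supported on immunity type `i` with the virus on
#' (`E4i`, coordinates \eqn{x_i = p_4/p_i},
#' \eqn{v = (a_i - b_i p_4/p_i)/c_i}), the Jacobian eigenvalues are known in
#' closed form: two transverse eigenvalues
#' \eqn{a_j - c_j (p_i a_i - p_4 b_i)/(c_i p_i)} for \eqn{j \neq i} and the
#' in-plane pair \eqn{(-p_4 b_i \pm \sqrt{\Delta})/(2 p_i)} with
#' \eqn{\Delta = p_4^2 b_i^2 - 4 p_i p_4^2 b_i + 4 p_4 p_i^2 a_i}. When the
#' point is admissible (\eqn{p_i a_i / b_i > p_4}), \eqn{\sqrt{\Delta} >
#' p_4 b_i}, so the pair has opposite signs and the point is a saddle.
#'
#' @param model An uncontrolled [immune_model()] with three types.
#' @param i Index of the supported immunity type.
#' @return Numeric vector of the 4 eigenvalues (transverse pair first, then
#'   the in-plane pair), with attribute `Delta`.
#' @export
e41_eigenvalues <- function(model, i = 1L) {
  a <- model$a; b <- model$b; cc <- model$c; p <- model$p; p4 <- model$p4
  Delta <- p4^2 * b[i]^2 - 4 * p[i] * p4^2 * b[i] + 4 * p4 * p[i]^2 * a[i]
  if (Delta < 0) {
    abort("negative discriminant: the point is not admissible (p_i a_i / b_i <= p4)")
  }
  j <- setdiff(seq_len(3), i)
  transverse <- a[j] - cc[j] * (p[i] * a[i] - p4 * b[i]) / (cc[i] * p[i])
  pair <- (-p4 * b[i] + c(1, -1) * sqrt(Delta)) / (2 * p[i])
  structure(c(transverse, pair), Delta = Delta)
}

#' Analytic stability verdicts for the uncontrolled catalogue
#'
#' Returns, for each of the 15 canonical labels, the classification implied
#' by the closed-form eigenvalue analysis of the uncontrolled system: the
#' origin is always a repeller; the virus-free coexistence point `E3` is an
#' attractor iff \eqn{p_4 < \sum_i p_i a_i / b_i} (a saddle for the reverse
#' strict inequality, nonhyperbolic on the threshold); every other
#' equilibrium is a saddle whenever it is biologically admissible. For
#' inadmissible virus-on points the verdict is `NA`.
#'
#' @param model An uncontrolled [immune_model()] with three types.
#' @param positive_tol Admissibility tolerance, as in [equilibria()].
#' @return A tibble with columns `label` and `predicted`.
#' @export
theorem_verdicts <- function(model, positive_tol = 1e-12) {
  eq <- equilibria(model, positive_tol = positive_tol)
  k <- sum(model$p * model$a / model$b)
  predicted <- purrr::pmap_chr(
    list(eq$label, eq$in_sigma_plus),
    function(label, ok) {
      if (label == "E0") return("repeller")
      if (label == "E3") {
        if (model$p4 < k) return("attractor_node")
        if (model$p4 > k) return("saddle")
        return("nonhyperbolic")
      }
      if (ok) "saddle" else NA_character_
    }
  )
  tibble(label = eq$label, predicted = predicted)
}

#' Complex-plane view of a stability report
#'
#' @param object A catalogue with eigenvalues from [classify_stability()].
#' @param ... Unused.
#' @return A ggplot of eigenvalues in the complex plane, faceted by label.
#' @export
autoplot.immune_stability <- function(object, ...) {
  df <- tidyr::unnest(
    tibble(label = object$label,
           classification = object$classification,
           lambda = object$eigenvalues),
    "lambda"
  )
  df$re <- Re(df$lambda); df$im <- Im(df$lambda)
  ggplot2::ggplot(df, ggplot2::aes(.data$re, .data$im, colour = .data$classification)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Re(lambda)", y = "Im(lambda)", colour = NULL)
}
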