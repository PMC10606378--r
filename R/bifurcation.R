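#' Transcritical-bifurcation surface residuals
#'
#' The uncontrolled system undergoes transcritical bifurcations on four
#' hyperplanes in clearance-parameter space. On
#' \eqn{S: \sum_i p_i a_i/b_i - p_4 = 0} the interior point `E6` collides
#' with the virus-free coexistence point `E3`. On
#' \eqn{S_{12}: p_1 (a_1/b_1 - a_3 c_1/(b_1 c_3)) +
#'              p_2 (a_2/b_2 - a_3 c_2/(b_2 c_3)) - p_4 = 0}
#' (feasible when \eqn{a_1 c_3 - a_3 c_1 > 0} and
#' \eqn{a_2 c_3 - a_3 c_2 > 0}) `E6` collides with `E512`, and analogously on
#' `S13` (`E513`) and `S23` (`E523`). The two-plane intersections
#' \eqn{\pi_1 = S_{12} \cap S_{13}}, \eqn{\pi_2 = S_{12} \cap S_{23}},
#' \eqn{\pi_3 = S_{13} \cap S_{23}} host collisions of `E6` with `E41`,
#' `E42`, `E43` respectively.
#'
#' @param model An uncontrolled [immune_model()] with three types.
#' @return A tibble with columns `surface`, `residual` (value of the defining
#'   expression; `NA` for the pi-planes, which are pairs of surfaces),
#'   `residual2` (second member for pi-planes), `feasible` and `collision`
#'   (which equilibria meet there).
#' @examples
#' m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 0.5)
#' surface_residuals(m)
#' @export
surface_residuals <- function(model) {
  a <- model$a; b <- model$b; cc <- model$c; p <- model$p; p4 <- model$p4
  s_res <- sum(p * a / b) - p4
  # S_ij: E6 meets E5ij where the omitted type's level hits zero (v = a_k/c_k)
  sij <- function(i, j, k) {
    res <- p[i] * (a[i] / b[i] - a[k] * cc[i] / (b[i] * cc[k])) +
      p[j] * (a[j] / b[j] - a[k] * cc[j] / (b[j] * cc[k])) - p4
    feas <- (a[i] * cc[k] - a[k] * cc[i]) > 0 && (a[j] * cc[k] - a[k] * cc[j]) > 0
    list(res = res, feas = feas)
  }
  s12 <- sij(1, 2, 3); s13 <- sij(1, 3, 2); s23 <- sij(2, 3, 1)
  tibble(
    surface = c("S", "S12", "S13", "S23", "pi1", "pi2", "pi3"),
    residual = c(s_res, s12$res, s13$res, s23$res,
                 s12$res, s12$res, s13$res),
    residual2 = c(NA, NA, NA, NA, s13$res, s23$res, s23$res),
    feasible = c(TRUE, s12$feas, s13$feas, s23$feas,
                 s12$feas && s13$feas, s12$feas && s23$feas,
                 s13$feas && s23$feas),
    collision = c("E6=E3", "E6=E512", "E6=E513", "E6=E523",
                  "E6=E41", "E6=E42", "E6=E43")
  )
}

#' Sotomayor's transcritical conditions at the virus-free coexistence point
#'
#' On the collision surface \eqn{p_4 = k := \sum_i p_i a_i/b_i} the Jacobian
#' at `E3` acquires a zero eigenvalue. Writing the system as
#' \eqn{\dot u = F(u, \mu)} with bifurcation parameter \eqn{\mu = p_4 - k},
#' Sotomayor's three conditions for a transcritical bifurcation are
#' evaluated with the right and left null vectors \eqn{v}, \eqn{w} of the
#' Jacobian and its transpose (computed numerically as the
#' smallest-magnitude eigenpairs, normalized so the last component is 1):
#' `cond1` \eqn{= w^T F_\mu = 0}, `cond2` \eqn{= w^T (DF_\mu) v = 1}, and
#' `cond3` \eqn{= w^T D^2F(v,v) = 2 \sum_i p_i c_i / b_i \neq 0}.
#' \eqn{F_\mu = (0,0,0,x_4)^T} and its Jacobian are analytic in the state;
#' the second differential is taken by central second differences along
#' \eqn{v} (near-exact, the vector field being quadratic).
#'
#' @param model An uncontrolled [immune_model()] with three types, with
#'   `p4` on the surface (within `surface_tol`).
#' @param tol Threshold for the verdict: `cond1` must vanish within it,
#'   `cond2` and `cond3` must exceed it in magnitude.
#' @param surface_tol Allowed distance of `p4` from the collision value.
#' @return An object of class `sotomayor_check`: list with `mu`, `k`,
#'   `right_eigvec`, `left_eigvec`, `cond1`, `cond2`, `cond3`, `verdict`.
#' @export
sotomayor_at_e3 <- function(model, tol = 1e-8, surface_tol = 1e-9) {
  if (model$control$kind != "none") abort("defined for the uncontrolled system")
  k <- sum(model$p * model$a / model$b)
  mu <- model$p4 - k
  if (abs(mu) > surface_tol * max(1, k)) {
    abort("parameters do not lie on the collision surface (p4 != sum p_i a_i / b_i)")
  }
  u0 <- c(model$a / model$b, 0)
  J <- model_jacobian(model, u0)
  v <- null_vector(J)
  w <- null_vector(t(J))
  scale <- max(1, max(Mod(eigen(J, only.values = TRUE)$values)))
  # F_mu = dF/d(p4) = (0, 0, 0, x4): analytic in the state
  F_mu <- function(u) c(0, 0, 0, u[4])
  cond1 <- sum(w * F_mu(u0))
  # DF_mu is the state-Jacobian of F_mu: only d(x4)/d(x4) = 1 survives
  DF_mu <- rbind(0, 0, 0, c(0, 0, 0, 1))
  cond2 <- drop(w %*% DF_mu %*% v)
  h <- 1e-4 * max(1, max(abs(u0)))
  d2 <- (vector_field(model, u0 + h * v) - 2 * vector_field(model, u0) +
           vector_field(model, u0 - h * v)) / h^2
  cond3 <- sum(w * d2)
  verdict <- abs(cond1) <= tol && abs(cond2) > tol && abs(cond3) > tol
  structure(list(mu = mu, k = k, right_eigvec = v, left_eigvec = w,
                 cond1 = cond1, cond2 = cond2, cond3 = cond3,
                 verdict = verdict, tol = tol),
            class = "sotomayor_check")
}

# null vector of a (near-)singular matrix via its smallest-magnitude
# eigenpair, normalized so the last component is +1
null_vector <- function(M) {
  es <- eigen(M)
  i <- which.min(Mod(es$values))
  if (Mod(es$values[i]) > 1e-6 * max(1, max(Mod(es$values)))) {
    abort("no zero eigenvalue found: not at a bifurcation point")
  }
  vec <- Re(es$vectors[, i])
  if (abs(vec[length(vec)]) < 1e-12) abort("null vector degenerate in the last component")
  vec / vec[length(vec)]
}

#' @export
print.sotomayor_check <- function(x, ...) {
  cat("<sotomayor_check> mu =", format(x$mu), " k =", format(x$k), "\n")
  cat(sprintf("  cond1 (w.F_mu)      = %.3e\n", x$cond1))
  cat(sprintf("  cond2 (w.DF_mu v)   = %.6f\n", x$cond2))
  cat(sprintf("  cond3 (w.D2F(v,v))  = %.6f\n", x$cond3))
  cat("  transcritical conditions met:", x$verdict, "\n")
  invisible(x)
}

#' @export
tidy.sotomayor_check <- function(x, ...) {
  tibble(condition = c("cond1", "cond2", "cond3"),
         value = c(x$cond1, x$cond2, x$cond3),
         requirement = c("zero", "nonzero", "nonzero"))
}

#' Locate the stability exchange between the coexistence and interior points
#'
#' Scans the viral proliferation rate `p4` across an interval and locates,
#' by bisection on the critical eigenvalue \eqn{\lambda_4(E_3) = p_4 - k},
#' the transcritical crossing at \eqn{p_4 = k = \sum_i p_i a_i/b_i}. On the
#' lower side `E3` is an attractor and the interior point `E6` is an
#' admissible saddle; on the upper side `E3` is a saddle and `E6` leaves the
#' positive orthant (its viral load turns negative). The two points merge at
#' the crossing.
#'
#' @param model An uncontrolled [immune_model()] with three types (its own
#'   `p4` is ignored during the scan).
#' @param p4_range Length-2 numeric interval to scan.
#' @param xtol Bisection tolerance on `p4`.
#' @param side_fraction Relative offset from the crossing at which the
#'   two-sided classifications are reported.
#' @return A list of class `crossing_scan`: `found`, `p4_crossing`, `k`, and
#'   a tibble `sides` (classification of `E3`, admissibility and `v` of `E6`,
#'   distance between them, on both sides).
#' @export
crossing_scan <- function(model, p4_range, xtol = 1e-10, side_fraction = 0.05) {
  stopifnot(length(p4_range) == 2L, diff(p4_range) > 0)
  k <- sum(model$p * model$a / model$b)
  lam4 <- function(p4) {
    m <- reparam(model, p4)
    J <- model_jacobian(m, c(m$a / m$b, 0))
    ev <- eigen(J, only.values = TRUE)$values
    Re(ev[which.min(Mod(ev - J[4, 4]))])
  }
  lo <- p4_range[1]; hi <- p4_range[2]
  flo <- lam4(lo); fhi <- lam4(hi)
  if (flo * fhi > 0) {
    return(structure(list(found = FALSE, p4_crossing = NA_real_, k = k,
                          sides = NULL), class = "crossing_scan"))
  }
  while (hi - lo > xtol) {
    mid <- (lo + hi) / 2
    if (lam4(lo) * lam4(mid) <= 0) hi <- mid else lo <- mid
  }
  p4c <- (lo + hi) / 2
  sides <- dplyr::bind_rows(purrr::map(
    c(-1, 1),
    function(s) side_report(model, p4c * (1 + s * side_fraction), k)
  ))
  structure(list(found = TRUE, p4_crossing = p4c, k = k, sides = sides),
            class = "crossing_scan")
}

reparam <- function(model, p4) {
  immune_model(model$a, model$b, model$c, model$p, p4, control = model$control)
}

side_report <- function(model, p4, k) {
  m <- reparam(model, p4)
  st <- classify_stability(m)
  e3 <- st[st$label == "E3", ]
  e6 <- st[st$label == "E6", ]
  co3 <- coords_of(e3, m$n_types)
  co6 <- coords_of(e6, m$n_types)
  tibble(
    p4 = p4,
    side = if (p4 < k) "below" else "above",
    e3_classification = e3$classification,
    e6_in_sigma_plus = e6$in_sigma_plus,
    e6_v = e6$v,
    e3_e6_distance = max(abs(co3 - co6))
  )
}

#' @export
print.crossing_scan <- function(x, ...) {
  if (!x$found) {
    cat("<crossing_scan> no eigenvalue crossing bracketed\n")
    return(invisible(x))
  }
  cat("<crossing_scan> crossing at p4 =", format(x$p4_crossing, digits = 12),
      "(collision value k =", format(x$k, digits = 12), ")\n")
  print(x$sides)
  invisible(x)
}

#' Exclude a Hopf-Hopf bifurcation at the interior equilibrium
#'
#' Two pure-imaginary eigenvalue pairs would force the eigenvalue sum to be
#' zero and the product positive, contradicting \eqn{A_3 > 0} and
#' \eqn{A_0 < 0}, which hold whenever the interior point is admissible. The
#' certificate reports both coefficients and additionally confirms
#' numerically that no quadruple \eqn{(\pm i\omega_1, \pm i\omega_2)} is
#' present within tolerance.
#'
#' @param model An uncontrolled [immune_model()] with three types and an
#'   admissible interior point.
#' @param tol Relative tolerance for the numeric eigenvalue confirmation.
#' @return A list with `excluded` (flag) and `certificate` (`A3`, `A0`,
#'   `max_abs_re`, the smallest real-part magnitude over the spectrum).
#' @export
hopf_hopf_exclusion_e6 <- function(model, tol = 1e-9) {
  eq <- equilibria(model)
  e6 <- eq[eq$label == "E6", ]
  if (!e6$in_sigma_plus) {
    abort("the interior equilibrium is not in the open positive orthant")
  }
  cp <- charpoly_e6(model)
  lambda <- eigen(model_jacobian(model, coords_of(e6, model$n_types)),
                  only.values = TRUE)$values
  scale <- max(1, max(Mod(lambda)))
  n_imaginary <- sum(abs(Re(lambda)) < tol * scale & abs(Im(lambda)) > tol * scale)
  excluded <- cp$A3 > 0 && cp$A0 < 0 && n_imaginary < 4L
  list(excluded = excluded,
       certificate = list(A3 = cp$A3, A0 = cp$A0,
                          min_abs_re = min(abs(Re(lambda))),
                          n_pure_imaginary = n_imaginary))
}
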