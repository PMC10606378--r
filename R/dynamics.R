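#' Integrate a model trajectory
#'
#' Adaptive integration of the selected system with `deSolve` (`lsodar`,
#' which switches automatically between non-stiff Adams and stiff BDF
#' formulas and supports root-triggered stopping). The integration halts
#' early when any component exceeds the escape threshold, a finite
#' operational proxy for divergence of the viral load to infinity.
#'
#' @param model An [immune_model()].
#' @param state0 Initial state (immunity levels then viral load),
#'   componentwise nonnegative.
#' @param t_end Final time (> 0).
#' @param n_out Number of output times (uniform grid from 0).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param escape_threshold Component level triggering the escape event;
#'   defaults to \eqn{10^6 \max(\max_i a_i/b_i, 1)}.
#' @return A tibble of class `immune_trajectory` with columns `time`,
#'   `x1..xn`, `v`; attributes `model`, `escaped` (flag) and
#'   `escape_threshold`.
#' @examples
#' m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 0.5)
#' traj <- simulate_model(m, c(0.9, 1.1, 1.0, 0.2), t_end = 50)
#' tail(traj, 1)  # close to the virus-free coexistence point (1, 1, 1, 0)
#' @export
simulate_model <- function(model, state0, t_end, n_out = 400L,
                           rtol = 1e-8, atol = 1e-10,
                           escape_threshold = NULL) {
  state0 <- check_state(model, state0)
  if (any(state0 < 0)) abort("initial state must be componentwise nonnegative")
  if (t_end <= 0) abort("`t_end` must be positive")
  n <- model$n_types
  if (is.null(escape_threshold)) {
    escape_threshold <- 1e6 * max(max(model$a / model$b), 1)
  }
  rhs <- function(t, y, parms) list(vector_field(model, y))
  jac <- function(t, y, parms) model_jacobian(model, y)
  root <- function(t, y, parms) max(y) - escape_threshold
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::lsodar(y = state0, times = times, func = rhs,
                         jacfunc = jac, jactype = "fullusr",
                         rootfunc = root, rtol = rtol, atol = atol)
  escaped <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  out <- as_tibble(as.data.frame(sol))
  names(out) <- c("time", paste0("x", seq_len(n)), "v")
  attr(out, "model") <- model
  attr(out, "escaped") <- escaped
  attr(out, "escape_threshold") <- escape_threshold
  class(out) <- c("immune_trajectory", class(out))
  out
}

#' Classify the long-run outcome of a trajectory
#'
#' A trajectory converges to a catalogued equilibrium when its final state
#' is within `tol` (max norm) of that point and the vector field there is
#' below `tol` in norm (guarding against slow saddle passages); it is
#' escaping when the escape event fired while the viral load was still
#' growing; otherwise the outcome is undetermined.
#'
#' @param traj An [simulate_model()] trajectory.
#' @param eq_tbl Equilibrium catalogue to match against; defaults to the
#'   closed-form catalogue of the trajectory's model.
#' @param tol Convergence tolerance (max norm and derivative norm).
#' @return A one-row tibble with columns `outcome`
#'   (`"converged"`/`"escaping"`/`"undetermined"`), `label` (matched
#'   equilibrium or `NA`), `time`, `distance` and `speed` (vector-field
#'   norm at the final state).
#' @export
classify_outcome <- function(traj, eq_tbl = NULL, tol = 1e-6) {
  model <- attr(traj, "model")
  n <- model$n_types
  if (is.null(eq_tbl)) {
    eq_tbl <- if (model$control$kind == "none") equilibria(model)
              else solve_equilibria(model)
  }
  final <- unlist(traj[nrow(traj), -1], use.names = FALSE)
  speed <- max(abs(vector_field(model, final)))
  co <- equilibrium_coords(eq_tbl, model)
  dists <- apply(co, 1, function(r) max(abs(r - final)))
  i <- which.min(dists)
  if (isTRUE(attr(traj, "escaped"))) {
    vdot <- vector_field(model, final)[n + 1L]
    if (vdot > 0) {
      return(tibble(outcome = "escaping", label = NA_character_,
                    time = traj$time[nrow(traj)], distance = min(dists),
                    speed = speed))
    }
  }
  if (dists[i] < tol && speed < tol) {
    return(tibble(outcome = "converged", label = eq_tbl$label[i],
                  time = traj$time[nrow(traj)], distance = dists[i],
                  speed = speed))
  }
  tibble(outcome = "undetermined", label = NA_character_,
         time = traj$time[nrow(traj)], distance = dists[i], speed = speed)
}

#' Audit positive-orthant invariance of the integrator
#'
#' The coordinate hyperplanes are invariant manifolds of the model, so no
#' orbit starting in the closed positive orthant may leave it. This audit
#' integrates seeded random starts in the open orthant and on each boundary
#' hyperplane and reports the most negative component ever stored.
#'
#' @param model An [immune_model()].
#' @param n_draws Random interior starts (the boundary adds one start per
#'   hyperplane per draw batch).
#' @param seed Integer seed.
#' @param t_end Integration horizon per start.
#' @return A list with `worst` (most negative component observed; 0 when
#'   positivity is never violated) and `details` (tibble per start).
#' @export
invariance_audit <- function(model, n_draws = 50L, seed = 0L, t_end = 30) {
  set.seed(seed)
  n <- model$n_types
  scale <- max(model$a / model$b)
  starts <- purrr::map(seq_len(n_draws), function(k) {
    exp(runif(n + 1L, log(1e-2), log(10))) * scale
  })
  # one start on each boundary hyperplane
  boundary <- purrr::map(seq_len(n + 1L), function(i) {
    s <- exp(runif(n + 1L, log(1e-2), log(2))) * scale
    s[i] <- 0
    s
  })
  starts <- c(starts, boundary)
  rows <- purrr::imap(starts, function(s, k) {
    traj <- simulate_model(model, s, t_end = t_end)
    m <- as.matrix(traj[, -1])
    tibble(start = k, on_boundary = any(s == 0),
           min_component = min(m))
  })
  details <- dplyr::bind_rows(rows)
  list(worst = min(details$min_component, 0), details = details)
}

#' @export
glance.immune_trajectory <- function(x, ...) {
  model <- attr(x, "model")
  final <- unlist(x[nrow(x), -1], use.names = FALSE)
  out <- tibble(t_end = x$time[nrow(x)],
                escaped = isTRUE(attr(x, "escaped")),
                final_v = final[length(final)],
                speed = max(abs(vector_field(model, final))))
  out
}

#' Plot a trajectory
#'
#' @param object An [simulate_model()] trajectory.
#' @param ... Unused.
#' @return A ggplot of all components against time (viral load highlighted).
#' @export
autoplot.immune_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time",
                            names_to = "component", values_to = "level")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$level,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "level", colour = NULL)
}
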