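#' Enumerate all equilibria of the uncontrolled system in closed form
#'
#' Every equilibrium of the uncontrolled system is determined by its support
#' pattern: the subset of immunity types at a positive level, and whether the
#' viral load is switched on. Virus-off equilibria put each supported type at
#' its carrying capacity \eqn{a_i/b_i}. Virus-on equilibria with support
#' \eqn{T} carry the viral load
#' \deqn{v_T = \frac{\sum_{i \in T} p_i a_i / b_i - p_4}
#'                  {\sum_{i \in T} p_i c_i / b_i}}
#' and immunity levels \eqn{x_i = (a_i - c_i v_T)/b_i} for \eqn{i \in T}.
#' For three immunity types this yields the canonical 15-point catalogue
#' (labels `E0`, `E11`..`E13`, `E212`..`E223`, `E3`, `E41`..`E43`,
#' `E512`..`E523`, `E6`); generically there are \eqn{2^{n+1} - 1} equilibria.
#'
#' The column `in_sigma_plus` flags biological admissibility: the point lies
#' in the closed positive orthant and every supported coordinate (and the
#' viral load, when on) is strictly positive. For the full-support interior
#' point this coincides with membership in the open orthant.
#'
#' @param model An uncontrolled [immune_model()]. For `equilibria()` with
#'   three immunity types the canonical labels are used; any other `n_types`
#'   falls through to the generic support-pattern enumeration.
#' @param positive_tol Coordinates larger than this count as positive when
#'   evaluating admissibility (guards round-off in the exact ratios).
#'
#' @return A tibble with one row per equilibrium and columns `label`,
#'   `support` (list of immunity indices), `virus_on`, the coordinates
#'   `x1`..`xn`, `v`, `in_sigma_plus`, and `derived` (list of auxiliary
#'   quantities: the viral load `v_T` and its denominator `d_T` for virus-on
#'   points). Supports degenerate parameter sets by construction: rows are
#'   indexed by support pattern, so coincident coordinates remain distinct
#'   rows (flagged via `coincident` attribute in [distinct_equilibria()]).
#'
#' @examples
#' m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 0.5)
#' equilibria(m)
#' @export
equilibria <- function(model, positive_tol = 1e-12) {
  if (model$control$kind != "none") {
    abort("closed-form enumeration applies to the uncontrolled system; use solve_equilibria() for controlled models")
  }
  n <- model$n_types
  supports <- support_patterns(n)
  rows <- purrr::pmap(supports, function(support, virus_on) {
    eq_for_support(model, support, virus_on)
  })
  out <- dplyr::bind_rows(rows)
  out$in_sigma_plus <- purrr::pmap_lgl(
    list(seq_len(nrow(out)), out$support, out$virus_on),
    function(i, supp, von) admissible(coords_of(out[i, ], n), supp, von, n, positive_tol)
  )
  if (n == 3L) out$label <- canonical_labels(out)
  out
}

# all support patterns: every subset of types virus-off, every nonempty-or-not
# subset virus-on except the empty virus-on pattern (p4 > 0 forbids it)
support_patterns <- function(n) {
  subsets <- purrr::map(0:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  tibble(
    support = c(subsets, subsets[-1]),
    virus_on = rep(c(FALSE, TRUE), c(length(subsets), length(subsets) - 1L))
  )
}

eq_for_support <- function(model, support, virus_on) {
  n <- model$n_types
  x <- numeric(n)
  derived <- list()
  if (virus_on) {
    d <- sum(model$p[support] * model$c[support] / model$b[support])
    v <- (sum(model$p[support] * model$a[support] / model$b[support]) - model$p4) / d
    x[support] <- (model$a[support] - model$c[support] * v) / model$b[support]
    derived <- list(v_T = v, d_T = d)
  } else {
    v <- 0
    x[support] <- model$a[support] / model$b[support]
  }
  row <- tibble(
    label = generic_label(support, virus_on),
    support = list(as.integer(support)),
    virus_on = virus_on
  )
  for (i in seq_len(n)) row[[paste0("x", i)]] <- x[i]
  row$v <- v
  row$derived <- list(derived)
  row
}

generic_label <- function(support, virus_on) {
  paste0("E[", paste(support, collapse = ","), if (virus_on) "+v", "]")
}

canonical_labels <- function(tbl) {
  purrr::map2_chr(tbl$support, tbl$virus_on, function(supp, von) {
    k <- length(supp)
    if (!von) {
      switch(as.character(k),
             "0" = "E0",
             "1" = paste0("E1", supp),
             "2" = paste0("E2", paste(supp, collapse = "")),
             "3" = "E3")
    } else {
      switch(as.character(k),
             "1" = paste0("E4", supp),
             "2" = paste0("E5", paste(supp, collapse = "")),
             "3" = "E6")
    }
  })
}

coords_of <- function(row, n) {
  unlist(row[c(paste0("x", seq_len(n)), "v")], use.names = FALSE)
}

admissible <- function(coords, support, virus_on, n, tol) {
  supported <- coords[c(support, if (virus_on) n + 1L)]
  all(coords > -tol) && all(supported > tol)
}

#' Flag coincident equilibria in a catalogue
#'
#' Enumeration is indexed by support pattern, so degenerate parameter sets
#' can make two patterns share coordinates (e.g. a virus-on point whose viral
#' load is exactly zero). Both rows are kept; this helper marks them.
#'
#' @param eq_tbl A catalogue from [equilibria()] or [solve_equilibria()].
#' @param model The model the catalogue came from.
#' @param tol Relative coordinate distance below which two rows count as the
#'   same point.
#' @return `eq_tbl` with an added logical column `coincident`.
#' @export
distinct_equilibria <- function(eq_tbl, model, tol = 1e-9) {
  n <- model$n_types
  co <- do.call(rbind, purrr::map(seq_len(nrow(eq_tbl)), ~ coords_of(eq_tbl[.x, ], n)))
  coincident <- rep(FALSE, nrow(eq_tbl))
  for (i in seq_len(nrow(eq_tbl))) for (j in seq_len(i - 1L)) {
    if (max(abs(co[i, ] - co[j, ])) / max(1, max(abs(co[i, ]))) < tol) {
      coincident[i] <- coincident[j] <- TRUE
    }
  }
  eq_tbl$coincident <- coincident
  eq_tbl
}

#' Numerically solve the controlled equilibrium systems
#'
#' For a controlled model the boundary equilibria keep simple closed forms
#' but the virus-free coexistence point and the interior point do not; this
#' solver finds equilibria support pattern by support pattern. Off-support
#' coordinates are pinned to zero and the reduced "divided" system (each
#' equation divided by its own state variable, which is positive on the
#' support) is solved by seeded multi-start Levenberg-Marquardt with the
#' analytic Jacobian, starting from log-uniform draws around the carrying
#' capacities plus the uncontrolled closed-form point. Distinct roots are
#' returned after deduplication.
#'
#' @param model A controlled (or uncontrolled) [immune_model()] with three
#'   immunity types.
#' @param supports Optional list of integer vectors restricting the support
#'   patterns searched; default is every pattern.
#' @param n_starts Random starts per support pattern.
#' @param seed Integer seed for the start draws.
#' @param residual_tol Roots whose full vector-field residual (max norm)
#'   exceeds this are rejected.
#' @param dedup_tol Relative distance under which two roots are merged.
#' @param positive_tol Passed to the admissibility flag.
#'
#' @return A tibble like [equilibria()] with an extra `residual` column.
#' @examples
#' m <- immune_model(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3), p4 = 0.5,
#'                   control = control_product(0.05, 0.05, 0.05))
#' nrow(solve_equilibria(m, seed = 1))
#' @export
solve_equilibria <- function(model, supports = NULL, n_starts = 32L, seed = 1L,
                             residual_tol = 1e-9, dedup_tol = 1e-7,
                             positive_tol = 1e-12) {
  n <- model$n_types
  if (n != 3L) abort("the numeric equilibrium solver is defined for three immunity types")
  pats <- support_patterns(n)
  if (!is.null(supports)) {
    keep <- purrr::map2_lgl(pats$support, pats$virus_on, function(s, von) {
      any(purrr::map_lgl(supports, ~ setequal(.x, s)))
    })
    pats <- pats[keep, ]
  }
  set.seed(seed)
  rows <- purrr::pmap(pats, function(support, virus_on) {
    solve_support(model, support, virus_on, n_starts, residual_tol, dedup_tol)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  # global deduplication across supports (a root can sit on a smaller support)
  co <- do.call(rbind, purrr::map(seq_len(nrow(out)), ~ coords_of(out[.x, ], n)))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] &&
          max(abs(co[i, ] - co[j, ])) / max(1, max(abs(co[j, ]))) < dedup_tol) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, ]
  out$in_sigma_plus <- purrr::pmap_lgl(
    list(seq_len(nrow(out)), out$support, out$virus_on),
    function(i, supp, von) admissible(coords_of(out[i, ], n), supp, von, n, positive_tol)
  )
  out$label <- canonical_labels(out)
  out
}

# reduced system on a support: equations divided by their state variable,
# polynomial in the support coordinates; off-support coordinates are 0
solve_support <- function(model, support, virus_on, n_starts, residual_tol,
                          dedup_tol) {
  n <- model$n_types
  m <- length(support) + as.integer(virus_on)
  embed <- function(z) {
    x <- numeric(n + 1L)
    x[support] <- z[seq_along(support)]
    if (virus_on) x[n + 1L] <- z[length(z)]
    x
  }
  divided <- function(z) {
    s <- embed(z)
    x <- s[seq_len(n)]
    v <- s[n + 1L]
    gi <- (model$a - model$b * x - model$c * v +
             control_terms_divided(model, x))[support]
    gv <- model$p4 - sum(model$p * x)
    c(gi, if (virus_on) gv)
  }
  if (m == 0L) {
    row <- eq_row_from_coords(model, numeric(n + 1L), support, virus_on)
    row$residual <- max(abs(vector_field(model, numeric(n + 1L))))
    return(row)
  }
  # starts: closed-form uncontrolled point plus log-uniform draws around
  # the carrying capacities
  cc <- model$a / model$b
  closed <- eq_for_support(model, support, virus_on)
  z0 <- coords_of(closed, n)[c(support, if (virus_on) n + 1L)]
  scale_z <- c(cc[support], if (virus_on) max(cc))
  starts <- c(list(z0), purrr::map(seq_len(n_starts), function(k) {
    scale_z * exp(runif(m, log(1e-3), log(10)))
  }))
  roots <- list()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = divided,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    z <- fit$par
    full <- embed(z)
    if (!all(is.finite(full))) next
    res <- max(abs(vector_field(model, full)))
    if (res >= residual_tol) next
    dup <- any(purrr::map_lgl(roots, function(r) {
      max(abs(r$coords - full)) / max(1, max(abs(r$coords))) < dedup_tol
    }))
    if (!dup) roots <- c(roots, list(list(coords = full, residual = res)))
  }
  dplyr::bind_rows(purrr::map(roots, function(r) {
    row <- eq_row_from_coords(model, r$coords, support, virus_on)
    row$residual <- r$residual
    row
  }))
}

# control term divided by the equation's own state variable (polynomial)
control_terms_divided <- function(model, x) {
  ctl <- model$control
  if (ctl$kind == "none") return(numeric(model$n_types))
  k <- c(ctl$alpha, ctl$beta, ctl$gamma)
  if (ctl$kind == "product") {
    sapply(1:3, function(i) k[i] * prod(x[-i]))
  } else {
    k * (sum(x) - x)
  }
}

eq_row_from_coords <- function(model, coords, support, virus_on) {
  n <- model$n_types
  row <- tibble(
    label = generic_label(support, virus_on),
    support = list(as.integer(support)),
    virus_on = virus_on
  )
  for (i in seq_len(n)) row[[paste0("x", i)]] <- coords[i]
  row$v <- coords[n + 1L]
  row$derived <- list(list())
  row
}

#' Closed-form two-type coexistence point under pairwise-sum control
#'
#' Under the pairwise-sum control the virus-free equilibrium supported on the
#' first two immunity types has the closed form
#' \deqn{x_1^* = \frac{a_1 b_2 + a_2 \alpha}{b_1 b_2 - \alpha\beta}, \quad
#'       x_2^* = \frac{a_2 b_1 + a_1 \beta}{b_1 b_2 - \alpha\beta},}
#' existing whenever \eqn{b_1 b_2 - \alpha\beta \neq 0}.
#'
#' @param model An [immune_model()] with pairwise-sum control.
#' @return A list with `exists`, `x1`, `x2` and the full coordinate vector
#'   `coords` (NULL when the denominator vanishes).
#' @export
e212_closed_form <- function(model) {
  stopifnot_kind(model, "pairwise_sum")
  al <- model$control$alpha; be <- model$control$beta
  den <- model$b[1] * model$b[2] - al * be
  if (den == 0) return(list(exists = FALSE, x1 = NA_real_, x2 = NA_real_, coords = NULL))
  x1 <- (model$a[1] * model$b[2] + model$a[2] * al) / den
  x2 <- (model$a[2] * model$b[1] + model$a[1] * be) / den
  list(exists = TRUE, x1 = x1, x2 = x2, coords = c(x1, x2, 0, 0))
}

#' Uniqueness determinant for the virus-free coexistence point under
#' pairwise-sum control
#'
#' The three-type virus-free equilibrium solves a linear system whose matrix
#' has determinant
#' \eqn{b_1 b_2 b_3 - 2\alpha\beta\gamma - b_1\beta\gamma - b_2\alpha\gamma
#'      - b_3\alpha\beta}; when this vanishes there is either a continuum of
#' such equilibria or none.
#'
#' @param model An [immune_model()] with pairwise-sum control.
#' @return The determinant value (scalar).
#' @export
e3_uniqueness_determinant <- function(model) {
  stopifnot_kind(model, "pairwise_sum")
  b <- model$b
  al <- model$control$alpha; be <- model$control$beta; ga <- model$control$gamma
  b[1] * b[2] * b[3] - 2 * al * be * ga - b[1] * be * ga -
    b[2] * al * ga - b[3] * al * be
}

stopifnot_kind <- function(model, kind) {
  if (model$control$kind != kind) {
    abort(sprintf("this operation requires %s control", kind))
  }
}

#' Extract the coordinate matrix of an equilibrium catalogue
#'
#' @param eq_tbl A catalogue tibble.
#' @param model The model it belongs to.
#' @return A numeric matrix, one row per equilibrium, columns
#'   `x1..xn, v`.
#' @export
equilibrium_coords <- function(eq_tbl, model) {
  n <- model$n_types
  m <- do.call(rbind, purrr::map(seq_len(nrow(eq_tbl)), ~ coords_of(eq_tbl[.x, ], n)))
  colnames(m) <- c(paste0("x", seq_len(n)), "v")
  rownames(m) <- eq_tbl$label
  m
}
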