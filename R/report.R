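#' Read and write model configurations
#'
#' Configurations are YAML or JSON mappings with keys `a`, `b`, `c`, `p`,
#' `p4`, optional `control: {kind, alpha, beta, gamma}`, optional
#' `state: {x, v}`, and optional analysis settings (`t_end`, `p4_range`,
#' `seed`, ...). `read_model_config()` validates and returns the parsed
#' list together with the constructed [immune_model()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with `model`, `state0` (or `NULL`) and `settings` (the
#'   remaining keys).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_to_model(cfg)
}

config_to_model <- function(cfg) {
  for (key in c("a", "b", "c", "p", "p4")) {
    if (is.null(cfg[[key]])) abort(sprintf("config is missing key `%s`", key))
  }
  control <- control_none()
  if (!is.null(cfg$control) && !identical(cfg$control$kind, "none")) {
    ctor <- switch(cfg$control$kind,
                   product = control_product,
                   pairwise_sum = control_pairwise_sum,
                   abort("control kind must be none, product or pairwise_sum"))
    control <- ctor(cfg$control$alpha %||% 0, cfg$control$beta %||% 0,
                    cfg$control$gamma %||% 0)
  }
  model <- immune_model(cfg$a, cfg$b, cfg$c, cfg$p, cfg$p4, control = control)
  state0 <- if (!is.null(cfg$state)) c(cfg$state$x, cfg$state$v)
  settings <- cfg[setdiff(names(cfg), c("a", "b", "c", "p", "p4", "control", "state"))]
  list(model = model, state0 = state0, settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_model_config
#' @param model An [immune_model()] to serialize.
#' @param state0 Optional initial state to embed.
#' @param settings Optional named list of extra keys.
#' @export
write_model_config <- function(model, path, state0 = NULL, settings = list()) {
  n <- model$n_types
  cfg <- list(a = model$a, b = model$b, c = model$c, p = model$p, p4 = model$p4)
  if (model$control$kind != "none") {
    cfg$control <- model$control[c("kind", "alpha", "beta", "gamma")]
  }
  if (!is.null(state0)) {
    cfg$state <- list(x = state0[seq_len(n)], v = state0[n + 1L])
  }
  cfg <- c(cfg, settings)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 12)
  }
  invisible(path)
}

#' Run a full equilibrium-and-stability analysis from a configuration
#'
#' Enumerates the equilibria (closed form for the uncontrolled system,
#' generic support enumeration for other `n_types`, numeric multi-start for
#' controlled models), classifies their stability, attaches the analytic
#' verdicts and bifurcation-surface residuals where applicable, and
#' optionally writes a CSV table and a JSON summary.
#'
#' @param config Path to a config file, or a parsed list from
#'   [read_model_config()].
#' @param out_dir Optional output directory for `equilibria.csv` and
#'   `summary.json`.
#' @param seed Seed for the numeric solver (controlled models).
#' @return The annotated equilibrium tibble (invisibly when `out_dir` is
#'   given).
#' @export
run_analysis <- function(config, out_dir = NULL, seed = 1L) {
  cfg <- if (is.character(config)) read_model_config(config) else config
  model <- cfg$model
  eq <- if (model$control$kind == "none") equilibria(model)
        else solve_equilibria(model, seed = seed)
  st <- classify_stability(model, eq)
  if (model$n_types == 3L && model$control$kind == "none") {
    st <- dplyr::left_join(st, theorem_verdicts(model), by = "label")
  }
  res <- max(purrr::map_dbl(seq_len(nrow(st)), function(i) {
    max(abs(vector_field(model, coords_of(st[i, ], model$n_types))))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- st
    flat$support <- purrr::map_chr(flat$support, paste, collapse = "+")
    flat$eigenvalues <- purrr::map_chr(flat$eigenvalues,
                                       ~ paste(format(.x, digits = 12), collapse = ";"))
    flat$derived <- NULL
    write.csv(flat, file.path(out_dir, "equilibria.csv"), row.names = FALSE)
    summary <- list(
      n_types = model$n_types,
      control = model$control$kind,
      n_equilibria = nrow(st),
      n_admissible = sum(st$in_sigma_plus),
      classification_counts = as.list(table(st$classification)),
      max_residual = res,
      parameters = list(a = model$a, b = model$b, c = model$c,
                        p = model$p, p4 = model$p4)
    )
    if (model$n_types == 3L && model$control$kind == "none") {
      summary$surfaces <- surface_residuals(model)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(st))
  }
  st
}

#' Run a trajectory simulation from a configuration
#'
#' Wraps [simulate_model()] and [classify_outcome()]; the config must carry
#' a `state` block and may set `t_end` (default 100).
#'
#' @inheritParams run_analysis
#' @return A list with `trajectory` and `outcome`; files `trajectory.csv`
#'   and `outcome.json` are written when `out_dir` is given.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_model_config(config) else config
  if (is.null(cfg$state0)) abort("config must provide a `state` block")
  t_end <- cfg$settings$t_end %||% 100
  if (t_end <= 0) abort("`t_end` must be positive")
  traj <- simulate_model(cfg$model, cfg$state0, t_end = t_end)
  outcome <- classify_outcome(traj)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(traj), file.path(out_dir, "trajectory.csv"),
              row.names = FALSE)
    jsonlite::write_json(as.list(outcome), file.path(out_dir, "outcome.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, outcome = outcome)
}

#' Run a bifurcation scan from a configuration
#'
#' Wraps [crossing_scan()] and, when the parameters lie on the collision
#' surface, [sotomayor_at_e3()]; the config may set `p4_range` (default
#' brackets the collision value by 20% on each side).
#'
#' @inheritParams run_analysis
#' @return A list with `scan`, `sotomayor` (or `NULL`) and `surfaces`;
#'   written to `scan.json` when `out_dir` is given.
#' @export
run_scan <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_model_config(config) else config
  model <- cfg$model
  k <- sum(model$p * model$a / model$b)
  p4_range <- cfg$settings$p4_range %||% (k * c(0.8, 1.2))
  scan <- crossing_scan(model, p4_range)
  soto <- NULL
  if (abs(model$p4 - k) <= 1e-9 * max(1, k)) {
    soto <- sotomayor_at_e3(model)
  }
  surfaces <- surface_residuals(model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    payload <- list(
      crossing = list(found = scan$found, p4_crossing = scan$p4_crossing,
                      k = scan$k, sides = scan$sides),
      sotomayor = if (!is.null(soto)) {
        list(cond1 = soto$cond1, cond2 = soto$cond2, cond3 = soto$cond3,
             verdict = soto$verdict)
      },
      surfaces = surfaces
    )
    jsonlite::write_json(payload, file.path(out_dir, "scan.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(scan = scan, sotomayor = soto, surfaces = surfaces)
}

#' Draw reproducible random parameter sets
#'
#' Rates are drawn log-uniformly within their ranges; control constants (if
#' a kind is given) uniformly. Draws are reproducible for a given seed.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @param n_types Immunity types per set.
#' @param rate_range Length-2 positive range for `a`, `b`, `c`, `p`.
#' @param p4_range Length-2 positive range for `p4`.
#' @param control_kind `"none"`, `"product"` or `"pairwise_sum"`.
#' @param control_range Length-2 range for the control constants.
#' @return A tibble with one row per draw, list-column `model` plus the
#'   flat parameter columns.
#' @export
sample_params <- function(n, seed = 0L, n_types = 3L,
                          rate_range = c(0.1, 10), p4_range = rate_range,
                          control_kind = "none", control_range = c(-3, 3)) {
  stopifnot(n >= 1, length(rate_range) == 2L, all(rate_range > 0),
            all(p4_range > 0))
  set.seed(seed)
  draws <- purrr::map(seq_len(n), function(k) {
    lu <- function(m, range) exp(runif(m, log(range[1]), log(range[2])))
    a <- lu(n_types, rate_range); b <- lu(n_types, rate_range)
    cc <- lu(n_types, rate_range); p <- lu(n_types, rate_range)
    p4 <- lu(1, p4_range)
    control <- switch(control_kind,
      none = control_none(),
      product = control_product(runif(1, control_range[1], control_range[2]),
                                runif(1, control_range[1], control_range[2]),
                                runif(1, control_range[1], control_range[2])),
      pairwise_sum = control_pairwise_sum(
        runif(1, control_range[1], control_range[2]),
        runif(1, control_range[1], control_range[2]),
        runif(1, control_range[1], control_range[2])),
      abort("invalid control kind")
    )
    immune_model(a, b, cc, p, p4, control = control)
  })
  tibble(
    draw = seq_len(n),
    model = draws,
    p4 = purrr::map_dbl(draws, "p4"),
    control_kind = control_kind
  )
}
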