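#' Root integral-time-squared error of blood pO2 from target
#'
#' `tITSE = sqrt( integral over the window of (t - t_onset) *
#' (pO2(t) - target)^2 dt )`, with time measured from perturbation onset
#' and trapezoidal quadrature on the trajectory grid. Its reciprocal is
#' the response speed of the circuit: a system that returns pO2 to target
#' quickly (and without late wobble, which the time weight penalizes) has
#' a small tITSE.
#'
#' @param traj An `erythro_trajectory` (or data frame with `time`, `pO2`).
#' @param target Target pO2; defaults to the trajectory's pre-onset value.
#' @param window Integration window `c(from, to)` in days; defaults to
#'   `[t_onset, end of trajectory]`.
#' @return Non-negative scalar.
#' @export
titse <- function(traj, target = NULL, window = NULL) {
  stopifnot(is.data.frame(traj), all(c("time", "pO2") %in% names(traj)))
  prof <- attr(traj, "profile")
  onset <- if (!is.null(prof)) prof$t_onset else min(traj$time)
  if (is.null(window)) window <- c(onset, max(traj$time))
  if (window[1] < min(traj$time) - 1e-9 || window[2] > max(traj$time) + 1e-9)
    stop("integration window outside the trajectory", call. = FALSE)
  i <- traj$time >= window[1] & traj$time <= window[2]
  tt <- traj$time[i] - window[1]
  if (is.null(target)) {
    pre <- traj$pO2[traj$time <= window[1]]
    target <- if (length(pre)) pre[length(pre)] else traj$pO2[1]
  }
  integrand <- tt * (traj$pO2[i] - target)^2
  sqrt(sum(diff(tt) * (utils::head(integrand, -1) +
                         utils::tail(integrand, -1)) / 2))
}

#' Over-production cost of a parameter set
#'
#' `1 / proe_survival(E*)` at the normoxic steady state: the burden of
#' producing ProE destined for apoptosis. A circuit in which all ProE
#' survive has cost 1; the documented baseline (survival 0.3) has cost
#' 10/3.
#'
#' @param params An [erythro_params()] object.
#' @export
overproduction_cost <- function(params) {
  params <- as_erythro_params(params)
  st <- steady_state(params)
  s <- proe_survival(st[["E"]], params)
  if (s <= 0) stop("degenerate parameters: zero ProE survival", call. = FALSE)
  1 / s
}

#' Performance of one parameterization under the hypoxic-onset assay
#'
#' Simulates the hypoxic response from the parameter set's own normoxic
#' steady state and returns the (cost, speed) pair used in the Pareto
#' analysis. The tITSE target is the set's own steady-state pO2 (each
#' circuit regulates around its own set point); `recovered` flags whether
#' pO2 returns within 2\% of that target by the horizon.
#'
#' @param params An [erythro_params()] object.
#' @param profile A [hypoxia_profile()].
#' @param tags Optional character note of which parameters deviate from
#'   baseline.
#' @return A one-row data frame: `cost`, `speed` (= 1/tITSE), `titse`,
#'   `recovered`, `E_star`, plus `tags`.
#' @export
performance_point <- function(params, profile = hypoxia_profile(),
                              tags = "") {
  params <- as_erythro_params(params)
  st <- steady_state(params)
  target <- params$c_O2 * st[["R"]]
  traj <- simulate_model(params, profile, init = st)
  tit <- titse(traj, target = target)
  data.frame(cost = 1 / proe_survival(st[["E"]], params),
             speed = 1 / tit, titse = tit,
             recovered = abs(traj$pO2[nrow(traj)] - target) <= 0.02 * target,
             E_star = st[["E"]], tags = tags, stringsAsFactors = FALSE)
}

#' One-at-a-time parameter scan from a baseline
#'
#' Replaces a single parameter by each grid value (all others, including
#' the baseline's oxygen-transport calibration, held fixed) and evaluates
#' the (cost, speed) performance of each variant. Deterministic.
#'
#' @param baseline An [erythro_params()] object.
#' @param name Name of the parameter to scan (a model field).
#' @param grid Numeric vector of values.
#' @param profile A [hypoxia_profile()].
#' @return Data frame with one row per grid value: `value`, `cost`,
#'   `speed`, `titse`, `recovered`, `E_star`, `tags`.
#' @export
scan_parameter <- function(baseline, name, grid,
                           profile = hypoxia_profile()) {
  baseline <- as_erythro_params(baseline)
  if (!name %in% .PARAM_FIELDS)
    stop("unknown parameter name: ", name, call. = FALSE)
  res <- lapply(grid, function(v) {
    p <- modify_one(baseline, name, v)
    cbind(value = v, performance_point(p, profile,
                                       tags = sprintf("%s=%g", name, v)))
  })
  do.call(rbind, res)
}

modify_one <- function(baseline, name, value) {
  args <- stats::setNames(list(value), name)
  do.call(modify_params, c(list(baseline), args))
}

#' Random ensemble of control-parameter sets
#'
#' Draws `n` parameter sets over physiological ranges (defaults:
#' `gmin` and `delta_g` uniform on \[0.3, 1.3\]/day, `Ka/Ks` log-uniform on
#' \[0.05, 20\] (the interval spans 2.6 decades), `na` uniform on \[1, 3\]),
#' holding all other parameters, including the oxygen-transport
#' calibration, at baseline. Each draw is scored with
#' [performance_point()]; non-recovering sets are flagged, not dropped.
#'
#' @param n Number of draws.
#' @param seed Integer seed (mandatory; the whole ensemble is reproducible
#'   from it).
#' @param baseline An [erythro_params()] object.
#' @param profile A [hypoxia_profile()].
#' @param ranges Named list of `c(lo, hi)` intervals for `gmin`, `delta_g`,
#'   `Ka_Ks`, `na`.
#' @param Ka_Ks_log Sample the `Ka/Ks` ratio log-uniformly (default) or
#'   uniformly.
#' @return An object of class `pareto_ensemble`: a data frame with the
#'   sampled parameters and their `cost`, `speed`, `recovered` columns.
#' @export
sample_ensemble <- function(n, seed, baseline = erythro_params(),
                            profile = hypoxia_profile(),
                            ranges = list(gmin = c(0.3, 1.3),
                                          delta_g = c(0.3, 1.3),
                                          Ka_Ks = c(0.05, 20),
                                          na = c(1, 3)),
                            Ka_Ks_log = TRUE) {
  stopifnot(n >= 1, is.numeric(seed), length(seed) == 1L)
  baseline <- as_erythro_params(baseline)
  for (r in ranges)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] >= r[2] || r[1] <= 0)
      stop("invalid sampling interval", call. = FALSE)
  rng <- .with_seed(as.integer(seed), {
    ratio <- if (Ka_Ks_log)
      exp(stats::runif(n, log(ranges$Ka_Ks[1]), log(ranges$Ka_Ks[2])))
    else stats::runif(n, ranges$Ka_Ks[1], ranges$Ka_Ks[2])
    data.frame(gmin = stats::runif(n, ranges$gmin[1], ranges$gmin[2]),
               delta_g = stats::runif(n, ranges$delta_g[1],
                                      ranges$delta_g[2]),
               Ka_Ks = ratio,
               na = stats::runif(n, ranges$na[1], ranges$na[2]))
  })
  perf <- lapply(seq_len(n), function(i) {
    p <- modify_params(baseline, gmin = rng$gmin[i],
                       delta_g = rng$delta_g[i],
                       Ka = rng$Ka_Ks[i] * baseline$Ks, na = rng$na[i])
    performance_point(p, profile)
  })
  out <- cbind(rng, do.call(rbind, perf))
  out$tags <- NULL
  structure(out, class = c("pareto_ensemble", "data.frame"),
            seed = as.integer(seed), baseline = baseline)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' @export
print.pareto_ensemble <- function(x, ...) {
  cat(sprintf("Control-parameter ensemble: %d draws (seed %d), %d on the Pareto front\n",
              nrow(x), attr(x, "seed"), nrow(pareto_front(x))))
  invisible(x)
}

#' @export
plot.pareto_ensemble <- function(x, ...) {
  graphics::plot(x$cost, x$speed, pch = 16, cex = 0.4,
                 col = "grey60", log = "x",
                 xlab = "over-production cost", ylab = "response speed (1/tITSE)",
                 ...)
  fr <- pareto_front(x)
  graphics::lines(fr$cost, fr$speed, col = 2, lwd = 2)
  invisible(x)
}

#' Pareto front of (cost, speed) performance points
#'
#' Returns the non-dominated subset: a point is dominated if another point
#' has no higher cost and no lower speed, with at least one strict
#' inequality. Ties are kept; the result is ordered by cost ascending.
#' The operation is idempotent.
#'
#' @param points Data frame with `cost` and `speed` columns (e.g. from
#'   [sample_ensemble()] or [scan_parameter()]).
#' @export
pareto_front <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 1,
            all(c("cost", "speed") %in% names(points)))
  ord <- order(points$cost, -points$speed)
  x <- points[ord, , drop = FALSE]
  n <- nrow(x)
  keep <- logical(n)
  best_prev <- -Inf  # max speed among strictly cheaper points
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x$cost[j + 1L] == x$cost[i]) j <- j + 1L
    grp <- i:j
    smax <- x$speed[i]  # within-group max (sorted descending)
    keep[grp] <- x$speed[grp] == smax & smax > best_prev
    best_prev <- max(best_prev, smax)
    i <- j + 1L
  }
  out <- x[keep, , drop = FALSE]
  class(out) <- "data.frame"
  out
}

#' Cytokine synergy experiment on the feedback model
#'
#' Runs four simulations from the common normoxic steady state (vehicle,
#' Epo, IL-17, Epo + IL-17) and compares the progenitor fold-change under
#' the combined treatment with the product of the single-treatment
#' fold-changes. Epo treatment is a constant exogenous Epo source over the
#' readout window (mirroring repeated injections); IL-17 acts by modulating
#' a control parameter:
#' * Model 1 (Epo-independent tuning): `gmin` is increased by the factor
#'   `1 + il17_strength`.
#' * Model 2 (Epo-sensitivity tuning): `Ka` is decreased by the factor
#'   `1 + il17_strength` (variant `"delta_g"`: `delta_g` increased).
#'
#' Under Model 1 the combined fold-change is close to multiplicative;
#' under Model 2 it is super-multiplicative (ratio > 1, growing with the
#' IL-17 strength).
#'
#' @param baseline An [erythro_params()] object.
#' @param model_id 1 or 2.
#' @param epo_dose Strength of the exogenous Epo source in units of the
#'   baseline endogenous production `delta_E * E*` (default 2, i.e., the
#'   injection adds twice the homeostatic Epo input).
#' @param il17_strength Non-negative modulation strength.
#' @param readout_time Days from treatment start to readout (default 3,
#'   mirroring a 72-h endpoint).
#' @param model2_target Which parameter Model 2 modulates: `"Ka"` or
#'   `"delta_g"`.
#' @param compartment Readout compartment: `"P"` (progenitors, primary) or
#'   `"Q"`.
#' @return An object of class `synergy_result`: list with `fc_epo`,
#'   `fc_il17`, `fc_combined`, `ratio = fc_combined/(fc_epo*fc_il17)`,
#'   `model_id`, `readout_time`.
#' @export
synergy_experiment <- function(baseline, model_id = 2, epo_dose = 2,
                               il17_strength = 0.5, readout_time = 3,
                               model2_target = c("Ka", "delta_g"),
                               compartment = c("P", "Q")) {
  baseline <- as_erythro_params(baseline)
  model2_target <- match.arg(model2_target)
  compartment <- match.arg(compartment)
  stopifnot(il17_strength >= 0, epo_dose >= 0, readout_time > 0,
            model_id %in% c(1, 2))
  st <- steady_state(baseline)
  D <- epo_dose * baseline$delta_E * st[["E"]]
  p_il17 <- if (il17_strength == 0) baseline
  else if (model_id == 1)
    modify_params(baseline, gmin = baseline$gmin * (1 + il17_strength))
  else if (model2_target == "Ka")
    modify_params(baseline, Ka = baseline$Ka / (1 + il17_strength))
  else
    modify_params(baseline, delta_g = baseline$delta_g * (1 + il17_strength))
  readout <- function(p, src) {
    traj <- simulate_model(p, times = seq(0, readout_time, by = 0.05),
                           epo_source = src, init = st)
    traj[[compartment]][nrow(traj)]
  }
  vehicle <- readout(baseline, 0)
  if (vehicle <= 0) stop("degenerate vehicle readout", call. = FALSE)
  fc_epo <- readout(baseline, D) / vehicle
  fc_il17 <- readout(p_il17, 0) / vehicle
  fc_combined <- readout(p_il17, D) / vehicle
  structure(list(fc_epo = fc_epo, fc_il17 = fc_il17,
                 fc_combined = fc_combined,
                 ratio = fc_combined / (fc_epo * fc_il17),
                 model_id = model_id, readout_time = readout_time,
                 il17_strength = il17_strength, epo_dose = epo_dose),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "Model %d synergy at %g d: Epo %.3f x, IL-17 %.3f x, combined %.3f x\n",
    x$model_id, x$readout_time, x$fc_epo, x$fc_il17, x$fc_combined))
  cat(sprintf("  combined / (Epo x IL-17) = %.4f (%s)\n", x$ratio,
              if (x$ratio > 1.05) "super-multiplicative"
              else if (x$ratio < 0.95) "sub-multiplicative"
              else "~multiplicative"))
  invisible(x)
}

#' Survival-saturated ("all ProE survive") model variant
#'
#' The configuration where Epo exclusively regulates proliferation:
#' `Ka/Ks >> 1`, so ProE survival is ~1 at the operating Epo level and the
#' over-production cost is ~1. The variant keeps the baseline's `Ka`,
#' `gmin` and `delta_g` and is calibrated at its own normoxic set point
#' (pO2* = target, E* = 1), since it represents a distinct organism
#' configuration rather than a perturbation of the baseline.
#'
#' @param baseline An [erythro_params()] object.
#' @param survival_star Steady-state survival of the variant (default
#'   0.999).
#' @export
all_survive_params <- function(baseline = erythro_params(),
                               survival_star = 0.999) {
  baseline <- as_erythro_params(baseline)
  erythro_params(gmin = baseline$gmin, delta_g = baseline$delta_g,
                 na = baseline$na, ns = baseline$ns, k_P = baseline$k_P,
                 k_Q = baseline$k_Q, delta_R = baseline$delta_R,
                 delta_E = baseline$delta_E, K_E = baseline$K_E,
                 m_E = baseline$m_E, influx_F = baseline$influx_F,
                 pO2_target = baseline$pO2_target,
                 survival_star = survival_star, Ka = baseline$Ka)
}

#' ProE-apoptosis requirement check
#'
#' Compares the hypoxic response speed of the survival-saturated variant
#' (cost ~ 1, Epo acts on proliferation only) against the baseline-style
#' configuration in which Epo regulates both proliferation and survival
#' (`Ka/Ks = 2`), across a grid of `gmin` values. The model recapitulates
#' the requirement for ProE over-production: the saturated variant is
#' slower than the survival-regulated circuit.
#'
#' @param baseline An [erythro_params()] object (the `Ka/Ks = 2`
#'   configuration).
#' @param profile A [hypoxia_profile()].
#' @param gmin_grid Values of `gmin` for the survival-regulated curve.
#' @return List with `star` (performance of the saturated variant) and
#'   `curve` (scan of the survival-regulated configuration over `gmin`),
#'   plus `satisfied`: whether the saturated variant is slower than the
#'   curve for at least one `gmin`.
#' @export
apoptosis_requirement_check <- function(baseline = erythro_params(),
                                        profile = hypoxia_profile(),
                                        gmin_grid = seq(0.3, 1.3, by = 0.2)) {
  baseline <- as_erythro_params(baseline)
  star <- performance_point(all_survive_params(baseline), profile,
                            tags = "Ka/Ks>>1")
  curve <- scan_parameter(baseline, "gmin", gmin_grid, profile)
  list(star = star, curve = curve,
       satisfied = any(curve$speed > star$speed))
}
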