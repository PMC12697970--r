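#' Time derivatives of the feedback circuit
#'
#' The canonical four-variable form:
#' \deqn{dP/dt = F + (g(E) - k_P) P}
#' \deqn{dQ/dt = k_P P - k_Q Q}
#' \deqn{dR/dt = k_Q s(E) Q - \delta_R R}
#' \deqn{dE/dt = \beta_E (1 - hill(pO_2, K_E, m_E)) + D - \delta_E E}
#' with `g(E)` the Epo-dependent proliferation rate, `s(E)` the ProE
#' survival fraction, `pO2 = c_O2 * alpha(t) * R`, and `D` an optional
#' constant exogenous Epo source (an injected-Epo treatment).
#'
#' @param state Named numeric `c(P, Q, R, E)`, all non-negative.
#' @param t Time, days.
#' @param params An [erythro_params()] object.
#' @param profile A [hypoxia_profile()]; `NULL` means normoxia.
#' @param epo_source Constant exogenous Epo input (Epo units/day).
#' @return Named numeric vector of `dP, dQ, dR, dE`.
#' @export
derivatives <- function(state, t = 0, params, profile = NULL, epo_source = 0) {
  params <- as_erythro_params(params)
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  if (any(state < 0)) stop("state components must be >= 0", call. = FALSE)
  P <- state[["P"]]; Q <- state[["Q"]]; R <- state[["R"]]; E <- state[["E"]]
  a <- if (is.null(profile)) 1 else alpha_at(t, profile)
  g <- proliferation_rate(E, params)
  s <- proe_survival(E, params)
  pO2 <- params$c_O2 * a * R
  c(dP = params$influx_F + (g - params$k_P) * P,
    dQ = params$k_P * P - params$k_Q * Q,
    dR = params$k_Q * s * Q - params$delta_R * R,
    dE = params$beta_E * (1 - hill(pO2, params$K_E, params$m_E)) +
      epo_source - params$delta_E * E)
}

#' Normoxic steady state of the feedback circuit
#'
#' Under constant `alpha = 1` the fixed point reduces to a scalar root
#' problem in Epo: given `E`, the compartments follow explicitly
#' (`P* = F/(k_P - g(E))`, `Q* = k_P P*/k_Q`, `R* = k_Q s(E) Q*/delta_R`),
#' and the Epo balance `beta_E (1 - hill(c_O2 R*, K_E, m_E)) = delta_E E`
#' is monotone decreasing in `E`, so the root is unique and bracketed.
#' `method = "integrate"` instead relaxes the ODE for a long time from a
#' rough initial guess; it is provided as an independent cross-check.
#'
#' @param params An [erythro_params()] object.
#' @param method `"root"` (default) or `"integrate"`.
#' @param tol Relative tolerance on the steady-state residual.
#' @return Named numeric `c(P, Q, R, E)` with all derivatives below `tol`
#'   (relative to compartment scale).
#' @export
steady_state <- function(params, method = c("root", "integrate"),
                         tol = 1e-8) {
  params <- as_erythro_params(params)
  method <- match.arg(method)
  st <- if (method == "root") .ss_root(params) else .ss_integrate(params)
  d <- derivatives(st, 0, params)
  scale <- pmax(abs(st), 1e-12)
  if (max(abs(d) / scale) > 100 * tol)
    stop(sprintf("steady state did not converge (max relative residual %.3g)",
                 max(abs(d) / scale)), call. = FALSE)
  st
}

.R_star_of_E <- function(E, p) {
  g <- p$gmin + p$delta_g * hill(E, p$Ka, p$na)
  if (g >= p$k_P) return(Inf)
  p$k_P * hill(E, p$Ks, p$ns) * p$influx_F / ((p$k_P - g) * p$delta_R)
}

.ss_root <- function(p) {
  f <- function(E)
    p$beta_E * (1 - hill(p$c_O2 * .R_star_of_E(E, p), p$K_E, p$m_E)) -
      p$delta_E * E
  E_up <- p$beta_E / p$delta_E
  if (p$gmin + p$delta_g > p$k_P) {
    # cap the bracket below the Epo level where proliferation would
    # outrun maturation (P* diverges there)
    h <- (p$k_P - p$gmin) / p$delta_g
    E_up <- min(E_up, p$Ka * (h / (1 - h))^(1 / p$na) * (1 - 1e-12))
  }
  E <- stats::uniroot(f, c(1e-12, E_up), tol = 1e-14)$root
  g <- p$gmin + p$delta_g * hill(E, p$Ka, p$na)
  P <- p$influx_F / (p$k_P - g)
  Q <- p$k_P * P / p$k_Q
  R <- p$k_Q * hill(E, p$Ks, p$ns) * Q / p$delta_R
  c(P = P, Q = Q, R = R, E = E)
}

.ss_integrate <- function(p, t_end = 4000) {
  y0 <- c(P = p$influx_F / p$k_P, Q = p$influx_F / p$k_Q,
          R = p$pO2_target / p$c_O2, E = 1)
  out <- .integrate(p, y0, times = c(0, t_end / 2, t_end),
                    profile = NULL, epo_source = 0)
  st <- as.numeric(out[nrow(out), c("P", "Q", "R", "E")])
  names(st) <- c("P", "Q", "R", "E")
  st
}

.parms_vector <- function(p, profile = NULL, epo_source = 0) {
  if (is.null(profile)) {
    prof <- c(t_onset = Inf, ramp_tau = 0, alpha_min = 1, ramp_shape = 0)
    prof["t_onset"] <- 1e30
  } else {
    prof <- c(t_onset = profile$t_onset, ramp_tau = profile$ramp_tau,
              alpha_min = profile$alpha_min,
              ramp_shape = as.numeric(profile$shape == "cosine"))
  }
  c(p$influx_F, p$gmin, p$delta_g, p$Ka, p$na, p$Ks, p$ns, p$k_P, p$k_Q,
    p$delta_R, p$beta_E, p$delta_E, p$K_E, p$m_E, p$c_O2,
    unname(prof), epo_source)
}

.integrate <- function(p, y0, times, profile, epo_source,
                       rtol = 1e-8, atol = 1e-10) {
  deSolve::ode(y = y0, times = times, func = "erythro_derivs",
               parms = .parms_vector(p, profile, epo_source),
               dllname = "erythrotune", initfunc = "erythro_init",
               rtol = rtol, atol = atol, method = "lsoda")
}

#' Simulate the feedback circuit
#'
#' Integrates the model with a stiff-capable adaptive integrator (lsoda)
#' from the normoxic steady state (unless `init` overrides it), under an
#' optional hypoxic-onset profile and optional constant exogenous Epo
#' source. Output is returned on a fixed grid for metric quadrature.
#'
#' @param params An [erythro_params()] object.
#' @param profile A [hypoxia_profile()] or `NULL` for constant normoxia.
#' @param times Output time grid, days; default `seq(0, horizon, by = 0.05)`.
#' @param epo_source Constant exogenous Epo input (Epo units/day).
#' @param init Optional initial state `c(P, Q, R, E)`.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `erythro_trajectory`: a data frame with
#'   columns `time, P, Q, R, E, alpha, pO2`, carrying the parameters and
#'   profile as attributes. Blood pO2 satisfies
#'   `pO2 = c_O2 * alpha * R` on every row.
#' @examples
#' p <- erythro_params()
#' traj <- simulate_model(p, hypoxia_profile(horizon = 30))
#' range(traj$pO2)
#' @export
simulate_model <- function(params, profile = NULL, times = NULL,
                           epo_source = 0, init = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  params <- as_erythro_params(params)
  horizon <- if (is.null(profile)) 60 else profile$horizon
  if (is.null(times)) times <- seq(0, horizon, by = 0.05)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.null(profile) && (min(times) < 0 || max(times) > profile$horizon))
    stop("'times' must lie within [0, horizon]", call. = FALSE)
  y0 <- if (is.null(init)) steady_state(params) else {
    stopifnot(length(init) == 4L, all(init >= 0))
    stats::setNames(as.numeric(init), c("P", "Q", "R", "E"))
  }
  out <- .integrate(params, y0, times, profile, epo_source, rtol, atol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure; see deSolve diagnostics", call. = FALSE)
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  low <- min(df$P, df$Q, df$R, df$E)
  if (low < -1e-6)
    stop(sprintf("negative state excursion beyond tolerance (%.3g)", low),
         call. = FALSE)
  if (low < 0) {
    warning("clipping tiny negative state excursions to zero")
    for (v in c("P", "Q", "R", "E")) df[[v]] <- pmax(df[[v]], 0)
  }
  df$alpha <- if (is.null(profile)) rep(1, nrow(df)) else
    alpha_at(df$time, profile)
  df$pO2 <- params$c_O2 * df$alpha * df$R
  structure(df, class = c("erythro_trajectory", "data.frame"),
            params = params, profile = profile, epo_source = epo_source)
}

#' @export
print.erythro_trajectory <- function(x, ...) {
  cat(sprintf(
    "Erythroid feedback trajectory: %d time points over [%.3g, %.3g] d\n",
    nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  pO2 range [%.4g, %.4g]; final E %.4g\n",
              min(x$pO2), max(x$pO2), x$E[nrow(x)]))
  invisible(x)
}

#' @export
plot.erythro_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$time, cbind(x$P, x$Q, x$R / max(x$R) * max(x$Q)),
                    type = "l", lty = 1, xlab = "time (d)",
                    ylab = "pool size (R rescaled)", ...)
  graphics::legend("topright", c("P", "Q", "R (scaled)"), col = 1:3, lty = 1,
                   bty = "n")
  graphics::plot(x$time, x$pO2, type = "l", xlab = "time (d)", ylab = "pO2")
  graphics::abline(h = attr(x, "params")$pO2_target, lty = 2)
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj An `erythro_trajectory`.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "erythro_trajectory"))
  utils::write.csv(as.data.frame(traj)[, c("time", "P", "Q", "R", "E",
                                           "alpha", "pO2")],
                   path, row.names = FALSE)
  invisible(path)
}
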