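#' Parameter set of the erythropoietic feedback circuit
#'
#' Constructs (and validates) the full parameter set of the four-compartment
#' feedback model: progenitors `P`, ProE/precursors `Q`, red blood cells `R`
#' and Epo `E`. Epo increases progenitor proliferation (half-max `Ka`,
#' coefficient `na`) and ProE survival (half-max `Ks`, coefficient `ns`);
#' circulating RBCs carry oxygen so that blood pO2 is proportional to
#' `alpha * R`, and pO2 represses Epo production through a steep Hill sensor
#' (`K_E`, `m_E`).
#'
#' The default set realizes the documented baseline: `gmin = 0.3`/day,
#' `delta_g = 0.9`/day, `Ka/Ks = 2`, RBC turnover `delta_R = 1/40`/day
#' (murine RBC lifespan), and a normoxic steady state with blood pO2 at its
#' target (normalized to 1), Epo at `E_star = 1` and ProE survival
#' `survival_star = 0.3` (i.e., substantial constitutive over-production).
#' Unless `beta_E` and `c_O2` are supplied explicitly they are calibrated
#' analytically so that this steady state holds exactly:
#' `Ks = E_star * ((1 - survival_star)/survival_star)^(1/ns)`,
#' `beta_E = delta_E * E_star / (1 - hill(1, K_E, m_E))`, and
#' `c_O2 = pO2_target / R_star`.
#'
#' @param gmin Epo-independent net proliferation rate, per day.
#' @param delta_g Maximal Epo-dependent proliferation increment, per day.
#' @param Ka_Ks Ratio of the proliferation to the survival Epo half-max;
#'   used to derive `Ka` when `Ka` is not given.
#' @param na Hill coefficient of Epo-dependent proliferation.
#' @param ns Hill coefficient of Epo-dependent ProE survival.
#' @param k_P Progenitor-to-ProE maturation rate, per day. Must exceed the
#'   Epo-independent floor `gmin` for a steady state to exist.
#' @param k_Q ProE transit rate, per day.
#' @param delta_R RBC turnover rate, per day.
#' @param delta_E Epo clearance rate, per day.
#' @param K_E pO2 half-repression constant of Epo production.
#' @param m_E Hill coefficient of the pO2 sensor. The default is steep,
#'   reflecting the orders-of-magnitude physiological Epo range compressed
#'   into a narrow pO2 band.
#' @param influx_F Cell influx from upstream multipotent progenitors,
#'   cells per day (boundary condition).
#' @param pO2_target Set-point blood pO2 (normalized to 1).
#' @param E_star Normoxic steady-state Epo level used for calibration.
#' @param survival_star Normoxic steady-state ProE survival used to derive
#'   `Ks` (ignored when `Ks` is supplied).
#' @param Ka,Ks,beta_E,c_O2 Optional explicit values overriding the
#'   derived/calibrated ones.
#' @return An object of class `erythro_params`: a named list with fields
#'   `influx_F, gmin, delta_g, Ka, na, Ks, ns, k_P, k_Q, delta_R, beta_E,
#'   delta_E, K_E, m_E, c_O2, pO2_target`.
#' @seealso [steady_state()], [simulate_model()], [hypoxia_profile()]
#' @examples
#' p <- erythro_params()
#' steady_state(p)
#' @export
erythro_params <- function(gmin = 0.3, delta_g = 0.9, Ka_Ks = 2, na = 2,
                           ns = 1, k_P = 1.35, k_Q = 1, delta_R = 1 / 40,
                           delta_E = 10, K_E = 0.9, m_E = 40, influx_F = 1,
                           pO2_target = 1, E_star = 1, survival_star = 0.3,
                           Ka = NULL, Ks = NULL, beta_E = NULL, c_O2 = NULL) {
  if (is.null(Ks)) {
    stopifnot(survival_star > 0, survival_star < 1)
    Ks <- E_star * ((1 - survival_star) / survival_star)^(1 / ns)
  }
  if (is.null(Ka)) Ka <- Ka_Ks * Ks
  if (is.null(beta_E))
    beta_E <- delta_E * E_star / (1 - hill(pO2_target, K_E, m_E))
  p <- list(influx_F = influx_F, gmin = gmin, delta_g = delta_g, Ka = Ka,
            na = na, Ks = Ks, ns = ns, k_P = k_P, k_Q = k_Q,
            delta_R = delta_R, beta_E = beta_E, delta_E = delta_E,
            K_E = K_E, m_E = m_E, c_O2 = NA_real_, pO2_target = pO2_target)
  if (is.null(c_O2)) {
    # R* at the calibration point E = E_star, then c_O2 pins pO2* there
    g_star <- gmin + delta_g * hill(E_star, Ka, na)
    if (g_star >= k_P)
      stop("k_P must exceed the steady-state proliferation rate", call. = FALSE)
    P_star <- influx_F / (k_P - g_star)
    R_star <- k_P * hill(E_star, Ks, ns) * P_star / delta_R
    c_O2 <- pO2_target / R_star
  }
  p$c_O2 <- c_O2
  validate_erythro_params(p)
  structure(p, class = "erythro_params")
}

.PARAM_FIELDS <- c("influx_F", "gmin", "delta_g", "Ka", "na", "Ks", "ns",
                   "k_P", "k_Q", "delta_R", "beta_E", "delta_E", "K_E",
                   "m_E", "c_O2", "pO2_target")

validate_erythro_params <- function(p) {
  miss <- setdiff(.PARAM_FIELDS, names(p))
  if (length(miss))
    stop("missing parameter field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in .PARAM_FIELDS) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (p$k_P <= p$gmin)
    stop("k_P must exceed gmin (no steady state otherwise)", call. = FALSE)
  invisible(p)
}

as_erythro_params <- function(p) {
  if (inherits(p, "erythro_params")) return(p)
  if (is.list(p) && all(.PARAM_FIELDS %in% names(p))) {
    p <- p[.PARAM_FIELDS]
    validate_erythro_params(p)
    return(structure(p, class = "erythro_params"))
  }
  stop("not an erythro_params object", call. = FALSE)
}

#' Replace fields of a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#' No recalibration is performed: `beta_E` and `c_O2` are kept as-is, so a
#' modified set inherits its baseline's oxygen-transport calibration (this
#' is what parameter scans and ensemble sampling require; the steady-state
#' Epo level then floats with the modified parameters).
#'
#' @param params An [erythro_params()] object.
#' @param ... Named fields to replace, e.g. `gmin = 0.5`.
#' @export
modify_params <- function(params, ...) {
  params <- as_erythro_params(params)
  repl <- list(...)
  bad <- setdiff(names(repl), .PARAM_FIELDS)
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  validate_erythro_params(params)
  structure(params, class = "erythro_params")
}

#' @export
print.erythro_params <- function(x, ...) {
  cat("Erythropoietic feedback circuit parameters\n")
  v <- unlist(x[.PARAM_FIELDS])
  print(signif(v, 5))
  invisible(x)
}

#' @export
as.list.erythro_params <- function(x, ...) unclass(x)

#' Read / write a parameter file
#'
#' Flat JSON or YAML with exactly the model's field names. Unknown keys are
#' rejected; missing keys are an error.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return An `erythro_params` object.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              json = jsonlite::read_json(path, simplifyVector = TRUE),
              yaml = , yml = yaml::read_yaml(path),
              stop("unsupported parameter file extension: ", ext,
                   call. = FALSE))
  extra <- setdiff(names(x), .PARAM_FIELDS)
  if (length(extra))
    stop("unknown key(s) in parameter file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  as_erythro_params(as.list(x))
}

#' @rdname read_params
#' @param params Parameter object to write.
#' @export
write_params <- function(params, path) {
  params <- as_erythro_params(params)
  ext <- tolower(tools::file_ext(path))
  x <- lapply(unclass(params), unname)
  switch(ext,
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
         yaml = , yml = yaml::write_yaml(x, path, precision = 15),
         stop("unsupported parameter file extension: ", ext, call. = FALSE))
  invisible(path)
}

#' Hypoxic-onset perturbation profile
#'
#' Describes the drop of oxygen absorbance through the lung, `alpha(t)`:
#' 1 before `t_onset`, a monotone ramp of duration `ramp_tau` down to
#' `alpha_min`, then constant. The default ramp is linear; `shape =
#' "cosine"` gives a smooth sigmoid-shaped alternative with the same
#' endpoints.
#'
#' @param t_onset Time of hypoxia onset, days.
#' @param ramp_tau Ramp duration, days (0 gives a step).
#' @param alpha_min Minimal absorbance fraction, in (0, 1].
#' @param horizon Total simulated time, days.
#' @param shape `"linear"` or `"cosine"`.
#' @return An object of class `hypoxia_profile`.
#' @examples
#' prof <- hypoxia_profile()
#' alpha_at(c(0, 5, 6, 7, 60), prof)
#' @export
hypoxia_profile <- function(t_onset = 5, ramp_tau = 2, alpha_min = 0.6,
                            horizon = 60, shape = c("linear", "cosine")) {
  shape <- match.arg(shape)
  if (!is.numeric(alpha_min) || length(alpha_min) != 1L ||
      alpha_min <= 0 || alpha_min > 1)
    stop("'alpha_min' must be in (0, 1]", call. = FALSE)
  stopifnot(t_onset >= 0, ramp_tau >= 0, horizon > t_onset)
  structure(list(t_onset = t_onset, ramp_tau = ramp_tau,
                 alpha_min = alpha_min, horizon = horizon, shape = shape),
            class = "hypoxia_profile")
}

#' Constant-normoxia profile (no perturbation)
#' @param horizon Total simulated time, days.
#' @export
normoxia_profile <- function(horizon = 60)
  hypoxia_profile(t_onset = horizon, ramp_tau = 0, alpha_min = 1,
                  horizon = horizon)

#' Lung absorbance at time t
#'
#' @param t Time(s), days, non-negative.
#' @param profile A [hypoxia_profile()].
#' @return `alpha(t)` fraction(s).
#' @export
alpha_at <- function(t, profile) {
  stopifnot(inherits(profile, "hypoxia_profile"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  t0 <- profile$t_onset; tau <- profile$ramp_tau
  frac <- pmin(pmax((t - t0) / max(tau, .Machine$double.eps), 0), 1)
  frac[t < t0] <- 0
  if (profile$shape == "cosine") frac <- 0.5 * (1 - cos(pi * frac))
  1 - (1 - profile$alpha_min) * frac
}

#' @export
print.hypoxia_profile <- function(x, ...) {
  cat(sprintf(
    "Hypoxic-onset profile: alpha 1 -> %.3g (%s ramp, t = %.3g-%.3g d), horizon %.3g d\n",
    x$alpha_min, x$shape, x$t_onset, x$t_onset + x$ramp_tau, x$horizon))
  invisible(x)
}
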