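#' One-compartment IV-infusion pharmacokinetics
#'
#' Analytic single-compartment model with linear (first-order) elimination
#' for a constant-rate intravenous infusion.  With infusion rate
#' R0 = Dose/T_inf, central volume V = Vc_per_kg x body weight and
#' elimination rate constant k = CL/V, the plasma concentration is
#' \deqn{C(t) = \frac{F R_0}{CL}\,(1 - e^{-kt}), \quad t \le T_{inf}}
#' \deqn{C(t) = C(T_{inf})\,e^{-k (t - T_{inf})}, \quad t > T_{inf}}
#' so the peak is reached exactly at the end of infusion and the total
#' exposure has the closed form AUC(0-inf) = F x Dose / CL, independent of
#' the distribution volume.  Units are mg, L and h throughout;
#' concentrations are reported in ug/mL (numerically equal to mg/L).
#'
#' @name pk_infusion
NULL

#' Pharmacokinetic parameter set
#'
#' @param dose_mg Administered dose, mg.
#' @param infusion_h Infusion duration, h.
#' @param clearance_L_h Plasma clearance, L/h.
#' @param vc_L_kg Central distribution volume per kg body weight, L/kg.
#' @param body_weight_kg Body weight, kg (default 70).
#' @param f Bioavailable fraction in (0, 1] (1 for a fully available IV
#'   dose).
#' @param sim_duration_h Simulated window, h (default 24); must be at least
#'   the infusion duration.
#' @return Validated object of class `pk_params`.
#' @examples
#' pk_params(dose_mg = 1250, infusion_h = 1, clearance_L_h = 168,
#'           vc_L_kg = 1.45)
#' @export
pk_params <- function(dose_mg, infusion_h, clearance_L_h, vc_L_kg,
                      body_weight_kg = 70, f = 1, sim_duration_h = 24) {
  vals <- c(dose_mg = dose_mg, infusion_h = infusion_h,
            clearance_L_h = clearance_L_h, vc_L_kg = vc_L_kg,
            body_weight_kg = body_weight_kg, sim_duration_h = sim_duration_h)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) {
    abort(sprintf("Parameter(s) must be strictly positive: %s.",
                  paste(bad, collapse = ", ")))
  }
  if (f <= 0 || f > 1) abort("`f` must be in (0, 1].")
  if (infusion_h > sim_duration_h) {
    abort("`infusion_h` must not exceed `sim_duration_h`.")
  }
  structure(list(
    dose_mg = dose_mg, infusion_h = infusion_h,
    clearance_L_h = clearance_L_h, vc_L_kg = vc_L_kg,
    body_weight_kg = body_weight_kg, f = f,
    sim_duration_h = sim_duration_h
  ), class = "pk_params")
}

pk_rates <- function(p) {
  v <- p$vc_L_kg * p$body_weight_kg            # L
  list(v = v,
       k = p$clearance_L_h / v,                # 1/h
       r0 = p$dose_mg / p$infusion_h)          # mg/h
}

pk_conc_at <- function(p, times) {
  r <- pk_rates(p)
  css <- p$f * r$r0 / p$clearance_L_h          # mg/L == ug/mL
  c_end <- css * (1 - exp(-r$k * p$infusion_h))
  ifelse(times <= p$infusion_h,
         css * (1 - exp(-r$k * times)),
         c_end * exp(-r$k * (times - p$infusion_h)))
}

#' Simulate an infusion concentration-time profile
#'
#' Evaluates the closed-form concentration on a uniform grid over the
#' simulation window, with the infusion end time included exactly (the peak
#' of a one-compartment infusion profile).
#'
#' @param params A [pk_params()] object.
#' @param n_points Number of uniform grid points (default 1441: 1-minute
#'   resolution over 24 h).
#' @return Object of class `pk_profile`: a tibble with `time_h` and
#'   `conc_ug_ml`, carrying the parameters and summary metrics (`cmax`,
#'   `tmax`, `auc_0_t`, `auc_0_inf`) as attributes; see
#'   [glance.pk_profile()].
#' @examples
#' gem <- pk_params(1250, 1, 168, 1.45, f = 0.99949)
#' prof <- simulate_infusion(gem)
#' glance(prof)
#' @export
simulate_infusion <- function(params, n_points = 1441) {
  stopifnot(inherits(params, "pk_params"))
  if (n_points < 2) abort("`n_points` must be at least 2.")
  times <- sort(unique(c(
    seq(0, params$sim_duration_h, length.out = n_points),
    params$infusion_h
  )))
  conc <- pk_conc_at(params, times)
  out <- tibble(time_h = times, conc_ug_ml = conc)
  attr(out, "params") <- params
  attr(out, "cmax") <- pk_cmax(params)
  attr(out, "tmax") <- params$infusion_h
  attr(out, "auc_0_inf") <- pk_auc_inf(params)
  attr(out, "auc_0_t") <- trapz_auc(times, conc)
  class(out) <- c("pk_profile", class(out))
  out
}

trapz_auc <- function(times, conc) {
  if (is.unsorted(times, strictly = FALSE)) {
    abort("Time grid must be sorted increasingly.")
  }
  sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Exposure extrapolated to infinity
#'
#' Closed form AUC(0-inf) = F x Dose / CL, in ug.h/mL; independent of the
#' distribution volume, body weight and infusion duration.
#'
#' @param params A [pk_params()] object.
#' @return Scalar AUC in ug.h/mL.
#' @examples
#' pk_auc_inf(pk_params(1250, 1, 168, 1.45, f = 0.99949))  # 7.4367
#' @export
pk_auc_inf <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  params$f * params$dose_mg / params$clearance_L_h
}

#' Exposure over the simulated window (trapezoidal)
#'
#' @param profile A [simulate_infusion()] profile.
#' @return Trapezoidal AUC over the profile grid, ug.h/mL.
#' @export
pk_auc_t <- function(profile) {
  stopifnot(inherits(profile, "pk_profile"))
  trapz_auc(profile$time_h, profile$conc_ug_ml)
}

#' Peak plasma concentration
#'
#' For the one-compartment infusion model the peak falls exactly at the end
#' of infusion: Cmax = (F R0 / CL)(1 - exp(-k T_inf)).
#'
#' @param x A [pk_params()] object (closed form) or a `pk_profile` (grid
#'   maximum).
#' @return Scalar Cmax, ug/mL.
#' @export
pk_cmax <- function(x) {
  if (inherits(x, "pk_profile")) return(max(x$conc_ug_ml))
  stopifnot(inherits(x, "pk_params"))
  r <- pk_rates(x)
  (x$f * r$r0 / x$clearance_L_h) * (1 - exp(-r$k * x$infusion_h))
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params: dose %g mg over %g h, CL %g L/h, Vc %g L/kg x %g kg, F %g>\n",
    x$dose_mg, x$infusion_h, x$clearance_L_h, x$vc_L_kg, x$body_weight_kg, x$f
  ))
  invisible(x)
}

#' One-row summary of a simulated profile
#'
#' @param x A `pk_profile`.
#' @param ... Unused.
#' @return Tibble with `cmax`, `tmax`, `auc_0_t`, `auc_0_inf`, `n_points`.
#' @exportS3Method generics::glance
glance.pk_profile <- function(x, ...) {
  tibble(
    cmax = attr(x, "cmax"), tmax = attr(x, "tmax"),
    auc_0_t = attr(x, "auc_0_t"), auc_0_inf = attr(x, "auc_0_inf"),
    n_points = nrow(x)
  )
}

#' @describeIn pk_infusion Concentration-time curve plot.
#' @param object A `pk_profile`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pk_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time_h, .data$conc_ug_ml)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "plasma concentration (µg/mL)",
                  title = "IV-infusion concentration-time profile")
}

#' Read pharmacokinetic parameters from YAML or JSON
#'
#' The file mirrors the [pk_params()] field names (`dose_mg`, `infusion_h`,
#' `clearance_L_h`, `vc_L_kg`, `body_weight_kg`, `f`, `sim_duration_h`);
#' missing optional fields take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pk_params` object.
#' @export
read_pk_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML parameter files requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pk_params, vals[intersect(names(vals), names(formals(pk_params)))])
}
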