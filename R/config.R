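#' Varied input parameters of the circulation model
#'
#' Constructs the ten-dimensional input vector varied in the sensitivity
#' study: the right-atrial and left-ventricular elastance amplitude/baseline
#' pairs (mmHg/mL), the five hydraulic resistances of the hepatic and
#' systemic branches (mmHg s/mL), and the resected liver-mass fraction
#' \code{hpx} (dimensionless, in \code{[0, 1)}).
#'
#' @param Ea_RA,Eb_RA right-atrial elastance amplitude and baseline (mmHg/mL)
#' @param Ea_LV,Eb_LV left-ventricular elastance amplitude and baseline
#'   (mmHg/mL)
#' @param R_pv,R_ha,R_hv whole-liver portal, hepatic-arterial and
#'   hepatic-venous resistances (mmHg s/mL); lobar values are derived from
#'   the configured lobe mass split
#' @param R_DO,R_OO digestive-organ and other-organ resistances (mmHg s/mL)
#' @param hpx fraction of total liver mass to be resected
#' @return a named numeric vector of class \code{parameter_vector}
#' @export
parameter_vector <- function(Ea_RA, Eb_RA, Ea_LV, Eb_LV,
                             R_pv, R_ha, R_hv, R_DO, R_OO, hpx = 0) {
  x <- c(Ea_RA = Ea_RA, Eb_RA = Eb_RA, Ea_LV = Ea_LV, Eb_LV = Eb_LV,
         R_pv = R_pv, R_ha = R_ha, R_hv = R_hv, R_DO = R_DO, R_OO = R_OO,
         hpx = hpx)
  validate_parameter_vector(x)
  structure(x, class = "parameter_vector")
}

#' @rdname parameter_vector
#' @param x a named numeric vector with the ten input names
#' @export
as_parameter_vector <- function(x) {
  x <- unlist(x)[input_names()]
  if (anyNA(x)) stop("missing input parameter(s): need ",
                     paste(input_names(), collapse = ", "))
  validate_parameter_vector(x)
  structure(x, class = "parameter_vector")
}

#' Names of the ten varied inputs, in canonical order
#' @export
input_names <- function() {
  c("Ea_RA", "Eb_RA", "Ea_LV", "Eb_LV",
    "R_pv", "R_ha", "R_hv", "R_DO", "R_OO", "hpx")
}

#' Names of the six cycle-averaged clinical outputs
#' @export
output_names <- function() c("P_pv", "PCG", "MAP", "CO", "Q_ha", "Q_pv")

validate_parameter_vector <- function(x) {
  pos <- setdiff(input_names(), "hpx")
  if (any(!is.finite(x)) )
    stop("non-finite input parameter")
  if (any(x[pos] <= 0))
    stop("elastances and resistances must be strictly positive")
  if (x["hpx"] < 0 || x["hpx"] >= 1)
    stop("hpx must satisfy 0 <= hpx < 1")
  invisible(x)
}

#' Fixed model configuration
#'
#' All non-varied constants of the closed-loop model: heart timing,
#' fixed-chamber elastances (right ventricle, left atrium), compartment
#' compliances and unstressed volumes, total blood volume, the right/left
#' liver mass split, valve regularization, integrator step, and the
#' periodicity stopping rule.
#'
#' Defaults are chosen to place the model at a typical resting adult
#' operating point (heart rate 70 bpm, total volume 5000 mL, arterial
#' compliance 1.6 mL/mmHg, large venous reservoir); the lobe split
#' defaults to 0.6/0.4 (right/left), matching typical liver anatomy.
#'
#' @param heart_period_s cardiac period (s)
#' @param lobe_split right/left liver mass fractions, summing to 1
#' @param total_volume_mL total blood volume (mL)
#' @param periodicity_tol relative cycle-to-cycle change below which the
#'   run is accepted as periodic
#' @param max_cycles maximum number of simulated cardiac cycles
#' @param dt_s integrator step (s)
#' @param ... overrides for any other configuration constant
#' @return a list of class \code{circulation_config}
#' @export
default_config <- function(heart_period_s = 60 / 70,
                           lobe_split = c(right = 0.6, left = 0.4),
                           total_volume_mL = 5000,
                           periodicity_tol = 1e-3,
                           max_cycles = 80,
                           dt_s = 2e-4, ...) {
  cfg <- list(
    heart_period_s = heart_period_s,
    t_vent_dur_s = 0.36,          # ventricular activation window
    t_atr_on_s = heart_period_s - 0.20,
    t_atr_dur_s = 0.18,           # atrial kick just before systole
    Ea_RV = 1.4, Eb_RV = 0.028,   # fixed right-ventricular elastance
    Ea_LA = 0.07, Eb_LA = 0.09,   # fixed left-atrial elastance
    R_tri = 0.005, R_pul = 0.005, R_mit = 0.005, R_aor = 0.005,
    R_pulm = 0.06, R_vr = 0.022,
    C_pa = 6, C_sa = 1.6, C_pv = 12, C_liv_per_mass = 4, C_vc = 80,
    V0_ra = 10, V0_rv = 20, V0_pa = 300, V0_la = 10, V0_lv = 15,
    V0_sa = 700, V0_pv = 250, V0_liv_per_mass = 450, V0_vc = 2250,
    total_volume_mL = total_volume_mL,
    lobe_split = lobe_split,
    eps_valve = 0.05,             # valve regularization width (mmHg)
    periodicity_tol = periodicity_tol,
    max_cycles = max_cycles,
    dt_s = dt_s)
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "circulation_config")
}

validate_config <- function(cfg) {
  s <- cfg$lobe_split
  if (length(s) != 2 || any(s <= 0) || any(s >= 1) ||
      abs(sum(s) - 1) > 1e-10)
    stop("lobe_split must be two fractions in (0,1) summing to 1")
  if (cfg$total_volume_mL <= 0) stop("total blood volume must be positive")
  if (cfg$periodicity_tol <= 0) stop("periodicity tolerance must be positive")
  if (cfg$dt_s <= 0 || cfg$heart_period_s <= 0) stop("invalid timing")
  invisible(cfg)
}

#' Read/write a model configuration as JSON
#' @param path file path
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$lobe_split <- unlist(cfg$lobe_split)
  validate_config(cfg)
  structure(cfg, class = "circulation_config")
}

#' @rdname read_config
#' @param config a \code{circulation_config}
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.circulation_config <- function(x, ...) {
  cat("<circulation_config>  period", format(x$heart_period_s, digits = 4),
      "s, total volume", x$total_volume_mL, "mL, lobe split",
      paste(format(x$lobe_split), collapse = "/"),
      "\n  periodicity tol", x$periodicity_tol,
      ", max cycles", x$max_cycles, ", dt", x$dt_s, "s\n")
  invisible(x)
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat("<parameter_vector>\n")
  print(unclass(x), ...)
  invisible(x)
}
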