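#' Patient calibration target
#'
#' The six pre-resection target outputs with their clinical-confidence
#' weights.  Portal and arterial flows default to the standard clinical
#' proxies of 20% and 5% of cardiac output
#' (\code{\link{derive_flow_targets}}).
#'
#' @param MAP,CO,P_pv,PCG measured targets (mmHg / L/min)
#' @param Q_pv,Q_ha flow targets (L/min); derived from CO when NULL
#' @param weights named weights; defaults 1 for PCG/MAP/CO, 2/3 for
#'   P_pv, 1/3 for the two flows
#' @param label patient label
#' @return object of class \code{calibration_target}
#' @export
calibration_target <- function(MAP, CO, P_pv, PCG, Q_pv = NULL,
                               Q_ha = NULL,
                               weights = c(P_pv = 2 / 3, PCG = 1,
                                           MAP = 1, CO = 1,
                                           Q_pv = 1 / 3, Q_ha = 1 / 3),
                               label = "") {
  if (is.null(Q_pv) || is.null(Q_ha)) {
    fl <- derive_flow_targets(CO)
    if (is.null(Q_pv)) Q_pv <- fl[["Q_pv"]]
    if (is.null(Q_ha)) Q_ha <- fl[["Q_ha"]]
  }
  y <- c(P_pv = P_pv, PCG = PCG, MAP = MAP, CO = CO,
         Q_pv = Q_pv, Q_ha = Q_ha)
  if (any(!is.finite(y))) stop("non-finite target")
  if (any(weights[names(y)] <= 0)) stop("weights must be positive")
  structure(list(targets = y, weights = weights[names(y)],
                 label = label),
            class = "calibration_target")
}

#' @export
print.calibration_target <- function(x, ...) {
  cat("<calibration_target>", x$label, "\n")
  print(round(x$targets, 3))
  invisible(x)
}

#' Flow targets derived from cardiac output
#'
#' Portal flow as 20% and hepatic-arterial flow as 5% of CO.
#' @param CO cardiac output (L/min), non-negative
#' @return named vector \code{c(Q_pv, Q_ha)} (L/min)
#' @export
derive_flow_targets <- function(CO) {
  stopifnot(CO >= 0)
  c(Q_pv = 0.20 * CO, Q_ha = 0.05 * CO)
}

#' Weighted relative calibration error
#'
#' \deqn{Err_{L^2} = \sqrt{\sum_i w_i ((Y_i^{target} - Y_i^{sim}) /
#'   Y_i^{target})^2}} over the six clinical outputs.
#'
#' @param target a \code{\link{calibration_target}}
#' @param simulated a \code{cycle_outputs} or named numeric with the six
#'   outputs
#' @export
weighted_error <- function(target, simulated) {
  y <- target$targets
  if (any(y == 0)) stop("zero target value")
  s <- unclass(simulated)[names(y)]
  if (anyNA(s)) stop("simulated outputs missing: ",
                     paste(names(y)[is.na(s)], collapse = ", "))
  sqrt(sum(target$weights * ((y - s) / y)^2))
}

#' Patient-specific resistances from the measured targets
#'
#' The calibration pipeline fixes the circulation resistances
#' algebraically from the patient's own measurements using the model's
#' cycle-averaged flow balances (caval pressure from
#' \code{P_pv - PCG}; one third of the portocaval gradient assigned to
#' the portal inflow resistance, two thirds to the hepatic-venous
#' outflow, matching the model's nominal operating point), so that the
#' optimizer only searches the heart elastances.
#'
#' @param target a \code{\link{calibration_target}}
#' @return named vector of the five resistances (mmHg s/mL)
#' @export
derive_resistances <- function(target) {
  y <- target$targets
  p_vc <- y[["P_pv"]] - y[["PCG"]]
  q_co <- y[["CO"]] / 0.06   # L/min -> mL/s
  q_pv <- y[["Q_pv"]] / 0.06
  q_ha <- y[["Q_ha"]] / 0.06
  gamma <- 1 / 3             # portal share of the portocaval gradient
  p_liv <- p_vc + (1 - gamma) * y[["PCG"]]
  c(R_OO = (y[["MAP"]] - p_vc) / (q_co - q_pv - q_ha),
    R_DO = (y[["MAP"]] - y[["P_pv"]]) / q_pv,
    R_pv = gamma * y[["PCG"]] / q_pv,
    R_hv = (1 - gamma) * y[["PCG"]] / (q_pv + q_ha),
    R_ha = (y[["MAP"]] - p_liv) / q_ha)
}

#' Calibrate heart elastances to a patient target
#'
#' Minimizes \code{\link{weighted_error}} of the simulated
#' pre-resection outputs with a derivative-free simplex search (with one
#' restart), under an evaluation budget.  Two strategies:
#' \describe{
#'   \item{original}{four free elastances (right atrium and left
#'     ventricle, amplitude and baseline each).}
#'   \item{reduced}{only the left-ventricular pair is free; the atrial
#'     pair is fixed at its population value, and proposals outside the
#'     filtered admissible region (\code{region}) are rejected by a
#'     penalty barrier.}
#' }
#' Resistances are fixed from the measurements by
#' \code{\link{derive_resistances}} in both strategies.
#'
#' @param target a \code{\link{calibration_target}}
#' @param strategy \code{"original"} or \code{"reduced"}
#' @param config model configuration
#' @param region \code{\link{filtered_input_summary}} result (required
#'   for the reduced strategy)
#' @param budget maximum model evaluations
#' @param start optional named start values for the free elastances
#' @return object of class \code{calibration_result}: fitted parameters,
#'   final \code{err}, \code{evaluations}, \code{converged}
#' @export
calibrate <- function(target, strategy = c("reduced", "original"),
                      config = default_config(), region = NULL,
                      budget = 300, start = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "reduced" && is.null(region))
    stop("the reduced strategy needs the filtered admissible region")
  res <- derive_resistances(target)
  atrial <- c(Ea_RA = 0.06, Eb_RA = 0.06) # population value when fixed
  free <- if (strategy == "original")
    c(Ea_RA = 0.06, Eb_RA = 0.06, Ea_LV = 2.5, Eb_LV = 0.09)
  else c(Ea_LV = 2.5, Eb_LV = 0.09)
  if (!is.null(start)) free[names(start)] <- start

  nev <- 0L
  # Patient-specific venous side.  The measurements pin the caval
  # pressure (P_pv - PCG) and the cardiac output jointly, which the
  # population venous constants cannot honor simultaneously, so two
  # venous quantities are derived per patient before the elastance
  # search: (i) the venous-return resistance from the right-ventricular
  # preload the target stroke volume requires (P_ra = Eb_RV (SV + ESV
  # margin)), and (ii) the blood volume, by a short damped fixed-point
  # matching the simulated caval pressure at the starting elastances.
  y <- target$targets
  pvc_t <- y[["P_pv"]] - y[["PCG"]]
  q_co <- y[["CO"]] / 0.06
  cfgp <- config
  sv_t <- q_co * config$heart_period_s
  p_ra_t <- config$Eb_RV * (sv_t + 6)
  cfgp$R_vr <- min(max((pvc_t - p_ra_t) / q_co, 0.004), 0.25)
  c_eff <- with(cfgp, C_vc + C_pv + C_liv_per_mass + C_pa + C_sa)
  pv0 <- c(Ea_RA = 0.06, Eb_RA = 0.06, Ea_LV = 2.5, Eb_LV = 0.09,
           res[c("R_pv", "R_ha", "R_hv", "R_DO", "R_OO")], hpx = 0)
  names(pv0) <- input_names()
  for (pass in 1:4) {
    tr0 <- try(simulate_to_periodic(as_parameter_vector(pv0), cfgp,
                                    trace_stride = 0, strict = FALSE),
               silent = TRUE)
    if (inherits(tr0, "try-error")) break
    nev <- nev + 1L
    p_vc <- attr(trace_outputs(tr0), "P_vc")
    cfgp$total_volume_mL <- cfgp$total_volume_mL +
      0.7 * c_eff * (pvc_t - p_vc)
  }
  best <- list(err = Inf, par = free)
  objective <- function(theta) {
    names(theta) <- names(free)
    if (any(theta <= 0)) return(10 + sum(pmax(-theta, 0)))
    full <- c(theta, if (strategy == "reduced") atrial)
    pv <- c(full[c("Ea_RA", "Eb_RA", "Ea_LV", "Eb_LV")],
            res[c("R_pv", "R_ha", "R_hv", "R_DO", "R_OO")],
            hpx = 0)
    names(pv) <- input_names()
    if (strategy == "reduced" &&
        !in_admissible_region(region, c(as.list(theta),
                                        as.list(res["R_OO"]))))
      return(10) # barrier: outside the physiologically retained region
    if (nev >= budget) return(best$err + 1)
    nev <<- nev + 1L
    tr <- try(simulate_to_periodic(as_parameter_vector(pv), cfgp,
                                   trace_stride = 0, strict = FALSE),
              silent = TRUE)
    if (inherits(tr, "try-error")) return(10)
    e <- weighted_error(target, trace_outputs(tr))
    if (e < best$err) best <<- list(err = e, par = theta)
    e
  }
  ctl <- list(maxit = budget, reltol = 1e-4, parscale = abs(free))
  opt <- stats::optim(free, objective, method = "Nelder-Mead",
                      control = ctl)
  if (nev < budget && best$err > 1e-3) { # restart the simplex from best
    opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = budget - nev,
                                       reltol = 1e-4,
                                       parscale = abs(best$par)))
  }
  fitted <- best$par
  full <- c(fitted, if (strategy == "reduced") atrial)
  structure(list(parameters = c(full[c("Ea_RA", "Eb_RA",
                                       "Ea_LV", "Eb_LV")],
                                res),
                 err = best$err, evaluations = nev,
                 strategy = strategy,
                 converged = nev <= budget && is.finite(best$err),
                 label = target$label),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s [%s]: Err_L2 = %.4f in %d evaluations%s\n",
              x$label, x$strategy, x$err, x$evaluations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' The nine representative virtual patients
#'
#' Preoperative measurement targets of the nine virtual patients
#' spanning baseline / hypodynamic / hyperdynamic circulation at low,
#' intermediate and high portal-hypertension risk; flow targets follow
#' the 20%/5%-of-CO rule.
#'
#' @return data frame with label, MAP (mmHg), CO (L/min), P_pv (mmHg),
#'   PCG (mmHg)
#' @export
virtual_patients <- function() {
  data.frame(
    label = c("baseline_low", "hypodynamic_low", "hyperdynamic_low",
              "baseline_high", "hypodynamic_high", "hyperdynamic_high",
              "baseline_mid", "hypodynamic_mid", "hyperdynamic_mid"),
    MAP = c(76, 60, 100, 76, 60, 100, 76, 60, 100),
    CO = c(4.65, 3, 7, 4.65, 3, 7, 4.65, 3, 7),
    P_pv = c(10, 10, 10, 18, 18, 18, 15, 15, 15),
    PCG = c(4, 4, 4, 14, 14, 14, 10, 10, 10))
}

#' Compare the original and reduced calibration strategies
#'
#' Calibrates every patient with both strategies under matched budgets
#' and reports per-patient and aggregate error and model-evaluation
#' counts, plus the relative evaluation saving of the reduced strategy.
#'
#' @param patients data frame as \code{\link{virtual_patients}}
#' @param config model configuration
#' @param region filtered admissible region for the reduced strategy
#' @param budget per-calibration evaluation budget
#' @return list with \code{per_patient} data frame and \code{summary}
#' @export
compare_strategies <- function(patients = virtual_patients(),
                               config = default_config(),
                               region, budget = 300) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    tg <- calibration_target(MAP = p$MAP, CO = p$CO, P_pv = p$P_pv,
                             PCG = p$PCG, label = p$label)
    orig <- calibrate(tg, "original", config, budget = budget)
    red <- calibrate(tg, "reduced", config, region = region,
                     budget = budget)
    data.frame(label = p$label,
               err_original = orig$err, evals_original = orig$evaluations,
               err_reduced = red$err, evals_reduced = red$evaluations)
  })
  per <- do.call(rbind, rows)
  summary <- list(
    mean_err_original = mean(per$err_original),
    mean_err_reduced = mean(per$err_reduced),
    total_evals_original = sum(per$evals_original),
    total_evals_reduced = sum(per$evals_reduced),
    eval_reduction = 1 - sum(per$evals_reduced) / sum(per$evals_original))
  list(per_patient = per, summary = summary)
}
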