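#' @useDynLib hepasens, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

state_names <- function() {
  c("V_ra", "V_rv", "V_pa", "V_la", "V_lv",
    "V_sa", "V_pv", "V_liv_R", "V_liv_L", "V_vc")
}

# Remaining lobe mass fractions (right, left) of a parameter vector;
# equal to the configured split while the liver is intact.
lobe_remaining <- function(params, config) {
  r <- attr(params, "lobe_remaining")
  if (is.null(r)) unname(config$lobe_split) else unname(r)
}

# Flatten varied + fixed parameters into the named vector the compiled
# core expects.  Lobar hepatic resistances scale inversely with the
# remaining mass fraction of each lobe; a fully resected lobe is flagged
# by a non-positive resistance and carries no flow.
pack_parameters <- function(params, config) {
  rem <- lobe_remaining(params, config)
  lobar <- function(R_total) {
    ifelse(rem > 1e-12, R_total / rem, -1)
  }
  rpv <- lobar(params[["R_pv"]]); rha <- lobar(params[["R_ha"]])
  rhv <- lobar(params[["R_hv"]])
  split <- unname(config$lobe_split)
  c(Ea_RA = params[["Ea_RA"]], Eb_RA = params[["Eb_RA"]],
    Ea_RV = config$Ea_RV, Eb_RV = config$Eb_RV,
    Ea_LA = config$Ea_LA, Eb_LA = config$Eb_LA,
    Ea_LV = params[["Ea_LV"]], Eb_LV = params[["Eb_LV"]],
    R_tri = config$R_tri, R_pul = config$R_pul,
    R_mit = config$R_mit, R_aor = config$R_aor,
    R_pulm = config$R_pulm, R_vr = config$R_vr,
    R_OO = params[["R_OO"]], R_DO = params[["R_DO"]],
    R_pv_R = rpv[1], R_pv_L = rpv[2],
    R_ha_R = rha[1], R_ha_L = rha[2],
    R_hv_R = rhv[1], R_hv_L = rhv[2],
    C_pa = config$C_pa, C_sa = config$C_sa, C_pv = config$C_pv,
    C_liv_R = config$C_liv_per_mass * split[1],
    C_liv_L = config$C_liv_per_mass * split[2],
    C_vc = config$C_vc,
    V0_ra = config$V0_ra, V0_rv = config$V0_rv, V0_pa = config$V0_pa,
    V0_la = config$V0_la, V0_lv = config$V0_lv, V0_sa = config$V0_sa,
    V0_pv = config$V0_pv,
    V0_liv_R = config$V0_liv_per_mass * split[1],
    V0_liv_L = config$V0_liv_per_mass * split[2],
    V0_vc = config$V0_vc,
    T = config$heart_period_s, t_vent_dur = config$t_vent_dur_s,
    t_atr_on = config$t_atr_on_s, t_atr_dur = config$t_atr_dur_s,
    eps_valve = config$eps_valve)
}

# Plausible initial volume distribution; the residual of the configured
# total is parked in the vena cava reservoir.
default_initial_state <- function(config) {
  split <- unname(config$lobe_split)
  v <- c(V_ra = config$V0_ra + 20, V_rv = config$V0_rv + 110,
         V_pa = config$V0_pa + config$C_pa * 15,
         V_la = config$V0_la + 25, V_lv = config$V0_lv + 110,
         V_sa = config$V0_sa + config$C_sa * 85,
         V_pv = config$V0_pv + config$C_pv * 9,
         V_liv_R = (config$V0_liv_per_mass +
                      config$C_liv_per_mass * 8) * split[1],
         V_liv_L = (config$V0_liv_per_mass +
                      config$C_liv_per_mass * 8) * split[2],
         V_vc = config$V0_vc)
  v["V_vc"] <- v["V_vc"] + (config$total_volume_mL - sum(v))
  if (v["V_vc"] <= 0) stop("total blood volume too small for configuration")
  v
}

#' Simulate the closed loop to a periodic steady state
#'
#' Integrates whole cardiac cycles until the cycle-to-cycle relative
#' change of all six cycle-averaged clinical outputs falls below the
#' configured periodicity tolerance, and returns the final cycle.
#'
#' @param params a \code{\link{parameter_vector}}
#' @param config a \code{\link{default_config}} list
#' @param state0 optional initial volume state (warm start); defaults to a
#'   plausible resting distribution of the configured total volume
#' @param phase label stored on the result (\code{"pre-hpx"}/\code{"post-hpx"})
#' @param trace_stride record every \code{trace_stride}-th integrator step
#'   of the final cycle (1 = every step)
#' @param strict error on non-convergence (default) instead of returning
#'   the last cycle flagged unconverged
#' @return a \code{circulation_trace}: time grid, per-compartment volumes
#'   and pressures (mmHg), branch flows (mL/s), per-cycle output history,
#'   terminal state and convergence diagnostics
#' @export
simulate_to_periodic <- function(params, config = default_config(),
                                 state0 = NULL, phase = "pre-hpx",
                                 trace_stride = 4, strict = TRUE) {
  validate_parameter_vector(params)
  validate_config(config)
  if (is.null(state0)) state0 <- default_initial_state(config)
  res <- .cpp_simulate_cycles(pack_parameters(params, config),
                              as.numeric(state0), config$dt_s,
                              as.integer(config$max_cycles),
                              config$periodicity_tol,
                              as.integer(trace_stride))
  if (!res$converged && strict) {
    cond <- structure(
      class = c("hepasens_convergence_failure", "error", "condition"),
      list(message = sprintf(
        "no periodic steady state within %d cycles (last residual %.3g, tol %.3g)",
        res$cycles, res$residual, config$periodicity_tol),
        call = sys.call(), residual = res$residual, phase = phase))
    stop(cond)
  }
  vols <- prs <- flw <- NULL
  if (trace_stride > 0) {
    vols <- res$trace_volumes; colnames(vols) <- state_names()
    prs <- res$trace_pressures
    colnames(prs) <- sub("^V", "P", state_names())
    flw <- res$trace_flows
    colnames(flw) <- c("Q_tri", "Q_pul", "Q_pulm", "Q_mit", "Q_aor",
                       "Q_oo", "Q_do", "Q_pv_R", "Q_pv_L", "Q_ha_R",
                       "Q_ha_L", "Q_hv_R", "Q_hv_L", "Q_vr")
  }
  co <- matrix(res$cycle_outputs, ncol = 7)
  colnames(co) <- c(output_names(), "P_vc")
  structure(list(time = if (trace_stride > 0) res$trace_time,
                 volumes = vols, pressures = prs,
                 flows = flw, cycle_history = co, phase = phase,
                 converged = res$converged, cycles = res$cycles,
                 residual = res$residual,
                 final_state = stats::setNames(res$final_state,
                                               state_names()),
                 period_s = config$heart_period_s, dt_s = res$dt),
            class = "circulation_trace")
}

#' @export
print.circulation_trace <- function(x, ...) {
  cat("<circulation_trace> phase", x$phase, "-",
      if (x$converged) "periodic" else "NOT periodic",
      "after", x$cycles, "cycles (residual",
      format(x$residual, digits = 3), ")\n")
  print(cycle_averages(x))
  invisible(x)
}

#' Cycle-averaged clinical outputs of a converged cycle
#'
#' Time-weighted means over the final cardiac cycle: portal pressure
#' \code{P_pv} (mmHg), portocaval gradient \code{PCG} = mean portal minus
#' mean caval pressure (mmHg), mean arterial pressure \code{MAP} (mmHg),
#' cardiac output \code{CO} and liver inflows \code{Q_ha}, \code{Q_pv}
#' (L/min).
#'
#' @param trace a \code{circulation_trace} spanning one period
#' @return named numeric of class \code{cycle_outputs} with the phase and
#'   the mean caval pressure (\code{P_vc}) as attributes
#' @export
cycle_averages <- function(trace) {
  if (!inherits(trace, "circulation_trace"))
    stop("cycle_averages() expects a circulation_trace")
  if (length(trace$time) < 2 ||
      diff(range(trace$time)) < trace$period_s - trace$period_s / 4)
    stop("trace does not span a full cardiac period")
  m <- function(v) mean(v) # uniform grid over one period
  p_pv <- m(trace$pressures[, "P_pv"])
  p_vc <- m(trace$pressures[, "P_vc"])
  out <- c(P_pv = p_pv, PCG = p_pv - p_vc,
           MAP = m(trace$pressures[, "P_sa"]),
           CO = m(trace$flows[, "Q_aor"]) * 0.06,
           Q_ha = m(trace$flows[, "Q_ha_R"] + trace$flows[, "Q_ha_L"]) * 0.06,
           Q_pv = m(trace$flows[, "Q_pv_R"] + trace$flows[, "Q_pv_L"]) * 0.06)
  structure(out, class = "cycle_outputs", phase = trace$phase, P_vc = p_vc)
}

#' @export
print.cycle_outputs <- function(x, ...) {
  cat("<cycle_outputs>", attr(x, "phase"), "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

# Final converged outputs as accumulated by the compiled core (every
# integrator step, not the strided trace).
trace_outputs <- function(trace) {
  co <- trace$cycle_history[nrow(trace$cycle_history), , drop = TRUE]
  structure(co[output_names()], class = "cycle_outputs",
            phase = trace$phase, P_vc = co[["P_vc"]])
}

#' Virtual hepatectomy operator on the input parameters
#'
#' Removes the fraction \code{hpx} of total liver mass, depleting the
#' right lobe first and taking any remainder from the left lobe.  Each
#' lobe's intrahepatic resistances (portal, arterial, venous) scale
#' inversely with its remaining mass fraction; a fully resected lobe is
#' removed from the network.  Extra-hepatic parameters are unchanged.
#'
#' @inheritParams simulate_to_periodic
#' @return the parameter vector with the post-resection remaining lobe
#'   fractions attached (attribute \code{lobe_remaining})
#' @export
apply_hepatectomy <- function(params, config = default_config()) {
  h <- params[["hpx"]]
  if (h >= 1) stop("hpx >= 1: no liver remaining")
  split <- unname(config$lobe_split)
  taken_right <- min(h, split[1])
  rem <- c(split[1] - taken_right, split[2] - (h - taken_right))
  out <- params
  attr(out, "lobe_remaining") <- pmax(rem, 0)
  out
}

#' Simulate one patient through the virtual hepatectomy
#'
#' Runs the model to periodicity, records the pre-resection outputs,
#' applies the hepatectomy operator and re-simulates starting from the
#' pre-resection terminal state (an instantaneous intra-operative
#' change), recording the post-resection outputs.
#'
#' @inheritParams simulate_to_periodic
#' @param state0 optional warm-start state for the pre-resection run
#' @return list with elements \code{pre} and \code{post}
#'   (\code{cycle_outputs}) and the two terminal states
#' @export
run_virtual_hepatectomy <- function(params, config = default_config(),
                                    state0 = NULL, strict = TRUE) {
  pre_tr <- withCallingHandlers(
    simulate_to_periodic(params, config, state0 = state0,
                         phase = "pre-hpx", trace_stride = 0,
                         strict = strict),
    hepasens_convergence_failure = function(c) c)
  post_par <- apply_hepatectomy(params, config)
  post_tr <- simulate_to_periodic(post_par, config,
                                  state0 = pre_tr$final_state,
                                  phase = "post-hpx", trace_stride = 0,
                                  strict = strict)
  list(pre = trace_outputs(pre_tr), post = trace_outputs(post_tr),
       pre_state = pre_tr$final_state, post_state = post_tr$final_state,
       converged = pre_tr$converged && post_tr$converged)
}

#' Evaluate a cohort of parameter vectors through the virtual hepatectomy
#'
#' Batch driver for sensitivity designs and cohort tables.  All runs are
#' warm-started from the periodic state of the cohort-median patient,
#' which roughly halves the cycles needed to reach periodicity.
#'
#' @param cohort data frame with the ten input columns
#'   (\code{\link{input_names}})
#' @param config model configuration
#' @param warm_start warm-start each run from a nominal periodic state
#' @return data frame with columns \code{pre_<output>},
#'   \code{post_<output>} and \code{converged}
#' @export
evaluate_cohort <- function(cohort, config = default_config(),
                            warm_start = TRUE) {
  stopifnot(all(input_names() %in% names(cohort)))
  n <- nrow(cohort)
  state0 <- NULL
  if (warm_start && n > 1) {
    med <- as_parameter_vector(vapply(cohort[input_names()],
                                      stats::median, numeric(1)))
    tr <- try(simulate_to_periodic(med, config, trace_stride = 0,
                                   strict = FALSE), silent = TRUE)
    if (!inherits(tr, "try-error")) state0 <- tr$final_state
  }
  pre <- matrix(NA_real_, n, 6)
  post <- matrix(NA_real_, n, 6)
  conv <- logical(n)
  for (i in seq_len(n)) {
    p <- as_parameter_vector(cohort[i, input_names()])
    res <- try(run_virtual_hepatectomy(p, config, state0 = state0,
                                       strict = FALSE), silent = TRUE)
    if (inherits(res, "try-error")) next
    pre[i, ] <- unclass(res$pre)
    post[i, ] <- unclass(res$post)
    conv[i] <- res$converged
  }
  colnames(pre) <- paste0("pre_", output_names())
  colnames(post) <- paste0("post_", output_names())
  cbind(as.data.frame(pre), as.data.frame(post),
        converged = conv)
}
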