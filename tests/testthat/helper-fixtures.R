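# Shared fixtures, built in code.  Heavyweight artifacts (the acceptance
# cohort and its surrogate) are computed once per session and cached.

nominal_params <- function(hpx = 0) {
  as_parameter_vector(c(Ea_RA = 0.06, Eb_RA = 0.06, Ea_LV = 2.5,
                        Eb_LV = 0.09, R_pv = 0.12, R_ha = 20,
                        R_hv = 0.19, R_DO = 4.8, R_OO = 1.4, hpx = hpx))
}

# a synthetic single-cycle trace for cycle_averages unit tests
synthetic_trace <- function(n = 800, period = 0.8,
                            p_pv = 10, p_vc = 4, q0 = 80) {
  tt <- seq(0, period, length.out = n + 1)[1:n]
  prs <- matrix(0, n, 10)
  colnames(prs) <- c("P_ra", "P_rv", "P_pa", "P_la", "P_lv", "P_sa",
                     "P_pv", "P_liv_R", "P_liv_L", "P_vc")
  prs[, "P_pv"] <- p_pv + 2 * sin(2 * pi * tt / period)
  prs[, "P_vc"] <- p_vc + 0.5 * cos(2 * pi * tt / period)
  prs[, "P_sa"] <- 90
  flw <- matrix(0, n, 14)
  colnames(flw) <- c("Q_tri", "Q_pul", "Q_pulm", "Q_mit", "Q_aor",
                     "Q_oo", "Q_do", "Q_pv_R", "Q_pv_L", "Q_ha_R",
                     "Q_ha_L", "Q_hv_R", "Q_hv_L", "Q_vr")
  flw[, "Q_aor"] <- q0 + 30 * sin(2 * pi * tt / period)
  structure(list(time = tt, volumes = NULL, pressures = prs,
                 flows = flw, phase = "pre-hpx", period_s = period),
            class = "circulation_trace")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# Study-scale artifacts shared by the acceptance checks: a synthetic
# cohort pushed through the virtual hepatectomy, the physiological
# filter, and the degree-4 filtered PCE surrogate.
study_artifacts <- function() {
  cached("study", {
    spec <- default_cohort_spec()
    config <- default_config()
    coh <- generate_synthetic_cohort(spec, n = 6200, seed = 101)
    ev <- evaluate_cohort(coh, config)
    mask <- apply_filter(ev)
    pop <- assemble_population(coh, ev, mask, seed = 101)
    dfp <- as.data.frame(pop)
    ycols <- c(paste0("pre_", output_names()),
               paste0("post_", output_names()))
    n_train <- 4200
    Xtr <- dfp[seq_len(n_train), input_names()]
    Ytr <- dfp[seq_len(n_train), ycols]
    Xte <- dfp[(n_train + 1):nrow(dfp), input_names()]
    Yte <- dfp[(n_train + 1):nrow(dfp), ycols]
    basis <- build_pce_basis(Xtr, 4)
    surrogate <- fit_pce(Xtr, Ytr, basis)
    list(spec = spec, config = config, cohort = coh, outputs = ev,
         mask = mask, population = pop,
         region = filtered_input_summary(pop),
         surrogate = surrogate, Xte = Xte, Yte = Yte,
         n_train = n_train)
  })
}
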