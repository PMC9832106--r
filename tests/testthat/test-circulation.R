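test_that("periodic steady state conserves volume and balances liver flows", {
  cfg <- default_config()
  tr <- simulate_to_periodic(nominal_params(), cfg, trace_stride = 1)
  expect_true(tr$converged)
  # closed loop: total volume constant to 1e-6 relative
  expect_lt(abs(sum(tr$final_state) - cfg$total_volume_mL) /
              cfg$total_volume_mL, 1e-6)
  out <- cycle_averages(tr)
  # flow continuity at periodicity: liver outflow = Q_pv + Q_ha within 1%
  q_out <- mean(tr$flows[, "Q_hv_R"] + tr$flows[, "Q_hv_L"]) * 0.06
  expect_lt(abs(q_out - (out[["Q_pv"]] + out[["Q_ha"]])) /
              (out[["Q_pv"]] + out[["Q_ha"]]), 0.01)
  # CO >= Q_pv + Q_ha >= 0 at steady state
  expect_gte(out[["CO"]], out[["Q_pv"]] + out[["Q_ha"]])
  expect_gte(out[["Q_pv"]] + out[["Q_ha"]], 0)
  # stored consistency: PCG = mean P_pv - mean P_vc
  expect_equal(out[["PCG"]], out[["P_pv"]] - attr(out, "P_vc"),
               tolerance = 1e-12)
})

test_that("without active contraction all flows decay toward zero", {
  p <- nominal_params()
  p[c("Ea_RA", "Ea_LV")] <- 1e-9
  cfg <- default_config(Ea_RV = 1e-9, Ea_LA = 1e-9, max_cycles = 120)
  tr <- simulate_to_periodic(p, cfg, strict = FALSE, trace_stride = 1)
  out <- cycle_averages(tr)
  expect_lt(out[["CO"]], 0.05)       # L/min: hydrostatic equilibrium
  expect_lt(out[["Q_pv"]], 0.05)
})

test_that("simulation is deterministic: identical inputs, bit-identical outputs", {
  cfg <- default_config()
  t1 <- simulate_to_periodic(nominal_params(), cfg, trace_stride = 2)
  t2 <- simulate_to_periodic(nominal_params(), cfg, trace_stride = 2)
  expect_identical(t1$pressures, t2$pressures)
  expect_identical(t1$final_state, t2$final_state)
})

test_that("non-convergence raises a condition carrying the last residual", {
  cfg <- default_config(max_cycles = 3)
  err <- tryCatch(simulate_to_periodic(nominal_params(), cfg),
                  hepasens_convergence_failure = function(c) c)
  expect_s3_class(err, "hepasens_convergence_failure")
  expect_true(is.finite(err$residual))
})

test_that("cycle averages are time-weighted means of the trace", {
  tr <- synthetic_trace(p_pv = 10, p_vc = 4, q0 = 80)
  out <- cycle_averages(tr)
  expect_equal(out[["MAP"]], 90, tolerance = 1e-10)  # constant signal
  expect_equal(out[["P_pv"]], 10, tolerance = 1e-3)  # sinusoid offset
  expect_equal(out[["PCG"]], 6, tolerance = 1e-3)    # mean(P_pv)-mean(P_vc)
  expect_equal(out[["CO"]], 80 * 0.06, tolerance = 1e-3) # mL/s -> L/min
  tr$time <- tr$time[1:3]
  expect_error(cycle_averages(tr), "full cardiac period")
})

test_that("hepatectomy operator depletes the right lobe first", {
  cfg <- default_config() # split 0.6/0.4
  p0 <- apply_hepatectomy(nominal_params(0), cfg)
  expect_equal(attr(p0, "lobe_remaining"), c(0.6, 0.4)) # identity case
  # hpx = 0.3: right lobe halved (resistances double), left untouched
  p3 <- apply_hepatectomy(nominal_params(0.3), cfg)
  expect_equal(attr(p3, "lobe_remaining"), c(0.3, 0.4))
  # hpx = right lobe fraction: right branch removed entirely
  p6 <- apply_hepatectomy(nominal_params(0.6), cfg)
  expect_equal(attr(p6, "lobe_remaining"), c(0, 0.4))
  # extra-hepatic parameters untouched
  expect_identical(unclass(p3)[c("R_DO", "R_OO", "Ea_LV")],
                   unclass(nominal_params(0.3))[c("R_DO", "R_OO", "Ea_LV")])
  expect_error(apply_hepatectomy(nominal_params(0.999999), cfg), NA)
  p <- nominal_params(0); p["hpx"] <- 1 - 1e-12
  expect_error(as_parameter_vector(replace(unclass(nominal_params(0)),
                                           "hpx", 1)), "hpx")
})

test_that("whole-liver resistance after full right-lobe resection equals the left lobe's", {
  cfg <- default_config()
  # with the right branch removed, all portal flow crosses R_pv/0.4
  p6 <- apply_hepatectomy(nominal_params(0.6), cfg)
  tr <- simulate_to_periodic(p6, cfg, trace_stride = 1, strict = FALSE)
  expect_equal(sum(abs(tr$flows[, c("Q_pv_R", "Q_ha_R", "Q_hv_R")])), 0)
  expect_gt(mean(tr$flows[, "Q_pv_L"]), 0)
})

test_that("virtual hepatectomy: identity at hpx = 0, monotone portal response in hpx", {
  cfg <- default_config()
  r0 <- run_virtual_hepatectomy(nominal_params(0), cfg)
  for (nm in output_names())
    expect_equal(r0$post[[nm]], r0$pre[[nm]],
                 tolerance = 2 * cfg$periodicity_tol)
  hgrid <- c(0.15, 0.35, 0.55, 0.7)
  runs <- lapply(hgrid, function(h)
    run_virtual_hepatectomy(nominal_params(h), cfg))
  ppv <- vapply(runs, function(r) r$post[["P_pv"]], 0)
  pcg <- vapply(runs, function(r) r$post[["PCG"]], 0)
  co <- vapply(runs, function(r) r$post[["CO"]], 0)
  expect_true(all(diff(ppv) > 0))
  expect_true(all(diff(pcg) > 0))
  # CO barely affected by the resection size
  expect_lt(max(abs(co - runs[[1]]$pre[["CO"]])) / runs[[1]]$pre[["CO"]],
            0.25)
})

test_that("two-point monotonicity probes point the physiological way", {
  cfg <- default_config()
  base <- cycle_averages(simulate_to_periodic(nominal_params(), cfg))
  bump <- function(nm, f) {
    p <- unclass(nominal_params()); p[nm] <- p[nm] * f
    cycle_averages(simulate_to_periodic(as_parameter_vector(p), cfg))
  }
  expect_gt(bump("R_OO", 2)[["MAP"]], base[["MAP"]])   # afterload up
  expect_lt(bump("R_ha", 2)[["Q_ha"]], base[["Q_ha"]]) # arterial inflow down
})

test_that("parameter and config validation reject unphysical values", {
  expect_error(parameter_vector(Ea_RA = -1, Eb_RA = 0.06, Ea_LV = 2.5,
                                Eb_LV = 0.09, R_pv = 0.12, R_ha = 20,
                                R_hv = 0.19, R_DO = 4.8, R_OO = 1.4),
               "strictly positive")
  expect_error(default_config(lobe_split = c(0.7, 0.7)), "lobe_split")
  expect_error(default_config(total_volume_mL = -1), "volume")
})
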