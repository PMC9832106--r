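#' Deterministic per-stage seed stream
#'
#' Expands one master seed into reproducible per-stage seeds by a
#' counter scheme (kept below 2^31).
#'
#' @param master integer master seed
#' @param stage stage counter (0, 1, 2, ...)
#' @export
seed_stream <- function(master, stage) {
  as.integer((as.numeric(master) * 1000 + 7919 * as.numeric(stage)) %%
               2147483647)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole study at a configurable scale: draw a Saltelli
#' design from the cohort marginals, evaluate every design point through
#' the virtual hepatectomy, estimate full-model Sobol indices, apply the
#' physiological filter, fit the filtered degree-q PCE surrogate,
#' validate it on disjoint filtered test couples, derive the analytic
#' Sobol indices, assemble the virtual population, and summarize the
#' admissible region.
#'
#' @param N Saltelli base sample size (model evaluations: \code{(d+2)N}
#'   virtual hepatectomies)
#' @param n_test extra independently sampled test patients for the
#'   surrogate validation
#' @param q PCE total degree
#' @param seed master seed
#' @param spec cohort specification supplying the sampling marginals
#' @param config model configuration
#' @param out_dir optional directory; when given, all artifacts (design,
#'   outputs, population, Sobol tables, Q2 report, manifest) are written
#'   as CSV/JSON
#' @return a run manifest (list) with every stage result and the counts
#'   \code{N}, \code{N_s}, \code{N_star}, \code{N_s_star},
#'   \code{n_test}, \code{n_test_star}
#' @export
run_full_pipeline <- function(N = 64, n_test = 32, q = 2, seed = 1L,
                              spec = default_cohort_spec(),
                              config = default_config(),
                              out_dir = NULL) {
  marg <- spec$inputs
  d <- length(marg)

  design <- build_saltelli_design(marg, N, seed = seed_stream(seed, 1))
  pts <- design_points(design)
  ev <- evaluate_cohort(as.data.frame(pts), config)
  pre <- as.matrix(ev[paste0("pre_", output_names())])
  post <- as.matrix(ev[paste0("post_", output_names())])

  sob_full <- list(
    pre = estimate_sobol(design, pre),
    post = estimate_sobol(design, post))

  bounds <- filter_bounds()
  mask <- apply_filter(ev, bounds)
  pop <- assemble_population(as.data.frame(pts), ev, mask, bounds,
                             seed = seed)
  region <- filtered_input_summary(pop)

  # surrogate on the filtered couples, validated on disjoint filtered draws
  Xtr <- as.data.frame(pop)[input_names()]
  Ytr <- as.data.frame(pop)[c(paste0("pre_", output_names()),
                              paste0("post_", output_names()))]
  test_coh <- generate_synthetic_cohort(spec, n = n_test,
                                        seed = seed_stream(seed, 2))
  test_ev <- evaluate_cohort(test_coh, config)
  test_mask <- apply_filter(test_ev, bounds)
  Xte <- test_coh[test_mask, , drop = FALSE]
  Yte <- test_ev[test_mask, c(paste0("pre_", output_names()),
                              paste0("post_", output_names()))]

  basis <- build_pce_basis(Xtr, q)
  surrogate <- fit_pce(Xtr, Ytr, basis)
  q2 <- q2_score(surrogate, Xte, Yte)
  sob_pce <- sobol_from_pce(surrogate)

  manifest <- list(
    seed = seed, d = d, N = N, N_s = (d + 2) * N,
    N_star = attr(pop, "n_retained"),
    N_s_star = attr(pop, "n_retained"),
    n_test = n_test, n_test_star = nrow(Xte),
    q = q, P = nrow(basis$indices),
    bounds = unclass(bounds),
    design = design, outputs = ev, population = pop,
    region = region, sobol_full = sob_full, sobol_pce = sob_pce,
    surrogate = surrogate, q2 = q2,
    classification = list(
      pre = classify_sensitivity(sob_full$pre),
      post = classify_sensitivity(sob_full$post)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(...) file.path(out_dir, ...)
    M <- pts; attr(M, "block") <- NULL
    utils::write.csv(cbind(block = attr(pts, "block"),
                           as.data.frame(M)),
                     f("design_points.csv"), row.names = FALSE)
    utils::write.csv(ev, f("model_outputs.csv"), row.names = FALSE)
    write_population(pop, f("virtual_population.csv"))
    jsonlite::write_json(list(
      S_pre = as.data.frame(sob_full$pre$S),
      ST_pre = as.data.frame(sob_full$pre$ST),
      S_post = as.data.frame(sob_full$post$S),
      ST_post = as.data.frame(sob_full$post$ST)),
      f("sobol_full_model.json"), digits = NA)
    jsonlite::write_json(list(S = as.data.frame(sob_pce$S),
                              ST = as.data.frame(sob_pce$ST)),
                         f("sobol_pce.json"), digits = NA)
    utils::write.csv(q2, f("q2_report.csv"), row.names = FALSE)
    counts <- manifest[c("seed", "d", "N", "N_s", "N_star", "N_s_star",
                         "n_test", "n_test_star", "q", "P")]
    artifacts <- list.files(out_dir)
    jsonlite::write_json(c(counts, list(artifacts = artifacts,
                                        md5 = as.list(tools::md5sum(
                                          file.path(out_dir, artifacts))))),
                         f("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$out_dir <- out_dir
  }
  manifest
}

#' Write the packaged study fixtures
#'
#' Regenerates, deterministically, the small text fixtures used across
#' the tests and examples: the nine-patient calibration table, the
#' default cohort specification, the physiological filter bounds, and
#' two small analytic benchmark datasets (Ishigami and an additive
#' two-input model).
#'
#' @param dir output directory
#' @param seed seed for the benchmark datasets
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(dir, ...)
  utils::write.csv(virtual_patients(), f("virtual_patients.csv"),
                   row.names = FALSE)
  spec <- default_cohort_spec()
  jsonlite::write_json(lapply(spec$inputs, function(d)
    d[c("family", "location", "scale", "lo", "hi")]),
    f("cohort_spec.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(filter_bounds()), f("filter_bounds.json"),
                       digits = NA)
  X <- with_seed(seed, matrix(stats::runif(200 * 3, -pi, pi), ncol = 3))
  colnames(X) <- paste0("X", 1:3)
  utils::write.csv(cbind(as.data.frame(X), Y = ishigami(X)),
                   f("ishigami_sample.csv"), row.names = FALSE)
  A <- with_seed(seed + 1, matrix(stats::runif(200 * 2), ncol = 2))
  colnames(A) <- c("X1", "X2")
  utils::write.csv(cbind(as.data.frame(A), Y = A[, 1] + 2 * A[, 2]),
                   f("additive_sample.csv"), row.names = FALSE)
  invisible(dir)
}
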