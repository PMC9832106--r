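#' Boundary-corrected kernel density estimate on a bounded support
#'
#' Gaussian-kernel KDE with Silverman's bandwidth and reflection at both
#' support bounds, normalized to unit mass on \code{[lo, hi]}.  The
#' resulting object exposes pdf/cdf/quantile evaluation
#' (\code{\link{dist_pdf}}, \code{\link{dist_cdf}},
#' \code{\link{dist_quantile}}) and inverse-cdf sampling
#' (\code{\link{sample_dist}}), the ingredients the sensitivity designs
#' need.
#'
#' @param samples numeric vector of at least 5 finite observations
#' @param bounds length-2 numeric, finite support \code{c(lo, hi)}
#' @param name input name carried through to reports
#' @return object of class \code{empirical_dist}
#' @export
fit_kde <- function(samples, bounds, name = deparse(substitute(samples))) {
  samples <- as.numeric(samples)
  if (length(samples) < 5) stop("need at least 5 samples")
  if (any(!is.finite(samples))) stop("non-finite samples")
  if (length(bounds) != 2 || any(!is.finite(bounds)) ||
      bounds[1] >= bounds[2])
    stop("bounds must be finite with lo < hi")
  if (any(samples < bounds[1] | samples > bounds[2]))
    stop("samples outside the stated support")
  s <- stats::sd(samples)
  iqr <- stats::IQR(samples)
  if (s < .Machine$double.eps * max(1, abs(mean(samples))) * 10)
    stop("degenerate samples: zero spread")
  spread <- min(s, if (iqr > 0) iqr / 1.34 else s)
  bw <- 0.9 * spread * length(samples)^(-0.2) # Silverman's rule
  lo <- bounds[1]; hi <- bounds[2]

  cdf_raw <- function(x) {
    # reflected-kernel cdf before normalization
    out <- numeric(length(x))
    for (k in seq_along(x)) {
      z <- x[k]
      out[k] <- mean(stats::pnorm(z, samples, bw) -
                       stats::pnorm(lo, samples, bw) +
                       stats::pnorm(z, 2 * lo - samples, bw) -
                       stats::pnorm(lo, 2 * lo - samples, bw) +
                       stats::pnorm(z, 2 * hi - samples, bw) -
                       stats::pnorm(lo, 2 * hi - samples, bw))
    }
    out
  }
  grid <- seq(lo, hi, length.out = 2048)
  cg <- cdf_raw(grid)
  mass <- cg[length(cg)]
  cg <- cg / mass
  cg <- cummax(cg) # guard round-off monotonicity
  structure(list(name = name, samples = samples, bw = bw,
                 lo = lo, hi = hi, grid = grid, cdf_grid = cg,
                 mass = mass),
            class = "empirical_dist")
}

#' Marginal distribution interface
#'
#' Generic pdf/cdf/quantile evaluation shared by the KDE marginals
#' (\code{empirical_dist}) and the truncated parametric families
#' (\code{trunc_family}) of the cohort generator.
#'
#' @param dist a marginal distribution object
#' @param x,p evaluation points / probabilities
#' @export
dist_pdf <- function(dist, x) UseMethod("dist_pdf")

#' @rdname dist_pdf
#' @export
dist_cdf <- function(dist, x) UseMethod("dist_cdf")

#' @rdname dist_pdf
#' @export
dist_quantile <- function(dist, p) UseMethod("dist_quantile")

#' @export
dist_pdf.empirical_dist <- function(dist, x) {
  out <- (rowMeans(outer(x, dist$samples, function(z, c)
    stats::dnorm(z, c, dist$bw))) +
    rowMeans(outer(x, 2 * dist$lo - dist$samples, function(z, c)
      stats::dnorm(z, c, dist$bw))) +
    rowMeans(outer(x, 2 * dist$hi - dist$samples, function(z, c)
      stats::dnorm(z, c, dist$bw)))) / dist$mass
  out[x < dist$lo | x > dist$hi] <- 0
  out
}

#' @export
dist_cdf.empirical_dist <- function(dist, x) {
  x <- pmin(pmax(x, dist$lo), dist$hi)
  stats::approx(dist$grid, dist$cdf_grid, xout = x, rule = 2)$y
}

#' @export
dist_quantile.empirical_dist <- function(dist, p) {
  if (any(p < 0 | p > 1)) stop("probabilities outside [0,1]")
  # invert the gridded cdf; strictly increasing after de-duplication
  keep <- !duplicated(dist$cdf_grid)
  stats::approx(dist$cdf_grid[keep], dist$grid[keep], xout = p,
                rule = 2)$y
}

#' @export
print.empirical_dist <- function(x, ...) {
  cat("<empirical_dist>", x$name, ":", length(x$samples),
      "samples on [", x$lo, ",", x$hi, "], bw",
      format(x$bw, digits = 3), "\n")
  invisible(x)
}

#' Draw reproducible samples from a marginal distribution
#'
#' Inverse-cdf sampling; the truncation bounds are honored exactly.
#'
#' @param dist a marginal distribution object
#' @param n number of draws
#' @param seed optional integer; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched
#' @export
sample_dist <- function(dist, n, seed = NULL) {
  stopifnot(n >= 1)
  u <- with_seed(seed, stats::runif(n))
  dist_quantile(dist, u)
}

# Run code under a temporary RNG state when seed is non-NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- truncated parametric families (cohort generator) ----------------

cohort_families <- function() {
  c("logistic", "uniform", "exponential", "normal", "cauchy")
}

family_funs <- function(family) {
  switch(family,
    logistic = list(p = stats::plogis, q = stats::qlogis, d = stats::dlogis),
    normal = list(p = stats::pnorm, q = stats::qnorm, d = stats::dnorm),
    cauchy = list(p = stats::pcauchy, q = stats::qcauchy, d = stats::dcauchy),
    uniform = list(p = function(x, location, scale)
                     stats::punif(x, location, location + scale),
                   q = function(p, location, scale)
                     stats::qunif(p, location, location + scale),
                   d = function(x, location, scale)
                     stats::dunif(x, location, location + scale)),
    exponential = list(p = function(x, location, scale)
                         stats::pexp(x - location, rate = 1 / scale),
                       q = function(p, location, scale)
                         location + stats::qexp(p, rate = 1 / scale),
                       d = function(x, location, scale)
                         stats::dexp(x - location, rate = 1 / scale)),
    stop("unknown family: ", family))
}

#' Truncated location-scale family marginal
#'
#' One of the five candidate families (logistic, uniform, exponential,
#' normal, cauchy), truncated exactly to \code{[lo, hi]} by cdf
#' inversion.  Heavy-tailed families therefore carry no mass outside the
#' stated support.
#'
#' @param family family name
#' @param location,scale location and scale (for the uniform family the
#'   support is \code{[location, location + scale]}; for the exponential,
#'   \code{location} shifts the origin and \code{scale} is the mean)
#' @param lo,hi truncation bounds (finite)
#' @param name input name
#' @export
trunc_family <- function(family, location, scale, lo, hi, name = family) {
  family <- match.arg(family, cohort_families())
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("truncation bounds must be finite with lo < hi")
  if (scale <= 0) stop("scale must be positive")
  f <- family_funs(family)
  plo <- f$p(lo, location, scale)
  phi <- f$p(hi, location, scale)
  if (phi - plo <= 0) stop("infeasible bounds: no mass inside [lo, hi]")
  structure(list(family = family, location = location, scale = scale,
                 lo = lo, hi = hi, plo = plo, phi = phi, name = name),
            class = "trunc_family")
}

#' @export
dist_cdf.trunc_family <- function(dist, x) {
  f <- family_funs(dist$family)
  p <- (f$p(pmin(pmax(x, dist$lo), dist$hi), dist$location, dist$scale) -
          dist$plo) / (dist$phi - dist$plo)
  pmin(pmax(p, 0), 1)
}

#' @export
dist_pdf.trunc_family <- function(dist, x) {
  f <- family_funs(dist$family)
  out <- f$d(x, dist$location, dist$scale) / (dist$phi - dist$plo)
  out[x < dist$lo | x > dist$hi] <- 0
  out
}

#' @export
dist_quantile.trunc_family <- function(dist, p) {
  if (any(p < 0 | p > 1)) stop("probabilities outside [0,1]")
  f <- family_funs(dist$family)
  q <- f$q(dist$plo + p * (dist$phi - dist$plo), dist$location, dist$scale)
  pmin(pmax(q, dist$lo), dist$hi)
}

#' @export
print.trunc_family <- function(x, ...) {
  cat(sprintf("<trunc_family> %s: %s(location=%g, scale=%g) on [%g, %g]\n",
              x$name, x$family, x$location, x$scale, x$lo, x$hi))
  invisible(x)
}

#' Synthetic cohort specification
#'
#' Per-input truncated family, cohort size and seed.  The default spec
#' emulates the distribution families reported for the clinical cohort
#' (logistic, uniform, exponential, normal and several truncated
#' Cauchy inputs), with locations and scales placed once so that the
#' simulated pre-resection outputs fall predominantly inside the
#' physiological acceptance box of \code{\link{filter_bounds}}.
#'
#' @param n cohort size
#' @param seed integer seed
#' @param inputs named list of \code{\link{trunc_family}} objects, one
#'   per model input
#' @return list of class \code{cohort_spec}
#' @export
cohort_spec <- function(inputs, n = 100, seed = 1L) {
  stopifnot(is.list(inputs), all(vapply(inputs, inherits, TRUE,
                                        "trunc_family")))
  if (!all(input_names() %in% names(inputs)))
    stop("inputs must cover: ", paste(input_names(), collapse = ", "))
  structure(list(inputs = inputs[input_names()], n = as.integer(n),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function(n = 100, seed = 1L) {
  tf <- function(fam, loc, sc, lo, hi, nm)
    trunc_family(fam, loc, sc, lo, hi, name = nm)
  inputs <- list(
    Ea_RA = tf("logistic", 0.060, 0.012, 0.020, 0.120, "Ea_RA"),
    Eb_RA = tf("uniform", 0.030, 0.070, 0.030, 0.100, "Eb_RA"),
    Ea_LV = tf("exponential", 1.0, 1.5, 1.0, 7.0, "Ea_LV"),
    Eb_LV = tf("normal", 0.100, 0.050, 0.020, 0.280, "Eb_LV"),
    R_pv = tf("cauchy", 0.12, 0.08, 0.02, 0.90, "R_pv"),
    R_ha = tf("logistic", 20, 4, 8, 45, "R_ha"),
    R_hv = tf("cauchy", 0.19, 0.12, 0.04, 1.10, "R_hv"),
    R_DO = tf("logistic", 4.8, 1.4, 1.5, 10.0, "R_DO"),
    R_OO = tf("cauchy", 1.4, 0.45, 0.5, 4.0, "R_OO"),
    hpx = tf("cauchy", 0.35, 0.15, 0.05, 0.95, "hpx"))
  cohort_spec(inputs, n = n, seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n =", x$n, ", seed =", x$seed, "\n")
  for (d in x$inputs)
    cat(sprintf("  %-6s %-12s loc=%g scale=%g on [%g, %g]\n", d$name,
                d$family, d$location, d$scale, d$lo, d$hi))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Draws the ten inputs independently from the truncated families of the
#' spec by inverse-cdf sampling; all draws honor the truncation bounds
#' exactly and the result is reproducible given the seed.
#'
#' @param spec a \code{\link{cohort_spec}}
#' @param n,seed optional overrides of the spec's size and seed
#' @return data frame with one column per input
#' @export
generate_synthetic_cohort <- function(spec, n = spec$n, seed = spec$seed) {
  u <- with_seed(seed, matrix(stats::runif(n * length(spec$inputs)),
                              nrow = n))
  out <- as.data.frame(mapply(function(d, j) dist_quantile(d, u[, j]),
                              spec$inputs, seq_along(spec$inputs),
                              SIMPLIFY = FALSE))
  names(out) <- names(spec$inputs)
  out
}

#' Write / read a cohort table as CSV with a JSON units sidecar
#' @param cohort cohort data frame
#' @param path CSV path; the sidecar is written next to it
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  units <- c(Ea_RA = "mmHg/mL", Eb_RA = "mmHg/mL", Ea_LV = "mmHg/mL",
             Eb_LV = "mmHg/mL", R_pv = "mmHg.s/mL", R_ha = "mmHg.s/mL",
             R_hv = "mmHg.s/mL", R_DO = "mmHg.s/mL", R_OO = "mmHg.s/mL",
             hpx = "1")
  jsonlite::write_json(as.list(units[names(cohort)]),
                       paste0(sub("\\.csv$", "", path), "_units.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) utils::read.csv(path)

#' Best-fitting known family for a sample
#'
#' Maximum-likelihood fit of each of the five candidate families
#' (logistic, uniform, exponential, normal, cauchy), compared by BIC.
#' Ties are broken by the smaller number of parameters, then by the
#' fixed family order above.  Families whose support cannot contain the
#' sample (exponential with non-positive values) are skipped.
#'
#' @param samples numeric vector, at least 20 values
#' @return list with \code{family}, \code{estimate} (fitted parameters)
#'   and the per-family BIC table
#' @export
best_fit_family <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 20) stop("need at least 20 samples")
  n <- length(samples)
  fits <- list()
  # order = candidate order used for tie-breaking
  npar <- c(logistic = 2, uniform = 2, exponential = 1, normal = 2,
            cauchy = 2)
  for (fam in cohort_families()) {
    fit <- switch(fam,
      uniform = {
        r <- range(samples)
        list(estimate = c(min = r[1], max = r[2]),
             loglik = -n * log(diff(r)))
      },
      exponential = {
        if (any(samples <= 0)) NULL else {
          rate <- 1 / mean(samples)
          list(estimate = c(rate = rate),
               loglik = sum(stats::dexp(samples, rate, log = TRUE)))
        }
      },
      {
        f <- try(suppressWarnings(
          fitdistrplus::fitdist(samples, switch(fam, logistic = "logis",
                                                normal = "norm",
                                                cauchy = "cauchy"))),
          silent = TRUE)
        if (inherits(f, "try-error")) NULL
        else list(estimate = f$estimate, loglik = f$loglik)
      })
    if (!is.null(fit)) {
      fit$bic <- -2 * fit$loglik + npar[[fam]] * log(n)
      fits[[fam]] <- fit
    }
  }
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  k <- npar[names(fits)]
  ord <- order(bic, k, match(names(fits), cohort_families()))
  best <- names(fits)[ord[1]]
  list(family = best, estimate = fits[[best]]$estimate,
       bic = sort(bic))
}
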