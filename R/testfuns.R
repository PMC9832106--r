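# Analytic benchmark functions with known Sobol indices, used to
# validate both the pick-freeze estimator and the PCE route.

#' Ishigami benchmark function
#'
#' \code{sin(x1) + a sin(x2)^2 + b x3^4 sin(x1)} on uniform(-pi, pi)
#' inputs; its Sobol indices are known in closed form
#' (\code{\link{ishigami_indices}}).
#'
#' @param X matrix/data frame with three columns
#' @param a,b shape constants
#' @export
ishigami <- function(X, a = 7, b = 0.1) {
  X <- as.matrix(X)
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

#' @rdname ishigami
#' @return list with first (\code{S}) and total (\code{ST}) indices
#' @export
ishigami_indices <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * (1 / 18 - 1 / 50) # 8/225 * pi^8 * b^2 / ... kept explicit
  V <- v1 + v2 + v13
  list(S = c(v1 / V, v2 / V, 0),
       ST = c((v1 + v13) / V, v2 / V, v13 / V))
}

#' Uniform marginals on an interval, for benchmark designs
#' @param d dimension
#' @param lo,hi interval
#' @export
uniform_marginals <- function(d, lo = -pi, hi = pi) {
  ms <- lapply(seq_len(d), function(j)
    trunc_family("uniform", lo, hi - lo, lo, hi,
                 name = paste0("X", j)))
  names(ms) <- paste0("X", seq_len(d))
  ms
}
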