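# Sobol' low-discrepancy sequence (Gray-code construction) with
# direction numbers from the published Joe--Kuo D(6) table (dims 2-24;
# dimension 1 is the van der Corput sequence in base 2).  31 bits.
.jk <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1, m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 15, 13, 25)),
  list(s = 6, a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(s = 7, a = 1, m = c(1, 3, 7, 11, 23, 15, 103)),
  list(s = 7, a = 4, m = c(1, 3, 7, 13, 13, 15, 69)),
  list(s = 7, a = 7, m = c(1, 1, 3, 13, 7, 35, 63)),
  list(s = 7, a = 8, m = c(1, 3, 5, 9, 1, 25, 53)),
  list(s = 7, a = 14, m = c(1, 3, 1, 13, 9, 35, 107)))

.sobol_bits <- 31L

# direction-number matrix (bits x d), integer
sobol_directions <- function(d) {
  B <- .sobol_bits
  V <- matrix(0L, B, d)
  V[, 1] <- bitwShiftL(1L, B - seq_len(B)) # van der Corput
  for (j in seq_len(d - 1)) {
    if (j > length(.jk))
      stop("Sobol' direction numbers available up to dimension ",
           length(.jk) + 1)
    e <- .jk[[j]]
    s <- e$s
    v <- integer(B)
    v[seq_len(s)] <- as.integer(e$m * 2^(B - seq_len(s)))
    if (B > s) for (k in (s + 1):B) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1) for (i in seq_len(s - 1))
        if (bitwAnd(bitwShiftR(e$a, s - 1 - i), 1L) == 1L)
          vk <- bitwXor(vk, v[k - i])
      v[k] <- vk
    }
    V[, j + 1] <- v
  }
  V
}

#' Sobol' quasi-random sequence
#'
#' First \code{n} points of the \code{d}-dimensional Sobol' sequence in
#' the unit hypercube, optionally randomized by a digital shift keyed by
#' \code{seed} (each dimension XOR-ed with an independent random bit
#' vector, preserving the low-discrepancy structure).
#'
#' @param n number of points
#' @param d dimension (up to 24)
#' @param seed integer; when non-NULL the sequence is scrambled
#' @return an \code{n x d} matrix in \code{(0, 1)}
#' @export
sobol_sequence <- function(n, d, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  V <- sobol_directions(d)
  X <- matrix(0L, n, d)
  cur <- integer(d)
  for (i in seq_len(n)) {
    if (i > 1) {
      k <- i - 2 # Gray-code: flip the lowest zero bit of i-2
      c <- 1L
      while (k %% 2 == 1) { k <- k %/% 2; c <- c + 1L }
      cur <- bitwXor(cur, V[c, ])
    }
    X[i, ] <- cur
  }
  if (!is.null(seed)) {
    shift <- with_seed(seed,
      as.integer(floor(stats::runif(d) * 2^.sobol_bits)))
    for (j in seq_len(d)) X[, j] <- bitwXor(X[, j], shift[j])
  }
  (X + 0.5) / 2^.sobol_bits
}

#' Saltelli pick-freeze design
#'
#' Builds the paired sample matrices A, B and the hybrid matrices AB_j
#' (A with column j replaced from B) that allow first and total order
#' Sobol indices for all \code{d} inputs at a cost of \code{(d+2)*N}
#' model evaluations.  Base points are a scrambled Sobol' sequence in
#' dimension \code{2d}, mapped through the marginal inverse cdfs.
#'
#' @param marginals named list of marginal distributions (objects
#'   understood by \code{\link{dist_quantile}})
#' @param N base sample size (>= 2)
#' @param seed integer scrambling seed
#' @return object of class \code{saltelli_design}
#' @export
build_saltelli_design <- function(marginals, N, seed = 1L) {
  stopifnot(N >= 2, length(marginals) >= 1)
  d <- length(marginals)
  nm <- names(marginals)
  if (is.null(nm)) nm <- paste0("X", seq_len(d))
  U <- sobol_sequence(N, 2 * d, seed = seed)
  A <- matrix(0, N, d, dimnames = list(NULL, nm))
  B <- A
  for (j in seq_len(d)) {
    A[, j] <- dist_quantile(marginals[[j]], U[, j])
    B[, j] <- dist_quantile(marginals[[j]], U[, d + j])
  }
  AB <- lapply(seq_len(d), function(j) { M <- A; M[, j] <- B[, j]; M })
  names(AB) <- nm
  structure(list(A = A, B = B, AB = AB, N = N, d = d, seed = seed,
                 names = nm),
            class = "saltelli_design")
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat("<saltelli_design> d =", x$d, ", N =", x$N, "->",
      (x$d + 2) * x$N, "evaluation points\n")
  invisible(x)
}

#' All evaluation points of a Saltelli design
#'
#' Stacks A, B and the AB_j blocks into a single \code{(d+2)N x d}
#' matrix; the block label of every row is attached as attribute
#' \code{block}.
#' @param design a \code{saltelli_design}
#' @export
design_points <- function(design) {
  M <- rbind(design$A, design$B, do.call(rbind, design$AB))
  attr(M, "block") <- c(rep("A", design$N), rep("B", design$N),
                        rep(paste0("AB_", design$names),
                            each = design$N))
  M
}

#' Pick-freeze estimation of first and total Sobol indices
#'
#' Saltelli-2010 estimator for the first order index,
#' \code{S_j = mean(Y_B * (Y_ABj - Y_A)) / var(Y)}, and the Jansen
#' estimator for the total index,
#' \code{ST_j = mean((Y_A - Y_ABj)^2) / (2 var(Y))}.  Small negative
#' estimates (Monte-Carlo noise) are reported as-is.
#'
#' @param design a \code{\link{build_saltelli_design}} result
#' @param outputs numeric vector or matrix with one row per design point
#'   (A block first, then B, then the AB_j blocks) and one column per
#'   model output
#' @return object of class \code{sobol_estimate} with matrices \code{S}
#'   and \code{ST} (outputs x inputs)
#' @export
estimate_sobol <- function(design, outputs) {
  Y <- as.matrix(outputs)
  N <- design$N; d <- design$d
  if (nrow(Y) != (d + 2) * N)
    stop("outputs must have (d+2)*N = ", (d + 2) * N, " rows")
  if (anyNA(Y)) stop("outputs contain missing values; ",
                     "failed rows are not allowed in the pick-freeze estimator")
  nout <- ncol(Y)
  onm <- colnames(Y)
  if (is.null(onm)) onm <- paste0("Y", seq_len(nout))
  YA <- Y[seq_len(N), , drop = FALSE]
  YB <- Y[N + seq_len(N), , drop = FALSE]
  S <- matrix(NA_real_, nout, d, dimnames = list(onm, design$names))
  ST <- S
  v <- apply(rbind(YA, YB), 2, stats::var)
  if (any(v <= 0)) stop("constant output: zero variance")
  for (j in seq_len(d)) {
    YABj <- Y[(1 + j) * N + seq_len(N), , drop = FALSE]
    S[, j] <- colMeans(YB * (YABj - YA)) / v
    ST[, j] <- colMeans((YA - YABj)^2) / (2 * v)
  }
  structure(list(S = S, ST = ST, N = N, d = d, seed = design$seed,
                 var = v, outputs = onm, method = "pick-freeze"),
            class = "sobol_estimate")
}

#' @export
print.sobol_estimate <- function(x, ...) {
  cat("<sobol_estimate>", x$method, "- N =", x$N, "\nFirst order:\n")
  print(round(x$S, 3))
  cat("Total order:\n")
  print(round(x$ST, 3))
  invisible(x)
}

#' Convergence error between two Sobol estimates
#'
#' Per output, the maximum over inputs of the absolute difference of the
#' first order indices (and separately of the total order indices)
#' between two estimates of the same quantities at different base sizes.
#'
#' @param est1,est2 \code{sobol_estimate} objects over identical
#'   input/output sets
#' @return data frame with \code{err_first} and \code{err_total} per
#'   output; symmetric in its arguments
#' @export
convergence_error <- function(est1, est2) {
  if (!identical(dimnames(est1$S), dimnames(est2$S)))
    stop("estimates cover different input/output sets")
  data.frame(output = rownames(est1$S),
             err_first = apply(abs(est1$S - est2$S), 1, max),
             err_total = apply(abs(est1$ST - est2$ST), 1, max),
             row.names = NULL)
}

#' Repeat-based confidence intervals for Sobol indices
#'
#' Percentile confidence intervals across independently seeded repeat
#' estimates of the same design size.
#'
#' @param estimates list of >= 2 \code{sobol_estimate} objects with
#'   identical N and index sets
#' @param level confidence level
#' @return list with arrays \code{mean}, \code{lower}, \code{upper} for
#'   first (\code{S}) and total (\code{ST}) indices
#' @export
confidence_intervals <- function(estimates, level = 0.95) {
  if (length(estimates) < 2) stop("need at least 2 repeat estimates")
  Ns <- vapply(estimates, `[[`, numeric(1), "N")
  if (length(unique(Ns)) != 1) stop("repeats must share the same N")
  a <- (1 - level) / 2
  summ <- function(field) {
    arr <- simplify2array(lapply(estimates, `[[`, field))
    list(mean = apply(arr, c(1, 2), mean),
         lower = apply(arr, c(1, 2), stats::quantile, probs = a),
         upper = apply(arr, c(1, 2), stats::quantile, probs = 1 - a))
  }
  list(S = summ("S"), ST = summ("ST"), level = level,
       repeats = length(estimates))
}

#' Classify inputs as sensitive / insensitive per output
#'
#' Operationalizes the usual qualitative reading of Sobol tables:
#' \emph{sensitive} when the first order index is well above 0.1,
#' \emph{fairly sensitive} when first and total indices sit together
#' around 0.1, \emph{insensitive} when the total index is approximately
#' zero, \emph{intermediate} otherwise.  Raw (possibly slightly
#' negative) estimates are classified without clipping.
#'
#' @param est a \code{sobol_estimate}
#' @param sensitive first-order threshold for "sensitive"
#' @param fair lower first-order threshold for "fairly sensitive"
#'   (with first and total indices within \code{gap} of each other)
#' @param insensitive total-order threshold for "insensitive"
#' @param gap maximum |ST - S| for "fairly sensitive"
#' @return character matrix (outputs x inputs)
#' @export
classify_sensitivity <- function(est, sensitive = 0.2, fair = 0.05,
                                 insensitive = 0.05, gap = 0.05) {
  lab <- matrix("intermediate", nrow(est$S), ncol(est$S),
                dimnames = dimnames(est$S))
  lab[est$S >= fair & est$S < sensitive &
        abs(est$ST - est$S) < gap] <- "fairly sensitive"
  lab[est$ST < insensitive] <- "insensitive"
  lab[est$S >= sensitive] <- "sensitive"
  lab
}
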