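#' Orthonormal polynomial recurrence from sample moments (discrete
#' Stieltjes procedure)
#'
#' Builds the three-term recurrence of the polynomials orthonormal with
#' respect to the empirical measure of \code{samples}, degree 0..q:
#' \deqn{b_{k+1} \psi_{k+1}(x) = (x - a_k)\psi_k(x) - b_k \psi_{k-1}(x)}
#' with \eqn{\psi_0 = 1}.  Coefficients are computed iteratively on the
#' sample values; if the empirical Gram matrix of the generated basis
#' deviates from identity by more than \code{gram_tol}, up to two
#' refinement passes re-orthogonalize the basis columns (full
#' Gram-Schmidt against all lower degrees) and refit the recurrence from
#' the exact inner products \eqn{a_k = \langle x\psi_k, \psi_k\rangle},
#' \eqn{b_k = \langle x\psi_{k-1}, \psi_k\rangle}.
#'
#' @param samples numeric vector; at least \code{50*q} values
#' @param q maximum degree
#' @param gram_tol per-entry tolerance on the empirical Gram matrix
#' @param name input name
#' @return object of class \code{pce_basis1d} with recurrence
#'   coefficients \code{alpha} (length q) and \code{beta} (length q)
#' @export
stieltjes_recurrence <- function(samples, q, gram_tol = 5e-2,
                                 name = "x") {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 50 * q) stop("need at least 50*q = ", 50 * q, " samples")
  if (any(!is.finite(x))) stop("non-finite samples")
  if (stats::sd(x) == 0) stop("degenerate samples: zero spread")

  build <- function() {
    Psi <- matrix(0, n, q + 1)
    Psi[, 1] <- 1
    alpha <- numeric(q); beta <- numeric(q)
    for (k in 0:(q - 1)) {
      pk <- Psi[, k + 1]
      alpha[k + 1] <- mean(x * pk * pk)
      t <- (x - alpha[k + 1]) * pk
      if (k > 0) t <- t - beta[k] * Psi[, k]
      bk1 <- sqrt(mean(t * t))
      if (!is.finite(bk1) || bk1 < 1e-12 * max(1, stats::sd(x)))
        stop("measure does not support degree ", k + 1,
             " (too few distinct samples)")
      beta[k + 1] <- bk1
      Psi[, k + 2] <- t / bk1
    }
    list(Psi = Psi, alpha = alpha, beta = beta)
  }
  b <- build()
  gram_dev <- function(Psi) max(abs(crossprod(Psi) / n -
                                      diag(ncol(Psi))))
  pass <- 0
  while (gram_dev(b$Psi) > gram_tol && pass < 2) {
    # full re-orthogonalization, then exact refit of the recurrence
    Psi <- b$Psi
    for (k in seq_len(q)) {
      v <- Psi[, k + 1]
      for (j in seq_len(k)) {
        v <- v - mean(v * Psi[, j]) * Psi[, j]
      }
      Psi[, k + 1] <- v / sqrt(mean(v * v))
    }
    alpha <- numeric(q); beta <- numeric(q)
    for (k in 0:(q - 1)) {
      alpha[k + 1] <- mean(x * Psi[, k + 1]^2)
      beta[k + 1] <- mean(x * Psi[, k + 1] * Psi[, k + 2])
    }
    b <- list(Psi = Psi, alpha = alpha, beta = beta)
    pass <- pass + 1
  }
  structure(list(name = name, q = q, alpha = b$alpha, beta = b$beta,
                 n = n, gram_dev = gram_dev(b$Psi)),
            class = "pce_basis1d")
}

#' Evaluate an orthonormal 1-D basis at new points
#' @param basis a \code{pce_basis1d}
#' @param x evaluation points
#' @return matrix \code{length(x) x (q+1)}, degree 0 first
#' @export
eval_basis1d <- function(basis, x) {
  q <- basis$q
  P <- matrix(0, length(x), q + 1)
  P[, 1] <- 1
  if (q >= 1) P[, 2] <- (x - basis$alpha[1]) / basis$beta[1]
  if (q >= 2) for (k in 2:q) {
    P[, k + 1] <- ((x - basis$alpha[k]) * P[, k] -
                     basis$beta[k - 1] * P[, k - 1]) / basis$beta[k]
  }
  P
}

#' @export
print.pce_basis1d <- function(x, ...) {
  cat("<pce_basis1d>", x$name, "degree", x$q, "on", x$n,
      "samples, Gram deviation", format(x$gram_dev, digits = 3), "\n")
  invisible(x)
}

#' Total-degree multi-index set
#'
#' All d-dimensional multi-indices with total degree <= q, in graded
#' lexicographic order (zero index first).  Cardinality
#' \code{choose(d+q, q)}.
#'
#' @param d dimension
#' @param q maximum total degree
#' @return integer matrix, one row per multi-index
#' @export
multi_index_set <- function(d, q) {
  stopifnot(d >= 1, q >= 0)
  rows <- list(integer(d))
  compositions <- function(total, parts) {
    if (parts == 1) return(list(total))
    out <- list()
    for (first in total:0)
      for (rest in compositions(total - first, parts - 1))
        out[[length(out) + 1]] <- c(first, rest)
    out
  }
  for (deg in seq_len(q))
    rows <- c(rows, compositions(deg, d))
  M <- do.call(rbind, rows)
  storage.mode(M) <- "integer"
  M
}

#' Tensorized orthonormal basis for all inputs
#'
#' Builds one \code{\link{stieltjes_recurrence}} basis per input column
#' and the total-degree multi-index set; multivariate basis functions
#' are products of the per-input orthonormal polynomials.
#'
#' @param samples data frame or matrix of input samples (the build
#'   measure), one column per input
#' @param q maximum total degree
#' @param gram_tol passed to \code{\link{stieltjes_recurrence}}
#' @return object of class \code{pce_basis}
#' @export
build_pce_basis <- function(samples, q, gram_tol = 5e-2) {
  X <- as.matrix(samples)
  d <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("X", seq_len(d))
  bases <- lapply(seq_len(d), function(j)
    stieltjes_recurrence(X[, j], q, gram_tol = gram_tol, name = nm[j]))
  names(bases) <- nm
  structure(list(bases = bases, indices = multi_index_set(d, q),
                 d = d, q = q, names = nm),
            class = "pce_basis")
}

#' @export
print.pce_basis <- function(x, ...) {
  cat("<pce_basis> d =", x$d, ", degree", x$q, "->",
      nrow(x$indices), "basis functions\n")
  invisible(x)
}

# multivariate design matrix: n x P
pce_design_matrix <- function(basis, X) {
  X <- as.matrix(X)
  if (ncol(X) != basis$d) stop("input dimension mismatch")
  per_dim <- lapply(seq_len(basis$d), function(j)
    eval_basis1d(basis$bases[[j]], X[, j]))
  M <- basis$indices
  P <- nrow(M)
  Psi <- matrix(1, nrow(X), P)
  for (k in seq_len(P))
    for (j in which(M[k, ] > 0L))
      Psi[, k] <- Psi[, k] * per_dim[[j]][, M[k, j] + 1L]
  Psi
}

#' Least-squares polynomial chaos surrogate
#'
#' Fits the expansion coefficients of each output on the tensorized
#' orthonormal basis by least squares.  Requires at least twice as many
#' training rows as basis functions.  If the design is severely
#' ill-conditioned (condition number above \code{cond_limit}) a small
#' ridge damping of \code{1e-8 * trace(Psi'Psi)} is applied with a
#' warning.
#'
#' @param inputs training inputs (rows aligned with \code{outputs})
#' @param outputs numeric vector or matrix of model outputs
#' @param basis a \code{\link{build_pce_basis}} result (typically built
#'   on the same, possibly filtered, training inputs)
#' @param cond_limit condition-number threshold for ridge damping
#' @return object of class \code{pce_surrogate}
#' @export
fit_pce <- function(inputs, outputs, basis, cond_limit = 1e10) {
  X <- as.matrix(inputs)
  Y <- as.matrix(outputs)
  if (nrow(X) != nrow(Y)) stop("inputs/outputs not row-aligned")
  P <- nrow(basis$indices)
  if (nrow(X) < 2 * P)
    stop("underdetermined fit: need at least ", 2 * P,
         " training rows for ", P, " basis functions, got ", nrow(X))
  Psi <- pce_design_matrix(basis, X)
  qrd <- qr(Psi, LAPACK = TRUE)
  R <- qr.R(qrd)
  cond <- kappa(R, exact = FALSE)
  if (is.finite(cond) && cond > cond_limit) {
    warning("ill-conditioned PCE design (cond ~ ", format(cond),
            "); applying ridge damping")
    G <- crossprod(Psi)
    lam <- 1e-8 * sum(diag(G))
    beta <- solve(G + diag(lam, P), crossprod(Psi, Y))
  } else {
    beta <- qr.coef(qrd, Y)
  }
  beta <- as.matrix(beta)
  onm <- colnames(Y)
  if (is.null(onm)) onm <- paste0("Y", seq_len(ncol(Y)))
  colnames(beta) <- onm
  resid <- Y - Psi %*% beta
  structure(list(basis = basis, beta = beta, n_train = nrow(X),
                 cond = cond, outputs = onm,
                 resid_rms = sqrt(colMeans(resid^2)),
                 train_key = row_keys(X)),
            class = "pce_surrogate")
}

# canonical row fingerprints used to enforce train/test disjointness
row_keys <- function(X) {
  apply(signif(as.matrix(X), 12), 1, paste, collapse = "|")
}

#' @export
print.pce_surrogate <- function(x, ...) {
  cat("<pce_surrogate> degree", x$basis$q, ",", nrow(x$basis$indices),
      "terms,", x$n_train, "training rows\n  residual RMS:",
      paste(x$outputs, format(x$resid_rms, digits = 3), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @param object a \code{pce_surrogate}
#' @param newdata matrix/data frame of inputs
#' @param chunk rows evaluated per block (bounds the memory of the
#'   transient design matrix on large designs)
#' @param ... unused
#' @rdname fit_pce
#' @export
predict.pce_surrogate <- function(object, newdata, chunk = 16384L, ...) {
  X <- as.matrix(newdata)
  n <- nrow(X)
  out <- matrix(0, n, ncol(object$beta),
                dimnames = list(NULL, colnames(object$beta)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    out[s:e, ] <- pce_design_matrix(object$basis,
                                    X[s:e, , drop = FALSE]) %*% object$beta
  }
  out
}

#' Analytic Sobol indices from PCE coefficients
#'
#' By orthonormality (Parseval), the output variance is the sum of the
#' squared coefficients over nonzero multi-indices; the first order
#' index of input j collects multi-indices involving only input j, the
#' total index all multi-indices with a nonzero power of input j.
#'
#' @param surrogate a fitted \code{\link{fit_pce}} surrogate
#' @return a \code{sobol_estimate} (method \code{"pce"})
#' @export
sobol_from_pce <- function(surrogate) {
  M <- surrogate$basis$indices
  beta <- surrogate$beta
  d <- ncol(M)
  nout <- ncol(beta)
  b2 <- beta[-1, , drop = FALSE]^2
  Mi <- M[-1, , drop = FALSE]
  V <- colSums(b2)
  if (any(V <= 0)) stop("constant output: zero total variance")
  S <- matrix(0, nout, d,
              dimnames = list(surrogate$outputs, surrogate$basis$names))
  ST <- S
  for (j in seq_len(d)) {
    only_j <- Mi[, j] > 0L & rowSums(Mi > 0L) == 1L
    any_j <- Mi[, j] > 0L
    S[, j] <- colSums(b2[only_j, , drop = FALSE]) / V
    ST[, j] <- colSums(b2[any_j, , drop = FALSE]) / V
  }
  structure(list(S = S, ST = ST, N = surrogate$n_train, d = d,
                 seed = NA_integer_, var = V,
                 outputs = surrogate$outputs, method = "pce"),
            class = "sobol_estimate")
}

#' Predictive squared correlation coefficient on held-out data
#'
#' \deqn{Q^2 = 1 - \sum_l (Y^{(l)} - \hat Y^{(l)})^2 /
#'   (N_{test} \mathrm{var}(Y))}
#' computed per output on a test set that must be disjoint from the
#' training set (enforced on the row values).
#'
#' @param surrogate a fitted \code{pce_surrogate}
#' @param inputs,outputs held-out test rows
#' @return data frame with \code{output}, \code{Q2}, \code{n_test}
#' @export
q2_score <- function(surrogate, inputs, outputs) {
  X <- as.matrix(inputs)
  Y <- as.matrix(outputs)
  if (nrow(X) < 2) stop("need at least 2 test rows")
  if (any(row_keys(X) %in% surrogate$train_key))
    stop("test set overlaps the training set")
  v <- apply(Y, 2, stats::var)
  if (any(v <= 0)) stop("zero test variance")
  pred <- predict(surrogate, X)
  q2 <- 1 - colSums((Y - pred)^2) / (nrow(Y) * v)
  data.frame(output = surrogate$outputs, Q2 = as.numeric(q2),
             n_test = nrow(Y), row.names = NULL)
}
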