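#' Univariate REML for linear mixed models with known covariance structures
#'
#' Restricted maximum likelihood for `y = Xb + sum_k Z_k u_k + e`, with
#' `u_k ~ N(0, S_k * theta_k)` for a known structure `S_k` (e.g. a pedigree
#' numerator relationship matrix, or an identity for litter, judge or session
#' effects) and `e ~ N(0, I * theta_e)`. The optimiser takes
#' average-information (AI) Newton steps with step-halving, falling back on
#' an expectation-maximization-style update when a proposed step leaves the
#' parameter space or decreases the restricted likelihood. Variance
#' components are kept at or above a lower boundary of `1e-6` times the
#' phenotypic variance; convergence requires the restricted log-likelihood
#' change below `tol_ll` and the relative component change below `tol_par`.
#'
#' @param y numeric response vector (no missing values).
#' @param X fixed-effect design matrix, full column rank.
#' @param random named list of random terms. Each term is a list with either
#'   `Z` (n x q incidence matrix) and optional `S` (q x q covariance
#'   structure, default identity), or a precomputed `M = Z S Z'` (n x n) with
#'   `q` (number of levels, used by the EM fallback).
#' @param maxit maximum number of iterations (default 200).
#' @param tol_ll absolute restricted log-likelihood convergence tolerance.
#' @param tol_par relative parameter-change convergence tolerance.
#' @param verbose print the iteration trace?
#' @return object of class `reml_fit`: list with `theta` (named variance
#'   components, last element `residual`), `vcov_theta` (inverse AI matrix),
#'   `beta` and `vcov_beta` (GLS fixed effects), `loglik` (restricted),
#'   `converged`, `iterations`, `ai_matrix`, `boundary` (logical per
#'   component), `gradient`, and bookkeeping (`n`, `p`, `lb`).
#' @seealso [reml_bivariate()] for two-trait models, [fit_animal_model()]
#'   for the pedigree front end.
#' @export
reml_fit <- function(y, X, random = list(), maxit = 200,
                     tol_ll = 1e-8, tol_par = 1e-6, verbose = FALSE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y))
  if (qr(X)$rank < ncol(X)) {
    stop("X is rank deficient; drop aliased columns before fitting")
  }
  prep <- lapply(random, function(term) {
    if (!is.null(term$M)) {
      list(M = as.matrix(term$M), q = if (!is.null(term$q)) term$q else nrow(term$M))
    } else {
      Z <- as.matrix(term$Z)
      M <- if (is.null(term$S)) tcrossprod(Z) else Z %*% as.matrix(term$S) %*% t(Z)
      list(M = M, q = ncol(Z))
    }
  })
  m <- length(prep)
  labels <- c(if (m) (if (is.null(names(random))) paste0("term", seq_len(m))
                      else names(random)), "residual")

  ols <- stats::lm.fit(X, y)
  vp0 <- sum(ols$residuals^2) / max(1, n - ncol(X))
  lb <- 1e-6 * vp0
  theta <- numeric(m + 1)
  if (m >= 1) theta[1] <- vp0 / 3
  if (m >= 2) theta[2:m] <- vp0 / 10
  theta[m + 1] <- max(vp0 - sum(theta[seq_len(m)]), vp0 / 3)
  names(theta) <- labels
  qlev <- c(vapply(prep, `[[`, 0, "q"), n)

  quantities <- function(theta) {
    V <- diag(theta[m + 1], n)
    for (k in seq_len(m)) V <- V + theta[k] * prep[[k]]$M
    cV <- tryCatch(chol(V), error = function(e)
      stop("phenotypic (co)variance matrix is singular", call. = FALSE))
    Vinv <- chol2inv(cV)
    VX <- Vinv %*% X
    XVX <- crossprod(X, VX)
    cX <- chol(XVX)
    XVXinv <- chol2inv(cX)
    Viy <- Vinv %*% y
    beta <- drop(XVXinv %*% crossprod(X, Viy))
    Py <- drop(Viy - VX %*% (XVXinv %*% crossprod(X, Viy)))
    yPy <- sum(y * Py)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + yPy)

    nk <- m + 1
    grad <- quad <- trPM <- numeric(nk)
    U <- matrix(0, n, nk)
    for (k in seq_len(nk)) {
      if (k <= m) {
        Mk <- prep[[k]]$M
        trVM <- sum(Vinv * Mk)
        MVX <- Mk %*% VX
        u <- drop(Mk %*% Py)
      } else {
        trVM <- sum(diag(Vinv))
        MVX <- VX
        u <- Py
      }
      trPM[k] <- trVM - sum(XVXinv * crossprod(VX, MVX))
      U[, k] <- u
      quad[k] <- sum(Py * u)
      grad[k] <- -0.5 * (trPM[k] - quad[k])
    }
    VinvU <- Vinv %*% U
    PU <- VinvU - VX %*% (XVXinv %*% crossprod(VX, U))
    AI <- 0.5 * crossprod(U, PU)
    AI <- (AI + t(AI)) / 2
    list(ll = ll, grad = grad, AI = AI, quad = quad, trPM = trPM,
         beta = beta, vcov_beta = XVXinv, Py = Py)
  }

  ll_only <- function(theta) {
    V <- diag(theta[m + 1], n)
    for (k in seq_len(m)) V <- V + theta[k] * prep[[k]]$M
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(-Inf)
    Vy <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
    VXl <- backsolve(cV, backsolve(cV, X, transpose = TRUE))
    XVX <- crossprod(X, VXl)
    cX <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(cX)) return(-Inf)
    Py <- Vy - VXl %*% (chol2inv(cX) %*% crossprod(X, Vy))
    -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + sum(y * Py))
  }

  em_step <- function(theta, q) {
    cand <- theta + theta^2 / qlev * (q$quad - q$trPM)
    pmax(cand, lb)
  }

  converged <- FALSE
  ll_prev <- -Inf
  rel_change <- Inf
  stall <- 0L
  it <- 0
  repeat {
    it <- it + 1
    q <- quantities(theta)
    if (verbose) {
      cat(sprintf("iter %3d  logL %.8f  theta %s\n", it, q$ll,
                  paste(signif(theta, 5), collapse = " ")))
    }
    stall <- if (it > 1 && abs(q$ll - ll_prev) < tol_ll) stall + 1L else 0L
    if (it > 1 && stall >= 1L && rel_change < tol_par) {
      converged <- TRUE
      break
    }
    if (stall >= 3L) {  # flat likelihood with only boundary re-projection left
      converged <- TRUE
      break
    }
    if (it >= maxit) break
    if (it == 1) {
      cand <- em_step(theta, q)
    } else {
      delta <- tryCatch(solve(q$AI, q$grad), error = function(e) NULL)
      cand <- NULL
      if (!is.null(delta)) {
        step <- 1
        for (h in 1:12) {
          trial <- pmax(theta + step * delta, lb)
          if (ll_only(trial) >= q$ll - 1e-10) {
            cand <- trial
            break
          }
          step <- step / 2
        }
      }
      if (is.null(cand)) {
        cand <- em_step(theta, q)
        # EM is monotone: a vanishing gain means a (boundary) optimum
        if (ll_only(cand) - q$ll < tol_ll) {
          theta <- cand
          converged <- TRUE
          break
        }
      }
    }
    rel_change <- max(abs(cand - theta) / pmax(abs(theta), 1e-4 * vp0))
    ll_prev <- q$ll
    theta <- cand
  }

  vcov_theta <- tryCatch(solve(q$AI), error = function(e) {
    warning("average-information matrix is singular; component SEs undefined",
            call. = FALSE)
    matrix(NA_real_, m + 1, m + 1)
  })
  dimnames(vcov_theta) <- list(labels, labels)
  dimnames(q$AI) <- list(labels, labels)
  beta <- q$beta
  names(beta) <- colnames(X)

  structure(list(theta = theta, vcov_theta = vcov_theta, beta = beta,
                 vcov_beta = q$vcov_beta, loglik = q$ll, converged = converged,
                 iterations = it, ai_matrix = q$AI, gradient = q$grad,
                 boundary = theta <= lb * (1 + 1e-8), n = n, p = ncol(X),
                 lb = lb, term_labels = labels),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", x$n, "records,", x$p, "fixed-effect columns\n")
  cat("restricted logL:", format(x$loglik, digits = 10),
      if (x$converged) sprintf("(converged in %d iterations)", x$iterations)
      else sprintf("(NOT converged after %d iterations)", x$iterations), "\n")
  se <- sqrt(pmax(diag(x$vcov_theta), 0))
  tab <- data.frame(component = names(x$theta),
                    estimate = signif(x$theta, 5),
                    se = signif(se, 3),
                    boundary = x$boundary)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bivariate REML with unstructured trait covariance matrices
#'
#' Two-trait extension of [reml_fit()]: each random term and the residual
#' carry an unstructured 2 x 2 (co)variance matrix. Records missing one trait
#' are retained for the other (the likelihood is taken over the observed
#' entries only). Correlations are clamped to [-0.999, 0.999] and variances
#' to the lower boundary during optimisation.
#'
#' @param Y n x 2 matrix (one column per trait), `NA` = trait not observed.
#' @param X fixed-effect design matrix shared by both traits, or a list of
#'   two matrices (one per trait), full rank on each trait's observed rows.
#' @param terms named list of random terms; each term is a list with
#'   `M` (n x n structure `Z S Z'` over all records) and optionally `q`.
#' @param fix_cov logical: fix all between-trait covariances at zero (used
#'   to compare against univariate margins).
#' @param maxit,tol_ll,tol_par,verbose as in [reml_fit()].
#' @return object of class `reml_biv` (and `reml_fit`): as [reml_fit()], with
#'   `theta` holding `term.11`, `term.12`, `term.22` entries per term plus the
#'   residual, and `K` a list of the fitted 2 x 2 matrices.
#' @export
reml_bivariate <- function(Y, X, terms = list(), fix_cov = FALSE,
                           maxit = 200, tol_ll = 1e-8, tol_par = 1e-6,
                           verbose = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2)
  n0 <- nrow(Y)
  Xs <- if (is.list(X)) X else list(X, X)
  Xs <- lapply(Xs, as.matrix)
  o1 <- which(!is.na(Y[, 1]))
  o2 <- which(!is.na(Y[, 2]))
  if (!length(o1) || !length(o2)) stop("each trait needs at least one record")
  n1 <- length(o1); n2 <- length(o2); N <- n1 + n2
  r1 <- seq_len(n1); r2 <- n1 + seq_len(n2)
  y <- c(Y[o1, 1], Y[o2, 2])

  X1 <- Xs[[1]][o1, , drop = FALSE]
  X2 <- Xs[[2]][o2, , drop = FALSE]
  for (Xt in list(X1, X2)) {
    if (qr(Xt)$rank < ncol(Xt)) {
      stop("X is rank deficient on a trait's observed rows")
    }
  }
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))
  p <- ncol(X)

  # per-term observed-row blocks; residual handled via the shared-record map
  mterm <- length(terms)
  labels <- if (mterm) {
    if (is.null(names(terms))) paste0("term", seq_len(mterm)) else names(terms)
  } else character(0)
  blocks <- lapply(terms, function(term) {
    M <- as.matrix(term$M)
    stopifnot(nrow(M) == n0)
    list(B11 = M[o1, o1, drop = FALSE], B22 = M[o2, o2, drop = FALSE],
         B12 = M[o1, o2, drop = FALSE],
         q = if (!is.null(term$q)) term$q else n0)
  })
  shared <- intersect(o1, o2)
  E12 <- matrix(0, n1, n2)
  if (length(shared)) E12[cbind(match(shared, o1), match(shared, o2))] <- 1
  blocks <- c(blocks, list(list(B11 = diag(n1), B22 = diag(n2), B12 = E12,
                                q = n0)))
  labels <- c(labels, "residual")
  nterm <- mterm + 1

  # parameter vector: (k.11, k.12, k.22) per term; covariances maskable
  par_names <- as.vector(t(outer(labels, c("11", "12", "22"),
                                 function(a, b) paste(a, b, sep = "."))))
  is_cov <- grepl("\\.12$", par_names)
  free <- if (fix_cov) which(!is_cov) else seq_along(par_names)

  vp0 <- vapply(1:2, function(t) {
    r <- stats::lm.fit(if (t == 1) X1 else X2, Y[if (t == 1) o1 else o2, t])$residuals
    sum(r^2) / max(1, length(r) - ncol(X1))
  }, 0)
  lb <- 1e-6 * vp0

  theta <- numeric(length(par_names))
  names(theta) <- par_names
  for (k in seq_len(nterm)) {
    share <- if (k == 1 && nterm > 1) 1 / 3
             else if (k < nterm) 1 / 10
             else 1 - (if (nterm > 1) 1 / 3 + (nterm - 2) / 10 else 0)
    v1 <- share * vp0[1]; v2 <- share * vp0[2]
    theta[3 * k - 2] <- v1
    theta[3 * k] <- v2
    if (!fix_cov) theta[3 * k - 1] <- 0.5 * sqrt(v1 * v2)
  }

  kmat <- function(theta, k) {
    matrix(c(theta[3 * k - 2], theta[3 * k - 1],
             theta[3 * k - 1], theta[3 * k]), 2, 2)
  }

  project <- function(theta) {
    for (k in seq_len(nterm)) {
      i11 <- 3 * k - 2; i12 <- 3 * k - 1; i22 <- 3 * k
      theta[i11] <- max(theta[i11], lb[1])
      theta[i22] <- max(theta[i22], lb[2])
      cap <- 0.999 * sqrt(theta[i11] * theta[i22])
      if (!fix_cov) theta[i12] <- min(max(theta[i12], -cap), cap) else theta[i12] <- 0
    }
    theta
  }
  theta <- project(theta)

  # V assembled blockwise (plain axpy on the three trait blocks) to avoid
  # repeated big-submatrix assignment
  build_V <- function(theta) {
    V11 <- matrix(0, n1, n1); V22 <- matrix(0, n2, n2); V12 <- matrix(0, n1, n2)
    for (k in seq_len(nterm)) {
      b <- blocks[[k]]
      V11 <- V11 + theta[3 * k - 2] * b$B11
      V22 <- V22 + theta[3 * k] * b$B22
      if (theta[3 * k - 1] != 0) V12 <- V12 + theta[3 * k - 1] * b$B12
    }
    rbind(cbind(V11, V12), cbind(t(V12), V22))
  }

  # Q_pi %*% W for parameter pi = (k, ab); W pre-split into its trait rows
  mulQ <- function(k, ab, W1, W2) {
    b <- blocks[[k]]
    if (ab == 1L) {
      rbind(b$B11 %*% W1, matrix(0, n2, ncol(W1)))
    } else if (ab == 3L) {
      rbind(matrix(0, n1, ncol(W1)), b$B22 %*% W2)
    } else {
      rbind(b$B12 %*% W2, crossprod(b$B12, W1))
    }
  }

  quantities <- function(theta, cV = NULL) {
    if (is.null(cV)) {
      V <- build_V(theta)
      cV <- tryCatch(chol(V), error = function(e)
        stop("phenotypic (co)variance matrix is singular", call. = FALSE))
    }
    Vinv <- chol2inv(cV)
    Vi11 <- Vinv[r1, r1]; Vi12 <- Vinv[r1, r2]; Vi22 <- Vinv[r2, r2]
    VX <- Vinv %*% X
    VX1 <- VX[r1, , drop = FALSE]; VX2 <- VX[r2, , drop = FALSE]
    XVX <- crossprod(X, VX)
    cX <- chol(XVX)
    XVXinv <- chol2inv(cX)
    Viy <- Vinv %*% y
    beta <- drop(XVXinv %*% crossprod(X, Viy))
    Py <- drop(Viy - VX %*% (XVXinv %*% crossprod(X, Viy)))
    Py1 <- matrix(Py[r1]); Py2 <- matrix(Py[r2])
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + sum(y * Py))

    nf <- length(free)
    grad <- quad <- trPM <- numeric(length(par_names))
    U <- matrix(0, N, nf)
    for (j in seq_len(nf)) {
      pi <- free[j]
      k <- (pi - 1) %/% 3 + 1
      ab <- (pi - 1) %% 3 + 1
      b <- blocks[[k]]
      trV <- if (ab == 1L) sum(Vi11 * b$B11)
             else if (ab == 3L) sum(Vi22 * b$B22)
             else 2 * sum(Vi12 * b$B12)
      MVX <- mulQ(k, ab, VX1, VX2)
      u <- drop(mulQ(k, ab, Py1, Py2))
      trPM[pi] <- trV - sum(XVXinv * crossprod(VX, MVX))
      U[, j] <- u
      quad[pi] <- sum(Py * u)
      grad[pi] <- -0.5 * (trPM[pi] - quad[pi])
    }
    VinvU <- Vinv %*% U
    PU <- VinvU - VX %*% (XVXinv %*% crossprod(VX, U))
    AI <- 0.5 * crossprod(U, PU)
    AI <- (AI + t(AI)) / 2
    list(ll = ll, grad = grad, AI = AI, quad = quad, trPM = trPM,
         beta = beta, vcov_beta = XVXinv)
  }

  # returns list(ll, cV) so an accepted trial's factor is reused
  ll_only <- function(theta) {
    V <- build_V(theta)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(ll = -Inf, cV = NULL))
    Vy <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
    VXl <- backsolve(cV, backsolve(cV, X, transpose = TRUE))
    XVX <- crossprod(X, VXl)
    cX <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(cX)) return(list(ll = -Inf, cV = NULL))
    Py <- Vy - VXl %*% (chol2inv(cX) %*% crossprod(X, Vy))
    list(ll = -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                        sum(y * Py)),
         cV = cV)
  }

  em_step <- function(theta, q) {
    cand <- theta
    for (k in seq_len(nterm)) {
      i <- (3 * k - 2):(3 * k)
      K <- kmat(theta, k)
      d <- q$quad[i] - q$trPM[i]
      Gm <- matrix(c(d[1], d[2] / 2, d[2] / 2, d[3]), 2, 2)
      Knew <- K + (K %*% Gm %*% K) / blocks[[k]]$q
      cand[i] <- c(Knew[1, 1], Knew[1, 2], Knew[2, 2])
    }
    project(cand)
  }

  # Boundary handling for the AI step. Variances stuck at the lower bound
  # with an outward gradient are dropped from the update; a covariance at
  # the correlation cap with an outward gradient is constrained to the cap
  # manifold a12 = +/- 0.999 sqrt(a11 a22), absorbed into the a11/a22
  # directions by the chain rule (Jacobian J), so the step moves along the
  # boundary instead of crawling against the projection.
  step_jacobian <- function(theta, grad) {
    dropped <- integer(0)
    capped <- integer(0)
    for (k in seq_len(nterm)) {
      i11 <- 3 * k - 2; i12 <- 3 * k - 1; i22 <- 3 * k
      if (theta[i11] <= lb[1] * (1 + 1e-6) && grad[i11] < 0) {
        dropped <- c(dropped, i11)
      }
      if (theta[i22] <= lb[2] * (1 + 1e-6) && grad[i22] < 0) {
        dropped <- c(dropped, i22)
      }
      cap <- 0.999 * sqrt(theta[i11] * theta[i22])
      if (i12 %in% free &&
          ((theta[i12] >= cap * (1 - 1e-6) && grad[i12] > 0) ||
           (theta[i12] <= -cap * (1 - 1e-6) && grad[i12] < 0))) {
        capped <- c(capped, i12)
      }
    }
    red <- setdiff(free, c(dropped, capped))
    if (!length(red)) return(NULL)
    J <- matrix(0, length(free), length(red))
    for (j in seq_along(red)) J[match(red[j], free), j] <- 1
    for (i12 in capped) {
      k <- (i12 - 1) %/% 3 + 1
      i11 <- 3 * k - 2; i22 <- 3 * k
      if (i11 %in% red) {
        J[match(i12, free), match(i11, red)] <- theta[i12] / (2 * theta[i11])
      }
      if (i22 %in% red) {
        J[match(i12, free), match(i22, red)] <- theta[i12] / (2 * theta[i22])
      }
    }
    J
  }

  converged <- FALSE
  ll_prev <- -Inf
  rel_change <- Inf
  stall <- 0L
  it <- 0
  cV_next <- NULL
  repeat {
    it <- it + 1
    q <- quantities(theta, cV = cV_next)
    cV_next <- NULL
    if (verbose) {
      cat(sprintf("iter %3d  logL %.8f\n", it, q$ll))
    }
    stall <- if (it > 1 && abs(q$ll - ll_prev) < tol_ll) stall + 1L else 0L
    if (it > 1 && stall >= 1L && rel_change < tol_par) {
      converged <- TRUE
      break
    }
    if (stall >= 3L) {  # flat likelihood with only boundary re-projection left
      converged <- TRUE
      break
    }
    if (it >= maxit) break
    if (it == 1) {
      cand <- em_step(theta, q)
    } else {
      J <- step_jacobian(theta, q$grad)
      delta_free <- if (!is.null(J)) {
        tryCatch(drop(J %*% solve(crossprod(J, q$AI %*% J),
                                  crossprod(J, q$grad[free]))),
                 error = function(e) NULL)
      } else NULL
      cand <- NULL
      if (!is.null(delta_free)) {
        delta <- numeric(length(theta))
        delta[free] <- delta_free
        step <- 1
        for (h in 1:8) {
          trial <- project(theta + step * delta)
          lt <- ll_only(trial)
          if (lt$ll >= q$ll - 1e-10) {
            cand <- trial
            cV_next <- lt$cV
            break
          }
          step <- step / 2
        }
      }
      if (is.null(cand)) {
        cand <- em_step(theta, q)
        # EM is monotone: a vanishing gain means a (boundary) optimum
        if (ll_only(cand)$ll - q$ll < tol_ll) {
          theta <- cand
          converged <- TRUE
          break
        }
      }
    }
    rel_change <- max(abs(cand - theta) / pmax(abs(theta), 1e-4 * mean(vp0)))
    ll_prev <- q$ll
    theta <- cand
  }

  vcov_free <- tryCatch(solve(q$AI), error = function(e) {
    warning("average-information matrix is singular; component SEs undefined",
            call. = FALSE)
    matrix(NA_real_, length(free), length(free))
  })
  vcov_theta <- matrix(0, length(par_names), length(par_names),
                       dimnames = list(par_names, par_names))
  vcov_theta[free, free] <- vcov_free
  AIfull <- matrix(NA_real_, length(par_names), length(par_names),
                   dimnames = list(par_names, par_names))
  AIfull[free, free] <- q$AI

  K <- lapply(seq_len(nterm), function(k) kmat(theta, k))
  names(K) <- labels
  boundary <- logical(length(par_names))
  for (k in seq_len(nterm)) {
    i11 <- 3 * k - 2; i12 <- 3 * k - 1; i22 <- 3 * k
    boundary[i11] <- theta[i11] <= lb[1] * (1 + 1e-8)
    boundary[i22] <- theta[i22] <= lb[2] * (1 + 1e-8)
    boundary[i12] <- abs(theta[i12]) >= 0.999 * sqrt(theta[i11] * theta[i22]) * (1 - 1e-8) &&
      theta[i12] != 0
  }
  names(boundary) <- par_names

  structure(list(theta = theta, K = K, vcov_theta = vcov_theta,
                 beta = q$beta, vcov_beta = q$vcov_beta, loglik = q$ll,
                 converged = converged, iterations = it, ai_matrix = AIfull,
                 gradient = q$grad, boundary = boundary,
                 n = c(n1, n2), p = p, lb = lb, term_labels = labels,
                 free = free, fix_cov = fix_cov),
            class = c("reml_biv", "reml_fit"))
}

#' @export
print.reml_biv <- function(x, ...) {
  cat("Bivariate REML fit:", x$n[1], "+", x$n[2], "records\n")
  cat("restricted logL:", format(x$loglik, digits = 10),
      if (x$converged) sprintf("(converged in %d iterations)", x$iterations)
      else sprintf("(NOT converged after %d iterations)", x$iterations), "\n")
  for (k in seq_along(x$K)) {
    cat(x$term_labels[k], "(co)variance matrix:\n")
    print(signif(x$K[[k]], 5))
  }
  invisible(x)
}
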