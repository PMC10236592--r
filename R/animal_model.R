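#' Build design matrices for a pedigree animal model
#'
#' Expands a fixed-effects formula into a full-rank design matrix (reference
#' level coding; aliased columns are dropped with a message), maps records to
#' pedigree positions (`Z_a`) and, optionally, to litter levels (`Z_c`), and
#' extracts the trait vector(s). Since each record belongs to exactly one
#' animal, the additive covariance structure on the record scale,
#' `Z_a A Z_a'`, is returned directly as the submatrix of A over the recorded
#' animals (`M_a`).
#'
#' @param data phenotype table, one row per animal; must contain
#'   `animal_id`, all formula columns, and `litter` column when requested.
#' @param trait character: name(s) of 1 or 2 response columns.
#' @param fixed one-sided formula of fixed effects, e.g.
#'   `~ sex + treatment + slaughter_bw`.
#' @param ped a [pedigree] covering every recorded animal.
#' @param A optional precomputed relationship matrix from
#'   [additive_relationship()] (computed from `ped` when `NULL`).
#' @param litter optional name of the litter (common environment) column.
#' @return list with `y` (vector or n x 2 matrix), `X`, `Z_a`, `Z_c` (or
#'   `NULL`), `M_a = Z_a A Z_a'`, `M_c = Z_c Z_c'` (or `NULL`), `q_a`, `q_c`,
#'   and `animal_ids`.
#' @export
build_design <- function(data, trait, fixed, ped, A = NULL, litter = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- as.character(data$animal_id)
  unknown <- setdiff(ids, ped$animal)
  if (length(unknown)) {
    stop("animal(s) absent from the pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  miss <- setdiff(all.vars(fixed), names(data))
  if (length(miss)) stop("formula column(s) missing from data: ",
                         paste(miss, collapse = ", "))

  X <- stats::model.matrix(fixed, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    message("dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    if (qr(X)$rank < ncol(X)) {
      stop("design remains rank deficient after dropping aliased columns")
    }
  }

  if (is.null(A)) A <- additive_relationship(ped)
  pos <- match(ids, rownames(A))
  Z_a <- matrix(0, nrow(data), nrow(A), dimnames = list(NULL, rownames(A)))
  Z_a[cbind(seq_len(nrow(data)), pos)] <- 1
  M_a <- A[pos, pos, drop = FALSE]

  Z_c <- M_c <- NULL
  q_c <- 0L
  if (!is.null(litter)) {
    lit <- factor(data[[litter]])
    Z_c <- stats::model.matrix(~ lit - 1)
    colnames(Z_c) <- levels(lit)
    M_c <- tcrossprod(Z_c)
    q_c <- nlevels(lit)
  }

  y <- if (length(trait) == 1) data[[trait]] else as.matrix(data[trait])
  list(y = y, X = X, Z_a = Z_a, Z_c = Z_c, M_a = M_a, M_c = M_c,
       q_a = length(unique(ids)), q_c = q_c, animal_ids = ids)
}

#' Fit a univariate pedigree animal model by REML
#'
#' `y = Xb + Z_a a + Z_c c + e` with `a ~ N(0, A * V_A)` (A = pedigree
#' numerator relationship matrix), an optional litter/common-environment term
#' `c ~ N(0, I * V_CE)` and `e ~ N(0, I * V_R)`. Records with a missing
#' trait value are excluded.
#'
#' @inheritParams build_design
#' @param lrt also compute a one-sided likelihood-ratio test of `V_A = 0`
#'   (refit without the animal term; p-value from the boundary-corrected
#'   0.5*chi-squared(1) mixture)?
#' @param ... passed to [reml_fit()].
#' @return object of class `animal_model_fit`: the [reml_fit()] result plus
#'   `trait`, `parameters` (from [genetic_parameters()]), `n_records`, and
#'   optionally `lrt_va` (list with `statistic`, `p_value`).
#' @export
fit_animal_model <- function(data, trait, fixed, ped, A = NULL, litter = NULL,
                             lrt = FALSE, ...) {
  keep <- !is.na(data[[trait]])
  data <- data[keep, , drop = FALSE]
  des <- build_design(data, trait, fixed, ped, A = A, litter = litter)
  random <- list(animal = list(M = des$M_a, q = des$q_a))
  if (!is.null(des$M_c)) random$litter <- list(M = des$M_c, q = des$q_c)
  fit <- reml_fit(des$y, des$X, random, ...)
  fit$trait <- trait
  fit$n_records <- nrow(data)
  fit$parameters <- genetic_parameters(fit)
  if (lrt) {
    random0 <- random[setdiff(names(random), "animal")]
    fit0 <- reml_fit(des$y, des$X, random0, ...)
    stat <- max(0, 2 * (fit$loglik - fit0$loglik))
    fit$lrt_va <- list(statistic = stat,
                       p_value = 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE))
  }
  class(fit) <- c("animal_model_fit", class(fit))
  fit
}

#' Fit a bivariate pedigree animal model by REML
#'
#' Two-trait animal model with unstructured additive-genetic, optional
#' litter, and residual 2 x 2 covariance matrices. Records missing one trait
#' are kept for the other trait (full-information likelihood over observed
#' entries).
#'
#' @inheritParams build_design
#' @param trait character vector of two response column names.
#' @param ... passed to [reml_bivariate()].
#' @return object of class `animal_model_biv`: the [reml_bivariate()] result
#'   plus `trait` and `parameters` (heritabilities per trait, genetic and
#'   phenotypic correlations with delta-method SEs).
#' @export
fit_animal_model_bivariate <- function(data, trait, fixed, ped, A = NULL,
                                       litter = NULL, ...) {
  stopifnot(length(trait) == 2)
  keep <- !is.na(data[[trait[1]]]) | !is.na(data[[trait[2]]])
  data <- data[keep, , drop = FALSE]
  des <- build_design(data, trait, fixed, ped, A = A, litter = litter)
  terms <- list(animal = list(M = des$M_a, q = des$q_a))
  if (!is.null(des$M_c)) terms$litter <- list(M = des$M_c, q = des$q_c)
  fit <- reml_bivariate(des$y, des$X, terms, ...)
  fit$trait <- trait
  fit$parameters <- genetic_parameters(fit)
  class(fit) <- c("animal_model_biv", class(fit))
  fit
}

#' Heritability, litter effect and correlations with standard errors
#'
#' From a fitted (bi)variate REML model: `h2 = V_A / (V_A + V_CE + V_R)`,
#' `CE2 = V_CE / V_P`, genetic correlation `r_g = cov_A / sqrt(V_A1 V_A2)`
#' and phenotypic correlation `r_p = (cov_A + cov_CE + cov_R) /
#' sqrt(V_P1 V_P2)`. Standard errors of the ratios come from a first-order
#' delta-method expansion around the inverse average-information matrix of
#' the variance components.
#'
#' @param fit a [reml_fit()] or [reml_bivariate()] result in which the first
#'   random term is the additive-genetic ("animal") term and an optional term
#'   named `litter` is the common-environment term.
#' @return object of class `genetic_parameters`: data frame with columns
#'   `parameter`, `trait`, `estimate`, `se`.
#' @export
genetic_parameters <- function(fit) {
  if (inherits(fit, "reml_biv")) {
    return(genetic_parameters_biv(fit))
  }
  theta <- fit$theta
  vp <- sum(theta)
  if (vp <= 0) stop("zero phenotypic variance")
  C <- fit$vcov_theta
  m <- length(theta)
  rows <- list()
  ratio_row <- function(k, label) {
    g <- rep(-theta[k] / vp^2, m)
    g[k] <- (vp - theta[k]) / vp^2
    data.frame(parameter = label, trait = fit$trait %||% NA_character_,
               estimate = theta[k] / vp, se = delta_se(g, C))
  }
  rows$h2 <- ratio_row(1L, "h2")
  if ("litter" %in% names(theta)) {
    rows$ce2 <- ratio_row(which(names(theta) == "litter"), "ce2")
  }
  g_vp <- rep(1, m)
  rows$vp <- data.frame(parameter = "vp", trait = fit$trait %||% NA_character_,
                        estimate = vp, se = delta_se(g_vp, C))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("genetic_parameters", "data.frame"))
}

genetic_parameters_biv <- function(fit) {
  theta <- fit$theta
  C <- fit$vcov_theta
  labels <- fit$term_labels
  traits <- fit$trait %||% c("trait1", "trait2")
  idx <- function(term, ab) {
    which(names(theta) == paste(term, ab, sep = "."))
  }
  np <- length(theta)
  rows <- list()

  for (t in 1:2) {
    ab <- if (t == 1) "11" else "22"
    ivar <- vapply(labels, idx, 0L, ab = ab)
    vp <- sum(theta[ivar])
    ia <- idx(labels[1], ab)
    g <- numeric(np)
    g[ivar] <- -theta[ia] / vp^2
    g[ia] <- g[ia] + 1 / vp
    rows[[paste0("h2_", t)]] <-
      data.frame(parameter = "h2", trait = traits[t],
                 estimate = theta[ia] / vp, se = delta_se(g, C))
    if ("litter" %in% labels) {
      ic <- idx("litter", ab)
      g <- numeric(np)
      g[ivar] <- -theta[ic] / vp^2
      g[ic] <- g[ic] + 1 / vp
      rows[[paste0("ce2_", t)]] <-
        data.frame(parameter = "ce2", trait = traits[t],
                   estimate = theta[ic] / vp, se = delta_se(g, C))
    }
  }

  # genetic correlation from the first (animal) term
  a11 <- idx(labels[1], "11"); a12 <- idx(labels[1], "12"); a22 <- idx(labels[1], "22")
  rg <- theta[a12] / sqrt(theta[a11] * theta[a22])
  g <- numeric(np)
  g[a12] <- 1 / sqrt(theta[a11] * theta[a22])
  g[a11] <- -rg / (2 * theta[a11])
  g[a22] <- -rg / (2 * theta[a22])
  rows$rg <- data.frame(parameter = "rg", trait = paste(traits, collapse = ":"),
                        estimate = rg, se = delta_se(g, C))

  i11 <- vapply(labels, idx, 0L, ab = "11")
  i12 <- vapply(labels, idx, 0L, ab = "12")
  i22 <- vapply(labels, idx, 0L, ab = "22")
  vp1 <- sum(theta[i11]); vp2 <- sum(theta[i22]); cp <- sum(theta[i12])
  rp <- cp / sqrt(vp1 * vp2)
  g <- numeric(np)
  g[i12] <- 1 / sqrt(vp1 * vp2)
  g[i11] <- -rp / (2 * vp1)
  g[i22] <- -rp / (2 * vp2)
  rows$rp <- data.frame(parameter = "rp", trait = paste(traits, collapse = ":"),
                        estimate = rp, se = delta_se(g, C))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("genetic_parameters", "data.frame"))
}

delta_se <- function(grad, C) {
  if (anyNA(C)) return(NA_real_)
  v <- drop(crossprod(grad, C %*% grad))
  if (v < 0) return(NA_real_)
  sqrt(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard errors of variance components
#'
#' Square roots of the diagonal of the inverse average-information matrix.
#'
#' @param fit a [reml_fit()] result.
#' @return named vector of component SEs (NA when the information matrix is
#'   singular).
#' @export
component_se <- function(fit) {
  sqrt(pmax(diag(fit$vcov_theta), 0))
}
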