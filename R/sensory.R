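#' Mixed model for sensory panel scores
#'
#' Fits `score = mu + Session + Judge + Sex + PE group + Fat thickness + e`
#' for one attribute, with judge and session as random effects (identity
#' covariance structures, estimated by the package's REML engine) and the
#' remaining factors fixed. Fixed factors with a single observed level are
#' dropped with a warning.
#'
#' @param data long-format score table with columns `judge`, `session`,
#'   `attribute`, `score`, and the fixed-effect columns (by default `sex`,
#'   `pe_group`, `fat_thickness`).
#' @param attribute which attribute to analyse (e.g. `"juiciness"`).
#' @param fixed character vector of fixed-effect column names.
#' @param ... passed to [reml_fit()].
#' @return object of class `sensory_fit`: the [reml_fit()] result (variance
#'   components `judge`, `session`, `residual`) plus `data`, `fixed_terms`,
#'   `attribute`, and the design `X`.
#' @export
fit_sensory <- function(data, attribute,
                        fixed = c("sex", "pe_group", "fat_thickness"), ...) {
  if (!all(c("judge", "session", "attribute", "score") %in% names(data))) {
    stop("sensory table must have columns judge, session, attribute, score")
  }
  dat <- data[data$attribute == attribute, , drop = FALSE]
  if (!nrow(dat)) stop("no records for attribute '", attribute, "'")
  if (any(dat$score < 0 | dat$score > 10, na.rm = TRUE)) {
    warning("score(s) outside the 0-10 scale", call. = FALSE)
  }

  keep <- character(0)
  for (f in fixed) {
    if (length(unique(dat[[f]])) < 2) {
      warning("fixed factor '", f, "' has a single level and was dropped",
              call. = FALSE)
    } else {
      keep <- c(keep, f)
      dat[[f]] <- factor(dat[[f]])
    }
  }
  form <- if (length(keep)) {
    stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  } else ~1
  X <- stats::model.matrix(form, dat)

  random <- list()
  for (r in c("judge", "session")) {
    lev <- factor(dat[[r]])
    if (nlevels(lev) < 2) {
      warning("random factor '", r, "' has a single level and was dropped",
              call. = FALSE)
      next
    }
    Z <- stats::model.matrix(~ lev - 1)
    random[[r]] <- list(Z = Z)
  }

  fit <- reml_fit(dat$score, X, random, ...)
  fit$data <- dat
  fit$fixed_terms <- keep
  fit$fixed_formula <- form
  fit$attribute <- attribute
  fit$X <- X
  class(fit) <- c("sensory_fit", class(fit))
  fit
}

#' Fisher's LSD mean separation after a sensory mixed-model fit
#'
#' Compares adjusted (population-marginal) means of one fixed factor,
#' pairwise, against the least significant difference
#' `LSD = t(1 - alpha/2, df) * sqrt(2 * MS_error / n_eff)`, where `MS_error`
#' is the residual variance component, `df` the residual degrees of freedom
#' of the fixed-effect projection (n - rank(X)), and `n_eff` the harmonic
#' mean of the two group sizes. Adjusted means average model predictions
#' over the levels of the other fixed factors with equal weight. Groups are
#' summarised with a compact letter display: groups sharing a letter are not
#' separated.
#'
#' @param fit a [fit_sensory()] result (or any `reml_fit` carrying `data`,
#'   `fixed_terms`, `X`).
#' @param factor name of the fixed factor to separate (default `pe_group`).
#' @param alpha significance level (default 0.05).
#' @return object of class `lsd_table`: list with `means` (level, adjusted
#'   mean, n, letters), `pairs` (level pair, difference, lsd, significant),
#'   `df`, `ms_error`, `alpha`. A zero residual variance gives a zero
#'   threshold and is flagged `degenerate`.
#' @export
fisher_lsd <- function(fit, factor = "pe_group", alpha = 0.05) {
  stopifnot(inherits(fit, "reml_fit"))
  dat <- fit$data
  if (!factor %in% fit$fixed_terms) {
    stop("'", factor, "' is not a fixed factor of the fit")
  }
  levs <- levels(dat[[factor]])
  if (length(levs) < 2) stop("factor needs at least 2 levels")

  # adjusted means: average predictions over the other fixed factors
  others <- setdiff(fit$fixed_terms, factor)
  grid_args <- c(stats::setNames(list(levs), factor),
                 lapply(stats::setNames(others, others),
                        function(f) levels(dat[[f]])))
  grid <- expand.grid(grid_args, stringsAsFactors = FALSE)
  for (f in c(factor, others)) grid[[f]] <- factor(grid[[f]], levels = levels(dat[[f]]))
  Xg <- stats::model.matrix(fit$fixed_formula, grid)
  Xg <- Xg[, colnames(fit$X), drop = FALSE]
  pred <- drop(Xg %*% fit$beta)
  means <- tapply(pred, grid[[factor]], mean)

  nobs <- table(dat[[factor]])[levs]
  dfres <- fit$n - fit$p
  mse <- unname(fit$theta["residual"])
  degenerate <- mse <= fit$lb * (1 + 1e-8)

  pairs <- utils::combn(levs, 2)
  ptab <- data.frame(
    level1 = pairs[1, ], level2 = pairs[2, ],
    diff = means[pairs[1, ]] - means[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  n_eff <- 2 / (1 / as.numeric(nobs[ptab$level1]) + 1 / as.numeric(nobs[ptab$level2]))
  ptab$lsd <- stats::qt(1 - alpha / 2, dfres) * sqrt(2 * mse / n_eff)
  ptab$significant <- abs(ptab$diff) > ptab$lsd
  rownames(ptab) <- NULL

  letters_tab <- lsd_letters(levs, means, ptab)
  means_tab <- data.frame(level = levs, mean = as.numeric(means[levs]),
                          n = as.numeric(nobs), letters = letters_tab[levs],
                          stringsAsFactors = FALSE)
  rownames(means_tab) <- NULL

  structure(list(means = means_tab, pairs = ptab, df = dfres, ms_error = mse,
                 alpha = alpha, degenerate = degenerate, factor = factor),
            class = "lsd_table")
}

# compact letter display by insert-and-absorb over the significance relation
lsd_letters <- function(levs, means, ptab) {
  ord <- levs[order(-as.numeric(means[levs]))]
  sig <- function(a, b) {
    hit <- (ptab$level1 == a & ptab$level2 == b) |
           (ptab$level1 == b & ptab$level2 == a)
    any(ptab$significant[hit])
  }
  groups <- list()
  for (lv in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], sig, TRUE, a = lv))) {
        groups[[gi]] <- c(groups[[gi]], lv)
        placed <- TRUE
      }
    }
    if (!placed) groups <- c(groups, list(lv))
  }
  # drop groups fully contained in another
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
          length(groups[[i]]) < length(groups[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  groups <- groups[keep]
  out <- stats::setNames(rep("", length(levs)), levs)
  for (gi in seq_along(groups)) {
    for (lv in groups[[gi]]) out[lv] <- paste0(out[lv], letters[gi])
  }
  out
}

#' @export
print.lsd_table <- function(x, ...) {
  cat("Fisher's LSD separation for", x$factor,
      sprintf("(alpha = %g, df = %d, MS_error = %.4g%s)\n", x$alpha, x$df,
              x$ms_error, if (x$degenerate) ", DEGENERATE: zero residual" else ""))
  print(x$means, row.names = FALSE)
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
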