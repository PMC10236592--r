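#' Ordinary least-squares fit of a candidate fixed-effect model
#'
#' Fits `response ~ terms` by OLS and returns the log-likelihood and AIC with
#' `k` counting the regression coefficients plus the residual variance.
#' Aliased terms are dropped by the fitter with a warning; a zero residual
#' variance (perfect fit or zero-variance response) has no finite AIC and is
#' an error.
#'
#' @param data data frame holding the response and all term columns.
#' @param response name of the response column.
#' @param terms character vector of model terms (main effects and `A:B`
#'   interactions); empty = intercept-only model.
#' @return list with `coefficients`, `loglik`, `k`, `aic`, `formula`.
#' @export
fit_fixed <- function(data, response, terms = character(0)) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) {
    warning("aliased term(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
            call. = FALSE)
  }
  rss <- sum(stats::residuals(fit)^2)
  if (!is.finite(rss) || rss <= 1e-20 * max(1, sum(data[[response]]^2))) {
    stop("residual variance is zero: AIC is undefined for this fit")
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")  # coefficients + residual variance
  list(coefficients = stats::coef(fit), loglik = as.numeric(ll), k = k,
       aic = -2 * as.numeric(ll) + 2 * k, formula = form)
}

#' All-subsets AIC screening of fixed-effect structures
#'
#' Enumerates every subset of the full term set that respects marginality
#' (an interaction `A:B` is only admitted together with both main effects),
#' fits each candidate by OLS, and ranks the candidates by AIC. The top set
#' is all models within `delta` AIC of the best; ties in AIC are broken by
#' fewer parameters, then by the lexicographic term string. The term set of
#' the single best model is what downstream animal models use as fixed
#' effects.
#'
#' @inheritParams fit_fixed
#' @param full_terms character vector of candidate terms (main effects and
#'   `A:B` interactions between them).
#' @param delta AIC window defining the top set (default 2).
#' @return list with `table` (data frame: `terms`, `k`, `loglik`, `aic`,
#'   `delta_aic`, sorted by AIC), `top_terms` (terms of the best model) and
#'   `top_set` (list of term vectors with `delta_aic < delta`).
#' @export
dredge_aic <- function(data, response, full_terms, delta = 2) {
  if (length(full_terms) > 20) {
    stop("more than 2^20 candidate models; reduce the term set")
  }
  main <- full_terms[!grepl(":", full_terms)]
  inter <- full_terms[grepl(":", full_terms)]
  parents <- lapply(inter, function(tm) strsplit(tm, ":", fixed = TRUE)[[1]])
  bad_parent <- vapply(parents, function(p) !all(p %in% main), TRUE)
  if (any(bad_parent)) {
    stop("interaction(s) without both main effects in the term set: ",
         paste(inter[bad_parent], collapse = ", "))
  }

  # enumerate admissible subsets: any subset of mains, then any subset of
  # interactions whose parents are all present
  subsets <- list(character(0))
  for (tm in main) {
    subsets <- c(subsets, lapply(subsets, c, tm))
  }
  candidates <- list()
  for (s in subsets) {
    ok_inter <- inter[vapply(parents, function(p) all(p %in% s), TRUE)]
    isub <- list(character(0))
    for (tm in ok_inter) {
      isub <- c(isub, lapply(isub, c, tm))
    }
    candidates <- c(candidates, lapply(isub, function(i) c(s, i)))
  }

  fits <- lapply(candidates, function(tms) fit_fixed(data, response, tms))
  tab <- data.frame(
    terms = vapply(candidates, function(tms)
      if (length(tms)) paste(sort(tms), collapse = " + ") else "(intercept)",
      character(1)),
    k = vapply(fits, `[[`, 0, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    stringsAsFactors = FALSE
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  ord <- order(tab$aic, tab$k, tab$terms)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  candidates <- candidates[ord]
  list(table = tab,
       top_terms = candidates[[1]],
       top_set = candidates[tab$delta_aic < delta])
}
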