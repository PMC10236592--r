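#' Derive phenotypes from raw tables and write the report
#'
#' Stage driver: runs [derive_phenotypes()] on a records table (and optional
#' meat-quality table), writes the derived-phenotype and QC tables as
#' tab-delimited files when `out_dir` is given, and logs the QC flag counts.
#'
#' @param records raw animal-record table (see [derive_phenotypes()]).
#' @param meat optional meat-quality table.
#' @param baseline a `baseline_composition`.
#' @param out_dir output directory (created if needed); `NULL` = no files.
#' @param drop_flagged drop QC-flagged animals?
#' @return the [derive_phenotypes()] result, invisibly carrying `paths`.
#' @export
run_derive <- function(records, meat = NULL, baseline = default_baseline(),
                       out_dir = NULL, drop_flagged = FALSE) {
  res <- derive_phenotypes(records, meat = meat, baseline = baseline,
                           drop_flagged = drop_flagged)
  if (nrow(res$qc)) {
    counts <- table(res$qc$flag)
    message("QC flags: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  } else {
    message("QC flags: none")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(phenotypes = file.path(out_dir, "derived_phenotypes.tsv"),
               qc = file.path(out_dir, "qc_flags.tsv"))
    write_tsv(res$phenotypes, paths["phenotypes"])
    write_tsv(res$qc, paths["qc"])
    res$paths <- paths
    write_manifest(out_dir, paths, list(stage = "derive",
                                        drop_flagged = drop_flagged))
  }
  invisible(res)
}

#' Univariate and bivariate genetic analysis with report tables
#'
#' Stage driver: fits a univariate animal model per trait (heritability,
#' litter effect, phenotypic variance with SEs) and a bivariate model per
#' configured trait pair, then assembles a variance-component report and
#' correlation matrices with genetic correlations above and phenotypic
#' correlations below the diagonal. Non-convergent fits are flagged in the
#' report and the run continues.
#'
#' @param pheno derived-phenotype table (one row per animal).
#' @param ped a [pedigree] covering the phenotyped animals.
#' @param traits character vector of trait columns to analyse (>= 1).
#' @param pairs list of character pairs for bivariate fits, or `"all"` for
#'   every pair of `traits`, or `NULL` for none.
#' @param fixed fixed-effects formula shared by the fits.
#' @param litter litter column name for the common-environment term, or
#'   `NULL` to omit it.
#' @param out_dir optional output directory for the report files.
#' @param ... passed to the fitters.
#' @return list with `univariate` (named list of fits), `bivariate` (named
#'   list), `heritability_table`, `correlations` (list with `matrix` in the
#'   genetic-above/phenotypic-below layout and `table`), `paths`.
#' @export
run_genetics <- function(pheno, ped, traits, pairs = "all", fixed,
                         litter = "litter_id", out_dir = NULL, ...) {
  if (!length(traits)) stop("empty trait list")
  missing_tr <- setdiff(traits, names(pheno))
  if (length(missing_tr)) stop("trait column(s) not in data: ",
                               paste(missing_tr, collapse = ", "))
  A <- additive_relationship(ped)

  uni <- lapply(traits, function(tr) {
    fit <- fit_animal_model(pheno, tr, fixed, ped, A = A, litter = litter, ...)
    if (!fit$converged) {
      message("univariate fit for '", tr, "' did not converge; flagged")
    }
    fit
  })
  names(uni) <- traits

  herit <- do.call(rbind, lapply(traits, function(tr) {
    fit <- uni[[tr]]
    par <- fit$parameters
    se <- component_se(fit)
    get <- function(p) {
      i <- which(par$parameter == p)
      if (length(i)) par$estimate[i[1]] else NA_real_
    }
    gse <- function(p) {
      i <- which(par$parameter == p)
      if (length(i)) par$se[i[1]] else NA_real_
    }
    data.frame(trait = tr, n = fit$n_records,
               v_a = unname(fit$theta["animal"]), v_a_se = unname(se["animal"]),
               h2 = get("h2"), h2_se = gse("h2"),
               v_ce = unname(fit$theta["litter"] %|NA|% NA_real_),
               v_ce_se = unname(se["litter"] %|NA|% NA_real_),
               ce2 = get("ce2"), ce2_se = gse("ce2"),
               v_p = get("vp"), v_p_se = gse("vp"),
               converged = fit$converged,
               stringsAsFactors = FALSE)
  }))

  biv <- list()
  cor_tab <- NULL
  if (!is.null(pairs)) {
    if (identical(pairs, "all")) {
      pairs <- if (length(traits) > 1) {
        cmb <- utils::combn(traits, 2)
        lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
      } else list()
    }
    for (pr in pairs) {
      key <- paste(pr, collapse = ":")
      fit <- fit_animal_model_bivariate(pheno, pr, fixed, ped, A = A,
                                        litter = litter, ...)
      if (!fit$converged) message("bivariate fit for ", key,
                                  " did not converge; flagged")
      biv[[key]] <- fit
    }
    cor_tab <- do.call(rbind, lapply(names(biv), function(key) {
      par <- biv[[key]]$parameters
      rg <- par[par$parameter == "rg", ]
      rp <- par[par$parameter == "rp", ]
      data.frame(pair = key, rg = rg$estimate, rg_se = rg$se,
                 rp = rp$estimate, rp_se = rp$se,
                 converged = biv[[key]]$converged, stringsAsFactors = FALSE)
    }))
  }

  cor_mat <- NULL
  if (length(biv)) {
    cor_mat <- matrix(NA_real_, length(traits), length(traits),
                      dimnames = list(traits, traits))
    diag(cor_mat) <- 1
    for (key in names(biv)) {
      pr <- strsplit(key, ":", fixed = TRUE)[[1]]
      par <- biv[[key]]$parameters
      i <- match(pr[1], traits); j <- match(pr[2], traits)
      # genetic above, phenotypic below the diagonal
      cor_mat[min(i, j), max(i, j)] <- par$estimate[par$parameter == "rg"]
      cor_mat[max(i, j), min(i, j)] <- par$estimate[par$parameter == "rp"]
    }
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(heritability = file.path(out_dir, "heritability.tsv"))
    write_tsv(format_heritability(herit), paths["heritability"])
    if (!is.null(cor_tab)) {
      paths["correlations"] <- file.path(out_dir, "correlations.tsv")
      write_tsv(cor_tab, paths["correlations"])
      paths["correlation_matrix"] <- file.path(out_dir, "correlation_matrix.tsv")
      write_tsv(data.frame(trait = rownames(cor_mat),
                           round(cor_mat, 2), check.names = FALSE),
                paths["correlation_matrix"])
    }
    write_manifest(out_dir, paths,
                   list(stage = "genetics", traits = traits, litter = litter,
                        fixed = deparse(fixed)))
  }

  list(univariate = uni, bivariate = biv, heritability_table = herit,
       correlations = list(matrix = cor_mat, table = cor_tab), paths = paths)
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

# report precision mirrors the field's convention: 2 decimals for ratios,
# scientific notation for small variances
format_heritability <- function(h) {
  fmt_var <- function(x, se) {
    ifelse(is.na(x), "-",
           paste(formatC(x, format = "g", digits = 3), "±",
                 formatC(se, format = "g", digits = 2)))
  }
  fmt_ratio <- function(x, se) {
    ifelse(is.na(x), "-",
           paste(formatC(round(x, 2), format = "f", digits = 2), "±",
                 formatC(round(se, 2), format = "f", digits = 2)))
  }
  data.frame(trait = h$trait, n = h$n,
             sigma2_a = fmt_var(h$v_a, h$v_a_se),
             h2 = fmt_ratio(h$h2, h$h2_se),
             sigma2_ce = fmt_var(h$v_ce, h$v_ce_se),
             ce2 = fmt_ratio(h$ce2, h$ce2_se),
             sigma2_p = fmt_var(h$v_p, h$v_p_se),
             converged = h$converged,
             stringsAsFactors = FALSE)
}

#' Sensory analysis driver with per-attribute LSD reports
#'
#' Fits the judge/session mixed model and runs Fisher's LSD separation of
#' the protein-efficiency groups for each attribute.
#'
#' @param sensory long-format score table (see [fit_sensory()]).
#' @param attributes attributes to analyse (default: all present).
#' @param factor fixed factor to separate (default `pe_group`).
#' @param alpha significance level.
#' @param out_dir optional output directory.
#' @param ... passed to [fit_sensory()].
#' @return list per attribute: `fit`, `lsd`; plus `summary` data frame
#'   (attribute, variance components, separation letters) and `paths`.
#' @export
run_sensory <- function(sensory, attributes = NULL, factor = "pe_group",
                        alpha = 0.05, out_dir = NULL, ...) {
  if (!"attribute" %in% names(sensory)) stop("missing 'attribute' column")
  if (is.null(attributes)) attributes <- unique(sensory$attribute)
  res <- list()
  summ <- list()
  for (at in attributes) {
    fit <- fit_sensory(sensory, at, ...)
    lsd <- fisher_lsd(fit, factor = factor, alpha = alpha)
    res[[at]] <- list(fit = fit, lsd = lsd)
    summ[[at]] <- data.frame(
      attribute = at,
      v_judge = unname(fit$theta["judge"] %|NA|% NA_real_),
      v_session = unname(fit$theta["session"] %|NA|% NA_real_),
      v_residual = unname(fit$theta["residual"]),
      separation = paste(lsd$means$level, lsd$means$letters,
                         sep = ":", collapse = " "),
      stringsAsFactors = FALSE)
  }
  summary_tab <- do.call(rbind, summ)
  rownames(summary_tab) <- NULL

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(summary = file.path(out_dir, "sensory_summary.tsv"))
    write_tsv(summary_tab, paths["summary"])
    pair_tab <- do.call(rbind, lapply(attributes, function(at) {
      cbind(attribute = at, res[[at]]$lsd$pairs)
    }))
    paths["pairs"] <- file.path(out_dir, "sensory_lsd_pairs.tsv")
    write_tsv(pair_tab, paths["pairs"])
    write_manifest(out_dir, paths, list(stage = "sensory", alpha = alpha))
  }

  c(res, list(summary = summary_tab, paths = paths))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reproducibility manifest: config echo, RNG state hashcode, output checksums
write_manifest <- function(out_dir, paths, config) {
  manifest <- list(
    package = "effigen",
    version = as.character(utils::packageVersion("effigen")),
    timestamp = NULL,  # deliberately omitted: manifests must be bit-stable
    config = config,
    outputs = as.list(tools::md5sum(unname(paths[file.exists(paths)])))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
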