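#' Default simulation configuration
#'
#' Study-shaped defaults for the synthetic-data generator: a three-generation
#' pedigree (39 sires and 79 dams, with 48 dams farrowing one litter, 23 two
#' and 8 three, across 14 farrowing series; parents themselves descend from a
#' small founder layer), five correlated efficiency/performance traits
#' (protein efficiency, phosphorus efficiency, ADG, FCR, ADFI) with additive,
#' litter and residual (co)variances calibrated to the published estimates,
#' a two-trait water-holding block (drip and cooking loss) on a carcass
#' subset, and a judge/session sensory block. Trait means and total
#' phenotypic spread target the published descriptive statistics; the
#' difference between the target spread and the model variance is allocated
#' to fixed effects (sex, treatment, year, slaughter weight, temperature).
#'
#' @param seed default RNG seed carried in the config.
#' @return object of class `sim_config` (a nested list); see the vignette
#'   for the meaning and provenance of each default.
#' @export
sim_config <- function(seed = 1) {
  traits <- data.frame(
    trait = c("pe", "phe", "adg", "fcr", "adfi"),
    mean = c(0.39, 0.43, 0.85, 2.67, 2.26),
    sd_target = c(0.04, 0.05, 0.11, 0.23, 0.31),
    v_a = c(5.2e-4, 5.6e-4, 1.3e-3, 8.1e-3, 1.2e-2),
    v_ce = c(5.8e-6, 1.2e-4, 4.2e-4, 2.2e-3, 2.7e-3),
    v_p = c(9.6e-4, 2.1e-3, 2.9e-3, 2.1e-2, 2.3e-2),
    stringsAsFactors = FALSE
  )
  traits$v_r <- traits$v_p - traits$v_a - traits$v_ce
  traits$var_fixed <- pmax(0, traits$sd_target^2 - traits$v_p)

  cor_g <- cor_p <- diag(5)
  fill <- function(M, vals) {
    M[upper.tri(M)] <- vals
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  # order of upper.tri pairs: (1,2) (1,3) (2,3) (1,4) (2,4) (3,4) (1,5) ...
  cor_g <- fill(cor_g, c(0.61, -0.19, -0.21, -0.55, -0.15, -0.12,
                         -0.53, -0.25, 0.74, 0.57))
  cor_p <- fill(cor_p, c(0.53, 0.05, -0.003, -0.50, -0.31, -0.38,
                         -0.36, -0.27, 0.59, 0.50))
  cor_ce <- cor_p  # litter-effect correlations are not published; see vignette

  sa <- sqrt(traits$v_a); sc <- sqrt(traits$v_ce)
  sp <- sqrt(traits$v_p); sr <- sqrt(traits$v_r)
  cov_r <- cor_p * outer(sp, sp) - cor_g * outer(sa, sa) - cor_ce * outer(sc, sc)
  cor_r <- cov_r / outer(sr, sr)
  diag(cor_r) <- 1
  cor_r <- make_psd_cor(cor_r)
  dimnames(cor_g) <- dimnames(cor_ce) <- dimnames(cor_p) <- dimnames(cor_r) <-
    list(traits$trait, traits$trait)

  structure(list(
    seed = seed,
    pedigree = list(n_gsires = 90, n_gdams = 170, n_sires = 39, n_dams = 79,
                    dams_per_litter_count = c(`1` = 48, `2` = 23, `3` = 8),
                    litter_size_mean = 9.08, n_series = 14),
    traits = traits,
    cor_g = cor_g, cor_ce = cor_ce, cor_r = cor_r, cor_p = cor_p,
    covariates = list(
      sex_probs = c(female = 0.46, castrate = 0.44, entire = 0.10),
      treatment_probs = c(control_a = 0.15, control_b = 0.04, control_c = 0.02,
                          treatment_a = 0.74, treatment_b = 0.05),
      years = 2013:2021,
      slaughter_bw = c(mean = 106, sd = 5),
      temperature = c(mean = 21, sd = 3),
      start_bw = c(mean = 22.3, sd = 1.6),
      start_age = c(mean = 70, sd = 4)
    ),
    var_shares = c(sex = 0.3, treatment = 0.2, year = 0.2,
                   weight = 0.2, temperature = 0.1),
    diet = list(cp_frac = 0.125, p_frac = 0.0052),
    carcass = list(dressing = 0.79, half_prop_mean = 0.5, half_prop_sd = 0.004),
    meat = list(n_subset = 509,
                traits = data.frame(trait = c("drip_loss", "cooking_loss"),
                                    mean = c(2.45, 26.91),
                                    v_a = c(0.62, 5.92),
                                    v_p = c(1.53, 16.26),
                                    stringsAsFactors = FALSE),
                rg = 0.39, rp = 0.39, w1 = c(mean = 95, sd = 4)),
    sensory = list(n_judges = 8, n_sessions = 6,
                   n_per_group = c(HPE = 12, MPE = 13, LPE = 14),
                   judge_sd = 1.0, session_sd = 0.55, resid_sd = 1.2,
                   overall_mean = 5,
                   group_effects = list(
                     firmness = c(HPE = 0, MPE = 0, LPE = 0),
                     tenderness = c(HPE = 0, MPE = 0, LPE = 0),
                     juiciness = c(HPE = -1, MPE = 0, LPE = 0),
                     flavour = c(HPE = 0, MPE = 0, LPE = 0)),
                   fat_probs = c(`<1.5cm` = 0.46, `1.5cm` = 0.31, `3cm` = 0.23),
                   sex_probs = c(castrate = 0.46, female = 0.54))
  ), class = "sim_config")
}

# clip tiny negative eigenvalues and rescale to unit diagonal
make_psd_cor <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  D <- 1 / sqrt(diag(M))
  M * outer(D, D)
}

#' Simulate a study-shaped pedigree
#'
#' Generates founder grand-parents, a parent generation of sires and dams
#' with known grand-parents, and a phenotyped offspring generation grouped
#' into litters (dams re-used across 1-3 litters) assigned to farrowing
#' series. Litter sizes are Poisson around the configured mean, so the
#' offspring count is ~1071 under the defaults.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default: `cfg$seed`); `NULL` = do not reseed.
#' @return a [pedigree] with attributes `litter_map` (data frame: `animal`,
#'   `litter_id`, `series`, `generation`) and `phenotyped` (offspring ids).
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  pc <- cfg$pedigree
  n_litters_per_dam <- rep(as.integer(names(pc$dams_per_litter_count)),
                           pc$dams_per_litter_count)
  if (length(n_litters_per_dam) != pc$n_dams) {
    stop("litters-per-dam counts must sum to n_dams")
  }
  if (max(n_litters_per_dam) > pc$n_series) {
    stop("infeasible design: a dam cannot farrow more litters than there are series")
  }
  n_litters_per_dam <- sample(n_litters_per_dam)

  gs <- sprintf("GS%03d", seq_len(pc$n_gsires))
  gd <- sprintf("GD%03d", seq_len(pc$n_gdams))
  sires <- sprintf("S%03d", seq_len(pc$n_sires))
  dams <- sprintf("D%03d", seq_len(pc$n_dams))

  animal <- c(gs, gd, sires, dams)
  sire <- c(rep(NA, length(gs) + length(gd)),
            sample(gs, pc$n_sires + pc$n_dams, replace = TRUE))
  dam <- c(rep(NA, length(gs) + length(gd)),
           sample(gd, pc$n_sires + pc$n_dams, replace = TRUE))

  lit_dam <- rep(dams, n_litters_per_dam)
  n_lit <- length(lit_dam)
  lit_sire <- sample(sires, n_lit, replace = TRUE)
  lit_series <- integer(n_lit)
  for (d in dams) {
    i <- which(lit_dam == d)
    lit_series[i] <- sort(sample.int(pc$n_series, length(i)))
  }
  lit_id <- sprintf("L%03d", seq_len(n_lit))
  lit_size <- pmax(1L, stats::rpois(n_lit, pc$litter_size_mean))

  off <- sprintf("P%04d", seq_len(sum(lit_size)))
  off_lit <- rep(seq_len(n_lit), lit_size)
  animal <- c(animal, off)
  sire <- c(sire, lit_sire[off_lit])
  dam <- c(dam, lit_dam[off_lit])
  series <- c(rep(NA, pc$n_gsires + pc$n_gdams + pc$n_sires + pc$n_dams),
              lit_series[off_lit])

  ped <- pedigree(animal, sire, dam, series = series)
  litter_map <- data.frame(
    animal = off, litter_id = lit_id[off_lit], series = lit_series[off_lit],
    generation = "offspring", stringsAsFactors = FALSE)
  attr(ped, "litter_map") <- litter_map
  attr(ped, "phenotyped") <- off
  ped
}

#' Simulate multi-trait breeding values down a pedigree
#'
#' Founders are drawn from `N(0, G_a)`; each non-founder is the parent
#' average plus a Mendelian-sampling deviation with covariance
#' `0.5 * G_a * (1 - (F_s + F_d) / 2)`, with parental inbreeding
#' coefficients F from the relationship-matrix recursion, so inbreeding is
#' handled exactly. An animal with one unknown parent takes half the known
#' parent's value and the founder-equivalent share of sampling variance.
#'
#' @param ped a [pedigree].
#' @param G_a additive-genetic covariance matrix (traits x traits), PSD.
#' @param seed RNG seed; `NULL` = do not reseed.
#' @return matrix of breeding values, animals (pedigree order) x traits.
#' @export
simulate_breeding_values <- function(ped, G_a, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G_a <- as.matrix(G_a)
  ev <- eigen(G_a, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("G_a is not positive semi-definite")
  }
  k <- nrow(G_a)
  n <- nrow(ped)
  f <- inbreeding(ped)$f
  # PSD square root (chol fails on singular G_a, e.g. the all-zero case)
  e <- eigen(G_a, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  bv <- matrix(0, n, k, dimnames = list(ped$animal, colnames(G_a)))
  Z <- matrix(stats::rnorm(n * k), n, k)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      bv[i, ] <- L %*% Z[i, ]
    } else {
      mid <- numeric(k); fs <- fd <- 0
      if (!is.na(s)) { mid <- mid + bv[s, ] / 2; fs <- f[s] }
      if (!is.na(d)) { mid <- mid + bv[d, ] / 2; fd <- f[d] }
      # unknown parent contributes a founder share of sampling variance
      msvar <- 0.5 * (1 - (fs + fd) / 2) + 0.25 * (is.na(s) + is.na(d))
      bv[i, ] <- mid + sqrt(msvar) * (L %*% Z[i, ])
    }
  }
  bv
}

#' Simulate phenotypes for the phenotyped generation
#'
#' Adds litter effects (shared within litter, covariance `G_ce`), residuals
#' (covariance `R`), fixed-effect contributions from generated covariates
#' (sex, treatment, year of entry, slaughter weight, temperature) and the
#' trait means to the breeding values of the phenotyped animals. Fixed
#' categorical level effects are drawn once per call, centred, and scaled so
#' the total fixed-effect variance per trait matches the configured
#' `var_fixed` allocation.
#'
#' @param ped a pedigree from [simulate_pedigree()] (needs its `litter_map`).
#' @param bv breeding values from [simulate_breeding_values()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed; `NULL` = do not reseed.
#' @return data frame with one row per phenotyped animal: `animal_id`,
#'   `litter_id`, `series`, covariate columns, and one column per trait;
#'   attribute `truth` echoes `cfg`.
#' @export
simulate_phenotypes <- function(ped, bv, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lm_map <- attr(ped, "litter_map")
  if (is.null(lm_map)) stop("pedigree carries no litter map; use simulate_pedigree()")
  tr <- cfg$traits
  miss <- setdiff(tr$trait, colnames(bv))
  if (length(miss)) stop("breeding values missing trait(s): ",
                         paste(miss, collapse = ", "))
  ids <- lm_map$animal
  n <- length(ids)
  k <- nrow(tr)

  G_ce <- cfg$cor_ce * outer(sqrt(tr$v_ce), sqrt(tr$v_ce))
  R <- cfg$cor_r * outer(sqrt(tr$v_r), sqrt(tr$v_r))
  lits <- unique(lm_map$litter_id)
  ce_lit <- mvn_draw(length(lits), G_ce)
  rownames(ce_lit) <- lits
  ce <- ce_lit[lm_map$litter_id, , drop = FALSE]
  resid <- mvn_draw(n, R)

  cv <- cfg$covariates
  sex <- sample(names(cv$sex_probs), n, replace = TRUE, prob = cv$sex_probs)
  treatment <- sample(names(cv$treatment_probs), n, replace = TRUE,
                      prob = cv$treatment_probs)
  yr_of_series <- cv$years[1 + (seq_len(cfg$pedigree$n_series) - 1) %%
                             length(cv$years)]
  year <- yr_of_series[lm_map$series]
  sw <- stats::rnorm(n, cv$slaughter_bw["mean"], cv$slaughter_bw["sd"])
  temp <- stats::rnorm(n, cv$temperature["mean"], cv$temperature["sd"])
  start_bw <- stats::rnorm(n, cv$start_bw["mean"], cv$start_bw["sd"])
  start_age <- stats::rnorm(n, cv$start_age["mean"], cv$start_age["sd"])

  sh <- cfg$var_shares
  fixed <- matrix(0, n, k)
  for (j in seq_len(k)) {
    vf <- tr$var_fixed[j]
    if (vf <= 0) next
    # level effects standardised so the population variance over the
    # assignment distribution equals the allocated share exactly
    eff <- function(labels, probs, share) {
      e <- stats::rnorm(length(labels))
      e <- e - sum(probs * e) / sum(probs)
      v <- sum(probs * e^2) / sum(probs)
      stats::setNames(e * sqrt(share * vf / v), labels)
    }
    sex_e <- eff(names(cv$sex_probs), cv$sex_probs, sh["sex"])
    trt_e <- eff(names(cv$treatment_probs), cv$treatment_probs, sh["treatment"])
    yr_lev <- as.character(unique(yr_of_series))
    yr_e <- eff(yr_lev, rep(1 / length(yr_lev), length(yr_lev)), sh["year"])
    fixed[, j] <- sex_e[sex] + trt_e[treatment] + yr_e[as.character(year)] +
      sqrt(sh["weight"] * vf) * (sw - cv$slaughter_bw["mean"]) / cv$slaughter_bw["sd"] +
      sqrt(sh["temperature"] * vf) * (temp - cv$temperature["mean"]) / cv$temperature["sd"]
  }

  pheno <- matrix(rep(tr$mean, each = n), n, k) +
    bv[ids, tr$trait, drop = FALSE] + ce + resid + fixed
  colnames(pheno) <- tr$trait

  out <- data.frame(animal_id = ids, litter_id = lm_map$litter_id,
                    series = lm_map$series, sex = sex, treatment = treatment,
                    year_of_change = factor(year),
                    slaughter_bw = sw, temperature = temp,
                    start_bw = start_bw, start_age = start_age,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pheno))
  attr(out, "truth") <- cfg
  out
}

mvn_draw <- function(n, S) {
  k <- nrow(S)
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  matrix(stats::rnorm(n * k), n, k) %*% t(L)
}

#' Back-generate raw animal records from simulated trait values
#'
#' Inverts the phenotype-derivation formulas so that running
#' [derive_phenotypes()] on the returned records reproduces the simulated
#' `pe`, `phe`, `adg` and `adfi` values to machine precision: the period
#' duration comes from ADG and the weights, total feed from ADFI, crude
#' protein and phosphorus intakes from configured dietary fractions, and the
#' DXA lean and bone-mineral masses are solved from the carcass-composition
#' calibrations given the required retained masses. The derived FCR is
#' ADFI/ADG by construction. Records whose inversion leaves the feasible
#' range (non-positive DXA masses) are re-drawn with a fresh half-carcass
#' proportion and flagged if still infeasible.
#'
#' @param pheno trait table from [simulate_phenotypes()] (needs columns
#'   `pe`, `phe`, `adg`, `adfi` and the covariates).
#' @param cfg a [sim_config()].
#' @param baseline a `baseline_composition`, see [default_baseline()].
#' @param seed RNG seed; `NULL` = do not reseed.
#' @return records data frame in the [derive_phenotypes()] input schema.
#' @export
back_generate_observables <- function(pheno, cfg = sim_config(),
                                      baseline = default_baseline(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("pe", "phe", "adg", "adfi", "sex", "slaughter_bw", "start_bw",
            "start_age")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(pheno)
  cc <- cfg$carcass

  duration <- (pheno$slaughter_bw - pheno$start_bw) / pheno$adg
  slaughter_age <- pheno$start_age + duration
  feed <- pheno$adfi * duration
  cp_intake <- feed * 1000 * cfg$diet$cp_frac
  p_intake <- feed * 1000 * cfg$diet$p_frac

  base <- baseline_content(pheno$sex, pheno$start_bw, baseline)
  cp_sl <- pheno$pe * cp_intake + base$protein
  ph_sl <- pheno$phe * p_intake + base$phosphorus

  total_cw <- cc$dressing * pheno$slaughter_bw
  flagged <- logical(n)
  half_prop <- lean <- bmc <- numeric(n)
  for (attempt in 1:10) {
    todo <- which(attempt == 1 | (lean <= 0 | bmc <= 0))
    if (!length(todo)) break
    hp <- stats::rnorm(length(todo), cc$half_prop_mean, cc$half_prop_sd)
    half_prop[todo] <- hp
    lean[todo] <- (cp_sl[todo] + 482.745) / (0.23 * hp)
    bmc[todo] <- (ph_sl[todo] + 6.388 - 0.004 * lean[todo] * hp) / (0.109 * hp)
  }
  flagged <- lean <= 0 | bmc <= 0
  if (any(flagged)) {
    warning(sum(flagged), " record(s) outside the invertible range of the ",
            "carcass calibrations", call. = FALSE)
  }

  out <- data.frame(
    animal_id = pheno$animal_id,
    sex = pheno$sex,
    start_bw = pheno$start_bw, start_age = pheno$start_age,
    slaughter_bw = pheno$slaughter_bw, slaughter_age = slaughter_age,
    feed_intake_total = feed, cp_intake = cp_intake, p_intake = p_intake,
    dxa_lean = lean, dxa_bmc = bmc,
    left_half_weight = half_prop * total_cw, total_carcass_weight = total_cw,
    infeasible = flagged,
    stringsAsFactors = FALSE
  )
  for (cov in c("treatment", "litter_id", "series", "year_of_change",
                "temperature")) {
    if (cov %in% names(pheno)) out[[cov]] <- pheno[[cov]]
  }
  out
}

#' Simulate the water-holding (meat-quality) block
#'
#' Drip and cooking loss for a subset of phenotyped animals, with their own
#' additive architecture on the shared pedigree (no litter term, matching
#' the carcass-trait models), back-generated into chop weights `w1 >= w2 >=
#' w3` so the water-holding formulas reproduce the simulated losses.
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed; `NULL` = do not reseed.
#' @return data frame `animal_id`, `w1`, `w2`, `w3` (g) plus true
#'   `drip_loss`, `cooking_loss` as attribute `truth_traits`.
#' @export
simulate_meat_quality <- function(ped, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mt <- cfg$meat$traits
  ids <- attr(ped, "phenotyped")
  ids <- ids[seq_len(min(cfg$meat$n_subset, length(ids)))]
  G_a <- cfg$meat$rg * outer(sqrt(mt$v_a), sqrt(mt$v_a))
  diag(G_a) <- mt$v_a
  dimnames(G_a) <- list(mt$trait, mt$trait)
  bv <- simulate_breeding_values(ped, G_a)
  v_r <- mt$v_p - mt$v_a
  cov_r <- cfg$meat$rp * sqrt(prod(mt$v_p)) - cfg$meat$rg * sqrt(prod(mt$v_a))
  R <- matrix(c(v_r[1], cov_r, cov_r, v_r[2]), 2)
  resid <- mvn_draw(length(ids), R)
  traits <- sweep(bv[ids, ] + resid, 2, mt$mean, "+")
  traits[traits < 0.1] <- 0.1  # losses cannot be negative; rare tail clip

  w1 <- stats::rnorm(length(ids), cfg$meat$w1["mean"], cfg$meat$w1["sd"])
  w2 <- w1 * (1 - traits[, "drip_loss"] / 100)
  w3 <- w2 * (1 - traits[, "cooking_loss"] / 100)
  out <- data.frame(animal_id = ids, w1 = w1, w2 = w2, w3 = w3,
                    stringsAsFactors = FALSE)
  attr(out, "truth_traits") <- data.frame(animal_id = ids,
                                          drip_loss = traits[, "drip_loss"],
                                          cooking_loss = traits[, "cooking_loss"])
  out
}

#' Simulate a sensory panel score table
#'
#' Every judge scores every sample in a session layout; scores are the
#' overall mean plus random judge and session effects, the configured
#' protein-efficiency group effect per attribute, and residual noise,
#' truncated to the 0-10 line scale.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; `NULL` = do not reseed.
#' @return long-format data frame: `judge`, `session`, `sample`, `sex`,
#'   `pe_group`, `fat_thickness`, `attribute`, `score`.
#' @export
simulate_sensory <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  sc <- cfg$sensory
  groups <- rep(names(sc$n_per_group), sc$n_per_group)
  n_samp <- length(groups)
  samples <- data.frame(
    sample = sprintf("M%02d", seq_len(n_samp)),
    pe_group = groups,
    sex = sample(names(sc$sex_probs), n_samp, replace = TRUE, prob = sc$sex_probs),
    fat_thickness = sample(names(sc$fat_probs), n_samp, replace = TRUE,
                           prob = sc$fat_probs),
    session = rep_len(seq_len(sc$n_sessions), n_samp),
    stringsAsFactors = FALSE
  )
  judges <- sprintf("J%d", seq_len(sc$n_judges))
  attrs <- names(sc$group_effects)

  out <- list()
  for (at in attrs) {
    je <- stats::rnorm(sc$n_judges, 0, sc$judge_sd)
    se <- stats::rnorm(sc$n_sessions, 0, sc$session_sd)
    grid <- expand.grid(judge = judges, sample = samples$sample,
                        stringsAsFactors = FALSE)
    si <- match(grid$sample, samples$sample)
    score <- sc$overall_mean + je[match(grid$judge, judges)] +
      se[samples$session[si]] +
      sc$group_effects[[at]][samples$pe_group[si]] +
      stats::rnorm(nrow(grid), 0, sc$resid_sd)
    out[[at]] <- data.frame(
      judge = grid$judge,
      session = sprintf("ses%d", samples$session[si]),
      sample = grid$sample,
      sex = samples$sex[si], pe_group = samples$pe_group[si],
      fat_thickness = samples$fat_thickness[si],
      attribute = at, score = pmin(10, pmax(0, score)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a complete study-shaped dataset
#'
#' Orchestrates pedigree, breeding values, phenotypes, back-generated raw
#' records, the meat-quality block and the sensory table under a single
#' seed.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return list with `pedigree`, `breeding_values`, `phenotypes` (true trait
#'   table), `records` (raw schema for [derive_phenotypes()]), `meat`,
#'   `sensory`, and `truth` (the config).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  ped <- simulate_pedigree(cfg, seed = NULL)
  G_a <- cfg$cor_g * outer(sqrt(cfg$traits$v_a), sqrt(cfg$traits$v_a))
  dimnames(G_a) <- list(cfg$traits$trait, cfg$traits$trait)
  bv <- simulate_breeding_values(ped, G_a)
  pheno <- simulate_phenotypes(ped, bv, cfg)
  records <- back_generate_observables(pheno, cfg)
  meat <- simulate_meat_quality(ped, cfg)
  sensory <- simulate_sensory(cfg, seed = NULL)
  list(pedigree = ped, breeding_values = bv, phenotypes = pheno,
       records = records, meat = meat, sensory = sensory, truth = cfg)
}
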