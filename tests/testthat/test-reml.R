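# half-sib study design used by several tests: s sires, k progeny each,
# animal model pedigree (sires + dams unrelated founders)
half_sib_data <- function(s = 50, k = 20, v_s = 0.3, v_e = 1, seed = 1,
                          beta_sex = 0) {
  set.seed(seed)
  sire <- rep(seq_len(s), each = k)
  u <- rnorm(s, 0, sqrt(v_s))
  sex <- rep_len(c(0, 1), s * k)
  y <- 2 + beta_sex * sex + u[sire] + rnorm(s * k, 0, sqrt(v_e))
  list(y = y, sire = factor(sire), sex = sex,
       X = cbind(`(Intercept)` = 1, sex = sex))
}

test_that("REML equals the closed-form ANOVA components on balanced data", {
  d <- half_sib_data(seed = 42)
  Z <- model.matrix(~ d$sire - 1)
  fit <- reml_fit(d$y, matrix(1, length(d$y), 1), list(sire = list(Z = Z)))
  ref <- anova_sire(d$y, d$sire)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta["sire"]), unname(ref["sigma2_s"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$theta["residual"]), unname(ref["sigma2_e"]),
               tolerance = 1e-4)
})

test_that("the REML optimum matches a brute-force likelihood grid on a toy pedigree", {
  ped <- pedigree(
    c("s1", "d1", "d2", "o1", "o2", "o3", "o4", "o5"),
    c(NA, NA, NA, "s1", "s1", "s1", "s1", "o1"),
    c(NA, NA, NA, "d1", "d1", "d2", "d2", "d2"))
  A <- additive_relationship(ped)
  set.seed(10)
  y <- c(0.2, -0.1, 0.4, 1.2, 0.8, 1.5, 0.3, 1.1)
  X <- matrix(1, 8, 1)
  fit <- reml_fit(y, X, list(animal = list(M = A, q = 8)))
  # coarse-to-fine grid at final resolution 1e-3
  coarse <- grid_reml(y, X, A, seq(0.001, 3, by = 0.02), seq(0.001, 3, by = 0.02))
  fine <- grid_reml(y, X, A,
                    seq(max(1e-4, coarse["v_a"] - 0.05), coarse["v_a"] + 0.05, by = 1e-3),
                    seq(max(1e-4, coarse["v_e"] - 0.05), coarse["v_e"] + 0.05, by = 1e-3))
  expect_lt(abs(fit$theta["animal"] - fine["v_a"]), 2e-3)
  expect_lt(abs(fit$theta["residual"] - fine["v_e"]), 2e-3)
})

test_that("pure-noise data drive the additive component to the boundary", {
  h2 <- vapply(1:20, function(r) {
    d <- half_sib_data(s = 25, k = 20, v_s = 0, v_e = 1, seed = 400 + r)
    Z <- model.matrix(~ d$sire - 1)
    fit <- reml_fit(d$y, matrix(1, length(d$y), 1), list(sire = list(Z = Z)))
    unname(fit$theta["sire"] / sum(fit$theta))
  }, 0)
  # estimates are truncated at the zero boundary, so their mean is a small
  # positive number even under the null; allow that truncation offset
  emp_se <- sd(h2) / sqrt(length(h2))
  expect_lt(mean(h2), 2 * emp_se + 0.01)
  expect_true(all(h2 >= 0))
  expect_gt(mean(h2 < 0.01), 0.3)  # most replicates sit at the boundary
})

test_that("restricted log-likelihood is monotone over the iteration trace", {
  d <- half_sib_data(s = 20, k = 8, seed = 77)
  Z <- model.matrix(~ d$sire - 1)
  trace <- capture.output(
    fit <- reml_fit(d$y, d$X, list(sire = list(Z = Z)), verbose = TRUE))
  ll <- as.numeric(sub(".*logL ([-0-9.]+).*", "\\1", trace[grepl("logL", trace)]))
  expect_true(all(diff(ll) >= -1e-7))
})

test_that("h2 is invariant to response rescaling and translation", {
  sim <- simulate_dataset(sim_config(seed = 55))
  ph <- sim$phenotypes[1:400, ]
  ped <- sim$pedigree
  f0 <- fit_animal_model(ph, "pe", ~ sex, ped, litter = "litter_id")
  ph$pe2 <- 1000 * ph$pe
  f1 <- fit_animal_model(ph, "pe2", ~ sex, ped, litter = "litter_id")
  expect_equal(f1$parameters$estimate[f1$parameters$parameter == "h2"],
               f0$parameters$estimate[f0$parameters$parameter == "h2"],
               tolerance = 1e-4)
  expect_equal(unname(f1$theta), unname(f0$theta) * 1e6, tolerance = 1e-3)
  # adding a sex-linked constant only shifts the fixed part
  ph$pe3 <- ph$pe + 5 + 2 * (ph$sex == "female")
  f2 <- fit_animal_model(ph, "pe3", ~ sex, ped, litter = "litter_id")
  expect_equal(unname(f2$theta), unname(f0$theta), tolerance = 1e-5)
})

test_that("true variance components are recovered on study-shaped replicates", {
  # scaled-down pedigree, protein-efficiency architecture
  cfg <- sim_config()
  cfg$pedigree$n_sires <- 12
  cfg$pedigree$n_dams <- 24
  cfg$pedigree$dams_per_litter_count <- c(`1` = 15, `2` = 6, `3` = 3)
  h2 <- ce2 <- numeric(20)
  for (r in 1:20) {
    sim <- simulate_dataset(cfg, seed = 500 + r)
    fx <- ~ sex + treatment + year_of_change + slaughter_bw + temperature
    fit_pe <- fit_animal_model(sim$phenotypes, "pe", fx,
                               sim$pedigree, litter = "litter_id")
    # litter-share recovery is checked on ADFI, which has a real litter
    # variance (the PE litter share is ~0 and its truncated-at-zero
    # estimates are uninformative at this scale)
    fit_adfi <- fit_animal_model(sim$phenotypes, "adfi", fx,
                                 sim$pedigree, litter = "litter_id")
    h2[r] <- fit_pe$parameters$estimate[fit_pe$parameters$parameter == "h2"]
    ce2[r] <- fit_adfi$parameters$estimate[fit_adfi$parameters$parameter == "ce2"]
  }
  tr <- cfg$traits[cfg$traits$trait == "pe", ]
  expect_lt(abs(mean(h2) - tr$v_a / tr$v_p), 2 * sd(h2) / sqrt(20))
  tra <- cfg$traits[cfg$traits$trait == "adfi", ]
  expect_lt(abs(mean(ce2) - tra$v_ce / tra$v_p),
            2 * sd(ce2) / sqrt(20) + 0.02)
})

test_that("delta-method SEs agree with a parametric bootstrap", {
  # simulate once, treat the REML fit as truth, bootstrap 200 draws
  d <- half_sib_data(s = 30, k = 14, v_s = 0.4, v_e = 1, seed = 123)
  n <- length(d$y)
  Z <- model.matrix(~ d$sire - 1)
  X <- matrix(1, n, 1)
  fit <- reml_fit(d$y, X, list(sire = list(Z = Z)))
  vs <- unname(fit$theta["sire"]); ve <- unname(fit$theta["residual"])
  h2_fun <- function(th) th[1] / sum(th)
  set.seed(321)
  boot <- vapply(1:200, function(b) {
    yb <- drop(X %*% fit$beta) + Z %*% rnorm(30, 0, sqrt(vs)) +
      rnorm(n, 0, sqrt(ve))
    fb <- reml_fit(drop(yb), X, list(sire = list(Z = Z)), tol_ll = 1e-6)
    c(fb$theta, h2 = h2_fun(fb$theta))
  }, c(sire = 0, residual = 0, h2 = 0))
  se_delta <- component_se(fit)
  expect_lt(abs(se_delta["sire"] - sd(boot["sire", ])),
            0.25 * sd(boot["sire", ]))
  expect_lt(abs(se_delta["residual"] - sd(boot["residual", ])),
            0.25 * sd(boot["residual", ]))
  par <- genetic_parameters(fit)
  se_h2 <- par$se[par$parameter == "h2"]
  expect_lt(abs(se_h2 - sd(boot["h2", ])), 0.25 * sd(boot["h2", ]))
})

test_that("delta-method h2 SE matches the hand formula for diagonal information", {
  # fabricated converged fit with known diagonal covariance of components
  fit <- structure(list(
    theta = c(animal = 0.4, litter = 0.1, residual = 0.5),
    vcov_theta = diag(c(0.01, 0.002, 0.005)),
    trait = "toy"), class = "reml_fit")
  par <- genetic_parameters(fit)
  # h2 = va/vp: grad = ((vp-va)/vp^2, -va/vp^2, -va/vp^2) with vp = 1
  g <- c(0.6, -0.4, -0.4)
  se_hand <- sqrt(sum(g^2 * c(0.01, 0.002, 0.005)))
  expect_equal(par$se[par$parameter == "h2"], se_hand)
  # infinite information (fixed components) -> zero SE
  fit$vcov_theta <- diag(c(0, 0, 0))
  expect_equal(genetic_parameters(fit)$se[1], 0)
})

test_that("rank-deficient X and pedigree gaps are rejected in build_design", {
  sim <- simulate_dataset(sim_config(seed = 66))
  ph <- sim$phenotypes[1:50, ]
  ph$dup <- ph$slaughter_bw
  expect_message(
    des <- build_design(ph, "pe", ~ slaughter_bw + dup, sim$pedigree,
                        litter = "litter_id"),
    "aliased")
  expect_equal(qr(des$X)$rank, ncol(des$X))
  ph2 <- ph
  ph2$animal_id[1] <- "ghost"
  expect_error(build_design(ph2, "pe", ~ sex, sim$pedigree), "ghost")
  # litter incidence has unit row sums
  expect_equal(unname(rowSums(des$Z_c)), rep(1, nrow(ph)))
})
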