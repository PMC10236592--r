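test_that("a one-litter design yields full sibs with a = 0.5", {
  cfg <- sim_config()
  cfg$pedigree$n_gsires <- 1
  cfg$pedigree$n_gdams <- 2
  cfg$pedigree$n_sires <- 1
  cfg$pedigree$n_dams <- 1
  cfg$pedigree$dams_per_litter_count <- c(`1` = 1)
  cfg$pedigree$litter_size_mean <- 2
  ped <- simulate_pedigree(cfg, seed = 3)
  off <- attr(ped, "phenotyped")
  A <- additive_relationship(ped)
  if (length(off) >= 2) {
    expect_gte(A[off[1], off[2]], 0.5)  # full sibs (>= if parents related)
  }
  expect_s3_class(ped, "pedigree")
})

test_that("the default design is study-shaped and deterministic under a seed", {
  cfg <- sim_config()
  ped1 <- simulate_pedigree(cfg, seed = 11)
  ped2 <- simulate_pedigree(cfg, seed = 11)
  expect_identical(ped1, ped2)
  n_off <- length(attr(ped1, "phenotyped"))
  # 118 litters x mean 9.08 piglets: ~1071 phenotyped, Poisson noise
  expect_lt(abs(n_off - 1071), 4 * sqrt(1071))
  # total pedigree is on the reported ~1468-animal scale
  expect_lt(abs(nrow(ped1) - 1468), 120)
  expect_equal(pedigree_depth(ped1), 3)
  lm_map <- attr(ped1, "litter_map")
  expect_equal(length(unique(lm_map$litter_id)), 48 + 2 * 23 + 3 * 8)
  expect_lte(max(lm_map$series), cfg$pedigree$n_series)
})

test_that("infeasible litter designs are rejected", {
  cfg <- sim_config()
  cfg$pedigree$dams_per_litter_count <- c(`1` = 79)
  cfg$pedigree$n_dams <- 78
  expect_error(simulate_pedigree(cfg, seed = 1), "sum to n_dams")
  cfg2 <- sim_config()
  cfg2$pedigree$n_series <- 2
  expect_error(simulate_pedigree(cfg2, seed = 1), "infeasible")
})

test_that("breeding values follow the Mendelian-sampling rule", {
  # zero genetic variance -> all breeding values zero
  ped <- simulate_pedigree(sim_config(), seed = 5)
  bv0 <- simulate_breeding_values(ped, matrix(0, 2, 2), seed = 1)
  expect_equal(max(abs(bv0)), 0)
  expect_error(simulate_breeding_values(ped, matrix(c(1, 2, 2, 1), 2), seed = 1),
               "positive semi-definite")

  # Mendelian deviation variance of offspring of fixed non-inbred parents
  trio <- pedigree(c(rep(NA, 0), "S", "D", paste0("O", 1:10000)),
                   c(NA, NA, rep("S", 10000)), c(NA, NA, rep("D", 10000)))
  v_a <- 0.8
  bv <- simulate_breeding_values(trio, matrix(v_a), seed = 42)
  dev <- bv[-(1:2), 1] - (bv["S", 1] + bv["D", 1]) / 2
  expect_lt(abs(var(dev) - 0.5 * v_a) / (0.5 * v_a), 0.03)

  # founder covariance reproduces G_a
  G <- matrix(c(1, 0.6, 0.6, 2), 2)
  found <- pedigree(paste0("F", 1:8000), rep(NA, 8000), rep(NA, 8000))
  bvf <- simulate_breeding_values(found, G, seed = 9)
  expect_lt(max(abs(cov(bvf) - G)), 0.1)
})

test_that("full-sib phenotypic covariance is near 0.5 V_A + V_CE", {
  cfg <- sim_config()
  cfg$traits$var_fixed[] <- 0  # isolate the random part
  covs <- vapply(1:30, function(r) {
    sim <- simulate_dataset(cfg, seed = 900 + r)
    ph <- sim$phenotypes
    # covariance between random pairs of littermates for pe
    sp <- split(ph$pe, ph$litter_id)
    pairs <- t(vapply(sp[lengths(sp) >= 2], function(v) v[1:2], c(0, 0)))
    cov(pairs[, 1], pairs[, 2])
  }, 0)
  tr <- cfg$traits[cfg$traits$trait == "pe", ]
  expected <- 0.5 * tr$v_a + tr$v_ce
  expect_lt(abs(mean(covs) - expected), 3 * sd(covs) / sqrt(length(covs)))
})

test_that("generator defaults hit the published protein-efficiency spread", {
  sim <- simulate_dataset(sim_config(seed = 1))
  pe <- sim$phenotypes$pe
  n <- length(pe)
  expect_lt(abs(mean(pe) - 0.39), 2 * 0.04 / sqrt(n) + 0.002)
  expect_lt(abs(sd(pe) - 0.04), 0.15 * 0.04)
})

test_that("back-generated records round-trip through derivation exactly", {
  sim <- simulate_dataset(sim_config(seed = 17))
  d <- derive_phenotypes(sim$records)$phenotypes
  for (tr in c("pe", "phe", "adg", "adfi")) {
    expect_lt(max(abs(d[[tr]] - sim$phenotypes[[tr]])), 1e-8)
  }
  # lean inversion example: target CP 4117.255 g at P = 0.5 -> 40 kg lean
  expect_equal((4117.255 + 482.745) / (0.23 * 0.5), 40000)
  # zero-retention protein efficiency maps to cp_slaughter == cp_start
  ph0 <- sim$phenotypes[1:3, ]
  ph0$pe <- 0
  rec0 <- back_generate_observables(ph0, sim$truth)
  base <- baseline_content(rec0$sex, rec0$start_bw)
  cp_sl <- carcass_protein(rec0$dxa_lean,
                           rec0$left_half_weight / rec0$total_carcass_weight)
  expect_equal(cp_sl, base$protein, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("offspring-midparent regression tracks h2 when V_CE = 0", {
  # single trait, no litter variance, no fixed effects; parents get
  # phenotypes too, so regress offspring on mid-parent directly
  v_a <- 0.5; v_e <- 0.5
  slope <- vapply(1:40, function(r) {
    set.seed(1000 + r)
    n_fam <- 150
    sires <- paste0("s", 1:n_fam); dams <- paste0("d", 1:n_fam)
    kids <- paste0("k", 1:n_fam)
    ped <- pedigree(c(sires, dams, kids), c(rep(NA, 2 * n_fam), sires),
                    c(rep(NA, 2 * n_fam), dams))
    bv <- simulate_breeding_values(ped, matrix(v_a))
    phen <- bv[, 1] + rnorm(3 * n_fam, 0, sqrt(v_e))
    mid <- (phen[sires] + phen[dams]) / 2
    coef(lm(phen[kids] ~ mid))[2]
  }, 0)
  h2 <- v_a / (v_a + v_e)
  expect_lt(abs(mean(slope) - h2), 2 * sd(slope) / sqrt(length(slope)))
})

test_that("whole datasets are byte-identical under a fixed seed", {
  s1 <- simulate_dataset(sim_config(seed = 33))
  s2 <- simulate_dataset(sim_config(seed = 33))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$sensory, s2$sensory)
  expect_identical(s1$meat, s2$meat)
})
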