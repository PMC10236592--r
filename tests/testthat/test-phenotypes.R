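test_that("carcass protein calibration matches direct arithmetic", {
  expect_equal(carcass_protein(40000, 0.5), 4117.255)
  # zero crossing of the calibration line (flagged as non-positive)
  x0 <- 482.745 / 0.23
  expect_warning(cp0 <- carcass_protein(x0 / 0.5, 0.5), "non-positive")
  expect_equal(cp0, 0, tolerance = 1e-12)
  expect_warning(carcass_protein(1000, 0.5), "non-positive")
})

test_that("carcass phosphorus calibration is linear with printed coefficients", {
  expect_equal(carcass_phosphorus(2000, 40000, 0.5), -6.388 + 109 + 80)
  expect_warning(
    expect_equal(carcass_phosphorus(1e-9, 1e-9, 0.5), -6.388, tolerance = 1e-6),
    "non-positive")
  # doubling both DXA masses doubles the non-intercept part exactly
  p1 <- carcass_phosphorus(1500, 30000, 0.48) + 6.388
  p2 <- carcass_phosphorus(3000, 60000, 0.48) + 6.388
  expect_equal(p2, 2 * p1)
})

test_that("baseline content multiplies per-kg composition by start weight", {
  base <- structure(list(protein_per_kg = c(female = 150, castrate = 150),
                         phosphorus_per_kg = c(female = 5, castrate = 5)),
                    class = "baseline_composition")
  got <- baseline_content("female", 20, base)
  expect_equal(got$protein, 3000, ignore_attr = TRUE)
  expect_equal(got$phosphorus, 100, ignore_attr = TRUE)
  # equal per-kg values give equal baselines at equal weight across sexes
  two <- baseline_content(c("female", "castrate"), c(25, 25), base)
  expect_equal(two$protein[1], two$protein[2])
  expect_warning(baseline_content("female", 5, base), "15-30")
  expect_error(baseline_content("entire", 20, base), "no baseline")
})

test_that("efficiency ratios follow the definition and flag bad inputs", {
  expect_equal(protein_efficiency(4117.255, 617.255, 10000), 0.35)
  expect_equal(phosphorus_efficiency(182.612, 82.612, 500), 0.2)
  expect_equal(protein_efficiency(500, 500, 1000), 0)
  expect_error(protein_efficiency(100, 50, 0), "positive")
  expect_error(phosphorus_efficiency(100, 50, -5), "positive")
  expect_warning(protein_efficiency(100, 200, 1000), "negative")
  # scale consistency: same multiplier on retained mass and intake
  expect_equal(protein_efficiency(300 * 7, 100 * 7, 1000 * 7),
               protein_efficiency(300, 100, 1000))
})

test_that("performance traits follow the growth-period formulas", {
  got <- performance_traits(22.3, 106, 70, 170, 250)
  expect_equal(got$adg, (106 - 22.3) / 100)
  expect_equal(got$adfi, 2.5)
  expect_equal(got$fcr, got$adfi / got$adg)
  expect_equal(round(got$fcr, 3), 2.987)
  # ADFI numerically equal to ADG gives FCR exactly 1
  same <- performance_traits(20, 120, 0, 100, 100)
  expect_equal(same$fcr, 1)
  expect_error(performance_traits(20, 100, 70, 70, 200), "exceed")
})

test_that("drip and cooking loss are percentage weight changes", {
  wh <- water_holding(100, 98, 71.54)
  expect_equal(wh$drip_loss, 2)
  expect_equal(wh$cooking_loss, 27)
  expect_warning(water_holding(100, 102, 95), "negative")
  expect_error(water_holding(100, 0, -3), "positive")
})

test_that("residual age is orthogonal to weight and shift-invariant", {
  got <- residual_age(c(170, 180, 175), c(100, 100, 110))
  expect_equal(unname(got), c(-5, 5, 0))
  set.seed(5)
  w <- rnorm(60, 106, 5)
  a <- 60 + 1.1 * w + rnorm(60, 0, 4)
  r <- residual_age(a, w)
  expect_lt(abs(cor(r, w)), 1e-10)
  expect_equal(sum(r), 0, tolerance = 1e-9)
  expect_equal(residual_age(a + 100, w), r, ignore_attr = TRUE)
  # exactly linear ages leave zero residuals
  expect_equal(unname(residual_age(2 * w + 3, w)), rep(0, 60),
               tolerance = 1e-10)
  expect_error(residual_age(a, rep(100, 60)), "degenerate")
})

test_that("derive_phenotypes keeps fcr * adg == adfi to machine precision", {
  sim <- simulate_dataset(sim_config(seed = 21))
  d <- derive_phenotypes(sim$records, meat = sim$meat)
  expect_equal(d$phenotypes$fcr * d$phenotypes$adg, d$phenotypes$adfi,
               tolerance = 1e-12)
  expect_true(all(c("drip_loss", "cooking_loss") %in% names(d$phenotypes)))
})

test_that("the derived synthetic cohort matches the generator targets", {
  sim <- simulate_dataset(sim_config(seed = 2))
  d <- derive_phenotypes(sim$records)$phenotypes
  n <- nrow(d)
  targets <- sim$truth$traits
  for (tr in c("pe", "phe", "adg", "adfi")) {
    i <- match(tr, targets$trait)
    # the cohort mean fluctuates beyond sd/sqrt(n): family breeding values
    # (~40 effective founder lines) and litter effects (~118 litters) are
    # shared across animals
    se_mean <- sqrt(targets$v_a[i] / 40 + targets$v_ce[i] / 80 +
                      targets$sd_target[i]^2 / n)
    expect_lt(abs(mean(d[[tr]]) - targets$mean[i]), 3 * se_mean)
    expect_lt(abs(sd(d[[tr]]) - targets$sd_target[i]),
              0.15 * targets$sd_target[i])
  }
})

test_that("measured carcass composition bypasses the DXA calibrations", {
  sim <- simulate_dataset(sim_config(seed = 31))
  rec <- sim$records[1:5, ]
  rec$cp_measured <- c(NA, 5000, NA, 6000, NA)
  d <- derive_phenotypes(rec)
  base <- baseline_content(rec$sex, rec$start_bw)
  expect_equal(d$phenotypes$pe[2], (5000 - base$protein[2]) / rec$cp_intake[2],
               ignore_attr = TRUE)
  # untouched rows still come from the DXA route
  expect_equal(d$phenotypes$pe[1], sim$phenotypes$pe[1], tolerance = 1e-10)
})

test_that("QC flags implausible efficiencies without dropping rows", {
  sim <- simulate_dataset(sim_config(seed = 41))
  rec <- sim$records[1:4, ]
  rec$dxa_lean[2] <- 1000  # carcass protein below baseline: retention < 0
  d <- suppressWarnings(derive_phenotypes(rec))
  expect_equal(nrow(d$phenotypes), 4)
  expect_true(any(d$qc$flag == "pe_outside_unit_interval"))
  d2 <- derive_phenotypes(rec, drop_flagged = TRUE)
  expect_lt(nrow(d2$phenotypes), 4)
})
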