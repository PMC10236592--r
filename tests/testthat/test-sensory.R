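sensory_sim <- function(seed = 1, judge_sd = 1, session_sd = 0.5,
                        resid_sd = 1, shift = c(HPE = 0, MPE = 0, LPE = 0)) {
  cfg <- sim_config(seed = seed)
  cfg$sensory$judge_sd <- judge_sd
  cfg$sensory$session_sd <- session_sd
  cfg$sensory$resid_sd <- resid_sd
  cfg$sensory$group_effects$juiciness <- shift
  simulate_sensory(cfg, seed = seed)
}

test_that("judge variance is recovered across seeded replicates", {
  # variance 4 for judges, residual 1; estimate averaged over replicates
  est <- vapply(1:20, function(r) {
    cfg <- sim_config(seed = r)
    cfg$sensory$judge_sd <- 2
    cfg$sensory$session_sd <- 0.5
    cfg$sensory$resid_sd <- 1
    dat <- simulate_sensory(cfg, seed = 300 + r)
    fit <- fit_sensory(dat, "firmness")
    unname(fit$theta["judge"])
  }, 0)
  emp_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 4), 2 * emp_se + 0.2)
})

test_that("constant scores drive all variance components to the boundary", {
  dat <- sensory_sim(seed = 2)
  dat$score <- 5
  fit <- suppressWarnings(fit_sensory(dat, "juiciness"))
  expect_lt(fit$theta["judge"], 1e-6)
  expect_lt(fit$theta["session"], 1e-6)
})

test_that("estimates are invariant to record order", {
  dat <- sensory_sim(seed = 3)
  fit1 <- fit_sensory(dat, "tenderness")
  set.seed(1)
  fit2 <- fit_sensory(dat[sample(nrow(dat)), ], "tenderness")
  expect_equal(fit1$theta, fit2$theta, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("the LSD threshold is t * sqrt(2 MSE / n_eff)", {
  expect_equal(qt(0.975, 20) * sqrt(2 * 1 / 8), 1.043, tolerance = 5e-4)
  dat <- sensory_sim(seed = 4)
  fit <- fit_sensory(dat, "flavour")
  lsd <- fisher_lsd(fit, "pe_group")
  n <- table(fit$data$pe_group)
  i <- which(lsd$pairs$level1 == "HPE" & lsd$pairs$level2 == "LPE")
  n_eff <- 2 / (1 / n[["HPE"]] + 1 / n[["LPE"]])
  expect_equal(lsd$pairs$lsd[i],
               qt(0.975, fit$n - fit$p) * sqrt(2 * fit$theta[["residual"]] / n_eff))
})

test_that("identical group means are never separated; symmetry holds", {
  dat <- sensory_sim(seed = 5)
  dat$score <- 5 + rep_len(c(-0.001, 0.001), nrow(dat))
  fit <- suppressWarnings(fit_sensory(dat, "juiciness"))
  lsd <- fisher_lsd(fit, "pe_group")
  expect_true(all(!lsd$pairs$significant))
  expect_true(all(nchar(lsd$means$letters) >= 1))
  # symmetry: the pair table covers each unordered pair exactly once
  keys <- apply(lsd$pairs[, c("level1", "level2")], 1,
                function(r) paste(sort(r), collapse = "|"))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("a 5-SD shifted group separates from both others (juiciness pattern)", {
  dat <- sensory_sim(seed = 6, judge_sd = 0.5, session_sd = 0.3, resid_sd = 1,
                     shift = c(HPE = -5, MPE = 0, LPE = 0))
  fit <- fit_sensory(dat, "juiciness")
  lsd <- fisher_lsd(fit, "pe_group")
  sig <- function(a, b) {
    i <- (lsd$pairs$level1 == a & lsd$pairs$level2 == b) |
         (lsd$pairs$level1 == b & lsd$pairs$level2 == a)
    lsd$pairs$significant[i]
  }
  expect_true(sig("HPE", "LPE"))
  expect_true(sig("HPE", "MPE"))
  expect_false(sig("MPE", "LPE"))
  # letters: HPE alone, MPE and LPE share a letter
  lh <- lsd$means$letters[lsd$means$level == "HPE"]
  lm <- lsd$means$letters[lsd$means$level == "MPE"]
  ll <- lsd$means$letters[lsd$means$level == "LPE"]
  expect_false(any(strsplit(lh, "")[[1]] %in% strsplit(lm, "")[[1]]))
  expect_true(any(strsplit(lm, "")[[1]] %in% strsplit(ll, "")[[1]]))
})

test_that("with no random effects and balance, LSD reduces to pairwise t-tests", {
  set.seed(8)
  g <- rep(c("HPE", "MPE", "LPE"), each = 12)
  dat <- data.frame(judge = "J1", session = "s1", attribute = "juiciness",
                    score = rnorm(36, 5 + (g == "HPE") * 1.2, 1),
                    pe_group = g, sex = rep(c("castrate", "female"), 18),
                    fat_thickness = "1.5cm")
  fit <- suppressWarnings(
    fit_sensory(dat, "juiciness", fixed = "pe_group"))
  lsd <- fisher_lsd(fit, "pe_group")
  for (i in seq_len(nrow(lsd$pairs))) {
    a <- lsd$pairs$level1[i]; b <- lsd$pairs$level2[i]
    tt <- t.test(dat$score[g == a], dat$score[g == b], var.equal = TRUE)
    # pooled-variance t-test on 22 df vs LSD on the 33-df model MSE:
    # same mean difference; significance agrees away from the margin
    expect_equal(unname(lsd$pairs$diff[i]), unname(diff(rev(tt$estimate))),
                 tolerance = 1e-8)
    p_lsd <- 2 * pt(-abs(lsd$pairs$diff[i]) /
                      sqrt(2 * lsd$ms_error / 12), lsd$df)
    expect_equal(lsd$pairs$significant[i], p_lsd < 0.05)
  }
})

test_that("single-level factors are dropped with a warning", {
  dat <- sensory_sim(seed = 9)
  dat$sex <- "castrate"
  expect_warning(fit <- fit_sensory(dat, "firmness"), "single level")
  expect_false("sex" %in% fit$fixed_terms)
})
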