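# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Gene dropping: estimate numerator relationships and inbreeding by
# simulating allele descent. Founders get unique allele labels; each
# offspring inherits one random allele per parent. a_ij is twice the
# probability that random alleles from i and j are identical by descent;
# F_i the probability i's two alleles are IBD.
gene_drop <- function(ped, ndrops = 1e5) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  a1 <- matrix(0L, ndrops, n)
  a2 <- matrix(0L, ndrops, n)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      a1[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(ndrops) < 0.5
      a1[, i] <- ifelse(pick, a1[, si[i]], a2[, si[i]])
    }
    if (is.na(di[i])) {
      a2[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(ndrops) < 0.5
      a2[, i] <- ifelse(pick, a1[, di[i]], a2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      p_ibd <- (mean(a1[, i] == a1[, j]) + mean(a1[, i] == a2[, j]) +
                mean(a2[, i] == a1[, j]) + mean(a2[, i] == a2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * p_ibd
    }
  }
  f <- vapply(seq_len(n), function(i) mean(a1[, i] == a2[, i]), 0)
  list(A = A, f = stats::setNames(f, ped$animal))
}

# random multi-generation pedigree for property tests
random_pedigree <- function(n_founders = 10, n_per_gen = 10, n_gen = 2,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  animal <- paste0("F", seq_len(n_founders))
  sire <- dam <- rep(NA_character_, n_founders)
  pool <- animal
  for (g in seq_len(n_gen)) {
    ids <- paste0("G", g, "_", seq_len(n_per_gen))
    s <- sample(pool, n_per_gen, replace = TRUE)
    d <- vapply(seq_len(n_per_gen), function(i) {
      cand <- setdiff(pool, s[i])
      sample(cand, 1)
    }, "")
    animal <- c(animal, ids)
    sire <- c(sire, s)
    dam <- c(dam, d)
    pool <- c(pool, ids)
  }
  pedigree(animal, sire, dam)
}

# closed-form REML surface for V = v_a * K + v_e * I via eigendecomposition
# on the fixed-effect residual space; supports brute-force grid search
grid_reml <- function(y, X, K, va_grid, ve_grid) {
  n <- length(y)
  p <- qr(X)$rank
  # contrast basis orthogonal to X
  Q <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  Kr <- crossprod(Q, K %*% Q)
  eg <- eigen(Kr, symmetric = TRUE)
  w <- drop(crossprod(eg$vectors, crossprod(Q, y)))
  best <- c(NA, NA, -Inf)
  for (va in va_grid) {
    lam <- va * eg$values
    for (ve in ve_grid) {
      d <- lam + ve
      ll <- -0.5 * (sum(log(d)) + sum(w^2 / d))
      if (ll > best[3]) best <- c(va, ve, ll)
    }
  }
  names(best) <- c("v_a", "v_e", "loglik")
  best
}

# balanced one-way ANOVA variance components (sire model closed form)
anova_sire <- function(y, sire) {
  sire <- factor(sire)
  k <- length(y) / nlevels(sire)
  gm <- mean(y)
  msb <- sum(tapply(y, sire, function(v) k * (mean(v) - gm)^2)) /
    (nlevels(sire) - 1)
  msw <- sum((y - stats::ave(y, sire))^2) / (length(y) - nlevels(sire))
  c(sigma2_s = (msb - msw) / k, sigma2_e = msw)
}
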