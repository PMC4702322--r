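test_that("BH adjustment matches the hand example and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.1, NA, 0.02)), c(0.1, NA, 0.04))

  set.seed(123)
  for (i in 1:50) {
    p <- round(runif(sample(3:40, 1)), 3)   # rounding forces ties
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("NB GLM agrees with the reference fixed-theta fit", {
  set.seed(201)
  x <- factor(rep(1:3, each = 6))
  X <- model.matrix(~x)
  mu <- exp(3 + c(0, 0.5, -0.4)[x])
  phi <- 0.15
  y <- rnbinom(length(x), mu = mu, size = 1 / phi)
  ours <- fit_nb_glm(y, X, phi)
  ref <- glm(y ~ x, family = MASS::negative.binomial(theta = 1 / phi))
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(ours$deviance, deviance(ref), tolerance = 1e-6)

  # intercept-only fit in the Poisson limit recovers the arithmetic mean
  f0 <- fit_nb_glm(y, X[, 1, drop = FALSE], 0)
  expect_equal(unname(exp(f0$coef[1])), mean(y), tolerance = 1e-8)

  # offsets shift the intercept exactly
  off <- log(seq(1, 2, length.out = length(y)))
  fo <- fit_nb_glm(y, X, phi, offset = off)
  refo <- glm(y ~ x + offset(off),
              family = MASS::negative.binomial(theta = 1 / phi))
  expect_equal(unname(fo$coef), unname(coef(refo)), tolerance = 1e-6)
})

test_that("deviance nesting and the saturated-model limit hold", {
  set.seed(202)
  x <- factor(rep(1:4, each = 5)); z <- factor(rep(1:2, 10))
  y <- rnbinom(20, mu = 40, size = 8)
  phi <- 0.12
  X0 <- model.matrix(~1, data.frame(x)); X1 <- model.matrix(~x)
  X2 <- model.matrix(~ x + z); Xs <- model.matrix(~ factor(seq_along(y)))
  devs <- sapply(list(X0, X1, X2), function(X) fit_nb_glm(y, X, phi)$deviance)
  expect_true(all(diff(devs) <= 1e-8))
  # one parameter per observation: deviance 0 up to tolerance
  expect_lt(fit_nb_glm(y, Xs, phi)$deviance, 1e-6)
})

test_that("LRT basics: identical fits give p = 1; effect strength is monotone", {
  set.seed(203)
  x <- factor(rep(1:2, each = 8)); X <- model.matrix(~x)
  y <- rnbinom(16, mu = 30, size = 10)
  f <- fit_nb_glm(y, X, 0.1)
  r <- fit_nb_glm(y, X[, 1, drop = FALSE], 0.1)
  same <- nb_lrt(f, f)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  lr <- nb_lrt(f, r)
  expect_gte(lr$stat, 0)
  expect_equal(lr$df, 1)

  stats_by_effect <- sapply(c(0, 0.5, 1, 2), function(b) {
    set.seed(204)
    mu <- exp(3 + b * (as.integer(x) - 1))
    yy <- rnbinom(16, mu = mu, size = 10)
    nb_lrt(fit_nb_glm(yy, X, 0.1),
           fit_nb_glm(yy, X[, 1, drop = FALSE], 0.1))$stat
  })
  expect_true(all(diff(stats_by_effect) > 0))
})

test_that("dispersion estimation recovers truth and applies the max rule", {
  set.seed(205)
  n_gene <- 600; n_per <- 8
  cellf <- factor(rep(1:4, each = n_per))
  mu_g <- exp(runif(n_gene, 2.5, 6))
  phi_true <- 0.2
  Y <- t(sapply(mu_g, function(m)
    rnbinom(length(cellf), mu = m, size = 1 / phi_true)))
  rownames(Y) <- paste0("g", seq_len(n_gene))
  disp <- estimate_dispersions(Y, data.frame(cell = cellf),
                               cell_formula = ~cell)
  expect_lt(abs(median(disp$raw) - phi_true) / phi_true, 0.15)
  # trend_max: final is the max of raw and fitted everywhere
  expect_equal(disp$final, pmax(disp$raw, disp$fitted))
  above <- disp$raw > disp$fitted
  expect_true(any(above))
  expect_equal(disp$final[above], disp$raw[above])

  # Poisson data: small final dispersions
  Yp <- t(sapply(mu_g[1:200], function(m) rpois(length(cellf), m)))
  dp <- estimate_dispersions(Yp, data.frame(cell = cellf),
                             cell_formula = ~cell)
  expect_lt(median(dp$final), 0.01)

  # eb_shrink pulls raw estimates toward the trend
  de <- estimate_dispersions(Y, data.frame(cell = cellf),
                             cell_formula = ~cell, mode = "eb_shrink")
  pulled <- abs(de$final - de$fitted) <= abs(de$raw - de$fitted) + 1e-12
  expect_true(all(pulled))
  expect_error(estimate_dispersions(Y[, 1, drop = FALSE],
                                    data.frame(cell = cellf[1]),
                                    cell_formula = ~cell),
               "unidentifiable")
})

test_that("ln-fold-change recovery is nearly unbiased at n = 8, phi = 0.1", {
  set.seed(206)
  n_gene <- 500
  x <- factor(rep(1:2, each = 8)); X <- model.matrix(~x)
  est <- vapply(seq_len(n_gene), function(g) {
    y <- rnbinom(16, mu = exp(3.5 + 1.0 * (as.integer(x) - 1)), size = 10)
    fit_nb_glm(y, X, 0.1)$coef[2]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 0.05)
})

test_that("the model ladder honors its structural identities", {
  cf <- simulation_config(n_genes = 150, n_intergenic = 10, a = 4, b = 2,
                          c = 2, n_per_cell = 3, rng_seed = 61)
  sim <- simulate_experiment(cf)
  y <- rounded_view(normalize_counts(sim$counts, "TC"))
  seqq <- test_terms(y, sim$design, approach = "sequential")
  add1 <- test_terms(y, sim$design, approach = "add_one")
  drop1 <- test_terms(y, sim$design, approach = "drop_one")
  # GxE: sequential == add-one; ExS: sequential == drop-one (same model pair)
  expect_equal(seqq$GxE$p, add1$GxE$p, tolerance = 1e-10)
  expect_equal(seqq$ExS$p, drop1$ExS$p, tolerance = 1e-10)
  # main effects identical across approaches by construction
  expect_equal(seqq$G$p, drop1$G$p, tolerance = 1e-12)
  # three-way term identical everywhere
  expect_equal(seqq$GxExS$p, add1$GxExS$p, tolerance = 1e-12)

  # all-zero gene: p = 1 for every term
  y0 <- y; y0[1, ] <- 0
  de0 <- test_terms(y0, sim$design, approach = "sequential")
  for (tm in names(de0)) expect_equal(de0[[tm]]$p[1], 1)
})

test_that("ln&ANOVA matches aov F tests on a balanced design", {
  cf <- simulation_config(n_genes = 40, n_intergenic = 10, a = 3, b = 2,
                          c = 2, n_per_cell = 3, n_spikeins = 0,
                          rng_seed = 62)
  sim <- simulate_experiment(cf)
  nm <- normalize_counts(sim$counts, "TC")
  la <- ln_anova(nm, sim$design)
  # balanced design: partial (Type III) F equals the sequential aov F
  d <- sim$design
  for (g in c(1, 7, 25)) {
    yv <- log(nm$values[g, ] + 1)
    fit <- aov(yv ~ sex * genotype * environment, data = d)
    tab <- summary(fit)[[1]]
    rownames(tab) <- trimws(rownames(tab))
    expect_equal(la$S$stat[g], tab["sex", "F value"], tolerance = 1e-8)
    expect_equal(la$GxE$stat[g],
                 tab["genotype:environment", "F value"], tolerance = 1e-8)
    expect_equal(la$GxExS$stat[g],
                 tab["sex:genotype:environment", "F value"], tolerance = 1e-8)
  }
  # constant gene -> p = 1 by contract
  v2 <- nm$values; v2[3, ] <- 5
  la2 <- ln_anova(v2, sim$design)
  for (tm in names(la2)) expect_equal(la2[[tm]]$p[3], 1)
})

test_that("NB LRT approaches the Poisson LRT as phi -> 0", {
  set.seed(207)
  x <- factor(rep(1:2, each = 8)); X <- model.matrix(~x)
  diffs <- vapply(1:200, function(i) {
    y <- rpois(16, 25)
    nb <- nb_lrt(fit_nb_glm(y, X, 1e-8),
                 fit_nb_glm(y, X[, 1, drop = FALSE], 1e-8))
    pois <- anova(glm(y ~ x, family = poisson()), test = "Chisq")
    abs(nb$p - pois$`Pr(>Chi)`[2])
  }, numeric(1))
  expect_lt(median(diffs), 1e-3)
})
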