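test_that("balanced one-way REML matches the ANOVA method-of-moments oracle", {
  for (s in c(1, 5, 9)) {
    ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 30, reps_per_line = 8,
                                                  var_line = 2, var_residual = 1,
                                                  seed = s))
    fm <- fit_line_model(ph)
    mom <- anova_varcomp_oracle(ph$value, ph$line)
    if (mom$var_line >= 0) {
      expect_equal(fm$varcomp$var_line, mom$var_line, tolerance = 1e-6)
      expect_equal(fm$varcomp$var_residual, mom$var_residual, tolerance = 1e-6)
    }
  }
})

test_that("null line effects give near-zero variance ratio and centred BLUPs", {
  ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 200, reps_per_line = 20,
                                                var_line = 0, var_residual = 1,
                                                seed = 2))
  fm <- fit_line_model(ph)
  expect_lt(fm$varcomp$var_line / fm$varcomp$var_total, 0.05)
  b <- blups(fm)
  if (sd(b) > 0) expect_lt(abs(sum(b)), 1e-6 * max(sd(b), 1e-12) + 1e-8)
})

test_that("BLUPs shrink line means by the closed-form balanced weight", {
  ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 40, reps_per_line = 6,
                                                var_line = 1.5, var_residual = 2,
                                                seed = 3))
  fm <- fit_line_model(ph)
  r <- 6
  w <- fm$varcomp$var_line / (fm$varcomp$var_line + fm$varcomp$var_residual / r)
  expect_true(w > 0 && w < 1)
  line_means <- tapply(ph$value, ph$line, mean)
  expected <- w * (line_means - mean(ph$value))
  expect_equal(unname(blups(fm)[names(line_means)]), as.numeric(expected),
               tolerance = 1e-6)
})

test_that("group and batch enter as fixed effects and errors are raised early", {
  ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 24, reps_per_line = 6,
                                                group_effects = c(A = 0, B = 4),
                                                batch_effects = c(b1 = 0, b2 = 1, b3 = -1),
                                                seed = 4))
  fm <- fit_line_model(ph)
  expect_true(any(grepl("group", names(coef(fm)))))
  expect_true(any(grepl("batch", names(coef(fm)))))
  expect_lt(abs(coef(fm)[["groupB"]] - 4), 0.5)
  red <- fit_line_model(ph, include_fixed = FALSE)
  expect_false(any(grepl("group", names(coef(red)))))
  expect_error(fit_line_model(data.frame(line = "a", value = 1:5)), "2 lines")
  bad <- ph; bad$value[1] <- NA
  expect_error(fit_line_model(bad), "missing")
})

test_that("heritability is the variance ratio, bounded, and reproducibly bootstrapped", {
  ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 60, reps_per_line = 8,
                                                seed = 5))
  fm <- fit_line_model(ph)
  h0 <- heritability(fm, n_boot = 0)
  expect_equal(h0$h2, fm$varcomp$var_line / fm$varcomp$var_total)
  expect_true(h0$h2 >= 0 && h0$h2 <= 1)

  # invariance to shifting and scaling the trait
  sh <- ph; sh$value <- sh$value + 100
  expect_equal(heritability(fit_line_model(sh), n_boot = 0)$h2, h0$h2,
               tolerance = 1e-6)
  sc <- ph; sc$value <- sc$value * 3
  expect_equal(heritability(fit_line_model(sc), n_boot = 0)$h2, h0$h2,
               tolerance = 1e-6)

  h1 <- heritability(fm, n_boot = 50, seed = 7)
  h2 <- heritability(fm, n_boot = 50, seed = 7)
  expect_identical(h1$boot, h2$boot)
  expect_true(h1$ci_low <= h1$ci_high)

  broken <- fm; broken$varcomp$var_total <- 0
  expect_error(heritability(broken, n_boot = 0), "zero")
})

test_that("Spearman validation matches the rank-then-Pearson oracle with ties", {
  x <- setNames(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4),
                paste0("l", 1:20))
  y <- setNames(c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5, 9, 0, 4, 5, 2, 3, 5, 3),
                paste0("l", 1:20))
  res <- correlate_with_human_scores(x, y)
  rho_oracle <- cor(rank(x), rank(y))
  expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
  t_oracle <- rho_oracle * sqrt((20 - 2) / (1 - rho_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_oracle), df = 18), tolerance = 1e-12)

  mono <- setNames(as.numeric(1:10), paste0("l", 1:10))
  expect_equal(correlate_with_human_scores(mono, mono^3)$rho, 1)
  expect_equal(correlate_with_human_scores(mono, -mono)$rho, -1)
  expect_error(correlate_with_human_scores(mono[1:2], mono[1:2]), "3 matched")
})

test_that("trait selection gates on heritability and correlation and uses the fixed taxonomy", {
  traits <- data.frame(trait = metric_names(), h2 = 0.2, rho = 0.5,
                       p = 0.001, stringsAsFactors = FALSE)
  tax <- select_traits(traits)
  expect_length(tax$central, 5L)
  expect_length(tax$dispersion, 9L)
  expect_setequal(tax$unclassified, c("ecc_sd", "radiusmin_mean"))
  expect_setequal(tax$central,
                  c("nn_mean", "ecc_mean", "area_mean", "radiusmean_mean",
                    "perimeter_mean"))

  low_h2 <- traits; low_h2$h2[low_h2$trait == "area_mean"] <- 0.04
  expect_true("area_mean" %in% select_traits(low_h2)$excluded)
  exactly_at <- traits; exactly_at$h2[exactly_at$trait == "nn_mean"] <- 0.05
  expect_true("nn_mean" %in% select_traits(exactly_at)$excluded)  # strict >
  bad_p <- traits; bad_p$p[bad_p$trait == "nn_sd"] <- 0.5
  expect_true("nn_sd" %in% select_traits(bad_p)$excluded)
  expect_error(select_traits(traits[-1, ]), "16 metrics")
})

test_that("transgene interaction model matches the normal-equations oracle", {
  # 12-observation toy dataset, hand-solved via the normal equations
  d <- data.frame(ab42 = c(0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1),
                  tau = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
                  value = c(1.0, 1.2, 0.8, 2.1, 1.9, 2.0,
                            3.2, 2.8, 3.1, 6.9, 7.2, 7.1))
  fit <- fit_transgene_interaction(d)
  X <- cbind(1, d$ab42, d$tau, d$ab42 * d$tau)
  oracle <- ols_oracle(d$value, X, 4)
  expect_equal(fit$beta_ab42, oracle$beta[2], tolerance = 1e-10)
  expect_equal(fit$beta_tau, oracle$beta[3], tolerance = 1e-10)
  expect_equal(fit$beta_interaction, oracle$beta[4], tolerance = 1e-10)
  expect_equal(fit$p_interaction, oracle$p, tolerance = 1e-10)

  # purely additive cell means: interaction ~ 0
  set.seed(13)
  n <- 50; a <- 3; b <- 5
  add <- data.frame(ab42 = rep(c(0, 1, 0, 1), each = n),
                    tau = rep(c(0, 0, 1, 1), each = n))
  add$value <- a * add$ab42 + b * add$tau + rnorm(4 * n, 0, 0.1)
  f_add <- fit_transgene_interaction(add)
  expect_gt(f_add$p_interaction, 0.05)
  # synergy c recovered within 2 SE
  syn <- add; syn$value <- syn$value + 2 * syn$ab42 * syn$tau
  f_syn <- fit_transgene_interaction(syn)
  se_int <- summary(f_syn$fit)$coefficients["a:t", "Std. Error"]
  expect_lt(abs(f_syn$beta_interaction - 2), 2 * se_int)

  expect_error(fit_transgene_interaction(add[add$ab42 == 0, ]), "four genotype cells")
})
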