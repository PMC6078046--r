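# Shared small study for several blocks (moderate scale keeps fits fast).
reml_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- simulate_trait_layer(quick_config(n = 700, seed = 51))
    st
  }
})

test_that("REML equals the ANOVA sire-component oracle on balanced half sibs", {
  withr::local_seed(14)
  ns <- 100; no <- 10
  sires <- sprintf("S%03d", 1:ns)
  off <- sprintf("O%04d", 1:(ns * no))
  ped <- as_pedigree(id = c(sires, off),
                     sire = c(rep(NA, ns), rep(sires, each = no)),
                     dam = rep(NA_character_, ns + ns * no))
  # V_A = 0.3 -> sire variance 0.075, interior ANOVA solution
  y <- rep(rnorm(ns, 0, sqrt(0.075)), each = no) + rnorm(ns * no, 0, sqrt(0.925))
  df <- data.frame(id = off, y = y, sire = rep(sires, each = no))
  ms <- anova(lm(y ~ sire, df))$`Mean Sq`
  sigma_s2 <- (ms[1] - ms[2]) / no
  fit <- carp_reml(y ~ 1, df, ped, se = FALSE)
  expect_equal(unname(fit$VA), 4 * sigma_s2, tolerance = 0.01)
})

test_that("null data give near-zero heritability and a non-significant LRT", {
  cfg <- sim_config(seed = 52, G = diag(1e-12, 5),
                    R = diag(5), sex_effects = matrix(0, 3, 5))
  st <- simulate_trait_layer(cfg)
  kern <- animal_kernel(st$pedigree, st$phenotypes$id)
  fit <- carp_reml(Logr_Fil ~ sex, st$phenotypes, st$pedigree, kernel = kern,
                   se = FALSE)
  expect_lt(fit$h2, 0.05)
  expect_true(fit$boundary)
  null <- carp_reml(Logr_Fil ~ sex, st$phenotypes, st$pedigree, kernel = kern,
                    animal = FALSE, se = FALSE)
  expect_false(lrt_animal_effect(fit, null)$significant)
})

test_that("a strong genetic signal is detected by the LRT", {
  st <- reml_study()
  kern <- animal_kernel(st$pedigree, st$phenotypes$id)
  fit <- carp_reml(Logr_Fil ~ sex, st$phenotypes, st$pedigree, kernel = kern,
                   se = FALSE)
  null <- carp_reml(Logr_Fil ~ sex, st$phenotypes, st$pedigree, kernel = kern,
                    animal = FALSE, se = FALSE)
  lrt <- lrt_animal_effect(fit, null)
  expect_true(lrt$significant)
  expect_gt(lrt$statistic, qchisq(0.95, 1))
  # mixture option halves the p-value
  expect_equal(lrt_animal_effect(fit, null, mixture = TRUE)$p_value,
               lrt$p_value / 2)
  expect_error(lrt_animal_effect(20, 10), "negative")
})

test_that("estimates are invariant to record order and sex-label recoding", {
  st <- reml_study()
  ph <- st$phenotypes
  fit <- carp_reml(Logr_Fil ~ sex, ph, st$pedigree, se = FALSE)
  withr::local_seed(15)
  shuf <- ph[sample(nrow(ph)), ]
  fit2 <- carp_reml(Logr_Fil ~ sex, shuf, st$pedigree, se = FALSE)
  expect_equal(fit2$h2, fit$h2, tolerance = 1e-5)
  expect_equal(fit2$m2logL, fit$m2logL, tolerance = 1e-6)
  relab <- ph
  relab$sex <- c(female = "Z_fem", male = "A_mal", unknown = "M_unk")[ph$sex]
  fit3 <- carp_reml(Logr_Fil ~ sex, relab, st$pedigree, se = FALSE)
  expect_equal(fit3$h2, fit$h2, tolerance = 1e-5)
})

test_that("univariate heritabilities match the bivariate diagonal", {
  st <- reml_study()
  kern <- animal_kernel(st$pedigree, st$phenotypes$id)
  u1 <- carp_reml(Logr_hlCarss ~ sex, st$phenotypes, st$pedigree,
                  kernel = kern, se = FALSE)
  bi <- carp_reml(cbind(Logr_hlCarss, Logr_Fil) ~ sex, st$phenotypes,
                  st$pedigree, kernel = kern, se = FALSE)
  expect_equal(unname(bi$h2[1]), unname(u1$h2), tolerance = 0.05)
  expect_true(abs(bi$rg[1, 2]) <= 1 + 1e-8)
  expect_true(all(abs(bi$rp[upper.tri(bi$rp)]) <= 1 + 1e-8))
})

test_that("the REML optimum improves on the starting value and is stable", {
  st <- reml_study()
  fit <- carp_reml(Mod_Fil ~ sex, st$phenotypes, st$pedigree, se = FALSE)
  expect_equal(fit$convergence, 0)
  expect_gte(fit$VA, 0)
  expect_gte(fit$VE, 0)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  # re-fitting from the solution does not find a better optimum
  fit2 <- carp_reml(Mod_Fil ~ sex, st$phenotypes, st$pedigree, se = FALSE,
                    control = list(restarts = 4))
  expect_equal(fit2$m2logL, fit$m2logL, tolerance = 1e-7)
})

test_that("standard errors are plausible at study scale", {
  st <- reml_study()
  fit <- carp_reml(Logr_Fil ~ sex, st$phenotypes, st$pedigree)
  expect_true(is.finite(fit$h2_se))
  expect_gt(fit$h2_se, 0.02); expect_lt(fit$h2_se, 0.4)
  bi <- carp_reml(cbind(Logr_hlCarss, Logr_Fil) ~ sex, st$phenotypes,
                  st$pedigree)
  expect_true(is.finite(bi$rg_se[1, 2]))
  expect_lt(bi$rg_se[1, 2], 0.3)
})

test_that("a simulated dam effect is found, and a negligible one is dropped", {
  # inject a common dam environment on top of the trait layer
  st <- simulate_trait_layer(quick_config(n = 600, seed = 53))
  ph <- st$phenotypes
  withr::local_seed(16)
  dam_eff <- setNames(rnorm(length(unique(ph$dam)), 0, sqrt(0.3)),
                      unique(ph$dam))
  ph$y_dam <- ph$Logr_Fil + dam_eff[ph$dam]
  fit <- carp_reml(y_dam ~ sex, ph, st$pedigree, dam = "dam", se = FALSE)
  expect_false(fit$dam_dropped)
  expect_gt(fit$dam_variance, 0.1)
  expect_lt(fit$h2, 0.65)
  # without an injected effect the term collapses and is dropped
  fit0 <- carp_reml(Logr_Fil ~ sex, ph, st$pedigree, dam = "dam", se = FALSE)
  expect_true(fit0$dam_dropped)
  expect_equal(fit0$dam_variance, 0)
  expect_error(carp_reml(cbind(Logr_Fil, Mod_Fil) ~ sex, ph, st$pedigree,
                         dam = "dam"), "univariate")
})

test_that("trait-specific fixed covariates are honoured", {
  st <- reml_study()
  ph <- st$phenotypes
  ph$BWcov <- 1900 + 280 * ph$size
  fit <- carp_reml(cbind(pct_Fat, Logr_Fil) ~ sex, ph, st$pedigree,
                   trait_covariates = list(pct_Fat = ~ BWcov), se = FALSE)
  expect_true(any(grepl("pct_Fat:BWcov", names(coef(fit)))))
  expect_false(any(grepl("Logr_Fil:BWcov", names(coef(fit)))))
  expect_true(abs(fit$rg[1, 2]) <= 1)
})

test_that("model frame and methods behave like a standard fit object", {
  st <- reml_study()
  fit <- carp_reml(Logr_Fil ~ sex, st$phenotypes, st$pedigree, se = FALSE)
  expect_s3_class(fit, "carp_reml")
  expect_equal(length(coef(fit)), 3)  # intercept + 2 sex contrasts
  expect_equal(dim(residuals(fit)), c(700, 1))
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(fit$Y))
  expect_output(print(fit), "h2")
  expect_s3_class(logLik(fit), "logLik")
  # Table-3-shaped parameter table
  bi <- carp_reml(cbind(Logr_hlCarss, Logr_Fil) ~ sex, st$phenotypes,
                  st$pedigree, se = FALSE)
  pt <- reml_param_table(bi)
  expect_equal(diag(pt), unname(bi$h2), ignore_attr = TRUE)
  expect_equal(pt[1, 2], bi$rg[1, 2])
  expect_equal(pt[2, 1], bi$rp[2, 1])
})

test_that("the genetic-correlation significance rule is exact", {
  expect_true(rg_significance(0.5, 0.1))
  expect_false(rg_significance(0.1, 0.1))
  expect_false(rg_significance(-0.15, 0.15))  # weak BW-yield correlation case
  expect_true(rg_significance(-0.52, 0.12))
  expect_error(rg_significance(0.5, -0.1))
})
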