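test_that("identical seeds give byte-identical studies; seeds differ otherwise", {
  a <- simulate_study(quick_config(n = 120, seed = 5))
  b <- simulate_study(quick_config(n = 120, seed = 5))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$true_breeding_values, b$true_breeding_values)
  c <- simulate_study(quick_config(n = 120, seed = 6))
  expect_false(identical(a$phenotypes, c$phenotypes))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(G = diag(c(1, 1, 1, 1, -0.1))), "positive semi-definite")
  expect_error(sim_config(R = matrix(0, 5, 5)), "positive definite")
  expect_error(sim_config(sex_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(offspring_total = 0))
  expect_error(sim_config(G = diag(2)), "5 x 5")
})

test_that("G = 0 leaves no between-family signal", {
  cfg <- sim_config(offspring_total = 1000, seed = 8,
                    G = diag(1e-12, 5), R = diag(5),
                    sex_effects = matrix(0, 3, 5))
  st <- simulate_trait_layer(cfg)
  fam <- paste(st$phenotypes$sire, st$phenotypes$dam)
  fm <- tapply(st$phenotypes$Logr_Fil, fam, mean)
  cnt <- tapply(st$phenotypes$Logr_Fil, fam, length)
  # between-family variance of family means should be ~ residual/n_fam only
  vb <- var(fm[cnt >= 4])
  expect_lt(vb, 3 / mean(cnt[cnt >= 4]))  # no excess over sampling noise
  expect_lt(abs(var(st$phenotypes$Logr_Fil) - 1), 0.15)
})

test_that("full-sib phenotypic covariance approaches G/2 (single trait)", {
  # 200 families x 8 sibs, V_A = 0.5, V_E = 0.5 -> sib covariance 0.25
  G1 <- diag(c(1e-10, 1e-10, 1e-10, 0.5, 1e-10)); R1 <- diag(5); diag(R1)[4] <- 0.5
  covs <- vapply(1:8, function(r) {
    cfg <- sim_config(offspring_total = 1600, seed = 300 + r,
                      G = G1, R = R1, sex_effects = matrix(0, 3, 5),
                      allocation = "uniform")
    st <- simulate_trait_layer(cfg)
    ph <- st$phenotypes
    fam <- paste(ph$sire, ph$dam)
    # average within-family covariance from pairs (first vs second half)
    fm <- split(ph$Logr_Fil, fam)
    pairs <- do.call(rbind, lapply(fm, function(v)
      cbind(v[seq(1, length(v) - 1, by = 2)], v[seq(2, length(v), by = 2)])))
    cov(pairs[, 1], pairs[, 2])
  }, numeric(1))
  expect_equal(mean(covs), 0.25, tolerance = 0.12)  # Monte-Carlo error band
})

test_that("founder breeding values realize G and offspring regress to midparent", {
  cfg <- sim_config(seed = 17, offspring_total = 400)
  reps <- 50
  acc <- matrix(0, 5, 5)
  slopes <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- simulate_trait_layer(sim_config(seed = 1000 + r, offspring_total = 150))
    founders <- st$pedigree$id[st$pedigree$generation == 0]
    acc <- acc + cov(st$true_breeding_values[founders, ])
    ph <- st$phenotypes
    bv_o <- st$true_breeding_values[ph$id, "Logr_Fil"]
    midp <- (st$true_breeding_values[ph$sire, "Logr_Fil"] +
             st$true_breeding_values[ph$dam, "Logr_Fil"]) / 2
    slopes[r] <- coef(lm(bv_o ~ midp))[2]
  }
  Gbar <- acc / reps
  expect_lt(max(abs(Gbar - cfg$G)), 0.12)
  # parent-offspring (midparent) regression slope ~ 1, i.e. 0.5 per parent
  expect_equal(mean(slopes), 1, tolerance = 0.05)
})

test_that("paper-mimic design realizes nearly all of the 200 families", {
  nf <- vapply(1:5, function(r) {
    st <- simulate_trait_layer(sim_config(seed = 40 + r))
    family_summary(st$pedigree, st$phenotypes$id)$n_families
  }, numeric(1))
  expect_true(all(nf <= 200))
  expect_true(all(nf >= 190))
  expect_lt(mean(200 - nf), 8)  # a handful of empty families, as designed
})

test_that("carcass layer: allometric slopes are recovered by log-log OLS", {
  st <- simulate_study(quick_config(n = 1500, seed = 21), layers = "carcass")
  ph <- qc_filter(st$phenotypes)$kept
  b_fil <- loglog_residuals(ph, "left_filet")$slope
  b_head <- loglog_residuals(ph, "head")$slope
  expect_equal(b_fil, 1.06, tolerance = 0.05 / 1.06)
  expect_equal(b_head, 0.90, tolerance = 0.05 / 0.90)
  expect_equal(loglog_residuals(ph, "left_filet")$allometry, "positive")
  expect_equal(loglog_residuals(ph, "head")$allometry, "negative")
  # a configured slope is recovered by the OLS oracle
  cfg <- quick_config(n = 1500, seed = 27)
  cfg$allometry$slope[cfg$allometry$portion == "left_filet"] <- 1.2
  st2 <- simulate_study(cfg, layers = "carcass")
  b2 <- loglog_residuals(qc_filter(st2$phenotypes)$kept, "left_filet")$slope
  expect_equal(b2, 1.2, tolerance = 0.05 / 1.2)
})

test_that("female fish have higher simulated fat and yield phenotypes", {
  st <- simulate_study(quick_config(n = 1200, seed = 22), layers = "carcass")
  ph <- ratio_traits(qc_filter(st$phenotypes)$kept)
  mf <- tapply(ph$pct_Fat, ph$sex, mean)
  expect_gt(mf[["female"]], mf[["male"]])
  my <- tapply(ph$pct_Fil, ph$sex, mean)
  expect_gt(my[["female"]], my[["male"]])
})

test_that("zero measurement error means every fish passes the QC sum rule", {
  cfg <- quick_config(n = 200, seed = 23)
  cfg$noise_scales$bw_loss <- c(0, 0)
  cfg$noise_scales$gross_rate <- 0
  st <- simulate_study(cfg, layers = "carcass")
  qc <- qc_filter(st$phenotypes)
  expect_equal(nrow(qc$kept), 200)
  expect_equal(sum(qc$report$reason == "portion_sum"), 0)
})

test_that("morphology layer links shape and ultrasound to the yield latents", {
  st <- simulate_study(quick_config(n = 800, seed = 24))
  pr <- predictor_table(st$landmarks, st$phenotypes)
  # negative head-axis loading: P1 anti-correlates with the filet latent
  expect_lt(cor(pr$P1, st$phenotypes$Logr_Fil), -0.1)
  # E8-driven P2 correlates positively
  expect_gt(cor(pr$P2, st$phenotypes$Logr_Fil), 0.2)
  # same seed -> identical landmark tables
  st2 <- simulate_study(quick_config(n = 800, seed = 24))
  expect_identical(st$landmarks, st2$landmarks)
})

test_that("zero loadings and jitter reproduce the template up to size scaling", {
  cfg <- quick_config(n = 20, seed = 25)
  cfg$morphology_loadings[c("head", "ventral", "caudal")] <- list(0, 0, 0)
  cfg$noise_scales$landmark_jitter <- 0
  st <- simulate_study(cfg)
  tpl <- template_landmarks()
  xy1 <- cbind(as.numeric(st$landmarks[1, paste0("x", 1:20)]),
               as.numeric(st$landmarks[1, paste0("y", 1:20)]))
  # centered shapes must be exactly proportional to the template
  c1 <- scale(xy1, scale = FALSE); ct <- scale(unclass(tpl), scale = FALSE)
  ratio <- c1 / ct
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-8)
})

test_that("study files round-trip and the truth echo is complete", {
  st <- simulate_study(quick_config(n = 30, seed = 26))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pedigree.csv", "phenotypes.csv", "landmarks.csv", "truth.json")))))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(st$pedigree))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$offspring_total, 30)
  expect_equal(as.matrix(truth$G), unclass(st$truth$G), ignore_attr = TRUE)
  # config file -> sim_config round trip drives an identical study
  cfg2 <- read_sim_config(file.path(dir, "truth.json"))
  st2 <- simulate_study(cfg2)
  expect_equal(st$phenotypes, st2$phenotypes)
})
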