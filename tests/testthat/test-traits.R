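make_portion_row <- function(id = "f1", BW = 1000,
                             shares = c(head = 0.185, left_filet = 0.227,
                                        viscera = 0.095, gonads = 0.020,
                                        left_skin = 0.022, half_carcass = 0.385,
                                        left_ribs = 0.028, fins = 0.023,
                                        scales = 0.015)) {
  df <- data.frame(id = id)
  for (p in names(shares)) df[[p]] <- shares[[p]] * BW
  df$BW <- sum(df[names(shares)])  # exact: sum of portions == BW
  df
}

test_that("QC sum rule keeps exact sums and excludes out-of-band fish", {
  ok <- make_portion_row("ok", BW = 1000)                 # sum == BW
  low <- make_portion_row("low", BW = 1000)
  low$BW <- sum(low[portion_cols <- c("head", "left_filet", "viscera", "gonads",
    "left_skin", "half_carcass", "left_ribs", "fins", "scales")]) / 0.969
  high <- make_portion_row("high", BW = 1000)
  high$BW <- sum(high[portion_cols]) / 1.0005             # sum = 1.0005 * BW
  tab <- rbind(ok, low, high)
  qc <- qc_filter(tab)
  expect_equal(qc$kept$id, "ok")
  expect_setequal(qc$report$id[qc$report$reason == "portion_sum"], c("low", "high"))
  expect_equal(qc$report$value[qc$report$id == "low"], 0.969, tolerance = 1e-10)
  expect_error(qc_filter(tab[, setdiff(names(tab), "scales")]), "scales")
})

test_that("aberrant-value screen flags by robust z and excludes only on request", {
  tab <- do.call(rbind, lapply(1:30, function(i) make_portion_row(paste0("f", i))))
  tab$SL <- c(seq(360, 400, length.out = 29), 900)  # one gross length outlier
  qc <- qc_filter(tab)
  expect_equal(nrow(qc$kept), 30)  # report-only by default
  expect_true("f30" %in% qc$report$id[qc$report$reason == "aberrant_value"])
  qc2 <- qc_filter(tab, exclude_aberrant = TRUE)
  expect_false("f30" %in% qc2$kept$id)
})

test_that("composite weights follow the definitions and their algebraic identity", {
  df <- data.frame(id = 1, left_filet = 400, left_skin = 50, left_ribs = 60,
                   half_carcass = 600)
  cw <- composite_weights(df)
  expect_equal(cw$hl_CarssW, 1110)
  expect_equal(cw$FiletW, 900)
  expect_equal(cw$AxisW, 90)
  zero <- data.frame(id = 2, left_filet = 0, left_skin = 0, left_ribs = 0,
                     half_carcass = 0)
  expect_equal(unlist(composite_weights(zero)[c("hl_CarssW", "FiletW", "AxisW")]),
               c(hl_CarssW = 0, FiletW = 0, AxisW = 0))
  # random tables: FiletW/2 + left_ribs + AxisW == half_carcass  (from defs)
  withr::local_seed(1)
  rnd <- data.frame(id = 1:50, left_filet = runif(50, 100, 500),
                    left_skin = runif(50, 10, 60), left_ribs = runif(50, 10, 80),
                    half_carcass = runif(50, 700, 1000))
  cw <- composite_weights(rnd)
  expect_equal(cw$FiletW / 2 + cw$left_ribs + cw$AxisW, cw$half_carcass)
})

test_that("ratio traits: percent yields, condition factor and fat mean", {
  df <- data.frame(id = 1, BW = 1800, SL = 380, BH = 140, HL = 112,
                   left_filet = 400, left_skin = 50,
                   fat1 = 10, fat2 = 11, fat3 = 12, fat4 = 13)
  rt <- ratio_traits(df)
  expect_equal(rt$pct_Fil, 50)            # (400+50)*2/1800*100
  expect_equal(rt$pct_Fat, 11.5)
  expect_equal(rt$RelBH, 140 / 380)
  expect_equal(rt$RelHL, 112 / 380)
  # the cubic form reproduces the conventional FC magnitude at market size
  fc <- ratio_traits(data.frame(id = 1, BW = 1910.5, SL = 383.1))$FC
  expect_equal(fc, 3.40, tolerance = 0.005)
  lit <- ratio_traits(data.frame(id = 1, BW = 1910.5, SL = 383.1), cubic = FALSE)$FC
  expect_equal(lit, 1e5 * 1910.5 / 383.1)
  expect_error(ratio_traits(data.frame(id = 1, BW = 0, SL = 10)))
})

test_that("percent yields stay in (0, 100] for physically consistent tables", {
  st <- simulate_study(quick_config(n = 400, seed = 31), layers = "carcass")
  ph <- ratio_traits(qc_filter(st$phenotypes)$kept)
  expect_true(all(ph$pct_Fil > 0 & ph$pct_Fil <= 100))
  expect_true(all(ph$pct_hlCarss > 0 & ph$pct_hlCarss <= 100))
})

test_that("log-log residuals: isometry, slope recovery, and invariances", {
  df <- data.frame(id = 1:10, BW = seq(800, 2600, length.out = 10))
  df$FiletW <- 0.5 * df$BW
  fit <- loglog_residuals(df, "FiletW")
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  expect_equal(fit$allometry, "isometric")
  expect_lt(abs(mean(fit$residuals)), 1e-10)
  # simulated b = 1.2 with noise sd 0.05 over n = 1500
  withr::local_seed(2)
  n <- 1500
  bw <- exp(rnorm(n, log(1900), 0.15))
  w <- exp(-1 + 1.2 * log(bw) + rnorm(n, 0, 0.05))
  fit2 <- loglog_residuals(data.frame(id = 1:n, BW = bw, portion = w), "portion")
  expect_equal(fit2$slope, 1.2, tolerance = 0.05 / 1.2)
  expect_equal(fit2$allometry, "positive")
  # residuals invariant to a global rescaling of the portion
  fit3 <- loglog_residuals(data.frame(id = 1:n, BW = bw, portion = 7 * w),
                           "portion")
  expect_equal(fit3$residuals, fit2$residuals, tolerance = 1e-10)
  expect_error(loglog_residuals(data.frame(id = 1, BW = 1, portion = -1),
                                "portion"), "non-positive")
})

test_that("the log-residual filet trait nearly matches log percent filet yield", {
  st <- simulate_study(quick_config(n = 800, seed = 32), layers = "carcass")
  ph <- ratio_traits(qc_filter(st$phenotypes)$kept)
  logr <- loglog_residuals(ph, "FiletW")$residuals
  expect_gt(cor(logr, log(ph$pct_Fil)), 0.9)
})

test_that("sex comparison: letters and F statistic", {
  # identical groups share a letter
  same <- sex_comparison(rep(c(1, 2, 3), 10), rep(c("f", "m"), 15))
  expect_equal(length(unique(same$letters)), 1)
  # widely separated groups get different letters
  withr::local_seed(3)
  v <- c(rnorm(50, 0), rnorm(50, 10))
  sp <- sex_comparison(v, rep(c("a", "b"), each = 50))
  expect_false(sp$letters[1] == sp$letters[2])
  # 3-group ANOVA F equals the hand-computed mean-square ratio
  g <- rep(c("f", "m", "u"), each = 20)
  y <- rnorm(60) + rep(c(0, 0.5, 1), each = 20)
  sc <- sex_comparison(y, g)
  gm <- tapply(y, g, mean); n_g <- tapply(y, g, length)
  msb <- sum(n_g * (gm - mean(y))^2) / 2
  msw <- sum((y - gm[g])^2) / 57
  expect_equal(unname(attr(sc, "anova")["F"]), msb / msw, tolerance = 1e-10)
  expect_error(sex_comparison(1:3, c("a", "a", "b")), ">= 2")
})
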