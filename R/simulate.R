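# Synthetic-study generator: partial factorial pedigree, multivariate
# additive-genetic trait layer, allometric carcass composition, landmark
# geometry and ultrasound measures. Every layer is a deterministic function
# of the configuration seed.

default_trait_names <- c("size", "pct_Fat", "Logr_hlCarss", "Logr_Fil", "Mod_Fil")

# Default genetic architecture: heritabilities and genetic/phenotypic
# correlations of the five latent traits (latent size driving body weight,
# muscle fat, the two log-log residual slaughter yields and the
# model-predicted filet yield), with unit phenotypic variance per trait.
default_genetic_architecture <- function() {
  h2 <- c(size = 0.63, pct_Fat = 0.68, Logr_hlCarss = 0.46,
          Logr_Fil = 0.50, Mod_Fil = 0.63)
  rg <- diag(5)
  rg[1, 2:5] <- c(0.13, -0.35, -0.35, -0.29)
  rg[2, 3:5] <- c(0.25, 0.27, 0.56)
  rg[3, 4:5] <- c(0.96, 0.87)
  rg[4, 5] <- 0.84
  rg[lower.tri(rg)] <- t(rg)[lower.tri(rg)]
  rp <- diag(5)
  rp[1, 2:5] <- c(0.21, -0.03, -0.02, -0.03)
  rp[2, 3:5] <- c(0.20, 0.27, 0.43)
  rp[3, 4:5] <- c(0.76, 0.72)
  rp[4, 5] <- 0.65
  rp[lower.tri(rp)] <- t(rp)[lower.tri(rp)]
  G <- diag(sqrt(h2)) %*% rg %*% diag(sqrt(h2))
  R <- rp - G
  dimnames(G) <- dimnames(R) <- list(default_trait_names, default_trait_names)
  list(G = G, R = R)
}

default_allometry <- function() {
  data.frame(
    portion = c("head", "left_filet", "viscera", "gonads", "left_skin",
                "half_carcass", "left_ribs", "fins", "scales"),
    share   = c(0.185, 0.227, 0.095, 0.020, 0.022, 0.385, 0.028, 0.023, 0.015),
    slope   = c(0.90, 1.06, 1.15, 0.30, 1.06, 1.00, 0.92, 0.92, 0.20),
    log_sd  = c(0.004, 0.004, 0.030, 0.250, 0.004, 0.004, 0.030, 0.050, 0.080)
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration of a synthetic carp study. The
#' defaults emulate the reference mating design and trait architecture: a
#' partial factorial of 4 series x (5 dams x 10 sires) = 60 founders, 1553
#' offspring, a three-level sex effect (~48.4% female / 48.6% male / 3.1%
#' unidentified), five latent traits with unit phenotypic variance whose
#' heritabilities and genetic/phenotypic correlations follow the published
#' estimates, allometric carcass composition (positive allometry for
#' filet/viscera/skin, negative for head/ribs/fins, near-zero body-weight
#' linkage for scales and gonads), and landmark/ultrasound layers whose
#' loadings tie morphology to the latent yields (negative head loading,
#' negative ventral-depth loading, positive caudal loading).
#'
#' The phenotypic SD of the log-residual yield traits is not an established
#' quantity; the latent traits are therefore simulated with V_P = 1 and
#' mapped to log units by `trait_scales$logr` (heritabilities and genetic
#' correlations are scale-free).
#'
#' @param n_series,dams_per_series,sires_per_series mating design (default
#'   4, 5, 10).
#' @param offspring_total number of phenotyped offspring (default 1553).
#' @param trait_names labels of the latent traits.
#' @param G,R additive-genetic and residual covariance matrices (G PSD, R
#'   positive definite, dimensions = number of traits).
#' @param sex_effects 3 x T matrix of fixed sex offsets (rows female, male,
#'   unknown) in latent-trait units.
#' @param sex_proportions length-3 simplex (female, male, unknown).
#' @param allocation `"dispersed"` (Dirichlet-multinomial family sizes,
#'   dispersion `alpha`) or `"uniform"` (near-equal deterministic counts).
#' @param alpha Dirichlet dispersion for `allocation = "dispersed"`;
#'   calibrated so a study of 1553 offspring leaves about 3 of the 200
#'   admissible families empty.
#' @param allometry data frame `portion`, `share`, `slope`, `log_sd`
#'   describing carcass composition at the reference size and its log-log
#'   slopes against latent size.
#' @param morphology_loadings named list: `head`, `ventral`, `caudal`
#'   (shape-axis loadings per latent yield SD), `e8`, `e23`, `e_other`
#'   (ultrasound loadings).
#' @param noise_scales named list: `bw_loss` (range of the relative
#'   processing loss making portion sums fall just below BW), `gross_rate`
#'   (probability of a gross recording error that the QC rule must catch),
#'   `gross_range` (its relative magnitude range), `fat_reading_sd` (SD of a
#'   single fat-meter reading, %), `landmark_jitter` (pixel SD),
#'   `ultrasound_sd` (mm), `sl_log_sd`, `relbh_log_sd`, `relhl_log_sd`.
#' @param trait_scales named list: `logr` (log-unit SD of yield latents),
#'   `fat_mean`, `fat_sd` (%), `bw_log_sd`, `bw_mean` (g).
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @examples
#' cfg <- sim_config(offspring_total = 200, seed = 42)
#' cfg$offspring_total
#' @export
sim_config <- function(n_series = 4, dams_per_series = 5, sires_per_series = 10,
                       offspring_total = 1553,
                       trait_names = default_trait_names,
                       G = NULL, R = NULL,
                       sex_effects = NULL,
                       sex_proportions = c(female = 751, male = 754,
                                           unknown = 48) / 1553,
                       allocation = c("dispersed", "uniform"), alpha = 6,
                       allometry = default_allometry(),
                       morphology_loadings = list(head = -0.015,
                                                  ventral = -0.010,
                                                  caudal = 0.005,
                                                  e8 = 0.05, e23 = -0.04,
                                                  e_other = 0.02),
                       noise_scales = list(bw_loss = c(0.002, 0.025),
                                           gross_rate = 0.03,
                                           gross_range = c(0.031, 0.09),
                                           fat_reading_sd = 0.7,
                                           landmark_jitter = 2,
                                           ultrasound_sd = 0.8,
                                           sl_log_sd = 0.03,
                                           relbh_log_sd = 0.06,
                                           relhl_log_sd = 0.04),
                       trait_scales = list(logr = 0.03, fat_mean = 11.56,
                                           fat_sd = 2.97, bw_log_sd = 0.146,
                                           bw_mean = 1910.5),
                       seed = 1L) {
  allocation <- match.arg(allocation)
  if (is.null(G) || is.null(R)) {
    arch <- default_genetic_architecture()
    if (is.null(G)) G <- arch$G
    if (is.null(R)) R <- arch$R
    if (!identical(trait_names, default_trait_names))
      stop("custom trait_names require explicit G and R")
  }
  T <- length(trait_names)
  G <- as.matrix(G); R <- as.matrix(R)
  if (!all(dim(G) == T) || !all(dim(R) == T))
    stop("G and R must be ", T, " x ", T, " to match trait_names")
  if (max(abs(G - t(G))) > 1e-8) stop("G is not symmetric")
  if (max(abs(R - t(R))) > 1e-8) stop("R is not symmetric")
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("G is not positive semi-definite")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop("R is not positive definite")
  dimnames(G) <- dimnames(R) <- list(trait_names, trait_names)
  if (is.null(sex_effects)) {
    sex_effects <- rbind(
      female  = c(0.04, 0.22, 0.48, 0.34, 0.31),
      male    = c(-0.04, -0.23, -0.50, -0.35, -0.31),
      unknown = c(-0.13, 0.18, 0.39, 0.25, 0.24))[, seq_len(T), drop = FALSE]
    colnames(sex_effects) <- trait_names
  }
  sex_effects <- as.matrix(sex_effects)
  stopifnot(nrow(sex_effects) == 3, ncol(sex_effects) == T)
  dimnames(sex_effects) <- list(c("female", "male", "unknown"), trait_names)
  if (abs(sum(sex_proportions) - 1) > 1e-8)
    stop("sex_proportions must sum to 1")
  stopifnot(offspring_total >= 1)
  structure(list(n_series = n_series, dams_per_series = dams_per_series,
                 sires_per_series = sires_per_series,
                 offspring_total = as.integer(offspring_total),
                 trait_names = trait_names, G = G, R = R,
                 sex_effects = sex_effects,
                 sex_proportions = sex_proportions,
                 allocation = allocation, alpha = alpha,
                 allometry = allometry,
                 morphology_loadings = morphology_loadings,
                 noise_scales = noise_scales, trait_scales = trait_scales,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration:", x$n_series, "series of",
      x$dams_per_series, "dams x", x$sires_per_series, "sires;",
      x$offspring_total, "offspring;", length(x$trait_names), "latent traits (",
      paste(x$trait_names, collapse = ", "), "); seed", x$seed, "\n")
  invisible(x)
}

rmvn <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(n * ncol(Sigma)), n) %*% L
}

#' Simulate the genetic trait layer
#'
#' Builds the pedigree of a partial factorial study and simulates breeding
#' values and latent trait phenotypes: founders draw breeding values from
#' N(0, G); each offspring receives the parental mean plus a Mendelian
#' sampling deviation with covariance G/2 (non-inbred parents); the
#' phenotype is sex effect + breeding value + residual with covariance R.
#' Offspring are allocated to the admissible sire x dam crosses either
#' near-uniformly or with Dirichlet-multinomial dispersion, which reproduces
#' unequal family sizes (about 197 of 200 families realized at the default
#' study size).
#'
#' @param config a [sim_config].
#' @return Object of class `synthetic_study`: `pedigree`
#'   ([carp_pedigree][as_pedigree]), `true_breeding_values` (animal x trait),
#'   `phenotypes` (data frame: id, sire, dam, series, sex, one column per
#'   latent trait), `truth` (the config).
#' @export
simulate_trait_layer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    founders <- build_partial_factorial(config$n_series, config$dams_per_series,
                                        config$sires_per_series)
    crosses <- attr(founders, "crosses")
    n <- config$offspring_total
    ncross <- nrow(crosses)
    counts <- if (config$allocation == "uniform") {
      base <- rep(n %/% ncross, ncross)
      extra <- n %% ncross
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      base
    } else {
      w <- rgamma(ncross, shape = config$alpha, rate = 1)
      drop(rmultinom(1, n, prob = w / sum(w)))
    }
    fam <- rep(seq_len(ncross), counts)
    off_id <- sprintf("F%05d", seq_len(n))
    ped <- as_pedigree(id = c(founders$id, off_id),
                       sire = c(rep(NA, nrow(founders)), crosses$sire[fam]),
                       dam = c(rep(NA, nrow(founders)), crosses$dam[fam]))
    T <- length(config$trait_names)
    nf <- nrow(founders)
    bv <- matrix(NA_real_, nf + n, T,
                 dimnames = list(c(founders$id, off_id), config$trait_names))
    bv[seq_len(nf), ] <- rmvn(nf, config$G)
    ms <- rmvn(n, config$G / 2)
    bv[nf + seq_len(n), ] <- (bv[crosses$sire[fam], , drop = FALSE] +
                              bv[crosses$dam[fam], , drop = FALSE]) / 2 + ms
    sex <- sample(c("female", "male", "unknown"), n, replace = TRUE,
                  prob = config$sex_proportions)
    resid <- rmvn(n, config$R)
    pheno <- config$sex_effects[sex, , drop = FALSE] +
      bv[nf + seq_len(n), , drop = FALSE] + resid
    df <- data.frame(id = off_id, sire = crosses$sire[fam],
                     dam = crosses$dam[fam], series = crosses$series[fam],
                     sex = sex, stringsAsFactors = FALSE)
    df[config$trait_names] <- as.data.frame(pheno)
    structure(list(pedigree = ped, true_breeding_values = bv,
                   phenotypes = df, truth = config),
              class = "synthetic_study")
  })
}

#' Simulate carcass composition, body measures and fat readings
#'
#' Generates the nine body-portion weights from a latent size and the latent
#' yield deviations through log-log allometry (`log w_p = log share_p +
#' b_p (log S - log S0) + yield-linked deviation + measurement noise`), then
#' *defines* body weight as the portion sum inflated by a small processing
#' loss, plus occasional gross recording errors — so the downstream QC rule
#' has a construction-level truth to recover. Lengths (TL/SL/BL/HL/BH/BWI)
#' and the four fat-meter readings are derived from the same latents.
#'
#' @param study a `synthetic_study` from [simulate_trait_layer()].
#' @param config optional override of `study$truth`.
#' @return The study with portion, BW, length, and fat-reading columns
#'   appended to `$phenotypes`, and a logical column `qc_error_injected`.
#' @export
simulate_carcass_layer <- function(study, config = study$truth) {
  ph <- study$phenotypes
  n <- nrow(ph)
  ts <- config$trait_scales
  ns <- config$noise_scales
  alw <- config$allometry
  with_seed(config$seed + 1L, {
    logS <- log(ts$bw_mean) - ts$bw_log_sd^2 / 2 + ts$bw_log_sd * ph$size
    zF <- ph$Logr_Fil
    zC <- ph$Logr_hlCarss
    zfat <- ph$pct_Fat
    # composite bookkeeping: the filet block carries the filet latent; the
    # rest of the headless carcass absorbs what is needed so that the
    # composite log-deviation equals the carcass latent
    sh <- setNames(alw$share, alw$portion)
    w_fil <- (sh["left_filet"] + sh["left_skin"]) /
      (sh["left_filet"] + sh["left_skin"] + sh["left_ribs"] + sh["half_carcass"])
    dev_fil <- ts$logr * zF
    dev_rest <- (ts$logr * zC - w_fil * dev_fil) / (1 - w_fil)
    dev <- list(head = -0.3 * ts$logr * zC,
                left_filet = dev_fil, left_skin = dev_fil,
                half_carcass = dev_rest, left_ribs = dev_rest,
                viscera = 0.5 * ts$logr * zfat,
                gonads = 0, fins = 0, scales = 0)
    # mass conservation: composition deviations reallocate weight between
    # portions at a fixed total, so the share-weighted log-deviations must
    # sum to zero; head/viscera/gonads/fins/scales absorb the balance
    # (higher-yield fish get proportionally smaller heads and viscera)
    absorb <- c("head", "viscera", "gonads", "fins", "scales")
    total_dev <- Reduce(`+`, Map(function(p) sh[[p]] * dev[[p]], alw$portion))
    for (p in absorb) dev[[p]] <- dev[[p]] - total_dev / sum(sh[absorb])
    gonad_mult <- c(female = 0.75, male = 1.5, unknown = 1)[ph$sex]
    for (k in seq_len(nrow(alw))) {
      p <- alw$portion[k]
      base <- log(sh[[p]] * ts$bw_mean) +
        alw$slope[k] * (logS - (log(ts$bw_mean) - ts$bw_log_sd^2 / 2))
      if (p == "gonads") base <- base + log(gonad_mult)
      ph[[p]] <- exp(base + dev[[p]] + rnorm(n, 0, alw$log_sd[k]))
    }
    psum <- rowSums(ph[, alw$portion])
    loss <- runif(n, ns$bw_loss[1], ns$bw_loss[2])
    gross <- runif(n) < ns$gross_rate
    loss[gross] <- sample(c(-1, 1), sum(gross), replace = TRUE) *
      runif(sum(gross), ns$gross_range[1], ns$gross_range[2])
    ph$BW <- psum * (1 + loss)
    ph$qc_error_injected <- gross
    # external measures: SL tracks the cube root of size; shape indices get
    # small negative links to the carcass yield latent (higher-yield fish
    # are slightly slimmer with smaller heads)
    ph$SL <- 383.1 * (ph$BW / ts$bw_mean)^(1 / 3) *
      exp(rnorm(n, 0, ns$sl_log_sd))
    ph$TL <- ph$SL * 1.19 * exp(rnorm(n, 0, 0.01))
    ph$BL <- ph$SL * 0.90 * exp(rnorm(n, 0, 0.01))
    ph$BH <- ph$SL * 0.365 * exp(rnorm(n, 0, ns$relbh_log_sd) - 0.010 * zC)
    ph$HL <- ph$SL * 0.295 * exp(rnorm(n, 0, ns$relhl_log_sd) - 0.015 * zC)
    ph$BWI <- ph$SL * 0.13 * exp(rnorm(n, 0, 0.05))
    fat_mean <- ts$fat_mean + ts$fat_sd * zfat
    for (k in 1:4)
      ph[[paste0("fat", k)]] <- pmax(fat_mean + rnorm(n, 0, ns$fat_reading_sd), 0.1)
  })
  study$phenotypes <- ph
  study
}

#' Simulate landmark geometry and ultrasound measures
#'
#' Starts from the packaged schematic template outline, applies isotropic
#' size scaling proportional to BW^(1/3), deformation along three shape axes
#' (head size, ventral depth, caudal development) driven by the latent yield
#' deviations with the configured loadings, plus Gaussian landmark jitter;
#' ultrasound thicknesses E4/E5/E6/E8/E23 are linear in the local body-depth
#' and filet-thickness latents plus noise.
#'
#' @inheritParams simulate_carcass_layer
#' @return The study with `$landmarks` (wide data frame: id, x1,y1...x20,y20,
#'   scale_mm_per_px) and ultrasound columns appended to `$phenotypes`.
#' @export
simulate_morphology_layer <- function(study, config = study$truth) {
  ph <- study$phenotypes
  if (is.null(ph$BW)) stop("carcass layer must be simulated first")
  n <- nrow(ph)
  ml <- config$morphology_loadings
  ns <- config$noise_scales
  tpl <- template_landmarks()
  for (poly in predictor_polygons) {
    if (!is_simple_polygon(tpl[poly, ]))
      stop("degenerate template: polygon ", paste(poly, collapse = "-"),
           " self-intersects")
  }
  scale_mm <- attr(tpl, "scale")
  centroid <- colMeans(tpl)
  head_idx <- 1:6
  ventral_idx <- c(6, 9, 10, 13, 18)
  caudal_idx <- c(12, 13, 14, 15, 16, 17, 18, 19, 20)
  lateral_y <- mean(tpl[c(4, 8, 11, 14, 17), 2])
  zF <- ph$Logr_Fil
  zC <- ph$Logr_hlCarss
  with_seed(config$seed + 2L, {
    coords <- matrix(NA_real_, n, 40)
    E8 <- E4 <- E5 <- E6 <- E23 <- numeric(n)
    for (i in seq_len(n)) {
      size_mult <- (ph$BW[i] / config$trait_scales$bw_mean)^(1 / 3)
      xy <- sweep(tpl, 2, centroid) * size_mult
      xy <- sweep(xy, 2, -centroid)   # re-translate to image frame
      # head axis: scale the head block about its own centroid
      hc <- colMeans(xy[head_idx, ])
      xy[head_idx, ] <- sweep(sweep(xy[head_idx, ], 2, hc) *
                                (1 + ml$head * zF[i]), 2, -hc)
      # ventral depth: compress/expand ventral landmarks toward lateral line
      yl <- lateral_y + (mean(xy[c(4, 8, 11), 2]) - lateral_y)
      xy[ventral_idx, 2] <- yl + (xy[ventral_idx, 2] - yl) * (1 + ml$ventral * zC[i])
      # caudal development: stretch the caudal block away from the body centroid
      cc <- mean(xy[, 1])
      xy[caudal_idx, 1] <- cc + (xy[caudal_idx, 1] - cc) * (1 + ml$caudal * zC[i])
      xy <- xy + matrix(rnorm(40, 0, ns$landmark_jitter), 20, 2)
      coords[i, ] <- as.vector(t(xy))  # x1 y1 x2 y2 ...
      h89 <- sqrt(sum((xy[8, ] - xy[9, ])^2)) * scale_mm
      bh_mm <- ph$BH[i]
      E8[i] <- h89 * (0.33 + ml$e8 * zF[i]) + rnorm(1, 0, ns$ultrasound_sd)
      E4[i] <- bh_mm * (0.20 + ml$e_other * zF[i]) + rnorm(1, 0, ns$ultrasound_sd)
      E5[i] <- bh_mm * (0.18 + ml$e_other * zF[i]) + rnorm(1, 0, ns$ultrasound_sd)
      E6[i] <- bh_mm * (0.15 + ml$e_other * zC[i]) + rnorm(1, 0, ns$ultrasound_sd)
      E23[i] <- bh_mm * (0.30 + ml$e23 * zF[i]) + rnorm(1, 0, ns$ultrasound_sd)
    }
  })
  lm_df <- data.frame(id = ph$id)
  for (j in 1:20) {
    lm_df[[paste0("x", j)]] <- coords[, 2 * j - 1]
    lm_df[[paste0("y", j)]] <- coords[, 2 * j]
  }
  lm_df$scale_mm_per_px <- scale_mm
  ph$E4 <- E4; ph$E5 <- E5; ph$E6 <- E6; ph$E8 <- pmax(E8, 0.5); ph$E23 <- E23
  study$phenotypes <- ph
  study$landmarks <- lm_df
  study
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_trait_layer()], [simulate_carcass_layer()] and
#' [simulate_morphology_layer()] in sequence. Identical seeds give
#' byte-identical studies.
#'
#' @param config a [sim_config].
#' @param layers subset of `c("carcass", "morphology")` to add on top of the
#'   trait layer.
#' @return A `synthetic_study`.
#' @examples
#' st <- simulate_study(sim_config(offspring_total = 50, seed = 7))
#' names(st$phenotypes)[1:8]
#' @export
simulate_study <- function(config,
                           layers = c("carcass", "morphology")) {
  study <- simulate_trait_layer(config)
  if ("carcass" %in% layers) study <- simulate_carcass_layer(study, config)
  if ("morphology" %in% layers) study <- simulate_morphology_layer(study, config)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$phenotypes), "phenotyped offspring,",
      nrow(x$pedigree) - nrow(x$phenotypes), "founders;",
      "layers:", paste(c("traits",
                         if (!is.null(x$phenotypes$BW)) "carcass",
                         if (!is.null(x$landmarks)) "morphology"),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to CSV/JSON files
#'
#' Writes `pedigree.csv` (id,sire,dam), `phenotypes.csv` (one row per fish),
#' `landmarks.csv` (id, x1,y1..x20,y20, scale_mm_per_px) and `truth.json`
#' (the full configuration echo).
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(study$pedigree, file.path(dir, "pedigree.csv"))
  write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(study$landmarks))
    write.csv(study$landmarks, file.path(dir, "landmarks.csv"),
              row.names = FALSE, quote = FALSE)
  truth <- study$truth
  truth$G <- unclass(truth$G); truth$R <- unclass(truth$R)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a simulation configuration from JSON or YAML
#'
#' @param file path to a JSON (or YAML, when the yaml package is available)
#'   configuration; fields are passed to [sim_config()].
#' @param seed optional seed override.
#' @return A [sim_config].
#' @export
read_sim_config <- function(file, seed = NULL) {
  cfg <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(file)
  } else jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(cfg$G)) cfg$G <- as.matrix(cfg$G)
  if (!is.null(cfg$R)) cfg$R <- as.matrix(cfg$R)
  if (!is.null(cfg$sex_effects)) cfg$sex_effects <- as.matrix(cfg$sex_effects)
  if (!is.null(seed)) cfg$seed <- seed
  do.call(sim_config, cfg)
}
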