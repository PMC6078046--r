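# End-to-end orchestration: simulate (or read) -> QC/traits -> morphometric
# predictors -> yield prediction -> pedigree REML -> expected gains.
# CSV is the inter-stage contract; the run report is a plain list (written
# as JSON when an output directory is given).

#' Pipeline configuration
#'
#' @param sim a [sim_config] for the simulation stage, or `NULL` to read
#'   inputs from files.
#' @param inputs named list of paths (`pedigree`, `phenotypes`, `landmarks`)
#'   used when `sim` is `NULL`.
#' @param outdir optional output directory; when given, stage outputs
#'   (derived-trait CSV, estimates JSON, gains CSV, run report) are written.
#' @param seed seed for stochastic stages (cross-validation partitions; the
#'   simulation stage uses `sim$seed`).
#' @param stages character subset of
#'   `c("simulate", "traits", "morpho", "predict", "reml", "gains")`.
#' @param qc list of [qc_filter()] options (`lower`, `upper`,
#'   `exclude_aberrant`).
#' @param reml_traits traits to fit univariately (columns of the derived
#'   table).
#' @param reml_pairs list of trait pairs for bivariate genetic correlations.
#' @param dam optional dam column name to include the common-environment
#'   term in univariate fits.
#' @param scenarios scenario data frame for [scenario_table()] (`trait`,
#'   `scheme`, `p`); default: MS/FSS on the filet yield plus IS on the
#'   predicted filet yield at 10% and 30% selected.
#' @param gain_target target trait for gains (default `"Logr_Fil"`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            inputs = NULL,
                            outdir = NULL,
                            seed = 1L,
                            stages = c("simulate", "traits", "morpho",
                                       "predict", "reml", "gains"),
                            qc = list(lower = 0.97, upper = 1.0,
                                      exclude_aberrant = FALSE),
                            reml_traits = c("Logr_hlCarss", "Logr_Fil",
                                            "Mod_Fil"),
                            reml_pairs = list(c("Logr_hlCarss", "Logr_Fil")),
                            dam = NULL,
                            scenarios = NULL,
                            gain_target = "Logr_Fil") {
  if (is.null(scenarios))
    scenarios <- data.frame(
      trait = c("Logr_Fil", "Logr_Fil", "Mod_Fil",
                "Logr_Fil", "Logr_Fil", "Mod_Fil"),
      scheme = c("MS", "FSS", "IS", "MS", "FSS", "IS"),
      p = c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3))
  structure(list(sim = sim, inputs = inputs, outdir = outdir, seed = seed,
                 stages = stages, qc = qc, reml_traits = reml_traits,
                 reml_pairs = reml_pairs, dam = dam, scenarios = scenarios,
                 gain_target = gain_target),
            class = "pipeline_config")
}

pipe_log <- function(report, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  report$log <- c(report$log, line)
  report
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order — simulate, QC + trait construction,
#' morphometric predictors, yield prediction, REML genetic parameters,
#' expected gains — each stage consuming the previous stage's tables, and
#' returns a machine-readable run report (per-stage record counts, the
#' parameter estimates, the gain table). Stage outputs are pure functions of
#' (inputs, config, seed); a failing stage stops with a stage-tagged error.
#'
#' @param config a [pipeline_config].
#' @return List of class `pipeline_report` with one section per executed
#'   stage plus a `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(log = character(), stages = config$stages)
  stage_error <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)

  # --- inputs ---
  if ("simulate" %in% config$stages && !is.null(config$sim)) {
    study <- tryCatch(simulate_study(config$sim),
                      error = function(e) stage_error("simulate", e))
    ped <- study$pedigree
    pheno <- study$phenotypes
    landmarks <- study$landmarks
    report$simulate <- list(n_offspring = nrow(pheno),
                            n_founders = nrow(ped) - nrow(pheno),
                            seed = config$sim$seed)
    report <- pipe_log(report, "simulate",
                       sprintf("%d offspring simulated (seed %d)",
                               nrow(pheno), config$sim$seed))
    fs <- family_summary(ped, pheno$id)
    report$simulate$n_families <- fs$n_families
    report$simulate$progeny_per_sire <- fs$per_sire
    report$simulate$progeny_per_dam <- fs$per_dam
  } else {
    if (is.null(config$inputs)) stop("stage 'input' failed: no inputs configured")
    ped <- read_pedigree(config$inputs$pedigree)
    pheno <- read.csv(config$inputs$phenotypes, stringsAsFactors = FALSE)
    landmarks <- if (!is.null(config$inputs$landmarks))
      read.csv(config$inputs$landmarks) else NULL
  }

  # --- traits (QC + composites + ratios + log-log residuals) ---
  if ("traits" %in% config$stages) {
    res <- tryCatch({
      qc <- qc_filter(pheno, lower = config$qc$lower %||% 0.97,
                      upper = config$qc$upper %||% 1.0,
                      exclude_aberrant = isTRUE(config$qc$exclude_aberrant))
      kept <- ratio_traits(composite_weights(qc$kept))
      for (tr in list(c("Logr_hlCarss", "hl_CarssW"),
                      c("Logr_Fil", "FiletW"))) {
        fit <- loglog_residuals(kept, tr[2])
        kept[[tr[1]]] <- unname(fit$residuals)
        attr(kept, paste0("slope_", tr[2])) <- fit$slope
      }
      list(kept = kept, report = qc$report)
    }, error = function(e) stage_error("traits", e))
    pheno <- res$kept
    report$traits <- list(n_in = nrow(pheno) + length(unique(res$report$id[
      res$report$reason == "portion_sum"])),
      n_kept = nrow(pheno),
      n_excluded_sum = length(unique(res$report$id[res$report$reason == "portion_sum"])),
      n_flagged_aberrant = length(unique(res$report$id[res$report$reason == "aberrant_value"])),
      exclusions = res$report,
      allometry_slopes = c(hl_CarssW = attr(pheno, "slope_hl_CarssW"),
                           FiletW = attr(pheno, "slope_FiletW")))
    report <- pipe_log(report, "traits",
                       sprintf("%d kept, %d excluded by the portion-sum rule",
                               nrow(pheno), report$traits$n_excluded_sum))
  }

  # --- morphometric predictors ---
  if ("morpho" %in% config$stages) {
    if (is.null(landmarks)) stop("stage 'morpho' failed: no landmark table")
    preds <- tryCatch(
      predictor_table(landmarks[landmarks$id %in% pheno$id, ], pheno),
      error = function(e) stage_error("morpho", e))
    pheno <- merge(pheno, preds[, c("id", "P1", "P2", "P3", "P5")],
                   by = "id", sort = FALSE)
    pheno$P4 <- pheno$BW
    report$morpho <- list(n = nrow(pheno),
                          predictor_means = colMeans(pheno[, paste0("P", 1:5)]))
    report <- pipe_log(report, "morpho",
                       sprintf("predictors P1-P5 computed for %d fish", nrow(pheno)))
  }

  # --- yield prediction ---
  if ("predict" %in% config$stages) {
    tryCatch({
      pheno$Mod_hlCarss <- apply_published_model(pheno, "Mod_hlCarss")
      pheno$Mod_Fil <- apply_published_model(pheno, "Mod_Fil")
    }, error = function(e) stage_error("predict", e))
    report$predict <- list(
      cor_published = c(
        Mod_hlCarss = cor(pheno$Mod_hlCarss, pheno$Logr_hlCarss),
        Mod_Fil = cor(pheno$Mod_Fil, pheno$Logr_Fil)))
    refit <- tryCatch(
      best_subset_regression(pheno[, paste0("P", 1:5)], pheno$Logr_Fil,
                             K = 20, seed = config$seed),
      error = function(e) stage_error("predict", e))
    report$predict$refit <- refit$selected
    # use the refitted equation for the synthetic cohort's Mod traits: the
    # published coefficients apply to the original study's measurement scales
    pheno$Mod_Fil_refit <- cbind(1, as.matrix(pheno[refit$selected$predictors])) %*%
      refit$selected$coefficients
    report <- pipe_log(report, "predict",
                       sprintf("best subset: %s (R2 = %.3f, R2cv = %.3f)",
                               paste(refit$selected$predictors, collapse = "+"),
                               refit$selected$r2, refit$selected$r2cv))
  }

  # --- REML genetic parameters ---
  if ("reml" %in% config$stages) {
    est <- tryCatch({
      kern <- animal_kernel(ped, pheno$id)
      uni <- lapply(config$reml_traits, function(tr) {
        fit <- carp_reml(as.formula(paste(tr, "~ sex")), pheno, ped,
                         kernel = kern, dam = config$dam)
        null <- carp_reml(as.formula(paste(tr, "~ sex")), pheno, ped,
                          kernel = kern, animal = FALSE, se = FALSE)
        lrt <- lrt_animal_effect(fit, null)
        list(trait = tr, h2 = unname(fit$h2), h2_se = unname(fit$h2_se),
             VA = unname(fit$VA), VP = unname(fit$VP),
             lrt_stat = lrt$statistic, lrt_significant = lrt$significant)
      })
      names(uni) <- config$reml_traits
      bi <- lapply(config$reml_pairs, function(pair) {
        fit <- carp_reml(as.formula(paste0("cbind(", pair[1], ",", pair[2],
                                           ") ~ sex")), pheno, ped,
                         kernel = kern)
        list(traits = pair, rg = fit$rg[1, 2], rg_se = fit$rg_se[1, 2],
             rp = fit$rp[1, 2],
             rg_significant = rg_significance(fit$rg[1, 2],
                                              fit$rg_se[1, 2] %||% Inf))
      })
      list(univariate = uni, bivariate = bi)
    }, error = function(e) stage_error("reml", e))
    report$reml <- est
    report <- pipe_log(report, "reml",
                       paste("h2:", paste(sprintf("%s=%.2f", config$reml_traits,
                         vapply(est$univariate, `[[`, 1, "h2")), collapse = " ")))
  }

  # --- expected gains ---
  if ("gains" %in% config$stages) {
    gains <- tryCatch({
      h2 <- vapply(report$reml$univariate, `[[`, 1, "h2")
      rg_t <- vapply(report$reml$bivariate, function(b) b$rg, 1)
      names(rg_t) <- vapply(report$reml$bivariate, function(b)
        setdiff(b$traits, config$gain_target)[1] %||% b$traits[1], "")
      # genetic correlations of IS criteria with the target, from extra
      # bivariate fits where not already available
      kern <- animal_kernel(ped, pheno$id)
      for (tr in setdiff(unique(config$scenarios$trait[
             config$scenarios$scheme == "IS"]), names(rg_t))) {
        fit <- carp_reml(as.formula(paste0("cbind(", tr, ",",
                                           config$gain_target, ") ~ sex")),
                         pheno, ped, kernel = kern, se = FALSE)
        rg_t[tr] <- fit$rg[1, 2]
      }
      scenario_table(config$scenarios, h2 = h2, rg_target = rg_t,
                     target = config$gain_target,
                     sigma_P = sd(pheno[[config$gain_target]]),
                     mean_pct = mean(pheno$pct_Fil))
    }, error = function(e) stage_error("gains", e))
    report$gains <- gains
    report <- pipe_log(report, "gains",
                       sprintf("%d scenarios evaluated (absolute mode)",
                               nrow(gains)))
  }

  # --- outputs ---
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(pheno, file.path(config$outdir, "derived_traits.csv"),
              row.names = FALSE)
    if (!is.null(report$traits))
      write.csv(report$traits$exclusions,
                file.path(config$outdir, "qc_exclusions.csv"),
                row.names = FALSE)
    if (!is.null(report$gains))
      write.csv(report$gains, file.path(config$outdir, "gains.csv"),
                row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "log")],
                         file.path(config$outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(report$log, file.path(config$outdir, "run.log"))
  }
  report$derived <- pheno
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run:\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
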