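# Truncation-selection intensity and expected genetic gain under mass (MS),
# full-sib (FSS) and indirect (IS) selection.

#' Selection intensity under truncation of a standard normal
#'
#' `i = phi(z) / p` with `z` the upper-`p` quantile: the mean standardized
#' deviation of the selected fraction under an infinite-population normal
#' model (no finite-sample correction).
#'
#' @param p selected proportion(s), in (0, 1].
#' @return Selection intensity (same length as `p`); `i = 0` at `p = 1`.
#' @examples
#' selection_intensity(c(0.10, 0.30))  # ~1.755, ~1.159
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p > 1)) stop("selected proportion must be in (0, 1]")
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Expected genetic gain per generation
#'
#' Breeder's-equation family of predictions for truncation selection:
#' \itemize{
#'   \item mass selection: `dG_MS = i * h2 * sigma_P`;
#'   \item full-sib (family) selection on `n` slaughtered sibs per family:
#'     `dG_FSS = i * sigma_P * h2 * n * r / sqrt(n * (1 + (n - 1) * t))`
#'     with sib relationship `r` (0.5 for full sibs) and phenotypic
#'     intraclass correlation `t = r * h2`;
#'   \item indirect selection on a correlated trait:
#'     `dG_IS = i * h1 * h2 * rg * sigma_P2`, with `h1`, `h2` the square
#'     roots of the heritabilities of the selection criterion and of the
#'     target, `rg` their genetic correlation and `sigma_P2` the target's
#'     phenotypic SD.
#' }
#' When the trait is a log-scale yield surrogate, the gain is rescaled to
#' percent body-weight units by multiplying by the population mean percent
#' yield (`mean_pct`).
#'
#' @param scheme `"MS"`, `"FSS"` or `"IS"`.
#' @param p selected proportion (used to compute `i`); alternatively pass
#'   `i` directly.
#' @param i selection intensity (overrides `p`).
#' @param h2 heritability of the trait under (direct) selection; for IS this
#'   is the heritability of the *indirect* criterion.
#' @param sigma_P phenotypic SD of the gain-bearing trait (the target trait
#'   for IS).
#' @param h2_target heritability of the target trait (IS only).
#' @param rg genetic correlation between criterion and target (IS only).
#' @param n,r sibs per family and sib relationship (FSS only).
#' @param mean_pct mean percent yield used to scale a log-unit gain to
#'   percent units (optional).
#' @return List: `i`, `dG` (trait units) and, when `mean_pct` is given,
#'   `dG_pct`.
#' @examples
#' predict_gain("MS", p = 0.1, h2 = 0.5, sigma_P = 1)
#' @export
predict_gain <- function(scheme = c("MS", "FSS", "IS"), p = NULL, i = NULL,
                         h2, sigma_P, h2_target = NULL, rg = NULL,
                         n = 10, r = 0.5, mean_pct = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(i)) {
    if (is.null(p)) stop("supply p or i")
    i <- selection_intensity(p)
  }
  if (sigma_P <= 0) stop("sigma_P must be positive")
  dG <- switch(scheme,
    MS = i * h2 * sigma_P,
    FSS = {
      t <- r * h2
      i * sigma_P * h2 * n * r / sqrt(n * (1 + (n - 1) * t))
    },
    IS = {
      if (is.null(rg) || is.null(h2_target))
        stop("IS needs rg and h2_target")
      i * sqrt(h2) * sqrt(h2_target) * rg * sigma_P
    })
  out <- list(scheme = scheme, i = i, dG = dG)
  if (!is.null(mean_pct)) out$dG_pct <- dG * mean_pct
  out
}

# gain of a scheme relative to mass selection on the target at the same
# intensity (sigma_P and i cancel)
gain_ratio_vs_ms <- function(scheme, h2_target, h2_indirect = NULL, rg = NULL,
                             n = 10, r = 0.5) {
  switch(scheme,
    MS = 1,
    FSS = {
      t <- r * h2_target
      n * r / sqrt(n * (1 + (n - 1) * t))
    },
    IS = sqrt(h2_indirect) * abs(rg) / sqrt(h2_target))
}

#' Expected-genetic-gain scenario table
#'
#' Computes percent-per-generation gains for a set of selection scenarios on
#' one target trait, in either of two modes:
#' \itemize{
#'   \item *absolute*: `sigma_P` (and `mean_pct` for log-unit traits) of the
#'     target must be supplied and the formulas of [predict_gain()] are
#'     applied directly;
#'   \item *ratio* (default when `anchor` is given): each scheme's gain is
#'     expressed relative to mass selection on the target at equal intensity
#'     (the intensity and `sigma_P` cancel) and multiplied by an anchoring
#'     mass-selection gain. This reproduces published gain tables when the
#'     phenotypic SD of the log-residual trait is not itself published.
#' }
#' Anchoring: `anchor` is a named vector of mass-selection gains in percent
#' per generation, named by selected proportion (e.g.
#' `c("0.1" = 0.70, "0.3" = 0.46)`). A scenario at a proportion with its own
#' anchor chains from it; a scenario without one is rescaled from the first
#' anchor by the truncation-intensity ratio `i(p)/i(p_anchor)`.
#'
#' @param scenarios data frame with columns `trait` (criterion label),
#'   `scheme` (`MS`/`FSS`/`IS`), `p` (selected proportion); optional `n`,
#'   `r` for FSS rows (defaults 10 and 0.5).
#' @param h2 named vector of heritabilities (must include the target and all
#'   criterion traits).
#' @param rg_target named vector of genetic correlations of each criterion
#'   with the target (IS rows).
#' @param target name of the target trait (entry of `h2`).
#' @param anchor named vector of anchoring MS gains (ratio mode), or `NULL`.
#' @param sigma_P,mean_pct absolute-mode parameters of the target trait.
#' @return The scenario data frame with columns `i`, `ratio_vs_MS` and
#'   `gain_pct` appended.
#' @examples
#' sc <- data.frame(trait = c("Logr_Fil", "Logr_Fil"),
#'                  scheme = c("MS", "FSS"), p = c(0.1, 0.1))
#' scenario_table(sc, h2 = c(Logr_Fil = 0.5), rg_target = NULL,
#'                target = "Logr_Fil", anchor = c("0.1" = 0.70))
#' @export
scenario_table <- function(scenarios, h2, rg_target = NULL, target,
                           anchor = NULL, sigma_P = NULL, mean_pct = NULL) {
  stopifnot(target %in% names(h2))
  if (is.null(anchor) && is.null(sigma_P))
    stop("supply either an anchor (ratio mode) or sigma_P (absolute mode)")
  if (!"n" %in% names(scenarios)) scenarios$n <- 10
  if (!"r" %in% names(scenarios)) scenarios$r <- 0.5
  scenarios$i <- selection_intensity(scenarios$p)
  ratio <- numeric(nrow(scenarios))
  for (k in seq_len(nrow(scenarios))) {
    sch <- scenarios$scheme[k]; tr <- scenarios$trait[k]
    if (sch == "IS") {
      if (!(tr %in% names(h2)) || !(tr %in% names(rg_target)))
        stop("unresolvable parameter reference for criterion '", tr, "'")
      ratio[k] <- gain_ratio_vs_ms("IS", h2[[target]], h2[[tr]], rg_target[[tr]])
    } else {
      ratio[k] <- gain_ratio_vs_ms(sch, h2[[target]],
                                   n = scenarios$n[k], r = scenarios$r[k])
    }
  }
  scenarios$ratio_vs_MS <- ratio
  if (!is.null(anchor)) {
    pa <- as.numeric(names(anchor))
    base <- numeric(nrow(scenarios))
    for (k in seq_len(nrow(scenarios))) {
      j <- match(scenarios$p[k], pa)
      base[k] <- if (!is.na(j)) anchor[[j]]
                 else anchor[[1]] * scenarios$i[k] / selection_intensity(pa[1])
    }
    scenarios$gain_pct <- base * ratio
  } else {
    g <- selection_intensity(scenarios$p) * h2[[target]] * sigma_P * ratio
    scenarios$gain_pct <- if (is.null(mean_pct)) g else g * mean_pct
  }
  scenarios
}
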