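# The nine recorded body portions (g). Their sum is compared with body weight
# by the QC rule, and they are the building blocks of every composite trait.
portion_cols <- c("head", "left_filet", "viscera", "gonads", "left_skin",
                  "half_carcass", "left_ribs", "fins", "scales")

#' Quality-control filter on carcass records
#'
#' Excludes fish whose portion-sum is inconsistent with the recorded body
#' weight: a fish is a recording error when the sum of all nine recorded
#' portions exceeds BW, or falls more than 3% below it
#' (`sum < lower * BW`, default `lower = 0.97`). An additional robust z-score
#' screen (|x - median| / MAD > `z_threshold` per measurement column) flags
#' aberrant external/internal measurements; it reports by default and excludes
#' only when `exclude_aberrant = TRUE`, since no quantitative rule for
#' "aberrant" is established. The two reasons are recorded independently.
#'
#' @param table phenotype data frame with `id`, `BW` and the nine portion
#'   columns (`head, left_filet, viscera, gonads, left_skin, half_carcass,
#'   left_ribs, fins, scales`).
#' @param lower lower tolerance on `sum(portions)/BW` (default 0.97).
#' @param upper upper tolerance (default 1: any sum above BW is excluded).
#' @param z_threshold robust z-score threshold for the aberrant-value screen.
#' @param z_columns measurement columns screened (default: lengths, fat
#'   readings and ultrasound measures present in the table).
#' @param exclude_aberrant drop fish flagged by the z-screen (default FALSE).
#' @return List with `kept` (filtered table) and `report` (data frame of
#'   exclusions/flags: id, reason, ratio or offending column, value).
#' @examples
#' ph <- data.frame(id = "f1", BW = 1000, head = 150, left_filet = 230,
#'   viscera = 95, gonads = 20, left_skin = 22, half_carcass = 385,
#'   left_ribs = 28, fins = 23, scales = 15)
#' qc_filter(ph)$kept$id  # sum = 968 < 970 -> excluded
#' @export
qc_filter <- function(table, lower = 0.97, upper = 1.0, z_threshold = 5,
                      z_columns = NULL, exclude_aberrant = FALSE) {
  missing_cols <- setdiff(c("BW", portion_cols), names(table))
  if (length(missing_cols))
    stop("missing portion column(s): ", paste(missing_cols, collapse = ", "))
  psum <- rowSums(table[, portion_cols])
  ratio <- psum / table$BW
  bad_sum <- ratio > upper | ratio < lower
  report <- data.frame(id = table$id[bad_sum],
                       reason = rep("portion_sum", sum(bad_sum)),
                       detail = rep("sum/BW", sum(bad_sum)),
                       value = ratio[bad_sum], stringsAsFactors = FALSE)
  if (is.null(z_columns))
    z_columns <- intersect(c("TL", "SL", "BL", "HL", "BH", "BWI",
                             "fat1", "fat2", "fat3", "fat4",
                             "E4", "E5", "E6", "E8", "E23"), names(table))
  flagged <- rep(FALSE, nrow(table))
  for (cl in z_columns) {
    x <- table[[cl]]
    s <- mad(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    z <- abs(x - median(x, na.rm = TRUE)) / s
    hit <- !is.na(z) & z > z_threshold
    if (any(hit)) {
      flagged <- flagged | hit
      report <- rbind(report, data.frame(id = table$id[hit], reason = "aberrant_value",
                                         detail = cl, value = table[[cl]][hit]))
    }
  }
  drop <- bad_sum | (exclude_aberrant & flagged)
  list(kept = table[!drop, , drop = FALSE], report = report)
}

#' Composite slaughter weights
#'
#' Adds the three composite weights to a QC-passed phenotype table:
#' headless carcass weight `hl_CarssW = left_filet + left_skin + left_ribs +
#' half_carcass` (left side dissected + intact right half), filet weight with
#' skin `FiletW = (left_filet + left_skin) * 2`, and vertebral axis weight
#' `AxisW = half_carcass - (left_filet + left_skin + left_ribs)`.
#'
#' @param table phenotype data frame with the portion columns.
#' @return The table with columns `hl_CarssW`, `FiletW`, `AxisW` appended.
#'   Negative `AxisW` values (physically impossible) raise a warning naming
#'   the fish.
#' @examples
#' df <- data.frame(id = 1, left_filet = 400, left_skin = 50, left_ribs = 60,
#'                  half_carcass = 600)
#' composite_weights(df)[, c("hl_CarssW", "FiletW", "AxisW")]  # 1110 900 90
#' @export
composite_weights <- function(table) {
  need <- c("left_filet", "left_skin", "left_ribs", "half_carcass")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing portion column(s): ", paste(missing_cols, collapse = ", "))
  table$hl_CarssW <- with(table, left_filet + left_skin + left_ribs + half_carcass)
  table$FiletW <- with(table, (left_filet + left_skin) * 2)
  table$AxisW <- with(table, half_carcass - (left_filet + left_skin + left_ribs))
  if (any(table$AxisW < 0))
    warning("negative AxisW for: ",
            paste(head(table$id[table$AxisW < 0]), collapse = ", "))
  table
}

#' Ratio and index traits
#'
#' Appends the percent yields and biometric indices:
#' `pct_hlCarss = hl_CarssW / BW * 100`,
#' `pct_Fil = (left_filet + left_skin) * 2 / BW * 100`,
#' Fulton's condition factor `FC = 1e5 * BW / SL^3` (BW in g, SL in mm),
#' `RelBH = BH / SL`, `RelHL = HL / SL`, and `pct_Fat` = mean of the four
#' repeated fat-meter readings.
#'
#' The cubic SL term in FC is required for gram/mm units to give the
#' conventional magnitude (about 3.4 for market carp); the non-cubic variant
#' `1e5 * BW / SL` is available via `cubic = FALSE` for comparison only.
#'
#' @param table phenotype data frame (needs `BW`, `SL`; `BH`, `HL`,
#'   `fat1..fat4` and portions where the corresponding traits are wanted).
#' @param cubic use `SL^3` in FC (default TRUE).
#' @return The table with the derived columns appended.
#' @export
ratio_traits <- function(table, cubic = TRUE) {
  if (any(table$BW <= 0) || ("SL" %in% names(table) && any(table$SL <= 0)))
    stop("BW and SL must be positive")
  if (!"hl_CarssW" %in% names(table) && all(portion_cols %in% names(table)))
    table <- composite_weights(table)
  if ("hl_CarssW" %in% names(table))
    table$pct_hlCarss <- table$hl_CarssW / table$BW * 100
  if (all(c("left_filet", "left_skin") %in% names(table)))
    table$pct_Fil <- (table$left_filet + table$left_skin) * 2 / table$BW * 100
  if ("SL" %in% names(table)) {
    table$FC <- if (cubic) 1e5 * table$BW / table$SL^3 else 1e5 * table$BW / table$SL
    if ("BH" %in% names(table)) table$RelBH <- table$BH / table$SL
    if ("HL" %in% names(table)) table$RelHL <- table$HL / table$SL
  }
  if (all(paste0("fat", 1:4) %in% names(table)))
    table$pct_Fat <- rowMeans(table[, paste0("fat", 1:4)])
  table
}

#' Allometric log-log residual trait
#'
#' Ordinary least squares of `log(portion weight)` on `log(BW)` over the
#' (QC-passed, pooled-sex) cohort. The residuals are the growth-independent
#' yield surrogate ("Logr" trait); the slope classifies the allometry as
#' positive (b > 1) or negative (b < 1). Residuals are invariant to
#' multiplying all portion weights by a constant (the intercept absorbs it).
#'
#' @param table phenotype data frame.
#' @param portion name of the (positive) weight column to regress, e.g.
#'   `"FiletW"`, `"hl_CarssW"` or any raw portion.
#' @param bw name of the body-weight column (default `"BW"`).
#' @return Object of class `allometric_fit`: `portion`, `intercept`, `slope`,
#'   `residuals` (named by fish id), `n`, `allometry` ("positive"/"negative"/
#'   "isometric").
#' @examples
#' df <- data.frame(id = 1:5, BW = c(800, 1200, 1600, 2000, 2400))
#' df$FiletW <- 0.5 * df$BW
#' fit <- loglog_residuals(df, "FiletW")
#' fit$slope            # 1 (isometry)
#' max(abs(fit$residuals))
#' @export
loglog_residuals <- function(table, portion, bw = "BW") {
  stopifnot(portion %in% names(table), bw %in% names(table))
  w <- table[[portion]]; b <- table[[bw]]
  bad <- !(w > 0) | !(b > 0)
  if (any(bad))
    stop("non-positive weights for fish: ",
         paste(head(table$id[bad]), collapse = ", "))
  if (nrow(table) < 3) stop("need at least 3 fish")
  fit <- lm(log(w) ~ log(b))
  slope <- unname(coef(fit)[2])
  res <- residuals(fit)
  names(res) <- as.character(table$id %||% seq_along(res))
  structure(list(portion = portion, intercept = unname(coef(fit)[1]),
                 slope = slope, residuals = res, n = nrow(table),
                 allometry = if (abs(slope - 1) < 1e-8) "isometric"
                             else if (slope > 1) "positive" else "negative"),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("log(%s) ~ log(BW): slope b = %.4f (%s allometry), n = %d\n",
              x$portion, x$slope, x$allometry, x$n))
  invisible(x)
}

#' Sex comparison with Tukey grouping letters
#'
#' One-way ANOVA of a trait on sex followed by Tukey's HSD at `alpha`;
#' groups sharing a letter do not differ significantly (the superscript
#' convention of descriptive trait tables).
#'
#' @param values numeric trait values.
#' @param sex factor/character group labels (>= 2 groups with >= 2
#'   observations each).
#' @param alpha significance level (default 0.05).
#' @return Data frame per group: `group`, `n`, `mean`, `sd`, `letters`, plus
#'   attributes `"anova"` (F statistic, df, p) and `"tukey"` (the HSD table).
#' @export
sex_comparison <- function(values, sex, alpha = 0.05) {
  sex <- factor(sex)
  tab <- table(sex)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 observations each")
  fit <- aov(values ~ sex)
  av <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$sex
  g <- levels(sex)
  # pairwise non-difference matrix
  ns <- matrix(TRUE, length(g), length(g), dimnames = list(g, g))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    ns[pair[1], pair[2]] <- ns[pair[2], pair[1]] <- tk[r, "p adj"] >= alpha
  }
  letters_assigned <- tukey_letters(ns, order(-tapply(values, sex, mean)))
  out <- data.frame(group = g,
                    n = as.integer(tab),
                    mean = as.numeric(tapply(values, sex, mean)),
                    sd = as.numeric(tapply(values, sex, sd)),
                    letters = letters_assigned)
  attr(out, "anova") <- c(F = av[1, "F value"], df1 = av[1, "Df"],
                          df2 = av[2, "Df"], p = av[1, "Pr(>F)"])
  attr(out, "tukey") <- tk
  out
}

# Homogeneous-group letters from a pairwise non-significance matrix.
# Each letter is a maximal set of mutually non-different groups; every
# non-different pair shares at least one letter. Groups are seeded in
# decreasing-mean order so 'a' attaches to the largest mean.
tukey_letters <- function(ns, ord) {
  g <- rownames(ns)
  grow <- function(seed) {
    # greedily extend a compatible set with further compatible groups
    for (gi in g[ord]) {
      if (!(gi %in% seed) && all(ns[gi, seed])) seed <- c(seed, gi)
    }
    sort(seed)
  }
  sets <- list()
  for (i in ord) sets[[length(sets) + 1]] <- grow(g[i])
  for (i in g) for (j in g) {
    if (i < j && ns[i, j]) sets[[length(sets) + 1]] <- grow(c(i, j))
  }
  sets <- unique(sets)
  keep <- vapply(seq_along(sets), function(k) {
    !any(vapply(seq_along(sets), function(l)
      l != k && length(sets[[l]]) > length(sets[[k]]) &&
        all(sets[[k]] %in% sets[[l]]), logical(1)))
  }, logical(1))
  sets <- sets[keep]
  # letter order follows the mean order of each set's best-ranked member
  rank_of <- setNames(match(g, g[ord]), g)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), 1))]
  vapply(g, function(gi) {
    paste(letters[which(vapply(sets, function(s) gi %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}
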