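# REML estimation of variance components under the pedigree animal model.
#
# Model per trait t:  y_t = X_t beta_t + a_t + e_t, with the stacked additive
# effects a ~ N(0, G kron A) and residuals e ~ N(0, R kron I). Only animals
# with records enter the likelihood, so A is reduced to the phenotyped block
# A_rr and eigendecomposed once (A_rr = U D U'). Rotating every trait by U'
# makes observations independent across eigen-index i with T x T covariance
# M_i = G d_i + R; a further generalized eigendecomposition of (G, R) (the
# canonical transformation) diagonalises every M_i simultaneously, so each
# REML likelihood evaluation is O(n). The restricted likelihood is maximised
# directly over a log-Cholesky parameterisation of (G, R).

# --- vech/Cholesky helpers (T <= 3) ---------------------------------------

nvech <- function(T) T * (T + 1) / 2

vech_to_sym <- function(v, T) {
  m <- matrix(0, T, T)
  m[lower.tri(m, diag = TRUE)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

sym_to_vech <- function(m) m[lower.tri(m, diag = TRUE)]

# theta: lower-tri Cholesky with log-diagonal -> SPD matrix
theta_to_cov <- function(theta, T) {
  L <- matrix(0, T, T)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

cov_to_theta <- function(m) {
  L <- t(chol(m + diag(1e-10 * mean(diag(m)), nrow(m))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

#' Eigen-kernel of the additive relationship matrix
#'
#' Precomputes the eigendecomposition of the numerator relationship matrix
#' restricted to the phenotyped animals. Several [carp_reml()] fits on the
#' same animals can share one kernel, which dominates the cost at study
#' scale.
#'
#' @param ped a [carp_pedigree][as_pedigree].
#' @param ids character vector of phenotyped animal ids (the record order).
#' @param A optional precomputed full relationship matrix (dimnames = ids).
#' @return List of class `animal_kernel`: `ids`, `d` (eigenvalues), `U`
#'   (eigenvectors).
#' @export
animal_kernel <- function(ped, ids, A = NULL) {
  ids <- as.character(ids)
  if (is.null(A)) A <- relationship_matrix(ped)
  if (!all(ids %in% rownames(A))) stop("phenotyped ids missing from pedigree")
  K <- A[ids, ids]
  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  structure(list(ids = ids, d = d, U = e$vectors), class = "animal_kernel")
}

# --- the REML objective (eigen path) --------------------------------------

# Yt: list over traits of rotated response (length n); Xt: list of rotated
# design matrices; d: eigenvalues; G, R: T x T. Returns -2 * restricted
# log-likelihood (including constants) plus fixed-effect solutions.
neg2_restricted_ll <- function(G, R, Yt, Xt, d) {
  T <- length(Yt); n <- length(d)
  Cc <- tryCatch(t(chol(R)), error = function(e) NULL)
  if (is.null(Cc)) return(list(value = Inf))
  M <- forwardsolve(Cc, t(forwardsolve(Cc, G)))   # C^-1 G C^-T
  M <- (M + t(M)) / 2
  eM <- eigen(M, symmetric = TRUE)
  lam <- pmax(eM$values, 0)
  Q <- solve(t(Cc)) %*% eM$vectors                # C^-T E: canonical traits
  # rotated responses in canonical space: Z = Y Q
  Ymat <- do.call(cbind, Yt)
  Z <- Ymat %*% Q
  logdetV <- 2 * n * sum(log(diag(Cc)))
  p <- vapply(Xt, ncol, 1L)
  P <- sum(p)
  Cmat <- matrix(0, P, P)
  rhs <- numeric(P)
  off <- c(0, cumsum(p))
  yVy <- 0
  for (k in seq_len(T)) {
    w <- 1 / (lam[k] * d + 1)
    logdetV <- logdetV + sum(log1p(lam[k] * d))
    yVy <- yVy + sum(w * Z[, k]^2)
    for (t in seq_len(T)) {
      it <- (off[t] + 1):off[t + 1]
      rhs[it] <- rhs[it] + Q[t, k] * crossprod(Xt[[t]], w * Z[, k])
      for (s in t:T) {
        is <- (off[s] + 1):off[s + 1]
        blk <- Q[t, k] * Q[s, k] * crossprod(Xt[[t]], w * Xt[[s]])
        Cmat[it, is] <- Cmat[it, is] + blk
        if (s > t) Cmat[is, it] <- Cmat[is, it] + t(blk)
      }
    }
  }
  ch <- tryCatch(chol(Cmat), error = function(e) NULL)
  if (is.null(ch)) return(list(value = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), rhs))
  yPy <- yVy - sum(rhs * beta)
  logdetC <- 2 * sum(log(diag(ch)))
  val <- logdetV + logdetC + yPy + (n * T - P) * log(2 * pi)
  list(value = val, beta = beta)
}

# --- fitting function ------------------------------------------------------

#' Pedigree animal-model REML
#'
#' Fits the mixed animal model `y = X beta + Z a + e` by restricted maximum
#' likelihood, with a random additive-genetic effect per animal correlated
#' through the pedigree numerator relationship matrix. Supports one to three
#' traits jointly (`cbind()` on the left-hand side), trait-specific fixed
#' covariates, and (univariate) an additional random effect common to dams
#' (non-genetic maternal environment). Returns heritabilities, genetic,
#' residual and phenotypic correlations with delta-method standard errors
#' from the numerically differentiated observed information.
#'
#' @param formula model formula, e.g. `y ~ sex` or `cbind(y1, y2) ~ sex`.
#'   The right-hand side gives the fixed effects shared by all traits.
#' @param data data frame with one row per phenotyped animal.
#' @param pedigree a [carp_pedigree][as_pedigree] containing every phenotyped
#'   animal (with ancestors).
#' @param id name of the animal-id column in `data` (default `"id"`).
#' @param kernel optional precomputed [animal_kernel()] for `data[[id]]`
#'   (must match the record set; records are reordered to the kernel order).
#' @param trait_covariates optional named list of one-sided formulas adding
#'   fixed covariates to single traits, e.g. `list(pct_Fat = ~ BW)`.
#' @param dam optional name of a dam-id column; adds a common-environment
#'   random effect for dams (univariate fits only). Following the usual
#'   practice, the term is dropped (and the model refitted without it) when
#'   its estimated variance falls below `1e-6 * V_P`.
#' @param animal set `FALSE` to fit the null model without the additive
#'   genetic effect (for likelihood-ratio testing).
#' @param se compute standard errors (default TRUE).
#' @param control list: `maxit` (default 4000), `reltol` (1e-12),
#'   `restarts` (2 extra Nelder-Mead restarts from the incumbent).
#' @return Object of class `carp_reml`; see [summary.carp_reml()]. Key
#'   fields: `VA`, `VE`, `VP`, `h2`, `h2_se`, `rg`, `rg_se`, `re`, `rp`,
#'   `G`, `R`, `beta`, `m2logL`, `convergence`, `boundary`.
#' @seealso [lrt_animal_effect()], [rg_significance()], [reml_param_table()]
#' @export
carp_reml <- function(formula, data, pedigree, id = "id", kernel = NULL,
                      trait_covariates = NULL, dam = NULL, animal = TRUE,
                      se = TRUE, control = list()) {
  ctl <- modifyList(list(maxit = 4000, reltol = 1e-12, restarts = 2), control)
  cl <- match.call()
  stopifnot(id %in% names(data))
  ids <- as.character(data[[id]])
  if (is.null(kernel)) {
    kernel <- animal_kernel(pedigree, ids)
  } else {
    if (!setequal(kernel$ids, ids)) stop("kernel ids do not match data ids")
    data <- data[match(kernel$ids, ids), , drop = FALSE]
    ids <- kernel$ids
  }
  mf <- model.frame(formula, data)
  Y <- model.response(mf)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(NULL, deparse(formula[[2]])))
  T <- ncol(Y)
  if (T > 3) stop("at most three traits at a time are supported")
  traits <- colnames(Y)
  n <- nrow(Y)
  Xbase <- model.matrix(attr(mf, "terms"), mf)
  Xt_raw <- lapply(seq_len(T), function(t) {
    X <- Xbase
    extra <- trait_covariates[[traits[t]]]
    if (!is.null(extra)) {
      Xe <- model.matrix(extra, data)[, -1, drop = FALSE]
      colnames(Xe) <- paste0(colnames(Xe))
      X <- cbind(X, Xe)
    }
    colnames(X) <- paste(traits[t], colnames(X), sep = ":")
    X
  })
  # standardize responses internally: makes the optimisation and the numeric
  # information matrix scale-free (h2 and correlations are invariant; the
  # component estimates are back-transformed afterwards)
  sy <- apply(Y, 2, sd)
  if (any(sy <= 0)) stop("constant response trait")
  Ys <- sweep(Y, 2, sy, "/")
  if (!is.null(dam)) {
    if (T > 1) stop("the dam common-environment term is supported for univariate fits only")
    return(reml_dense_dam(formula, data, pedigree, id, dam, Y, sy, Xt_raw[[1]],
                          kernel, cl, se, ctl))
  }
  d <- kernel$d
  U <- kernel$U
  Yt <- lapply(seq_len(T), function(t) crossprod(U, Ys[, t]))
  Xt <- lapply(Xt_raw, function(X) crossprod(U, X))
  # start: split the OLS residual covariance evenly between G and R
  Res <- vapply(seq_len(T), function(t)
    lm.fit(Xt_raw[[t]], Ys[, t])$residuals, numeric(n))
  S0 <- crossprod(Res) / (n - ncol(Xbase))
  nv <- nvech(T)
  objective <- function(par) {
    if (animal) {
      G <- theta_to_cov(par[seq_len(nv)], T)
      R <- theta_to_cov(par[nv + seq_len(nv)], T)
    } else {
      G <- matrix(0, T, T)
      R <- theta_to_cov(par, T)
    }
    neg2_restricted_ll(G, R, Yt, Xt, d)$value
  }
  par0 <- if (animal) c(cov_to_theta(S0 / 2), cov_to_theta(S0 / 2))
          else cov_to_theta(S0)
  if (length(par0) == 1) {
    opt <- optim(par0, objective, method = "Brent",
                 lower = par0 - 15, upper = par0 + 10,
                 control = list(reltol = ctl$reltol))
  } else {
    opt <- optim(par0, objective, method = "Nelder-Mead",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    for (r in seq_len(ctl$restarts)) {
      opt2 <- optim(opt$par, objective, method = "Nelder-Mead",
                    control = list(maxit = ctl$maxit, reltol = ctl$reltol))
      if (opt2$value < opt$value - 1e-10) opt <- opt2 else {opt <- opt2; break}
    }
  }
  if (animal) {
    G <- theta_to_cov(opt$par[seq_len(nv)], T)
    R <- theta_to_cov(opt$par[nv + seq_len(nv)], T)
  } else {
    G <- matrix(0, T, T)
    R <- theta_to_cov(opt$par, T)
  }
  final <- neg2_restricted_ll(G, R, Yt, Xt, d)
  # back-transform to the original response scale
  p <- vapply(Xt_raw, ncol, 1L)
  beta <- final$beta * rep(sy, p)
  names(beta) <- unlist(lapply(Xt_raw, colnames))
  Gb <- diag(sy, T) %*% G %*% diag(sy, T)
  Rb <- diag(sy, T) %*% R %*% diag(sy, T)
  m2 <- final$value + 2 * n * sum(log(sy))
  fit <- build_reml_fit(Gb, Rb, traits, cl, n, T, beta, m2, opt,
                        method = "eigen")
  fit$data_order <- ids
  fit$Xt <- Xt_raw
  fit$Y <- Y
  if (se && animal) {
    fit <- add_reml_se(fit, function(phi) {
      Gp <- vech_to_sym(phi[seq_len(nv)], T)
      Rp <- vech_to_sym(phi[nv + seq_len(nv)], T)
      neg2_restricted_ll(Gp, Rp, Yt, Xt, d)$value
    }, c(sym_to_vech(G), sym_to_vech(R)), T)
  }
  fit
}

# assemble the common parts of a carp_reml object
build_reml_fit <- function(G, R, traits, cl, n, T, beta, m2logL, opt, method,
                           extra = list()) {
  dimnames(G) <- dimnames(R) <- list(traits, traits)
  P <- G + R
  h2 <- diag(G) / diag(P)
  dG <- sqrt(diag(G)); dR <- sqrt(diag(R)); dP <- sqrt(diag(P))
  rg <- G / outer(dG, dG); re <- R / outer(dR, dR); rp <- P / outer(dP, dP)
  rg[!is.finite(rg)] <- NA; re[!is.finite(re)] <- NA
  structure(c(list(call = cl, traits = traits, n = n, T = T,
                   G = G, R = R, Pcov = P,
                   VA = diag(G), VE = diag(R), VP = diag(P),
                   h2 = h2, h2_se = rep(NA_real_, T),
                   rg = rg, rg_se = matrix(NA_real_, T, T,
                                           dimnames = dimnames(G)),
                   re = re, rp = rp,
                   beta = beta, m2logL = m2logL,
                   logLik = -m2logL / 2,
                   convergence = opt$convergence,
                   boundary = any(diag(G) < 1e-6 * diag(P)),
                   method = method), extra),
            class = "carp_reml")
}

# numeric observed information + delta method for h2 and rg
add_reml_se <- function(fit, negll_phi, phi_hat, T) {
  nv <- nvech(T)
  # at a boundary solution (V_A ~ 0 or |r_g| ~ 1, i.e. singular G) the
  # observed information is not a valid SE source; leave SEs as NA
  eg <- eigen(vech_to_sym(phi_hat[seq_len(nv)], T), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(eg) < 1e-6 * max(abs(eg))) {
    fit$boundary <- TRUE
    return(fit)
  }
  H <- tryCatch(pracma::hessian(negll_phi, phi_hat), error = function(e) NULL)
  if (is.null(H)) return(fit)
  Vphi <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(Vphi)) return(fit)
  fit$vcov_components <- Vphi
  derived <- function(phi) {
    G <- vech_to_sym(phi[seq_len(nv)], T)
    R <- vech_to_sym(phi[nv + seq_len(nv)], T)
    h2 <- diag(G) / (diag(G) + diag(R))
    out <- h2
    if (T > 1) {
      dg <- sqrt(diag(G))
      rg <- (G / outer(dg, dg))[lower.tri(G)]
      out <- c(out, rg)
    }
    out
  }
  J <- pracma::jacobian(derived, phi_hat)
  Vd <- J %*% Vphi %*% t(J)
  ses <- sqrt(pmax(diag(Vd), 0))
  fit$h2_se <- ses[seq_len(T)]
  if (T > 1) {
    rg_se <- matrix(0, T, T, dimnames = dimnames(fit$G))
    rg_se[lower.tri(rg_se)] <- ses[-seq_len(T)]
    rg_se <- rg_se + t(rg_se)
    fit$rg_se <- rg_se
  }
  fit
}

# dense-V univariate path with the dam common-environment term
reml_dense_dam <- function(formula, data, pedigree, id, dam, Y, sy, X, kernel,
                           cl, se, ctl) {
  y <- Y[, 1] / sy; n <- length(y)
  K <- with(kernel, U %*% (d * t(U)))  # A_rr back from its eigen form
  damf <- factor(as.character(data[[dam]]))
  Zc <- model.matrix(~ damf - 1)
  ZZ <- tcrossprod(Zc)
  negll <- function(lv) {
    V <- exp(lv[1]) * K + exp(lv[2]) * ZZ + diag(exp(lv[3]), n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    C <- crossprod(X, Vi_X)
    rhs <- crossprod(X, Vi_y)
    ch2 <- chol(C)
    beta <- backsolve(ch2, forwardsolve(t(ch2), rhs))
    yPy <- sum(y * Vi_y) - sum(rhs * beta)
    2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + yPy +
      (n - ncol(X)) * log(2 * pi)
  }
  v0 <- var(y) / 3
  opt <- optim(log(c(v0, v0 / 4, v0)), negll, method = "Nelder-Mead",
               control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  vs <- exp(opt$par)
  VP <- sum(vs)
  dam_dropped <- vs[2] < 1e-6 * VP
  if (dam_dropped) {
    refit <- carp_reml(formula, data, pedigree, id = id, kernel = kernel,
                       se = se, control = ctl)
    refit$dam_variance <- 0
    refit$dam_dropped <- TRUE
    refit$call <- cl
    return(refit)
  }
  vs_o <- vs * sy^2  # back to the original response scale
  G <- matrix(vs_o[1], 1, 1); R <- matrix(vs_o[3], 1, 1)
  fit <- build_reml_fit(G, R, colnames(Y), cl, n, 1L, beta = NULL,
                        m2logL = opt$value + 2 * n * log(sy), opt = opt,
                        method = "dense",
                        extra = list(dam_variance = vs_o[2], dam_dropped = FALSE))
  fit$VP <- sum(vs_o)
  fit$h2 <- vs_o[1] / fit$VP
  if (se) {
    H <- tryCatch(pracma::hessian(function(p) negll(log(p)), vs),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Vphi <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
      if (!is.null(Vphi)) {
        g <- c(1 / sum(vs) - vs[1] / sum(vs)^2,
               -vs[1] / sum(vs)^2, -vs[1] / sum(vs)^2)
        fit$h2_se <- sqrt(max(t(g) %*% Vphi %*% g, 0))
      }
    }
  }
  fit
}

# --- methods ---------------------------------------------------------------

#' @export
print.carp_reml <- function(x, digits = 3, ...) {
  cat("Pedigree animal-model REML fit (", x$T, " trait",
      if (x$T > 1) "s", ", n = ", x$n, ")\n", sep = "")
  for (t in seq_len(x$T)) {
    cat(sprintf("  %-14s V_A = %s  V_P = %s  h2 = %.*f",
                x$traits[t], format(signif(x$VA[t], digits)),
                format(signif(x$VP[t], digits)), digits, x$h2[t]))
    if (is.finite(x$h2_se[t])) cat(sprintf(" +/- %.*f", digits, x$h2_se[t]))
    cat("\n")
  }
  if (x$T > 1) {
    for (i in seq_len(x$T - 1)) for (j in (i + 1):x$T) {
      cat(sprintf("  r_g(%s, %s) = %.*f", x$traits[i], x$traits[j],
                  digits, x$rg[i, j]))
      if (is.finite(x$rg_se[i, j]))
        cat(sprintf(" +/- %.*f", digits, x$rg_se[i, j]))
      cat(sprintf("   r_p = %.*f\n", digits, x$rp[i, j]))
    }
  }
  if (!is.null(x$dam_variance))
    cat("  dam common-environment variance:", format(x$dam_variance, digits = digits),
        if (isTRUE(x$dam_dropped)) "(dropped as negligible)", "\n")
  cat("  -2 log restricted likelihood:", format(x$m2logL, digits = 10), "\n")
  if (x$boundary) cat("  note: a genetic variance is at/near the zero boundary\n")
  if (x$convergence != 0) cat("  warning: optimizer convergence code",
                              x$convergence, "\n")
  invisible(x)
}

#' Summarise a pedigree REML fit
#'
#' @param object a [carp_reml] fit.
#' @param ... unused.
#' @return The fit, invisibly; prints the parameter table (heritabilities on
#'   the diagonal, phenotypic correlations below, genetic correlations with
#'   SEs above) plus fixed effects.
#' @export
summary.carp_reml <- function(object, ...) {
  print(object)
  if (!is.null(object$beta)) {
    cat("Fixed effects:\n")
    print(object$beta)
  }
  if (object$T > 1) {
    cat("Parameter table (h2 diagonal, r_p below, r_g above):\n")
    print(round(reml_param_table(object), 3))
  }
  invisible(object)
}

#' @export
coef.carp_reml <- function(object, ...) object$beta

#' @export
logLik.carp_reml <- function(object, ...) {
  structure(object$logLik, df = if (object$method == "dense") 3 else
    2 * nvech(object$T), class = "logLik")
}

#' @export
vcov.carp_reml <- function(object, ...) object$vcov_components

#' @export
fitted.carp_reml <- function(object, ...) {
  if (is.null(object$beta)) return(NULL)
  p <- vapply(object$Xt, ncol, 1L)
  off <- c(0, cumsum(p))
  out <- vapply(seq_len(object$T), function(t)
    drop(object$Xt[[t]] %*% object$beta[(off[t] + 1):off[t + 1]]),
    numeric(object$n))
  colnames(out) <- object$traits
  out
}

#' @export
residuals.carp_reml <- function(object, ...) {
  f <- fitted(object)
  if (is.null(f)) return(NULL)
  object$Y - f
}

#' Parameter table in the conventional layout
#'
#' Square trait-by-trait matrix with heritabilities on the diagonal,
#' phenotypic correlations below the diagonal and genetic correlations above
#' it — the layout used to report multi-trait animal-model results.
#'
#' @param fit a [carp_reml] fit (2 or 3 traits).
#' @return Numeric matrix.
#' @export
reml_param_table <- function(fit) {
  stopifnot(inherits(fit, "carp_reml"), fit$T > 1)
  m <- matrix(NA_real_, fit$T, fit$T, dimnames = list(fit$traits, fit$traits))
  diag(m) <- fit$h2
  m[upper.tri(m)] <- fit$rg[upper.tri(fit$rg)]
  m[lower.tri(m)] <- fit$rp[lower.tri(fit$rp)]
  m
}

#' Likelihood-ratio test for the additive genetic effect
#'
#' Compares nested REML fits with and without the animal effect: the
#' difference in -2 log restricted likelihood is referred to the chi-squared
#' distribution with 1 degree of freedom at p < 0.05 (threshold 3.841). A
#' 50:50 boundary-mixture correction (which halves the p-value) is available
#' via `mixture = TRUE`.
#'
#' @param fit_with a [carp_reml] fit including the animal effect.
#' @param fit_without the matching `animal = FALSE` fit, or its `-2 logL`.
#' @param mixture use the 0.5*chi2(0) + 0.5*chi2(1) boundary mixture.
#' @param alpha significance level.
#' @return List: `statistic` (delta -2logL), `p_value`, `significant`,
#'   `threshold`.
#' @export
lrt_animal_effect <- function(fit_with, fit_without, mixture = FALSE,
                              alpha = 0.05) {
  m2_with <- if (inherits(fit_with, "carp_reml")) fit_with$m2logL else fit_with
  m2_without <- if (inherits(fit_without, "carp_reml")) fit_without$m2logL else fit_without
  stat <- m2_without - m2_with
  if (stat < -1e-6)
    stop("negative LRT statistic (", format(stat),
         "): the richer model has a worse likelihood; check convergence")
  stat <- max(stat, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- p / 2
  threshold <- qchisq(1 - alpha, df = 1)
  list(statistic = stat, p_value = p,
       significant = if (mixture) p < alpha else stat > threshold,
       threshold = threshold)
}

#' Significance rule for a genetic correlation
#'
#' A genetic correlation is declared significant when
#' `|r_g| - 1.96 * SE > 0` (two-tailed normal rule on the estimate).
#'
#' @param rg estimated genetic correlation.
#' @param se its standard error (>= 0).
#' @return Logical.
#' @examples
#' rg_significance(0.5, 0.1)    # TRUE
#' rg_significance(-0.15, 0.15) # FALSE
#' @export
rg_significance <- function(rg, se) {
  if (any(is.na(se))) return(NA)
  stopifnot(se >= 0)
  abs(rg) - 1.96 * se > 0
}
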