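#' Generalized least squares with a known covariance structure
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 C)` by maximum likelihood:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, computed by Cholesky whitening.
#' `sigma^2` uses the ML (1/n) estimate for the likelihood; standard errors use
#' the small-sample 1/(n-p) variance. If the Cholesky factorization fails, a
#' jitter of `1e-10 * mean(diag(C))` is added once.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column yourself).
#' @param C Covariance structure: a `phylo_cov` or a plain matrix, rows
#'   aligned with `y`.
#' @return List: `beta`, `se`, `sigma2` (ML), `logL`, `rss` (whitened residual
#'   sum of squares), `fitted`, `residuals`, `n`, `p`, `XtCiX_inv`.
#' @export
gls_fit <- function(y, X, C) {
  if (inherits(C, "phylo_cov")) C <- C$C
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n) {
    stop("y, X and C dimensions disagree (alignment error)")
  }
  U <- tryCatch(chol(C), error = function(e) {
    chol(C + diag(1e-10 * mean(diag(C)), n))
  })
  # whiten: z = L^-1 y with C = L L', L = t(U)
  z <- backsolve(U, y, transpose = TRUE)
  Z <- backsolve(U, X, transpose = TRUE)

  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) stop("singular X' C^-1 X: collinear predictors")
  beta <- qr.coef(qrz, z)
  resid_w <- z - Z %*% beta
  rss <- sum(resid_w^2)
  p <- ncol(X)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(U)))

  logL <- if (sigma2_ml > 0) {
    -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  } else {
    Inf  # degenerate: exact fit
  }
  XtCiX_inv <- chol2inv(qr.R(qrz))
  s2_unbiased <- if (n > p) rss / (n - p) else NA_real_
  se <- sqrt(pmax(diag(XtCiX_inv) * s2_unbiased, 0))

  list(beta = as.numeric(beta), se = as.numeric(se), sigma2 = sigma2_ml,
       logL = logL, rss = rss, fitted = as.numeric(X %*% beta),
       residuals = y - as.numeric(X %*% beta), n = n, p = p,
       XtCiX_inv = XtCiX_inv)
}

# Profile log-likelihood of an intercept-only (or general X) GLS model as a
# function of a covariance built by cov_fun(par).
profile_logL <- function(y, X, cov_fun) {
  function(par) {
    C <- cov_fun(par)
    fit <- try(gls_fit(y, X, C), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$logL)) -1e10 else fit$logL
  }
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles lambda on \[0, 1\] for a single trait (intercept-only model): for
#' each lambda the off-diagonals of the Brownian covariance are scaled, and the
#' root mean and rate are concentrated out analytically by GLS. The fitted
#' model is compared against the star phylogeny (lambda = 0) with a
#' likelihood-ratio test on one degree of freedom; the LRT statistic is clamped
#' at 0 (the boundary can produce tiny negative values).
#'
#' @param y Named trait vector (names = tip labels) or plain vector aligned to
#'   `tree$tip.label`.
#' @param tree An [ape::phylo] tree pruned to the taxa with data.
#' @param tol Optimizer tolerance on lambda.
#' @return Object of class `signal_fit`: `lambda`, `sigma2`, `root_mean`,
#'   `logL`, `logL_star`, `LRT`, `df`, `p_value`, `n`, `degenerate`.
#' @export
fit_lambda_ml <- function(y, tree, tol = 1e-8) {
  y <- align_to_tree(y, tree)
  n <- length(y)
  if (n < 4) stop("lambda estimation needs at least 4 taxa with data")
  X <- matrix(1, n, 1)
  if (stats::sd(y) == 0) {
    return(structure(list(lambda = NA_real_, sigma2 = 0, root_mean = y[1],
                          logL = NA_real_, logL_star = NA_real_, LRT = 0,
                          df = 1L, p_value = 1, n = n, degenerate = TRUE),
                     class = "signal_fit"))
  }
  bm <- bm_covariance(tree)
  f <- profile_logL(y, X, function(l) lambda_transform(bm, l))
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = tol)
  # the interior optimum can be dominated by a boundary
  cand_l <- c(opt$maximum, 0, 1)
  cand_v <- c(opt$objective, f(0), f(1))
  best <- which.max(cand_v)
  lambda_hat <- cand_l[best]
  logL <- cand_v[best]
  logL_star <- cand_v[2]

  fit_hat <- gls_fit(y, X, lambda_transform(bm, lambda_hat))
  LRT <- max(0, 2 * (logL - logL_star))
  structure(list(lambda = lambda_hat, sigma2 = fit_hat$sigma2,
                 root_mean = fit_hat$beta[1], logL = logL,
                 logL_star = logL_star, LRT = LRT, df = 1L,
                 p_value = stats::pchisq(LRT, df = 1, lower.tail = FALSE),
                 n = n, degenerate = FALSE),
            class = "signal_fit")
}

#' @export
print.signal_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda fit (n = %d)\n", x$n))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: trait has no variance; lambda unidentifiable\n")
  } else {
    cat(sprintf("  lambda = %.3f, chi-square = %.2f (df 1), P = %.4g\n",
                x$lambda, x$LRT, x$p_value))
  }
  invisible(x)
}

align_to_tree <- function(y, tree) {
  if (!is.null(names(y))) {
    missing <- setdiff(tree$tip.label, names(y))
    if (length(missing) > 0) {
      stop("trait values missing for tips: ", paste(missing, collapse = ", "))
    }
    y <- y[tree$tip.label]
  } else if (length(y) != length(tree$tip.label)) {
    stop("unnamed trait vector length differs from number of tips")
  }
  as.numeric(y)
}

# Covariance for a given evolutionary model; OU/EB nuisance parameters are
# profiled by bounded ML with bounds tied to the tree depth T.
model_covariance <- function(tree, model, y, X) {
  bm <- bm_covariance(tree)
  Tdepth <- max(diag(bm$C))
  if (model == "BM") {
    return(list(C = bm, par = NULL))
  }
  if (model == "OU") {
    f <- profile_logL(y, X, function(a) ou_transform(tree, a))
    opt <- stats::optimize(f, interval = c(1e-8, 50 / Tdepth), maximum = TRUE)
    a <- if (f(1e-8) >= opt$objective) 1e-8 else opt$maximum
    return(list(C = ou_transform(tree, a), par = c(alpha = a)))
  }
  if (model == "EB") {
    f <- profile_logL(y, X, function(r) eb_transform(tree, r))
    opt <- stats::optimize(f, interval = c(-10 / Tdepth, 0), maximum = TRUE)
    r <- if (f(0) >= opt$objective) 0 else opt$maximum
    return(list(C = eb_transform(tree, r), par = c(r = r)))
  }
  stop("unknown model '", model, "'")
}

#' Univariate phylogenetic generalized least squares regression
#'
#' Regresses a response on one predictor with phylogenetically structured
#' errors. Under `"BM"` the covariance is fixed by the tree; under `"OU"` and
#' `"EB"` the covariance parameter (alpha, r) is profiled by bounded maximum
#' likelihood with bounds tied to tree depth. The slope's p-value is two-sided
#' t with n - 2 degrees of freedom. The model R-squared compares the GLS
#' residual sum of squares against the intercept-only GLS fit under the same
#' covariance; the adjusted value can be negative.
#'
#' @param y,x Named vectors (names = tip labels) or vectors aligned to
#'   `tree$tip.label`; pairs with missing values are dropped (with the tree
#'   pruned to match).
#' @param tree An [ape::phylo] tree.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @return Object of class `comparative_fit` with `estimate`, `se`, `t_stat`,
#'   `p_value`, `adjusted_R2`, `logL`, `AIC`, `BIC`, `k`, `n`, `model`,
#'   `intercept`, `cov_parameter`.
#' @export
fit_pgls_model <- function(y, x, tree, model = c("BM", "OU", "EB")) {
  model <- match.arg(model)
  if (!is.null(names(y)) && !is.null(names(x))) {
    taxa <- intersect(intersect(names(y)[!is.na(y)], names(x)[!is.na(x)]),
                      tree$tip.label)
    if (length(taxa) < 5) {
      stop("fewer than 5 taxa with complete (y, x) pairs")
    }
    tree <- prune_to_taxa(tree, taxa)
    y <- y[tree$tip.label]
    x <- x[tree$tip.label]
  } else {
    keep <- !is.na(y) & !is.na(x)
    if (!all(keep)) stop("unnamed inputs with missing values cannot be aligned")
    if (length(y) < 5) stop("fewer than 5 taxa with complete (y, x) pairs")
    y <- align_to_tree(y, tree)
    x <- align_to_tree(x, tree)
  }
  n <- length(y)
  X <- cbind(1, as.numeric(x))

  mc <- model_covariance(tree, model, y, X)
  fit <- gls_fit(y, X, mc$C)
  fit0 <- gls_fit(y, matrix(1, n, 1), mc$C)

  est <- fit$beta[2]
  se <- fit$se[2]
  t_stat <- est / se
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  R2 <- if (fit0$rss > 0) 1 - fit$rss / fit0$rss else NA_real_
  adjR2 <- if (is.na(R2)) NA_real_ else adjusted_r2(R2, n, 1)

  k <- 3L + length(mc$par)  # intercept, slope, sigma2 (+ profiled cov param)
  structure(list(model = model, estimate = est, se = se, t_stat = t_stat,
                 p_value = p, adjusted_R2 = adjR2, R2 = R2, logL = fit$logL,
                 AIC = -2 * fit$logL + 2 * k,
                 BIC = -2 * fit$logL + k * log(n),
                 k = k, n = n, intercept = fit$beta[1],
                 cov_parameter = mc$par),
            class = "comparative_fit")
}

#' @export
print.comparative_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s), n = %d: slope = %.4f (SE %.4f), P = %.4g, adj-R2 = %.4f\n",
              x$model, x$n, x$estimate, x$se, x$p_value, x$adjusted_R2))
  invisible(x)
}

#' Compare PGLS fits across evolutionary models
#'
#' Ranks fits by AIC, reports AIC/BIC differences from the best model, and
#' selects a representative: Brownian motion whenever all models are within 2
#' AIC of the best (the models are then statistically indistinguishable and BM
#' is the simplest), otherwise the AIC-best model.
#'
#' @param fits List of `comparative_fit` objects on identical data.
#' @return List: `table` (model, logL, k, AIC, BIC, delta_AIC, delta_BIC),
#'   `all_within_2_AIC`, `representative`.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fitted models to compare")
  models <- vapply(fits, function(f) f$model, character(1))
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  tab <- data.frame(model = models,
                    logL = vapply(fits, function(f) f$logL, numeric(1)),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    AIC = aic, BIC = bic,
                    delta_AIC = aic - min(aic), delta_BIC = bic - min(bic),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  within2 <- all(tab$delta_AIC <= 2)
  rep_model <- if (within2 && "BM" %in% models) "BM" else tab$model[1]
  list(table = tab, all_within_2_AIC = within2, representative = rep_model)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`; may be negative for weak fits.
#'
#' @param R2 Coefficient of determination.
#' @param n Sample size.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted value.
#' @export
adjusted_r2 <- function(R2, n, p) {
  if (n <= p + 1) stop("adjusted R-squared undefined for n <= p + 1")
  1 - (1 - R2) * (n - 1) / (n - p - 1)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `q`: the largest i with
#' sorted p_(i) <= (i/m) q and everything smaller is flagged. Implemented via
#' [stats::p.adjust()].
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @return Logical vector in the input order.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Pearson correlation with a two-sided p-value
#'
#' Raw (non-phylogenetic) correlation: r with p from
#' `t = r sqrt((n - 2)/(1 - r^2))` on n - 2 degrees of freedom. Pairs with
#' missing values are dropped.
#'
#' @param x,y Numeric vectors.
#' @return List: `r`, `p_value`, `n`, `degenerate` (TRUE when either vector
#'   has zero variance, with `r` and `p_value` NA).
#' @export
pearson_with_p <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
       degenerate = FALSE)
}
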