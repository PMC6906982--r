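test_that("GLS with identity covariance reduces to ordinary least squares", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    fit <- gls_fit(y, cbind(1, x), diag(n))
    ols <- lm(y ~ x)
    expect_equal(fit$beta, unname(coef(ols)), tolerance = 1e-10)
    expect_equal(fit$se, unname(sqrt(diag(vcov(ols)))), tolerance = 1e-10)
  }
})

test_that("GLS matches nlme's ML fit under a Brownian correlation structure", {
  skip_if_not_installed("nlme")
  set.seed(6)
  tree <- simulate_tree(25, seed = 6)
  C <- bm_covariance(tree)$C
  L <- chol_lower(C)
  y <- bm_deviate(L); x <- bm_deviate(L)
  fit <- gls_fit(y, cbind(1, x), C)
  df <- data.frame(y = y, x = x, taxon = tree$tip.label)
  gfit <- nlme::gls(y ~ x, data = df, method = "ML",
                    correlation = ape::corBrownian(1, tree, form = ~taxon))
  expect_equal(fit$beta, unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$logL, as.numeric(logLik(gfit)), tolerance = 1e-6)
})

test_that("GLS flags collinearity and dimension mismatches", {
  x <- rnorm(10)
  expect_error(gls_fit(rnorm(10), cbind(1, x, x), diag(10)), "singular")
  expect_error(gls_fit(rnorm(10), cbind(1, x), diag(9)), "alignment")
})

test_that("lambda ML recovers signal extremes and dominates the endpoints", {
  tree <- simulate_tree(150, seed = 40)
  C <- bm_covariance(tree)$C
  L <- chol_lower(C / max(diag(C)))
  set.seed(41)
  y_bm <- setNames(bm_deviate(L), tree$tip.label)
  y_iid <- setNames(rnorm(150), tree$tip.label)

  f_bm <- fit_lambda_ml(y_bm, tree)
  f_iid <- fit_lambda_ml(y_iid, tree)
  expect_gt(f_bm$lambda, 0.7)
  expect_lt(f_iid$lambda, 0.2)
  # optimizer dominance: logL at lambda-hat beats both endpoints
  X <- matrix(1, 150, 1)
  bm <- bm_covariance(tree)
  at <- function(y, l) gls_fit(unname(y), X, lambda_transform(bm, l))$logL
  for (pair in list(list(y_bm, f_bm), list(y_iid, f_iid))) {
    expect_gte(pair[[2]]$logL + 1e-6, at(pair[[1]], 0))
    expect_gte(pair[[2]]$logL + 1e-6, at(pair[[1]], 1))
  }
  expect_gte(f_bm$LRT, 0)
  expect_lt(f_bm$p_value, 0.05)
})

test_that("lambda ML agrees with phytools on a Brownian trait", {
  skip_if_not_installed("phytools")
  tree <- simulate_tree(80, seed = 13)
  C <- bm_covariance(tree)$C
  set.seed(13)
  y <- setNames(bm_deviate(chol_lower(C)), tree$tip.label)
  ours <- fit_lambda_ml(y, tree)
  ref <- phytools::phylosig(tree, y, method = "lambda")
  expect_equal(ours$lambda, min(ref$lambda, 1), tolerance = 0.02)
})

test_that("constant traits are flagged degenerate with a null LRT", {
  tree <- simulate_tree(10, seed = 1)
  y <- setNames(rep(1.3, 10), tree$tip.label)
  f <- fit_lambda_ml(y, tree)
  expect_true(f$degenerate)
  expect_equal(f$LRT, 0)
  expect_equal(f$p_value, 1)
})

test_that("PGLS under BM equals OLS-through-origin on independent contrasts", {
  set.seed(77)
  for (i in 1:10) {
    tree <- ape::rcoal(24)
    C <- bm_covariance(tree)$C
    L <- chol_lower(C)
    y <- setNames(bm_deviate(L), tree$tip.label)
    x <- setNames(0.3 * y + bm_deviate(L), tree$tip.label)
    fit <- fit_pgls_model(y, x, tree, "BM")
    py <- ape::pic(y, tree); px <- ape::pic(x, tree)
    expect_equal(fit$estimate, sum(px * py) / sum(px^2), tolerance = 1e-8)
  }
})

test_that("a perfect linear relationship gives slope 2 and adjusted R2 of 1", {
  tree <- simulate_tree(12, seed = 3)
  x <- setNames(scale(rnorm(12))[, 1], tree$tip.label)
  y <- 2 * x
  fit <- fit_pgls_model(y, x, tree, "BM")
  expect_equal(fit$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$adjusted_R2, 1, tolerance = 1e-10)
})

test_that("OU and EB fits profile their covariance parameter and count it in AIC", {
  tree <- simulate_tree(60, seed = 19)
  C <- bm_covariance(tree)$C
  set.seed(19)
  L <- chol_lower(C)
  y <- setNames(bm_deviate(L), tree$tip.label)
  x <- setNames(0.4 * y + bm_deviate(L), tree$tip.label)
  bm <- fit_pgls_model(y, x, tree, "BM")
  ou <- fit_pgls_model(y, x, tree, "OU")
  eb <- fit_pgls_model(y, x, tree, "EB")
  expect_equal(bm$k, 3)
  expect_equal(ou$k, 4)
  expect_equal(eb$k, 4)
  # the profiled models nest BM, so their logL cannot be worse
  expect_gte(ou$logL, bm$logL - 1e-6)
  expect_gte(eb$logL, bm$logL - 1e-6)
  # AIC/BIC identities
  for (f in list(bm, ou, eb)) {
    expect_equal(f$AIC, -2 * f$logL + 2 * f$k)
    expect_equal(f$BIC, -2 * f$logL + f$k * log(f$n))
  }
})

test_that("PGLS recovers a planted Brownian slope without bias", {
  tree <- simulate_tree(500, seed = 23)
  C <- bm_covariance(tree)$C
  L <- chol_lower(C / max(diag(C)))
  set.seed(24)
  est <- vapply(1:50, function(rep) {
    x <- setNames(bm_deviate(L), tree$tip.label)
    y <- 0.15 * x + bm_deviate(L)
    fit_pgls_model(y, x, tree, "BM")$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.15), 0.03)
})

test_that("missing pairs are pruned and small overlaps rejected", {
  tree <- simulate_tree(20, seed = 9)
  set.seed(9)
  y <- setNames(rnorm(20), tree$tip.label)
  x <- setNames(rnorm(20), tree$tip.label)
  x[1:4] <- NA
  fit <- fit_pgls_model(y, x, tree, "BM")
  expect_equal(fit$n, 16)
  x[1:16] <- NA
  expect_error(fit_pgls_model(y, x, tree, "BM"), "fewer than 5")
})

test_that("model comparison ranks by AIC and prefers BM inside the 2-AIC band", {
  mk <- function(model, logL, k, n = 50) {
    structure(list(model = model, logL = logL, k = k,
                   AIC = -2 * logL + 2 * k, BIC = -2 * logL + k * log(n),
                   n = n), class = "comparative_fit")
  }
  # identical likelihoods: tie resolved to BM
  tie <- compare_models(list(mk("OU", -10, 3), mk("BM", -10, 3)))
  expect_true(tie$all_within_2_AIC)
  expect_equal(tie$representative, "BM")
  # clear AIC separation: best model wins
  sep <- compare_models(list(mk("BM", -12, 3), mk("OU", -10, 3)))
  expect_equal(sep$table$delta_AIC, c(0, 4))
  expect_false(sep$all_within_2_AIC)
  expect_equal(sep$representative, "OU")
  # within 2 AIC: BM representative even when not AIC-best
  close <- compare_models(list(mk("BM", -10.95, 3), mk("OU", -10, 3)))
  expect_true(close$all_within_2_AIC)
  expect_equal(close$representative, "BM")
})

test_that("adjusted R2 follows its formula, including negative values", {
  expect_equal(adjusted_r2(1, 30, 1), 1)
  expect_equal(adjusted_r2(0, 100, 1), -1 / 98, tolerance = 1e-6)
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_error(adjusted_r2(0.5, 2, 1), "undefined")
})

test_that("Benjamini-Hochberg flags match the step-up definition", {
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(FALSE, 5))
  expect_equal(benjamini_hochberg(c(0.001, 0.02, 0.03, 0.04, 0.2)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(benjamini_hochberg(0.04), TRUE)
  expect_error(benjamini_hochberg(c(0.1, 1.7)), "\\[0, 1\\]")
})

test_that("Pearson correlation and its t-based p-value are correct", {
  expect_equal(pearson_with_p(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)
  pc <- pearson_with_p(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(pc$r, 0.6)
  t_stat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(pc$p_value, 2 * pt(abs(t_stat), 2, lower.tail = FALSE))
  expect_true(pearson_with_p(rep(1, 5), rnorm(5))$degenerate)
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})
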