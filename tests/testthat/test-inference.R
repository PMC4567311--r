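# Mixed models, AICc comparison and correlations.

# Simulate a plot-structured dataset directly from the linear predictor.
sim_lmm_data <- function(n_plots = 15, per_plot = 5, beta0 = -2,
                         beta = -0.26, sigma_plot = 0.2,
                         sigma_resid = 0.4, seed = 1) {
  set.seed(seed)
  richness <- rep(rep(1:4, length.out = n_plots), each = per_plot)
  plot_id <- rep(sprintf("p%02d", 1:n_plots), each = per_plot)
  b <- rep(rnorm(n_plots, 0, sigma_plot), each = per_plot)
  eta <- beta0 + beta * richness + b + rnorm(n_plots * per_plot, 0,
                                             sigma_resid)
  data.frame(plot_id = plot_id, richness = richness, td = exp(eta))
}

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-69.3, K = 3, n = 66),
               2 * 69.3 + 6 + 2 * 3 * 4 / (66 - 3 - 1))
  # converges to AIC as n grows
  expect_equal(aicc(-100, K = 4, n = 1e8), 208, tolerance = 1e-5)
  expect_error(aicc(-10, K = 5, n = 6), "undefined")
})

test_that("fit_lmm recovers a known slope and reports K correctly", {
  d <- sim_lmm_data(seed = 42)
  fit <- fit_lmm(d, "richness")
  expect_equal(fit$K, 4)  # intercept + slope + 2 variance parameters
  expect_equal(fit_lmm(d, character(0))$K, 3)
  # replicate-averaged recovery: the mean estimate over 10 draws sits
  # within ~2.6 standard errors of the mean of the generating value
  est <- vapply(1:10, function(s) {
    f <- fit_lmm(sim_lmm_data(seed = s), "richness")
    f$coefficients$estimate[f$coefficients$term == "richness"]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.26)), 0.05)
  expect_error(fit_lmm(transform(d, td = td - 1), "richness"), "positive")
})

test_that("intercept-only fit on zero-plot-variance data is the grand mean", {
  d <- sim_lmm_data(sigma_plot = 0, seed = 5)
  fit <- fit_lmm(d, character(0))
  expect_equal(fit$coefficients$estimate[1], mean(log(d$td)),
               tolerance = 1e-6)
})

test_that("with zero plot variance estimates equal the OLS oracle", {
  d <- sim_lmm_data(sigma_plot = 0, seed = 8)
  fit <- fit_lmm(d, "richness", method = "ML")
  expect_true(fit$singular)
  X <- cbind(1, d$richness)
  beta_ols <- solve(t(X) %*% X, t(X) %*% log(d$td))  # normal equations
  expect_equal(fit$coefficients$estimate, as.numeric(beta_ols),
               tolerance = 1e-6)
})

test_that("Akaike weights and the MAM rule behave as specified", {
  # two identical models: delta 0 and 0, weights one half each
  w <- exp(-c(0, 0) / 2); w <- w / sum(w)
  expect_equal(w, c(0.5, 0.5))
  # delta (0, 2) -> weights (0.731, 0.269)
  w2 <- exp(-c(0, 2) / 2); w2 <- w2 / sum(w2)
  expect_equal(w2, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w2, 3), c(0.731, 0.269))

  # K = (3, 4, 4), delta = (1.9, 0, 0.14): the K = 3 model is the MAM
  expect_equal(mam_select(c(3, 4, 4), c(101.9, 100, 100.14)), 1)
  # brute-force check of the rule over random tables
  set.seed(21)
  for (i in 1:200) {
    K <- sample(3:6, 8, replace = TRUE)
    a <- 100 + c(0, cumsum(abs(rnorm(7))))[sample.int(8)]
    cand <- which(a - min(a) <= 2)
    best <- cand[order(K[cand], a[cand])][1]
    expect_equal(mam_select(K, a), best)
    # invariant to a constant shift
    expect_equal(mam_select(K, a + 57.3), best)
  }
})

test_that("compare_models orders by AICc with normalized weights", {
  d <- sim_lmm_data(seed = 11)
  d$noise <- rnorm(nrow(d))
  ms <- list(null = character(0), richness = "richness", noise = "noise",
             both = c("richness", "noise"))
  tab <- compare_models(d, ms)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(min(tab$delta), 0)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_equal(tab$K[match(c("null", "richness", "both"), tab$model)],
               c(3, 4, 5))
  # the generating predictor wins by a wide margin
  expect_equal(tab$model[1], "richness")
  expect_gt(tab$delta[tab$model == "null"], 2)
  # univariate rows carry slope estimates, multivariate rows do not
  expect_false(is.na(tab$estimate[tab$model == "richness"]))
  expect_true(is.na(tab$estimate[tab$model == "both"]))
})

test_that("scaling the response changes intercepts but not slopes or weights", {
  d <- sim_lmm_data(seed = 13)
  d$noise <- rnorm(nrow(d))
  ms <- list(null = character(0), richness = "richness", noise = "noise")
  t1 <- compare_models(d, ms)
  d2 <- transform(d, td = td * 100)  # percent instead of proportion
  t2 <- compare_models(d2, ms)
  expect_equal(t1$delta, t2$delta, tolerance = 1e-6)
  expect_equal(t1$weight, t2$weight, tolerance = 1e-6)
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-6)
  expect_equal(t1$t, t2$t, tolerance = 1e-4)
})

test_that("sequential decomposition separates correlated predictors", {
  # orthogonal predictors: each term's p identical in both orderings
  set.seed(19)
  n_plots <- 12; per <- 6
  d <- data.frame(plot_id = rep(sprintf("p%d", 1:n_plots), each = per))
  x1 <- rep(rnorm(n_plots), each = per)
  x2 <- rnorm(n_plots * per)
  x2 <- residuals(lm(x2 ~ x1))  # exactly orthogonal
  d$x1 <- x1; d$x2 <- x2
  d$td <- exp(-2 + 0.3 * x1 - 0.2 * x2 +
                rep(rnorm(n_plots, 0, 0.2), each = per) +
                rnorm(nrow(d), 0, 0.3))
  sq <- sequential_decomposition(d, "x1", "x2")
  p_x1 <- sq$orders$p[sq$orders$term == "x1"]
  p_x2 <- sq$orders$p[sq$orders$term == "x2"]
  # orthogonality holds in the fixed design; variance components are
  # re-estimated per fit, so agreement is near- but not machine-exact
  expect_lt(abs(p_x1[1] - p_x1[2]), 0.05)
  expect_lt(abs(p_x2[1] - p_x2[2]), 0.05)

  # collinear predictors are rejected
  d$x3 <- d$x1
  expect_error(sequential_decomposition(d, "x1", "x3"), "collinear")
})

test_that("only-causal predictor stays significant in both orders", {
  # x1 causal, x2 correlated (r ~ -0.5) but not causal: x1 significant
  # in both orders, x2 only when fitted first
  set.seed(23)
  n_plots <- 15; per <- 4
  u <- rnorm(n_plots)
  x1 <- rep(u, each = per) + rnorm(n_plots * per, 0, 0.6)
  x2 <- rep(-0.6 * u, each = per) + rnorm(n_plots * per, 0, 0.6)
  d <- data.frame(plot_id = rep(sprintf("p%d", 1:n_plots), each = per),
                  x1 = x1, x2 = x2)
  d$td <- exp(-2 + 0.5 * x1 + rep(rnorm(n_plots, 0, 0.1), each = per) +
                rnorm(nrow(d), 0, 0.25))
  sq <- sequential_decomposition(d, "x1", "x2")
  ord <- sq$orders
  expect_lt(ord$p[ord$term == "x1"][1], 0.05)  # fitted first
  expect_lt(ord$p[ord$term == "x1"][2], 0.05)  # fitted second
  expect_gt(ord$p[ord$order == "x1 then x2" & ord$term == "x2"], 0.05)
})

test_that("pearson matches hand computation and flags degeneracy", {
  expect_equal(pearson(1:10, 1:10)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  got <- pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$r, 0.6)
  expect_equal(got$n, 4)
  expect_warning(z <- pearson(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z$r))
})

test_that("model sets have the published sizes and K structure", {
  expect_equal(length(plot_model_set()), 6)
  expect_equal(length(neighborhood_model_set()), 15)
  k_of <- function(tt) length(tt) + 1 + 2
  expect_equal(sort(unique(vapply(neighborhood_model_set(), k_of,
                                  numeric(1)))), c(3, 4, 5, 6))
})
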