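test_that("family selection returns three finite AICs and honours preconditions", {
  tab <- simulate_rate_table(shape = 5, stim_effects = c(0.8, 0.7, 0.9, 0.9),
                             seed = 1)
  sel <- select_rate_family(tab)
  expect_named(sel$aic, c("Gamma", "InverseGaussian", "Gaussian"))
  expect_true(all(is.finite(sel$aic)))
  expect_s3_class(sel$model, "glm")

  one_stim <- tab[tab$stimulus == "water", ]
  expect_error(select_rate_family(one_stim), "stimuli")
  one_loc <- tab[tab$location == "mid", ]
  expect_error(select_rate_family(one_loc), "location")
  withz <- tab
  withz$rate_1s[1] <- 0
  expect_warning(select_rate_family(withz), "0.5")
})

test_that("AIC ordering is invariant to row order of the rate table", {
  tab <- simulate_rate_table(shape = 5, stim_effects = c(0.5, 0.4, 0.6, 0.6),
                             seed = 3)
  a <- select_rate_family(tab)$aic
  set.seed(1)
  b <- select_rate_family(tab[sample(nrow(tab)), ])$aic
  expect_equal(a, b)
})

test_that("Gamma-generated rates select the Gamma family most of the time", {
  # 30-replicate spot check (the 100-replicate sweep runs with acceptance)
  picks <- vapply(1:30, function(s) {
    tab <- simulate_rate_table(shape = 5, intercept = log(20),
                               stim_effects = c(0.8, 0.7, 0.9, 0.9),
                               loc_effect = 0.2, seed = s)
    select_rate_family(tab)$family
  }, character(1))
  expect_gte(mean(picks == "Gamma"), 0.8)
})

test_that("homoscedastic Gaussian rates favour the Gaussian AIC over Gamma", {
  wins <- vapply(1:30, function(s) {
    tab <- simulate_rate_table(seed = 200 + s)
    set.seed(300 + s)
    tab$rate_1s <- rnorm(nrow(tab), 30, 3)
    aic <- select_rate_family(tab)$aic
    aic[["Gaussian"]] <= aic[["Gamma"]]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("Wald terms report chi-square tests for all three terms", {
  tab <- simulate_rate_table(shape = 5, stim_effects = c(1, 0.9, 1.1, 1.1),
                             loc_effect = 0.3,
                             interaction = c(0, 0, 0.4, 0.4), seed = 2)
  sel <- select_rate_family(tab)
  w <- wald_terms(sel$model)
  expect_equal(w$term, c("stimulus", "location", "stimulus:location"))
  expect_equal(w$df, c(4, 1, 4))
  expect_true(all(w$p >= 0 & w$p <= 1))
  # injected log-mean shifts of ~1 are detected decisively
  expect_lt(w$p[w$term == "stimulus"], 0.001)
})

test_that("a singular design raises an error naming the aliased term", {
  tab <- simulate_rate_table(seed = 5)
  confounded <- tab[(tab$stimulus == "water" & tab$location == "mid") |
                      (tab$stimulus == "sucrose" & tab$location == "tip"), ]
  confounded$stimulus <- factor(confounded$stimulus)
  confounded$location <- factor(confounded$location)
  m <- suppressWarnings(glm(rate_1s ~ stimulus * location,
                            family = Gamma(link = "log"),
                            data = confounded))
  expect_error(wald_terms(m), "aliased")
})

test_that("marginal-mean contrasts are complete, antisymmetric and adjusted", {
  tab <- simulate_rate_table(shape = 5, stim_effects = c(0.6, 0.5, 0.7, 0.7),
                             seed = 4)
  two <- tab[tab$stimulus %in% c("water", "sucrose"), ]
  sel2 <- suppressWarnings(select_rate_family(two))
  pm2 <- pairwise_marginal_means(sel2$model)
  expect_equal(nrow(pm2$within), 2)           # 1 contrast per location
  expect_equal(nrow(pm2$between), 2)          # tip-mid per stimulus

  sel <- select_rate_family(tab)
  pm <- pairwise_marginal_means(sel$model)
  expect_equal(nrow(pm$within), 2 * choose(5, 2))
  # symmetry: A-B and B-A estimates are exact negatives; emmeans reports one
  # orientation, so check reversing the factor order flips the sign
  tab_rev <- tab
  tab_rev$stimulus <- factor(tab_rev$stimulus,
                             levels = rev(sort(unique(tab$stimulus))))
  sel_rev <- select_rate_family(tab_rev)
  pm_rev <- pairwise_marginal_means(sel_rev$model)
  est <- pm$within$estimate[pm$within$contrast == "caffeine - NaCl" &
                              pm$within$location == "mid"]
  est_rev <- pm_rev$within$estimate[pm_rev$within$contrast ==
                                      "NaCl - caffeine" &
                                      pm_rev$within$location == "mid"]
  expect_equal(est, -est_rev, tolerance = 1e-8)
  # Tukey adjustment never reduces a p-value
  raw <- pairwise_marginal_means(sel$model, adjust = "none")
  expect_true(all(pm$within$p.value >= raw$within$p.value - 1e-12))
})

test_that("the temporal Gamma mixed model detects distinct tonic rates", {
  bt <- simulate_bin_table(n_bees = 10, seed = 3)
  rep <- fit_temporal_glmm(bt)
  expect_false(rep$fallback)
  expect_equal(rep$anova$term, c("stimulus", "time", "stimulus:time"))
  expect_lt(rep$anova$p[rep$anova$term == "stimulus"], 0.01)
  # per-time contrasts: one stimulus pair at each of 20 bins
  expect_equal(nrow(rep$pairwise_by_time), 20)
})

test_that("all-zero bins degrade gracefully to an offset-only fit", {
  bt <- simulate_bin_table(n_bees = 4, seed = 8)
  bt$count <- 0
  rep <- fit_temporal_glmm(bt, contrasts_by_time = FALSE)
  expect_true(rep$degenerate)
  expect_equal(rep$anova$p, rep(1, 3))
  expect_equal(rep$anova$chisq, rep(0, 3))
})

test_that("Gamma GLM coefficients recover generator truth at nominal coverage", {
  # Wald 2-SE coverage pooled over the four stimulus effects; nominal 95%
  true_eff <- c(0.8, 0.7, 0.9, 0.9)
  hits <- integer(0)
  for (s in 1:60) {
    tab <- simulate_rate_table(shape = 5, stim_effects = true_eff,
                               seed = 700 + s)
    tab$stimulus <- relevel(factor(tab$stimulus), ref = "water")
    tab$location <- factor(tab$location)
    m <- suppressWarnings(glm(rate_1s ~ stimulus * location,
                              family = Gamma(link = "log"), data = tab))
    sm <- summary(m)$coefficients
    nm <- paste0("stimulus", c("NaCl", "quinine", "sucrose", "caffeine"))
    truth <- c(true_eff[2], true_eff[3], true_eff[1], true_eff[4])
    ok <- abs(sm[nm, "Estimate"] - truth) <= 2 * sm[nm, "Std. Error"]
    hits <- c(hits, ok)
  }
  expect_gte(mean(hits), 0.93)
})
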