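test_that("all-at-chance response rates give a degenerate Wilcoxon with p = 1", {
  res <- wilcoxon_vs_random(rep(0.5, 12))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_equal(res$n_used, 0)
})

test_that("five tied rates above chance reproduce the exact enumeration p", {
  # independent oracle: enumerate all 2^5 sign assignments of the tied
  # |differences| (average ranks are all 3), so W = 3 * (#positive signs)
  d <- arcsine_sqrt(rep(0.6, 5)) - pi / 4
  r <- rep(3, 5)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  Wdist <- as.vector(signs %*% r)
  w_obs <- sum(r)  # all five differences positive
  p_oracle <- min(1, 2 * min(mean(Wdist <= w_obs), mean(Wdist >= w_obs)))
  expect_equal(p_oracle, 0.0625)

  res <- wilcoxon_vs_random(rep(0.6, 5))
  expect_equal(res$W, 15)
  expect_equal(res$p, 0.0625)
  expect_equal(res$method, "enumeration")
})

test_that("the Wilcoxon result is invariant to permutation of the rates", {
  set.seed(10)
  rates <- round(runif(12, 0.2, 0.9), 2)
  a <- wilcoxon_vs_random(rates)
  b <- wilcoxon_vs_random(sample(rates))
  expect_equal(a$W, b$W)
  expect_equal(a$p, b$p)
  expect_equal(a$median, b$median)
})

test_that("untied samples take the standard exact branch and agree with wilcox.test", {
  set.seed(77)
  rates <- sin(rnorm(12, pi / 4 + 0.15, 0.1))^2
  res <- wilcoxon_vs_random(rates)
  expect_equal(res$method, "exact")
  ref <- wilcox.test(arcsine_sqrt(rates), mu = pi / 4, exact = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$W, unname(ref$statistic))
  # large samples fall back to the corrected normal approximation
  big <- sin(rnorm(30, pi / 4, 0.1))^2
  expect_equal(wilcoxon_vs_random(big)$method, "normal_approx")
  expect_error(wilcoxon_vs_random(c(0.5, 0.6)), "at least 5")
})

test_that("candidate learning models cover the declared family and order-invariance", {
  coh <- simulate_conditioning_cohort("sucrose", n_bees = 6, seed = 21)
  summ <- summarize_conditioning(coh)
  lms <- fit_learning_models(summ)
  expect_equal(nrow(lms$table), 8)
  expect_setequal(lms$table$group_structure,
                  c("all_same", "control_vs_conditioned", "all_distinct"))
  expect_true(lms$selected %in% lms$table$id)
  # parsimony rule: the selected model sits within 2 AIC of the minimum
  sel_row <- lms$table[lms$table$id == lms$selected, ]
  expect_lte(sel_row$delta_aic, 2)
  # row-order invariance
  set.seed(3)
  lms2 <- fit_learning_models(summ[sample(nrow(summ)), ])
  expect_equal(lms$table$aic, lms2$table$aic)
  expect_equal(lms$selected, lms2$selected)

  expect_error(fit_learning_models(summ[summ$group != "control", ]),
               "control")
})

test_that("learning-curve selection separates learners from cue-blind bees", {
  # learners: the group-structured model with experience wins decisively
  coh <- simulate_conditioning_cohort("sucrose", n_bees = 10, seed = 9)
  lms <- fit_learning_models(summarize_conditioning(coh))
  expect_gt(learning_separation_delta(lms), 2)
  sel <- lms$table[lms$table$id == lms$selected, ]
  expect_equal(sel$group_structure, "control_vs_conditioned")

  # cue-blind bees: the intercept-only model is selected (spot check; the
  # 100-replicate sweep runs with acceptance)
  nulls <- vapply(1:20, function(s) {
    coh0 <- simulate_conditioning_cohort("sucrose", n_bees = 10,
                                         params = forager_params(seed = 1),
                                         seed = derive_seed(7, s))
    fit_learning_models(summarize_conditioning(coh0))$selected
  }, character(1))
  expect_gte(mean(nulls == "null"), 0.8)
})

test_that("letter groupings follow the pairwise p-matrix", {
  gn <- c("control", "neg", "pos")
  pm <- function(p12, p13, p23) {
    m <- matrix(1, 3, 3, dimnames = list(gn, gn))
    m["control", "neg"] <- m["neg", "control"] <- p12
    m["control", "pos"] <- m["pos", "control"] <- p13
    m["neg", "pos"] <- m["pos", "neg"] <- p23
    m
  }
  # all indistinguishable
  expect_equal(unname(letter_groups(pm(0.9, 0.8, 0.7))), rep("a", 3))
  # all distinct
  expect_equal(unname(letter_groups(pm(0.01, 0.01, 0.01))),
               c("a", "b", "c"))
  # chain: control != pos, but neg bridges both
  lg <- letter_groups(pm(0.2, 0.01, 0.3))
  expect_equal(nchar(lg[["neg"]]), 2)
  expect_false(any(strsplit(lg[["control"]], "")[[1]] %in%
                     strsplit(lg[["pos"]], "")[[1]]))
  expect_true(any(strsplit(lg[["neg"]], "")[[1]] %in%
                    strsplit(lg[["control"]], "")[[1]]))
})

test_that("the test-phase ANOVA has the design degrees of freedom", {
  coh <- simulate_conditioning_cohort("quinine", n_bees = 10, seed = 14)
  res <- test_phase_anova(summarize_conditioning(coh))
  expect_equal(res$df, c(2, 27))
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(nrow(res$tukey), 3)
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
})

test_that("equal group means give F = 0 and a group needs two bees", {
  summ <- data.frame(bee_id = sprintf("b%02d", 1:9),
                     group = rep(c("control", "neg", "pos"), each = 3),
                     test_t = rep(c(0.4, 0.5, 0.6), times = 3))
  res <- test_phase_anova(summ)
  expect_equal(res$F, 0)
  expect_equal(unname(res$letters), rep("a", 3))

  tiny <- summ[-(1:2), ]
  expect_error(test_phase_anova(tiny), "at least 2")
})

test_that("the full behavioural chain detects conditioning but not its absence", {
  # end-to-end power property: with learning, both conditioned groups beat
  # control in the test phase (Tukey p < 0.05) in at least 70% of
  # replicates; with salience 0 a difference is claimed in at most 7%
  n_rep <- 200
  hit <- fp <- logical(n_rep)
  for (r in 1:n_rep) {
    coh <- simulate_conditioning_cohort("sucrose", n_bees = 10,
                                        seed = derive_seed(23, r))
    res <- test_phase_anova(summarize_conditioning(coh))
    ctrl_p <- res$tukey$p_adj[grepl("control", res$tukey$contrast)]
    hit[r] <- all(ctrl_p < 0.05)

    coh0 <- simulate_conditioning_cohort("sucrose", n_bees = 10,
                                         params = forager_params(seed = 1),
                                         seed = derive_seed(29, r))
    res0 <- test_phase_anova(summarize_conditioning(coh0))
    ctrl_p0 <- res0$tukey$p_adj[grepl("control", res0$tukey$contrast)]
    fp[r] <- any(ctrl_p0 < 0.05)
  }
  expect_gte(mean(hit), 0.70)
  expect_lte(mean(fp), 0.07)
})
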