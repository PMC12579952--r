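# Inferential statistics on per-bee behavioural summaries: one-sample
# Wilcoxon tests of tastant surface response rates against chance, the
# candidate family of learning-curve GLMs with AIC/parsimony selection, and
# the test-phase one-way ANOVA with Tukey post hoc letter groupings.

#' One-sample Wilcoxon signed-rank test of response rates against chance
#'
#' Arcsine square-root transforms the per-bee rates and tests them two-tailed
#' against the transformed chance level `asin(sqrt(0.5)) = pi/4` (0.79 to two
#' decimals). Zero differences are dropped. The null distribution is the
#' standard exact one when the remaining differences are untied and `n <= 25`;
#' with ties (or zeros dropped) and `n <= max_enumerate` all `2^n` sign
#' assignments are enumerated (average ranks), and otherwise a normal
#' approximation with continuity correction is used. If every difference is
#' zero the result is flagged degenerate and `p = 1`.
#'
#' @param rates Per-bee response rates (proportions).
#' @param mu Baseline on the transformed scale (default `asin(sqrt(0.5))`).
#' @param max_enumerate Largest n for the sign-flip enumeration branch.
#' @return A list of class `preference_test` with `n` (bees), `n_used`
#'   (non-zero differences), `median`, `min`, `max` (raw rates), `W`, `p`,
#'   `method` and `degenerate`.
#' @export
wilcoxon_vs_random <- function(rates, mu = asin(sqrt(0.5)),
                               max_enumerate = 15) {
  if (length(rates) < 5) stop("need at least 5 bees", call. = FALSE)
  tr <- arcsine_sqrt(rates)
  d <- tr - mu
  d_nz <- d[d != 0]
  n <- length(d_nz)
  res <- list(n = length(rates), n_used = n,
              median = stats::median(rates), min = min(rates),
              max = max(rates))
  if (n == 0) {
    res <- c(res, list(W = NA_real_, p = 1, method = "degenerate",
                       degenerate = TRUE))
    return(structure(res, class = "preference_test"))
  }
  r <- rank(abs(d_nz))
  W <- sum(r[d_nz > 0])
  ties <- anyDuplicated(abs(d_nz)) > 0
  dropped <- n < length(d)
  if (!ties && !dropped && n <= 25) {
    wt <- stats::wilcox.test(d_nz, mu = 0, alternative = "two.sided",
                             exact = TRUE)
    p <- wt$p.value
    method <- "exact"
  } else if (n <= max_enumerate) {
    # randomization null: enumerate all 2^n sign assignments of the observed
    # |differences|, with average ranks; two-sided p = 2 * min(tail probs)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wdist <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(Wdist <= W), mean(Wdist >= W)))
    method <- "enumeration"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d_nz, mu = 0, alternative = "two.sided",
                         exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "normal_approx"
  }
  res <- c(res, list(W = W, p = p, method = method, degenerate = FALSE))
  structure(res, class = "preference_test")
}

#' @export
print.preference_test <- function(x, ...) {
  cat(sprintf("One-sample Wilcoxon vs chance (transformed mu = pi/4)\n"))
  cat(sprintf("  n = %d bees | response rate median %.2f (range %.2f-%.2f)\n",
              x$n, x$median, x$min, x$max))
  cat(sprintf("  W = %s, two-tailed p = %.4g [%s]\n",
              format(x$W), x$p, x$method))
  invisible(x)
}

# ---- learning-curve model selection --------------------------------------

learning_candidates <- function() {
  data.frame(
    id = c("null", "experience", "group2", "group3",
           "group2_experience", "group3_experience",
           "group2_x_experience", "group3_x_experience"),
    group_structure = c("all_same", "all_same", "control_vs_conditioned",
                        "all_distinct", "control_vs_conditioned",
                        "all_distinct", "control_vs_conditioned",
                        "all_distinct"),
    experience = c("none", "additive", "none", "none", "additive",
                   "additive", "interaction", "interaction"),
    formula = c("y ~ 1", "y ~ experience", "y ~ cond2", "y ~ group",
                "y ~ cond2 + experience", "y ~ group + experience",
                "y ~ cond2 * experience", "y ~ group * experience"),
    stringsAsFactors = FALSE)
}

#' Fit the candidate learning-curve models and select by AIC with parsimony
#'
#' Builds the long table of transformed training success rates (one row per
#' bee per 10-visit interval) and fits the candidate family of Gaussian GLMs
#' crossing three group structures (all groups share one curve; control vs
#' conditioned; all three groups distinct) with three experience structures
#' (no experience term; experience — the visit-interval covariate, i.e. the
#' underlying learning parameter — additive; group x experience interaction).
#' The selected model is the most parsimonious (fewest parameters) among
#' those within `delta` AIC of the minimum.
#'
#' @param summaries A conditioning bee-summary table (from
#'   [summarize_conditioning()]) for the three groups of one tastant.
#' @param groups Optional named character vector or data frame (bee_id ->
#'   group); defaults to the `group` column of `summaries`.
#' @param delta Parsimony band on the AIC scale (default 2).
#' @return A list of class `learning_model_set` with `table` (candidates,
#'   AIC, delta AIC, n_par), `selected` (model id), `models` (fits) and
#'   `data` (the long table used).
#' @export
fit_learning_models <- function(summaries, groups = NULL, delta = 2) {
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- stats::setNames(groups$group, groups$bee_id)
    }
    summaries$group <- unname(groups[summaries$bee_id])
  }
  g <- unique(summaries$group)
  if (length(g) != 3 || !"control" %in% g) {
    stop("need the control group plus the two conditioned groups of one tastant",
         call. = FALSE)
  }
  s_cols <- grep("^s[0-9]+_t$", names(summaries), value = TRUE)
  if (length(s_cols) == 0) {
    stop("summaries must carry transformed interval success columns (s10_t..s70_t)",
         call. = FALSE)
  }
  intervals <- as.numeric(sub("_t$", "", sub("^s", "", s_cols)))
  long <- do.call(rbind, lapply(seq_along(s_cols), function(j) {
    data.frame(bee_id = summaries$bee_id, group = summaries$group,
               experience = intervals[j] / 10,   # interval index 1..7
               y = summaries[[s_cols[j]]], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$bee_id, long$experience), ]
  long$group <- stats::relevel(factor(long$group), ref = "control")
  long$cond2 <- factor(ifelse(long$group == "control", "control",
                              "conditioned"), levels = c("control",
                                                         "conditioned"))
  cand <- learning_candidates()
  models <- lapply(cand$formula, function(f) {
    stats::glm(stats::as.formula(f), family = stats::gaussian(), data = long)
  })
  names(models) <- cand$id
  cand$aic <- vapply(models, stats::AIC, numeric(1))
  cand$n_par <- vapply(models, function(m) length(stats::coef(m)) + 1L,
                       integer(1))  # + dispersion
  cand$delta_aic <- cand$aic - min(cand$aic)
  in_band <- cand$delta_aic <= delta
  sel <- cand$id[in_band][order(cand$n_par[in_band],
                                cand$aic[in_band])][1]
  structure(list(table = cand[, c("id", "group_structure", "experience",
                                  "n_par", "aic", "delta_aic")],
                 selected = sel, models = models, data = long),
            class = "learning_model_set")
}

#' @export
print.learning_model_set <- function(x, ...) {
  cat("Learning-curve candidate models (Gaussian GLM on transformed success)\n")
  tab <- x$table
  tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Selected (parsimony, dAIC <= 2): %s\n", x$selected))
  invisible(x)
}

#' AIC separation of group-structured learning models from all-same models
#'
#' The margin by which the best model that both separates the control group
#' from the conditioned groups and includes an experience term beats the best
#' model with no group structure. Positive values mean the group-structured
#' learning model wins; > 2 is the conventional decisive margin.
#'
#' @param lms A `learning_model_set`.
#' @return Numeric AIC difference (all-same minimum minus structured
#'   minimum).
#' @export
learning_separation_delta <- function(lms) {
  tab <- lms$table
  structured <- tab$group_structure != "all_same" & tab$experience != "none"
  allsame <- tab$group_structure == "all_same"
  min(tab$aic[allsame]) - min(tab$aic[structured])
}

# ---- test-phase ANOVA -----------------------------------------------------

#' Compact letter display from a pairwise p-value matrix
#'
#' Two groups share a letter iff their pairwise p-value is at least `alpha`
#' (no significant difference). Letters correspond to the maximal cliques of
#' the "not significantly different" graph, so sharing is consistent and the
#' display is minimal for small numbers of groups.
#'
#' @param pmat Symmetric matrix of pairwise p-values with group names as
#'   dimnames (diagonal ignored).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
letter_groups <- function(pmat, alpha = 0.05) {
  gn <- rownames(pmat)
  k <- length(gn)
  if (k == 1) return(stats::setNames("a", gn))
  adj <- pmat >= alpha
  diag(adj) <- FALSE
  # Bron-Kerbosch without pivoting; k is small (3 groups in the design)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(setdiff(P, v), nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  letters_out <- rep("", k)
  for (i in seq_along(cliques)) {
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]],
                                        letters[i])
  }
  stats::setNames(letters_out, gn)
}

#' Test-phase one-way ANOVA with Tukey post hoc letter groupings
#'
#' Compares arcsine square-root transformed test-phase success rates across
#' the control, tastant-positive and tastant-negative groups with a one-way
#' ANOVA (between df = 2, within df = n - 3 for three groups), Tukey HSD
#' pairwise comparisons and a compact letter display at `alpha`.
#'
#' @param summaries A conditioning bee-summary table for the three groups of
#'   one tastant (needs columns `bee_id`, `group`, `test_t`).
#' @param groups Optional bee_id -> group mapping as in
#'   [fit_learning_models()].
#' @param alpha Significance level for the letter display.
#' @return A list of class `test_phase_result` with `F`, `df` (length 2),
#'   `p`, `tukey` (data frame contrast/diff/p_adj), `letters` and
#'   `group_means` (on both scales).
#' @export
test_phase_anova <- function(summaries, groups = NULL, alpha = 0.05) {
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- stats::setNames(groups$group, groups$bee_id)
    }
    summaries$group <- unname(groups[summaries$bee_id])
  }
  counts <- table(summaries$group)
  if (any(counts < 2)) {
    stop(sprintf("every group needs at least 2 bees (got: %s)",
                 paste(sprintf("%s=%d", names(counts), counts),
                       collapse = ", ")), call. = FALSE)
  }
  d <- data.frame(y = summaries$test_t, group = factor(summaries$group))
  fit <- stats::aov(y ~ group, data = d)
  an <- summary(fit)[[1]]
  Fval <- an[["F value"]][1]
  if (is.na(Fval) && an[["Sum Sq"]][1] == 0) Fval <- 0
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  gn <- levels(d$group)
  pmat <- matrix(1, length(gn), length(gn), dimnames = list(gn, gn))
  for (i in seq_len(nrow(tukey))) {
    pair <- strsplit(tukey$contrast[i], "-", fixed = TRUE)[[1]]
    pv <- tukey$p_adj[i]
    if (is.na(pv)) pv <- 1  # degenerate (zero-variance) data: no difference
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- pv
  }
  means <- tapply(d$y, d$group, mean)
  structure(list(F = Fval, df = c(an$Df[1], an$Df[2]),
                 p = an[["Pr(>F)"]][1], tukey = tukey,
                 letters = letter_groups(pmat, alpha),
                 group_means = data.frame(group = gn,
                                          mean_transformed = as.numeric(means),
                                          mean_success = sin(as.numeric(means))^2),
                 alpha = alpha),
            class = "test_phase_result")
}

#' @export
print.test_phase_result <- function(x, ...) {
  cat(sprintf("Test-phase ANOVA: F(%d, %d) = %.2f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$tukey, row.names = FALSE)
  cat("Letter groups:",
      paste(sprintf("%s=%s", names(x$letters), x$letters), collapse = "  "),
      "\n")
  invisible(x)
}
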