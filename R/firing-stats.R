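# Inferential statistics on firing records: AIC-selected GLM family for 1 s
# rates with stimulus x location effects, type-II Wald tests, estimated
# marginal-mean pairwise contrasts, and a Gamma mixed model for 100 ms bins.

prepare_rate_table <- function(table) {
  needed <- c("location", "stimulus", "rate_1s")
  if (!all(needed %in% names(table))) {
    stop("rate table needs columns location, stimulus, rate_1s", call. = FALSE)
  }
  if (length(unique(table$stimulus)) < 2) {
    stop("need at least 2 stimuli to model stimulus effects", call. = FALSE)
  }
  if (length(unique(table$location)) < 2) {
    stop("need both sensillum locations (mid and tip)", call. = FALSE)
  }
  if (any(table$rate_1s <= 0)) {
    warning("non-positive rates replaced by 0.5 spikes/s for the Gamma and inverse-Gaussian families")
    table$rate_1s[table$rate_1s <= 0] <- 0.5
  }
  table$stimulus <- factor(table$stimulus)
  table$location <- factor(table$location)
  table
}

#' Select the error family for the firing-rate GLM by AIC
#'
#' Fits `rate_1s ~ stimulus * location` under Gamma (log link), inverse
#' Gaussian (log link) and Gaussian (identity link) families, and returns the
#' AIC table with the minimum-AIC family and its fitted model.
#'
#' @param table A rate table: data frame with columns `location`
#'   (`mid`/`tip`), `stimulus` and `rate_1s` (spikes/s). Non-positive rates
#'   are replaced by 0.5 spikes/s with a warning.
#' @return A list of class `rate_family_selection` with `aic` (named vector),
#'   `family` (the winner), and `model` (the winning `glm` fit).
#' @export
select_rate_family <- function(table) {
  table <- prepare_rate_table(table)
  fams <- list(
    Gamma = stats::Gamma(link = "log"),
    InverseGaussian = stats::inverse.gaussian(link = "log"),
    Gaussian = stats::gaussian(link = "identity"))
  fits <- lapply(fams, function(f) {
    tryCatch(stats::glm(rate_1s ~ stimulus * location, family = f,
                        data = table),
             error = function(e) NULL, warning = function(w) {
               suppressWarnings(stats::glm(rate_1s ~ stimulus * location,
                                           family = f, data = table))
             })
  })
  aic <- vapply(fits, function(m) if (is.null(m)) Inf else stats::AIC(m),
                numeric(1))
  best <- names(aic)[which.min(aic)]
  structure(list(aic = aic, family = best, model = fits[[best]]),
            class = "rate_family_selection")
}

#' @export
print.rate_family_selection <- function(x, ...) {
  cat("Firing-rate GLM family selection (rate_1s ~ stimulus * location)\n")
  for (f in names(x$aic)) {
    cat(sprintf("  %-16s AIC = %s%s\n", f,
                formatC(x$aic[[f]], format = "f", digits = 2),
                if (f == x$family) "  <- selected" else ""))
  }
  invisible(x)
}

#' Type-II Wald tests for the firing-rate model terms
#'
#' @param model A fitted GLM (or glmmTMB model) with stimulus, location and
#'   interaction terms.
#' @return A data frame with columns `term`, `chisq`, `df`, `p`.
#' @export
wald_terms <- function(model) {
  cf <- stats::coef(model)
  if (is.numeric(cf) && anyNA(cf)) {
    stop(sprintf("singular design: aliased coefficient(s) %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  a <- car::Anova(model, type = "II", test.statistic = "Wald")
  a <- as.data.frame(a)
  keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
  a <- a[keep, , drop = FALSE]
  chisq_col <- grep("Chisq", names(a), value = TRUE)[1]
  p_col <- grep("^Pr", names(a), value = TRUE)[1]
  data.frame(term = rownames(a), chisq = a[[chisq_col]], df = a$Df,
             p = a[[p_col]], row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise stimulus contrasts from estimated marginal means
#'
#' Computes the marginal mean per stimulus within each level of `by` on the
#' link scale, all pairwise within-`by` differences with Tukey family-wise
#' adjustment, and the between-location contrast for each stimulus.
#'
#' @param model A fitted firing-rate model.
#' @param by Conditioning factor for the within-group contrasts (default
#'   `"location"`).
#' @param adjust Multiplicity adjustment (default `"tukey"`).
#' @return A list with `emmeans` (marginal means), `within` (pairwise
#'   stimulus contrasts within each `by` level) and `between`
#'   (location contrast per stimulus), each a data frame.
#' @export
pairwise_marginal_means <- function(model, by = "location",
                                    adjust = "tukey") {
  emm <- emmeans::emmeans(model, specs = "stimulus", by = by)
  within <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise",
                                                    adjust = adjust)))
  emm_loc <- emmeans::emmeans(model, specs = by, by = "stimulus")
  between <- as.data.frame(summary(emmeans::contrast(emm_loc,
                                                     method = "pairwise",
                                                     adjust = adjust)))
  list(emmeans = as.data.frame(summary(emm)), within = within,
       between = between)
}

#' Fit the temporal Gamma mixed model to binned spike counts
#'
#' Fits `count + 1 ~ stimulus * time_bin + (1 | bee_id)` with a Gamma
#' distribution and log link (the +1 offset accounts for empty bins), assesses
#' the fixed effects with a type-II ANOVA, and computes per-time pairwise
#' stimulus contrasts. If the mixed model fails to converge the function
#' falls back to the fixed-effects GLM and flags the report.
#'
#' @param table A bin table: data frame with columns `bee_id`, `stimulus`,
#'   `time_bin` (1..20) and `count` (or `count_plus_one`).
#' @param contrasts_by_time Compute per-time-bin pairwise stimulus contrasts
#'   (can be slow for many bins; default TRUE).
#' @return A list of class `temporal_glmm_report` with `model`, `anova`
#'   (data frame of term tests), `pairwise_by_time` (or NULL), `converged`
#'   and `fallback` flags.
#' @export
fit_temporal_glmm <- function(table, contrasts_by_time = TRUE) {
  needed <- c("bee_id", "stimulus", "time_bin")
  if (!all(needed %in% names(table))) {
    stop("bin table needs columns bee_id, stimulus, time_bin and count",
         call. = FALSE)
  }
  if (!"count_plus_one" %in% names(table)) {
    if (!"count" %in% names(table)) stop("need a count column", call. = FALSE)
    table$count_plus_one <- table$count + 1
  }
  if (any(table$count_plus_one < 1)) {
    stop("count_plus_one must be >= 1", call. = FALSE)
  }
  table$stimulus <- factor(table$stimulus)
  table$time <- factor(table$time_bin)
  table$bee_id <- factor(table$bee_id)

  degenerate <- stats::var(table$count_plus_one) == 0
  fit <- NULL
  converged <- FALSE
  if (!degenerate) {
    fit <- tryCatch(
      withCallingHandlers(
        glmmTMB::glmmTMB(count_plus_one ~ stimulus * time + (1 | bee_id),
                         family = stats::Gamma(link = "log"), data = table),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      converged <- isTRUE(fit$fit$convergence == 0) &&
        isTRUE(fit$sdr$pdHess)
    }
  }
  fallback <- !converged
  if (fallback) {
    fit <- suppressWarnings(
      stats::glm(count_plus_one ~ stimulus * time,
                 family = stats::Gamma(link = "log"), data = table))
  }

  terms <- c("stimulus", "time", "stimulus:time")
  if (degenerate) {
    an <- data.frame(term = terms, chisq = 0, df = NA_real_, p = 1,
                     stringsAsFactors = FALSE)
  } else {
    a <- as.data.frame(car::Anova(fit, type = "II"))
    a <- a[rownames(a) %in% terms, , drop = FALSE]
    chisq_col <- grep("Chisq", names(a), value = TRUE)[1]
    p_col <- grep("^Pr", names(a), value = TRUE)[1]
    an <- data.frame(term = rownames(a), chisq = a[[chisq_col]], df = a$Df,
                     p = a[[p_col]], row.names = NULL,
                     stringsAsFactors = FALSE)
  }

  pw <- NULL
  if (contrasts_by_time && !degenerate) {
    emm <- emmeans::emmeans(fit, specs = "stimulus", by = "time")
    pw <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise",
                                                  adjust = "tukey")))
  }
  structure(list(model = fit, anova = an, pairwise_by_time = pw,
                 converged = converged, fallback = fallback,
                 degenerate = degenerate),
            class = "temporal_glmm_report")
}

#' @export
print.temporal_glmm_report <- function(x, ...) {
  cat("Temporal Gamma mixed model: count + 1 ~ stimulus * time + (1 | bee)\n")
  if (x$fallback) cat("  [mixed model did not converge; fixed-effects fallback]\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}
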