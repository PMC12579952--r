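# Visit-level scoring: favouring/not-favouring classification for the
# spontaneous-preference design, correct/incorrect classification for
# differential conditioning, tastant surface response rates, success-rate
# curves at 10-visit intervals and the test-phase success rate.

#' Classify preference-design visits as favouring treated flowers or not
#'
#' A visit favours treated flowers iff the bee probed a treated flower
#' (positive selection) or left an untreated flower without probing
#' (rejection of flowers lacking the tastant).
#'
#' @param flower_class Character vector, `"treated"` or `"untreated"`.
#' @param probed Logical or 0/1 vector.
#' @return Logical vector: `TRUE` = favouring.
#' @export
classify_preference_visit <- function(flower_class, probed) {
  bad <- setdiff(unique(flower_class), c("treated", "untreated"))
  if (length(bad)) {
    stop(sprintf("preference visits must have flower_class treated/untreated, got: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  probed <- as.logical(probed)
  (flower_class == "treated" & probed) |
    (flower_class == "untreated" & !probed)
}

#' Classify conditioning-design visits as correct or incorrect
#'
#' A visit is correct iff the bee probed a rewarding flower or left a
#' non-rewarding flower without probing.
#'
#' @param flower_class Character vector, `"rewarding"` or `"nonrewarding"`.
#' @param probed Logical or 0/1 vector.
#' @return Logical vector: `TRUE` = correct.
#' @export
classify_conditioning_visit <- function(flower_class, probed) {
  bad <- setdiff(unique(flower_class), c("rewarding", "nonrewarding"))
  if (length(bad)) {
    stop(sprintf("conditioning visits must have flower_class rewarding/nonrewarding, got: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  probed <- as.logical(probed)
  (flower_class == "rewarding" & probed) |
    (flower_class == "nonrewarding" & !probed)
}

#' Tastant surface response rate for one bee
#'
#' The proportion of a bee's landings whose outcome favoured treated flowers.
#' Under random foraging on a balanced array the expected rate is 0.5;
#' preferences push it above, aversions below.
#'
#' @param visits One bee's preference-design visit records.
#' @return Proportion in `[0, 1]`.
#' @export
tastant_response_rate <- function(visits) {
  if (nrow(visits) == 0) stop("empty visit log", call. = FALSE)
  if (length(unique(visits$bee_id)) != 1) {
    stop("expected visits from exactly one bee", call. = FALSE)
  }
  mean(classify_preference_visit(visits$flower_class, visits$probed))
}

#' Success-rate curve for one bee's conditioning log
#'
#' The success rate (proportion of correct visits) over each consecutive
#' block of ten training visits — visits 1-10, 11-20, ..., 61-70 — plus the
#' success rate across the 20 test-phase visits. Incomplete logs fail loudly,
#' listing the missing visits.
#'
#' @param visits One bee's full conditioning visit records (70 training + 20
#'   test visits).
#' @param n_training,n_test Expected phase lengths.
#' @param interval Interval width in visits (default 10).
#' @return A list of class `bee_success_curve` with `success_by_interval`
#'   (named s10..s70), `test_success`, `n_mouthpart_contact` and `bee_id`.
#' @export
success_curve <- function(visits, n_training = 70, n_test = 20,
                          interval = 10) {
  if (length(unique(visits$bee_id)) != 1) {
    stop("expected visits from exactly one bee", call. = FALSE)
  }
  tr <- visits[visits$phase == "training", ]
  te <- visits[visits$phase == "test", ]
  missing_tr <- setdiff(seq_len(n_training), tr$visit_index)
  missing_te <- setdiff(seq_len(n_test), te$visit_index)
  if (length(missing_tr) || length(missing_te)) {
    stop(sprintf("incomplete conditioning log for bee %s; missing training visits: %s; missing test visits: %s",
                 visits$bee_id[1],
                 if (length(missing_tr)) paste(missing_tr, collapse = ",") else "none",
                 if (length(missing_te)) paste(missing_te, collapse = ",") else "none"),
         call. = FALSE)
  }
  tr <- tr[order(tr$visit_index), ]
  correct <- classify_conditioning_visit(tr$flower_class, tr$probed)
  ends <- seq(interval, n_training, by = interval)
  s <- vapply(ends, function(k) mean(correct[(k - interval + 1):k]), numeric(1))
  names(s) <- sprintf("s%d", ends)
  test_correct <- classify_conditioning_visit(te$flower_class, te$probed)
  structure(list(bee_id = visits$bee_id[1],
                 success_by_interval = s,
                 test_success = mean(test_correct),
                 n_mouthpart_contact = sum(visits$mouthpart_contact)),
            class = "bee_success_curve")
}

#' Arcsine square-root transform for proportions
#'
#' The variance-stabilizing transform `asin(sqrt(p))` applied before the
#' Wilcoxon, learning-curve and ANOVA analyses; maps `[0, 1]` to
#' `[0, pi/2]` and 0.5 to `pi/4` (0.79 to two decimals).
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Transformed value(s).
#' @export
arcsine_sqrt <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("'p' must be proportions in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Summarize a preference-design visit log per bee
#'
#' @param visits A preference visit-log data frame (any number of bees).
#' @return A data frame with one row per bee: bee_id, group, n_visits,
#'   n_mouthpart_contact, rr (tastant surface response rate) and rr_t
#'   (transformed).
#' @export
summarize_preference <- function(visits) {
  out <- lapply(split(visits, visits$bee_id), function(d) {
    rr <- tastant_response_rate(d)
    data.frame(bee_id = d$bee_id[1], group = d$group[1], n_visits = nrow(d),
               n_mouthpart_contact = sum(d$mouthpart_contact),
               rr = rr, rr_t = arcsine_sqrt(rr), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize a conditioning visit log per bee
#'
#' @param visits A conditioning visit-log data frame (any number of bees).
#' @return A data frame with one row per bee: bee_id, group, s10..s70,
#'   s10_t..s70_t (transformed), test, test_t and n_mouthpart_contact.
#' @export
summarize_conditioning <- function(visits) {
  out <- lapply(split(visits, visits$bee_id), function(d) {
    sc <- success_curve(d)
    s <- as.list(sc$success_by_interval)
    st <- as.list(arcsine_sqrt(sc$success_by_interval))
    names(st) <- paste0(names(s), "_t")
    as.data.frame(c(list(bee_id = d$bee_id[1], group = d$group[1]), s, st,
                    list(test = sc$test_success,
                         test_t = arcsine_sqrt(sc$test_success),
                         n_mouthpart_contact = sc$n_mouthpart_contact)),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
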