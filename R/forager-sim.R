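# Agent-based forager simulation producing visit logs with the statistical
# structure the behavioural scoring and inference assume. The agent is a
# Rescorla-Wagner learner: it probes a visited flower with probability
# p(class) = clamp(p_probe_init + cue_salience * V(class) + scent_salience *
# S(class)), and during conditioning training updates the learned value V of
# the visited class toward +1 (sucrose reward) or -1 (water) by learn_rate.
# The scent channel S models marks left on probed flowers; it is the only cue
# available to control-group bees and is reset for the fresh flower set of the
# test phase.

#' Parameters of the simulated forager agent
#'
#' @param p_probe_init Baseline probing probability (default 0.5, the chance
#'   level of the scoring rules).
#' @param learn_rate Rescorla-Wagner learning rate in `[0, 1]`.
#' @param cue_salience Weight (>= 0) of the learned surface-cue value in the
#'   probing decision; 0 gives a cue-blind agent.
#' @param forget_rate Per-visit decay in `[0, 1]` of learned values of
#'   unvisited flower classes.
#' @param scent_salience Weight (>= 0) of the scent-mark channel (default 0 =
#'   off); enables above-chance training performance without surface cues.
#' @param mouthpart_contact_rate Per-visit probability of rare mouthpart
#'   contact with the flower disc (default 0.002).
#' @param seed Integer master seed; per-bee streams are derived with
#'   [derive_seed()].
#' @return An object of class `forager_params`.
#' @export
forager_params <- function(p_probe_init = 0.5, learn_rate = 0,
                           cue_salience = 0, forget_rate = 0,
                           scent_salience = 0, mouthpart_contact_rate = 0.002,
                           seed = 1) {
  check_number(p_probe_init, "p_probe_init", 0, 1)
  check_number(learn_rate, "learn_rate", 0, 1)
  check_number(cue_salience, "cue_salience", 0)
  check_number(forget_rate, "forget_rate", 0, 1)
  check_number(scent_salience, "scent_salience", 0)
  check_number(mouthpart_contact_rate, "mouthpart_contact_rate", 0, 1)
  check_count(seed, "seed")
  structure(list(p_probe_init = p_probe_init, learn_rate = learn_rate,
                 cue_salience = cue_salience, forget_rate = forget_rate,
                 scent_salience = scent_salience,
                 mouthpart_contact_rate = mouthpart_contact_rate,
                 seed = as.integer(seed)),
            class = "forager_params")
}

#' The nine differential-conditioning groups
#'
#' A control group (both flower variants untreated) plus a tastant-positive
#' (rewarding flowers treated) and tastant-negative (non-rewarding flowers
#' treated) group for each of sucrose, NaCl, quinine and caffeine.
#'
#' @return Character vector of the nine group labels.
#' @export
conditioning_groups <- function() {
  c("control",
    "sucrose_positive", "sucrose_negative",
    "nacl_positive", "nacl_negative",
    "quinine_positive", "quinine_negative",
    "caffeine_positive", "caffeine_negative")
}

#' Experimental design specification for visit-log simulation
#'
#' @param design `"preference"` (12 bees/tastant foraging to 20 landings on
#'   six treated + six untreated flowers) or `"conditioning"` (70 training
#'   visits on six rewarding + six non-rewarding flowers followed by 20
#'   unrewarded test visits).
#' @param group For conditioning, one of [conditioning_groups()]; for
#'   preference, the tastant label applied to treated flowers.
#' @param n_flowers_per_class Flowers per class in the array (default 6/6).
#' @param n_visits Visits per bee in the preference design (default 20).
#' @param n_training_visits,n_test_visits Conditioning phase lengths
#'   (defaults 70 and 20).
#' @param max_visits_per_bout Bout boundaries are inserted every this many
#'   visits (default 20).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(design = c("preference", "conditioning"),
                        group = if (design[1] == "conditioning") "control" else "sucrose",
                        n_flowers_per_class = 6, n_visits = 20,
                        n_training_visits = 70, n_test_visits = 20,
                        max_visits_per_bout = 20) {
  design <- match.arg(design)
  if (design == "conditioning" && !group %in% conditioning_groups()) {
    stop(sprintf("'group' must be one of: %s",
                 paste(conditioning_groups(), collapse = ", ")), call. = FALSE)
  }
  check_count(n_flowers_per_class, "n_flowers_per_class", lower = 1)
  check_count(n_visits, "n_visits", lower = 1)
  check_count(n_training_visits, "n_training_visits", lower = 1)
  check_count(n_test_visits, "n_test_visits", lower = 1)
  check_count(max_visits_per_bout, "max_visits_per_bout", lower = 1)
  structure(list(design = design, group = group,
                 n_flowers_per_class = n_flowers_per_class,
                 n_visits = n_visits, n_training_visits = n_training_visits,
                 n_test_visits = n_test_visits,
                 max_visits_per_bout = max_visits_per_bout),
            class = "design_spec")
}

# one bee's log; assumes the RNG seed has been set by the caller
simulate_bee_visits <- function(params, spec, bee_id) {
  classes <- if (spec$design == "preference") c("treated", "untreated")
             else c("rewarding", "nonrewarding")
  V <- stats::setNames(c(0, 0), classes)   # learned surface-cue values
  S <- stats::setNames(c(0, 0), classes)   # scent-mark channel
  phases <- if (spec$design == "preference") {
    list(preference = spec$n_visits)
  } else {
    list(training = spec$n_training_visits, test = spec$n_test_visits)
  }
  out <- vector("list", length(phases))
  for (ph in names(phases)) {
    nv <- phases[[ph]]
    if (ph == "test") S[] <- 0  # fresh, unmarked flower set
    cl <- probed <- mouth <- vector("integer", nv)
    cls <- character(nv)
    for (i in seq_len(nv)) {
      # uniform over the 12-flower array composition (balanced classes)
      k <- sample(c(1L, 2L), 1)
      p <- clamp01(params$p_probe_init +
                     params$cue_salience * V[k] +
                     params$scent_salience * S[k])
      pr <- stats::runif(1) < p
      if (spec$design == "conditioning" && ph == "training") {
        # outcome feedback only when the bee probes and samples the well
        if (pr) {
          reward <- if (classes[k] == "rewarding") 1 else -1
          V[k] <- V[k] + params$learn_rate * (reward - V[k])
          S[k] <- S[k] + params$learn_rate * (reward - S[k])
        }
        V[-k] <- V[-k] * (1 - params$forget_rate)
      }
      cls[i] <- classes[k]
      probed[i] <- as.integer(pr)
      mouth[i] <- as.integer(stats::runif(1) < params$mouthpart_contact_rate)
    }
    out[[ph]] <- data.frame(
      bee_id = bee_id, group = spec$group, phase = ph,
      bout = (seq_len(nv) - 1L) %/% spec$max_visits_per_bout + 1L,
      visit_index = seq_len(nv), flower_class = cls,
      probed = probed, mouthpart_contact = mouth,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate a visit log for one or more simulated foragers
#'
#' Each bee draws flowers uniformly from the balanced array, decides to probe
#' according to its current probing probability and (conditioning training
#' only) updates its learned values by the delta rule. Test-phase visits are
#' unrewarded and trigger no updates, but the log retains the training-phase
#' flower-class labels, which is how test visits are scored. Bout indices
#' advance every `max_visits_per_bout` visits and restart each phase.
#'
#' @param params A [forager_params()].
#' @param spec A [design_spec()].
#' @param n_bees Number of bees to simulate.
#' @param bee_prefix Prefix for generated bee ids.
#' @return A data frame of visit records with columns bee_id, group, phase,
#'   bout, visit_index (1-based within phase), flower_class, probed (0/1),
#'   mouthpart_contact (0/1).
#' @examples
#' log <- generate_visit_log(forager_params(seed = 3),
#'                           design_spec("preference", group = "sucrose"))
#' nrow(log)  # 20 visits
#' @export
generate_visit_log <- function(params, spec, n_bees = 1,
                               bee_prefix = "bee") {
  stopifnot(inherits(params, "forager_params"), inherits(spec, "design_spec"))
  check_count(n_bees, "n_bees", lower = 1)
  logs <- lapply(seq_len(n_bees), function(i) {
    set.seed(derive_seed(params$seed, i))
    simulate_bee_visits(params, spec, sprintf("%s%03d", bee_prefix, i))
  })
  do.call(rbind, c(logs, list(make.row.names = FALSE)))
}

#' Simulate a full conditioning cohort (one tastant, three groups)
#'
#' Convenience wrapper producing the control, tastant-positive and
#' tastant-negative groups of one tastant, with `n_bees` bees each. The
#' control group forages without a usable surface cue (`cue_salience` forced
#' to 0) but shares the scent-mark channel with the conditioned groups.
#'
#' @param tastant One of `"sucrose"`, `"nacl"`, `"quinine"`, `"caffeine"`.
#' @param n_bees Bees per group (default 10).
#' @param params A [forager_params()] used for the conditioned groups.
#' @param seed Master seed; group-level streams are derived from it.
#' @param bee_prefix Optional prefix prepended to generated bee ids (useful
#'   when several cohorts are combined in one table).
#' @return A visit-log data frame covering the three groups, with distinct
#'   bee ids.
#' @export
simulate_conditioning_cohort <- function(tastant = "sucrose", n_bees = 10,
                                         params = forager_params(
                                           learn_rate = 0.2, cue_salience = 1),
                                         seed = params$seed,
                                         bee_prefix = "") {
  groups <- c("control", paste0(tastant, c("_positive", "_negative")))
  logs <- lapply(seq_along(groups), function(g) {
    p <- params
    p$seed <- derive_seed(seed, g * 1000L)
    if (groups[g] == "control") p$cue_salience <- 0
    log <- generate_visit_log(p, design_spec("conditioning", group = groups[g]),
                              n_bees = n_bees,
                              bee_prefix = paste0(bee_prefix, groups[g],
                                                  "_bee"))
    log
  })
  do.call(rbind, c(logs, list(make.row.names = FALSE)))
}
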