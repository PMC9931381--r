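#' Study design for the simulated grip-sincerity cohort
#'
#' Captures the design of the bimanual maximal/submaximal grip study the
#' simulator replicates: 54 healthy subjects (25 males, 29 females; 52
#' right-handed), two sessions, three five-second trials per hand per
#' session, one hand gripping with maximal and the other with submaximal
#' effort in each session, the submaximal hand swapping between sessions.
#' With the defaults this yields 648 trial records, 324 per effort class.
#'
#' @param n_subjects Number of subjects (default 54).
#' @param n_males Number of male subjects (default 25).
#' @param n_right_handed Number of right-handed subjects (default 52).
#' @param sessions Number of sessions/visits (default 2).
#' @param trials_per_hand_per_session Trials per hand per session (default 3).
#' @param age_range Two-element age range in years (default `c(19, 53)`).
#' @param seed Integer seed for all randomness derived from this design.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 54, n_males = 25, n_right_handed = 52,
                         sessions = 2, trials_per_hand_per_session = 3,
                         age_range = c(19, 53), seed = 1L) {
  stopifnot(n_subjects > 0, sessions > 0, trials_per_hand_per_session > 0,
            n_males >= 0, n_right_handed >= 0,
            length(age_range) == 2, age_range[1] <= age_range[2])
  if (n_males > n_subjects) stop("n_males exceeds n_subjects")
  if (n_right_handed > n_subjects) stop("n_right_handed exceeds n_subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_males = as.integer(n_males),
                 n_right_handed = as.integer(n_right_handed),
                 sessions = as.integer(sessions),
                 trials_per_hand_per_session =
                   as.integer(trials_per_hand_per_session),
                 age_range = age_range, seed = as.integer(seed)),
            class = "study_design")
}

#' Effort model: how submaximal effort changes force and load distribution
#'
#' Under submaximal (insincere) effort the total grip force drops to a
#' random fraction of the subject's strength, drawn uniformly from
#' `[force_fraction_low, force_fraction_high]` (defaults 1/2 to 3/4), and
#' the percent load composition shifts by `redistribution_delta` percentage
#' points (then renormalised to 100). The default delta keeps the thumb and
#' index finger relatively preserved and unloads the thenar most, with a
#' mildly negative hypothenar; every sign is configurable because the
#' hypothenar's direction of change is not settled (see the package
#' vignette).
#'
#' @param force_fraction_low,force_fraction_high Bounds of the submaximal
#'   force fraction (defaults 0.5 and 0.75).
#' @param redistribution_delta Named numeric of percentage-point shifts per
#'   area applied under submaximal effort; must sum to 0. Default:
#'   I +2.5, II +1.5, III -0.5, IV -0.5, V -0.5, TH -1.5, HY -1.0.
#' @param delta_jitter_sd Per-trial Gaussian jitter (percentage points) on
#'   each area's delta (default 0.5).
#' @param trial_force_cv Multiplicative log-normal trial-to-trial noise on
#'   total force (sd on the log scale; default 0.05).
#' @return An object of class `effort_model`.
#' @export
effort_model <- function(force_fraction_low = 0.5, force_fraction_high = 0.75,
                         redistribution_delta = c(I = 2.5, II = 1.5,
                                                  III = -0.5, IV = -0.5,
                                                  V = -0.5, TH = -1.5,
                                                  HY = -1.0),
                         delta_jitter_sd = 0.5, trial_force_cv = 0.05) {
  stopifnot(force_fraction_low > 0,
            force_fraction_low <= force_fraction_high,
            force_fraction_high <= 1,
            delta_jitter_sd >= 0, trial_force_cv >= 0)
  stopifnot(length(redistribution_delta) == 7)
  if (is.null(names(redistribution_delta))) {
    names(redistribution_delta) <- hand_areas()
  } else {
    stopifnot(setequal(names(redistribution_delta), hand_areas()))
    redistribution_delta <- redistribution_delta[hand_areas()]
  }
  if (abs(sum(redistribution_delta)) > 1e-6)
    stop("redistribution_delta must sum to 0 (got ",
         format(sum(redistribution_delta)), ")")
  structure(list(force_fraction_low = force_fraction_low,
                 force_fraction_high = force_fraction_high,
                 redistribution_delta = redistribution_delta,
                 delta_jitter_sd = delta_jitter_sd,
                 trial_force_cv = trial_force_cv),
            class = "effort_model")
}

# Dirichlet sampler via normalised gamma draws.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) { # numerically possible only for tiny alphas
    g <- alpha
    s <- sum(g)
  }
  g / s
}

# Default population mean composition (percent per area). A configuration
# value chosen for the simulator, not an empirical estimate.
default_population_mean <- function() {
  c(I = 20, II = 12, III = 16, IV = 13, V = 8, TH = 16, HY = 15)
}

#' Generate a cohort of subject profiles
#'
#' Draws per-subject covariates (age, sex, handedness), grip strength, a
#' subject-specific baseline load composition per hand, and the seeded
#' pseudo-random assignment of which hand performs the submaximal effort in
#' session 1. Sex and handedness counts match the design exactly.
#' Deterministic given `design$seed`.
#'
#' Strength (total cylinder grip load, newtons) is drawn from sex-specific
#' normals truncated below at 100 N; baseline compositions are drawn from a
#' Dirichlet distribution centred on `population_mean`, and each hand's
#' baseline additionally receives independent Gaussian perturbations scaled
#' so the between-hand difference per area has standard deviation
#' `asymmetry_sd` percentage points. All of these are simulator
#' configuration values, not estimates from any dataset.
#'
#' @param design A [study_design()].
#' @param population_mean Named length-7 percent vector; population mean
#'   composition (default [default_population_mean()]).
#' @param subject_concentration Dirichlet concentration for between-subject
#'   composition variation (default 400; larger = more homogeneous cohort).
#' @param asymmetry_sd Between-hand physiological difference scale in
#'   percentage points (default 1, so sincere bimanual differences rarely
#'   exceed 3 points).
#' @param trial_concentration Dirichlet concentration for trial-to-trial
#'   compositional noise (default 1500); `Inf` removes trial noise.
#' @param strength_mean,strength_sd Named vectors (`male`, `female`) of
#'   strength distribution parameters in newtons.
#' @return A `data.frame` with one row per subject: covariates, `strength`,
#'   `asymmetry_sd`, `trial_concentration`, `submax_hand_session1`, and the
#'   per-hand baseline composition columns `bl_left_*` / `bl_right_*`.
#' @export
make_cohort <- function(design,
                        population_mean = default_population_mean(),
                        subject_concentration = 400,
                        asymmetry_sd = 1,
                        trial_concentration = 1500,
                        strength_mean = c(male = 400, female = 280),
                        strength_sd = c(male = 60, female = 50)) {
  stopifnot(inherits(design, "study_design"),
            length(population_mean) == 7,
            abs(sum(population_mean) - 100) < 1e-6,
            subject_concentration > 0, asymmetry_sd >= 0,
            trial_concentration > 0)
  population_mean <- population_mean[hand_areas()]
  n <- design$n_subjects
  set.seed(design$seed)
  sex <- sample(rep(c("male", "female"),
                    c(design$n_males, n - design$n_males)))
  handedness <- sample(rep(c("right", "left"),
                           c(design$n_right_handed,
                             n - design$n_right_handed)))
  age <- sample(seq(design$age_range[1], design$age_range[2]), n,
                replace = TRUE)
  strength <- pmax(100, stats::rnorm(n, strength_mean[sex], strength_sd[sex]))
  # online-randomizer stand-in: coin flip per subject
  submax1 <- sample(c("left", "right"), n, replace = TRUE)
  bl <- matrix(NA_real_, n, 14)
  for (i in seq_len(n)) {
    base <- 100 * rdirichlet1(subject_concentration * population_mean / 100)
    e <- stats::rnorm(14, 0, asymmetry_sd / sqrt(2))
    left <- pmax(0.2, base + e[1:7])
    right <- pmax(0.2, base + e[8:14])
    bl[i, ] <- c(100 * left / sum(left), 100 * right / sum(right))
  }
  colnames(bl) <- c(paste0("bl_left_", hand_areas()),
                    paste0("bl_right_", hand_areas()))
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             age = age, sex = sex, handedness = handedness,
             strength = strength, asymmetry_sd = asymmetry_sd,
             trial_concentration = trial_concentration,
             submax_hand_session1 = submax1, bl,
             stringsAsFactors = FALSE)
}

#' Simulate one grip trial
#'
#' Produces one trial record for one hand of one subject. The total force is
#' `strength * f` with `f = 1` for maximal effort and `f ~ Uniform(low,
#' high)` for submaximal effort, times multiplicative log-normal trial
#' noise. The percent composition is drawn from a Dirichlet distribution
#' centred on the hand's baseline composition, shifted by the effort model's
#' redistribution delta (plus per-trial jitter) when submaximal, with spread
#' set by the subject's `trial_concentration`; an infinite concentration
#' with zero jitter returns the (shifted, renormalised) baseline exactly.
#'
#' @param profile One-row slice of a [make_cohort()] data frame.
#' @param session Session number.
#' @param trial Trial index within the session.
#' @param hand `"left"` or `"right"`.
#' @param effort `"maximal"` or `"submaximal"`.
#' @param model An [effort_model()].
#' @param seed Optional integer seed for this trial's random draws.
#' @return A one-row trials `data.frame` (see [read_trials()] columns) plus
#'   an `effort_fraction` column holding the instructed force fraction
#'   (1 for maximal effort) before trial noise.
#' @export
simulate_trial <- function(profile, session, trial, hand, effort, model,
                           seed = NULL) {
  stopifnot(nrow(profile) == 1L, hand %in% c("left", "right"),
            effort %in% c("maximal", "submaximal"),
            inherits(model, "effort_model"))
  if (!is.null(seed)) set.seed(seed)
  base <- as.numeric(profile[paste0("bl_", hand, "_", hand_areas())])
  names(base) <- hand_areas()
  f <- if (effort == "maximal") 1 else
    stats::runif(1, model$force_fraction_low, model$force_fraction_high)
  force <- profile$strength * f *
    exp(stats::rnorm(1, 0, model$trial_force_cv))
  target <- base
  if (effort == "submaximal") {
    delta <- model$redistribution_delta +
      stats::rnorm(7, 0, model$delta_jitter_sd)
    target <- base + delta
  }
  target <- pmax(0.1, target)
  target <- 100 * target / sum(target)
  conc <- profile$trial_concentration
  pct <- if (is.finite(conc)) 100 * rdirichlet1(conc * target / 100)
         else target
  out <- data.frame(subject_id = profile$subject_id,
                    session = as.integer(session),
                    trial = as.integer(trial), hand = hand, effort = effort,
                    age = profile$age, sex = profile$sex,
                    handedness = profile$handedness, total_force = force,
                    stringsAsFactors = FALSE)
  out[paste0("pct_", hand_areas())] <- as.list(pct)
  # instructed effort fraction before trial noise; 1 for maximal effort.
  # Carried for simulator diagnostics; write_trials() drops it.
  out$effort_fraction <- f
  out
}

#' Simulate the full study
#'
#' Runs the whole design: per subject and session, three maximal trials on
#' one hand and three submaximal trials on the other, with the submaximal
#' hand swapping between sessions. The default design yields 648 records,
#' 324 maximal and 324 submaximal. Each trial draws from its own seed
#' derived from `design$seed` and the record's position in the design, so
#' records are reproducible and independent of generation order.
#'
#' @param design A [study_design()].
#' @param model An [effort_model()] (default [effort_model()]).
#' @param cohort Optional pre-built cohort from [make_cohort()]; defaults to
#'   `make_cohort(design, ...)` via `...`.
#' @param ... Passed to [make_cohort()] when `cohort` is `NULL`.
#' @return A trials `data.frame` (see [read_trials()] columns).
#' @export
#' @examples
#' trials <- simulate_study(study_design(n_subjects = 2, seed = 7))
#' table(trials$effort)
simulate_study <- function(design, model = effort_model(), cohort = NULL,
                           ...) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(cohort)) cohort <- make_cohort(design, ...)
  n_tr <- design$trials_per_hand_per_session
  rows <- vector("list",
                 design$n_subjects * design$sessions * n_tr * 2L)
  k <- 0L
  base_seed <- abs(design$seed) %% 1000003L
  for (i in seq_len(design$n_subjects)) {
    prof <- cohort[i, , drop = FALSE]
    for (s in seq_len(design$sessions)) {
      submax <- prof$submax_hand_session1
      if (s %% 2 == 0) submax <- setdiff(c("left", "right"), submax)
      for (t in seq_len(n_tr)) {
        for (h in c("left", "right")) {
          k <- k + 1L
          eff <- if (h == submax) "submaximal" else "maximal"
          rows[[k]] <- simulate_trial(prof, s, t, h, eff, model,
                                      seed = base_seed * 1297L + k)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
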