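#' Configuration of the two-way choice experiment design
#'
#' Defaults mirror the published protocol: 28 dogs with 10 test trials each
#' (owner's voice from the side the owner hides on), 2 olfaction-control
#' trials (voice and person sides swapped; scoring follows the voice) for
#' the 23 dogs that completed them, 14 unfamiliar control speakers (half
#' male), owner hiding sides and last speakers balanced 5/5 within a dog and
#' pseudorandomized with at most 3 consecutive trials on the same side.
#'
#' @param n_dogs Number of dogs in the test phase.
#' @param n_test_trials Test trials per dog (even).
#' @param n_olfaction_trials Olfaction-control trials per dog.
#' @param n_olfaction_dogs Number of dogs that completed the olfaction phase.
#' @param n_controls Number of unfamiliar control speakers.
#' @param max_run Longest permitted run of the owner on one side.
#' @return List of class \code{"design_config"}.
#' @export
design_config <- function(n_dogs = 28, n_test_trials = 10,
                          n_olfaction_trials = 2, n_olfaction_dogs = 23,
                          n_controls = 14, max_run = 3) {
  stopifnot(
    n_dogs >= 1, n_test_trials >= 2, n_test_trials %% 2 == 0,
    n_olfaction_trials >= 0, n_olfaction_dogs <= n_dogs,
    n_controls >= 2, max_run >= 1
  )
  structure(
    list(
      n_dogs = n_dogs, n_test_trials = n_test_trials,
      n_olfaction_trials = n_olfaction_trials,
      n_olfaction_dogs = n_olfaction_dogs,
      n_controls = n_controls, max_run = max_run
    ),
    class = "design_config"
  )
}

# balanced binary sequence (n/2 of each) with no run longer than max_run
balanced_sequence <- function(n, max_run, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    s <- sample(rep(c(0L, 1L), n / 2))
    if (max(rle(s)$lengths) <= max_run) return(s)
  }
  stop("could not satisfy the side-run constraint; check max_run", call. = FALSE)
}

#' Generate the pseudorandomized trial design
#'
#' Produces one row per trial. Per dog: owner sides and last speakers are
#' balanced over the test trials and the side sequence respects the
#' maximum-run constraint; the control speaker of each trial is drawn
#' without replacement from the control pool; gender match is derived from
#' the owner's and the control's genders. Olfaction-control trials (for the
#' first \code{n_olfaction_dogs} dogs) swap voice and person sides, but all
#' variables follow the voice.
#'
#' @param cfg A \code{\link{design_config}}.
#' @param speakers Optional \code{\link{speaker_profiles}} table supplying
#'   control-speaker ids and genders (its first row is treated as the owner
#'   voice pool); defaults to generic ids with alternating gender.
#' @param seed Integer seed.
#' @return Data frame with columns \code{dog_id}, \code{phase},
#'   \code{trial}, \code{owner_side}, \code{last_speaker},
#'   \code{owner_speaker_id}, \code{control_speaker_id},
#'   \code{owner_gender}, \code{control_gender}, \code{gender_match}.
#' @export
generate_design <- function(cfg = design_config(), speakers = NULL, seed = 1L) {
  if (is.null(speakers)) {
    speakers <- data.frame(
      speaker_id = sprintf("S%02d", seq_len(cfg$n_controls + 1)),
      gender = rep(c("female", "male"), length.out = cfg$n_controls + 1),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(speakers) < cfg$n_controls + 1) {
    stop("speaker table smaller than n_controls + 1", call. = FALSE)
  }
  with_seed(seed, {
    rows <- vector("list", cfg$n_dogs)
    for (d in seq_len(cfg$n_dogs)) {
      # each dog's owner voice is drawn from the speaker pool; the remaining
      # speakers act as that dog's unfamiliar controls
      owner_idx <- 1L + (d - 1L) %% nrow(speakers)
      pool <- setdiff(seq_len(nrow(speakers)), owner_idx)
      sides <- balanced_sequence(cfg$n_test_trials, cfg$max_run)
      last <- sample(rep(c("owner", "control"), cfg$n_test_trials / 2))
      ctrl <- sample(pool, cfg$n_test_trials,
                     replace = cfg$n_test_trials > length(pool))
      test <- data.frame(
        dog_id = sprintf("dog%02d", d),
        phase = "test",
        trial = seq_len(cfg$n_test_trials),
        owner_side = ifelse(sides == 1L, "left", "right"),
        last_speaker = last,
        owner_speaker_id = speakers$speaker_id[owner_idx],
        control_speaker_id = speakers$speaker_id[ctrl],
        owner_gender = speakers$gender[owner_idx],
        control_gender = speakers$gender[ctrl],
        stringsAsFactors = FALSE
      )
      rows[[d]] <- test
      if (d <= cfg$n_olfaction_dogs && cfg$n_olfaction_trials > 0) {
        n_olf <- cfg$n_olfaction_trials
        olf_sides <- if (n_olf %% 2 == 0) {
          sample(rep(c("left", "right"), n_olf / 2))
        } else {
          sample(c("left", "right"), n_olf, replace = TRUE)
        }
        olf_last <- if (n_olf %% 2 == 0) {
          sample(rep(c("owner", "control"), n_olf / 2))
        } else {
          sample(c("owner", "control"), n_olf, replace = TRUE)
        }
        octrl <- sample(pool, n_olf)
        rows[[d]] <- rbind(rows[[d]], data.frame(
          dog_id = sprintf("dog%02d", d),
          phase = "olfaction",
          trial = cfg$n_test_trials + seq_len(n_olf),
          owner_side = olf_sides,
          last_speaker = olf_last,
          owner_speaker_id = speakers$speaker_id[owner_idx],
          control_speaker_id = speakers$speaker_id[octrl],
          owner_gender = speakers$gender[owner_idx],
          control_gender = speakers$gender[octrl],
          stringsAsFactors = FALSE
        ))
      }
    }
    out <- do.call(rbind, rows)
    out$gender_match <- ifelse(out$owner_gender == out$control_gender,
                               "same", "different")
    rownames(out) <- NULL
    out
  })
}

#' Generative effect structure for behavioral outcomes
#'
#' Defaults are the published fixed-effect estimates: choosing success is
#' Bernoulli with log-odds \code{1.601} (intercept) \code{+ 0.688} when the
#' owner hides left \code{+ 0.630} when the owner speaks last, plus a dog
#' random intercept; looking time (percent of the stimulus window toward the
#' owner's side) is Gaussian around an intercept of 60 with
#' \code{-1.107} for different-gender speaker pairs, slopes \code{5.613}
#' (f0-mean distance) and \code{4.010} (jitter distance) per SD of distance,
#' and \code{-8.956} for the f0-distance by gender-match interaction (so the
#' different-gender f0 slope is \code{5.613 - 8.956 = -3.343}). Random-effect
#' and residual SDs are not reported in the source tables; the defaults
#' (dog SD 1.0 on the logit scale; looking-time dog SD 5 and residual SD 25
#' percentage points) give choice rates and dispersion resembling the
#' published summaries.
#'
#' @param choice_intercept,side_left,last_owner Log-odds terms of the choice
#'   model.
#' @param sigma_dog SD of the dog random intercept (logit scale).
#' @param lt_intercept Looking-time intercept, percent.
#' @param gender_match Looking-time shift for different-gender pairs.
#' @param f0_dist,ppj_dist Looking-time slopes per SD of z-scored distance.
#' @param f0_gender Interaction: extra f0-distance slope for
#'   different-gender pairs.
#' @param sigma_dog_lt SD of the dog random intercept for looking time.
#' @param sigma_resid Residual SD of looking time, percentage points.
#' @return List of class \code{"effect_config"}.
#' @export
effect_config <- function(choice_intercept = 1.601,
                          side_left = 0.688,
                          last_owner = 0.630,
                          sigma_dog = 1.0,
                          lt_intercept = 60,
                          gender_match = -1.107,
                          f0_dist = 5.613,
                          ppj_dist = 4.010,
                          f0_gender = -8.956,
                          sigma_dog_lt = 5,
                          sigma_resid = 25) {
  structure(
    list(
      choice_intercept = choice_intercept, side_left = side_left,
      last_owner = last_owner, sigma_dog = sigma_dog,
      lt_intercept = lt_intercept, gender_match = gender_match,
      f0_dist = f0_dist, ppj_dist = ppj_dist, f0_gender = f0_gender,
      sigma_dog_lt = sigma_dog_lt, sigma_resid = sigma_resid
    ),
    class = "effect_config"
  )
}

#' Simulate behavioral outcomes for a trial design
#'
#' Adds \code{choice} (1 = owner's voice chosen), \code{looking_time}
#' (percent, truncated to [0, 100]) and \code{latency_s} to the design
#' table. The choice model uses the logistic intercept + side + last-speaker
#' structure with a dog random intercept; the looking-time model uses the
#' distance covariates and the f0-by-gender interaction. Latency is weakly
#' negatively coupled to looking time but carries no structural effect.
#'
#' @param design Trial table from \code{\link{generate_design}}, already
#'   carrying z-scored distance columns \code{zdist_f0_mean} and
#'   \code{zdist_ppj} (see \code{\link{zscore_distances}}; missing columns
#'   are treated as zero with a message).
#' @param eff An \code{\link{effect_config}}.
#' @param seed Integer seed.
#' @return The trial table with outcome columns appended.
#' @export
simulate_outcomes <- function(design, eff = effect_config(), seed = 1L) {
  zf0 <- design$zdist_f0_mean
  zppj <- design$zdist_ppj
  if (is.null(zf0)) {
    message("no zdist_f0_mean column; distance effects enter as zero")
    zf0 <- numeric(nrow(design))
  }
  if (is.null(zppj)) zppj <- numeric(nrow(design))
  gm_diff <- as.numeric(design$gender_match == "different")
  with_seed(seed, {
    dogs <- unique(design$dog_id)
    u_choice <- stats::setNames(stats::rnorm(length(dogs), 0, eff$sigma_dog), dogs)
    u_lt <- stats::setNames(stats::rnorm(length(dogs), 0, eff$sigma_dog_lt), dogs)
    eta <- eff$choice_intercept +
      eff$side_left * (design$owner_side == "left") +
      eff$last_owner * (design$last_speaker == "owner") +
      u_choice[design$dog_id]
    design$choice <- stats::rbinom(nrow(design), 1, stats::plogis(eta))
    mu <- eff$lt_intercept +
      eff$gender_match * gm_diff +
      eff$f0_dist * zf0 +
      eff$ppj_dist * zppj +
      eff$f0_gender * zf0 * gm_diff +
      u_lt[design$dog_id]
    lt <- mu + stats::rnorm(nrow(design), 0, eff$sigma_resid)
    design$looking_time <- pmin(pmax(lt, 0), 100)
    design$latency_s <- pmax(
      0.5, 8 - 0.02 * design$looking_time + stats::rnorm(nrow(design), 0, 2)
    )
  })
  design
}

#' Attach per-trial acoustic distances from a feature table
#'
#' For each trial, draws one sentence of the owner and one of the control
#' speaker from the per-sentence feature table and records the absolute
#' feature difference on every marker, then z-scores each distance column
#' across the trial table.
#'
#' @param design Trial table from \code{\link{generate_design}}.
#' @param features Per-sentence feature table (columns \code{speaker_id} +
#'   marker columns).
#' @param markers Marker names.
#' @param seed Integer seed for the sentence draws.
#' @return The trial table with \code{dist_*} and \code{zdist_*} columns.
#'   Trials with a missing marker value are flagged in
#'   \code{distance_missing}.
#' @export
attach_distances <- function(design, features, markers, seed = 1L) {
  with_seed(seed, {
    n <- nrow(design)
    for (mk in markers) design[[paste0("dist_", mk)]] <- NA_real_
    design$distance_missing <- FALSE
    by_spk <- split(seq_len(nrow(features)), features$speaker_id)
    for (i in seq_len(n)) {
      oi <- by_spk[[design$owner_speaker_id[i]]]
      ci <- by_spk[[design$control_speaker_id[i]]]
      if (is.null(oi) || is.null(ci)) {
        design$distance_missing[i] <- TRUE
        next
      }
      orow <- features[sample(oi, 1), markers, drop = FALSE]
      crow <- features[sample(ci, 1), markers, drop = FALSE]
      dv <- abs(unlist(orow) - unlist(crow))
      if (any(is.na(dv))) design$distance_missing[i] <- TRUE
      for (mk in markers) design[[paste0("dist_", mk)]][i] <- dv[[mk]]
    }
  })
  zscore_distances(design, markers)
}
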