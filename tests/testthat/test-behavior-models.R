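sim_choice_data <- function(n_dogs, n_trials, intercept, sigma_dog, seed) {
  set.seed(seed)
  u <- rnorm(n_dogs, 0, sigma_dog)
  data.frame(
    dog_id = rep(sprintf("d%02d", seq_len(n_dogs)), each = n_trials),
    choice = rbinom(n_dogs * n_trials, 1,
                    plogis(intercept + rep(u, each = n_trials)))
  )
}

test_that("odds ratios are exp(estimate) and attach to binomial fits", {
  expect_equal(odds_ratio(0), 1)
  d <- sim_choice_data(20, 10, 1.2, 0.8, seed = 1)
  fit <- fit_mixed(model_spec("choice", random = "dog_id",
                              family = "binomial"), d)
  expect_equal(fit$coefficients$odds_ratio,
               exp(fit$coefficients$estimate), tolerance = 1e-12)
})

test_that("a gaussian fit on noiseless linear data is exact", {
  d <- data.frame(x = 1:30, g = rep(letters[1:3], 10))
  d$y <- 2 + 0.5 * d$x
  fit <- suppressWarnings(
    fit_mixed(model_spec("y", fixed = "x", random = character(0),
                         family = "gaussian"), d))
  expect_equal(fit$coefficients$estimate, c(2, 0.5), tolerance = 1e-8)
})

test_that("the intercept-only binomial fit matches the closed-form logit", {
  d <- sim_choice_data(28, 10, 1.6, 0, seed = 2)
  fit <- fit_mixed(model_spec("choice", random = "dog_id",
                              family = "binomial"), d)
  expect_equal(fit$coefficients$estimate[1], qlogis(mean(d$choice)),
               tolerance = 1e-6)
  expect_lt(fit$ranef_var[["dog_id"]], 1e-4)
})

test_that("near-separation keeps the intercept finite and positive", {
  d <- data.frame(
    dog_id = rep(sprintf("d%d", 1:10), each = 10),
    choice = rep(c(0L, rep(1L, 9)), 10)
  )
  fit <- fit_mixed(model_spec("choice", random = "dog_id",
                              family = "binomial"), d)
  est <- fit$coefficients$estimate[1]
  expect_true(is.finite(est) && est > 0)
})

test_that("random factors with one level are dropped with a message", {
  d <- sim_choice_data(15, 8, 1, 0.5, seed = 3)
  d$speaker <- "only_one"
  expect_message(
    fit <- fit_mixed(model_spec("choice", random = c("dog_id", "speaker"),
                                family = "binomial"), d),
    "speaker")
  expect_true(inherits(fit$fit, "glmerMod"))
})

test_that("mixed estimates are invariant to row order and dog relabeling", {
  d <- sim_choice_data(20, 10, 1.2, 0.8, seed = 4)
  fit1 <- fit_mixed(model_spec("choice", random = "dog_id",
                               family = "binomial"), d)
  d2 <- d[sample(nrow(d)), ]
  d2$dog_id <- paste0("zz_", d2$dog_id)
  fit2 <- fit_mixed(model_spec("choice", random = "dog_id",
                               family = "binomial"), d2)
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit1$ranef_var[["dog_id"]], fit2$ranef_var[["dog_id"]],
               tolerance = 1e-6)
})

test_that("backwards elimination keeps strong terms and empties null sets", {
  set.seed(5)
  n <- 400
  d <- data.frame(
    dog_id = rep(sprintf("d%d", 1:20), each = 20),
    strong = rnorm(n), null1 = rnorm(n), null2 = rnorm(n)
  )
  d$y <- 3 * d$strong + rnorm(n)
  fit <- backwards_eliminate(
    model_spec("y", fixed = c("strong", "null1", "null2"),
               random = "dog_id", family = "gaussian"), d)
  kept <- fit$coefficients$term
  expect_true("strong" %in% kept)
  log <- attr(fit, "elimination")
  expect_true(all(log$dropped %in% c("null1", "null2")))

  empty <- backwards_eliminate(
    model_spec("y", fixed = character(0), random = "dog_id",
               family = "gaussian"), d)
  expect_identical(empty$coefficients$term, "(Intercept)")
})

test_that("interactions are eliminated before their main effects", {
  set.seed(6)
  n <- 300
  d <- data.frame(dog_id = rep(sprintf("d%d", 1:15), each = 20),
                  a = rnorm(n), b = rnorm(n))
  d$y <- 2 * d$a + rnorm(n)  # b and a:b are null
  fit <- backwards_eliminate(
    model_spec("y", fixed = c("a", "b", "a:b"), random = "dog_id",
               family = "gaussian"), d)
  log <- attr(fit, "elimination")
  if ("b" %in% log$dropped && "a:b" %in% log$dropped) {
    expect_lt(which(log$dropped == "a:b"), which(log$dropped == "b"))
  }
  expect_true("a" %in% fit$coefficients$term)
})

test_that("the wilcoxon phase test matches its closed forms and reference", {
  z0 <- wilcoxon_phase_test(rep(0.8, 23), rep(0.8, 23))
  expect_identical(z0$Z, 0)
  expect_identical(z0$p, 1)

  set.seed(7)
  x <- runif(23, 0.4, 0.7)
  shifted <- wilcoxon_phase_test(x + 0.3, x)
  expect_lt(shifted$p, 0.01)

  d <- c(0.1, -0.1, 0.2, -0.2, 0.3, -0.3)
  anti <- wilcoxon_phase_test(d, numeric(6))
  expect_equal(anti$Z, 0, tolerance = 1e-12)

  # tie-corrected normal approximation agrees with the reference
  set.seed(8)
  a <- round(runif(15), 1); b <- round(runif(15), 1)
  ours <- wilcoxon_phase_test(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  expect_error(wilcoxon_phase_test(numeric(0), numeric(0)), "length")
})

test_that("simple slopes recombine coefficients of the looking-time model", {
  set.seed(9)
  n_dogs <- 40
  d <- expand.grid(dog_id = sprintf("d%d", 1:n_dogs), trial = 1:10)
  d$gender_match <- sample(c("same", "different"), nrow(d), replace = TRUE)
  for (mk in c("f0_mean", "f0_sd", "dF", "HNR", "ent", "ppj")) {
    d[[paste0("zdist_", mk)]] <- rnorm(nrow(d))
  }
  gm <- as.numeric(d$gender_match == "different")
  d$looking_time <- 55 + 6 * d$zdist_f0_mean - 9 * d$zdist_f0_mean * gm +
    4 * d$zdist_ppj + rnorm(nrow(d), 0, 3)
  res <- suppressMessages(looking_time_model(d))
  expect_false(is.null(res$simple_slopes))
  same <- res$simple_slopes[res$simple_slopes$gender == "same", ]
  diff_ <- res$simple_slopes[res$simple_slopes$gender == "different", ]
  expect_equal(same$estimate, 6, tolerance = 0.15)
  expect_equal(diff_$estimate, -3, tolerance = 0.3)
  expect_true(all(res$simple_slopes$df > 0))
  # null distance terms were eliminated
  kept <- res$fit$coefficients$term
  expect_false(any(grepl("zdist_dF|zdist_HNR", kept)))
})

test_that("speaker voice comparison runs LR tests and degrades gracefully", {
  set.seed(10)
  n_spk <- 12
  spk <- data.frame(
    speaker_id = sprintf("S%02d", 1:n_spk),
    speaker_type = rep(c("owner_included", "owner_excluded", "control"), 4),
    gender = rep(c("female", "male"), 6),
    f0_base = c(rnorm(6, 200, 15), rnorm(6, 120, 15))[order(rep(1:2, 6))]
  )
  rows <- do.call(rbind, lapply(1:n_spk, function(i) {
    data.frame(speaker_id = spk$speaker_id[i],
               speaker_type = spk$speaker_type[i],
               gender = spk$gender[i],
               f0_mean = rnorm(6, spk$f0_base[i], 4),
               ppj = exp(rnorm(6, log(0.02), 0.2)))
  }))
  res <- speaker_voice_comparison(rows)
  expect_named(res, c("f0_mean", "ppj"))
  expect_true(all(res$f0_mean$p >= 0 & res$f0_mean$p <= 1))
  expect_equal(res$ppj$effect, c("speaker_type", "speaker_type:gender"))

  single <- rows[rows$gender == "female", ]
  expect_warning(res2 <- speaker_voice_comparison(single), "gender")
  expect_equal(nrow(res2$f0_mean), 1)
  expect_error(speaker_voice_comparison(rows[rows$speaker_type == "control", ]),
               "speaker types")
})

test_that("a shifted speaker type is detected by the LR test", {
  set.seed(11)
  n_spk <- 18
  types <- rep(c("owner_included", "owner_excluded", "control"), each = 6)
  base <- rnorm(n_spk, 180, 10) + ifelse(types == "control", 30, 0)
  rows <- do.call(rbind, lapply(1:n_spk, function(i) {
    data.frame(speaker_id = sprintf("S%02d", i), speaker_type = types[i],
               gender = rep(c("female", "male"), 9)[i],
               f0_mean = rnorm(8, base[i], 4),
               ppj = exp(rnorm(8, log(0.02), 0.2)))
  }))
  res <- suppressWarnings(speaker_voice_comparison(rows))  # optimizer chatter
  expect_lt(res$f0_mean$p[res$f0_mean$effect == "speaker_type"], 0.05)
})
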