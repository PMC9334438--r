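#!/usr/bin/env Rscript
# Stage 4: the behavioral mixed-model analyses. Intercept-only choice models
# per phase, the design-parameter model with backwards elimination, the
# looking-time model with acoustic-distance covariates and per-gender simple
# slopes, and the Wilcoxon phase comparison. Reads results/trials.csv;
# writes one CSV per model table.

suppressMessages(library(voicemarkers))

trials <- read.csv("results/trials.csv", stringsAsFactors = FALSE)
test <- trials[trials$phase == "test", ]
olf <- trials[trials$phase == "olfaction", ]

save_tab <- function(tab, file) {
  write.csv(tab, file.path("results", file), row.names = FALSE)
  message("wrote results/", file)
}

message("-- intercept-only choice models (per phase) --")
it <- fit_mixed(model_spec("choice", random = "dog_id", family = "binomial"),
                test)
print(it)
save_tab(it$coefficients, "intercept_test.csv")
io <- tryCatch(
  fit_mixed(model_spec("choice", random = "dog_id", family = "binomial"), olf),
  error = function(e) { message("olfaction model: ", conditionMessage(e)); NULL })
if (!is.null(io)) save_tab(io$coefficients, "intercept_olfaction.csv")

message("-- design-parameter effects with backwards elimination --")
test$owner_left <- as.numeric(test$owner_side == "left")
test$owner_last <- as.numeric(test$last_speaker == "owner")
test$gender_diff <- as.numeric(test$gender_match == "different")
de <- backwards_eliminate(
  model_spec("choice",
             fixed = c("trial", "owner_last", "owner_left", "gender_diff"),
             random = c("dog_id", "control_speaker_id"), family = "binomial"),
  test)
print(de)
print(attr(de, "elimination"))
save_tab(de$coefficients, "design_effects.csv")

message("-- looking time vs acoustic distances --")
lt <- looking_time_model(test)
print(lt$fit)
if (!is.null(lt$simple_slopes)) {
  message("per-gender simple slopes of f0-mean distance:")
  print(lt$simple_slopes)
  save_tab(lt$simple_slopes, "simple_slopes.csv")
}
save_tab(lt$fit$coefficients, "looking_time.csv")

message("-- phase comparison (Wilcoxon signed-rank) --")
per_dog <- merge(aggregate(choice ~ dog_id, test, mean),
                 aggregate(choice ~ dog_id, olf, mean),
                 by = "dog_id", suffixes = c("_test", "_olf"))
wz <- wilcoxon_phase_test(per_dog$choice_test, per_dog$choice_olf)
message(sprintf("Z = %.3f, p = %.3f (n = %d non-tied pairs)",
                wz$Z, wz$p, wz$n_used))
save_tab(data.frame(Z = wz$Z, p = wz$p, n_used = wz$n_used),
         "phase_wilcoxon.csv")
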