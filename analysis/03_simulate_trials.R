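#!/usr/bin/env Rscript
# Stage 3: simulate the two-way choice experiment. Generates the
# pseudorandomized design (28 dogs x 10 test trials, 23 dogs x 2 olfaction
# trials; sides and last speakers balanced, side runs capped at 3), attaches
# per-trial acoustic distances on the six published markers, and draws
# choices and looking times from the published effect structure. Writes
# results/trials.csv.

suppressMessages(library(voicemarkers))

profiles <- read.csv("results/speaker_profiles.csv", stringsAsFactors = FALSE)
features <- read.csv("results/features.csv", stringsAsFactors = FALSE)

design <- generate_design(design_config(), speakers = profiles, seed = 2L)
message(sprintf("design: %d trials for %d dogs", nrow(design),
                length(unique(design$dog_id))))

markers <- c("f0_mean", "f0_sd", "dF", "HNR", "ent", "ppj")
trials <- attach_distances(design, features, markers, seed = 3L)
message(sprintf("%d trials flagged for missing distances",
                sum(trials$distance_missing)))

trials <- simulate_outcomes(trials, effect_config(), seed = 4L)
test <- trials[trials$phase == "test", ]
olf <- trials[trials$phase == "olfaction", ]
message(sprintf("simulated choice rate: %.3f (test), %.3f (olfaction control)",
                mean(test$choice), mean(olf$choice)))
message(sprintf("mean looking time toward owner: %.1f%%",
                mean(test$looking_time)))

write.csv(trials, "results/trials.csv", row.names = FALSE)
message("wrote results/trials.csv")
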