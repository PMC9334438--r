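#!/usr/bin/env Rscript
# Stage 2: collinearity filtering, linear discriminant analysis of speaker
# identity, leave-one-out discrimination success, and loading-based marker
# selection. Reads results/features.csv; writes results/lda_report.json and
# results/loadings.csv.

suppressMessages(library(voicemarkers))

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)

retained <- collinearity_filter(features, r_max = 0.8)
message(sprintf("collinearity filter (|r| >= 0.8): %d of 25 features retained",
                length(retained)))
message("dropped: ", paste(attr(retained, "dropped"), collapse = ", "))

lda <- fit_lda(features, retained)
resub <- classification_success(lda, features, "resubstitution")
loo <- classification_success(lda, features, "loo")
message(sprintf("discrimination success: %.1f%% resubstitution, %.1f%% leave-one-out",
                resub, loo))

markers <- lda$selected_markers
message("markers with |loading| > 1.3: ",
        if (length(markers)) paste(markers, collapse = ", ") else "(none)")

write.csv(data.frame(feature = rownames(lda$loadings),
                     round(lda$loadings, 4)),
          "results/loadings.csv", row.names = FALSE)
jsonlite::write_json(
  list(retained_features = retained,
       classification = list(resubstitution = resub, loo = loo),
       selection_threshold = lda$selection_threshold,
       selected_markers = markers),
  "results/lda_report.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/loadings.csv, results/lda_report.json")
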