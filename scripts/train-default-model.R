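#!/usr/bin/env Rscript
# Regenerates the packaged default risk model (inst/extdata/model-default.json)
# from the synthetic generator. Run from the repository root.
library(sraholter)

ts <- make_training_set(n_per_class = 100, seed = 42, snip_minutes = 60)
model <- train_risk_model(ts$features, ts$labels, seed = 42)
save_model(model, file.path("inst", "extdata", "model-default.json"))
cat("wrote inst/extdata/model-default.json\n")
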