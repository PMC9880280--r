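#!/usr/bin/env Rscript
# Fits the default RS and FS transfer functions shipped under inst/extdata/
# (single-neuron AdEx simulations at the default parameters; see ?fit_tf).
# Rerun from the repository root after changing neuron parameters:
#   Rscript scripts/fit_default_tf.R
library(adexbrain)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

t0 <- Sys.time()
tf_fs <- fit_tf(population = "FS", seed = 202)
message(sprintf("FS fit: operating-region RMS %.3f Hz (%.0f s)",
                tf_fs$fit$rms_hz, as.numeric(Sys.time() - t0, units = "secs")))
t0 <- Sys.time()
tf_rs <- fit_tf(population = "RS", seed = 201)
message(sprintf("RS fit: operating-region RMS %.3f Hz (%.0f s)",
                tf_rs$fit$rms_hz, as.numeric(Sys.time() - t0, units = "secs")))

write_tf_json(tf_rs, "inst/extdata/tf_rs_default.json")
write_tf_json(tf_fs, "inst/extdata/tf_fs_default.json")
message("wrote inst/extdata/tf_{rs,fs}_default.json")
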