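#!/usr/bin/env Rscript
# Train the Auto-Contractive Map on the encoded matrix. Online updates in
# dataset order make the fit bit-reproducible; the epoch trace of the mean
# absolute output signal documents the contraction.

suppressPackageStartupMessages(library(autocmap))

em <- read_encoded("results/encoded.csv")
cfg <- autocm_config() # C = N, alpha 0.1, tol 1e-6, up to 5000 epochs
fit <- autocm_train(em, cfg)
write_autocm(fit, "results/model")

cat(sprintf("trained %d-node Auto-CM (C = %.0f): %s after %d epochs\n",
            length(fit$v), fit$C,
            if (fit$converged) "converged" else "stopped", fit$epochs_run))
cat(sprintf("epoch mean |output|: start %.3g, peak %.3g (epoch %d), final %.3g\n",
            fit$trace[1], max(fit$trace), which.max(fit$trace),
            fit$trace[length(fit$trace)]))
cat(sprintf("hidden weights v: %.2f-%.2f of C\n",
            min(fit$v) / fit$C, max(fit$v) / fit$C))
cat("wrote results/model/ (model.yml, v.csv, w.csv)\n")
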