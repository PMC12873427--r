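#!/usr/bin/env Rscript
# HDX-MS pH normalization: intrinsic-rate correction factors across the
# experimental pH range, matched time points against the 20 s ... 63,000 s
# grid, back-exchange correction, and matched-exposure differential uptake
# separating protein dynamics from exchange chemistry.

suppressMessages(library(clcdyn))
dir.create("results", showWarnings = FALSE)

model <- intrinsic_rate_model()
pH_grid <- c(3.0, 3.5, 4.0, 4.5, 6.5)
tp <- c(20, 63, 200, 633, 2000, 6325, 20000, 63000)

fac <- vapply(pH_grid, function(p)
  as.numeric(correction_factor(model, 6.5, p)), numeric(1))
approx_flag <- vapply(pH_grid, function(p)
  attr(correction_factor(model, 6.5, p), "approximate"), logical(1))
cf <- data.frame(pH = pH_grid, factor_vs_pH6.5 = fac,
                 matched_time_for_20s_s = 20 * fac,
                 approximate = approx_flag)
write.table(cf, "results/hdx_correction_factors.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("correction factors vs pH 6.5 (flagged approximate below pH 3.5):\n")
print(cf, row.names = FALSE)

# two synthetic peptides: one with pH-independent protection (pure
# chemistry) and one whose protection drops 10x at low pH (a
# conformational change)
stable <- make_hdx_curves("stable", list(1000), c(6.5, 4.5),
                          timepoints = tp, noise_sd = 0.02, seed = 61,
                          model = model)
dyn_hi <- make_hdx_curves("dynamic", list(1000), 6.5, timepoints = tp,
                          noise_sd = 0.02, seed = 62, model = model)
dyn_lo <- make_hdx_curves("dynamic", list(100), 4.5, timepoints = tp,
                          noise_sd = 0.02, seed = 63, model = model)

d_stable <- differential_uptake(stable$curves[["stable 6.5"]],
                                stable$curves[["stable 4.5"]], model)
d_dyn <- differential_uptake(dyn_hi$curves[["dynamic 6.5"]],
                             dyn_lo$curves[["dynamic 4.5"]], model)
diff_tab <- rbind(cbind(peptide = "stable", d_stable),
                  cbind(peptide = "dynamic", d_dyn))
write.table(diff_tab, "results/hdx_differential.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("\nmatched-exposure differential (pH 4.5 - 6.5):\n"))
cat(sprintf("  stable peptide (chemistry only): mean %.3f Da\n",
            mean(d_stable$difference)))
cat(sprintf("  dynamic peptide (10x less protected at low pH): mean %+.3f Da\n",
            mean(d_dyn$difference)))

# back-exchange correction and protection-factor recovery
fd <- stable$fd_controls[["stable"]]
# measurement noise can nudge a late timepoint past the FD plateau; the
# correction warns about it by contract, which is expected here
corr <- suppressWarnings(back_exchange_correct(stable$curves[["stable 6.5"]],
                                               fd))
fit <- fit_protection_factor(stable$curves[["stable 6.5"]], model,
                             fd_efficiency = 0.85)
cat(sprintf("\nFD control %.2f Da; recovered protection factor log10 P = %.2f (planted 3.00)\n",
            fd$fd_level, fit$log10_P))
cat("Wrote results/hdx_correction_factors.tsv, results/hdx_differential.tsv\n")
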