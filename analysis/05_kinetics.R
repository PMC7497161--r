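#!/usr/bin/env Rscript
# FRET kinetics: catalytic efficiencies from the fitted Michaelis-Menten
# parameters, the mutant/unmutated gains, a synthetic assay round trip
# (generate -> calibrate -> slopes -> fit), and the free-energy-to-rate
# conversion.

suppressPackageStartupMessages(library(caspkit))
dir.create("results", showWarnings = FALSE)

ref <- mm_reference_parameters()
ref$eff_recomputed <- vapply(seq_len(nrow(ref)), function(i) {
  catalytic_constants(kinetics_fit(KM = ref$KM_uM[i],
                                   kcat = ref$kcat[i]))[["efficiency"]]
}, numeric(1))
cat("catalytic efficiencies recomputed from (KM, kcat) [1/(M s)]:\n")
print(data.frame(ref[, c("p1prime", "enzyme")],
                 published = ref$efficiency,
                 recomputed = signif(ref$eff_recomputed, 3)),
      row.names = FALSE)
cat("(cells that differ in the last digit derive from unrounded fits)\n\n")

gain <- sapply(split(ref, ref$p1prime), function(d) {
  d$eff_recomputed[d$enzyme == "D323T_H226A"] /
    d$eff_recomputed[d$enzyme == "unmutated"]
})
cat("double-mutant efficiency gain per P1' amino acid:\n")
print(round(gain, 1))
write.table(data.frame(p1prime = names(gain), gain = round(gain, 2)),
            "results/efficiency_gains.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# synthetic assay round trip at realistic noise
cal <- fret_calibration(slope = 120, intercept = 40)
truth <- list(KM = 89, Vmax = 7.1e-3)
curves <- gen_progress_curves(truth$KM, truth$Vmax,
                              S_list = rep(c(200, 100, 50, 20, 10), 3),
                              calibration = cal, noise_sd = 0.5,
                              duration = 180, seed = 20260924)
rates <- data.frame(
  S = vapply(curves, `[[`, numeric(1), "substrate_conc"),
  v = vapply(curves, initial_slope, numeric(1), calibration = cal,
             window = 180))
fit <- fit_mm(rates, enzyme_conc = 1)
cat("\nsynthetic FRET round trip (truth KM 89 uM, Vmax 7.1e-3 uM/s):\n")
print(fit)

# free energy -> rate factor
cat(sprintf("\nDDG of 7 kJ/mol corresponds to a factor of %.1f in kcat/KM\n",
            ddg_to_rate_factor(7)))
cat(sprintf("observed Ile efficiency gain: %.1f-fold\n", gain[["Ile"]]))
cat("the gap reflects that the tetrahedral intermediate is a proxy, not\n")
cat("the kinetically relevant transition state.\n")
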