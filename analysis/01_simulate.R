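#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-experiment urine-stability study.
#
# Emulates the study design: Exp. 1 stores pooled urine at room
# temperature (RT) and 4 degrees C (C4) over 0-72 h on a dense early
# grid; Exp. 2 adds a boric-acid preservative arm (Pres) on a 12-h grid
# with delayed bacterial growth. Triplicates throughout, a pooled-urine
# QC injection every 10 study injections, leading blanks, two ionisation
# modes, planted injection-order drift, and 12 bacteria-affected plus 7
# chemically unstable metabolites at a 3-fold 72-h effect.

library(urostab)

out <- "results/01_simulated"
cfg <- sim_config(seed = 20141223)
sim <- simulate_study(cfg)
write_study(sim, out)

message("blocks written: ", paste(names(sim$tables), collapse = ", "))
for (key in names(sim$tables)) {
  t <- sim$tables[[key]]
  message(sprintf("  %s: %d features x %d injections (%d study, %d QC, %d blank)",
                  key, nrow(t$intensities), ncol(t$intensities),
                  sum(is_study(t)), sum(is_qc(t)), sum(is_blank(t))))
}
tr <- table(sim$truth$features$class)
message("planted classes per mode: ",
        paste(names(tr), tr / length(cfg$ion_modes), collapse = ", "))
message("turbidity curves: ", nrow(sim$turbidity), " OD620 readings")
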