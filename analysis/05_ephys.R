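#!/usr/bin/env Rscript
# Single-channel electrophysiology companion to the imaging: a two-state
# gating model at the cAMP-state open probability (0.25), three channels
# in the bilayer at 4 pA, idealized by half-amplitude thresholds; then the
# cGMP-state regime as a 1000-fold opening-rate reduction.

suppressPackageStartupMessages(library(hsafm))
dir.create("results", showWarnings = FALSE)

gm3 <- gating_model(n_channels = 3L)
tr3 <- simulate_trace(gm3, 100, seed = 51L)
id3 <- idealize(tr3, gm3$amplitude, gm3$n_channels)
cc <- count_channels(tr3, gm3$amplitude)
cat(sprintf("3-channel bilayer, 100 s: Po = %.3f (stationary %.3f), %d channels seen (P_obs %.2f)\n",
            estimate_po(id3), stationary_po(gm3), cc$n_channels,
            cc$p_all_open_observed))
write.csv(id3$events, "results/ephys_events_camp.csv", row.names = FALSE)

# cGMP regime: k_open / 1000 -> Po ~ 3e-4; longer recording for the rare
# openings
gmg <- gating_model(k_open = 0.015, k_close = 45, sample_rate = 5000)
trg <- simulate_trace(gmg, 3000, seed = 52L)
pog <- estimate_po(idealize(trg, gmg$amplitude, gmg$n_channels))
cat(sprintf("cGMP regime, 3000 s: Po = %.2e (stationary %.2e), fold change %.0f\n",
            pog, stationary_po(gmg), estimate_po(id3) / pog))

po_tab <- data.frame(condition = c("cAMP (3 ch)", "cGMP regime (1 ch)"),
                     po = c(estimate_po(id3), pog))
write.csv(po_tab, "results/ephys_po.csv", row.names = FALSE)
cat("\nThe ~1000-fold Po drop with intact unitary amplitude mirrors the\n",
    "imaging: the same molecules repack and close when cGMP displaces cAMP.\n")
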