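#!/usr/bin/env Rscript
# Kinetics of the ligand-induced transition. Two levels:
#  (a) image level — register the simulated transition movie, classify the
#      per-molecule states frame by frame, and compare against the
#      generator's ground-truth trajectory;
#  (b) model level — simulate the border-nucleated domino model at its
#      calibrated default (t50 ~ 150 s on a 20x20 patch), extract t50 and
#      rise time, and estimate the hazard as a function of the number of
#      already-transitioned neighbours. Requires 01_simulate_crystals.R.

suppressPackageStartupMessages(library(hsafm))
dir.create("results", showWarnings = FALSE)

# -- (a) state recovery from images
mv <- read_movie("results/movies/transition.tif")
sites <- read.csv("results/movies/transition_sites.csv")
truth_states <- read.csv("results/movies/transition_states.csv")
fl <- flatten_movie(mv)
reg <- register_movie(fl, estimate_drift(fl))
st <- classify_states(reg, sites)
truth <- matrix(truth_states$state[order(truth_states$site_id, truth_states$frame)],
                nrow = n_frames(mv))
resolved <- st != "unresolved"
agree <- mean((st == truth)[resolved])
cat(sprintf("frame-site state recovery: %.1f%% (on %.0f%% resolved)\n",
            100 * agree, 100 * mean(resolved)))

curve_img <- fraction_transitioned(st, target = "resting", times_s = mv$timestamps)
write.csv(curve_img, "results/transition_curve_imaged.csv", row.names = FALSE)

# -- (b) the calibrated domino model
g <- grid_graph(20L)
traj <- simulate_domino(sthk_domino_model(), g, seed = 21L)
frames <- seq(0, max(traj$times) + 1, by = 1)
curve <- fraction_transitioned(traj, times_s = frames)
tf <- fit_transition_time(curve)
write.csv(curve, "results/transition_curve_model.csv", row.names = FALSE)
cat(sprintf("domino default on 20x20 patch: t50 = %.0f s, 10-90%% rise = %.0f s\n",
            tf$t50, tf$rise))
first <- order(traj$times)[1:10]
cat(sprintf("first 10 transitions at border sites: %d/10\n", sum(g$border[first])))

nr <- neighbor_rate_analysis(traj)
write.csv(nr, "results/neighbor_hazards.csv", row.names = FALSE)
cat("hazard by transitioned-neighbour count (1/s):\n")
print(nr, row.names = FALSE, digits = 3)
cat("\nHazards climbing ~3x per transitioned neighbour reproduce the\n",
    "domino picture: border molecules with fewer lattice contacts start\n",
    "the wave, and each completed neighbour lowers the barrier further.\n")
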