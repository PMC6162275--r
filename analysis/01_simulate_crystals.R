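#!/usr/bin/env Rscript
# Simulate the two crystal polymorphs of the tetrameric channel as seen by
# HS-AFM, from both membrane faces, and write the calibrated TIFF stacks
# plus their ground-truth site tables. Everything downstream (02-05) can
# be reproduced from these movies; the ground truth is what turns the
# later scripts into parameter-recovery checks.

suppressPackageStartupMessages(library(hsafm))
seed <- 1L
dir.create("results/movies", recursive = TRUE, showWarnings = FALSE)

tip <- tip_model(2)            # 2 nm apex, the assumed sharp-tip regime
scan <- scan_params()          # 0.35 nm px, 0.05 nm noise, 1 s frames

scenes <- list(
  activated_intra = list(state = "activated", face = "intracellular", extent = 6L),
  activated_extra = list(state = "activated", face = "extracellular", extent = 6L),
  resting_intra   = list(state = "resting",   face = "intracellular", extent = 8L),
  resting_extra   = list(state = "resting",   face = "extracellular", extent = 8L))

for (nm in names(scenes)) {
  sc <- scenes[[nm]]
  lattice <- sthk_lattice(sc$state, extent = sc$extent)
  fp <- sthk_footprint(sc$face, sc$state)
  surf <- render_surface(lattice, fp, scan$pixel_size)
  sites <- attr(surf, "sites")
  dil <- tip_dilate(surf, tip)
  scan$seed <- seed + match(nm, names(scenes))
  mv <- apply_scan_artifacts(topo_movie(list(unclass(dil)), scan$pixel_size), scan)
  write_movie(mv, file.path("results/movies", paste0(nm, ".tif")))
  write.csv(sites, file.path("results/movies", paste0(nm, "_sites.csv")),
            row.names = FALSE)
  cat(sprintf("%-16s %d molecules, frame %d x %d px\n", nm, nrow(sites),
              nrow(mv$frames[[1]]), ncol(mv$frames[[1]])))
}

# a transition movie: cAMP-state patch switching to the cGMP state by the
# border-nucleated domino process (used by 03)
scene <- list(lattice = sthk_lattice("activated", extent = 4L, patch_radius = 26),
              footprints = list(activated = sthk_footprint("intracellular", "activated"),
                                resting = sthk_footprint("intracellular", "resting")),
              tip = tip)
scan$seed <- seed + 10L
mv <- simulate_movie(scene, scan, n_frames = 20,
                     transition = list(model = domino_model(0.06, 3),
                                       from = "activated", to = "resting",
                                       seed = seed + 11L))
write_movie(mv, "results/movies/transition.tif")
write.csv(mv$truth$sites, "results/movies/transition_sites.csv", row.names = FALSE)
write.csv(data.frame(site_id = mv$truth$sites$site_id,
                     transition_time_s = mv$truth$transition_times),
          "results/movies/transition_truth.csv", row.names = FALSE)
st <- mv$truth$states
write.csv(data.frame(frame = rep(seq_len(nrow(st)), ncol(st)),
                     site_id = rep(mv$truth$sites$site_id, each = nrow(st)),
                     state = as.vector(st)),
          "results/movies/transition_states.csv", row.names = FALSE)
cat(sprintf("transition        %d sites x %d frames\n", ncol(st), nrow(st)))
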