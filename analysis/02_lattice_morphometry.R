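#!/usr/bin/env Rscript
# Flatten the simulated crystal frames, detect the unit cells of the two
# packing polymorphs, and measure the per-molecule height classes: the
# activated (cAMP) cell should come out near 11.6 nm with 0.3/0.6 nm
# (extracellular) and 4.3/4.6 nm (intracellular) classes, the resting
# (cGMP) cell near 8.1 nm. Requires 01_simulate_crystals.R.

suppressPackageStartupMessages(library(hsafm))
dir.create("results", showWarnings = FALSE)

frame_of <- function(name) {
  mv <- read_movie(file.path("results/movies", paste0(name, ".tif")))
  plane_flatten(movie_frame(mv, 1L))
}
sites_of <- function(name)
  read.csv(file.path("results/movies", paste0(name, "_sites.csv")))

lat_rows <- list(); cls_rows <- list()
for (nm in c("activated_intra", "activated_extra", "resting_intra", "resting_extra")) {
  fr <- frame_of(nm)
  lat <- detect_lattice(fr)
  lat_rows[[nm]] <- data.frame(scene = nm, a_nm = lat$len_a, b_nm = lat$len_b,
                               gamma_deg = lat$gamma, n_basis = lat$n_basis)
  win <- if (grepl("intra", nm)) 8 else 6
  h <- molecule_heights(fr, sites_of(nm), window_nm = win)
  cl <- classify_height_classes(h$height_nm, k = 2L)
  cls_rows[[nm]] <- data.frame(
    scene = nm, k = cl$k,
    mean_low = cl$means[1], mean_high = cl$means[length(cl$means)],
    delta = if (cl$k == 2L) cl$delta else NA_real_)
}
lat_tab <- do.call(rbind, lat_rows)
cls_tab <- do.call(rbind, cls_rows)
write.csv(lat_tab, "results/unit_cells.csv", row.names = FALSE)
write.csv(cls_tab, "results/height_classes.csv", row.names = FALSE)

cat("Detected unit cells:\n"); print(lat_tab, row.names = FALSE, digits = 4)
cat("\nHeight classes (nm above membrane):\n")
print(cls_tab, row.names = FALSE, digits = 3)
cat("\nThe activated crystal repacks from an 11.6 nm two-tetramer cell to\n",
    "the 8.1 nm one-tetramer resting cell; the 0.3 nm class split is the\n",
    "alternating vertical packing offset seen from the extracellular face.\n")
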