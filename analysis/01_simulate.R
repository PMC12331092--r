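#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study datasets.
#
# Three simulation conditions mirror the polar-core regimes of interest:
#   - IM_C7pp2: peptide-bound intermediate; the switch arginine stays
#     disengaged from the gate loop (held at the peptide glutamate), so the
#     mean switch-gate distance sits near 10 A.
#   - apo: no peptide; the salt bridge to the gate loop re-forms in a
#     substantial fraction of frames (mean ~6 A).
#   - E358A: peptide present but its glutamate anchor removed; behaves like
#     apo (mean ~6 A).
# Each condition gets 5 replicates of 300 frames at 1 ns spacing (300 ns).
# A separate symmetric-switching ensemble (10 x 200 frames) emulates the
# C-tail rebinding runs used for conformer clustering.
#
# ITC: one biphasic "wild-type" isotherm built from the two mutant-isolated
# dissociation constants (site I 1.1 uM, site II 16.4 uM) and two
# single-site "mutant" isotherms, all with 2% heat noise.
# HDX: the default synthetic peptide panel (3 replicates, sigma 0.05 Da).
#
# Everything is seed-deterministic; ground truth is stored next to the data.

suppressPackageStartupMessages(library(arrswitch))

out <- "results/synthetic"
dir.create(file.path(out, "trajectories"), recursive = TRUE,
           showWarnings = FALSE)

conditions <- list(
  IM_C7pp2 = list(p_dis = 0.05, p_eng = 0.001, start = "disengaged"),
  apo      = list(p_dis = 0.01, p_eng = 0.02, start = "disengaged"),
  E358A    = list(p_dis = 0.01, p_eng = 0.02, start = "disengaged"))

truth <- list()
for (cn in names(conditions)) {
  cc <- conditions[[cn]]
  for (r in 1:5) {
    g <- gen_switch_trajectory(
      switch_sim_params(n_frames = 300, p_disengage = cc$p_dis,
                        p_engage = cc$p_eng, start_state = cc$start,
                        dt_ns = 1, seed = 1000 * r + match(cn, names(conditions))),
      replicate_id = sprintf("rep%d", r), condition = cn)
    path <- file.path(out, "trajectories", sprintf("%s_rep%d.pdb", cn, r))
    write_trajectory(g$trajectory, path)
    truth[[sprintf("%s_rep%d", cn, r)]] <- list(
      engaged_fraction = mean(g$states == "engaged"))
    message(sprintf("wrote %s (engaged fraction %.3f)", path,
                    mean(g$states == "engaged")))
  }
}

# rebinding-style ensemble for clustering (symmetric two-state switching)
for (r in 1:10) {
  g <- gen_switch_trajectory(
    switch_sim_params(n_frames = 200, p_disengage = 0.05, p_engage = 0.05,
                      dt_ns = 1, seed = 9000 + r),
    replicate_id = sprintf("rep%d", r), condition = "rebinding")
  write_trajectory(g$trajectory,
                   file.path(out, "trajectories",
                             sprintf("rebinding_rep%d.pdb", r)))
  truth[[sprintf("rebinding_rep%d", r)]] <- list(
    engaged_fraction = mean(g$states == "engaged"))
}

# ITC isotherms
ex <- itc_experiment()
itc_sets <- list(
  wt    = binding_params(kd1 = 1.1, dh1 = -8, kd2 = 16.4, dh2 = -4),
  R394A = binding_params(kd1 = 1.1, dh1 = -8),
  R166A = binding_params(kd1 = 16.4, dh1 = -4))
for (nm in names(itc_sets)) {
  g <- gen_itc_isotherm(ex, itc_sets[[nm]], noise_sigma = 0.02,
                        seed = 7000 + match(nm, names(itc_sets)))
  path <- file.path(out, sprintf("itc_%s.csv", nm))
  write.csv(g$isotherm[, c("injection", "volume_uL", "heat_kcal_per_mol")],
            path, row.names = FALSE)
  truth[[paste0("itc_", nm)]] <- unclass(g$truth)[c("kd1", "kd2", "dh1", "dh2")]
  message("wrote ", path)
}

# HDX uptake table
gh <- gen_hdx_dataset(hdx_sim_params(seed = 8000))
write.csv(gh$data, file.path(out, "hdx_uptake.csv"), row.names = FALSE)
truth$hdx <- gh$truth
message("wrote ", file.path(out, "hdx_uptake.csv"))

jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("ground truth recorded in ", file.path(out, "truth.json"))
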