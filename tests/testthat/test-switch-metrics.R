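make_pair_traj <- function(pos_a, pos_b) {
  # 1-frame, 2-atom trajectory with atoms at the given positions
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 1, ] <- pos_a
  coords[1, 2, ] <- pos_b
  top <- topology(c("CZ", "CG"), c("ARG", "ASP"), c(394L, 299L), "A")
  trajectory(top, coords)
}

test_that("specific-mode distances are plain Euclidean distances", {
  tr <- make_pair_traj(c(0, 0, 0), c(3, 4, 0))
  cd <- contact_definition("R394-D299", 1L, 2L, mode = "specific")
  expect_equal(distance_series(tr, cd)$values, 5.0)
  tr0 <- make_pair_traj(c(1, 2, 3), c(1, 2, 3))
  expect_equal(distance_series(tr0, cd)$values, 0.0)
})

test_that("min-group mode equals the exhaustive cross-pair minimum", {
  set.seed(13)
  nf <- 1000
  coords <- array(rnorm(nf * 5 * 3, sd = 3), dim = c(nf, 5, 3))
  tr <- toy_trajectory(coords)
  cd <- contact_definition("grp", 1:3, 4:5, mode = "min-group")
  got <- distance_series(tr, cd)$values
  want <- vapply(seq_len(nf), function(f)
    min_cross_distance(matrix(coords[f, 1:3, ], ncol = 3),
                       matrix(coords[f, 4:5, ], ncol = 3)),
    numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("min-group distance never exceeds any specific pair within the groups", {
  set.seed(14)
  coords <- array(rnorm(50 * 4 * 3, sd = 2), dim = c(50, 4, 3))
  tr <- toy_trajectory(coords)
  grp <- distance_series(
    tr, contact_definition("g", 1:2, 3:4, mode = "min-group"))$values
  for (i in 1:2) for (j in 3:4) {
    spec <- distance_series(
      tr, contact_definition("s", i, j, mode = "specific"))$values
    expect_true(all(grp <= spec + 1e-12))
  }
})

test_that("contact fractions: degenerate cutoffs and monotonicity", {
  tr <- make_pair_traj(c(0, 0, 0), c(3, 0, 0))
  cd <- contact_definition("c", 1L, 2L, mode = "specific")
  s <- distance_series(tr, cd)
  expect_equal(contact_fraction(s, cutoff = 4.0)$fraction, 1.0)
  expect_equal(contact_fraction(s, cutoff = 1e-9)$fraction, 0.0)

  set.seed(15)
  coords <- array(rnorm(200 * 2 * 3, sd = 3), dim = c(200, 2, 3))
  s2 <- distance_series(toy_trajectory(coords), cd)
  cuts <- seq(0.5, 10, by = 0.5)
  fr <- vapply(cuts, function(ct) contact_fraction(s2, ct)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("pooled contact fraction is the frame-weighted mean of replicate fractions", {
  set.seed(16)
  series <- lapply(c(50, 120, 80), function(nf) {
    coords <- array(rnorm(nf * 2 * 3, sd = 3), dim = c(nf, 2, 3))
    distance_series(toy_trajectory(coords, replicate_id = paste0("r", nf)),
                    contact_definition("c", 1L, 2L, mode = "specific"))
  })
  cf <- contact_fraction(series, cutoff = 4)
  n <- vapply(series, function(s) length(s$values), numeric(1))
  expect_equal(cf$fraction, sum(cf$per_replicate * n) / sum(n))
  expect_equal(cf$n_frames, sum(n))
})

test_that("contact fraction equals generator ground truth for separated states", {
  for (seed in 1:3) {
    g <- gen_switch_trajectory(switch_sim_params(
      n_frames = 2000, p_disengage = 0.1, p_engage = 0.1, seed = seed))
    s <- polar_core_series(g$trajectory)
    cf <- contact_fraction(s, cutoff = 6.0)
    expect_equal(cf$fraction, mean(g$states == "engaged"))
  }
})

test_that("polar-core series uses the switch and gate charged-group carbons", {
  tr <- make_pair_traj(c(10, 0, 0), c(0, 0, 0))
  expect_equal(polar_core_series(tr)$values, 10.0)
  # missing atom names the residue and atom
  top_bad <- topology(c("CZ", "CB"), c("ARG", "ASP"), c(394L, 299L), "A")
  tr_bad <- trajectory(top_bad, array(0, dim = c(1, 2, 3)) + 1)
  expect_error(polar_core_series(tr_bad), "'CG' of residue 299")
})

test_that("engaged-only synthetic runs reproduce the engaged geometry", {
  g <- gen_switch_trajectory(switch_sim_params(
    n_frames = 500, p_disengage = 0, p_engage = 0, seed = 21,
    positional_noise_sigma = 0.2))
  expect_true(all(g$states == "engaged"))
  s <- polar_core_series(g$trajectory)
  expect_lt(abs(mean(s$values) - 3.9), 0.05)
})

test_that("static trajectories have zero RMSF", {
  coords <- array(rep(matrix(rnorm(12), 4, 3), each = 10), dim = c(10, 4, 3))
  tr <- toy_trajectory(coords)
  sel <- structure(list(expression = "all", indices = 1:4),
                   class = "atom_selection")
  prof <- rmsf_profile(tr, sel)
  expect_equal(prof$rmsf, rep(0, 4))
})

test_that("single-frame RMSF is zero with a warning", {
  tr <- toy_trajectory(array(rnorm(12), dim = c(1, 4, 3)))
  sel <- structure(list(expression = "all", indices = 1:4),
                   class = "atom_selection")
  expect_warning(prof <- rmsf_profile(tr, sel), "single-frame")
  expect_equal(prof$rmsf, rep(0, 4))
})

test_that("isotropic jitter gives RMSF = sigma * sqrt(3)", {
  g <- gen_peptide_trajectory(346:359, sigmas = 0.5, n_frames = 5000,
                              seed = 31)
  sel <- select_atoms(g$trajectory$topology, "name CA")
  prof <- rmsf_profile(g$trajectory, sel, align_selection = NULL)
  expect_true(all(abs(prof$rmsf - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))
})

test_that("site-resolved mobility ordering is recovered in the RMSF profile", {
  # site I (residues 350, 352) tight, site II (residue 358) mobile
  ids <- 346:359
  sig <- ifelse(ids %in% c(349, 350, 351, 352), 0.3,
                ifelse(ids %in% c(357, 358, 359), 1.0, 0.6))
  g <- gen_peptide_trajectory(ids, sigmas = sig, n_frames = 2000, seed = 32)
  prof <- rmsf_profile(g$trajectory,
                       select_atoms(g$trajectory$topology, "name CA"),
                       align_selection = NULL)
  site1 <- prof$rmsf[prof$residue_id %in% c(349, 350, 351, 352)]
  site2 <- prof$rmsf[prof$residue_id %in% c(357, 358, 359)]
  expect_true(max(site1) < min(site2))
})

test_that("RMSF with alignment is invariant under a global rigid transform", {
  set.seed(33)
  g <- gen_peptide_trajectory(1:8, sigmas = 0.4, n_frames = 300, seed = 34)
  tr <- g$trajectory
  sel <- select_atoms(tr$topology, "name CA")
  base <- rmsf_profile(tr, sel, align_selection = sel)
  R <- random_rotation(); t <- c(12, -5, 30)
  tr2 <- tr
  for (f in seq_len(n_frames(tr2)))
    tr2$coords[f, , ] <- sweep(tr2$coords[f, , ] %*% R, 2, t, `+`)
  moved <- rmsf_profile(tr2, sel, align_selection = sel)
  expect_equal(moved$rmsf, base$rmsf, tolerance = 1e-6)
})

test_that("state classification thresholds and fractions behave as defined", {
  mk <- function(vals) new_series <- structure(
    list(name = "pc", values = vals, replicate_id = "r", condition = "c"),
    class = "distance_series")
  cs <- classify_states(mk(rep(3, 10)), threshold = 6)
  expect_true(all(cs$states == "engaged"))
  cs2 <- classify_states(mk(rep(c(3, 12), 10)), threshold = 6)
  expect_equal(cs2$engaged_fraction, 0.5)
  expect_error(classify_states(mk(rep(3, 4)), threshold = -1), "> 0")
})

test_that("classification recovers the hidden state sequence exactly", {
  for (seed in c(41, 42)) {
    g <- gen_switch_trajectory(switch_sim_params(
      n_frames = 5000, p_disengage = 0.05, p_engage = 0.05, seed = seed))
    cs <- classify_states(polar_core_series(g$trajectory), threshold = 6.0)
    got <- ifelse(cs$states == "engaged", "engaged", "disengaged")
    expect_identical(got, g$states)
  }
})

test_that("per-replicate state summaries pool consistently", {
  gs <- lapply(1:3, function(s) gen_switch_trajectory(
    switch_sim_params(n_frames = 400, seed = s), replicate_id = paste0("r", s),
    condition = "apo"))
  series <- lapply(gs, function(g) polar_core_series(g$trajectory))
  tab <- switch_state_summary(series, threshold = 6.0)
  pooled <- tab[tab$replicate == "pooled", ]
  per <- tab[tab$replicate != "pooled", ]
  expect_equal(pooled$engaged_fraction,
               sum(per$engaged_fraction * per$n_frames) / sum(per$n_frames))
})
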