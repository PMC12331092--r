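test_that("PDB topology parsing preserves order, numbering and atom names", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb_lines(f)
  top <- read_topology(f)
  expect_s3_class(top, "topology")
  expect_equal(nrow(top), 3L)
  expect_equal(top$atom_name, c("CZ", "NH1", "NH2"))
  expect_equal(unique(top$residue_id), 394L)
  expect_equal(unique(top$residue_name), "ARG")
})

test_that("duplicate atom serials are accepted; indices stay positional", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb_lines(f, serials = c(7, 7, 7))
  top <- suppressWarnings(read_topology(f))
  expect_equal(nrow(top), 3L)
})

test_that("reading a file with no atoms is an error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_topology(f))
  expect_error(read_topology("no/such/file.pdb"), "not found")
})

test_that("multi-model PDB reading yields one frame per MODEL block", {
  f <- withr::local_tempfile(fileext = ".pdb")
  coords <- array(rnorm(2 * 3 * 3, sd = 2) + 10, dim = c(2, 3, 3))
  tr <- toy_trajectory(coords)
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(n_frames(tr2), 2L)

  # single-frame file
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb_lines(f1)
  tr1 <- read_trajectory(f1)
  expect_equal(n_frames(tr1), 1L)
})

test_that("write/read round trip preserves topology and coordinates to PDB precision", {
  set.seed(42)
  g <- gen_switch_trajectory(switch_sim_params(n_frames = 100, seed = 11))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$topology$atom_name, g$trajectory$topology$atom_name)
  expect_equal(tr2$topology$residue_id, g$trajectory$topology$residue_id)
  expect_equal(tr2$topology$residue_name, g$trajectory$topology$residue_name)
  expect_equal(tr2$topology$chain_id, g$trajectory$topology$chain_id)
  expect_lte(max(abs(tr2$coords - g$trajectory$coords)), 0.001)
})

test_that("atom-count mismatch between topology and trajectory is a shape error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb_lines(f)
  wrong <- topology(c("CA", "CB"), c("ALA", "ALA"), c(1L, 1L), "A")
  expect_error(read_trajectory(f, topology = wrong), "atom-count mismatch")
})

test_that("selection grammar resolves the documented atom selections", {
  g <- gen_switch_trajectory(switch_sim_params(n_frames = 2, seed = 1))
  top <- g$trajectory$topology
  expect_length(select_atoms(top, "resid 394 and name CZ")$indices, 1L)
  expect_length(select_atoms(top, "resid 350 352 and name P")$indices, 2L)
  expect_length(select_atoms(top, "chain B and resname GLU")$indices, 4L)
  expect_warning(sel <- select_atoms(top, "name ZZ9"), "matched no atoms")
  expect_length(sel$indices, 0L)
})

test_that("selection grammar rejects malformed expressions with a position", {
  top <- topology("CA", "GLY", 1L, "A")
  expect_error(select_atoms(top, "bogus 1"), "token 1")
  expect_error(select_atoms(top, "resid 1 name CA"), "expected 'and'")
  expect_error(select_atoms(top, "resid 1 and"), "dangling")
  expect_error(select_atoms(top, "resid x"), "non-integer")
  expect_error(select_atoms(top, "resid"), "no values")
})

test_that("selection is idempotent and clause-order independent", {
  g <- gen_switch_trajectory(switch_sim_params(n_frames = 2, seed = 1))
  top <- g$trajectory$topology
  a <- select_atoms(top, "resid 394 and name CZ NH1")$indices
  b <- select_atoms(top, "name NH1 CZ and resid 394")$indices
  expect_identical(a, b)
  expect_identical(a, sort(unique(a)))
})

test_that("superposition undoes random rigid-body transforms", {
  set.seed(7)
  m <- 12
  base <- matrix(rnorm(m * 3, sd = 4), ncol = 3)
  nf <- 8
  coords <- array(0, dim = c(nf, m, 3))
  coords[1, , ] <- base
  for (f in 2:nf) {
    R <- random_rotation()
    coords[f, , ] <- sweep(base %*% R, 2, rnorm(3, sd = 10), `+`)
  }
  tr <- toy_trajectory(coords)
  sel <- structure(list(expression = "all", indices = seq_len(m)),
                   class = "atom_selection")
  out <- superpose(tr, 1L, sel)
  for (f in seq_len(nf)) {
    rmsd <- sqrt(mean(rowSums((out$coords[f, , ] - base)^2)))
    expect_lt(rmsd, 1e-6)
  }
})

test_that("superposition is a near-identity on already-aligned frames and exact for pure translation", {
  set.seed(8)
  m <- 6
  base <- matrix(rnorm(m * 3, sd = 3), ncol = 3)
  aligned <- array(rep(base, each = 3), dim = c(3, m, 3))
  tr <- toy_trajectory(aligned)
  sel <- structure(list(expression = "all", indices = seq_len(m)),
                   class = "atom_selection")
  out <- superpose(tr, 1L, sel)
  expect_lt(max(abs(out$coords - aligned)), 1e-9)

  shifted <- array(0, dim = c(2, m, 3))
  shifted[1, , ] <- base
  shifted[2, , ] <- sweep(base, 2, c(5, 0, 0), `+`)
  tr2 <- superpose(toy_trajectory(shifted), 1L, sel)
  expect_lt(max(abs(tr2$coords[2, , ] - base)), 1e-9)
})

test_that("superposition preserves all intra-frame distances (rigid-body property)", {
  set.seed(9)
  g <- gen_switch_trajectory(switch_sim_params(n_frames = 5, seed = 5))
  tr <- g$trajectory
  sel <- select_atoms(tr$topology, "name CA")
  out <- superpose(tr, 1L, sel)
  for (f in seq_len(n_frames(tr)))
    expect_lt(max(abs(frame_distances(out$coords[f, , ]) -
                      frame_distances(tr$coords[f, , ]))), 1e-6)
})

test_that("collinear fit selections are rejected", {
  coords <- array(0, dim = c(2, 4, 3))
  coords[, , 1] <- matrix(rep(1:4, each = 2), nrow = 2)  # atoms on the x axis
  tr <- toy_trajectory(coords)
  sel <- structure(list(expression = "all", indices = 1:4),
                   class = "atom_selection")
  expect_error(superpose(tr, 1L, sel), "collinear|rank")
})

test_that("superposition matches the bio3d least-squares fit", {
  set.seed(10)
  m <- 10; nf <- 4
  coords <- array(rnorm(nf * m * 3, sd = 3), dim = c(nf, m, 3))
  tr <- toy_trajectory(coords)
  sel <- structure(list(expression = "all", indices = seq_len(m)),
                   class = "atom_selection")
  ours <- superpose(tr, 1L, sel)
  xyz <- t(apply(coords, 1, function(fr) as.vector(t(fr))))
  ref <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                        fixed.inds = seq_len(3 * m),
                        mobile.inds = seq_len(3 * m))
  theirs <- aperm(array(t(ref), dim = c(3, m, nf)), c(3, 2, 1))
  expect_lt(max(abs(ours$coords - theirs)), 1e-6)
})

test_that("analysis windows select the trailing time span", {
  g <- gen_switch_trajectory(switch_sim_params(n_frames = 100, dt_ns = 1,
                                               seed = 2))
  tr <- g$trajectory
  w <- apply_window(tr, "last 50 ns")
  expect_equal(n_frames(w), 50L)
  expect_equal(min(w$frame_times), 51)
  expect_identical(apply_window(tr, "all"), tr)
  expect_error(apply_window(tr, "last -3 s"), "invalid analysis window")
  tr$frame_times <- NULL
  expect_error(apply_window(tr, "last 50 ns"), "frame_times")
})

test_that("replicate sets enforce shared condition and topology size", {
  a <- gen_switch_trajectory(switch_sim_params(n_frames = 5, seed = 1),
                             condition = "apo")$trajectory
  b <- gen_switch_trajectory(switch_sim_params(n_frames = 5, seed = 2),
                             condition = "bound")$trajectory
  expect_error(replicate_set(list(a, b)), "one condition")
  b$condition <- "apo"
  rs <- replicate_set(list(a, b), window = "all")
  expect_s3_class(rs, "replicate_set")
  expect_error(replicate_set(list()), "non-empty")
})
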