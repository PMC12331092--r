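# Seed-deterministic generators. Each runs under its own RNG stream and
# restores the caller's .Random.seed, and each returns the ground truth
# needed to score the downstream stage (hidden states, binding constants,
# uptake deltas).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the two-state switch simulator
#'
#' The simulator emulates the engaged/disengaged dynamics of an
#' Arg394-like switch side chain as a first-order, frame-discrete two-state
#' Markov chain. In the engaged state the guanidinium carbon sits at the
#' gate-contact geometry (switch-gate distance ~3.9 Angstrom, intact polar
#' core); in the disengaged state it sits at the disrupted-core geometry
#' (~10 Angstrom from the gate, 4.2 Angstrom from the peptide glutamate's
#' C-delta). Isotropic Gaussian positional noise is added to every atom in
#' every frame.
#'
#' @param n_frames number of frames to simulate
#' @param p_disengage per-frame probability of leaving the engaged state
#' @param p_engage per-frame probability of re-engaging
#' @param engaged_geometry engaged switch-gate distance in Angstrom (3.9)
#' @param disengaged_geometry disengaged switch-gate distance in Angstrom (10)
#' @param e358_distance disengaged switch-to-peptide-glutamate distance (4.2)
#' @param positional_noise_sigma per-coordinate Gaussian sigma in Angstrom (0.2)
#' @param start_state `"engaged"` or `"disengaged"`
#' @param dt_ns frame spacing in ns (sets `frame_times`)
#' @param seed integer RNG seed
#' @return object of class `switch_sim_params`
#' @export
switch_sim_params <- function(n_frames = 1000L, p_disengage = 0.02,
                              p_engage = 0.02, engaged_geometry = 3.9,
                              disengaged_geometry = 10.0,
                              e358_distance = 4.2,
                              positional_noise_sigma = 0.2,
                              start_state = c("engaged", "disengaged"),
                              dt_ns = 0.2, seed = 1L) {
  start_state <- match.arg(start_state)
  if (p_disengage < 0 || p_disengage > 1 || p_engage < 0 || p_engage > 1)
    stop("transition probabilities must be in [0, 1]")
  if (disengaged_geometry <= engaged_geometry)
    stop("disengaged geometry must exceed engaged geometry")
  if (positional_noise_sigma <= 0) stop("noise sigma must be > 0")
  structure(list(n_frames = as.integer(n_frames), p_disengage = p_disengage,
                 p_engage = p_engage, engaged_geometry = engaged_geometry,
                 disengaged_geometry = disengaged_geometry,
                 e358_distance = e358_distance,
                 positional_noise_sigma = positional_noise_sigma,
                 start_state = start_state, dt_ns = dt_ns,
                 seed = as.integer(seed)),
            class = "switch_sim_params")
}

# Pseudo-molecule base geometry: only the atoms the metrics read. Group
# centres in Angstrom; the switch arginine (394) has two centres, one per
# state. The gate aspartate's carboxylate carbon is at the origin.
switch_base_layout <- function(params) {
  res <- list(
    list(id = 299L, name = "ASP", chain = "A", center = c(0, 0, 0)),
    list(id = 27L,  name = "ASP", chain = "A", center = c(0, -6, 0)),
    list(id = 292L, name = "ASP", chain = "A", center = c(-4, 3, 0)),
    list(id = 170L, name = "ARG", chain = "A", center = c(-4, -3, 0)),
    list(id = 77L,  name = "ARG", chain = "A", center = c(3.3, 20, 0)),
    list(id = 148L, name = "ARG", chain = "A", center = c(-3.3, 20, 0)),
    list(id = 166L, name = "ARG", chain = "A", center = c(0, 23.3, 0)),
    list(id = 394L, name = "ARG", chain = "A",
         center = c(params$engaged_geometry, 0, 0)),
    list(id = 350L, name = "SEP", chain = "B", center = c(0, 20, 0)),
    list(id = 352L, name = "TPO", chain = "B", center = c(0, 16.7, 0)),
    list(id = 358L, name = "GLU", chain = "B",
         center = c(params$disengaged_geometry + params$e358_distance, 0, 0))
  )
  res
}

residue_atoms <- function(resname) {
  switch(resname,
    ASP = list(c("CA", 0, 0, 1.5), c("CG", 0, 0, 0),
               c("OD1", 0.6, 0.9, 0), c("OD2", 0.6, -0.9, 0)),
    ARG = list(c("CA", 0, 0, 1.5), c("CZ", 0, 0, 0),
               c("NH1", 0.6, 1.0, 0), c("NH2", 0.6, -1.0, 0)),
    GLU = list(c("CA", 0, 0, 1.5), c("CD", 0, 0, 0),
               c("OE1", -0.6, 0.9, 0), c("OE2", -0.6, -0.9, 0)),
    SEP = ,
    TPO = list(c("CA", 0, 0, 1.5), c("P", 0, 0, 0),
               c("O1P", 1.2, 0, 0), c("O2P", -0.6, 1.0, 0),
               c("O3P", -0.6, -1.0, 0)),
    stop("unknown residue template: ", resname))
}

#' Generate a two-state switch trajectory with known hidden states
#'
#' Builds a minimal pseudo-molecule topology (gate and anchor aspartates,
#' the site-I arginines and phosphoresidues, the peptide glutamate, and the
#' switch arginine), simulates the hidden engaged/disengaged Markov chain,
#' and emits per-frame coordinates at the state's geometry plus isotropic
#' Gaussian noise on every atom. The returned ground-truth state sequence
#' lets every downstream classifier and contact statistic be scored
#' exactly.
#'
#' @param params a [switch_sim_params()]
#' @param replicate_id,condition metadata tags for the trajectory
#' @return list: `trajectory` ([trajectory()] with `frame_times`), `states`
#'   (character vector of hidden states), `params`
#' @export
gen_switch_trajectory <- function(params = switch_sim_params(),
                                  replicate_id = "rep1",
                                  condition = "synthetic") {
  stopifnot(inherits(params, "switch_sim_params"))
  layout <- switch_base_layout(params)
  atom_name <- character(0); residue_name <- character(0)
  residue_id <- integer(0); chain_id <- character(0)
  base <- NULL
  switch_rows <- integer(0)
  for (r in layout) {
    atoms <- residue_atoms(r$name)
    for (a in atoms) {
      atom_name <- c(atom_name, a[1])
      residue_name <- c(residue_name, r$name)
      residue_id <- c(residue_id, r$id)
      chain_id <- c(chain_id, r$chain)
      base <- rbind(base, r$center + as.numeric(a[2:4]))
      if (r$id == 394L) switch_rows <- c(switch_rows, nrow(base))
    }
  }
  top <- topology(atom_name, residue_name, residue_id, chain_id)
  na <- nrow(base)
  disp <- params$disengaged_geometry - params$engaged_geometry
  with_seed(params$seed, {
    states <- character(params$n_frames)
    s <- params$start_state
    u <- stats::runif(params$n_frames)
    for (f in seq_len(params$n_frames)) {
      states[f] <- s
      s <- if (s == "engaged") {
        if (u[f] < params$p_disengage) "disengaged" else "engaged"
      } else {
        if (u[f] < params$p_engage) "engaged" else "disengaged"
      }
    }
    coords <- array(0, dim = c(params$n_frames, na, 3))
    noise <- array(stats::rnorm(params$n_frames * na * 3,
                                sd = params$positional_noise_sigma),
                   dim = c(params$n_frames, na, 3))
    for (f in seq_len(params$n_frames)) {
      fr <- base
      if (states[f] == "disengaged")
        fr[switch_rows, 1] <- fr[switch_rows, 1] + disp
      coords[f, , ] <- fr + noise[f, , ]
    }
    traj <- trajectory(top, coords,
                       frame_times = seq_len(params$n_frames) * params$dt_ns,
                       replicate_id = replicate_id, condition = condition)
    list(trajectory = traj, states = states, params = params)
  })
}

#' Generate a peptide-like trajectory with per-residue mobility
#'
#' A C-alpha-only chain (default: residues 346-359, the receptor C-tail
#' peptide numbering) jittered with per-residue isotropic Gaussian noise
#' about fixed positions. Used to emulate the site-I-stable /
#' site-II-mobile RMSF contrast: give site-I residues a small sigma and
#' site-II residues a large one.
#'
#' @param residue_ids integer residue numbers
#' @param sigmas per-residue noise sigma in Angstrom (recycled)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param chain_id chain for the peptide (default "B")
#' @return list: `trajectory`, `sigmas` (named by residue)
#' @export
gen_peptide_trajectory <- function(residue_ids = 346:359, sigmas = 0.5,
                                   n_frames = 1000L, seed = 1L,
                                   chain_id = "B") {
  nr <- length(residue_ids)
  sigmas <- rep_len(sigmas, nr)
  top <- topology(rep("CA", nr), rep("ALA", nr), residue_ids, chain_id)
  base <- cbind(3.8 * seq_len(nr), 0, 0)
  with_seed(seed, {
    coords <- array(0, dim = c(n_frames, nr, 3))
    for (i in seq_len(nr))
      coords[, i, ] <- matrix(rep(base[i, ], each = n_frames), ncol = 3) +
        stats::rnorm(n_frames * 3, sd = sigmas[i])
    traj <- trajectory(top, coords, replicate_id = "rep1",
                       condition = "peptide-synthetic")
    list(trajectory = traj, sigmas = stats::setNames(sigmas, residue_ids))
  })
}

#' Generate a noisy isotherm with known binding parameters
#'
#' [simulate_isotherm()] plus i.i.d. Gaussian heat noise scaled to the
#' maximum absolute heat; the truth record keeps the generating parameters
#' for recovery scoring.
#'
#' @param exp an [itc_experiment()]
#' @param params a [binding_params()] (the ground truth)
#' @param noise_sigma noise SD as a fraction of max |heat| (e.g. 0.02)
#' @param seed RNG seed
#' @return list: `isotherm`, `truth` (the `params`), `noise_sigma_kcal`
#' @export
gen_itc_isotherm <- function(exp, params, noise_sigma = 0.02, seed = 1L) {
  iso <- simulate_isotherm(exp, params)
  sd_abs <- noise_sigma * max(abs(iso$heat_kcal_per_mol))
  with_seed(seed, {
    iso$heat_kcal_per_mol <- iso$heat_kcal_per_mol +
      stats::rnorm(nrow(iso), sd = sd_abs)
    list(isotherm = iso, truth = params, noise_sigma_kcal = sd_abs)
  })
}

#' Parameters of the HDX uptake simulator
#'
#' Per-peptide single-exponential amide exchange:
#' D(t) = n_amides * (1 - exp(-(k_int / P) * t)) with intrinsic rate k_int
#' (per second) slowed by a state-dependent protection factor P >= 1;
#' replicate uptakes add Gaussian noise (floored at 0 Da). The default
#' peptide panel emulates the regions of interest around the arrestin gate
#' loop and C-terminal beta-strand: exchange increases there on peptide
#' binding (protection drops), decreases in the central loops, and is
#' unchanged elsewhere.
#'
#' @param peptides data.frame with columns `start`, `end`, `n_amides`,
#'   `k_int`, `P_a` (state A protection), `P_b` (state B protection)
#' @param timepoints_s exchange times in seconds
#' @param sigma_Da replicate noise SD in Da
#' @param n_replicates replicates per state and timepoint
#' @param seed RNG seed
#' @return object of class `hdx_sim_params`
#' @export
hdx_sim_params <- function(peptides = default_hdx_peptides(),
                           timepoints_s = c(10, 100, 1000, 10000),
                           sigma_Da = 0.05, n_replicates = 3L, seed = 1L) {
  need <- c("start", "end", "n_amides", "k_int", "P_a", "P_b")
  missing <- setdiff(need, names(peptides))
  if (length(missing) > 0L)
    stop("peptides table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(peptides$k_int <= 0)) stop("k_int must be > 0")
  if (any(peptides$P_a < 1 | peptides$P_b < 1))
    stop("protection factors must be >= 1")
  structure(list(peptides = peptides, timepoints_s = timepoints_s,
                 sigma_Da = sigma_Da, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "hdx_sim_params")
}

#' Default synthetic HDX peptide panel
#'
#' Gate loop (292-302) and the C-terminal strand's N-part (382-389) gain
#' exchange in the bound state; the central-loop peptides (119-133,
#' 283-291, 305-317) lose exchange; two control peptides are unchanged.
#'
#' @return peptides data.frame for [hdx_sim_params()]
#' @export
default_hdx_peptides <- function() {
  data.frame(
    start = c(292L, 382L, 119L, 283L, 305L, 50L, 200L),
    end   = c(302L, 389L, 133L, 291L, 317L, 60L, 210L),
    n_amides = c(10L, 7L, 14L, 8L, 12L, 10L, 10L),
    k_int = 1.0,
    P_a = c(1000, 2000, 300, 300, 300, 500, 500),
    P_b = c(300, 600, 1000, 1000, 1000, 500, 500)
  )
}

hdx_uptake_mean <- function(n_amides, k_int, P, t) {
  n_amides * (1 - exp(-(k_int / P) * t))
}

#' Generate a synthetic differential HDX dataset
#'
#' @param params an [hdx_sim_params()]
#' @param state_a,state_b state labels for the two protection profiles
#' @return list: `data` (tidy HDX table, see [read_hdx_csv()]), `truth`
#'   (per peptide x timepoint: noiseless `delta_Da` = B - A)
#' @export
gen_hdx_dataset <- function(params = hdx_sim_params(), state_a = "apo",
                            state_b = "bound") {
  stopifnot(inherits(params, "hdx_sim_params"))
  pep <- params$peptides
  grid <- expand.grid(pi = seq_len(nrow(pep)),
                      timepoint_s = params$timepoints_s,
                      replicate = seq_len(params$n_replicates),
                      state = c(state_a, state_b),
                      stringsAsFactors = FALSE)
  mu <- with(grid, {
    P <- ifelse(state == state_a, pep$P_a[pi], pep$P_b[pi])
    hdx_uptake_mean(pep$n_amides[pi], pep$k_int[pi], P, timepoint_s)
  })
  with_seed(params$seed, {
    uptake <- pmax(0, mu + stats::rnorm(length(mu), sd = params$sigma_Da))
    data <- data.frame(peptide_start = pep$start[grid$pi],
                       peptide_end = pep$end[grid$pi],
                       state = grid$state,
                       timepoint_s = grid$timepoint_s,
                       replicate = grid$replicate,
                       uptake_Da = uptake)
    truth <- expand.grid(pi = seq_len(nrow(pep)),
                         timepoint_s = params$timepoints_s)
    truth <- data.frame(
      peptide_start = pep$start[truth$pi], peptide_end = pep$end[truth$pi],
      timepoint_s = truth$timepoint_s,
      delta_Da = hdx_uptake_mean(pep$n_amides[truth$pi], pep$k_int[truth$pi],
                                 pep$P_b[truth$pi], truth$timepoint_s) -
                 hdx_uptake_mean(pep$n_amides[truth$pi], pep$k_int[truth$pi],
                                 pep$P_a[truth$pi], truth$timepoint_s))
    list(data = data, truth = truth)
  })
}
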