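#' Define a monitored contact
#'
#' Two conventions are supported. `"specific"` monitors one named atom on
#' each side (the convention used for monitoring plots: phosphorus of a
#' phosphoresidue vs. the guanidinium carbon C-zeta of an arginine, or
#' C-delta of a glutamate vs. C-zeta). `"min-group"` takes, per frame, the
#' minimum over all cross pairs between the two selections — the standard
#' salt-bridge criterion when applied to side-chain acidic/phosphate oxygens
#' vs. basic nitrogens with a 4.0 Angstrom cutoff.
#'
#' @param name contact label, e.g. `"pS350-R77"`
#' @param sel_a,sel_b [select_atoms()] results (or index vectors)
#' @param mode `"specific"` (exactly one atom each side) or `"min-group"`
#' @param cutoff contact cutoff in Angstrom (must be > 0)
#' @return object of class `contact_definition`
#' @export
contact_definition <- function(name, sel_a, sel_b,
                               mode = c("specific", "min-group"),
                               cutoff = 4.0) {
  mode <- match.arg(mode)
  ia <- sel_indices(sel_a); ib <- sel_indices(sel_b)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(ia) == 0L || length(ib) == 0L)
    stop(sprintf("contact '%s': empty selection", name))
  if (mode == "specific" && (length(ia) != 1L || length(ib) != 1L))
    stop(sprintf("contact '%s': 'specific' mode requires exactly 1 atom per side (got %d and %d)",
                 name, length(ia), length(ib)))
  structure(list(name = name, ia = ia, ib = ib, mode = mode, cutoff = cutoff),
            class = "contact_definition")
}

new_distance_series <- function(name, values, replicate_id, condition,
                                frame_times = NULL) {
  if (length(values) == 0L) stop("empty distance series")
  if (!all(is.finite(values)) || any(values < 0))
    stop("distances must be finite and non-negative")
  structure(list(name = name, values = as.numeric(values),
                 replicate_id = replicate_id, condition = condition,
                 frame_times = frame_times),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> '%s' [%s/%s]: %d frames, mean %.2f A\n",
              x$name, x$condition, x$replicate_id, length(x$values),
              mean(x$values)))
  invisible(x)
}

#' Per-frame distance for a contact definition
#'
#' @param traj a [trajectory()]
#' @param contact a [contact_definition()]
#' @return a `distance_series` (per-frame Angstrom, tagged with the
#'   trajectory's replicate and condition)
#' @export
distance_series <- function(traj, contact) {
  stopifnot(inherits(contact, "contact_definition"))
  ca <- traj$coords[, contact$ia, , drop = FALSE]
  cb <- traj$coords[, contact$ib, , drop = FALSE]
  nf <- n_frames(traj)
  if (contact$mode == "specific") {
    A <- matrix(ca[, 1, ], ncol = 3)
    B <- matrix(cb[, 1, ], ncol = 3)
    d <- sqrt(rowSums((A - B)^2))
  } else {
    d <- vapply(seq_len(nf), function(f) {
      A <- matrix(ca[f, , ], ncol = 3)
      B <- matrix(cb[f, , ], ncol = 3)
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      sqrt(max(0, min(d2)))
    }, numeric(1))
  }
  new_distance_series(contact$name, d, traj$replicate_id, traj$condition,
                      traj$frame_times)
}

#' Contact-stability fraction over replicate distance series
#'
#' The fraction of frames in which the contact distance is at or below the
#' cutoff, pooled across replicates (as a population-weighted count), plus
#' the per-replicate breakdown. This is the "stability percent" statistic
#' reported for phosphopeptide--arrestin salt bridges.
#'
#' @param series_set a `distance_series` or list of them sharing one contact
#' @param cutoff contact cutoff in Angstrom; defaults to the cutoff stored in
#'   the first series' definition when available, otherwise 4.0
#' @return list with `fraction` (pooled, in \[0,1\]), `per_replicate`
#'   (named numeric), `n_frames` (pooled frame count)
#' @export
contact_fraction <- function(series_set, cutoff = 4.0) {
  if (inherits(series_set, "distance_series")) series_set <- list(series_set)
  if (length(series_set) == 0L) stop("empty series set")
  stopifnot(all(vapply(series_set, inherits, logical(1), "distance_series")))
  nms <- unique(vapply(series_set, `[[`, character(1), "name"))
  if (length(nms) != 1L)
    stop("all series must share one contact definition (got: ",
         paste(nms, collapse = ", "), ")")
  hits <- vapply(series_set, function(s) sum(s$values <= cutoff), numeric(1))
  tot <- vapply(series_set, function(s) length(s$values), numeric(1))
  if (sum(tot) == 0) stop("empty frame set")
  per <- hits / tot
  names(per) <- vapply(series_set, `[[`, character(1), "replicate_id")
  list(contact = nms, cutoff = cutoff, fraction = sum(hits) / sum(tot),
       per_replicate = per, n_frames = sum(tot))
}

#' Polar-core integrity specification
#'
#' The polar core of beta-arrestin-2 is the buried charge network (Asp27,
#' Arg170, Asp292, Asp299, Arg394) that locks the inactive state. Its
#' integrity is monitored as the distance between the switch arginine's
#' guanidinium carbon (C-zeta of Arg394) and the gate-loop aspartate's
#' carboxylate carbon (C-gamma of Asp299): small values mean an intact core
#' (inactive-like), large values a disrupted core (intermediate).
#'
#' @param switch_residue residue id of the switch arginine (default 394)
#' @param switch_atom atom name on the switch residue (default "CZ")
#' @param gate_residue residue id of the gate-loop aspartate (default 299)
#' @param gate_atom atom name on the gate residue (default "CG")
#' @param anchor_residues other polar-core residues, recorded for reference
#' @return object of class `polar_core_spec`
#' @export
polar_core_spec <- function(switch_residue = 394L, switch_atom = "CZ",
                            gate_residue = 299L, gate_atom = "CG",
                            anchor_residues = c(27L, 292L, 170L)) {
  structure(list(switch_residue = switch_residue, switch_atom = switch_atom,
                 gate_residue = gate_residue, gate_atom = gate_atom,
                 anchor_residues = anchor_residues),
            class = "polar_core_spec")
}

resolve_single_atom <- function(topology, residue, atom) {
  sel <- suppressWarnings(
    select_atoms(topology, sprintf("resid %d and name %s", residue, atom)))
  if (length(sel$indices) == 0L)
    stop(sprintf("atom '%s' of residue %d not found in topology", atom, residue))
  sel
}

#' Polar-core distance series
#'
#' @param traj a [trajectory()]
#' @param spec a [polar_core_spec()]
#' @return a `distance_series` of the switch-gate distance per frame
#' @export
polar_core_series <- function(traj, spec = polar_core_spec()) {
  stopifnot(inherits(spec, "polar_core_spec"))
  sa <- resolve_single_atom(traj$topology, spec$switch_residue, spec$switch_atom)
  sb <- resolve_single_atom(traj$topology, spec$gate_residue, spec$gate_atom)
  cd <- contact_definition(
    sprintf("R%d-D%d", spec$switch_residue, spec$gate_residue),
    sa, sb, mode = "specific", cutoff = 4.0)
  distance_series(traj, cd)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of selected atoms about their time-averaged
#' positions: each frame is superposed on the time-averaged structure over
#' the alignment selection (two refinement passes, starting from the first
#' frame), then RMSF_i = sqrt(mean_t |x_i(t) - mean(x_i)|^2). With multiple
#' replicates the per-replicate profiles are averaged. Pass
#' `align_selection = NULL` to skip superposition (appropriate when frames
#' come from backbone-restrained simulations or a fixed lab frame).
#'
#' @param replicates a [replicate_set()] or single [trajectory()]
#' @param atom_selection selection of atoms to profile (typically C-alpha
#'   atoms of the peptide)
#' @param align_selection selection to superpose on, or `NULL` to disable
#' @return object of class `rmsf_profile`: data.frame with `residue_id`,
#'   `atom_name` and `rmsf` (Angstrom)
#' @export
rmsf_profile <- function(replicates, atom_selection, align_selection = NULL) {
  if (inherits(replicates, "trajectory"))
    replicates <- replicate_set(list(replicates),
                                window = "all")
  stopifnot(inherits(replicates, "replicate_set"))
  idx <- sel_indices(atom_selection)
  if (length(idx) == 0L) stop("empty atom selection for RMSF")
  trajs <- windowed_trajectories(replicates)
  profs <- lapply(trajs, function(tr) {
    if (n_frames(tr) < 2L) {
      warning("single-frame trajectory: RMSF is identically zero")
      return(rep(0, length(idx)))
    }
    if (!is.null(align_selection)) {
      aidx <- sel_indices(align_selection)
      ref <- tr$coords[1, , , drop = TRUE]
      for (pass in 1:2) {
        for (f in seq_len(n_frames(tr))) {
          fit <- kabsch_fit(tr$coords[f, aidx, , drop = TRUE],
                            ref[aidx, , drop = FALSE])
          tr$coords[f, , ] <- sweep(tr$coords[f, , , drop = TRUE] %*% fit$R,
                                    2, fit$t, `+`)
        }
        ref <- apply(tr$coords, c(2, 3), mean)
      }
    }
    mu <- apply(tr$coords[, idx, , drop = FALSE], c(2, 3), mean)
    dev2 <- sweep(tr$coords[, idx, , drop = FALSE], c(2, 3), mu)^2
    sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and xyz, times 3 dims
  })
  rmsf <- Reduce(`+`, profs) / length(profs)
  top <- replicates$trajectories[[1]]$topology
  out <- data.frame(residue_id = top$residue_id[idx],
                    atom_name = top$atom_name[idx],
                    rmsf = rmsf)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Classify switch states from a distance series
#'
#' A frame is "engaged" when the switch-gate distance is at or below the
#' threshold (intact polar core, inactive-like) and "disengaged" otherwise
#' (disrupted core, intermediate-like). The default 6.0 Angstrom threshold
#' separates the intact-core regime from the disrupted regime on the
#' C-zeta/C-gamma metric.
#'
#' @param series a `distance_series`
#' @param threshold state threshold in Angstrom (> 0)
#' @return object of class `switch_states`: list with per-frame `states`,
#'   `threshold`, `engaged_fraction`, `mean_distance`, `replicate_id`,
#'   `condition`
#' @export
classify_states <- function(series, threshold = 6.0) {
  stopifnot(inherits(series, "distance_series"))
  if (threshold <= 0) stop("threshold must be > 0")
  st <- ifelse(series$values <= threshold, "engaged", "disengaged")
  structure(list(states = st, threshold = threshold,
                 engaged_fraction = mean(st == "engaged"),
                 mean_distance = mean(series$values),
                 replicate_id = series$replicate_id,
                 condition = series$condition),
            class = "switch_states")
}

#' Per-replicate switch-state summary
#'
#' @param series_list list of `distance_series` (one per replicate)
#' @param threshold state threshold in Angstrom
#' @return data.frame with one row per replicate plus a pooled row
#' @export
switch_state_summary <- function(series_list, threshold = 6.0) {
  if (inherits(series_list, "distance_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    cs <- classify_states(s, threshold)
    data.frame(condition = cs$condition, replicate = cs$replicate_id,
               n_frames = length(s$values),
               engaged_fraction = cs$engaged_fraction,
               mean_distance = cs$mean_distance)
  })
  out <- do.call(rbind, rows)
  pooled <- unlist(lapply(series_list, `[[`, "values"))
  rbind(out, data.frame(condition = out$condition[1], replicate = "pooled",
                        n_frames = length(pooled),
                        engaged_fraction = mean(pooled <= threshold),
                        mean_distance = mean(pooled)))
}

#' Tidy per-frame distance table for a set of contacts
#'
#' @param trajs list of [trajectory()] objects
#' @param contacts list of [contact_definition()]
#' @return data.frame with columns condition, replicate, frame, contact_name,
#'   distance_A
#' @export
distance_table <- function(trajs, contacts) {
  rows <- list()
  for (tr in trajs) for (cd in contacts) {
    s <- distance_series(tr, cd)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = s$condition, replicate = s$replicate_id,
      frame = seq_along(s$values), contact_name = s$name,
      distance_A = s$values)
  }
  do.call(rbind, rows)
}
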