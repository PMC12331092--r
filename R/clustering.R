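#' Pairwise RMSD matrix over a selection
#'
#' Frames are optionally superposed once, globally, on `presuperpose`
#' (reference = first frame); the RMSD over `selection` is then computed
#' WITHOUT further per-pair fitting. This matches clustering of a flexible
#' side chain's conformation relative to a fixed (backbone-restrained) body:
#' per-pair refitting would discard exactly the positional signal being
#' clustered.
#'
#' @param traj a [trajectory()]
#' @param selection atoms whose conformation is compared (e.g. the switch
#'   arginine's heavy atoms)
#' @param presuperpose selection for one global superposition, or `NULL`
#' @return symmetric frames x frames matrix of RMSD in Angstrom, zero diagonal
#' @export
pairwise_rmsd <- function(traj, selection, presuperpose = NULL) {
  if (n_frames(traj) < 2L) stop("pairwise RMSD needs at least 2 frames")
  if (!is.null(presuperpose)) traj <- superpose(traj, 1L, presuperpose)
  idx <- sel_indices(selection)
  if (length(idx) == 0L) stop("empty selection")
  m <- length(idx)
  X <- t(apply(traj$coords[, idx, , drop = FALSE], 1,
               function(fr) as.vector(fr)))
  if (n_frames(traj) == 1L) X <- matrix(X, nrow = 1)
  g <- tcrossprod(X)
  sq <- diag(g)
  d2 <- (outer(sq, sq, `+`) - 2 * g) / m
  d2[d2 < 0] <- 0
  mat <- sqrt(d2)
  diag(mat) <- 0
  (mat + t(mat)) / 2
}

#' Greedy quality-threshold clustering of an RMSD matrix
#'
#' The classic trajectory-clustering heuristic: repeatedly pick, among the
#' still-unassigned frames, the frame with the most unassigned neighbours
#' within `cutoff` (ties broken by lowest frame index), make it a cluster
#' centre, assign it together with those neighbours, and remove them; stop
#' when all frames are assigned or `max_clusters` clusters have been formed
#' (remaining frames go to the unassigned pool). By construction cluster
#' sizes are non-increasing and every member lies within `cutoff` of its
#' centre.
#'
#' @param mat symmetric pairwise RMSD matrix with zero diagonal
#' @param cutoff neighbour cutoff in Angstrom (> 0)
#' @param max_clusters maximum number of clusters, `Inf` for unlimited
#' @return object of class `qt_clusters`: `assignment` (per-frame cluster id,
#'   1 = largest, `NA` = unassigned pool), `populations` (percent per
#'   cluster), `unassigned_pct`, `centers` (representative frame index per
#'   cluster), `sizes`, `cutoff`
#' @export
qt_cluster <- function(mat, cutoff, max_clusters = Inf) {
  if (length(mat) == 0L) stop("empty RMSD matrix")
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n != ncol(mat)) stop("RMSD matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8) stop("RMSD matrix must be symmetric")
  if (cutoff <= 0) stop("cutoff must be > 0")
  adj <- mat <= cutoff
  diag(adj) <- FALSE
  unassigned <- rep(TRUE, n)
  assignment <- rep(NA_integer_, n)
  centers <- integer(0)
  k <- 0L
  while (any(unassigned) && k < max_clusters) {
    counts <- colSums(adj[unassigned, , drop = FALSE]) # unassigned neighbours
    counts[!unassigned] <- -1L
    center <- which.max(counts)  # which.max takes the first (lowest index) tie
    members <- which(unassigned & (adj[center, ] | seq_len(n) == center))
    k <- k + 1L
    assignment[members] <- k
    centers[k] <- center
    unassigned[members] <- FALSE
  }
  sizes <- if (k > 0L) tabulate(assignment, nbins = k) else integer(0)
  structure(list(assignment = assignment,
                 populations = 100 * sizes / n,
                 unassigned_pct = 100 * sum(unassigned) / n,
                 centers = centers, sizes = sizes,
                 n_frames = n, cutoff = cutoff),
            class = "qt_clusters")
}

#' @export
print.qt_clusters <- function(x, ...) {
  cat(sprintf("<qt_clusters> %d frames, cutoff %.2f A: %d clusters",
              x$n_frames, x$cutoff, length(x$sizes)))
  if (x$unassigned_pct > 0)
    cat(sprintf(" (+%.1f%% unassigned)", x$unassigned_pct))
  cat("\n")
  for (i in seq_along(x$sizes))
    cat(sprintf("  cluster %d: %5.1f%% (center frame %d)\n",
                i, x$populations[i], x$centers[i]))
  invisible(x)
}

#' Representative (centre) frame of a cluster
#'
#' The representative is the greedy seed of the cluster — the frame that had
#' the most neighbours within the cutoff when the cluster was formed; it is
#' the structure one extracts for docking or for onward simulation.
#'
#' @param result a [qt_cluster()] result
#' @param cluster_id cluster id (1 = largest)
#' @return frame index of the cluster centre
#' @export
representative_frame <- function(result, cluster_id) {
  stopifnot(inherits(result, "qt_clusters"))
  if (!is.numeric(cluster_id) || length(cluster_id) != 1L ||
      is.na(cluster_id) || cluster_id < 1 ||
      cluster_id > length(result$centers))
    stop(sprintf("unknown cluster id '%s' (have %d clusters)",
                 as.character(cluster_id)[1], length(result$centers)))
  result$centers[[cluster_id]]
}

#' Cluster switch-residue conformers of a trajectory
#'
#' Convenience wrapper: pairwise RMSD over the given selection (default:
#' all atoms of residue 394, i.e. the switch arginine's heavy atoms in a
#' hydrogen-free topology) followed by greedy quality-threshold clustering.
#'
#' @param traj a [trajectory()] (typically pooled frames across replicates)
#' @param selection selection to cluster on; default `"resid 394"`
#' @param cutoff RMSD cutoff in Angstrom (3.7 for C-tail rebinding
#'   ensembles, 1.0 for relaxation ensembles)
#' @param presuperpose optional selection for one global superposition
#' @param max_clusters cap on the number of clusters
#' @return a [qt_cluster()] result
#' @export
cluster_conformers <- function(traj, selection = NULL, cutoff = 3.7,
                               presuperpose = NULL, max_clusters = Inf) {
  if (is.null(selection)) selection <- select_atoms(traj$topology, "resid 394")
  mat <- pairwise_rmsd(traj, selection, presuperpose)
  qt_cluster(mat, cutoff, max_clusters)
}

#' Concatenate trajectories into one pooled trajectory
#'
#' Frames are pooled in list order; metadata is taken from the first member
#' with replicate_id `"pooled"`. All members must share the topology size.
#'
#' @param trajs list of [trajectory()] objects
#' @return a pooled [trajectory()]
#' @export
pool_frames <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  na <- vapply(trajs, function(t) n_atoms(t$topology), integer(1))
  if (length(unique(na)) != 1L) stop("trajectories differ in atom count")
  coords <- do.call(abind3, lapply(trajs, `[[`, "coords"))
  trajectory(trajs[[1]]$topology, coords,
             replicate_id = "pooled", condition = trajs[[1]]$condition)
}

# rbind for frames x atoms x 3 arrays
abind3 <- function(...) {
  parts <- list(...)
  nf <- vapply(parts, function(p) dim(p)[1], integer(1))
  out <- array(0, dim = c(sum(nf), dim(parts[[1]])[2], 3))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
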