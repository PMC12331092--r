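#' Build a topology table
#'
#' A topology is an ordered atom table: one row per atom, in the same order
#' as the coordinate dimension of every trajectory bound to it. Residue ids
#' follow the author numbering of the source file (e.g., rat beta-arrestin-2
#' numbering, so the switch arginine is residue 394); no renumbering is ever
#' applied. Atom indices are positional and 1-based.
#'
#' @param atom_name character vector of PDB-style atom names ("CZ", "CG", "P", ...)
#' @param residue_name character vector of residue names ("ARG", "ASP", "SEP", ...)
#' @param residue_id integer vector of author residue numbers
#' @param chain_id single-character chain identifiers
#' @return object of class `topology` (a data.frame)
#' @export
topology <- function(atom_name, residue_name, residue_id, chain_id = "A") {
  n <- length(atom_name)
  if (n == 0L) stop("empty topology: at least one atom is required")
  top <- data.frame(
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    chain_id = rep_len(as.character(chain_id), n),
    stringsAsFactors = FALSE
  )
  if (any(nchar(top$chain_id) != 1L)) stop("chain_id must be single characters")
  class(top) <- c("topology", "data.frame")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(paste(x$chain_id, x$residue_id))),
              paste(unique(x$chain_id), collapse = ",")))
  invisible(x)
}

n_atoms <- function(top) nrow(top)

#' Construct a trajectory
#'
#' Binds a frames x atoms x 3 coordinate array (Angstrom) to a topology,
#' together with replicate/condition metadata used by all downstream
#' ensemble statistics. Frame times in ns are optional and only used to
#' resolve "last T ns" analysis windows.
#'
#' @param topology a [topology()]
#' @param coords numeric array, frames x atoms x 3, finite, in Angstrom
#' @param frame_times optional numeric vector of frame times in ns
#' @param replicate_id string tag of the replicate this trajectory belongs to
#' @param condition string condition label (e.g. "IM+C7pp2", "apo", "E358A")
#' @return object of class `trajectory`
#' @export
trajectory <- function(topology, coords, frame_times = NULL,
                       replicate_id = "rep1", condition = "unspecified") {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1L) stop("trajectory must contain at least one frame")
  if (dim(coords)[2] != n_atoms(topology))
    stop(sprintf("atom-count mismatch: topology has %d atoms, coords have %d",
                 n_atoms(topology), dim(coords)[2]))
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    stop("frame_times length must equal the number of frames")
  structure(
    list(topology = topology, coords = coords, frame_times = frame_times,
         replicate_id = replicate_id, condition = condition),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms [%s / %s]\n",
              n_frames(x), n_atoms(x$topology), x$condition, x$replicate_id))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

pdb_to_topology <- function(pdb, path) {
  at <- pdb$atom
  if (nrow(at) == 0L) stop(sprintf("no ATOM/HETATM records found in '%s'", path))
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != "")) {
    bad <- which(!is.na(ins) & ins != "")[1]
    stop(sprintf("insertion codes are not supported (atom record %d in '%s')",
                 bad, path))
  }
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  topology(at$elety, at$resid, at$resno, ch)
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records, preserving file order. Duplicate atom serials
#' are accepted (indices are positional); insertion codes are rejected.
#'
#' @param path path to a PDB file
#' @return a [topology()]
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop(sprintf(
                    "failed to parse '%s' as PDB: %s", path, conditionMessage(e))))
  pdb_to_topology(pdb, path)
}

#' Read a trajectory from file
#'
#' Multi-model PDB is the canonical format (one MODEL block per frame; a
#' plain single-structure PDB yields a one-frame trajectory). DCD is
#' supported as an optional binary format behind the same interface.
#' Coordinates are returned in Angstrom, frames in file order.
#'
#' @param path path to the trajectory file
#' @param topology optional [topology()] the frames must match; for PDB input
#'   it defaults to the topology parsed from the same file, for DCD it is
#'   required
#' @param format "pdb" (multi-model) or "dcd"
#' @inheritParams trajectory
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path, topology = NULL, format = c("pdb", "dcd"),
                            frame_times = NULL, replicate_id = "rep1",
                            condition = "unspecified") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    top <- pdb_to_topology(pdb, path)
    if (!is.null(topology)) {
      if (n_atoms(topology) != n_atoms(top))
        stop(sprintf("atom-count mismatch: expected %d atoms from topology, found %d in '%s'",
                     n_atoms(topology), n_atoms(top), path))
      top <- topology
    }
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    coords <- aperm(array(t(xyz), dim = c(3L, n_atoms(top), nf)), c(3, 2, 1))
  } else {
    if (is.null(topology)) stop("a topology is required to read DCD trajectories")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * n_atoms(topology))
      stop(sprintf("atom-count mismatch: expected %d atoms, found %d in '%s'",
                   n_atoms(topology), ncol(xyz) %/% 3L, path))
    top <- topology
    nf <- nrow(xyz)
    coords <- aperm(array(t(xyz), dim = c(3L, n_atoms(top), nf)), c(3, 2, 1))
  }
  trajectory(top, coords, frame_times = frame_times,
             replicate_id = replicate_id, condition = condition)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, coordinates at the PDB fixed-width
#' precision of 0.001 Angstrom.
#'
#' @param traj a [trajectory()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj)
  na <- n_atoms(top)
  # bio3d expects frames as rows of x1,y1,z1,x2,...
  xyz <- t(apply(traj$coords, 1, function(fr) as.vector(t(fr))))
  if (nf == 1L) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$residue_id, resid = top$residue_name,
                   eleno = seq_len(na), elety = top$atom_name,
                   chain = top$chain_id)
  invisible(path)
}

# ---- atom selection grammar ---------------------------------------------

sel_keywords <- c("resid", "resname", "name", "chain")

#' Select atoms by a small selection grammar
#'
#' The grammar is a conjunction of clauses joined by `and`; each clause is a
#' keyword followed by one or more values:
#' `resid <int>...`, `resname <name>...`, `name <name>...`, `chain <char>...`.
#' Within a clause values are alternatives (OR); clauses are combined with
#' AND. Example: `"resid 394 and name CZ"` resolves the guanidinium carbon
#' of the switch arginine. Resolution is deterministic; indices are returned
#' sorted ascending and unique (1-based).
#'
#' @param topology a [topology()]
#' @param expression selection string in the grammar above
#' @return object of class `atom_selection`: list with `expression` and
#'   integer `indices`
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "topology"))
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  if (length(toks) == 0L || identical(toks, ""))
    stop("selection syntax error at position 1: empty expression")
  clauses <- list()
  i <- 1L
  expect_keyword <- TRUE
  while (i <= length(toks)) {
    tok <- toks[i]
    if (expect_keyword) {
      if (!tok %in% sel_keywords)
        stop(sprintf("selection syntax error at token %d ('%s'): expected one of %s",
                     i, tok, paste(sel_keywords, collapse = ", ")))
      kw <- tok
      vals <- character(0)
      i <- i + 1L
      while (i <= length(toks) && !toks[i] %in% c("and", sel_keywords)) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      if (length(vals) == 0L)
        stop(sprintf("selection syntax error at token %d: clause '%s' has no values", i, kw))
      clauses[[length(clauses) + 1L]] <- list(keyword = kw, values = vals)
      expect_keyword <- FALSE
    } else {
      if (tok != "and")
        stop(sprintf("selection syntax error at token %d ('%s'): expected 'and'", i, tok))
      i <- i + 1L
      expect_keyword <- TRUE
      if (i > length(toks))
        stop(sprintf("selection syntax error at token %d: dangling 'and'", i))
    }
  }
  keep <- rep(TRUE, nrow(topology))
  for (cl in clauses) {
    keep <- keep & switch(
      cl$keyword,
      resid = {
        ids <- suppressWarnings(as.integer(cl$values))
        if (anyNA(ids))
          stop(sprintf("selection syntax error: non-integer resid value '%s'",
                       cl$values[which(is.na(ids))[1]]))
        topology$residue_id %in% ids
      },
      resname = topology$residue_name %in% cl$values,
      name = topology$atom_name %in% cl$values,
      chain = topology$chain_id %in% cl$values
    )
  }
  idx <- sort(unique(which(keep)))
  if (length(idx) == 0L)
    warning(sprintf("selection '%s' matched no atoms", expression))
  structure(list(expression = expression, indices = idx),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> '%s' -> %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

sel_indices <- function(sel) {
  if (inherits(sel, "atom_selection")) sel$indices
  else if (is.numeric(sel)) as.integer(sel)
  else stop("expected an atom_selection or integer indices")
}

# ---- rigid-body superposition -------------------------------------------

# Kabsch least-squares fit: returns the rotation R and translation such that
# mobile %*% R + t is optimally aligned onto ref (row-vector convention).
kabsch_fit <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cr - as.vector(cm %*% R))
}

check_fit_selection <- function(coords_sel) {
  if (nrow(coords_sel) < 3L)
    stop("superposition requires at least 3 atoms in the fit selection")
  centered <- sweep(coords_sel, 2, colMeans(coords_sel))
  if (qr(centered)$rank < 2L)
    stop("degenerate (collinear) fit selection: rank < 2")
}

#' Superpose trajectory frames on a reference frame
#'
#' Rigid-body least-squares superposition (Kabsch): every frame is rotated
#' and translated so that the RMSD of the fit-selection atoms to the same
#' atoms in the reference frame is minimal. Internal geometry is untouched
#' (all intra-frame distances preserved).
#'
#' @param traj a [trajectory()]
#' @param reference_frame frame index (1-based) used as the fixed reference
#' @param selection an [select_atoms()] result with at least 3 non-collinear
#'   atoms to fit on
#' @return the superposed [trajectory()]
#' @export
superpose <- function(traj, reference_frame = 1L, selection) {
  idx <- sel_indices(selection)
  if (reference_frame < 1L || reference_frame > n_frames(traj))
    stop("reference_frame out of range")
  ref <- traj$coords[reference_frame, idx, , drop = TRUE]
  check_fit_selection(ref)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fit <- kabsch_fit(out[f, idx, , drop = TRUE], ref)
    out[f, , ] <- sweep(out[f, , , drop = TRUE] %*% fit$R, 2, fit$t, `+`)
  }
  traj$coords <- out
  traj
}

# ---- replicate sets and analysis windows --------------------------------

#' Group replicate trajectories of one condition
#'
#' All members must share the same condition and an identical atom ordering.
#' The analysis window is either `"all"` or `"last <T> ns"` (e.g.
#' `"last 50 ns"`), the equilibrated-tail convention used for relaxation
#' runs; resolving a time window requires `frame_times` on every member.
#'
#' @param trajectories list of [trajectory()] objects
#' @param window `"all"` or `"last <T> ns"`
#' @return object of class `replicate_set`
#' @export
replicate_set <- function(trajectories, window = "all") {
  if (length(trajectories) == 0L) stop("replicate set must be non-empty")
  stopifnot(all(vapply(trajectories, inherits, logical(1), "trajectory")))
  conds <- unique(vapply(trajectories, `[[`, character(1), "condition"))
  if (length(conds) != 1L)
    stop("all trajectories in a replicate set must share one condition")
  na <- vapply(trajectories, function(t) n_atoms(t$topology), integer(1))
  if (length(unique(na)) != 1L)
    stop("all trajectories in a replicate set must share the topology size")
  parse_window(window)  # validate early
  structure(list(trajectories = trajectories, window = window,
                 condition = conds),
            class = "replicate_set")
}

parse_window <- function(window) {
  if (identical(window, "all")) return(list(kind = "all"))
  m <- regmatches(window, regexec("^last\\s+([0-9.]+)\\s*ns$", window))[[1]]
  if (length(m) != 2L)
    stop(sprintf("invalid analysis window '%s': use \"all\" or \"last <T> ns\"", window))
  list(kind = "last_ns", t = as.numeric(m[2]))
}

#' Restrict a trajectory to an analysis window
#'
#' @param traj a [trajectory()]
#' @param window `"all"` or `"last <T> ns"`
#' @return the windowed [trajectory()]
#' @export
apply_window <- function(traj, window = "all") {
  w <- parse_window(window)
  if (w$kind == "all") return(traj)
  if (is.null(traj$frame_times))
    stop("a time window requires frame_times on the trajectory")
  t_end <- max(traj$frame_times)
  keep <- which(traj$frame_times > t_end - w$t)
  if (length(keep) == 0L) stop("analysis window selects no frames")
  traj$coords <- traj$coords[keep, , , drop = FALSE]
  traj$frame_times <- traj$frame_times[keep]
  traj
}

windowed_trajectories <- function(rs) {
  lapply(rs$trajectories, apply_window, window = rs$window)
}
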