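# Independent oracles and small fixture builders used across the suite.
# Each oracle is a from-definitions implementation kept deliberately
# separate from the package's code paths.

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# tiny toy trajectory: n frames of m atoms with given coordinates
toy_trajectory <- function(coords, atom_names = NULL, residue_ids = NULL,
                           condition = "toy", replicate_id = "rep1") {
  m <- dim(coords)[2]
  if (is.null(atom_names)) atom_names <- sprintf("C%d", seq_len(m))
  if (is.null(residue_ids)) residue_ids <- seq_len(m)
  top <- topology(atom_names, rep("GLY", m), residue_ids, "A")
  trajectory(top, coords, condition = condition, replicate_id = replicate_id)
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (valid without ties); mirrors the tail-doubling convention
mwu_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  us <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  list(U = u_obs, p = min(1, p))
}

# exhaustive greedy quality-threshold clustering, written from the rule:
# scan unassigned frames in index order, count unassigned neighbours by
# explicit double loop, seed at the first maximum, remove, repeat
qt_oracle <- function(mat, cutoff, max_clusters = Inf) {
  n <- nrow(mat)
  un <- seq_len(n)
  assignment <- rep(NA_integer_, n)
  centers <- integer(0)
  k <- 0L
  while (length(un) > 0L && k < max_clusters) {
    best <- -1L; bi <- NA_integer_
    for (i in un) {
      cnt <- 0L
      for (j in un) if (j != i && mat[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; bi <- i }
    }
    mem <- bi
    for (j in un) if (j != bi && mat[bi, j] <= cutoff) mem <- c(mem, j)
    k <- k + 1L
    assignment[mem] <- k
    centers[k] <- bi
    un <- setdiff(un, mem)
  }
  list(assignment = assignment, centers = centers)
}

# closed-form free ligand for a single site class via the quadratic formula
one_site_free_ligand <- function(l_total, m_total, kd, n = 1) {
  b <- kd + n * m_total - l_total
  (-b + sqrt(b^2 + 4 * kd * l_total)) / 2
}

# brute-force per-frame minimum cross-pair distance
min_cross_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# all intra-frame pairwise distances of a frame matrix (atoms x 3)
frame_distances <- function(fr) as.vector(dist(fr))

# write a minimal hand-rolled PDB (used to test the reader independently
# of the writer)
write_toy_pdb_lines <- function(path, serials = 1:3) {
  lines <- c(
    sprintf("ATOM  %5d  CZ  ARG A 394      10.000  10.000  10.000  1.00  0.00           C", serials[1]),
    sprintf("ATOM  %5d  NH1 ARG A 394      11.200  10.000  10.000  1.00  0.00           N", serials[2]),
    sprintf("ATOM  %5d  NH2 ARG A 394      10.000  11.200  10.000  1.00  0.00           N", serials[3]),
    "END")
  writeLines(lines, path)
  path
}
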