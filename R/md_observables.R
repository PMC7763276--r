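# Trajectory-level estimators: lag-time MSD, per-residue RMSF, geometric
# hydrogen-bond counting and atom-atom contact counting.

#' Trajectory container
#'
#' Coordinates over time plus per-atom metadata, including the
#' donor/acceptor/hydrogen flags used by geometric hydrogen-bond counting.
#'
#' @param coords Numeric array `frames x atoms x 3`, Angstrom.
#' @param dt Frame spacing, ps.
#' @param atoms data.frame with one row per atom: columns `element`,
#'   `resid`, `name`, `is_donor`, `is_acceptor`, `is_hydrogen`.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(coords, dt, atoms) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1L) stop("need at least 1 frame")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (dt <= 0) stop("dt must be > 0")
  need <- c("element", "resid", "name", "is_donor", "is_acceptor",
            "is_hydrogen")
  if (!all(need %in% names(atoms))) stop("atoms missing required columns")
  if (nrow(atoms) != dim(coords)[2]) stop("atoms rows must match coords")
  structure(list(coords = coords, dt = dt, atoms = atoms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ps\n",
              dim(x$coords)[1], dim(x$coords)[2], x$dt))
  invisible(x)
}

#' Lag-time mean square displacement
#'
#' `MSD(tau) = < [r(t + tau) - r(t)]^2 >` averaged over all overlapping time
#' origins and over the selected atoms.  For free diffusion the Einstein
#' relation gives `MSD(tau) = 6 D tau`; for motion confined to a sphere of
#' radius R the long-lag plateau is `(6/5) R^2`.
#'
#' @param traj A [trajectory()].
#' @param tau Lag time, ps; must be a multiple of the frame spacing and
#'   smaller than the trajectory span. Vectorized.
#' @param selection Optional integer or logical atom mask (default: all
#'   atoms).
#' @return MSD values in Angstrom^2, one per `tau`.
#' @export
#' @examples
#' tr <- gen_trajectory("free", list(d = 0.1), n_atoms = 50,
#'                      n_frames = 400, dt = 1, seed = 11)
#' msd_lag(tr, tau = c(5, 10))   # ~ 6 * 0.1 * tau
msd_lag <- function(traj, tau, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  x <- if (is.null(selection)) traj$coords
       else traj$coords[, selection, , drop = FALSE]
  vapply(tau, function(tt) {
    k <- tt / traj$dt
    if (abs(k - round(k)) > 1e-8)
      stop("tau must be a multiple of the frame spacing dt")
    k <- as.integer(round(k))
    if (k < 0 || k >= nf) stop("tau must be in [0, span)")
    if (k == 0L) return(0)
    d <- x[(k + 1):nf, , , drop = FALSE] - x[1:(nf - k), , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is first superposed onto the time-mean structure by
#' least-squares rigid-body fitting (removing global translation/rotation),
#' then the per-atom RMSF about the mean position is computed and averaged
#' within each residue.
#'
#' @param traj A [trajectory()] with at least 10 frames.
#' @param superpose Superpose frames onto the mean structure first
#'   (default TRUE).
#' @return Named numeric vector of RMSF values (Angstrom), one per residue.
#' @export
rmsf_per_residue <- function(traj, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]; na <- dim(traj$coords)[2]
  if (nf < 10L) stop("need at least 10 frames")
  # frames x 3N matrix in bio3d xyz layout (x1 y1 z1 x2 ...)
  xyz <- matrix(aperm(traj$coords, c(3, 2, 1)), nrow = nf, byrow = TRUE)
  if (superpose) {
    for (pass in 1:2) {
      ref <- colMeans(xyz)
      xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                            fixed.inds = seq_len(3 * na),
                            mobile.inds = seq_len(3 * na))
    }
  }
  mu <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mu)^2
  per_atom_ms <- colMeans(dev2[, seq(1, 3 * na, 3), drop = FALSE] +
                            dev2[, seq(2, 3 * na, 3), drop = FALSE] +
                            dev2[, seq(3, 3 * na, 3), drop = FALSE])
  rmsf <- sqrt(per_atom_ms)
  out <- tapply(rmsf, traj$atoms$resid, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Hydrogen-bond geometric criteria
#'
#' @param d_max Donor-acceptor distance cutoff, Angstrom (default 3.2).
#' @param angle_max Maximum deviation of the donor-hydrogen...acceptor
#'   angle from linear, degrees (default 40); must lie in (0, 90).
#' @return An object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(d_max = 3.2, angle_max = 40) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (angle_max <= 0 || angle_max >= 90) stop("angle_max must be in (0, 90)")
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criteria")
}

#' Count geometric hydrogen bonds in one frame
#'
#' A bond is a donor-hydrogen-acceptor triple with donor-acceptor distance
#' at most `d_max` and the D-H...A angle within `angle_max` of linear (the
#' convention of common visualization tools).  Hydrogens are associated to
#' the nearest flagged donor within 1.2 Angstrom; flagged donors without an
#' attached hydrogen are skipped with a warning.
#'
#' @param traj A [trajectory()] with donor/acceptor/hydrogen flags.
#' @param criteria An [hbond_criteria()] object.
#' @param frame Frame index to analyze (default 1).
#' @return Integer count of qualifying triples.
#' @export
count_hbonds <- function(traj, criteria = hbond_criteria(), frame = 1L) {
  stopifnot(inherits(traj, "trajectory"), inherits(criteria, "hbond_criteria"))
  xyz <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  don <- which(traj$atoms$is_donor)
  acc <- which(traj$atoms$is_acceptor)
  hyd <- which(traj$atoms$is_hydrogen)
  if (!length(don) || !length(acc) || !length(hyd)) return(0L)
  count <- 0L
  orphan <- 0L
  cos_min <- cos((180 - criteria$angle_max) * pi / 180)
  for (d in don) {
    dh <- sqrt(colSums((t(xyz[hyd, , drop = FALSE]) - xyz[d, ])^2))
    hs <- hyd[dh <= 1.2]
    if (!length(hs)) { orphan <- orphan + 1L; next }
    da <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
    cand <- acc[da <= criteria$d_max & acc != d]
    if (!length(cand)) next
    for (h in hs) {
      hd_vec <- xyz[d, ] - xyz[h, ]
      for (a in cand) {
        ha_vec <- xyz[a, ] - xyz[h, ]
        ct <- sum(hd_vec * ha_vec) /
          sqrt(sum(hd_vec^2) * sum(ha_vec^2))
        # D-H...A angle >= 180 - angle_max  <=>  cos(angle) <= cos_min
        if (ct <= cos_min) count <- count + 1L
      }
    }
  }
  if (orphan > 0L)
    warning(orphan, " flagged donor(s) without an attached hydrogen skipped")
  count
}

# brute-force cross-group pair count; the oracle for the cell-list version
count_contacts_brute <- function(group_a, group_b, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(group_a))) {
    d2 <- colSums((t(group_b) - group_a[i, ])^2)
    n <- n + sum(d2 <= cutoff^2)
  }
  n
}

#' Count atom-atom contacts between two groups
#'
#' Number of cross-group atom pairs within `cutoff` Angstrom, computed with
#' a cell-list (spatial binning) algorithm so cost scales with the number
#' of neighboring pairs rather than all pairs.
#'
#' @param group_a,group_b Coordinate matrices, `n x 3`, Angstrom.
#' @param cutoff Distance cutoff, Angstrom. Must be > 0.
#' @return Integer pair count.
#' @export
#' @examples
#' a <- matrix(c(0, 0, 0), 1); b <- matrix(c(1.9, 0, 0), 1)
#' count_contacts(a, b, cutoff = 2)
count_contacts <- function(group_a, group_b, cutoff) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!nrow(group_a) || !nrow(group_b)) return(0L)
  origin <- pmin(apply(group_a, 2, min), apply(group_b, 2, min))
  key <- function(m) {
    cells <- floor(sweep(m, 2, origin) / cutoff)
    paste(cells[, 1], cells[, 2], cells[, 3])
  }
  cell_b <- split(seq_len(nrow(group_b)), key(group_b))
  cells_a <- floor(sweep(group_a, 2, origin) / cutoff)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  n <- 0L
  cut2 <- cutoff^2
  for (i in seq_len(nrow(group_a))) {
    neigh <- sweep(offs, 2, cells_a[i, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    js <- unlist(cell_b[keys], use.names = FALSE)
    if (!length(js)) next
    d2 <- colSums((t(group_b[js, , drop = FALSE]) - group_a[i, ])^2)
    n <- n + sum(d2 <= cut2)
  }
  n
}

infer_atom_flags <- function(atoms, xyz1) {
  el <- toupper(substr(trimws(atoms$element), 1, 1))
  is_h <- el == "H"
  polar <- el %in% c("N", "O")
  is_donor <- rep(FALSE, nrow(atoms))
  if (any(polar) && any(is_h)) {
    hpos <- xyz1[is_h, , drop = FALSE]
    for (i in which(polar)) {
      d <- sqrt(colSums((t(hpos) - xyz1[i, ])^2))
      if (any(d <= 1.2)) is_donor[i] <- TRUE
    }
  }
  atoms$is_donor <- is_donor
  atoms$is_acceptor <- polar
  atoms$is_hydrogen <- is_h
  atoms
}

#' Read a multi-model PDB file as a trajectory
#'
#' Uses bio3d for parsing; donor/acceptor/hydrogen flags are inferred from
#' elements (N/O acceptors; N/O with a hydrogen within 1.2 Angstrom in the
#' first frame donors) unless a `flags` table overrides them.
#'
#' @param path PDB file with one MODEL per frame.
#' @param dt Frame spacing, ps.
#' @param flags Optional data.frame with columns `index`, `is_donor`,
#'   `is_acceptor`, `is_hydrogen` overriding the inference.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt = 1, flags = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- aperm(array(t(xyz), c(3, na, nf)), c(3, 2, 1))
  el <- pdb$atom$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el))))
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  atoms <- data.frame(element = trimws(el), resid = pdb$atom$resno,
                      name = trimws(pdb$atom$elety),
                      is_donor = FALSE, is_acceptor = FALSE,
                      is_hydrogen = FALSE)
  atoms <- infer_atom_flags(atoms, coords[1, , , drop = TRUE])
  if (!is.null(flags))
    atoms[flags$index, c("is_donor", "is_acceptor", "is_hydrogen")] <-
      flags[, c("is_donor", "is_acceptor", "is_hydrogen")]
  trajectory(coords, dt = dt, atoms = atoms)
}

#' Read an XYZ frame series as a trajectory
#'
#' Standard multi-frame XYZ: per frame, an atom-count line, a comment line,
#' then `element x y z` records.  Flags are inferred as in
#' [read_trajectory_pdb()].
#'
#' @inheritParams read_trajectory_pdb
#' @return A [trajectory()].
#' @export
read_trajectory_xyz <- function(path, dt = 1, flags = NULL) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); elements <- NULL
  while (pos <= length(lines)) {
    natoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(natoms)) break
    block <- lines[(pos + 2L):(pos + 1L + natoms)]
    fields <- strsplit(trimws(block), "\\s+")
    el <- vapply(fields, `[`, "", 1L)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + natoms
  }
  if (!length(frames)) stop("no frames found in ", path)
  nf <- length(frames); na <- nrow(frames[[1]])
  coords <- array(0, c(nf, na, 3))
  for (i in seq_len(nf)) coords[i, , ] <- frames[[i]]
  atoms <- data.frame(element = elements, resid = seq_len(na),
                      name = elements, is_donor = FALSE,
                      is_acceptor = FALSE, is_hydrogen = FALSE)
  atoms <- infer_atom_flags(atoms, coords[1, , , drop = TRUE])
  if (!is.null(flags))
    atoms[flags$index, c("is_donor", "is_acceptor", "is_hydrogen")] <-
      flags[, c("is_donor", "is_acceptor", "is_hydrogen")]
  trajectory(coords, dt = dt, atoms = atoms)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]; na <- dim(traj$coords)[2]
  con <- file(path, "w"); on.exit(close(con))
  for (t in seq_len(nf)) {
    writeLines(c(as.character(na), sprintf("frame %d", t)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$element,
                       traj$coords[t, , 1], traj$coords[t, , 2],
                       traj$coords[t, , 3]), con)
  }
  invisible(path)
}
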