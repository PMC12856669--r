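# Trajectory post-processing: rigid-body superposition, C-alpha RMSD
# stability windows, medoid ("representative") frame selection, and
# hydrogen-bond occupancy with replicate statistics.
#
# Frames are indexed 1-based throughout (R convention); coordinates are in
# Angstrom.

#' Construct a trajectory object
#'
#' @param xyz Numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param atoms Data frame with one row per atom: `chain`, `resno`, `name`
#'   (atom name, e.g. `"CA"`).  The roster is identical across frames.
#' @param replicate Replicate identifier carried into reports.
#' @return A `trajectory` object.
#' @export
trajectory <- function(xyz, atoms, replicate = 1L) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3,
            dim(xyz)[2] == nrow(atoms),
            all(c("chain", "resno", "name") %in% names(atoms)))
  if (dim(xyz)[1] < 2) stop("a trajectory needs at least 2 frames")
  structure(list(xyz = xyz, atoms = atoms, replicate = replicate),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Coordinates of one frame
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$xyz[i, , ], ncol = 3)
}

#' Select atoms from a trajectory roster
#'
#' @param traj A [trajectory()].
#' @param chain Chain id(s) to keep (default: all).
#' @param atom Atom name(s) to keep, e.g. `"CA"` (default: all).
#' @param drop_terminal Number of residues to drop at each end of each
#'   selected chain ("nonterminal residues"; default 0).
#' @return Integer vector of atom indices (error if empty).
#' @export
select_atoms <- function(traj, chain = NULL, atom = NULL, drop_terminal = 0) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(atom)) keep <- keep & a$name %in% atom
  if (drop_terminal > 0) {
    for (ch in unique(a$chain[keep])) {
      in_ch <- a$chain == ch
      rr <- range(a$resno[in_ch])
      keep <- keep & !(in_ch & (a$resno < rr[1] + drop_terminal |
                                  a$resno > rr[2] - drop_terminal))
    }
  }
  idx <- which(keep)
  if (length(idx) == 0) stop("atom selection is empty")
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing
#' the RMSD between `mobile %*% R + t` and `reference` over the fitted
#' atoms, via singular value decomposition of the cross-covariance matrix.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices.
#' @param fit_idx Atom indices used for the fit (default: all).  At least 3
#'   non-collinear atoms are required.
#' @return A list `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (post-fit, over `fit_idx`), and `apply(x)` transforming any
#'   `n x 3` matrix.
#' @export
superpose <- function(mobile, reference, fit_idx = seq_len(nrow(mobile))) {
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (length(fit_idx) < 3) stop("superposition needs >= 3 atoms")
  X <- mobile[fit_idx, , drop = FALSE]
  Y <- reference[fit_idx, , drop = FALSE]
  # collinearity check: rank of the centered coordinates must be >= 2
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(svd(Xc)$d > 1e-8 * max(svd(Xc)$d, 1e-300)) < 2)
    stop("degenerate (collinear) selection: superposition is ill-posed")
  mx <- colMeans(X); my <- colMeans(Y)
  H <- t(sweep(X, 2, mx)) %*% sweep(Y, 2, my)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  tr <- my - as.vector(mx %*% R)
  fitted <- sweep(X %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd,
       apply = function(x) sweep(x %*% R, 2, tr, "+"))
}

#' RMSD of one frame against another after superposition
#'
#' @param mobile,reference `n_atoms x 3` matrices.
#' @param fit_idx Atoms used both for the fit and the reported RMSD.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, reference, fit_idx = seq_len(nrow(mobile))) {
  superpose(mobile, reference, fit_idx)$rmsd
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is rigid-body superposed onto the reference frame over the
#' selection and the post-fit RMSD over that selection is reported; the
#' element at the reference index is 0.
#'
#' @param traj A [trajectory()].
#' @param sel_idx Atom indices (e.g. from [select_atoms()]).
#' @param reference Reference frame index (default 1).
#' @return Numeric vector of length `n_frames(traj)`, Angstrom.
#' @export
rmsd_series <- function(traj, sel_idx, reference = 1) {
  nf <- n_frames(traj)
  stopifnot(reference >= 1, reference <= nf)
  ref <- frame_coords(traj, reference)
  vapply(seq_len(nf), function(i) {
    if (i == reference) return(0)
    rmsd_fit(frame_coords(traj, i), ref, sel_idx)
  }, numeric(1))
}

#' Detect the longest stable window of an RMSD series
#'
#' Formalizes "a relatively stable portion determined by inspection": the
#' longest contiguous window covering at least `min_fraction` of the frames
#' whose RMSD spread (max - min) does not exceed `max_range`.  Ties are
#' broken toward the latest such window (late-trajectory equilibrated
#' segments are preferred).
#'
#' @param series Numeric RMSD series, Angstrom (length >= 5).
#' @param min_fraction Minimum window length as a fraction of the series
#'   (default 0.2).
#' @param max_range Maximum allowed RMSD spread within the window, Angstrom
#'   (default 1.0).
#' @return A list `start`, `end` (1-based, inclusive), `ok`; `ok = FALSE`
#'   with `NA` bounds when no window qualifies.
#' @export
detect_stable_window <- function(series, min_fraction = 0.2, max_range = 1.0) {
  n <- length(series)
  if (n < 5) stop("series too short (need >= 5 frames)")
  min_len <- max(2L, ceiling(min_fraction * n))
  best <- NULL
  for (s in seq_len(n)) {
    hi <- lo <- series[s]
    for (e in s:n) {
      hi <- max(hi, series[e]); lo <- min(lo, series[e])
      if (hi - lo > max_range) break
      len <- e - s + 1
      if (len >= min_len &&
          (is.null(best) || len > best$len ||
             (len == best$len && s > best$start)))
        best <- list(start = s, end = e, len = len)
    }
  }
  if (is.null(best)) return(list(start = NA_integer_, end = NA_integer_, ok = FALSE))
  list(start = best$start, end = best$end, ok = TRUE)
}

#' Medoid (representative) frame of a stable window
#'
#' After superposing every frame onto a common reference (the window's
#' first frame) over `align_idx` -- fixing the receptor in place so the
#' partner's motion is what is scored -- computes, for each window frame
#' `i`, the metric `sum_n sum_j d_ij^n`: the displacement of each scored
#' atom `n` between frames `i` and `j`, summed over scored atoms and over
#' frames `j`.  The window frame with the lowest metric is the medoid; ties
#' go to the lowest index.
#'
#' @param traj A [trajectory()].
#' @param align_idx Atoms used for the common superposition (e.g.
#'   nonterminal receptor C-alpha atoms).
#' @param score_idx Atoms whose displacements are summed (e.g. partner
#'   C-alpha atoms).
#' @param window `c(start, end)` frame range, 1-based inclusive (default:
#'   all frames).
#' @param all_frames If TRUE, the inner sum over `j` runs over every
#'   trajectory frame rather than only the window (default FALSE:
#'   window-only, matching "similarity within the stable region").
#' @return A list `frame` (absolute 1-based index), `metric` (named vector
#'   of the per-frame sums, Angstrom).
#' @export
medoid_frame <- function(traj, align_idx, score_idx,
                         window = c(1, n_frames(traj)), all_frames = FALSE) {
  nf <- n_frames(traj)
  w <- seq.int(window[1], window[2])
  if (length(w) == 0 || window[1] < 1 || window[2] > nf)
    stop("invalid or empty window")
  jset <- if (all_frames) seq_len(nf) else w
  ref <- frame_coords(traj, w[1])
  need <- sort(unique(c(w, jset)))
  scored <- lapply(need, function(i) {
    fit <- superpose(frame_coords(traj, i), ref, align_idx)
    fit$apply(frame_coords(traj, i))[score_idx, , drop = FALSE]
  })
  names(scored) <- as.character(need)
  metric <- vapply(w, function(i) {
    xi <- scored[[as.character(i)]]
    sum(vapply(jset, function(j) {
      sum(sqrt(rowSums((xi - scored[[as.character(j)]])^2)))
    }, numeric(1)))
  }, numeric(1))
  names(metric) <- as.character(w)
  list(frame = w[which.min(metric)], metric = metric)
}

#' Hydrogen-bond geometric criterion
#'
#' @param donor,hydrogen,acceptor Each a list or vector
#'   `(chain, resno, atom)` naming one atom.
#' @param max_distance Maximum donor-acceptor distance, Angstrom
#'   (default 3.0).
#' @param min_angle Minimum donor-hydrogen-acceptor angle, degrees
#'   (default 135).
#' @return An `hbond_criterion` object.
#' @export
hbond_criterion <- function(donor, hydrogen, acceptor,
                            max_distance = 3.0, min_angle = 135) {
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  as_triple <- function(x) list(chain = as.character(x[[1]]),
                                resno = as.integer(x[[2]]),
                                name = as.character(x[[3]]))
  structure(list(donor = as_triple(donor), hydrogen = as_triple(hydrogen),
                 acceptor = as_triple(acceptor),
                 max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criterion")
}

.find_atom <- function(traj, triple) {
  a <- traj$atoms
  idx <- which(a$chain == triple$chain & a$resno == triple$resno &
                 a$name == triple$name)
  if (length(idx) != 1)
    stop(sprintf("atom (%s, %d, %s) not found uniquely in roster",
                 triple$chain, triple$resno, triple$name))
  idx
}

#' Per-frame hydrogen-bond presence
#'
#' A frame satisfies the bond when the donor-acceptor distance is at most
#' `max_distance` AND the donor-hydrogen-acceptor angle (vertex at the
#' hydrogen) is at least `min_angle`.
#'
#' @param traj A [trajectory()].
#' @param criterion An [hbond_criterion()].
#' @return Logical vector, one element per frame.
#' @export
hbond_present <- function(traj, criterion) {
  iD <- .find_atom(traj, criterion$donor)
  iH <- .find_atom(traj, criterion$hydrogen)
  iA <- .find_atom(traj, criterion$acceptor)
  D <- traj$xyz[, iD, , drop = FALSE]; dim(D) <- c(n_frames(traj), 3)
  H <- traj$xyz[, iH, , drop = FALSE]; dim(H) <- c(n_frames(traj), 3)
  A <- traj$xyz[, iA, , drop = FALSE]; dim(A) <- c(n_frames(traj), 3)
  dDA <- sqrt(rowSums((D - A)^2))
  v1 <- D - H; v2 <- A - H
  cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dDA <= criterion$max_distance & ang >= criterion$min_angle
}

#' Hydrogen-bond occupancy across replicate trajectories
#'
#' Per trajectory, the percentage of frames inside its analysis window that
#' satisfy both the distance and angle conditions; across replicates, the
#' mean and sample standard deviation of these percentages.
#'
#' @param trajs A list of [trajectory()] objects (replicates).
#' @param criterion An [hbond_criterion()].
#' @param windows Optional list of `c(start, end)` windows, one per
#'   trajectory (default: all frames of each).
#' @return A list `per_replicate` (percent occupancies), `mean`, `sd`
#'   (percent; `sd` is `NA` for a single replicate).
#' @export
hbond_occupancy <- function(trajs, criterion, windows = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  occ <- vapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    w <- if (is.null(windows)) c(1, n_frames(tr)) else windows[[k]]
    present <- hbond_present(tr, criterion)[seq.int(w[1], w[2])]
    100 * mean(present)
  }, numeric(1))
  list(per_replicate = occ, mean = mean(occ),
       sd = if (length(occ) > 1) stats::sd(occ) else NA_real_)
}

# ---- multi-model PDB I/O -------------------------------------------------

#' Read a multi-model PDB file as a trajectory
#'
#' Uses `bio3d::read.pdb(multi = TRUE)`; every MODEL becomes a frame.  The
#' atom roster (chain, residue number, atom name) is taken from the first
#' model and must be shared by all.
#'
#' @param path PDB file path.
#' @param replicate Replicate id attached to the trajectory.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, replicate = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyzm <- pdb$xyz                       # n_frames x 3*n_atoms
  if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  nf <- nrow(xyzm); na <- ncol(xyzm) / 3
  xyz <- array(NA_real_, c(nf, na, 3))
  for (d in 1:3) xyz[, , d] <- xyzm[, seq(d, 3 * na, by = 3), drop = FALSE]
  atoms <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                      name = pdb$atom$elety, resid = pdb$atom$resid,
                      stringsAsFactors = FALSE)
  trajectory(xyz, atoms, replicate = replicate)
}

.pdb_atom_lines <- function(coords, atoms) {
  el <- substr(trimws(atoms$name), 1, 1)
  resid <- if ("resid" %in% names(atoms)) atoms$resid else rep("ALA", nrow(atoms))
  # PDB columns: names < 4 chars start in column 14
  aname <- ifelse(nchar(atoms$name) < 4,
                  sprintf(" %-3s", atoms$name), sprintf("%-4s", atoms$name))
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)), aname, resid, atoms$chain, atoms$resno,
          coords[, 1], coords[, 2], coords[, 3], 1.00, 0.00, el)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, standard fixed-width ATOM records.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param frames Frame indices to write (default: all).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, frames = seq_len(n_frames(traj))) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in frames) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.pdb_atom_lines(frame_coords(traj, i), traj$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single frame as a PDB file
#'
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_pdb <- function(traj, i, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.pdb_atom_lines(frame_coords(traj, i), traj$atoms), con)
  writeLines("END", con)
  invisible(path)
}
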