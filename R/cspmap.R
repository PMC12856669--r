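# Chemical-shift-perturbation mapping from paired 1H-15N HSQC peak lists.
#
# Protocol: peaks lost on partner addition are "vanished" and counted as
# affected outright; remaining assignments are transferred to the nearest
# perturbed peak, with ambiguous transfers excluded from analysis; for each
# matched residue an intensity ratio and the composite shift metric
# S = 5|dH| + |dN| are computed; a residue is called affected when its
# intensity ratio falls below half the mean ratio OR its shift metric
# exceeds twice the mean metric.

#' Construct an amide peak list
#'
#' @param residue_id Integer residue numbers (unique).
#' @param dH Proton chemical shifts, ppm.
#' @param dN Nitrogen chemical shifts, ppm.
#' @param intensity Peak intensities, arbitrary units (> 0).
#' @param state State label, e.g. `"dark-alone"`, `"dark+binder"`, `"light"`.
#' @return A `peak_list` data frame.  Shifts outside typical amide windows
#'   (5-12 ppm 1H, 100-140 ppm 15N) raise a warning.
#' @export
peak_list <- function(residue_id, dH, dN, intensity, state = "unspecified") {
  stopifnot(length(residue_id) == length(dH),
            length(dH) == length(dN), length(dN) == length(intensity))
  residue_id <- as.integer(residue_id)
  if (anyDuplicated(residue_id)) stop("residue ids must be unique")
  if (any(intensity <= 0)) stop("intensities must be > 0")
  if (any(dH < 5 | dH > 12) || any(dN < 100 | dN > 140))
    warning("shifts outside typical amide windows (5-12 ppm 1H, 100-140 ppm 15N)")
  structure(data.frame(residue_id = residue_id, dH = dH, dN = dN,
                       intensity = intensity),
            state = state, class = c("peak_list", "data.frame"))
}

#' Read a Sparky-style peak list
#'
#' Whitespace-separated four-column text: assignment label (`<res><num>N-H`,
#' e.g. `R57N-H`), w1 (15N shift, ppm), w2 (1H shift, ppm), intensity.
#' Lines starting with `#` and a leading `Assignment` header line are
#' skipped.  Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @param state State label attached to the returned list.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, state = "unspecified") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^\\s*Assignment", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty peak list: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- idx[vapply(toks, length, 1L) != 4L]
  if (length(bad))
    stop("malformed peak-list line(s) ", paste(bad, collapse = ", "),
         " in ", path, " (expected 4 columns)")
  m <- do.call(rbind, toks)
  lab <- m[, 1]
  hit <- regmatches(lab, regexec("^[A-Za-z]([0-9]+)N-H$", lab))
  ok <- vapply(hit, length, 1L) == 2L
  if (!all(ok))
    stop("unparsable assignment label(s): ", paste(lab[!ok], collapse = ", "))
  res <- as.integer(vapply(hit, `[`, "", 2L))
  if (anyDuplicated(res))
    stop("duplicate residue id(s): ",
         paste(unique(res[duplicated(res)]), collapse = ", "))
  peak_list(residue_id = res,
            dN = as.numeric(m[, 2]), dH = as.numeric(m[, 3]),
            intensity = as.numeric(m[, 4]), state = state)
}

#' Write a Sparky-style peak list
#'
#' Inverse of [read_peak_list()]; one-letter residue code is written as `R`
#' for every residue (the parser keys on the residue number only).
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  lines <- c("      Assignment         w1         w2   Data Height",
             sprintf("%15s %10.4f %10.4f %14.6e",
                     sprintf("R%dN-H", peaks$residue_id),
                     peaks$dN, peaks$dH, peaks$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Composite chemical-shift-perturbation metric
#'
#' `S = 5 |dH| + |dN|`, weighting the proton dimension fivefold to put the
#' two nuclei on a comparable ppm scale.
#'
#' @param delta_H Proton shift change, ppm.
#' @param delta_N Nitrogen shift change, ppm.
#' @return Composite metric, ppm (>= 0).
#' @export
csp_metric <- function(delta_H, delta_N) {
  if (any(!is.finite(delta_H)) || any(!is.finite(delta_N)))
    stop("shift changes must be finite")
  5 * abs(delta_H) + abs(delta_N)
}

#' Match reference and perturbed peak lists
#'
#' Each reference peak is matched to the nearest perturbed peak (by the
#' composite metric `5|dH| + |dN|`) lying within the tolerance box
#' `|dH| <= tol_H`, `|dN| <= tol_N`; when the box is empty but exactly one
#' residual perturbed peak lies within a 3x tolerance box, the assignment is
#' transferred to it (a strongly shifted but still identifiable peak).  A
#' reference peak with no candidate in either box is *vanished*
#' (exchange-broadened beyond detection).  A reference peak with two or more
#' candidates, or a perturbed peak claimed by two or more references, marks
#' the residues involved *ambiguous* and they are excluded from analysis.
#' Perturbed peaks weaker than `intensity_floor` times the median reference
#' intensity are treated as absent when judging vanishing.
#'
#' @param reference,perturbed [peak_list()] objects.
#' @param tol_H,tol_N Matching tolerances, ppm (defaults 0.05 and 0.5).
#' @param intensity_floor Fraction of the median reference intensity below
#'   which a perturbed peak does not count as present (default 0.05).
#' @return A `csp_table` data frame with one row per reference residue:
#'   `residue_id`, `matched`, `vanished`, `ambiguous`, `delta_H`, `delta_N`,
#'   `shift_metric`, `intensity_ratio`, `call` (all `NA` calls; fill with
#'   [call_affected()]).
#' @export
match_peaks <- function(reference, perturbed, tol_H = 0.05, tol_N = 0.5,
                        intensity_floor = 0.05) {
  if (nrow(reference) == 0 || nrow(perturbed) == 0)
    stop("both peak lists must be nonempty")
  floor_abs <- intensity_floor * stats::median(reference$intensity)
  pert <- perturbed[perturbed$intensity >= floor_abs, , drop = FALSE]

  n <- nrow(reference)
  dH <- outer(reference$dH, pert$dH, "-")
  dN <- outer(reference$dN, pert$dN, "-")
  inbox  <- abs(dH) <= tol_H     & abs(dN) <= tol_N
  nearby <- abs(dH) <= 3 * tol_H & abs(dN) <= 3 * tol_N
  metric <- 5 * abs(dH) + abs(dN)

  matched <- vanished <- ambiguous <- logical(n)
  match_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(inbox[i, ])
    if (length(cand) == 0) cand <- which(nearby[i, ])
    if (length(cand) == 0) {
      vanished[i] <- TRUE
    } else if (length(cand) > 1) {
      ambiguous[i] <- TRUE
    } else {
      matched[i] <- TRUE
      match_idx[i] <- cand
    }
  }
  # a perturbed peak claimed by >= 2 references invalidates all claimants;
  # references whose sole candidate fell in another reference's box too
  claims <- table(match_idx[matched])
  contested <- as.integer(names(claims)[claims >= 2])
  if (length(contested)) {
    hit <- matched & match_idx %in% contested
    matched[hit] <- FALSE
    match_idx[hit] <- NA_integer_
    ambiguous[hit] <- TRUE
  }

  delta_H <- delta_N <- s_metric <- ratio <- rep(NA_real_, n)
  j <- match_idx[matched]
  delta_H[matched] <- pert$dH[j] - reference$dH[matched]
  delta_N[matched] <- pert$dN[j] - reference$dN[matched]
  s_metric[matched] <- csp_metric(delta_H[matched], delta_N[matched])
  ratio[matched] <- pert$intensity[j] / reference$intensity[matched]

  structure(data.frame(residue_id = reference$residue_id,
                       matched = matched, vanished = vanished,
                       ambiguous = ambiguous,
                       delta_H = delta_H, delta_N = delta_N,
                       shift_metric = s_metric, intensity_ratio = ratio,
                       call = NA_character_),
            tol_H = tol_H, tol_N = tol_N,
            class = c("csp_table", "data.frame"))
}

#' Call affected residues from a CSP table
#'
#' Vanished residues are affected by definition.  Over matched,
#' non-ambiguous residues the mean intensity ratio `m_I` and mean shift
#' metric `m_S` are computed (vanished and ambiguous residues are excluded
#' from both means); a residue is *affected* when its intensity ratio is
#' strictly below `m_I / 2` or its shift metric strictly above `2 m_S`.
#' Ambiguous residues are called `no-data`.
#'
#' @param table A `csp_table` from [match_peaks()].
#' @return The table with the `call` column filled
#'   (`affected` / `unaffected` / `no-data`) and attributes
#'   `mean_intensity_ratio`, `mean_shift_metric`, `intensity_threshold`,
#'   `shift_threshold`.
#' @export
call_affected <- function(table) {
  use <- table$matched & !table$ambiguous
  if (!any(use)) stop("no matched residues: cannot compute reference means")
  m_I <- mean(table$intensity_ratio[use])
  m_S <- mean(table$shift_metric[use])
  thr_I <- m_I / 2
  thr_S <- 2 * m_S
  call <- rep("no-data", nrow(table))
  call[use] <- ifelse(table$intensity_ratio[use] < thr_I |
                        table$shift_metric[use] > thr_S,
                      "affected", "unaffected")
  call[table$vanished] <- "affected"
  table$call <- call
  attr(table, "mean_intensity_ratio") <- m_I
  attr(table, "mean_shift_metric") <- m_S
  attr(table, "intensity_threshold") <- thr_I
  attr(table, "shift_threshold") <- thr_S
  table
}

#' Affected residues from a called CSP table
#'
#' @param table A `csp_table` with calls filled.
#' @return Sorted integer vector of affected residue numbers.
#' @export
affected_residues <- function(table) {
  if (all(is.na(table$call))) stop("calls not computed: run call_affected() first")
  sort(table$residue_id[table$call == "affected"])
}

#' Export affected residues as docking restraints
#'
#' Writes the affected residue numbers one per line ("active residues" in
#' ambiguous-interaction-restraint terms), with a commented header naming
#' the construct and the numbering convention.  Residues without data are
#' never exported.
#'
#' @param table A called `csp_table`.
#' @param path Output path.
#' @param construct Construct name for the header comment.
#' @return The affected residue vector, invisibly.  An empty file (header
#'   only) plus a warning results when nothing is affected.
#' @export
export_active_residues <- function(table, path, construct = "receptor") {
  act <- affected_residues(table)
  header <- c(sprintf("# active residues of %s (perturbation-affected)", construct),
              "# residue numbering as in the assignment labels, one residue per line")
  writeLines(c(header, as.character(act)), path)
  if (length(act) == 0) warning("no affected residues: wrote an empty restraint file")
  invisible(act)
}

#' Read a restraint file written by [export_active_residues()]
#'
#' @param path File path.
#' @return Sorted integer vector of residue numbers.
#' @export
read_active_residues <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sort(as.integer(lines))
}

#' Overlap statistics between two residue sets
#'
#' @param a,b Integer vectors of residue numbers.
#' @return A list `intersection` (size) and `jaccard` (index; 0 for two
#'   empty sets).
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(intersection = inter, jaccard = if (uni == 0) 0 else inter / uni)
}

#' Write a CSP table as TSV
#'
#' Columns carry units in their headers; thresholds and tolerances are
#' recorded in comment lines.
#'
#' @param table A `csp_table` (called or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csp_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  thr_I <- attr(table, "intensity_threshold")
  if (!is.null(thr_I))
    writeLines(sprintf(
      "# intensity threshold (mean/2) = %.6g; shift threshold (2*mean) = %.6g ppm",
      thr_I, attr(table, "shift_threshold")), con)
  writeLines(paste("residue", "matched", "vanished", "ambiguous",
                   "delta_H_ppm", "delta_N_ppm", "shift_metric_ppm",
                   "intensity_ratio", "call", sep = "\t"), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}
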