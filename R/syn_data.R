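# Synthetic-data generators for every experimental input the pipeline
# consumes: thermal-reversion decay traces, fluorescence titrations,
# paired HSQC peak lists, and toy two-chain trajectories.  Every generator
# records its ground truth so recovery tests are well-posed, and is
# deterministic for a given (parameters, seed) pair.

# run code with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth record for a synthetic dataset
#'
#' @param true_params Named list of the generating parameters, names
#'   matching the consuming module's fields.
#' @param seed Integer RNG seed used.
#' @param noise_sd Noise standard deviation, in the units of the generated
#'   signal.
#' @param warnings Character vector of generation-time caveats (e.g. effect
#'   size below noise).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(true_params, seed, noise_sd, warnings = character()) {
  structure(list(true_params = true_params, seed = as.integer(seed),
                 noise_sd = noise_sd, warnings = warnings),
            class = "ground_truth")
}

#' Serialize a ground truth record to JSON text
#' @param gt A [ground_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground truth record written by [write_ground_truth()]
#' @param path File path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(as.list(x$true_params), x$seed, x$noise_sd,
               as.character(unlist(x$warnings)))
}

#' Generate thermal-reversion decay traces over a binder grid
#'
#' Each trace decays as `A exp(-k_eff t) + c` with `k_eff` given by
#' [effective_rate()] at that binder concentration (rapid-equilibrium
#' light-state binding; free binder approximated by total binder, the
#' excess-binder regime), plus i.i.d. Gaussian noise.  With
#' `rate_law = "linearized"` the rates follow [linearized_k_obs()] instead,
#' i.e. exactly the working law that [fit_reversion_series()] inverts, so
#' that noiseless generation-plus-fit is an identity.
#'
#' @param model A [four_state_model()].
#' @param binder_concs Total binder concentrations, M (>= 0).
#' @param duration Trace duration, s (> 0).
#' @param n_points Points per trace (>= 5).
#' @param noise_sd Gaussian noise SD, signal units (>= 0).
#' @param seed Integer RNG seed.
#' @param amplitude,offset Decay amplitude and baseline, signal units.
#' @param rate_law `"rapid-equilibrium"` (default) or `"linearized"`.
#' @return A list `traces` (list of [kinetic_trace()], one per
#'   concentration) and `ground_truth`.
#' @export
gen_reversion_traces <- function(model, binder_concs, duration, n_points,
                                 noise_sd, seed, amplitude = 1, offset = 0.05,
                                 rate_law = c("rapid-equilibrium", "linearized")) {
  stopifnot(inherits(model, "four_state_model"))
  rate_law <- match.arg(rate_law)
  if (duration <= 0) stop("duration must be > 0")
  if (n_points < 5) stop("n_points must be >= 5")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(binder_concs < 0)) stop("binder concentrations must be >= 0")
  times <- seq(0, duration, length.out = n_points)
  traces <- .with_seed(seed, lapply(binder_concs, function(B) {
    k <- if (rate_law == "linearized")
      linearized_k_obs(model$k_u, model$K_d_dark, B)
    else effective_rate(model, B)
    y <- amplitude * exp(-k * times) + offset +
      stats::rnorm(n_points, sd = noise_sd)
    kinetic_trace(times, y, binder_total = B)
  }))
  gt <- ground_truth(
    list(k_u = model$k_u, k_b = model$k_b, K_d_dark = model$K_d_dark,
         K_d_light = model$K_d_light, binder_concs = binder_concs,
         amplitude = amplitude, offset = offset),
    seed, noise_sd)
  list(traces = traces, ground_truth = gt)
}

#' Generate a 1:1 fluorescence titration series
#'
#' Signal is `F0 + dF * fraction_bound + noise` with the bound fraction from
#' the exact 1:1 mass balance ([fraction_bound_exact()]).
#'
#' @param K_d Dissociation constant, M.
#' @param receptor_total Total receptor concentration, M (> 0).
#' @param binder_grid Total binder concentrations, M (nonempty, >= 0).
#' @param F0 Baseline signal, a.u.
#' @param dF Signal change at saturation, a.u.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param seed Integer RNG seed.
#' @return A list `series` (a [titration_series()]) and `ground_truth`.
#' @export
gen_titration <- function(K_d, receptor_total, binder_grid, F0 = 1, dF = -0.6,
                          noise_sd = 0, seed = 1) {
  if (length(binder_grid) == 0) stop("binder grid must be nonempty")
  if (any(binder_grid < 0)) stop("binder grid must be >= 0")
  if (receptor_total <= 0) stop("receptor_total must be > 0")
  fb <- fraction_bound_exact(K_d, receptor_total, binder_grid)
  y <- .with_seed(seed,
                  F0 + dF * fb + stats::rnorm(length(binder_grid), sd = noise_sd))
  list(series = titration_series(binder_grid, y, receptor_total),
       ground_truth = ground_truth(
         list(K_d = K_d, receptor_total = receptor_total, F0 = F0, dF = dF),
         seed, noise_sd))
}

#' Generate a reference/perturbed pair of HSQC peak lists
#'
#' Reference amide peaks are placed on a seeded, jittered grid spanning the
#' amide region (1H 6.5-10.5 ppm, 15N 103-137 ppm) so that any two peaks
#' are separated by more than the default matching tolerance plus the
#' effect size -- recovery of the ground truth is then well-posed.  In the
#' perturbed list, `affected` residues carry the stated shift change
#' (random sign per dimension) and intensity attenuation, `vanish` residues
#' are absent, and every surviving peak carries Gaussian shift noise and
#' multiplicative intensity noise.
#'
#' @param n_residues Number of residues (reference peaks).
#' @param affected Integer residue ids carrying the perturbation.
#' @param shift_effect Length-2 numeric `(ppm_H, ppm_N)` shift change
#'   applied to affected residues.
#' @param intensity_factor Multiplicative intensity change for affected
#'   residues (e.g. 0.3 = attenuated to 30%).
#' @param vanish Integer residue ids absent from the perturbed list
#'   (vanished residues are affected by definition).
#' @param noise Length-3 numeric `(ppm_H, ppm_N, intensity fraction)`
#'   noise SDs applied to perturbed peaks.
#' @param seed Integer RNG seed.
#' @return A list `reference`, `perturbed` (both [peak_list()]) and
#'   `ground_truth` (whose `warnings` note effect sizes below 3x noise).
#' @export
gen_peak_lists <- function(n_residues, affected = integer(),
                           shift_effect = c(0.05, 0.4),
                           intensity_factor = 1,
                           vanish = integer(),
                           noise = c(0.002, 0.02, 0.02),
                           seed = 1) {
  res <- seq_len(n_residues)
  affected <- as.integer(affected); vanish <- as.integer(vanish)
  if (!all(affected %in% res) || !all(vanish %in% res))
    stop("affected and vanish must be subsets of the residue ids")
  warn <- character()
  if (any(shift_effect > 0) &&
      (shift_effect[1] < 3 * noise[1] || shift_effect[2] < 3 * noise[2]))
    warn <- c(warn, "shift effect below 3x shift noise: calls may not be recoverable")
  if (intensity_factor < 1 && abs(1 - intensity_factor) < 3 * noise[3])
    warn <- c(warn, "intensity effect below 3x intensity noise")

  out <- .with_seed(seed, {
    # grid placement with per-peak jitter; cells are large enough that
    # neighbours stay outside the matching box even after the shift effect
    ncol_g <- ceiling(sqrt(n_residues))
    nrow_g <- ceiling(n_residues / ncol_g)
    cell_H <- 4.0 / ncol_g
    cell_N <- 34.0 / nrow_g
    cells <- sample.int(ncol_g * nrow_g, n_residues)
    ci <- (cells - 1) %% ncol_g
    ri <- (cells - 1) %/% ncol_g
    jit_H <- min(0.05, cell_H / 8)
    jit_N <- min(0.5, cell_N / 8)
    dH <- 6.5 + (ci + 0.5) * cell_H + stats::runif(n_residues, -jit_H, jit_H)
    dN <- 103 + (ri + 0.5) * cell_N + stats::runif(n_residues, -jit_N, jit_N)
    intensity <- exp(stats::rnorm(n_residues, mean = log(1e6), sd = 0.2))
    reference <- peak_list(res, dH, dN, intensity, state = "reference")

    sgnH <- sample(c(-1, 1), n_residues, replace = TRUE)
    sgnN <- sample(c(-1, 1), n_residues, replace = TRUE)
    is_aff <- res %in% affected
    dH2 <- dH + ifelse(is_aff, sgnH * shift_effect[1], 0) +
      stats::rnorm(n_residues, sd = noise[1])
    dN2 <- dN + ifelse(is_aff, sgnN * shift_effect[2], 0) +
      stats::rnorm(n_residues, sd = noise[2])
    int2 <- intensity * ifelse(is_aff, intensity_factor, 1) *
      (1 + stats::rnorm(n_residues, sd = noise[3]))
    keep <- !(res %in% vanish)
    perturbed <- peak_list(res[keep], dH2[keep], dN2[keep],
                           pmax(int2[keep], 1e-12), state = "perturbed")
    list(reference = reference, perturbed = perturbed)
  })
  gt <- ground_truth(
    list(n_residues = n_residues, affected = sort(unique(c(affected, vanish))),
         vanish = sort(vanish), shift_effect = shift_effect,
         intensity_factor = intensity_factor),
    seed, noise_sd = noise, warnings = warn)
  c(out, list(ground_truth = gt))
}

#' Build a toy two-chain template structure
#'
#' A poly-alanine-like pair of helical chains with explicit backbone atoms
#' (N, H, CA, C, O) so hydrogen-bond geometry is well defined and the
#' C-alpha trace is non-collinear (superposition well-posed): chain A (the
#' receptor stand-in) spirals along x around y = 0 and chain B (the
#' partner) around y = 12 Angstrom.
#'
#' @param n_res_A,n_res_B Residues per chain.
#' @param spacing Residue spacing along x, Angstrom.
#' @return A list `coords` (`n_atoms x 3`) and `atoms` (roster data frame).
#' @export
make_template_complex <- function(n_res_A = 20, n_res_B = 10, spacing = 1.5) {
  build_chain <- function(chain, n_res, y0) {
    offs <- list(N = c(-0.5, 0.8, 0), H = c(-0.5, 1.8, 0), CA = c(0, 0, 0),
                 C = c(0.5, -0.5, 0), O = c(0.5, -1.7, 0))
    atoms <- expand.grid(name = names(offs), resno = seq_len(n_res),
                         stringsAsFactors = FALSE)
    coords <- t(vapply(seq_len(nrow(atoms)), function(i) {
      r <- atoms$resno[i]
      phase <- r * 100 * pi / 180        # ~100 deg twist per residue
      c(spacing * r, y0 + 2.3 * cos(phase), 2.3 * sin(phase)) +
        offs[[atoms$name[i]]]
    }, numeric(3)))
    list(coords = coords,
         atoms = data.frame(chain = chain, resno = atoms$resno,
                            name = atoms$name, resid = "ALA",
                            stringsAsFactors = FALSE))
  }
  a <- build_chain("A", n_res_A, 0)
  b <- build_chain("B", n_res_B, 10)
  list(coords = rbind(a$coords, b$coords), atoms = rbind(a$atoms, b$atoms))
}

#' Generate a toy trajectory with drift, a stable phase, and a scheduled
#' hydrogen bond
#'
#' The first `drift_frames` frames translate chain B progressively along x
#' (by `drift_step` Angstrom per frame); the remaining frames jitter about
#' the final pose with i.i.d. Gaussian coordinate noise.  A designated
#' donor-hydrogen-acceptor triple (chain B mid-residue amide N-H donating
#' to a chain A mid-residue carbonyl O) is placed frame by frame to satisfy
#' or violate the default hydrogen-bond criterion according to
#' `hbond_schedule`.
#'
#' @param n_frames Number of frames (> drift_frames).
#' @param template A [make_template_complex()] structure (must contain
#'   chains A and B with N/H/O atoms).
#' @param drift_frames Frames in the drift phase (>= 0).
#' @param jitter_sd Coordinate jitter SD in the stable phase, Angstrom.
#' @param hbond_schedule Logical vector of length `n_frames` (or empty for
#'   no scheduling): TRUE frames satisfy the bond, FALSE frames break it.
#' @param seed Integer RNG seed.
#' @param drift_step Per-frame chain-B translation during drift, Angstrom
#'   (default 4, large enough that drift frames can never join a stable
#'   window at the default 1 Angstrom RMSD spread).
#' @return A list `traj` (a [trajectory()]), `hbond` (the scheduled
#'   [hbond_criterion()]) and `ground_truth` (records the drift schedule,
#'   stable range `c(drift_frames + 1, n_frames)`, and H-bond schedule).
#' @export
gen_toy_trajectory <- function(n_frames, template = make_template_complex(),
                               drift_frames = 0, jitter_sd = 0,
                               hbond_schedule = logical(), seed = 1,
                               drift_step = 4) {
  if (drift_frames >= n_frames) stop("drift_frames must be < n_frames")
  if (length(hbond_schedule) && length(hbond_schedule) != n_frames)
    stop("hbond_schedule must be empty or of length n_frames")
  at <- template$atoms
  need <- list(c("B", "N"), c("B", "H"), c("A", "O"))
  for (nd in need)
    if (!any(at$chain == nd[1] & at$name == nd[2]))
      stop("template lacks required chain/atom: ", nd[1], "/", nd[2])
  resB <- sort(unique(at$resno[at$chain == "B"]))
  resA <- sort(unique(at$resno[at$chain == "A"]))
  rB <- resB[ceiling(length(resB) / 2)]
  rA <- resA[ceiling(length(resA) / 2)]
  iD <- which(at$chain == "B" & at$resno == rB & at$name == "N")
  iH <- which(at$chain == "B" & at$resno == rB & at$name == "H")
  iA <- which(at$chain == "A" & at$resno == rA & at$name == "O")
  crit <- hbond_criterion(donor = c("B", rB, "N"), hydrogen = c("B", rB, "H"),
                          acceptor = c("A", rA, "O"))
  chainB <- at$chain == "B"
  na <- nrow(at)
  xyz <- .with_seed(seed, {
    arr <- array(NA_real_, c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      co <- template$coords
      shift <- if (f <= drift_frames) (f - 1) * drift_step
               else drift_frames * drift_step
      co[chainB, 1] <- co[chainB, 1] + shift
      if (f > drift_frames && jitter_sd > 0)
        co <- co + matrix(stats::rnorm(3 * na, sd = jitter_sd), ncol = 3)
      if (length(hbond_schedule)) {
        u <- co[iH, ] - co[iD, ]
        u <- u / sqrt(sum(u^2))
        co[iA, ] <- co[iD, ] + u * (if (hbond_schedule[f]) 2.8 else 4.5)
      }
      arr[f, , ] <- co
    }
    arr
  })
  gt <- ground_truth(
    list(n_frames = n_frames, drift_frames = drift_frames,
         drift_step = drift_step,
         stable_range = c(drift_frames + 1, n_frames),
         hbond_schedule = hbond_schedule,
         donor_residue = rB, acceptor_residue = rA),
    seed, noise_sd = jitter_sd)
  list(traj = trajectory(xyz, at), hbond = crit, ground_truth = gt)
}

# ---- tabular I/O ---------------------------------------------------------

#' Write a kinetic trace as CSV
#'
#' Header `time_s,signal`; the binder concentration is recorded in a
#' `# binder_M =` comment line.
#'
#' @param trace A [kinetic_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# binder_M = %.10g", attr(trace, "binder_total")), con)
  writeLines("time_s,signal", con)
  utils::write.table(trace, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a kinetic trace CSV written by [write_kinetic_trace()]
#' @param path File path.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path) {
  lines <- readLines(path)
  b <- 0
  m <- regmatches(lines, regexec("^#\\s*binder_M\\s*=\\s*(\\S+)", lines))
  hit <- which(vapply(m, length, 1L) == 2L)
  if (length(hit)) b <- as.numeric(m[[hit[1]]][2])
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  kinetic_trace(df$time_s, df$signal, binder_total = b)
}

#' Write a titration series as CSV
#'
#' Header `binder_M,signal`; the receptor concentration is recorded in a
#' `# receptor_M =` comment line.
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# receptor_M = %.10g", attr(series, "receptor_total")), con)
  writeLines("binder_M,signal", con)
  utils::write.table(series, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a titration CSV written by [write_titration()]
#' @param path File path.
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec("^#\\s*receptor_M\\s*=\\s*(\\S+)", lines))
  hit <- which(vapply(m, length, 1L) == 2L)
  if (!length(hit)) stop("no '# receptor_M =' line in ", path)
  r <- as.numeric(m[[hit[1]]][2])
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  titration_series(df$binder_M, df$signal, receptor_total = r)
}
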