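# End-to-end orchestration: configuration, staged pipeline runs, a combined
# human-readable report and a machine-readable metrics file.
#
# Concentrations are micromolar (uM) at the configuration surface, matching
# how binding studies report them, and molar internally.

#' Default pipeline configuration
#'
#' All stages run on synthetic data generated from the seed; every
#' parameter can be overridden via a config file ([parse_run_config()]) or
#' by editing the returned list.  Concentrations are in uM.
#'
#' @param seed Integer seed controlling every source of randomness.
#' @param out_dir Output directory.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("photoppi_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    kinetics = list(
      k_u = 0.0116,            # 1/s; ~1 min light-state half-life
      K_d_dark_uM = 3,
      K_d_light_uM = 1000,
      binder_uM = c(0, 1, 2, 4, 8),
      duration_s = 300, n_points = 200, noise_sd = 0.005),
    titration = list(
      K_d_uM = 7, receptor_uM = 0.5,
      binder_uM = c(0, 1, 2, 4, 7, 10, 15, 20, 30, 50, 75, 100),
      F0 = 1, dF = -0.6, noise_sd = 0.006),
    csp = list(
      n_residues = 120, n_affected = 15, n_vanish = 3,
      shift_effect = c(0.05, 0.4), intensity_factor = 0.3,
      noise = c(0.002, 0.02, 0.02),
      tol_H = 0.05, tol_N = 0.5),
    traj = list(
      n_replicates = 3, n_frames = 100, drift_frames = 30,
      jitter_sd = 0.3, hbond_occupancy_target = c(96.0, 96.5, 95.8),
      hbond_max_distance = 3.0, hbond_min_angle = 135,
      drop_terminal = 5)
  ), class = "run_config")
}

#' Parse a flat key = value configuration file
#'
#' Sections in square brackets (`[kinetics]`) scope the keys that follow;
#' values are parsed as numeric vectors when possible (comma-separated),
#' otherwise kept as strings.  Keys not present fall back to
#' [default_run_config()] values.
#'
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
parse_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  section <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[i]))
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("\\[|\\]", "", line)
      next
    }
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("config line ", i, " is not 'key = value': ", lines[i])
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    parsed <- if (all(!is.na(num))) num else val
    if (is.null(section)) cfg[[key]] <- parsed
    else cfg[[section]][[key]] <- parsed
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Validate a run configuration
#'
#' Checks types, positivity and any referenced input paths before any
#' computation is attempted.
#'
#' @param config A `run_config`.
#' @return The config, invisibly; errors on the first problem found.
#' @export
validate_run_config <- function(config) {
  if (!is.numeric(config$seed)) stop("config: seed must be an integer")
  for (key in c("kinetics", "titration", "csp", "traj"))
    if (!is.list(config[[key]])) stop("config: missing section [", key, "]")
  paths <- config$input_paths
  if (!is.null(paths))
    for (p in unlist(paths))
      if (!file.exists(p)) stop("config: input path does not exist: ", p)
  if (config$kinetics$k_u <= 0) stop("config: kinetics k_u must be > 0")
  if (config$titration$receptor_uM <= 0)
    stop("config: titration receptor_uM must be > 0")
  invisible(config)
}

.write_config_text <- function(config, path) {
  fmt <- function(v) paste(format(v, digits = 12, trim = TRUE), collapse = ", ")
  out <- c(sprintf("seed = %d", config$seed))
  for (sec in c("kinetics", "titration", "csp", "traj")) {
    out <- c(out, sprintf("[%s]", sec),
             vapply(names(config[[sec]]),
                    function(k) sprintf("%s = %s", k, fmt(config[[sec]][[k]])),
                    ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> fit-kinetics -> fit-titration -> csp -> trajectory
#' stages, writing per-stage outputs, a human-readable `report.txt` and a
#' machine-readable `metrics.json` (which embeds the seed and an MD5 hash
#' of the resolved configuration).  A stage failure aborts with a
#' stage-named message and leaves a `FAILED` marker beside any partial
#' outputs.
#'
#' @param config A `run_config` list or the path of a config file.
#' @return The metrics list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- parse_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  cfg_path <- .write_config_text(config, out("config.txt"))
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stage <- "init"
  on.exit(writeLines(paste("failed at stage:", stage), out("FAILED")))
  log <- function(...) message(sprintf("[%s] ", stage), sprintf(...))
  uM <- 1e-6
  metrics <- list(seed = config$seed, config_md5 = cfg_hash)

  # -- kinetics -------------------------------------------------------
  stage <- "fit-kinetics"
  kin <- config$kinetics
  model <- four_state_model(k_u = kin$k_u, K_d_dark = kin$K_d_dark_uM * uM,
                            K_d_light = kin$K_d_light_uM * uM)
  sim <- gen_reversion_traces(model, kin$binder_uM * uM, kin$duration_s,
                              kin$n_points, kin$noise_sd,
                              seed = config$seed)
  fits <- lapply(sim$traces, fit_exponential)
  bad <- !vapply(fits, `[[`, TRUE, "ok")
  if (any(bad)) stop("fit-kinetics: exponential fit failed for trace(s) ",
                     paste(which(bad), collapse = ", "))
  ser <- reversion_series(vapply(fits, `[[`, 0, "binder_total"),
                          vapply(fits, `[[`, 0, "k_obs"),
                          vapply(fits, `[[`, 0, "k_obs_se"))
  aff <- fit_reversion_series(ser, K_d_light = model$K_d_light)
  if (!aff$ok) stop("fit-kinetics: ", aff$message)
  tab <- cbind(binder_uM = ser$binder_total / uM,
               k_obs_per_s = ser$k_obs, k_obs_se_per_s = ser$k_obs_se)
  utils::write.table(format(tab, digits = 8), out("kinetics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("K_d,D = %.3g uM (k_u = %.4g /s)", aff$K_d_dark_hat / uM, aff$k_u_hat)
  metrics$kinetics <- list(K_d_dark_uM = aff$K_d_dark_hat / uM,
                           K_d_dark_se_uM = aff$K_d_dark_se / uM,
                           k_u_per_s = aff$k_u_hat,
                           half_life_s = half_life(aff$k_u_hat))

  # -- titration ------------------------------------------------------
  stage <- "fit-titration"
  tit <- config$titration
  tsim <- gen_titration(tit$K_d_uM * uM, tit$receptor_uM * uM,
                        tit$binder_uM * uM, tit$F0, tit$dF, tit$noise_sd,
                        seed = config$seed + 1)
  write_titration(tsim$series, out("titration.csv"))
  bfit <- fit_titration(tsim$series)
  if (!bfit$ok) stop("fit-titration: ", bfit$message)
  fold <- fold_selectivity(kin$K_d_light_uM * uM, aff$K_d_dark_hat,
                           light_is_lower_bound = TRUE)
  metrics$titration <- list(K_d_uM = bfit$K_d_hat / uM,
                            K_d_se_uM = bfit$K_d_se / uM,
                            deltaG_kcal_mol = deltaG_from_Kd(bfit$K_d_hat),
                            fold_selectivity_min = fold$value)
  log("K_d = %.3g uM; fold selectivity >= %.3g", bfit$K_d_hat / uM, fold$value)

  # -- csp ------------------------------------------------------------
  stage <- "csp"
  cs <- config$csp
  set.seed(config$seed + 2)
  aff_res <- sort(sample.int(cs$n_residues, cs$n_affected))
  van_res <- sort(sample(aff_res, cs$n_vanish))
  psim <- gen_peak_lists(cs$n_residues, affected = aff_res,
                         shift_effect = cs$shift_effect,
                         intensity_factor = cs$intensity_factor,
                         vanish = van_res, noise = cs$noise,
                         seed = config$seed + 2)
  tbl <- call_affected(match_peaks(psim$reference, psim$perturbed,
                                   tol_H = cs$tol_H, tol_N = cs$tol_N))
  write_csp_table(tbl, out("csp_table.tsv"))
  called <- export_active_residues(tbl, out("active_residues.txt"))
  ov <- set_overlap(called, psim$ground_truth$true_params$affected)
  metrics$csp <- list(n_affected_called = length(called),
                      jaccard_vs_truth = ov$jaccard)
  log("%d affected residues (Jaccard vs truth %.3f)", length(called), ov$jaccard)

  # -- trajectory -----------------------------------------------------
  stage <- "traj"
  tj <- config$traj
  reps <- lapply(seq_len(tj$n_replicates), function(r) {
    sched_frac <- tj$hbond_occupancy_target[r] / 100
    n_on <- round(sched_frac * (tj$n_frames - tj$drift_frames))
    sched <- rep(TRUE, tj$n_frames)
    off <- tj$drift_frames +
      seq_len((tj$n_frames - tj$drift_frames) - n_on)
    sched[off] <- FALSE
    gen_toy_trajectory(tj$n_frames, drift_frames = tj$drift_frames,
                       jitter_sd = tj$jitter_sd, hbond_schedule = sched,
                       seed = config$seed + 2 + r)
  })
  tr1 <- reps[[1]]$traj
  ca_A <- select_atoms(tr1, chain = "A", atom = "CA",
                       drop_terminal = tj$drop_terminal)
  ca_B <- select_atoms(tr1, chain = "B", atom = "CA")
  ca_all <- select_atoms(tr1, atom = "CA")
  series <- rmsd_series(tr1, ca_all)
  win <- detect_stable_window(series)
  if (!win$ok) stop("traj: no stable window found")
  med <- medoid_frame(tr1, ca_A, ca_B, window = c(win$start, win$end))
  write_frame_pdb(tr1, med$frame, out("medoid_frame.pdb"))
  crit <- hbond_criterion(reps[[1]]$hbond$donor, reps[[1]]$hbond$hydrogen,
                          reps[[1]]$hbond$acceptor,
                          max_distance = tj$hbond_max_distance,
                          min_angle = tj$hbond_min_angle)
  occ <- hbond_occupancy(lapply(reps, `[[`, "traj"), crit,
                         windows = rep(list(c(tj$drift_frames + 1, tj$n_frames)),
                                       tj$n_replicates))
  utils::write.table(
    data.frame(frame = seq_along(series), ca_rmsd_A = series),
    out("rmsd_series.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  metrics$traj <- list(stable_window = c(win$start, win$end),
                       medoid_frame = med$frame,
                       hbond_occupancy_pct = occ$per_replicate,
                       hbond_mean_pct = occ$mean, hbond_sd_pct = occ$sd)
  log("stable window %d..%d; medoid frame %d; H-bond %.1f +/- %.2f %%",
      win$start, win$end, med$frame, occ$mean, occ$sd)

  # -- report ---------------------------------------------------------
  stage <- "report"
  jsonlite::write_json(metrics, out("metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rpt <- c(
    "photoswitchable-interaction pipeline report",
    sprintf("seed: %d    config md5: %s", config$seed, cfg_hash),
    "",
    sprintf("[kinetics]  K_d,D = %.3g +/- %.2g uM; k_u = %.4g /s (t1/2 = %.3g s)",
            metrics$kinetics$K_d_dark_uM, metrics$kinetics$K_d_dark_se_uM,
            metrics$kinetics$k_u_per_s, metrics$kinetics$half_life_s),
    sprintf("[titration] K_d = %.3g +/- %.2g uM; dG = %.3g kcal/mol; selectivity >= %.3g-fold",
            metrics$titration$K_d_uM, metrics$titration$K_d_se_uM,
            metrics$titration$deltaG_kcal_mol,
            metrics$titration$fold_selectivity_min),
    sprintf("[csp]       %d affected residues -> active_residues.txt",
            metrics$csp$n_affected_called),
    sprintf("[traj]      stable window %d..%d (frames); medoid frame %d; H-bond occupancy %.1f +/- %.2f %% (n = %d replicates)",
            win$start, win$end, med$frame, occ$mean, occ$sd,
            length(occ$per_replicate)))
  writeLines(rpt, out("report.txt"))
  on.exit()   # clear FAILED marker hook
  invisible(metrics)
}

#' Built-in oracle self-check
#'
#' Re-derives three core results against independent brute-force routes:
#' the medoid frame against an exhaustive double-loop sum on a random toy
#' trajectory, the exact 1:1 bound fraction against the hyperbolic form in
#' the dilute-receptor limit, and the rapid-equilibrium rate against its
#' linearization within the stated validity region.  Failures are
#' reported, never raised.
#'
#' @param seed Seed for the randomized checks.
#' @return Named logical vector (TRUE = pass) of class `selfcheck`.
#' @export
selfcheck <- function(seed = 42) {
  res <- c(medoid_bruteforce = FALSE, quadratic_hyperbolic_limit = FALSE,
           linearization_bound = FALSE)
  try({
    sim <- gen_toy_trajectory(12, make_template_complex(8, 5),
                              drift_frames = 0, jitter_sd = 1.5, seed = seed)
    aidx <- select_atoms(sim$traj, chain = "A", atom = "CA")
    sidx <- select_atoms(sim$traj, chain = "B", atom = "CA")
    med <- medoid_frame(sim$traj, aidx, sidx)
    # brute force: aligned coords, explicit double loop
    ref <- frame_coords(sim$traj, 1)
    al <- lapply(seq_len(n_frames(sim$traj)), function(i)
      superpose(frame_coords(sim$traj, i), ref, aidx)$apply(
        frame_coords(sim$traj, i))[sidx, , drop = FALSE])
    m <- vapply(al, function(xi)
      sum(vapply(al, function(xj) sum(sqrt(rowSums((xi - xj)^2))), 0)), 0)
    res["medoid_bruteforce"] <- which.min(m) == med$frame
  }, silent = TRUE)
  try({
    set.seed(seed)
    Kd <- 10^stats::runif(200, -8, -4)
    B <- Kd * 10^stats::runif(200, -1, 1)
    R <- 0.01 * Kd
    dev <- abs(fraction_bound_exact(Kd, R, B) -
                 fraction_bound_hyperbolic(Kd, B)) /
      fraction_bound_hyperbolic(Kd, B)
    res["quadratic_hyperbolic_limit"] <- all(dev < 0.01)
  }, silent = TRUE)
  try({
    set.seed(seed + 1)
    ok <- replicate(200, {
      KdD <- 10^stats::runif(1, -7, -5)
      KdL <- KdD * 10^stats::runif(1, 1.5, 3)
      m <- four_state_model(k_u = 10^stats::runif(1, -3, -1),
                            K_d_dark = KdD, K_d_light = KdL)
      B <- stats::runif(1, 0, 0.05 * KdL)
      lin <- linearized_k_obs(m$k_u, KdD, B)
      abs(effective_rate(m, B) - lin) / lin <= 0.05
    })
    res["linearization_bound"] <- all(ok)
  }, silent = TRUE)
  class(res) <- c("selfcheck", class(res))
  res
}

#' @export
print.selfcheck <- function(x, ...) {
  for (k in names(x)) cat(sprintf("%s = %s\n", k, ifelse(x[k], "pass", "fail")))
  invisible(x)
}
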