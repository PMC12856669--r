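test_that("superposition is exact for rigidly transformed copies", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  self <- superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  for (i in 1:20) {
    y <- rigid_copy(x)
    fit <- superpose(y, x)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$apply(y), x, tolerance = 1e-9)
  }
})

test_that("superposed RMSD matches direct numerical minimization", {
  # 4-atom toy: one atom displaced by 1 A, the others fixed
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob <- ref
  mob[4, ] <- mob[4, ] + c(1, 0, 0)
  got <- superpose(mob, ref)$rmsd
  # oracle: brute-force minimization over Euler angles + translation
  obj <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    sqrt(mean(rowSums((sweep(mob %*% t(R), 2, p[4:6], "+") - ref)^2)))
  }
  oracle <- optim(rep(0, 6), obj, method = "BFGS",
                  control = list(reltol = 1e-14))$value
  expect_equal(got, oracle, tolerance = 1e-6)
  # and against the reference implementation in bio3d (rounds to 3 dp)
  b3d <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)), fit = TRUE)
  expect_equal(round(got, 3), b3d)
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear|degenerate")
  x <- matrix(rnorm(30), ncol = 3)
  expect_error(superpose(x, x, fit_idx = 1:2), ">= 3")
})

test_that("RMSD series is zero for static frames and rises through drift", {
  sim0 <- gen_toy_trajectory(10, drift_frames = 0, jitter_sd = 0, seed = 1)
  ca <- select_atoms(sim0$traj, atom = "CA")
  expect_equal(rmsd_series(sim0$traj, ca), rep(0, 10), tolerance = 1e-9)

  sim <- gen_toy_trajectory(40, drift_frames = 20, jitter_sd = 0.1, seed = 2)
  s <- rmsd_series(sim$traj, select_atoms(sim$traj, atom = "CA"))
  expect_true(all(diff(s[1:20]) > 0))
})

test_that("RMSD series is invariant to atom ordering in the roster", {
  sim <- gen_toy_trajectory(8, drift_frames = 3, jitter_sd = 0.2, seed = 5)
  tr <- sim$traj
  set.seed(9)
  perm <- sample(nrow(tr$atoms))
  tr2 <- trajectory(tr$xyz[, perm, , drop = FALSE], tr$atoms[perm, ])
  s1 <- rmsd_series(tr, select_atoms(tr, atom = "CA"))
  s2 <- rmsd_series(tr2, select_atoms(tr2, atom = "CA"))
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("stable window detection matches its definition and an exhaustive search", {
  expect_equal(detect_stable_window(rep(0, 10))[c("start", "end")],
               list(start = 1L, end = 10L))
  # forced example: only the final low-spread stretch qualifies
  w <- detect_stable_window(c(5, 4, 3, 1.0, 1.1, 0.9, 1.0), max_range = 0.5)
  expect_equal(c(w$start, w$end), c(4, 7))
  expect_error(detect_stable_window(c(1, 2)), "short")
  no <- detect_stable_window(seq(0, 50, length.out = 10), max_range = 0.5)
  expect_false(no$ok)

  for (seed in 1:20) {
    set.seed(seed)
    s <- cumsum(rnorm(30, sd = 0.4))
    got <- detect_stable_window(s, min_fraction = 0.2, max_range = 1.0)
    want <- oracle_stable_window(s, min_fraction = 0.2, max_range = 1.0)
    if (is.null(want)) expect_false(got$ok)
    else expect_equal(c(got$start, got$end), want)
  }
})

test_that("medoid frame minimizes the summed-displacement metric", {
  # all frames identical: metric zero everywhere, tie -> first window frame
  sim0 <- gen_toy_trajectory(6, drift_frames = 0, jitter_sd = 0, seed = 1)
  ca_A <- select_atoms(sim0$traj, chain = "A", atom = "CA")
  ca_B <- select_atoms(sim0$traj, chain = "B", atom = "CA")
  expect_equal(medoid_frame(sim0$traj, ca_A, ca_B, window = c(2, 6))$frame, 2)

  # 3 frames, 1 scored atom at 0/1/10 A along a line, alignment identity:
  # summed displacements are 11/10/19, so the middle frame wins
  tpl <- make_template_complex(n_res_A = 3, n_res_B = 1)
  xyz <- array(rep(tpl$coords, each = 3), c(3, nrow(tpl$atoms), 3))
  scored <- which(tpl$atoms$chain == "B" & tpl$atoms$name == "CA")
  xyz[1, scored, 1] <- 0; xyz[2, scored, 1] <- 1; xyz[3, scored, 1] <- 10
  tr <- trajectory(xyz, tpl$atoms)
  med <- medoid_frame(tr, select_atoms(tr, chain = "A", atom = "CA"), scored)
  expect_equal(med$frame, 2)
  expect_equal(unname(med$metric), c(11, 10, 19), tolerance = 1e-9)
})

test_that("medoid equals the exhaustive double-loop oracle on random toys", {
  for (seed in 1:10) {
    tr <- random_toy_traj(n_frames_ = 12, n_atoms_b = 8, seed = seed)
    aidx <- select_atoms(tr, chain = "A", atom = "CA")
    sidx <- select_atoms(tr, chain = "B", atom = "CA")
    expect_equal(medoid_frame(tr, aidx, sidx, window = c(2, 11))$frame,
                 oracle_medoid(tr, aidx, sidx, window = c(2, 11)))
    # all-frames variant of the inner sum
    expect_equal(
      medoid_frame(tr, aidx, sidx, window = c(3, 10), all_frames = TRUE)$frame,
      oracle_medoid(tr, aidx, sidx, window = c(3, 10), all_frames = TRUE))
  }
})

test_that("medoid choice is invariant under a global rigid transformation", {
  tr <- random_toy_traj(n_frames_ = 10, n_atoms_b = 6, seed = 3)
  aidx <- select_atoms(tr, chain = "A", atom = "CA")
  sidx <- select_atoms(tr, chain = "B", atom = "CA")
  base <- medoid_frame(tr, aidx, sidx)$frame
  set.seed(4)
  R <- random_rotation(); t <- rnorm(3, sd = 20)
  xyz2 <- tr$xyz
  for (f in seq_len(n_frames(tr)))
    xyz2[f, , ] <- sweep(matrix(tr$xyz[f, , ], ncol = 3) %*% R, 2, t, "+")
  expect_equal(medoid_frame(trajectory(xyz2, tr$atoms), aidx, sidx)$frame, base)
})

test_that("hydrogen-bond occupancy follows the schedule and the cutoffs", {
  sim <- gen_toy_trajectory(4, drift_frames = 0, jitter_sd = 0,
                            hbond_schedule = c(TRUE, FALSE, TRUE, FALSE),
                            seed = 1)
  occ <- hbond_occupancy(sim$traj, sim$hbond)
  expect_equal(occ$mean, 50)

  always <- gen_toy_trajectory(6, drift_frames = 0, jitter_sd = 0,
                               hbond_schedule = rep(TRUE, 6), seed = 1)
  occ3 <- hbond_occupancy(list(always$traj, always$traj, always$traj),
                          always$hbond)
  expect_equal(occ3$mean, 100)
  expect_equal(occ3$sd, 0)

  # monotone: tighter distance or higher angle can only lower occupancy
  jig <- gen_toy_trajectory(50, drift_frames = 0, jitter_sd = 0.25, seed = 8)
  tri <- jig$hbond
  occ_at <- function(d, a) hbond_occupancy(
    jig$traj, hbond_criterion(tri$donor, tri$hydrogen, tri$acceptor,
                              max_distance = d, min_angle = a))$mean
  dists <- c(3.5, 3.0, 2.5); angs <- c(120, 135, 160)
  expect_true(all(diff(vapply(dists, occ_at, 0, a = 135)) <= 0))
  expect_true(all(diff(vapply(angs, occ_at, 0, d = 3.0))  <= 0))
  expect_error(hbond_occupancy(jig$traj,
    hbond_criterion(c("B", 99, "N"), c("B", 99, "H"), c("A", 1, "O"))),
    "not found")
})

test_that("multi-model PDB output re-reads as the same trajectory", {
  sim <- gen_toy_trajectory(5, drift_frames = 2, jitter_sd = 0.2, seed = 13)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(sim$traj, f)
  back <- read_trajectory_pdb(f)
  expect_equal(n_frames(back), 5)
  expect_equal(back$atoms$chain, sim$traj$atoms$chain)
  expect_equal(back$atoms$resno, sim$traj$atoms$resno)
  expect_equal(back$atoms$name, sim$traj$atoms$name)
  expect_equal(back$xyz, sim$traj$xyz, tolerance = 1e-3)  # PDB prints 3 dp

  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_frame_pdb(sim$traj, 3, f1)
  one <- bio3d::read.pdb(f1, verbose = FALSE)
  expect_equal(matrix(one$xyz, ncol = 3, byrow = TRUE),
               frame_coords(sim$traj, 3), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("atom selection honours chains, names and terminal trimming", {
  sim <- gen_toy_trajectory(3, seed = 1)
  tr <- sim$traj
  ca_A <- select_atoms(tr, chain = "A", atom = "CA")
  expect_equal(length(ca_A), 20)
  trimmed <- select_atoms(tr, chain = "A", atom = "CA", drop_terminal = 5)
  expect_equal(length(trimmed), 10)
  expect_true(all(tr$atoms$resno[trimmed] %in% 6:15))
  expect_error(select_atoms(tr, chain = "Z"), "empty")
})
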