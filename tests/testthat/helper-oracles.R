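# Independent brute-force oracles and small fixtures shared across tests.

default_model <- function() {
  four_state_model(k_u = 0.0116, K_d_dark = 3e-6, K_d_light = 1e-3)
}

# exhaustive O(F^2 N) medoid: explicit double loop over aligned coordinates
oracle_medoid <- function(traj, align_idx, score_idx,
                          window = c(1, n_frames(traj)), all_frames = FALSE) {
  w <- seq.int(window[1], window[2])
  jset <- if (all_frames) seq_len(n_frames(traj)) else w
  ref <- frame_coords(traj, w[1])
  al <- lapply(seq_len(n_frames(traj)), function(i)
    superpose(frame_coords(traj, i), ref, align_idx)$apply(
      frame_coords(traj, i))[score_idx, , drop = FALSE])
  metric <- sapply(w, function(i) {
    s <- 0
    for (j in jset)
      for (n in seq_along(score_idx))
        s <- s + sqrt(sum((al[[i]][n, ] - al[[j]][n, ])^2))
    s
  })
  w[which.min(metric)]
}

# exhaustive stable-window search: try every (start, end) pair
oracle_stable_window <- function(series, min_fraction = 0.2, max_range = 1.0) {
  n <- length(series)
  min_len <- max(2L, ceiling(min_fraction * n))
  best <- NULL
  for (s in seq_len(n)) for (e in s:n) {
    len <- e - s + 1
    if (len < min_len) next
    if (diff(range(series[s:e])) > max_range) next
    if (is.null(best) || len > best[3] || (len == best[3] && s > best[1]))
      best <- c(s, e, len)
  }
  if (is.null(best)) NULL else best[1:2]
}

# random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random rigid-motion copy of an n x 3 coordinate matrix
rigid_copy <- function(x) {
  R <- random_rotation()
  sweep(x %*% R, 2, rnorm(3, sd = 10), "+")
}

# small random toy trajectory for medoid-oracle comparisons
random_toy_traj <- function(n_frames_ = 20, n_atoms_b = 30, seed = 1) {
  set.seed(seed)
  tpl <- make_template_complex(n_res_A = 10, n_res_B = n_atoms_b)
  na <- nrow(tpl$atoms)
  xyz <- array(NA_real_, c(n_frames_, na, 3))
  chainB <- tpl$atoms$chain == "B"
  for (f in seq_len(n_frames_)) {
    co <- tpl$coords
    co[chainB, ] <- co[chainB, ] + matrix(rnorm(sum(chainB) * 3, sd = 2),
                                          ncol = 3)
    co <- co + matrix(rnorm(na * 3, sd = 0.2), ncol = 3)
    xyz[f, , ] <- co
  }
  trajectory(xyz, tpl$atoms)
}
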