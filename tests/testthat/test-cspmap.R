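make_table <- function(ratio, metric, vanished = rep(FALSE, length(ratio)),
                       ambiguous = rep(FALSE, length(ratio))) {
  n <- length(ratio)
  structure(data.frame(residue_id = seq_len(n),
                       matched = !vanished & !ambiguous,
                       vanished = vanished, ambiguous = ambiguous,
                       delta_H = rep(0, n), delta_N = rep(0, n),
                       shift_metric = metric, intensity_ratio = ratio,
                       call = rep(NA_character_, n)),
            class = c("csp_table", "data.frame"))
}

test_that("Sparky-style peak lists parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("      Assignment         w1         w2   Data Height",
               "R57N-H 120.0 8.20 1.0e6",
               "G58N-H 108.5 7.95 8.5e5"), f)
  pl <- read_peak_list(f)
  expect_equal(pl$residue_id, c(57L, 58L))
  expect_equal(pl$dN[1], 120.0)
  expect_equal(pl$dH[1], 8.20)
  expect_equal(pl$intensity[1], 1e6)

  f2 <- withr::local_tempfile(fileext = ".list")
  write_peak_list(pl, f2)
  pl2 <- read_peak_list(f2)
  expect_equal(pl2$residue_id, pl$residue_id)
  expect_equal(pl2$dH, pl$dH, tolerance = 1e-4)
  expect_equal(pl2$intensity, pl$intensity, tolerance = 1e-6)
})

test_that("malformed peak lists are rejected with informative errors", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  expect_error(read_peak_list(f), "empty")
  writeLines(c("R57N-H 120.0 8.20 1e6", "R57N-H 121.0 8.40 1e6"), f)
  expect_error(read_peak_list(f), "duplicate")
  writeLines("whatisthis 120.0 8.20 1e6", f)
  expect_error(read_peak_list(f), "whatisthis")
  writeLines("R57N-H 120.0 8.20", f)
  expect_error(read_peak_list(f), "line")
})

test_that("composite shift metric weights the proton dimension fivefold", {
  expect_equal(csp_metric(0, 0), 0)
  expect_equal(csp_metric(0.02, 0.10), 0.20)
  expect_equal(csp_metric(-0.03, -0.7), csp_metric(0.03, 0.7))
  expect_error(csp_metric(NA, 0))
})

test_that("peak matching classifies matched, vanished and ambiguous residues", {
  ref <- peak_list(c(10, 20, 30), dH = c(8.20, 7.60, 9.10),
                   dN = c(120.0, 112.0, 126.0), intensity = c(1e6, 1e6, 1e6))
  # residue 10 moves slightly; residue 20 vanishes; residue 30 unmoved
  pert <- peak_list(c(10, 30), dH = c(8.21, 9.10), dN = c(120.2, 126.0),
                    intensity = c(9e5, 1e6))
  tab <- match_peaks(ref, pert)
  expect_equal(tab$matched, c(TRUE, FALSE, TRUE))
  expect_equal(tab$vanished, c(FALSE, TRUE, FALSE))
  expect_equal(tab$delta_H[1], 0.01, tolerance = 1e-9)
  expect_equal(tab$delta_N[1], 0.2, tolerance = 1e-9)

  # two perturbed candidates inside one reference box: ambiguous, no data
  pert2 <- peak_list(c(1, 2), dH = c(8.19, 8.22), dN = c(120.1, 119.9),
                     intensity = c(1e6, 1e6))
  tab2 <- match_peaks(ref, pert2)
  expect_true(tab2$ambiguous[1])
  expect_false(tab2$matched[1])

  # one perturbed peak claimed by two references: both ambiguous
  ref3 <- peak_list(c(1, 2), dH = c(8.20, 8.23), dN = c(120.0, 120.1),
                    intensity = c(1e6, 1e6))
  pert3 <- peak_list(1, dH = 8.215, dN = 120.05, intensity = 1e6)
  tab3 <- match_peaks(ref3, pert3)
  expect_true(all(tab3$ambiguous))
})

test_that("affected calls follow the mean/2 and 2x-mean thresholds exactly", {
  t1 <- call_affected(make_table(ratio = c(1.0, 0.9, 0.95, 1.05, 0.30),
                                 metric = rep(0.001, 5)))
  expect_equal(attr(t1, "mean_intensity_ratio"), 0.84)
  expect_equal(attr(t1, "intensity_threshold"), 0.42)
  expect_equal(t1$call, c(rep("unaffected", 4), "affected"))

  t2 <- call_affected(make_table(ratio = rep(1, 5),
                                 metric = c(0.01, 0.01, 0.01, 0.01, 0.30)))
  expect_equal(attr(t2, "mean_shift_metric"), 0.068)
  expect_equal(attr(t2, "shift_threshold"), 0.136)
  expect_equal(t2$call, c(rep("unaffected", 4), "affected"))

  # strict thresholds: a residue sitting exactly on a threshold is unaffected
  t3 <- call_affected(make_table(ratio = c(1, 1, 1, 0.75), metric = rep(0, 4)))
  expect_equal(attr(t3, "intensity_threshold"), 0.46875)
  expect_equal(t3$call[4], "unaffected")  # 0.75 > 0.46875
})

test_that("vanished implies affected; ambiguous implies no-data and exclusion", {
  tab <- make_table(ratio = c(1, 1, NA, NA), metric = c(0.01, 0.01, NA, NA),
                    vanished = c(FALSE, FALSE, TRUE, FALSE),
                    ambiguous = c(FALSE, FALSE, FALSE, TRUE))
  out <- call_affected(tab)
  expect_equal(out$call, c("unaffected", "unaffected", "affected", "no-data"))
  # means computed from the two matched residues only
  expect_equal(attr(out, "mean_intensity_ratio"), 1)
  expect_error(call_affected(make_table(numeric(), numeric())), "matched")
})

test_that("calls are invariant to uniform intensity rescaling", {
  sim <- gen_peak_lists(60, affected = c(5, 12, 40), intensity_factor = 0.2,
                        seed = 31)
  base <- call_affected(match_peaks(sim$reference, sim$perturbed))
  for (s in c(1e-3, 7, 1e4)) {
    ref2 <- sim$reference; ref2$intensity <- ref2$intensity * s
    pert2 <- sim$perturbed; pert2$intensity <- pert2$intensity * s
    out <- call_affected(match_peaks(ref2, pert2))
    expect_identical(out$call, base$call)
  }
})

test_that("adding a typical unaffected residue does not flip calls", {
  sim <- gen_peak_lists(60, affected = c(5, 12, 40), intensity_factor = 0.2,
                        seed = 7)
  base <- call_affected(match_peaks(sim$reference, sim$perturbed))
  # append one residue with exactly average behaviour, far from the others
  ref2 <- rbind(as.data.frame(sim$reference),
                data.frame(residue_id = 61L, dH = 11.5, dN = 139,
                           intensity = 1e6))
  pert2 <- rbind(as.data.frame(sim$perturbed),
                 data.frame(residue_id = 61L, dH = 11.5, dN = 139,
                            intensity = 1e6 * attr(base, "mean_intensity_ratio")))
  out <- suppressWarnings(
    call_affected(match_peaks(
      peak_list(ref2$residue_id, ref2$dH, ref2$dN, ref2$intensity),
      peak_list(pert2$residue_id, pert2$dH, pert2$dN, pert2$intensity))))
  expect_identical(out$call[seq_len(60)], base$call)
})

test_that("synthetic recall: well-separated effects are recovered exactly", {
  truth <- c(3L, 17L, 25L, 44L, 58L, 59L, 94L)
  sim <- gen_peak_lists(100, affected = truth, vanish = c(58, 94),
                        intensity_factor = 0.3, seed = 11)
  tab <- call_affected(match_peaks(sim$reference, sim$perturbed))
  expect_identical(affected_residues(tab), sort(truth))
  # vanished residues are called affected, always
  expect_true(all(tab$call[tab$residue_id %in% c(58, 94)] == "affected"))
})

test_that("restraint export round-trips and skips no-data residues", {
  tab <- make_table(ratio = c(1, 1, 1, 0.1, NA), metric = c(0, 0, 0, 0, NA),
                    ambiguous = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- call_affected(tab)
  f <- withr::local_tempfile(fileext = ".txt")
  act <- export_active_residues(out, f, construct = "receptor(1052-1206)")
  expect_equal(act, 4L)
  expect_identical(read_active_residues(f), 4L)
  expect_match(readLines(f)[1], "receptor\\(1052-1206\\)")

  none <- call_affected(make_table(ratio = c(1, 1, 1), metric = c(0, 0, 0)))
  expect_warning(export_active_residues(none, f), "empty")
  expect_length(read_active_residues(f), 0)
})

test_that("set overlap statistics are standard", {
  expect_equal(set_overlap(c(1, 2, 3), c(2, 3, 4)),
               list(intersection = 2L, jaccard = 0.5))
  expect_equal(set_overlap(1:3, 4:6)$jaccard, 0)
  expect_equal(set_overlap(1:5, 1:5), list(intersection = 5L, jaccard = 1))
})
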