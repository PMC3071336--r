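oc <- load_fixture("table7_oc")
noc <- load_fixture("table7_noc")

test_that("value_at returns grid values exactly and interpolates linearly", {
  expect_identical(value_at(oc, 5, "resistance"), 0.72)
  expect_identical(value_at(oc, 25, "reactance"), 0.11)
  s <- ios_spectrum(c(10, 20), c(0.5, 0.3), c(-0.1, 0.05))
  expect_equal(value_at(s, 15, "resistance"), 0.4)
  expect_error(value_at(ios_spectrum(c(3, 35), c(1, 1), c(0, 0)), 2),
               class = "iosmodel_out_of_range")
  expect_error(value_at(oc, 36, "reactance"), class = "iosmodel_out_of_range")
})

test_that("fdR equals R5 - R20 on the averaged impaired-group spectra", {
  expect_equal(compute_fdr(oc), 0.31)
  expect_equal(compute_fdr(noc), 0.31)
  flat <- ios_spectrum(c(3, 5, 10, 20), rep(0.5, 4), c(-0.2, -0.1, 0, 0.1))
  expect_equal(compute_fdr(flat), 0)
})

test_that("resonant frequency is the first interpolated zero crossing", {
  # hand interpolation between the 15 and 20 Hz cells: 15 + 5 * 0.12/0.14
  expect_equal(compute_fres(oc), 15 + 5 * 0.12 / 0.14, tolerance = 1e-12)
  exact <- ios_spectrum(c(5, 10, 15), c(0.5, 0.4, 0.35), c(-0.2, -0.1, 0))
  expect_identical(compute_fres(exact), 15)
  allneg <- ios_spectrum(c(5, 10, 15), c(0.5, 0.4, 0.35), c(-0.3, -0.2, -0.1))
  expect_true(is.na(compute_fres(allneg)))
  # first crossing wins with noisy multiple sign changes
  noisy <- ios_spectrum(c(5, 10, 15, 20, 25), c(0.5, 0.45, 0.4, 0.38, 0.36),
                        c(-0.2, 0.1, -0.05, 0.1, 0.2))
  expect_equal(compute_fres(noisy), 5 + 5 * 0.2 / 0.3)
})

test_that("reactance area follows the trapezoid-with-triangle construction", {
  tri <- ios_spectrum(c(5, 10, 15), c(0.5, 0.4, 0.35), c(-1, -0.5, 0))
  expect_equal(compute_ax(tri), 5.0)  # triangle: 0.5 * 10 * 1
  # hand trapezoid on the averaged spectrum: 1.325 + 0.825 + 0.2571
  expect_equal(compute_ax(oc), 1.325 + 0.825 + 0.5 * 0.12 * (5 * 0.12 / 0.14),
               tolerance = 1e-12)
  pos <- ios_spectrum(c(5, 10), c(0.5, 0.4), c(0.1, 0.2))
  expect_identical(compute_ax(pos), 0)
  allneg <- ios_spectrum(c(5, 10, 35), c(0.5, 0.4, 0.35), c(-0.3, -0.2, -0.1))
  expect_true(is.na(compute_ax(allneg)))
})

test_that("reactance area matches a fine-grid numeric integral", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    p <- c(Rc = 0.4, I = 0.0018, Rp = runif(1, 0.6, 1), Cp = runif(1, 0.03, 0.08))
    s <- eval_eric(p, c(3, 5, 10, 15, 20, 25, 35))
    fres <- compute_fres(s)
    expect_equal(compute_ax(s), brute_ax(s, fres), tolerance = 1e-6)
  }
})

test_that("compute_indices bundles the per-spectrum indices", {
  idx <- compute_indices(oc)
  expect_equal(idx$r5, 0.72)
  expect_equal(idx$r20, 0.41)
  expect_equal(idx$fdr, 0.31)
  expect_equal(idx$x5, -0.32)
  expect_equal(idx$fres, 19.2857, tolerance = 1e-4)
  expect_equal(idx$ax, 2.4071, tolerance = 1e-4)
  expect_identical(idx$fdr, idx$r5 - idx$r20)

  # Rp = 0: no peripheral branch, X = wI > 0 everywhere
  s <- eval_eric(c(Rc = 0.5, I = 0.002, Rp = 0, Cp = 0.1), c(3, 5, 10, 20, 35))
  idx0 <- compute_indices(s)
  expect_equal(idx0$fdr, 0)
  expect_identical(idx0$ax, 0)

  # spectra are canonically sorted, so input row order cannot matter
  shuffled <- oc[c(4, 1, 7, 3, 2, 6, 5), ]
  resorted <- ios_spectrum(shuffled$frequency, shuffled$resistance,
                           shuffled$reactance)
  expect_identical(compute_indices(resorted), idx)
})

test_that("less negative reactance shrinks AX; larger Rp grows fdR", {
  base <- eval_eric(c(Rc = 0.4, I = 0.0018, Rp = 0.8, Cp = 0.05),
                    c(3, 5, 10, 15, 20, 25, 35))
  ax0 <- compute_ax(base)
  for (delta in c(0.01, 0.05, 0.1)) {
    shifted <- ios_spectrum(base$frequency, base$resistance,
                            base$reactance + delta)
    expect_lt(compute_ax(shifted), ax0)
  }

  # monotone over the physiological range (saturates once w*Rp*Cp >> 1)
  fdrs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(rp) {
    compute_fdr(eval_eric(c(Rc = 0.4, I = 0.0018, Rp = rp, Cp = 0.03),
                          c(3, 5, 10, 15, 20, 25, 35)))
  }, numeric(1))
  expect_true(all(fdrs > 0))
  expect_true(all(diff(fdrs) > 0))
})

test_that("measured-grid Fres matches the closed form on dense noiseless spectra", {
  n_checked <- 0
  for (p in rand_eric(60, seed = 41)) {
    fr <- model_fres(p)
    if (is.na(fr) || fr < 4 || fr > 34) next
    dense <- eval_eric(p, seq(3, 35, by = 0.25))
    expect_equal(compute_fres(dense), fr, tolerance = 1e-2)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})
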