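test_that("zero-CV draws hit the archetype means exactly", {
  cfg <- cohort_config(cv = 0, seed = 5)
  lat <- sample_subject(cfg, "SAI", seed = 123)
  expect_equal(unname(lat), c(0.40, 0.0018, 0.824, 0.045))
  lat_h <- sample_subject(cfg, "H", seed = 123)
  expect_equal(unname(lat_h), c(0.35, 0.0020, 0.501, 0.115))
})

test_that("subject draws are deterministic and log-normal with the stated mean", {
  cfg <- cohort_config(cv = 0.3, seed = 5)
  expect_identical(sample_subject(cfg, "SAI", 42), sample_subject(cfg, "SAI", 42))
  expect_false(identical(sample_subject(cfg, "SAI", 42),
                         sample_subject(cfg, "SAI", 43)))

  # law of large numbers: the arithmetic-mean parameterisation must hold
  draws <- vapply(1:10000, function(s) sample_subject(cfg, "SAI", s),
                  numeric(4))
  means <- rowMeans(draws)
  expect_equal(unname(means), c(0.40, 0.0018, 0.824, 0.045), tolerance = 0.03)
  # and the draws really spread (CV near the configured value)
  expect_equal(unname(apply(draws, 1, sd) / means), rep(0.3, 4),
               tolerance = 0.15)
})

test_that("effects multiply the latent parameters elementwise", {
  arch <- default_archetypes()$SAI
  lat <- c(Rc = 0.40, I = 0.0018, Rp = 0.824, Cp = 0.045)
  grown <- apply_effect(lat, "growth", arch)
  expect_equal(grown[["Rp"]], 0.824 * 0.73)  # ~0.601, the published trajectory
  expect_equal(grown[["Cp"]], 0.045 * 1.25)

  ident <- group_archetype("SAI", means = lat,
                           cv = c(Rc = 0, I = 0, Rp = 0, Cp = 0),
                           growth = c(Rc = 1, I = 1, Rp = 1, Cp = 1),
                           bronchodilator = c(Rc = 1, I = 1, Rp = 1, Cp = 1))
  expect_identical(apply_effect(lat, "growth", ident), lat)

  expect_error(group_archetype("SAI", means = lat,
                               cv = c(Rc = 0, I = 0, Rp = 0, Cp = 0),
                               growth = c(Rc = 0, I = 1, Rp = 1, Cp = 1),
                               bronchodilator = c(Rc = 1, I = 1, Rp = 1, Cp = 1)),
               class = "iosmodel_invalid_input")
})

test_that("visit synthesis is exact without noise and reproducible with it", {
  lat <- c(Rc = 0.40, I = 0.0018, Rp = 0.824, Cp = 0.045)
  grid <- c(3, 5, 10, 15, 20, 25, 35)
  clean <- synthesize_visit(lat, grid, 0, 0, seed = 1)
  expect_equal(clean, eval_eric(lat, grid))

  n1 <- synthesize_visit(lat, grid, 0.01, 0.01, seed = 7)
  n2 <- synthesize_visit(lat, grid, 0.01, 0.01, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, clean))

  # single-replicate regression: refitting a noisy spectrum recovers Cp
  fit <- fit_model(n1, "eric")
  expect_lt(abs(fit$parameters[["Cp"]] - lat[["Cp"]]) / lat[["Cp"]], 0.15)
})

test_that("hopeless noise levels raise a degenerate-noise error", {
  lat <- c(Rc = 0.01, I = 0.0018, Rp = 0.01, Cp = 0.045)
  expect_error(synthesize_visit(lat, 1:30, 1000, 0.01, seed = 1),
               class = "iosmodel_degenerate_noise")
})

test_that("cohort generation has the study's record structure", {
  co <- generate_cohort(cohort_config(n_h = 1, n_sai = 1, seed = 2))
  expect_equal(nrow(co), 6)  # 2 subjects x (2006 preB, 2008 preB, 2008 postB)
  expect_equal(sum(co$visit == "2006" & co$condition == "postB"), 0)
  per_subj <- table(co$subject_id)
  expect_true(all(per_subj == 3))
  expect_true(all(vapply(co$latent, function(l) all(l > 0), logical(1))))

  cfg <- cohort_config(n_h = 2, n_sai = 3, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(cohort_config(n_h = 2, n_sai = 3, seed = 10))
  expect_false(identical(generate_cohort(cfg)$spectrum, other$spectrum))
})

test_that("subject substreams are stable under cohort-size changes", {
  small <- generate_cohort(cohort_config(n_h = 1, n_sai = 1, seed = 4, cv = 0.25))
  big <- generate_cohort(cohort_config(n_h = 1, n_sai = 5, seed = 4, cv = 0.25))
  s01_small <- small[small$subject_id == "S01", ]
  s01_big <- big[big$subject_id == "S01", ]
  expect_identical(s01_small$latent, s01_big$latent)
  expect_identical(s01_small$spectrum, s01_big$spectrum)
})

test_that("a degenerate cohort reproduces the archetype trajectory through the full pipeline", {
  co <- generate_cohort(cohort_config(n_h = 1, n_sai = 1, cv = 0,
                                      noise_sd_r = 0, noise_sd_x = 0, seed = 1))
  fits <- fit_cohort(co, "eric")
  sai <- fits[fits$group == "SAI", ]
  sai <- sai[order(sai$visit, dplyr::desc(sai$condition)), ]
  expect_equal(sai$Cp, c(0.045, 0.045 * 1.25, 0.045 * 1.25 * 1.35),
               tolerance = 1e-5)
  expect_equal(sai$Rp, c(0.824, 0.824 * 0.73, 0.824 * 0.73 * 0.79),
               tolerance = 1e-5)
})
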