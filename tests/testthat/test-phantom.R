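test_that("realized tissue fractions match the targets to a voxel quantum", {
  spec <- small_spec(seed = 7, imat_frac = 0.081, imct_frac = 0.12)
  tr <- generate_labels(spec)
  for (i in 1:3) {
    n_mask <- sum(tr$muscle_id == i)
    n_imat <- sum(tr$muscle_id == i & tr$labels == 2L)
    n_imct <- sum(tr$muscle_id == i & tr$labels == 3L)
    expect_lte(abs(n_imat - 0.081 * n_mask), 1)
    expect_lte(abs(n_imct - 0.12 * n_mask), 1)
  }
})

test_that("zero IMAT fraction yields no IMAT labels", {
  tr <- generate_labels(small_spec(seed = 1, imat_frac = 0))
  expect_equal(sum(tr$labels == 2L), 0)
})

test_that("label generation is seed-deterministic", {
  a <- generate_labels(small_spec(seed = 11))
  b <- generate_labels(small_spec(seed = 11))
  c3 <- generate_labels(small_spec(seed = 12))
  expect_identical(a$labels, b$labels)
  expect_identical(a$t2star, b$t2star)
  expect_false(identical(a$labels, c3$labels))
})

test_that("truth volumes equal label counts times voxel volume", {
  tr <- generate_labels(small_spec(seed = 4))
  vx <- prod(tr$spacing) / 1000
  for (i in 1:3) {
    expect_equal(tr$volumes_cm3$imat_cm3[i],
                 sum(tr$muscle_id == i & tr$labels == 2L) * vx)
    expect_equal(tr$volumes_cm3$total_cm3[i], sum(tr$muscle_id == i) * vx)
  }
  # fat-fraction reference is 1 on adipose labels, 0 on muscle/IMCT
  expect_true(all(tr$fat_fraction[tr$labels == 2L] == 1))
  expect_true(all(tr$fat_fraction[tr$labels %in% c(1L, 3L)] == 0))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(imat_frac = 0.6, imct_frac = 0.5), "fractions")
  expect_error(phantom_spec(imat_frac = -0.1), "fractions")
  expect_error(phantom_spec(t2star_ranges = list(muscle = c(19, 14))), "T2")
  expect_error(phantom_spec(bias_amplitude = 1.2), "bias_amplitude")
  # geometry that does not fit the grid
  bad <- phantom_spec(muscles = list(
    gm = list(center = c(32, 30, 100), axes = c(200, 13, 80)),
    gl = list(center = c(66, 30, 100), axes = c(12, 12, 75)),
    sol = list(center = c(48, 62, 100), axes = c(30, 18, 90))))
  expect_error(generate_labels(bad), "fit")
})

test_that("UTE contrasts follow the mono-exponential decay law", {
  spec <- small_spec(seed = 5, noise_sigma = 0, bias_amplitude = 0)
  tr <- generate_labels(spec)
  e1 <- simulate_contrast(tr, spec, "ute_echo1")
  e2 <- simulate_contrast(tr, spec, "ute_echo2")
  sel <- tr$labels == 1L  # muscle
  ratio <- e2$data[sel] / e1$data[sel]
  expect_equal(ratio, exp(-(2.6 - 0.008) / tr$t2star[sel]), tolerance = 1e-12)
  # closed-form spot values: T2* = 16 ms and 3 ms
  expect_equal(exp(-(2.6 - 0.008) / 16), 0.850, tolerance = 1e-3)
  expect_equal(exp(-(2.6 - 0.008) / 3), 0.4215, tolerance = 1e-3)
  # IMCT decays much faster than muscle between echoes
  imct_ratio <- mean(e2$data[tr$labels == 3L] / e1$data[tr$labels == 3L])
  expect_lt(imct_ratio, min(ratio))
})

test_that("saturation contrasts suppress the right tissues", {
  spec <- small_spec(seed = 5, noise_sigma = 0, bias_amplitude = 0)
  tr <- generate_labels(spec)
  ws <- simulate_contrast(tr, spec, "water_sat_fgre")
  fs <- simulate_contrast(tr, spec, "fat_sat_fgre")
  expect_true(all(ws$data[tr$labels == 2L] > 10 * ws$data[tr$labels == 1L][1]))
  expect_equal(unique(ws$data[tr$labels == 1L]), 5)   # muscle suppressed
  expect_equal(unique(fs$data[tr$labels == 2L]), 5)   # fat suppressed
  expect_error(simulate_contrast(tr, spec, "nonsense"), "sequence_tag")
})

test_that("bias fields are bounded, mean-one and seed-deterministic", {
  f0 <- make_bias_field(c(16, 16, 8), order = 2, amplitude = 0, seed = 1)
  expect_true(all(f0 == 1))
  f <- make_bias_field(c(16, 16, 8), order = 2, amplitude = 0.3, seed = 9)
  expect_true(all(f >= 0.7 - 1e-12) && all(f <= 1.3 + 1e-12))
  expect_equal(max(abs(f - 1)), 0.3, tolerance = 1e-9)
  expect_equal(mean(f), 1, tolerance = 1e-9)
  expect_identical(f, make_bias_field(c(16, 16, 8), order = 2,
                                      amplitude = 0.3, seed = 9))
  v <- vol3(array(2, c(16, 16, 8)))
  expect_identical(apply_bias_field(v, amplitude = 0, seed = 1)$data, v$data)
})

test_that("Rician noise has the Rayleigh background mean and is reproducible", {
  v0 <- vol3(array(0, c(40, 40, 25)))
  n <- add_rician_noise(v0, sigma = 3, seed = 21)
  # background (x = 0) mean is sigma * sqrt(pi / 2)
  expect_equal(mean(n$data), 3 * sqrt(pi / 2), tolerance = 0.01)
  expect_identical(n$data, add_rician_noise(v0, sigma = 3, seed = 21)$data)
  expect_identical(add_rician_noise(v0, sigma = 0, seed = 1)$data, v0$data)
})

test_that("cohort generation reproduces the group parameters", {
  co <- generate_cohort(5, 5, seed = 31)
  expect_equal(nrow(co), 10)
  expect_identical(co, generate_cohort(5, 5, seed = 31))
  big <- generate_cohort(200, 200, seed = 32)
  y <- big[big$cohort == "young", ]
  ts <- y$vol_gm_cm3 + y$vol_gl_cm3 + y$vol_sol_cm3
  # sample mean within 2 SE of the young triceps-surae volume 539.6 cm^3
  expect_lt(abs(mean(ts) - 539.6), 2 * 63.9 / sqrt(200))
  # physiological truncation: positive tissue, fractions below one
  expect_true(all(big$imat_gm_cm3 > 0 & big$imct_gm_cm3 > 0))
  expect_true(all(big$imat_gm_cm3 + big$imct_gm_cm3 < big$vol_gm_cm3))
  expect_true(all(big$imat_sol_cm3 < big$vol_sol_cm3))
  expect_true(all(big$theta_deg > 0 & big$theta_deg < 90))
  expect_true(all(big$p_adj > 0 & big$p_adj < 1))
})
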