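ute_pair <- function(m1, m2, te1 = 0.008, te2 = 2.6, spacing = c(1, 1, 1)) {
  list(e1 = image_volume(m1, spacing, sequence_tag = "ute_echo1", te_ms = te1),
       e2 = image_volume(m2, spacing, sequence_tag = "ute_echo2", te_ms = te2))
}

test_that("T2* mapping inverts the forward decay model exactly", {
  # ratio e: T2* = TE2 - TE1
  p <- ute_pair(array(exp(1), c(2, 2, 2)), array(1, c(2, 2, 2)))
  t2 <- compute_t2star(p$e1, p$e2)
  expect_equal(unique(as.vector(t2$t2star_ms)), 2.6 - 0.008)
  # forward-simulate the canonical tissue values and recover them
  truth <- c(2, 4, 8, 16)
  s0 <- 100
  m1 <- array(s0 * exp(-0.008 / truth), c(4, 1, 1))
  m2 <- array(s0 * exp(-2.6 / truth), c(4, 1, 1))
  p <- ute_pair(m1, m2)
  t2 <- compute_t2star(p$e1, p$e2)
  expect_lt(max(abs(as.vector(t2$t2star_ms) - truth)), 1e-9)
  expect_true(all(t2$valid))
})

test_that("undefined ratios are flagged invalid", {
  m <- array(5, c(2, 2, 2))
  p <- ute_pair(m, m)          # M1 = M2: ln 1 = 0
  t2 <- compute_t2star(p$e1, p$e2)
  expect_true(all(!t2$valid))
  expect_true(all(is.na(t2$t2star_ms)))
  m2 <- m; m2[1, 1, 1] <- 0    # zero second echo
  t2b <- compute_t2star(ute_pair(m * 2, m2)$e1, ute_pair(m * 2, m2)$e2)
  expect_false(t2b$valid[1, 1, 1])
  # metadata contract
  bad <- ute_pair(m, m, te1 = 3, te2 = 2.6)
  expect_error(compute_t2star(bad$e1, bad$e2), "TE")
})

test_that("T2* is monotone in the echo ratio", {
  ratios <- seq(1.1, 10, length.out = 20)
  m1 <- array(ratios, c(20, 1, 1)); m2 <- array(1, c(20, 1, 1))
  p <- ute_pair(m1, m2)
  t2 <- as.vector(compute_t2star(p$e1, p$e2)$t2star_ms)
  expect_true(all(diff(t2) < 0))  # larger M1/M2 decays faster: smaller T2*
})

test_that("echo subtraction suppresses long-T2* tissue and clips negatives", {
  m <- array(5, c(2, 2, 2))
  p <- ute_pair(m, m)
  expect_true(all(echo_subtraction(p$e1, p$e2)$data == 0))
  # equal S0, short vs long T2*: subtraction is larger for short T2*
  s_short <- 100 * exp(-c(0.008, 2.6) / 3)
  s_long <- 100 * exp(-c(0.008, 2.6) / 16)
  expect_gt(s_short[1] - s_short[2], s_long[1] - s_long[2])
  # clipping where echo2 > echo1
  p2 <- ute_pair(array(1, c(2, 2, 2)), array(4, c(2, 2, 2)))
  expect_true(all(echo_subtraction(p2$e1, p2$e2)$data == 0))
})

test_that("8 ms threshold separates muscle from IMAT/IMCT ranges", {
  spec <- small_spec(seed = 14, noise_sigma = 0, bias_amplitude = 0)
  ph <- generate_phantom(spec)
  t2 <- compute_t2star(ph$volumes$ute_echo1, ph$volumes$ute_echo2)
  nm <- segment_nonmuscle(t2, ph$masks, threshold_ms = 8)
  lbl <- ph$truth$labels
  expect_true(all(!nm[lbl == 1L]))          # muscle 14-19 ms excluded
  expect_true(all(nm[lbl == 3L]))           # IMCT 2-4 ms included
  expect_true(all(nm[lbl == 2L]))           # IMAT 4-6 ms included
  expect_true(all(!nm[!mask_union(ph$masks)]))  # nothing outside the masks
  expect_equal(sum(segment_nonmuscle(t2, ph$masks, threshold_ms = 0)), 0)
})

test_that("IMCT derivation removes IMAT and records the count", {
  nm <- array(FALSE, c(4, 4, 4)); nm[1:8] <- TRUE
  imat <- array(FALSE, c(4, 4, 4)); imat[5:8] <- TRUE
  ic <- derive_imct(nm, imat)
  expect_equal(sum(ic$map), 4)
  expect_equal(ic$removed_imat_voxels, 4)
  # imat empty: IMCT equals nonmuscle
  expect_identical(derive_imct(nm, array(FALSE, c(4, 4, 4)))$map, nm)
  # nonmuscle subset of imat: empty IMCT
  expect_equal(sum(derive_imct(imat, nm)$map), 0)
})

test_that("tissue maps partition the mask union (conservation)", {
  spec <- small_spec(seed = 15, noise_sigma = 0, bias_amplitude = 0)
  cfg <- default_run_config(withr::local_tempdir(), seed = 15,
                            phantom = spec, verbose = FALSE)
  res <- suppressMessages(run_pipeline(cfg))
  ph <- generate_phantom(spec)
  u <- mask_union(ph$masks)
  imat <- res$imat$map; imct <- res$imct$map
  contractile <- u & !imat & !imct
  expect_equal(sum(imat & imct), 0)
  expect_true(all((imat | imct | contractile) == u))
  # exact recovery of truth maps in the noise-free case
  expect_identical(imat, ph$truth$labels == 2L)
  expect_identical(imct, ph$truth$labels == 3L)
})

test_that("manual agreement reports percent non-contractile differences", {
  mask <- matrix(TRUE, 10, 10)
  auto <- matrix(FALSE, 10, 10); auto[1:12] <- TRUE     # 12%
  manual <- matrix(FALSE, 10, 10); manual[1:8] <- TRUE  # 8%
  res <- manual_agreement(auto, manual, mask)
  expect_equal(res$auto_pct, 12)
  expect_equal(res$manual_pct, 8)
  expect_equal(res$difference, 4.0)
  same <- manual_agreement(auto, auto, mask)
  expect_equal(same$difference, 0)
  zero <- manual_agreement(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10), mask)
  expect_equal(unlist(zero), c(auto_pct = 0, manual_pct = 0, difference = 0))
  expect_error(manual_agreement(auto, manual, matrix(FALSE, 10, 10)), "empty")
})

test_that("max CSA slice picks the largest union cross-section", {
  z <- array(FALSE, c(6, 6, 5))
  gm <- z; gm[1:2, 1, 2] <- TRUE          # 2 voxels on slice 2 (index 1)
  gl <- z; gl[1:3, 2, 4] <- TRUE          # 3 voxels on slice 4 (index 3)
  sol <- z
  m <- mask_set(gm, gl, sol, c(1, 1, 1))
  expect_equal(max_csa_slice(m), 3L)
  # tie: lower index wins
  gl2 <- z; gl2[1:2, 2, 4] <- TRUE
  expect_equal(max_csa_slice(mask_set(gm, gl2, sol, c(1, 1, 1))), 1L)
  # phantom ellipsoids peak at the equator slice
  ph <- generate_phantom(small_spec(seed = 16, noise_sigma = 0))
  nz <- dim(ph$truth$labels)[3]
  expect_equal(max_csa_slice(ph$masks), as.integer(nz / 2) - 1L,
               tolerance = 1.01)
  expect_error(max_csa_slice(mask_set(z, z, z, c(1, 1, 1))), "empty")
})
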