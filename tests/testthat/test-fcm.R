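test_that("FCM finds separated delta masses exactly", {
  res2 <- fcm_cluster_1d(c(0, 0, 0, 10, 10, 10), fcm_config(n_clusters = 2))
  expect_equal(res2$centroids, c(0, 10), tolerance = 1e-6)
  # crisp memberships on the deltas
  expect_true(all(res2$membership[1:3, 1] > 0.999))
  expect_true(all(res2$membership[4:6, 2] > 0.999))

  x <- c(rep(1, 20), rep(5, 30), rep(9, 25))
  res3 <- fcm_cluster_1d(x, fcm_config())
  expect_equal(res3$centroids, c(1, 5, 9), tolerance = 1e-4)
  expect_true(res3$converged)
})

test_that("memberships always sum to one and centroids stay sorted", {
  set.seed(99)
  for (i in 1:5) {
    x <- c(rnorm(50, 5, 1), rnorm(20, 50, 5), rnorm(10, 100, 5))
    res <- fcm_cluster_1d(x, fcm_config())
    expect_equal(rowSums(res$membership), rep(1, length(x)), tolerance = 1e-9)
    expect_true(all(res$membership >= 0 & res$membership <= 1))
    expect_true(!is.unsorted(res$centroids))
  }
})

test_that("too few distinct values raises an error", {
  expect_error(fcm_cluster_1d(c(1, 1, 1, 2, 2), fcm_config()), "distinct")
})

test_that("valley threshold is the membership-equality point", {
  res <- structure(list(centroids = c(1, 5, 9), m = 2), class = "fcm_result")
  expect_equal(slice_threshold(res), 7.0)
  # brute-force membership-equality search on a fine grid
  u_top2 <- function(x, v, m = 2) {
    d <- abs(x - v); d[d < 1e-15] <- 1e-15
    w <- d^(-2 / (m - 1)); u <- w / sum(w)
    u[2:3]
  }
  grid <- seq(5, 9, by = 1e-4)
  gap <- vapply(grid, function(x) {
    u <- u_top2(x, c(1, 5, 9)); abs(u[1] - u[2])
  }, numeric(1))
  expect_equal(grid[which.min(gap)], 7.0, tolerance = 1e-3)
  # scale equivariance
  res2 <- structure(list(centroids = c(2, 10, 18), m = 2), class = "fcm_result")
  expect_equal(slice_threshold(res2), 14.0)
  # degenerate top centroids
  bad <- structure(list(centroids = c(1, 9, 9), m = 2), class = "fcm_result")
  expect_error(slice_threshold(bad), "degenerate")
})

test_that("noise-free phantom IMAT is recovered exactly", {
  ph <- generate_phantom(small_spec(seed = 8, noise_sigma = 0,
                                    bias_amplitude = 0))
  ws <- remove_subcutaneous_fat(ph$volumes$water_sat_fgre, ph$masks)
  seg <- suppressMessages(segment_imat(ws, ph$masks))
  expect_identical(seg$map, ph$truth$labels == 2L)
  # per-slice provenance covers all slices
  expect_equal(nrow(seg$slices), dim(ws$data)[3])
  # fat-free slices yield zero IMAT
  fatfree <- which(apply(ph$truth$labels == 2L, 3, sum) == 0)
  expect_true(all(!seg$map[, , fatfree]))
})

test_that("adding fat voxels never decreases a slice's IMAT volume", {
  ph <- generate_phantom(small_spec(seed = 9, noise_sigma = 0,
                                    bias_amplitude = 0))
  ws <- remove_subcutaneous_fat(ph$volumes$water_sat_fgre, ph$masks)
  z <- max_csa_slice(ph$masks) + 1L
  base <- suppressMessages(segment_imat(ws, ph$masks))
  n0 <- sum(base$map[, , z])
  # paint 30 additional in-mask muscle voxels to fat intensity
  sl <- ws$data[, , z]
  cand <- which(mask_union(ph$masks)[, , z] & sl < 50)
  sl[cand[1:30]] <- 100
  ws2 <- ws; ws2$data[, , z] <- sl
  seg2 <- suppressMessages(segment_imat(ws2, ph$masks))
  expect_gte(sum(seg2$map[, , z]), n0 + 30)
})

test_that("imat_volumes aggregates counts and percentages", {
  ph <- generate_phantom(small_spec(seed = 10, noise_sigma = 0,
                                    bias_amplitude = 0))
  tr <- ph$truth
  vols <- imat_volumes(tr$labels == 2L, ph$masks)
  expect_equal(vols$imat_cm3[1:3], tr$volumes_cm3$imat_cm3)
  expect_equal(vols$imat_cm3[4], sum(tr$volumes_cm3$imat_cm3))
  expect_equal(vols$imat_pct[1:3],
               100 * tr$volumes_cm3$imat_cm3 / tr$volumes_cm3$total_cm3)
  empty <- imat_volumes(array(FALSE, dim(tr$labels)), ph$masks)
  expect_true(all(empty$imat_cm3 == 0) && all(empty$imat_pct == 0))
})

test_that("reference calibration selects the objective's argmin", {
  ph <- generate_phantom(small_spec(seed = 12, noise_sigma = 5))
  ws <- remove_subcutaneous_fat(ph$volumes$water_sat_fgre, ph$masks)
  ref <- ph$volumes$fat_fraction_reference
  # self-consistency: noise-free volume against its own truth reference
  ph0 <- generate_phantom(small_spec(seed = 12, noise_sigma = 0,
                                     bias_amplitude = 0))
  ws0 <- remove_subcutaneous_fat(ph0$volumes$water_sat_fgre, ph0$masks)
  cal0 <- calibrate_against_reference(ws0, ph0$masks,
                                      ph0$volumes$fat_fraction_reference,
                                      list(fcm_config()))
  expect_equal(cal0$stats$mean_abs_diff_cm3, 0, tolerance = 1e-9)
  expect_equal(cal0$stats$pearson_r, 1, tolerance = 1e-9)

  # grid over the fuzziness exponent: chosen candidate is the exhaustive argmin
  cands <- list(fcm_config(m = 1.5), fcm_config(m = 2),
                fcm_config(m = 3, threshold_offset = 20))
  cal <- calibrate_against_reference(ws, ph$masks, ref, cands)
  objective <- vapply(cands, function(cfg) {
    seg <- suppressMessages(segment_imat(ws, ph$masks, cfg))
    got <- imat_volumes(seg, ph$masks)
    got <- got$imat_cm3[match(c("gm", "gl", "sol"), got$muscle)]
    vx <- prod(ph$masks$spacing) / 1000
    refv <- vapply(c("gm", "gl", "sol"),
                   function(m) sum(ref$data[ph$masks[[m]]]) * vx, numeric(1))
    mean(abs(got - refv))
  }, numeric(1))
  expect_equal(cal$all$mean_abs_diff_cm3, objective, tolerance = 1e-9)
  expect_identical(cal$config, cands[[which.min(objective)]])
  # candidate set of one returns it
  one <- calibrate_against_reference(ws, ph$masks, ref, cands[2])
  expect_identical(one$config, cands[[2]])
  expect_error(calibrate_against_reference(ws, ph$masks, ref, list()), "empty")
})
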