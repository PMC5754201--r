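test_that("membrane_intensity is the supra-threshold sum", {
  v <- array(3, dim = c(4, 5, 5, 1))
  s <- image_stack(v, c(glia = 1))
  # everything below threshold
  expect_equal(membrane_intensity(s, policy = threshold_policy("glia", "absolute", 10)), 0)
  # uniform value 10 with threshold 5: 10 * N voxels
  v10 <- array(10, dim = c(4, 5, 5, 1))
  s10 <- image_stack(v10, c(glia = 1))
  expect_equal(membrane_intensity(s10, policy = threshold_policy("glia", "absolute", 5)),
               10 * 4 * 5 * 5)
  # restricted to an ROI
  expect_equal(membrane_intensity(s10, roi(0, 2, 0, 3),
                                  threshold_policy("glia", "absolute", 5)),
               10 * 4 * 2 * 3)

  set.seed(13)
  sr <- random_stack(nz = 8, ny = 10, nx = 10)
  for (thr in c(0, 120, 350)) {
    pol <- threshold_policy("glia", "absolute", thr)
    expect_equal(membrane_intensity(sr, policy = pol),
                 oracle_masked_sum(channel(sr, "glia"), thr))
  }
})

test_that("membrane intensity and volume are monotone in the threshold", {
  set.seed(19)
  s <- random_stack(nz = 6, ny = 9, nx = 9)
  thrs <- seq(0, 500, by = 50)
  mi <- vapply(thrs, function(th)
    membrane_intensity(s, policy = threshold_policy("glia", "absolute", th)),
    numeric(1))
  nv <- vapply(thrs, function(th)
    neuronal_volume(s, policy = threshold_policy("neuron", "absolute", th)),
    numeric(1))
  expect_true(all(diff(mi) <= 0))
  expect_true(all(diff(nv) <= 0))
})

test_that("scaling intensities and threshold together scales the total exactly", {
  set.seed(29)
  s <- random_stack(nz = 5, ny = 8, nx = 8)
  thr <- 200
  base <- membrane_intensity(s, policy = threshold_policy("glia", "absolute", thr))
  k <- 3
  sk <- image_stack(s$voxels * k, s$channel_roles)
  scaled <- membrane_intensity(sk, policy = threshold_policy("glia", "absolute", thr * k))
  expect_equal(scaled, k * base)
  # with an unscaled threshold the total can only grow
  unscaled <- membrane_intensity(sk, policy = threshold_policy("glia", "absolute", thr))
  expect_gte(unscaled, k * base)
})

test_that("membrane_to_nsc_ratio is an exact quotient", {
  expect_equal(membrane_to_nsc_ratio(1000, 10), 100)
  expect_equal(membrane_to_nsc_ratio(1000, 20), 50)  # doubling halves
  expect_error(membrane_to_nsc_ratio(1000, 0), "undefined")
})

test_that("count_nuclei counts 26-connected supra-threshold components", {
  pol <- threshold_policy("nsc", "absolute", 90)
  # empty channel
  s0 <- image_stack(array(0, dim = c(5, 6, 6, 1)), c(nsc = 1))
  expect_identical(count_nuclei(s0, "nsc", pol), 0L)

  # 12 non-touching spheres, noiseless render
  centers <- as.matrix(expand.grid(z = c(8, 16), y = c(10, 30, 50),
                                   x = c(12, 36)))[, c("z", "y", "x")]
  cfg <- scene_config(shape = c(24, 64, 64), nsc_centers = centers,
                      nsc_radius = 2.5, noise_sd = 0, neuron_count = 5,
                      neuron_depth_band = c(16, 20), seed = 2)
  sc <- generate_scene(cfg)
  expect_identical(count_nuclei(sc$stack, "nsc", pol, min_volume = 5), 12L)
  expect_identical(sc$truth$nsc_count, 12L)

  # two overlapping spheres merge into one component (known limitation)
  cfg2 <- scene_config(shape = c(12, 24, 24),
                       nsc_centers = rbind(c(6, 10, 10), c(6, 12, 12)),
                       nsc_depth_band = c(4, 8), nsc_radius = 3,
                       noise_sd = 0, neuron_count = 2,
                       neuron_depth_band = c(8, 10), seed = 2)
  sc2 <- generate_scene(cfg2)
  expect_identical(count_nuclei(sc2$stack, "nsc", pol, min_volume = 5), 1L)

  # min_volume rejects speckle
  v <- array(0, dim = c(6, 8, 8, 1))
  v[2, 2, 2, 1] <- 100            # single voxel
  v[4:5, 5:6, 5:6, 1] <- 100      # 8-voxel blob
  ss <- image_stack(v, c(nsc = 1))
  expect_identical(count_nuclei(ss, "nsc", pol, min_volume = 1), 2L)
  expect_identical(count_nuclei(ss, "nsc", pol, min_volume = 2), 1L)
  expect_error(count_nuclei(ss, "glia", pol), "not present")
})

test_that("component labelling matches an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(37)
  for (i in 1:8) {
    mask <- array(runif(10 * 12 * 12) < 0.12, dim = c(10, 12, 12))
    lab <- label_components(mask)
    expect_identical(max(lab), oracle_component_count(mask))
    for (mv in c(2L, 5L)) {
      sizes <- tabulate(lab[lab > 0])
      expect_identical(sum(sizes >= mv), oracle_component_count(mask, mv))
    }
    # labels partition the mask
    expect_identical(lab > 0, mask)
  }
})

test_that("neuronal_volume counts supra-threshold voxels", {
  pol <- threshold_policy("neuron", "absolute", 50)
  s0 <- image_stack(array(0, dim = c(4, 5, 5, 1)), c(neuron = 1))
  expect_equal(neuronal_volume(s0, policy = pol), 0)

  v <- array(0, dim = c(12, 12, 12, 1))
  v[2:11, 2:11, 2:11, 1] <- 80
  s <- image_stack(v, c(neuron = 1))
  expect_equal(neuronal_volume(s, policy = pol), 1000)
  expect_equal(neuronal_volume(s, policy = pol, voxel_volume = 0.25),
               250)

  set.seed(43)
  sr <- random_stack(nz = 6, ny = 8, nx = 8)
  expect_equal(neuronal_volume(sr, policy = pol),
               oracle_masked_count(channel(sr, "neuron"), 50))
})

test_that("marker_positive_fraction handles boundaries and errors", {
  expect_equal(marker_positive_fraction(0, 50), 0)
  expect_equal(marker_positive_fraction(50, 50), 1)
  expect_equal(marker_positive_fraction(7, 28), 0.25)
  expect_error(marker_positive_fraction(3, 0), "positive")
  expect_error(marker_positive_fraction(5, 4), "<=")
})

test_that("normalize_volumes centres the control mean at one", {
  out <- normalize_volumes(c(2, 4, 3), c(2, 4))
  expect_equal(out, c(2 / 3, 4 / 3, 1))
  expect_equal(normalize_volumes(rep(5, 4), rep(5, 4)), rep(1, 4))
  set.seed(47)
  vals <- runif(10, 1, 9)
  norm <- normalize_volumes(vals, vals[1:4])
  expect_equal(mean(norm[1:4]), 1)
  expect_equal(norm[2] / norm[7], vals[2] / vals[7])   # ratio-preserving
  expect_identical(order(norm), order(vals))
  expect_error(normalize_volumes(vals, numeric(0)), "empty")
  expect_error(normalize_volumes(vals, c(0, 0)), "positive")
})

test_that("quantile and otsu threshold policies resolve sensibly", {
  set.seed(53)
  v <- array(c(rpois(800, 10), rpois(200, 200)), dim = c(10, 10, 10, 1))
  s <- image_stack(v, c(glia = 1))
  q <- resolve_threshold(s, threshold_policy("glia", "quantile", 0.5))
  expect_equal(q, quantile(v, 0.5, type = 7, names = FALSE))
  expect_error(threshold_policy("glia", "quantile", 1.5), "\\[0, 1\\]")
  expect_error(threshold_policy("glia", "absolute"), "finite")
  skip_if_not_installed("EBImage")
  ot <- resolve_threshold(s, threshold_policy("glia", "otsu"))
  expect_gt(ot, 30)   # separates the two Poisson populations
  expect_lt(ot, 190)
})

test_that("niche_metrics assembles one tidy row per specimen", {
  sc <- generate_scene(fed_preset(shape = c(24, 64, 64), seed = 5))
  m <- niche_metrics(sc$stack, policies = test_policies(), min_volume = 10)
  expect_equal(nrow(m), 1)
  expect_equal(m$condition, "fed")
  expect_equal(m$nsc_count, sc$truth$nsc_count)
  expect_equal(m$membrane_nsc_ratio, m$membrane_intensity / m$nsc_count)
  expect_equal(m$glia_threshold, 40)
  expect_error(niche_metrics(sc$stack, policies = test_policies()[1:2]),
               "must include")

  # zero NSC detection flags an undefined ratio
  v <- array(0, dim = c(5, 6, 6, 3)); v[2, , , 1] <- 100
  s0 <- image_stack(v, c(glia = 1, nsc = 2, neuron = 3))
  expect_warning(m0 <- niche_metrics(s0, policies = test_policies()),
                 "undefined")
  expect_true(is.na(m0$membrane_nsc_ratio))
})

test_that("manual count CSVs are read and validated", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(specimen_id = c("a", "a", "b"),
                       marker = c("PH3", "TUNEL", "PH3"),
                       count = c(4L, 0L, 7L)),
            tf, row.names = FALSE)
  tab <- read_manual_counts(tf)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$count, c(4, 0, 7))
  expect_equal(marker_positive_fraction(tab$count[1], 16), 0.25)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(specimen_id = "a", marker = "PH3", count = -2),
            bad, row.names = FALSE)
  expect_error(read_manual_counts(bad), "non-negative")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", n = 1), bad2, row.names = FALSE)
  expect_error(read_manual_counts(bad2), "columns")
})
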