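test_that("mean_intensity_by_depth matches definition and brute force", {
  # constant stack
  v <- array(7, dim = c(5, 4, 4, 1))
  s <- image_stack(v, c(glia = 1))
  expect_equal(mean_intensity_by_depth(s, "glia"), rep(7, 5))

  # zero everywhere except one slice inside the roi
  v <- array(0, dim = c(8, 6, 6, 1))
  v[5, 2:4, 2:4, 1] <- 10
  s <- image_stack(v, c(glia = 1))
  m <- mean_intensity_by_depth(s, "glia", roi(1, 4, 1, 4))
  expect_equal(m, c(0, 0, 0, 0, 10, 0, 0, 0))

  # random stack against the triple-loop oracle
  set.seed(7)
  s <- random_stack(nz = 10, ny = 7, nx = 9)
  r <- roi(1, 6, 2, 7)
  for (role in c("glia", "nsc", "neuron"))
    expect_equal(mean_intensity_by_depth(s, role, r),
                 oracle_mean_by_depth(s, role, r))
})

test_that("normalize_profile scales the peak to one and preserves shape", {
  expect_equal(normalize_profile(c(0, 2, 4, 2)), c(0, 0.5, 1, 0.5))
  x <- c(0, 0.25, 1, 0.5)
  expect_equal(normalize_profile(x), x)          # idempotent
  set.seed(5)
  raw <- runif(12, 0, 100)
  nm <- normalize_profile(raw)
  expect_identical(max(nm), 1)
  expect_equal(nm / nm[1], raw / raw[1])         # ratios preserved
  expect_error(normalize_profile(c(0, 0, 0)), "empty channel")
  expect_error(normalize_profile(c(1, 2)), "at least 3")
  expect_error(normalize_profile(c(1, NA, 2)), "finite")
})

test_that("refine_peak recovers the vertex of any sampled concave quadratic", {
  # the spec'd closed-form case: y(z) = 1 - 0.04 (z - 7.25)^2 on z = 0..14
  z <- 0:14
  y <- 1 - 0.04 * (z - 7.25)^2
  pk <- refine_peak(y)
  expect_true(pk$refined)
  expect_equal(pk$refined_position, 7.25, tolerance = 1e-12)
  expect_equal(pk$argmax_slice, 7)

  # symmetric neighbours give the integer argmax exactly
  pk2 <- refine_peak(c(0, 1, 3, 1, 0))
  expect_true(pk2$refined)
  expect_identical(pk2$refined_position, 2)
})

test_that("refined vertex equals an independent least-squares quadratic fit", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    vtx <- runif(1, 1.2, n - 2.2)
    a <- -runif(1, 0.01, 2)
    y <- a * ((0:(n - 1)) - vtx)^2 + runif(1, 1, 5)
    pk <- refine_peak(y)
    zi <- (pk$argmax_slice - 1):(pk$argmax_slice + 1)
    fit_vertex <- oracle_quadfit_vertex(zi, y[zi + 1])
    expect_true(pk$refined)
    expect_equal(pk$refined_position, fit_vertex, tolerance = 1e-9)
    expect_lt(abs(pk$refined_position - pk$argmax_slice), 1)
  }
})

test_that("sub-slice accuracy on noiseless Gaussian profiles improves with width", {
  gauss <- function(z, mu, sigma) exp(-(z - mu)^2 / (2 * sigma^2))
  z <- 0:29
  pk <- refine_peak(gauss(z, 12.4, 3))
  dense <- oracle_dense_argmax(function(t) gauss(t, 12.4, 3), 10, 15, 5000)
  expect_lt(abs(pk$refined_position - 12.4), 0.05)
  expect_lt(abs(pk$refined_position - dense), 0.05 + 1e-3)

  # refinement error shrinks as sigma grows; < 0.25 slices for sigma >= 2
  worst <- vapply(c(2, 3, 4, 5), function(sigma) {
    errs <- vapply(seq(10, 11, by = 0.1), function(mu)
      abs(refine_peak(gauss(z, mu, sigma))$refined_position - mu), numeric(1))
    max(errs)
  }, numeric(1))
  expect_true(all(diff(worst) <= 1e-12))
  expect_true(all(worst < 0.25))
})

test_that("boundary and degenerate peaks fall back to the integer argmax", {
  # monotone decreasing: maximum on slice 0
  pk <- refine_peak(c(9, 7, 5, 3))
  expect_false(pk$refined)
  expect_identical(pk$refined_position, 0)

  # maximum on the last slice
  pk2 <- refine_peak(c(1, 2, 3, 9))
  expect_false(pk2$refined)
  expect_identical(pk2$refined_position, 3)

  # plateau: ties break to the lowest slice; the (0, 5, 5) stencil is
  # still strictly concave so the vertex lands between the tied slices
  pk3 <- refine_peak(c(0, 5, 5, 5, 0))
  expect_identical(pk3$argmax_slice, 1L)
  expect_true(pk3$refined)
  expect_equal(pk3$refined_position, 1.5)

  # constant curve degenerates to slice 0, unrefined
  pk4 <- refine_peak(rep(2, 6))
  expect_false(pk4$refined)
  expect_identical(pk4$refined_position, 0)

  expect_error(refine_peak(c(1, 2)), "at least 3")
  expect_error(refine_peak(c(1, Inf, 2)), "finite")
})

test_that("profiles and refined peaks are invariant to channel scaling", {
  set.seed(23)
  raw <- c(1, 4, 9, 14, 11, 6, 2) + runif(7)
  for (k in c(0.01, 3.7, 1000)) {
    expect_equal(normalize_profile(k * raw), normalize_profile(raw))
    pk <- refine_peak(raw); pks <- refine_peak(k * raw)
    expect_equal(pks$refined_position, pk$refined_position)
    expect_identical(pks$argmax_slice, pk$argmax_slice)
  }
})

test_that("build_chart composes profiles per role and flags empty channels", {
  curves <- list(glia = c(0, 5, 10, 5, 0, 0, 0),
                 nsc = c(0, 0, 2, 8, 2, 0, 0),
                 neuron = c(0, 0, 0, 1, 6, 9, 3))
  s <- curve_stack(curves)
  ch <- build_chart(s)
  expect_s3_class(ch, "chamber_chart")
  expect_equal(ch$profiles$glia$raw, curves$glia)
  expect_identical(max(ch$profiles$nsc$normalized), 1)
  pks <- peak_table(ch)
  expect_true(all(!pks$empty))
  expect_true(pks$refined_position[pks$role == "glia"] <
              pks$refined_position[pks$role == "nsc"])

  # identical channels give identical profiles and peaks
  same <- curve_stack(list(glia = curves$glia, nsc = curves$glia,
                           neuron = curves$glia))
  chs <- build_chart(same)
  expect_equal(chs$profiles$glia$raw, chs$profiles$neuron$raw)
  offs <- peak_offsets(chs)
  expect_equal(offs$nsc_offset, 0)
  expect_equal(offs$neuron_offset, 0)

  # an all-zero channel is flagged; the chart is still built for the rest
  curves0 <- curves; curves0$nsc <- rep(0, 7)
  s0 <- curve_stack(curves0)
  expect_warning(ch0 <- build_chart(s0), "empty channel 'nsc'")
  expect_true(ch0$profiles$nsc$empty)
  expect_false(ch0$profiles$glia$empty)
  expect_error(peak_offsets(ch0), "empty channel 'nsc'")

  expect_error(build_chart(curve_stack(curves[1:2],
                                       roles = c(glia = 1, nsc = 2))),
               "lacks role")
})

test_that("peak offsets are differences of refined positions", {
  # constructed peaks at 8, 12, 18: offsets (4, 10)
  gauss <- function(z, mu) exp(-(z - mu)^2 / 8)
  z <- 0:29
  s <- curve_stack(list(glia = gauss(z, 8), nsc = gauss(z, 12),
                        neuron = gauss(z, 18)))
  offs <- peak_offsets(build_chart(s))
  expect_equal(offs$nsc_offset, 4, tolerance = 1e-6)
  expect_equal(offs$neuron_offset, 10, tolerance = 1e-6)
})

test_that("chart tables are tidy and complete", {
  s <- curve_stack(list(glia = c(0, 3, 1, 0), nsc = c(0, 1, 3, 0),
                        neuron = c(1, 0, 0, 3)))
  ch <- build_chart(s)
  tab <- chart_table(ch)
  expect_equal(nrow(tab), 12)
  expect_setequal(unique(tab$role), c("glia", "nsc", "neuron"))
  expect_equal(tab$slice[tab$role == "glia"], 0:3)
  pk <- peak_table(ch)
  expect_equal(nrow(pk), 3)
  expect_false("refined_position_um" %in% names(pk))  # no spacing known
  p <- plot_chart(ch)
  expect_s3_class(p, "ggplot")

  # micrometre conversion appears when the stack carries a Z spacing
  s2 <- s; s2$z_spacing <- 0.5
  pk2 <- peak_table(build_chart(s2))
  expect_equal(pk2$refined_position_um, pk2$refined_position * 0.5)
})

test_that("optional smoothing is off by default and recorded when used", {
  set.seed(3)
  raw <- c(0, 1, 10, 2, 8, 1, 0)
  s <- curve_stack(list(glia = raw, nsc = raw, neuron = raw))
  ch <- build_chart(s)
  expect_null(ch$smooth_window)
  expect_equal(ch$profiles$glia$raw, raw)
  chs <- build_chart(s, smooth_window = 3)
  expect_equal(chs$smooth_window, 3)
  expect_equal(chs$profiles$glia$raw[3], mean(raw[2:4]))
  expect_error(build_chart(s, smooth_window = 4))
})
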