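#' Synthetic niche scene configuration
#'
#' Describes a 3D three-channel scene emulating a confocal stack of the
#' larval ventral nerve cord: a dense cortex-glial membrane sheet (the
#' "top layer") plus a chequerboard of vertical chamber walls in the glial
#' channel, NSC nuclei rendered as spheres in a shallow depth band, and
#' neuronal nuclei as smaller spheres in a deeper band. Additive Gaussian
#' noise (clipped at zero) and optional isotropic Gaussian blur give the
#' render a microscopy-like texture; voxels are quantized to 16-bit
#' integers, the native bit depth of confocal exports.
#'
#' Depth coordinates are 0-based slice units. NSC nuclei sit on a jittered
#' chamber grid (one nucleus per chamber cell), which guarantees
#' non-touching objects for counting tests; explicit `nsc_centers`
#' override the grid. Within a depth band, nucleus depths follow a
#' symmetric triangular distribution, so each nuclear channel has a single
#' well-defined true peak at the band centre.
#'
#' @param shape integer (slices, height, width).
#' @param z_spacing slice spacing in micrometres.
#' @param glia_top_depth true depth of the glial top sheet (slice units).
#' @param glia_sheet_thickness axial thickness of the sheet (slices); the
#'   sheet's axial profile is Gaussian with sigma = thickness / 2.
#' @param chamber_wall_density fraction of chequerboard wall segments
#'   present, in \[0, 1\].
#' @param chamber_size chamber cell pitch in pixels.
#' @param wall_thickness wall thickness in pixels.
#' @param nsc_centers optional matrix of (z, y, x) NSC centres; when NULL
#'   they are placed on the jittered chamber grid.
#' @param nsc_count optional number of grid cells to occupy (default all).
#' @param nsc_depth_band (min, max) depth band for NSC nuclei.
#' @param nsc_radius NSC nucleus radius (pixels).
#' @param neuron_depth_band (min, max) depth band for neuronal nuclei.
#' @param neuron_count number of neuronal nuclei.
#' @param neuron_radius neuronal nucleus radius (pixels).
#' @param membrane_amplitude peak intensity of the glial sheet; walls
#'   render at 40% of it.
#' @param nuclei_amplitude peak intensity of nuclear signals.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param blur_sigma isotropic Gaussian blur sigma in voxels (0 = none).
#' @param trachea add a bright off-target tube in the glial channel near
#'   the image edge (outside the clean ROI reported in the ground truth).
#' @param seed integer RNG seed; renders are voxel-identical for a fixed
#'   config and seed.
#' @param condition condition label stamped on the generated stack.
#' @return A `scene_config`.
#' @export
scene_config <- function(shape = c(30, 128, 128), z_spacing = 1,
                         glia_top_depth = 8, glia_sheet_thickness = 2,
                         chamber_wall_density = 0.7, chamber_size = 24,
                         wall_thickness = 2,
                         nsc_centers = NULL, nsc_count = NULL,
                         nsc_depth_band = c(11, 14), nsc_radius = 2.5,
                         neuron_depth_band = c(16, 24), neuron_count = 120,
                         neuron_radius = 1.6,
                         membrane_amplitude = 200, nuclei_amplitude = 180,
                         noise_sd = 8, blur_sigma = 0,
                         trachea = FALSE, seed = 1,
                         condition = "synthetic") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L))
  nz <- shape[1]
  bands <- rbind(nsc_depth_band, neuron_depth_band)
  if (any(bands < 0) || any(bands > nz - 1))
    stop("depth bands must lie within [0, slices - 1]")
  if (nsc_depth_band[1] > nsc_depth_band[2] ||
      neuron_depth_band[1] > neuron_depth_band[2])
    stop("inconsistent depth band (min > max)")
  if (glia_top_depth < 0 || glia_top_depth > nz - 1)
    stop("glia_top_depth outside stack")
  if (chamber_wall_density < 0 || chamber_wall_density > 1)
    stop("chamber_wall_density must lie in [0, 1]")
  if (membrane_amplitude <= 0 || nuclei_amplitude <= 0)
    stop("amplitudes must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(nsc_centers)) {
    nsc_centers <- as.matrix(nsc_centers)
    if (ncol(nsc_centers) != 3L) stop("nsc_centers must be (z, y, x) rows")
    if (any(nsc_centers[, 1] < 0) || any(nsc_centers[, 1] > nz - 1) ||
        any(nsc_centers[, 2] < 0) || any(nsc_centers[, 2] > shape[2] - 1) ||
        any(nsc_centers[, 3] < 0) || any(nsc_centers[, 3] > shape[3] - 1))
      stop("nsc_centers out of bounds")
  }
  structure(list(shape = shape, z_spacing = z_spacing,
                 glia_top_depth = glia_top_depth,
                 glia_sheet_thickness = glia_sheet_thickness,
                 chamber_wall_density = chamber_wall_density,
                 chamber_size = as.integer(chamber_size),
                 wall_thickness = as.integer(wall_thickness),
                 nsc_centers = nsc_centers, nsc_count = nsc_count,
                 nsc_depth_band = nsc_depth_band, nsc_radius = nsc_radius,
                 neuron_depth_band = neuron_depth_band,
                 neuron_count = as.integer(neuron_count),
                 neuron_radius = neuron_radius,
                 membrane_amplitude = membrane_amplitude,
                 nuclei_amplitude = nuclei_amplitude,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 trachea = trachea, seed = as.integer(seed),
                 condition = condition),
            class = "scene_config")
}

check_preset_shape <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || shape[1] < 24L || shape[2] < 64L ||
      shape[3] < 64L)
    stop("preset needs shape of at least (24, 64, 64) to separate depth bands")
  shape
}

#' Fed-condition scene preset
#'
#' The ordered niche: dense glial top sheet at depth 8, NSC nuclei in the
#' 11-14 band directly beneath it, neuronal nuclei deeper still (band
#' 16-24, truncated for shallow stacks), and a high chamber wall density.
#' The resulting chart shows glia peaking first, then NSCs, then neurons.
#'
#' @param shape (slices, height, width), at least (24, 64, 64).
#' @param seed RNG seed.
#' @return A `scene_config` with condition `"fed"`.
#' @export
fed_preset <- function(shape = c(30, 128, 128), seed = 1) {
  shape <- check_preset_shape(shape)
  nz <- shape[1]
  scene_config(shape = shape,
               glia_top_depth = 8,
               nsc_depth_band = c(11, 14),
               neuron_depth_band = c(16, min(24, nz - 4)),
               chamber_wall_density = 0.7,
               neuron_count = max(30L, round(120 * shape[2] * shape[3] / 128^2)),
               membrane_amplitude = 200,
               seed = seed, condition = "fed")
}

#' Starved-condition scene preset
#'
#' The collapsed niche: glial, NSC and neuronal signals all concentrated
#' at the same depth (glial sheet at 12, both nuclear bands 10.5-13.5),
#' sparse chamber walls and a reduced membrane amplitude, emulating the
#' loss of cortex-glial membrane under starvation. All three chart peaks
#' coincide to within a slice.
#'
#' @inheritParams fed_preset
#' @return A `scene_config` with condition `"starved"`.
#' @export
starved_preset <- function(shape = c(30, 128, 128), seed = 1) {
  shape <- check_preset_shape(shape)
  scene_config(shape = shape,
               glia_top_depth = 12,
               nsc_depth_band = c(10.5, 13.5),
               neuron_depth_band = c(10.5, 13.5),
               chamber_wall_density = 0.1,
               neuron_count = max(30L, round(120 * shape[2] * shape[3] / 128^2)),
               membrane_amplitude = 70,
               seed = seed, condition = "starved")
}

#' Intermediate (partially remodelled) scene preset
#'
#' Partway between the collapsed and ordered architectures: moderate wall
#' density, partially separated depth bands and intermediate membrane
#' amplitude, emulating a niche captured mid-remodelling.
#'
#' @inheritParams fed_preset
#' @return A `scene_config` with condition `"intermediate"`.
#' @export
intermediate_preset <- function(shape = c(30, 128, 128), seed = 1) {
  shape <- check_preset_shape(shape)
  nz <- shape[1]
  scene_config(shape = shape,
               glia_top_depth = 9,
               nsc_depth_band = c(11, 13),
               neuron_depth_band = c(14, min(20, nz - 4)),
               chamber_wall_density = 0.4,
               neuron_count = max(30L, round(120 * shape[2] * shape[3] / 128^2)),
               membrane_amplitude = 140,
               seed = seed, condition = "intermediate")
}

# in-plane integrated intensity of one anti-aliased sphere of the given
# radius at axial offset d from its centre (relative units): the radial
# integral of the soft-edged indicator min(1, max(0, r + 1/2 - dist))
.kernel_cache <- new.env(parent = emptyenv())

sphere_depth_kernel <- function(radius, d) {
  ad <- abs(d)
  key <- sprintf("r%.6f", radius)
  cached <- get0(key, envir = .kernel_cache)
  if (is.null(cached)) {
    grid <- seq(0, radius + 1, by = 0.005)
    kern <- vapply(grid, function(dd) {
      stats::integrate(function(rho)
        pmin(1, pmax(0, radius + 0.5 - sqrt(dd^2 + rho^2))) * 2 * pi * rho,
        0, radius + 1)$value
    }, numeric(1))
    cached <- list(grid = grid, kern = kern)
    assign(key, cached, envir = .kernel_cache)
  }
  grid <- cached$grid; kern <- cached$kern
  out <- rep(0, length(ad))
  inside <- ad <= radius + 1
  out[inside] <- stats::approx(grid, kern, ad[inside])$y
  out
}

# true (noise-free, continuous-depth) peak position of a nuclear channel:
# dense-grid argmax of the summed axial profiles of the placed spheres
true_sphere_peak <- function(centers_z, radius) {
  zs <- seq(min(centers_z) - radius, max(centers_z) + radius, by = 0.002)
  offs <- outer(zs, centers_z, "-")
  g <- rowSums(matrix(sphere_depth_kernel(radius, as.vector(offs)),
                      nrow = length(zs)))
  zs[which.max(g)]
}

# symmetric triangular draw on [lo, hi]
rtriangular <- function(n, lo, hi) {
  if (hi <= lo) return(rep(lo, n))
  lo + (hi - lo) * (runif(n) + runif(n)) / 2
}

# paint anti-aliased spheres (max-composited) into a (nz, ny, nx) volume
paint_spheres <- function(vol, centers, radius, amplitude) {
  d <- dim(vol)
  for (k in seq_len(nrow(centers))) {
    cz <- centers[k, 1]; cy <- centers[k, 2]; cx <- centers[k, 3]
    zr <- max(0, floor(cz - radius - 1)):min(d[1] - 1, ceiling(cz + radius + 1))
    yr <- max(0, floor(cy - radius - 1)):min(d[2] - 1, ceiling(cy + radius + 1))
    xr <- max(0, floor(cx - radius - 1)):min(d[3] - 1, ceiling(cx + radius + 1))
    dz2 <- (zr - cz)^2; dy2 <- (yr - cy)^2; dx2 <- (xr - cx)^2
    dist <- sqrt(outer(outer(dz2, dy2, "+"), dx2, "+"))
    val <- amplitude * pmin(1, pmax(0, radius + 0.5 - dist))
    sub <- vol[zr + 1L, yr + 1L, xr + 1L, drop = FALSE]
    vol[zr + 1L, yr + 1L, xr + 1L] <- pmax(sub, val)
  }
  vol
}

# chequerboard wall mask: grid lines of pitch s, thickness wt, each
# cell-length segment present with probability density
wall_mask <- function(ny, nx, s, wt, density) {
  m <- matrix(FALSE, ny, nx)
  if (density <= 0) return(m)
  ycells <- seq(0, ny - 1, by = s)
  xcells <- seq(0, nx - 1, by = s)
  for (xl in xcells) {        # vertical lines (constant x), segmented in y
    cols <- (xl + 1):min(nx, xl + wt)
    for (y0 in ycells) {
      if (runif(1) <= density) {
        rows <- (y0 + 1):min(ny, y0 + s)
        m[rows, cols] <- TRUE
      }
    }
  }
  for (yl in ycells) {        # horizontal lines (constant y), segmented in x
    rows <- (yl + 1):min(ny, yl + wt)
    for (x0 in xcells) {
      if (runif(1) <= density) {
        cols <- (x0 + 1):min(nx, x0 + s)
        m[rows, cols] <- TRUE
      }
    }
  }
  m
}

# separable Gaussian blur along every axis of a 3D array
gaussian_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    b <- aperm(a, perm)
    db <- dim(b)
    b <- K %*% matrix(b, nrow = n)
    dim(b) <- db
    aperm(b, order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

#' Render a synthetic niche scene
#'
#' Deterministically renders the scene described by a [scene_config()]
#' (fixed config + seed gives voxel-identical output) and returns the
#' 16-bit quantized `image_stack` together with the ground truth needed to
#' verify every downstream measurement: true per-role peak depths, object
#' counts and centres, and the integrated supra-threshold glial intensity
#' of the noise-free render at a stated threshold (half the membrane
#' amplitude).
#'
#' The true peak depths are those of the noise-free scene: the glial sheet
#' depth for the glial channel, and for each nuclear channel the
#' continuous-depth maximum of the summed axial profiles of the placed
#' spheres (computed analytically on a dense grid, independent of the
#' voxelized render). This is what a perfect profiler would recover from
#' an unlimited-resolution, noiseless acquisition of the same scene.
#'
#' @param config a `scene_config`.
#' @return List with elements `stack` (an `image_stack`) and `truth`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
  zs <- 0:(nz - 1)

  # --- glial channel: top sheet + chequerboard walls -----------------
  glia <- array(0, dim = c(nz, ny, nx))
  sheet_sigma <- config$glia_sheet_thickness / 2
  sheet_w <- exp(-(zs - config$glia_top_depth)^2 / (2 * sheet_sigma^2))
  walls <- wall_mask(ny, nx, config$chamber_size, config$wall_thickness,
                     config$chamber_wall_density)
  wall_amp <- 0.4 * config$membrane_amplitude
  wall_top <- config$glia_top_depth
  wall_bottom <- min(nz - 1, max(config$neuron_depth_band) + 1)
  for (z in seq_len(nz)) {
    sl <- matrix(config$membrane_amplitude * sheet_w[z], ny, nx)
    if (zs[z] >= wall_top && zs[z] <= wall_bottom)
      sl <- pmax(sl, wall_amp * walls)
    glia[z, , ] <- sl
  }
  if (config$trachea) {
    # bright off-target tube along x near the y = 0 edge
    ty <- 4; tz <- config$glia_top_depth + 3; tr <- 3
    for (z in seq_len(nz)) {
      dz <- zs[z] - tz
      if (abs(dz) > tr) next
      wy <- which(abs((0:(ny - 1)) - ty) <= sqrt(tr^2 - dz^2))
      if (length(wy))
        glia[z, wy, ] <- pmax(glia[z, wy, ], 2 * config$membrane_amplitude)
    }
  }

  # --- NSC channel: one nucleus per chamber cell (jittered grid) -----
  if (is.null(config$nsc_centers)) {
    s <- config$chamber_size
    cy <- seq(s / 2, ny - s / 2, by = s)
    cx <- seq(s / 2, nx - s / 2, by = s)
    grid <- expand.grid(y = cy, x = cx)
    if (!is.null(config$nsc_count)) {
      if (config$nsc_count > nrow(grid))
        stop("nsc_count exceeds available chamber cells")
      grid <- grid[sample.int(nrow(grid), config$nsc_count), , drop = FALSE]
    }
    jit <- max(0, min(4, s / 2 - config$nsc_radius - 2))
    ncen <- nrow(grid)
    nsc_centers <- cbind(
      z = rtriangular(ncen, config$nsc_depth_band[1], config$nsc_depth_band[2]),
      y = grid$y + runif(ncen, -jit, jit),
      x = grid$x + runif(ncen, -jit, jit))
  } else {
    nsc_centers <- config$nsc_centers
    colnames(nsc_centers) <- c("z", "y", "x")
  }
  nsc <- array(0, dim = c(nz, ny, nx))
  nsc <- paint_spheres(nsc, nsc_centers, config$nsc_radius,
                       config$nuclei_amplitude)

  # --- neuron channel: nuclei in the deep band -----------------------
  nn <- config$neuron_count
  mar <- config$neuron_radius + 1
  neuron_centers <- cbind(
    z = rtriangular(nn, config$neuron_depth_band[1],
                    config$neuron_depth_band[2]),
    y = runif(nn, mar, ny - 1 - mar),
    x = runif(nn, mar, nx - 1 - mar))
  neuron <- array(0, dim = c(nz, ny, nx))
  neuron <- paint_spheres(neuron, neuron_centers, config$neuron_radius,
                          config$nuclei_amplitude)

  if (config$blur_sigma > 0) {
    glia <- gaussian_blur3(glia, config$blur_sigma)
    nsc <- gaussian_blur3(nsc, config$blur_sigma)
    neuron <- gaussian_blur3(neuron, config$blur_sigma)
  }

  # ground truth measured on the noise-free render
  stated_thr <- config$membrane_amplitude / 2
  clean_glia <- round(glia)
  truth_intensity <- sum(clean_glia[clean_glia >= stated_thr])

  quantize <- function(a) {
    if (config$noise_sd > 0)
      a <- a + rnorm(length(a), 0, config$noise_sd)
    pmin(65535, pmax(0, round(a)))
  }
  v <- array(0, dim = c(nz, ny, nx, 3L))
  v[, , , 1] <- quantize(glia)
  v[, , , 2] <- quantize(nsc)
  v[, , , 3] <- quantize(neuron)

  stack <- image_stack(v, c(glia = 1L, nsc = 2L, neuron = 3L),
                       z_spacing = config$z_spacing,
                       specimen_id = sprintf("%s_seed%d", config$condition,
                                             config$seed),
                       condition = config$condition)
  truth <- list(
    peak_depth = c(glia = config$glia_top_depth,
                   nsc = true_sphere_peak(nsc_centers[, "z"],
                                          config$nsc_radius),
                   neuron = true_sphere_peak(neuron_centers[, "z"],
                                             config$neuron_radius)),
    nsc_count = nrow(nsc_centers),
    neuron_count = nn,
    nsc_centers = nsc_centers,
    neuron_centers = neuron_centers,
    nsc_radius = config$nsc_radius,
    neuron_radius = config$neuron_radius,
    glia_threshold = stated_thr,
    glia_suprathreshold_intensity = truth_intensity,
    clean_roi = if (config$trachea) roi(12L, ny, 0L, nx) else NULL)
  list(stack = stack, truth = truth, config = config)
}

#' Simulate a cohort of scenes for one condition
#'
#' @param n number of specimens.
#' @param preset `"fed"`, `"starved"` or `"intermediate"`.
#' @param shape stack shape passed to the preset.
#' @param base_seed base RNG seed; specimen i uses
#'   `base_seed * 1000 + i` so cohorts with different base seeds never
#'   share scene seeds.
#' @return List of `generate_scene()` results.
#' @export
simulate_cohort <- function(n = 6, preset = c("fed", "starved", "intermediate"),
                            shape = c(30, 128, 128), base_seed = 1) {
  preset <- match.arg(preset)
  maker <- switch(preset, fed = fed_preset, starved = starved_preset,
                  intermediate = intermediate_preset)
  lapply(seq_len(n), function(i) {
    generate_scene(maker(shape = shape,
                         seed = (base_seed * 1000 + i) %% .Machine$integer.max))
  })
}
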