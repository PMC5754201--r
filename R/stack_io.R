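#' Construct a multi-channel image stack
#'
#' The universal input container of the pipeline: a 4D non-negative
#' intensity array with axes (z, y, x, channel), voxel spacing along Z and
#' a map from biological channel roles to channel indices.
#'
#' The canonical roles are `"glia"` (cortex-glial membrane, e.g.
#' Nrv2::GFP), `"nsc"` (NSC nuclei, e.g. Deadpan) and `"neuron"` (neuronal
#' nuclei, e.g. ElaV); additional marker roles are allowed. Depth is
#' measured in slice units with slice 0 at the top of the stack.
#'
#' @param voxels 4D numeric array, dims (z, y, x, channel); all values must
#'   be finite and non-negative, with at least 3 Z slices (the three-point
#'   peak refinement needs them).
#' @param channel_roles named integer vector mapping role names to 1-based
#'   channel indices, e.g. `c(glia = 1, nsc = 2, neuron = 3)`.
#' @param z_spacing optional slice spacing in micrometres.
#' @param specimen_id,condition free-text specimen metadata (condition
#'   labels such as `"fed"` / `"starved"` drive downstream comparisons).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_roles, z_spacing = NULL,
                        specimen_id = "", condition = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop("voxels must be a 4D array with dims (z, y, x, channel)")
  d <- dim(voxels)
  if (any(d == 0L)) stop("voxels must have positive extent on every axis")
  if (d[1] < 3L) stop("too few slices: at least 3 Z slices are required")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  if (any(voxels < 0)) stop("voxels must be non-negative")
  if (is.null(names(channel_roles)) || any(!nzchar(names(channel_roles))))
    stop("channel_roles must be a named vector of channel indices")
  if (anyDuplicated(names(channel_roles)))
    stop("channel roles must be unique")
  idx <- as.integer(channel_roles)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > d[4]))
    stop("invalid channel index in channel_roles")
  if (anyDuplicated(idx))
    stop("each role must map to a distinct channel")
  if (!is.null(z_spacing)) {
    stopifnot(is.numeric(z_spacing), length(z_spacing) == 1L, z_spacing > 0)
  }
  structure(
    list(voxels = voxels,
         channel_roles = setNames(idx, names(channel_roles)),
         z_spacing = z_spacing,
         specimen_id = as.character(specimen_id),
         condition = as.character(condition)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d slices x %d x %d px, %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                x$channel_roles), collapse = ", "), "\n")
  if (!is.null(x$z_spacing))
    cat(sprintf("  z spacing: %g um/slice\n", x$z_spacing))
  if (nzchar(x$specimen_id))
    cat(sprintf("  specimen: %s (%s)\n", x$specimen_id,
                if (nzchar(x$condition)) x$condition else "no condition"))
  invisible(x)
}

#' Number of Z slices in a stack
#' @param stack an `image_stack`.
#' @export
n_slices <- function(stack) dim(stack$voxels)[1]

#' Extract one channel of a stack by role
#'
#' @param stack an `image_stack`.
#' @param role a role name present in `stack$channel_roles`.
#' @return 3D array (z, y, x).
#' @export
channel <- function(stack, role) {
  if (!role %in% names(stack$channel_roles))
    stop(sprintf("role '%s' not present in stack", role))
  ch <- stack$channel_roles[[role]]
  v <- stack$voxels[, , , ch, drop = FALSE]
  dim(v) <- dim(v)[1:3]
  v
}

#' Rectangular X,Y region of interest
#'
#' Pixel bounds are 0-based and half-open: the ROI covers rows
#' `[y0, y1)` and columns `[x0, x1)` on every slice. ROIs restrict all
#' intensity measurements to a region free of off-target signal (e.g.
#' tracheal GFP).
#'
#' @param y0,y1,x0,x1 integer pixel bounds, `0 <= y0 < y1`, `0 <= x0 < x1`.
#' @return An object of class `roi`.
#' @export
roi <- function(y0, y1, x0, x1) {
  b <- c(y0 = y0, y1 = y1, x0 = x0, x1 = x1)
  if (any(b != floor(b))) stop("roi bounds must be integers")
  if (y0 < 0 || x0 < 0 || y1 <= y0 || x1 <= x0)
    stop("invalid roi: need 0 <= y0 < y1 and 0 <= x0 < x1")
  structure(as.list(as.integer(b)), names = names(b), class = "roi")
}

#' Full-extent ROI of a stack
#' @param stack an `image_stack`.
#' @export
full_roi <- function(stack) {
  d <- dim(stack$voxels)
  roi(0L, d[2], 0L, d[3])
}

check_roi <- function(stack, r) {
  d <- dim(stack$voxels)
  if (r$y1 > d[2] || r$x1 > d[3])
    stop("roi outside stack extent")
  invisible(r)
}

#' Restrict a stack to an X,Y region of interest
#'
#' Crops every slice and channel to `[y0, y1) x [x0, x1)`; the Z extent is
#' unchanged. Idempotent for a fixed ROI.
#'
#' @param stack an `image_stack`.
#' @param r an [roi()].
#' @return A cropped `image_stack`.
#' @export
apply_roi <- function(stack, r) {
  stopifnot(inherits(stack, "image_stack"), inherits(r, "roi"))
  check_roi(stack, r)
  v <- stack$voxels[, (r$y0 + 1L):r$y1, (r$x0 + 1L):r$x1, , drop = FALSE]
  image_stack(v, stack$channel_roles, z_spacing = stack$z_spacing,
              specimen_id = stack$specimen_id, condition = stack$condition)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write a stack to a multi-page TIFF with a YAML metadata sidecar
#'
#' Voxels are stored as unsigned integer samples (8 or 16 bit, one TIFF
#' page per slice, channels as samples per pixel); channel roles, Z
#' spacing, specimen id and condition go to a `.yaml` sidecar next to the
#' image. Intensities must be integer-valued and fit the bit depth — the
#' native representation of confocal exports — so that
#' `read_stack(write_stack(s))` reproduces the voxel data exactly.
#'
#' @param stack an `image_stack` with integer-valued intensities.
#' @param path output file path (`.tif`).
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  v <- stack$voxels
  if (any(v != round(v)))
    stop("voxels must be integer-valued for lossless TIFF storage; quantize first")
  maxv <- 2^bits - 1
  if (any(v > maxv))
    stop(sprintf("intensities exceed %d; use a higher bit depth", maxv))
  d <- dim(v)
  if (d[4] > 4L)
    stop("TIFF storage supports at most 4 channels (samples per pixel)")
  pages <- lapply(seq_len(d[1]), function(z) {
    v[z, , , , drop = TRUE] / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none", reduce = FALSE)
  meta <- list(
    channel_roles = as.list(stack$channel_roles),
    z_spacing = stack$z_spacing,
    specimen_id = stack$specimen_id,
    condition = stack$condition,
    bits_per_sample = as.integer(bits),
    n_channels = d[4])
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads a (Z pages) x (Y, X, channel) TIFF written by [write_stack()] or
#' any compatible export, restoring integer intensities from the stored
#' bit depth. Metadata comes from the YAML sidecar when present; arguments
#' override the sidecar.
#'
#' @param path TIFF file path.
#' @param channel_roles optional named integer vector of role -> channel
#'   (1-based); required when no sidecar exists.
#' @param z_spacing,specimen_id,condition optional metadata overrides.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, channel_roles = NULL, z_spacing = NULL,
                       specimen_id = NULL, condition = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- yaml::read_yaml(sp)
  # libtiff flags 2-sample grayscale pages as having ExtraSamples; benign
  pages <- withCallingHandlers(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!is.list(pages)) pages <- list(pages)
  bits <- meta$bits_per_sample
  if (is.null(bits)) {
    bits <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  }
  maxv <- 2^bits - 1
  first <- pages[[1]]
  if (length(dim(first)) == 2L) {
    ny <- dim(first)[1]; nx <- dim(first)[2]; nc <- 1L
  } else {
    ny <- dim(first)[1]; nx <- dim(first)[2]; nc <- dim(first)[3]
  }
  nz <- length(pages)
  if (nz < 3L) stop("too few slices: at least 3 Z slices are required")
  v <- array(0, dim = c(nz, ny, nx, nc))
  for (z in seq_len(nz)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
    v[z, , , ] <- round(pg * maxv)
  }
  cr <- channel_roles
  if (is.null(cr)) {
    if (is.null(meta$channel_roles))
      stop("channel_roles must be given when no metadata sidecar exists")
    cr <- unlist(meta$channel_roles)
  }
  image_stack(
    v, cr,
    z_spacing = if (!is.null(z_spacing)) z_spacing else meta$z_spacing,
    specimen_id = if (!is.null(specimen_id)) specimen_id
                  else if (!is.null(meta$specimen_id)) meta$specimen_id else "",
    condition = if (!is.null(condition)) condition
                else if (!is.null(meta$condition)) meta$condition else "")
}
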