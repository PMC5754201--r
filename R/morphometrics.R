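#' Threshold policy for one channel
#'
#' Intensity measurements and counts use a single supra-threshold rule per
#' channel per experiment, chosen once and applied identically to every
#' condition being compared. Three modes are supported:
#' * `"absolute"`: `value` is the intensity threshold itself;
#' * `"quantile"`: `value` in \[0, 1\] is an intensity quantile of the
#'   (ROI-restricted) channel, resolved by linear interpolation;
#' * `"otsu"`: Otsu's between-class variance criterion on a 256-level
#'   histogram of the channel (via EBImage).
#'
#' @param role channel role the policy applies to.
#' @param mode one of `"absolute"`, `"quantile"`, `"otsu"`.
#' @param value threshold parameter (intensity for absolute, quantile for
#'   quantile mode; ignored for otsu).
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(role, mode = c("absolute", "quantile", "otsu"),
                             value = NULL) {
  mode <- match.arg(mode)
  if (mode == "absolute") {
    if (is.null(value) || !is.finite(value))
      stop("absolute mode needs a finite threshold value")
  } else if (mode == "quantile") {
    if (is.null(value) || value < 0 || value > 1)
      stop("quantile must lie in [0, 1]")
  }
  structure(list(role = role, mode = mode, value = value),
            class = "threshold_policy")
}

#' Resolve a threshold policy on a stack
#'
#' @param stack an `image_stack`.
#' @param policy a [threshold_policy()].
#' @param r optional [roi()] restricting the intensities used to resolve
#'   quantile/otsu thresholds.
#' @return The numeric intensity threshold.
#' @export
resolve_threshold <- function(stack, policy, r = NULL) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (policy$mode == "absolute") return(policy$value)
  if (!is.null(r)) stack <- apply_roi(stack, r)
  v <- channel(stack, policy$role)
  if (policy$mode == "quantile")
    return(quantile(v, policy$value, type = 7, names = FALSE))
  # otsu
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("otsu mode requires the EBImage package")
  m <- max(v)
  if (m == 0) return(0)
  EBImage::otsu(matrix(v / m, nrow = dim(v)[1]), range = c(0, 1),
                levels = 256L) * m
}

supra_mask <- function(stack, role, thr, r = NULL) {
  if (!is.null(r)) stack <- apply_roi(stack, r)
  v <- channel(stack, role)
  list(values = v, mask = v >= thr)
}

#' Total supra-threshold glial membrane intensity
#'
#' Sum of glial-channel voxel intensities at or above the resolved
#' threshold, over all slices within the ROI — the numerator of the
#' membrane-to-NSC ratio.
#'
#' @param stack an `image_stack` with a `glia` role.
#' @param r optional [roi()].
#' @param policy a [threshold_policy()] (role `"glia"`).
#' @return Total intensity (intensity-times-voxel units).
#' @export
membrane_intensity <- function(stack, r = NULL,
                               policy = threshold_policy("glia", "absolute", 0)) {
  thr <- resolve_threshold(stack, policy, r)
  sm <- supra_mask(stack, policy$role, thr, r)
  sum(sm$values[sm$mask])
}

#' Membrane-to-NSC ratio
#'
#' Summed supra-threshold glial membrane intensity divided by the NSC
#' count: the per-lineage proxy for cortex-glial membrane abundance.
#'
#' @param membrane total supra-threshold glial intensity.
#' @param nsc_count positive integer NSC count.
#' @return The ratio.
#' @export
membrane_to_nsc_ratio <- function(membrane, nsc_count) {
  if (nsc_count <= 0) stop("ratio undefined: nsc_count must be positive")
  membrane / nsc_count
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask 3D logical array (z, y, x).
#' @return Integer array of the same shape; 0 = background, components
#'   numbered 1..k.
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  lab <- .label3d_cpp(as.logical(mask), as.integer(dim(mask)))
  array(lab, dim = dim(mask))
}

#' Count nuclei by thresholding and 3D connected components
#'
#' Thresholds one nuclear channel and counts 26-connected components whose
#' voxel volume reaches `min_volume` (rejecting speckle). Touching nuclei
#' merge into one component — a documented limitation; externally supplied
#' manual counts (see [read_manual_counts()]) may be used instead.
#'
#' @param stack an `image_stack`.
#' @param role nuclear channel role (e.g. `"nsc"`).
#' @param policy a [threshold_policy()] for that role.
#' @param min_volume minimum component volume in voxels.
#' @param r optional [roi()].
#' @return Integer count.
#' @export
count_nuclei <- function(stack, role, policy, min_volume = 1L, r = NULL) {
  thr <- resolve_threshold(stack, policy, r)
  sm <- supra_mask(stack, role, thr, r)
  if (!any(sm$mask)) return(0L)
  lab <- label_components(sm$mask)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_volume)
}

#' Fraction of marker-positive cells
#'
#' @param positive non-negative count of marker-positive cells.
#' @param total positive total cell count, `positive <= total`.
#' @return `positive / total`, in \[0, 1\].
#' @export
marker_positive_fraction <- function(positive, total) {
  if (total <= 0) stop("total must be positive")
  if (positive < 0 || positive > total)
    stop("need 0 <= positive <= total")
  positive / total
}

#' Thresholded neuronal volume
#'
#' Counts supra-threshold voxels in the neuron channel within the ROI;
#' multiplied by `voxel_volume` when given, otherwise reported in voxels.
#'
#' @param stack an `image_stack` with a `neuron` role.
#' @param r optional [roi()].
#' @param policy a [threshold_policy()] (role `"neuron"`).
#' @param voxel_volume optional physical volume of one voxel.
#' @return Volume (voxels, or `voxel_volume` units).
#' @export
neuronal_volume <- function(stack, r = NULL,
                            policy = threshold_policy("neuron", "absolute", 0),
                            voxel_volume = NULL) {
  thr <- resolve_threshold(stack, policy, r)
  sm <- supra_mask(stack, policy$role, thr, r)
  n <- sum(sm$mask)
  if (is.null(voxel_volume)) n else n * voxel_volume
}

#' Centre volumes on the control mean
#'
#' Divides every specimen's volume by the mean control volume, so the
#' control group averages exactly 1; a scale-only transform that preserves
#' all between-specimen ratios.
#'
#' @param values numeric volumes for all specimens.
#' @param control_values the subset of `values` belonging to the control
#'   condition (non-empty, positive mean).
#' @return `values / mean(control_values)`.
#' @export
normalize_volumes <- function(values, control_values) {
  if (length(control_values) == 0L) stop("control group is empty")
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values / m
}

#' Compute all niche metrics for one specimen
#'
#' One-stop morphometrics: supra-threshold membrane intensity, NSC count,
#' membrane-to-NSC ratio and thresholded neuronal volume for a single
#' stack, as one tidy row.
#'
#' @param stack an `image_stack` with glia, nsc and neuron roles.
#' @param r optional [roi()].
#' @param policies named list of [threshold_policy()] objects for roles
#'   `glia`, `nsc` and `neuron`.
#' @param min_volume minimum nucleus volume in voxels for NSC counting.
#' @return A one-row data.frame: specimen_id, condition,
#'   membrane_intensity, nsc_count, membrane_nsc_ratio (NA when no NSC
#'   found), neuron_volume, and the resolved thresholds.
#' @export
niche_metrics <- function(stack, r = NULL, policies, min_volume = 1L) {
  for (role in c("glia", "nsc", "neuron"))
    if (is.null(policies[[role]]))
      stop(sprintf("policies must include role '%s'", role))
  thr <- vapply(c("glia", "nsc", "neuron"), function(role)
    resolve_threshold(stack, policies[[role]], r), numeric(1))
  memb <- membrane_intensity(stack, r, policies$glia)
  nsc <- count_nuclei(stack, "nsc", policies$nsc, min_volume, r)
  vol <- neuronal_volume(stack, r, policies$neuron)
  ratio <- if (nsc > 0) membrane_to_nsc_ratio(memb, nsc) else NA_real_
  if (nsc == 0) warning("no NSC detected: membrane-to-NSC ratio undefined")
  data.frame(specimen_id = stack$specimen_id,
             condition = stack$condition,
             membrane_intensity = memb,
             nsc_count = nsc,
             membrane_nsc_ratio = ratio,
             neuron_volume = vol,
             glia_threshold = thr[["glia"]],
             nsc_threshold = thr[["nsc"]],
             neuron_threshold = thr[["neuron"]],
             row.names = NULL)
}

#' Read externally supplied manual counts
#'
#' CSV schema: `specimen_id`, `marker`, `count` — the escape hatch for
#' counts done by eye (or by other software) instead of the automated
#' connected-component counter.
#'
#' @param path CSV file path.
#' @return data.frame with validated columns.
#' @export
read_manual_counts <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "marker", "count")
  if (!all(need %in% names(tab)))
    stop("manual counts CSV needs columns: specimen_id, marker, count")
  if (any(!is.finite(tab$count)) || any(tab$count < 0) ||
      any(tab$count != round(tab$count)))
    stop("counts must be non-negative integers")
  tab[need]
}
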