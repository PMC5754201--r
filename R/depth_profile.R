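#' Mean intensity per slice for one channel
#'
#' The raw material of the chamber organisation chart: the arithmetic mean
#' of one channel's intensities over the ROI pixels, computed separately
#' for every Z slice.
#'
#' @param stack an `image_stack`.
#' @param role channel role name.
#' @param r optional [roi()]; default is the full X,Y extent.
#' @return Numeric vector of length `n_slices(stack)`.
#' @export
mean_intensity_by_depth <- function(stack, role, r = NULL) {
  if (!is.null(r)) stack <- apply_roi(stack, r)
  v <- channel(stack, role)
  nz <- dim(v)[1]
  rowMeans(matrix(v, nrow = nz))
}

#' Peak-normalize an intensity-versus-depth curve
#'
#' Scales the curve so its maximum is exactly 1. The chart compares the
#' depth distribution of each marker, not its absolute brightness, so each
#' channel is normalized independently.
#'
#' @param raw numeric vector of per-slice mean intensities (length >= 3,
#'   finite, non-negative).
#' @return The curve divided by its maximum.
#' @export
normalize_profile <- function(raw) {
  if (length(raw) < 3L) stop("profile must have at least 3 slices")
  if (!all(is.finite(raw))) stop("profile must be finite")
  if (any(raw < 0)) stop("profile must be non-negative")
  m <- max(raw)
  if (m == 0) stop("empty channel: all-zero profile cannot be normalized")
  raw / m
}

#' Sub-slice peak localization by three-point parabolic interpolation
#'
#' Finds the slice of maximal mean intensity, fits a quadratic through that
#' sample and its two immediate neighbours, and takes the vertex of the
#' parabola (the zero of its derivative) as the refined peak depth:
#' \deqn{z^* = z_0 + \frac{y_- - y_+}{2\,(y_- - 2 y_0 + y_+)}}
#' where \eqn{y_-, y_0, y_+} are the curve values at slices
#' \eqn{z_0 - 1, z_0, z_0 + 1}. This localizes the peak with precision
#' better than the slice spacing. When the maximum sits on the first or
#' last slice, or the three-point stencil is not strictly concave (a
#' plateau), no refinement is attempted and the integer argmax is returned
#' with `refined = FALSE`. Ties in the argmax break to the lowest slice.
#'
#' Depth is in slice units with slice 0 at the top of the stack; the
#' refinement is invariant to positive rescaling of the curve, so raw and
#' peak-normalized profiles give identical positions.
#'
#' @param raw numeric vector of per-slice mean intensities (length >= 3).
#' @return A `peak_estimate`: list with `argmax_slice` (0-based integer),
#'   `refined_position` (real, slice units) and `refined` (logical).
#' @export
refine_peak <- function(raw) {
  if (length(raw) < 3L) stop("profile must have at least 3 slices")
  if (!all(is.finite(raw))) stop("profile must be finite")
  i <- which.max(raw)            # first maximum: lowest-index tie-break
  z0 <- i - 1L                   # 0-based slice coordinate
  refined <- FALSE
  pos <- as.numeric(z0)
  if (i > 1L && i < length(raw)) {
    ym <- raw[i - 1L]; y0 <- raw[i]; yp <- raw[i + 1L]
    curv <- ym - 2 * y0 + yp
    if (curv < 0) {              # strictly concave stencil
      pos <- z0 + (ym - yp) / (2 * curv)
      refined <- TRUE
    }
  }
  structure(list(argmax_slice = z0, refined_position = pos,
                 refined = refined),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak_estimate> argmax slice %d, position %.4f (%s)\n",
              x$argmax_slice, x$refined_position,
              if (x$refined) "refined" else "not refined"))
  invisible(x)
}

#' Build a chamber organisation chart
#'
#' For each requested channel role, computes the mean-intensity-versus-depth
#' curve within the ROI, peak-normalizes it and refines the peak position.
#' A channel whose curve is identically zero is flagged `empty` and carries
#' no normalized curve or peak; the chart is still built for the remaining
#' roles.
#'
#' @param stack an `image_stack` carrying at least the `glia`, `nsc` and
#'   `neuron` roles (or whatever `roles` requests).
#' @param r optional [roi()].
#' @param roles character vector of roles to profile.
#' @param smooth_window optional odd integer; when given, a centred moving
#'   average of this width is applied to each raw curve before
#'   normalization and peak refinement. Off by default (no smoothing) and
#'   recorded in the chart when used.
#' @return A `chamber_chart`: named list of per-role profiles plus
#'   specimen metadata and the ROI used.
#' @export
build_chart <- function(stack, r = NULL, roles = c("glia", "nsc", "neuron"),
                        smooth_window = NULL) {
  missing_roles <- setdiff(roles, names(stack$channel_roles))
  if (length(missing_roles))
    stop(sprintf("stack lacks role(s): %s",
                 paste(missing_roles, collapse = ", ")))
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  }
  used_roi <- if (is.null(r)) full_roi(stack) else r
  profiles <- lapply(roles, function(role) {
    raw <- mean_intensity_by_depth(stack, role, r)
    if (!is.null(smooth_window) && smooth_window > 1)
      raw <- moving_average(raw, smooth_window)
    if (max(raw) == 0) {
      warning(sprintf("empty channel '%s': no signal in ROI", role))
      return(structure(list(role = role, raw = raw, normalized = NULL,
                            peak = NULL, empty = TRUE),
                       class = "depth_profile"))
    }
    structure(list(role = role, raw = raw,
                   normalized = normalize_profile(raw),
                   peak = refine_peak(raw), empty = FALSE),
              class = "depth_profile")
  })
  names(profiles) <- roles
  structure(list(profiles = profiles,
                 specimen_id = stack$specimen_id,
                 condition = stack$condition,
                 roi = used_roi,
                 z_spacing = stack$z_spacing,
                 n_slices = n_slices(stack),
                 smooth_window = smooth_window),
            class = "chamber_chart")
}

moving_average <- function(x, w) {
  h <- (w - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' @export
print.chamber_chart <- function(x, ...) {
  cat(sprintf("<chamber_chart> %s%s, %d slices\n",
              if (nzchar(x$specimen_id)) x$specimen_id else "unnamed",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              x$n_slices))
  for (p in x$profiles) {
    if (p$empty) {
      cat(sprintf("  %-8s empty channel\n", p$role))
    } else {
      cat(sprintf("  %-8s peak at slice %.3f%s\n", p$role,
                  p$peak$refined_position,
                  if (p$peak$refined) "" else " (unrefined)"))
    }
  }
  invisible(x)
}

#' Peak depth offsets relative to the glial top layer
#'
#' The chart's headline statistic: refined NSC and neuron peak depths minus
#' the refined glial peak depth, in slice units. Positive offsets mean
#' deeper than the cortex-glial top layer; an ordered niche shows
#' `0 < nsc_offset < neuron_offset`, while a collapsed niche has both
#' offsets near zero.
#'
#' @param chart a `chamber_chart` with non-empty glia, nsc and neuron
#'   profiles.
#' @return List with `nsc_offset` and `neuron_offset`.
#' @export
peak_offsets <- function(chart) {
  need <- c("glia", "nsc", "neuron")
  for (role in need) {
    p <- chart$profiles[[role]]
    if (is.null(p)) stop(sprintf("chart lacks role '%s'", role))
    if (p$empty) stop(sprintf("empty channel '%s': no peak available", role))
  }
  g <- chart$profiles$glia$peak$refined_position
  list(nsc_offset = chart$profiles$nsc$peak$refined_position - g,
       neuron_offset = chart$profiles$neuron$peak$refined_position - g)
}

#' Tidy table of chart curves
#'
#' @param chart a `chamber_chart`.
#' @return data.frame with columns `slice` (0-based), `role`, `raw`,
#'   `normalized` (NA for empty channels).
#' @export
chart_table <- function(chart) {
  do.call(rbind, lapply(chart$profiles, function(p) {
    data.frame(slice = seq_along(p$raw) - 1L,
               role = p$role,
               raw = p$raw,
               normalized = if (p$empty) NA_real_ else p$normalized,
               row.names = NULL)
  }))
}

#' Tidy table of refined peak positions
#'
#' Depths are reported in slice units; when the chart's stack carried a Z
#' spacing, a micrometre conversion is appended as
#' `refined_position_um`.
#'
#' @param chart a `chamber_chart`.
#' @return data.frame with one row per role: `argmax_slice`,
#'   `refined_position`, `refined`, `empty` (plus `refined_position_um`
#'   when the Z spacing is known).
#' @export
peak_table <- function(chart) {
  tab <- do.call(rbind, lapply(chart$profiles, function(p) {
    data.frame(role = p$role,
               argmax_slice = if (p$empty) NA_integer_ else p$peak$argmax_slice,
               refined_position = if (p$empty) NA_real_
                                  else p$peak$refined_position,
               refined = if (p$empty) NA else p$peak$refined,
               empty = p$empty,
               row.names = NULL)
  }))
  if (!is.null(chart$z_spacing))
    tab$refined_position_um <- tab$refined_position * chart$z_spacing
  tab
}

role_colours <- c(glia = "forestgreen", nsc = "grey35",
                  neuron = "firebrick", marker = "steelblue")

#' Plot a chamber organisation chart
#'
#' Depth (slice units) on the X axis, peak-normalized mean intensity on
#' the Y axis, one curve per channel with a vertical line through each
#' refined peak position. Colour code follows the field's convention:
#' glial membrane green, NSC grey, neurons red.
#'
#' @param chart a `chamber_chart`.
#' @param normalized plot normalized (default) or raw curves.
#' @return A ggplot object.
#' @export
plot_chart <- function(chart, normalized = TRUE) {
  tab <- chart_table(chart)
  tab$value <- if (normalized) tab$normalized else tab$raw
  tab <- tab[!is.na(tab$value), ]
  pk <- peak_table(chart)
  pk <- pk[!pk$empty, ]
  cols <- role_colours[unique(tab$role)]
  cols[is.na(cols)] <- "black"
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$slice, y = .data$value,
                                    colour = .data$role)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(data = pk,
                        ggplot2::aes(xintercept = .data$refined_position,
                                     colour = .data$role),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = "depth (slice)",
                  y = if (normalized) "normalized mean intensity"
                      else "mean intensity",
                  colour = NULL,
                  title = if (nzchar(chart$specimen_id))
                    sprintf("%s%s", chart$specimen_id,
                            if (nzchar(chart$condition))
                              paste0(" (", chart$condition, ")") else "")
                    else NULL) +
    ggplot2::theme_minimal()
}
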