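#' Profile a set of specimens and write chart outputs
#'
#' The profiling stage of the pipeline: builds a chamber organisation
#' chart for every stack, writes per-specimen curve CSVs and peak JSONs
#' (and optionally chart plots) under `out_dir`, records the resolved run
#' configuration as YAML, and returns a tidy per-specimen table of peak
#' positions and offsets. Reruns with identical inputs and configuration
#' produce byte-identical CSV/JSON outputs.
#'
#' Per-specimen quality flags (empty channels, unrefined boundary peaks,
#' mixed Z spacings across the set) are collected in the returned table
#' and surfaced as warnings.
#'
#' @param stacks list of `image_stack` objects (or a single stack).
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param r optional [roi()] applied to every specimen.
#' @param roles roles to profile.
#' @param smooth_window optional odd moving-average width (see
#'   [build_chart()]).
#' @param write_plots also write a PNG chart per specimen.
#' @return data.frame, one row per specimen: specimen_id, condition, per
#'   role refined peak position and refinement flag, nsc_offset,
#'   neuron_offset, n_warnings.
#' @export
run_profile <- function(stacks, out_dir = NULL, r = NULL,
                        roles = c("glia", "nsc", "neuron"),
                        smooth_window = NULL, write_plots = FALSE) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (!length(stacks)) stop("no input stacks")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spacings <- unique(vapply(stacks, function(s)
    if (is.null(s$z_spacing)) NA_real_ else s$z_spacing, numeric(1)))
  if (length(spacings[!is.na(spacings)]) > 1L)
    warning("mixing stacks with different z spacings; slice-unit depths are not comparable across specimens")
  rows <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    sid <- if (nzchar(s$specimen_id)) s$specimen_id else sprintf("specimen%02d", i)
    nwarn <- 0L
    chart <- withCallingHandlers(
      build_chart(s, r = r, roles = roles, smooth_window = smooth_window),
      warning = function(w) nwarn <<- nwarn + 1L)
    pk <- peak_table(chart)
    offs <- if (all(c("glia", "nsc", "neuron") %in% roles) &&
                !any(pk$empty[pk$role %in% c("glia", "nsc", "neuron")])) {
      peak_offsets(chart)
    } else list(nsc_offset = NA_real_, neuron_offset = NA_real_)
    nwarn <- nwarn + sum(!pk$refined & !pk$empty, na.rm = TRUE)
    row <- data.frame(specimen_id = sid, condition = s$condition,
                      row.names = NULL)
    for (role in roles) {
      row[[paste0(role, "_peak")]] <- pk$refined_position[pk$role == role]
      row[[paste0(role, "_refined")]] <- pk$refined[pk$role == role]
    }
    row$nsc_offset <- offs$nsc_offset
    row$neuron_offset <- offs$neuron_offset
    row$n_warnings <- nwarn
    rows[[i]] <- row
    if (!is.null(out_dir)) {
      write.csv(chart_table(chart),
                file.path(out_dir, paste0(sid, "_chart.csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(specimen_id = sid, condition = s$condition,
             peaks = peak_table(chart),
             nsc_offset = offs$nsc_offset,
             neuron_offset = offs$neuron_offset),
        file.path(out_dir, paste0(sid, "_peaks.json")),
        auto_unbox = TRUE, digits = NA, na = "null")
      if (write_plots) {
        p <- plot_chart(chart)
        ggplot2::ggsave(file.path(out_dir, paste0(sid, "_chart.png")), p,
                        width = 6, height = 4, dpi = 150)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(out, file.path(out_dir, "profile_summary.csv"),
              row.names = FALSE)
    cfg <- list(
      stage = "profile",
      roles = roles,
      roi = if (is.null(r)) "full" else unclass(r),
      smooth_window = smooth_window,
      specimens = lapply(stacks, function(s) list(
        specimen_id = s$specimen_id, condition = s$condition,
        dims = dim(s$voxels), z_spacing = s$z_spacing,
        voxel_checksum = sprintf("%.0f", sum(s$voxels)))))
    yaml::write_yaml(cfg, file.path(out_dir, "profile_config.yaml"))
  }
  out
}

#' Compare a metric between two conditions and write the report
#'
#' The reporting stage: unpaired Student's t-test on one per-specimen
#' metric between two conditions, with group summaries, significance
#' stars, and optional bar (mean +/- SEM) and whisker (five-number) plots,
#' written as CSV + JSON under `out_dir`.
#'
#' @param metrics tidy per-specimen metrics table (e.g. from
#'   [niche_metrics()] or [run_profile()]) with a `condition` column.
#' @param metric metric column name.
#' @param cond_a,cond_b condition labels, each with at least 2 specimens.
#' @param out_dir output directory (`NULL` skips file output).
#' @param convention a [star_convention()].
#' @param var_equal,use_summary test variants, see [compare_conditions()].
#' @param write_plots also write bar and whisker plots (PNG).
#' @return The `condition_comparison`, invisibly returned after writing.
#' @export
run_compare <- function(metrics, metric, cond_a, cond_b, out_dir = NULL,
                        convention = star_convention(),
                        var_equal = TRUE, use_summary = FALSE,
                        write_plots = FALSE) {
  conds <- unique(metrics$condition)
  if (length(conds) < 2L)
    stop("need at least 2 conditions to compare")
  cmp <- compare_conditions(metrics, metric, cond_a, cond_b,
                            convention = convention, var_equal = var_equal,
                            use_summary = use_summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("%s_%s_vs_%s", metric, cond_a, cond_b)
    write.csv(as.data.frame(cmp),
              file.path(out_dir, paste0(tag, "_comparison.csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(metric = cmp$metric, conditions = cmp$conditions,
           groups = lapply(cmp$summaries, function(s) list(
             condition = s$condition, n = s$n, mean = s$mean, sem = s$sem,
             five_number = as.list(s$five_number))),
           t = cmp$t, df = cmp$df, p_value = cmp$p_value,
           stars = cmp$stars, test = cmp$test),
      file.path(out_dir, paste0(tag, "_comparison.json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    if (write_plots) {
      sub <- metrics[metrics$condition %in% c(cond_a, cond_b), ]
      ggplot2::ggsave(file.path(out_dir, paste0(tag, "_bars.png")),
                      plot_group_bars(sub, metric),
                      width = 4, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, paste0(tag, "_whiskers.png")),
                      plot_group_whiskers(sub, metric),
                      width = 4, height = 4, dpi = 150)
    }
  }
  invisible(cmp)
}
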