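# End-to-end console pipeline: stream frames one at a time, compute leaflet
# assignment -> inclusion insertion -> per-leaflet tessellation -> APL / MT /
# neighbors -> selections, and write frame exports, XVG time series and
# optional Voronoi maps.

#' Build a run configuration
#'
#' @param topology Path to the PDB topology.
#' @param trajectories Character vector of XTC/TRR paths (>= 1).
#' @param output_dir Output directory (created if missing).
#' @param first,last,stride Frame window (0-based, inclusive; `last = NULL`
#'   means end of file).
#' @param leaflet_method `"orientation"` or `"position"`.
#' @param degree Midsurface polynomial degree (position method).
#' @param all_atoms Fit the midsurface to all lipid atoms.
#' @param lipid_defs Lipid definitions (list of [lipid_def()] or a
#'   definitions file path).
#' @param inclusions Insert non-lipid atoms into the tessellations.
#' @param slab_margin Inclusion slab margin, nm.
#' @param selection Optional selection expression (see [parse_query()]);
#'   adds a selection-mean column to the time series.
#' @param freeze_frame `NULL` for per-frame (dynamic) selection membership,
#'   or a 0-based frame position to pin membership to.
#' @param export_format `"txt"`, `"xml"`, both, or `NULL` for none.
#' @param statistics Time-series statistics to compute.
#' @param render_maps Write a Voronoi map PNG per leaflet for the first
#'   frame.
#' @param scale_name,vmin,vmax Color scale for rendered maps (NULL bounds =
#'   per-frame min/max).
#' @param offsets,strides Per-trajectory synchronization (see
#'   [sync_spec()]), recycled to the number of trajectories.
#' @param labels Trajectory labels for combined series columns.
#' @return A `run_config`.
#' @export
run_config <- function(topology, trajectories, output_dir,
                       first = 0L, last = NULL, stride = 1L,
                       leaflet_method = c("orientation", "position"),
                       degree = 2L, all_atoms = FALSE,
                       lipid_defs = default_lipid_defs(),
                       inclusions = TRUE, slab_margin = 0.5,
                       selection = NULL, freeze_frame = NULL,
                       export_format = "txt",
                       statistics = c("mean_apl", "mean_thickness"),
                       render_maps = FALSE, scale_name = "locs",
                       vmin = NULL, vmax = NULL,
                       offsets = 0L, strides = 1L, labels = NULL) {
  leaflet_method <- match.arg(leaflet_method)
  if (length(trajectories) < 1L) stop2("need at least one trajectory")
  if (!file.exists(topology)) stop2("topology not found: ", topology)
  missing_traj <- trajectories[!file.exists(trajectories)]
  if (length(missing_traj))
    stop2("trajectory not found: ", paste(missing_traj, collapse = ", "))
  if (is.character(lipid_defs) && length(lipid_defs) == 1L)
    lipid_defs <- read_lipid_defs(lipid_defs)
  range <- frame_range(first, last, stride)  # validates
  if (!is.null(selection)) parse_query(selection)  # validate early
  stopifnot(all(statistics %in% c("mean_apl", "mean_thickness")))
  nt <- length(trajectories)
  structure(list(topology = topology, trajectories = trajectories,
                 output_dir = output_dir, range = range,
                 leaflet_method = leaflet_method, degree = as.integer(degree),
                 all_atoms = isTRUE(all_atoms), lipid_defs = lipid_defs,
                 inclusions = isTRUE(inclusions), slab_margin = slab_margin,
                 selection = selection, freeze_frame = freeze_frame,
                 export_format = export_format, statistics = statistics,
                 render_maps = isTRUE(render_maps), scale_name = scale_name,
                 vmin = vmin, vmax = vmax,
                 sync = sync_spec(rep_len(as.integer(offsets), nt),
                                  rep_len(as.integer(strides), nt)),
                 labels = labels %||%
                   tools::file_path_sans_ext(basename(trajectories))),
            class = "run_config")
}

.write_run_cfg <- function(config, path) {
  flat <- c(topology = config$topology,
            trajectories = paste(config$trajectories, collapse = ","),
            first = config$range$first,
            last = config$range$last %||% "end",
            stride = config$range$stride,
            leaflet_method = config$leaflet_method,
            degree = config$degree, all_atoms = config$all_atoms,
            inclusions = config$inclusions,
            slab_margin = config$slab_margin,
            selection = config$selection %||% "",
            export_format = paste(config$export_format, collapse = ","),
            statistics = paste(config$statistics, collapse = ","),
            offsets = paste(config$sync$offsets, collapse = ","),
            strides = paste(config$sync$strides, collapse = ","))
  con <- file(path, "wb")
  writeLines(paste0(names(flat), " = ", unlist(flat)), con, sep = "\n")
  close(con)
}

#' Run the analysis pipeline
#'
#' Streams each trajectory frame by frame (a single frame in memory at a
#' time), computes per-lipid metrics, writes per-frame TXT/XML exports and
#' per-statistic XVG time series into the output directory, and — with
#' multiple trajectories — synchronized multi-column XVGs on the aligned
#' frame axis. A `run.cfg` provenance copy of the configuration is written
#' alongside.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-trajectory series, combined series,
#'   and output paths.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  frames_dir <- file.path(config$output_dir, "frames")
  if (length(config$export_format))
    dir.create(frames_dir, showWarnings = FALSE)
  .write_run_cfg(config, file.path(config$output_dir, "run.cfg"))

  topology <- read_topology(config$topology, config$lipid_defs)
  sel_query <- if (!is.null(config$selection)) parse_query(config$selection)

  per_traj <- vector("list", length(config$trajectories))
  lengths <- integer(length(config$trajectories))
  outputs <- character()

  for (j in seq_along(config$trajectories)) {
    traj <- config$trajectories[[j]]
    label <- config$labels[[j]]
    reader <- open_trajectory(traj, topology, config$range)
    stats_acc <- lapply(config$statistics, function(s) list())
    names(stats_acc) <- config$statistics
    sel_acc <- list()
    frozen_ids <- NULL
    xs <- numeric()
    pos <- 0L
    first_tess <- NULL
    while (!is.null(fr <- next_frame(reader))) {
      pos <- pos + 1L
      assignment <- assign_leaflets(fr, topology, config$leaflet_method,
                                    config$degree, config$all_atoms)
      metrics <- compute_frame_metrics(fr, topology, assignment,
                                       inclusions = config$inclusions,
                                       slab_margin = config$slab_margin)
      if (is.null(first_tess)) first_tess <- list(metrics = metrics)
      xs <- c(xs, fr$frame_index)
      ids <- NULL
      if (!is.null(sel_query)) {
        ids <- if (!is.null(config$freeze_frame)) {
          if (pos - 1L == config$freeze_frame || is.null(frozen_ids))
            frozen_ids <- evaluate_selection(metrics, sel_query, topology)
          frozen_ids
        } else evaluate_selection(metrics, sel_query, topology)
        sel_acc[[pos]] <- ids
      }
      for (s in config$statistics) {
        v <- if (s == "mean_apl") metrics$apl else metrics$thickness
        row <- c(all = mean(v),
                 upper = mean(v[metrics$leaflet == "upper"]),
                 lower = mean(v[metrics$leaflet == "lower"]))
        if (!is.null(sel_query))
          row <- c(row, selection = if (length(ids))
            mean(v[metrics$lipid_id %in% ids]) else NA_real_)
        stats_acc[[s]][[pos]] <- row
      }
      for (fmt in config$export_format) {
        fp <- file.path(frames_dir,
                        sprintf("%s_f%05d.%s", label, fr$frame_index, fmt))
        write_frame_export(metrics, fmt, fp)
        outputs <- c(outputs, fp)
      }
    }
    lengths[[j]] <- pos
    series <- list()
    for (s in config$statistics) {
      mat <- do.call(rbind, stats_acc[[s]])
      df <- cbind(data.frame(frame = xs), as.data.frame(mat))
      attr(df, "xlabel") <- "frame"
      attr(df, "ylabel") <- if (s == "mean_apl") "APL (nm^2)" else
        "thickness (nm)"
      xvg <- file.path(config$output_dir, sprintf("%s_%s.xvg", label, s))
      write_xvg(df, xvg, title = sprintf("%s of %s", s, label))
      outputs <- c(outputs, xvg)
      series[[s]] <- df
    }
    if (!is.null(sel_query)) {
      ns <- data.frame(frame = xs,
                       n_selected = vapply(sel_acc, length, integer(1)))
      attr(ns, "ylabel") <- "lipids selected"
      xvg <- file.path(config$output_dir,
                       sprintf("%s_selection_count.xvg", label))
      write_xvg(ns, xvg, title = paste("selection:", config$selection))
      outputs <- c(outputs, xvg)
      series$selection_count <- ns
    }
    if (config$render_maps && !is.null(first_tess)) {
      tl <- attr(first_tess$metrics, "tessellations")
      for (lf in names(tl)) {
        tess <- tl[[lf]]
        mm <- first_tess$metrics
        vals <- mm$apl[match(tess$generators$lipid_id[
          tess$generators$kind == "lipid"], mm$lipid_id)]
        vmin <- config$vmin %||% min(vals)
        vmax <- config$vmax %||% max(vals)
        if (vmin >= vmax) { vmin <- vmin - 0.5; vmax <- vmax + 0.5 }
        png <- file.path(config$output_dir,
                         sprintf("%s_%s_apl.png", label, lf))
        render_voronoi_map(tess, vals,
                           color_scale(config$scale_name, vmin, vmax),
                           highlight = if (!is.null(sel_query))
                             evaluate_selection(first_tess$metrics, sel_query)
                           else integer(),
                           out_path = png, label = toupper(lf))
        outputs <- c(outputs, png)
      }
    }
    per_traj[[j]] <- series
  }

  combined <- NULL
  if (length(config$trajectories) > 1L) {
    alignment <- synchronize(lengths, config$sync)
    combined <- list()
    for (s in config$statistics) {
      sl <- lapply(per_traj, function(tr)
        tr[[s]][, c("frame", "upper")])
      cmb <- series_compare(sl, alignment, labels = config$labels)
      attr(cmb, "ylabel") <- if (s == "mean_apl") "APL (nm^2)" else
        "thickness (nm)"
      xvg <- file.path(config$output_dir, sprintf("combined_%s.xvg", s))
      write_xvg(cmb, xvg,
                title = sprintf("%s (upper leaflet), synchronized", s))
      outputs <- c(outputs, xvg)
      combined[[s]] <- cmb
    }
  }
  invisible(list(per_traj = setNames(per_traj, config$labels),
                 combined = combined, lengths = lengths, outputs = outputs))
}
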