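#' Default pipeline configuration
#'
#' One structured list drives the whole run: phantom geometry, bubble flow,
#' rendering, clutter filtering, localization/tracking, map accumulation,
#' segmentation and metrics. The tracking gate defaults to the maximum
#' expected per-frame displacement (twice the fastest mean speed, the
#' Poiseuille centerline maximum, times the frame interval) with a 1.5x
#' safety margin.
#'
#' @param seed global integer seed; per-stage child seeds are derived from
#'   it deterministically.
#' @return nested configuration list for [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = default_phantom_config(),
    flow = list(bubbles_per_frame = 1.0, duration = 400L, frame_rate = 500),
    render = list(psf_sigma_um = 20,
                  clutter = list(rank = 2L, amplitude = 100, drift = 0.1),
                  noise_sigma = 0.05),
    filter = list(cutoff = "auto"),
    track = list(intensity_threshold = 6, min_separation = 4, w = 3L,
                 max_link_um = NULL, min_track_len = 15L),
    maps = list(grid_factor = 4L, interpolate = TRUE),
    segment = list(rule = list(method = "count", k = 2), close_radius = 2L,
                   min_size = 30L, prune_px = 5L),
    metrics = list(axial = TRUE, min_chord_um = 20)
  )
}

validate_config <- function(config) {
  ref <- default_run_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), setdiff(names(ref), c("seed", "phantom")))) {
    extra <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(extra))
      stop("unknown keys in config$", blk, ": ", paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

default_gate_um <- function(config) {
  vmax <- max(vapply(config$phantom$regions,
                     function(r) max(r$speed_mm_s %||% 0), numeric(1)))
  2 * vmax * 1000 / config$flow$frame_rate * 1.5
}

#' Dice overlap between a recovered vessel mask and the true mask
#'
#' Both masks must live on the same grid. With `grid_factor` given, both are
#' first reduced to the acquisition grid identically (a coarse pixel is
#' vessel if any of its fine pixels is): a finite number of bubble transits
#' traces lumens without saturating them at super-resolution, so the
#' acquisition grid is where segmentation quality is meaningfully judged.
#' This is the deterministic segmentation-quality gate of the pipeline.
#'
#' @param mask_sr logical recovered mask.
#' @param truth_mask logical truth mask on the same grid.
#' @param grid_factor optional block size for the symmetric coarse reduction.
#' @return Dice coefficient in `[0, 1]`.
#' @export
segmentation_dice <- function(mask_sr, truth_mask, grid_factor = NULL) {
  stopifnot(identical(dim(mask_sr), dim(truth_mask)))
  if (!is.null(grid_factor) && grid_factor > 1L) {
    mask_sr <- downsample_density(mask_sr + 0, grid_factor) > 0
    truth_mask <- downsample_density(truth_mask + 0, grid_factor) > 0
  }
  2 * sum(mask_sr & truth_mask) / (sum(mask_sr) + sum(truth_mask))
}

#' Run the full ULM pipeline
#'
#' simulate -> filter -> track -> reconstruct -> segment -> metrics ->
#' compare, writing every stage's artifacts into `out_dir` (TIFF/CSV/JSON/
#' PNG only) when given. Re-running with the same config produces
#' bit-identical CSV outputs. A stage failure aborts with the stage named;
#' artifacts of completed stages are preserved.
#'
#' @param config configuration list ([default_run_config()]).
#' @param out_dir optional output directory.
#' @return list with `phantom`, `trajectories`, `movie`, `filtered`,
#'   `spectrum`, `localizations`, `tracks`, `maps`, `mask`, `graph`,
#'   `metrics` (per-region data frame), `segment_table` (per-segment data
#'   frame), `comparison` (stats table or NULL), `dice`, `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(
      list(seed = seed, r_version = R.version.string,
           package_version = as.character(utils::packageVersion("ulmvasc"))),
      file.path(out_dir, "run.json"), auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  res <- list(config = config)
  res$phantom <- stage("simulate", generate_phantom(config$phantom,
                                                    stage_seed(seed, "phantom")))
  res$trajectories <- stage("simulate", simulate_bubble_flow(
    res$phantom, config$flow$bubbles_per_frame, config$flow$duration,
    config$flow$frame_rate, stage_seed(seed, "flow")))
  res$movie <- stage("simulate", render_movie(
    res$trajectories, config$render$psf_sigma_um, config$render$clutter,
    config$render$noise_sigma, stage_seed(seed, "render")))
  if (!is.null(out_dir)) {
    write_frame_stack(res$movie, file.path(out_dir, "movie.tiff"), seed = seed)
    write_csv_det(as.data.frame(res$trajectories),
                  file.path(out_dir, "truth_trajectories.csv"))
    write_mask_png(phantom_vessel_mask(res$phantom),
                   file.path(out_dir, "truth_vessel_mask.png"))
  }

  flt <- stage("filter", svd_filter(res$movie, config$filter$cutoff))
  res$filtered <- flt$filtered
  res$spectrum <- flt$spectrum
  if (!is.null(out_dir)) {
    write_csv_det(data.frame(index = seq_along(flt$spectrum$values),
                             value = flt$spectrum$values,
                             cutoff = flt$spectrum$cutoff),
                  file.path(out_dir, "spectrum.csv"))
  }

  res$localizations <- stage("track", localize_stack(
    res$filtered, intensity_threshold = config$track$intensity_threshold,
    min_separation = config$track$min_separation, w = config$track$w))
  gate <- config$track$max_link_um %||% default_gate_um(config)
  res$tracks <- stage("track", link_tracks(res$localizations, gate,
                                           config$track$min_track_len))
  if (!is.null(out_dir)) {
    write_csv_det(res$localizations, file.path(out_dir, "localizations.csv"))
    write_csv_det(tracks_to_df(res$tracks, config$flow$frame_rate),
                  file.path(out_dir, "tracks.csv"))
  }

  res$maps <- stage("reconstruct", accumulate_maps(
    res$tracks, res$phantom$grid, config$flow$frame_rate,
    config$maps$grid_factor, config$maps$interpolate))
  if (!is.null(out_dir)) write_maps(res$maps, file.path(out_dir, "maps"))

  res$mask <- stage("segment", binarize_density(
    res$maps$density, config$segment$rule, config$segment$close_radius,
    config$segment$min_size))
  skel <- stage("segment", skeletonize_mask(res$mask))
  res$graph <- stage("segment", extract_graph(skel, res$maps$pixel_size_um,
                                              config$segment$prune_px))
  if (length(res$graph$segments) > 0L && any(res$mask)) {
    res$graph <- stage("segment", estimate_diameters(res$mask, res$graph))
  }
  res$dice <- segmentation_dice(
    res$mask, phantom_vessel_mask(res$phantom, config$maps$grid_factor),
    config$maps$grid_factor)
  if (!is.null(out_dir)) {
    write_mask_png(res$mask, file.path(out_dir, "vessel_mask.png"))
    write_mask_png(skel, file.path(out_dir, "skeleton.png"))
    write_csv_det(res$graph$nodes, file.path(out_dir, "nodes.csv"))
    write_csv_det(segments_df(res$graph), file.path(out_dir, "segments.csv"))
  }

  gf <- config$maps$grid_factor
  regions <- sort(unique(as.vector(res$phantom$region_map)))
  met <- lapply(regions, function(rg) {
    roi <- region_roi(res$phantom, rg, gf)
    m <- stage("metrics", region_metrics(
      res$maps, res$graph, res$mask, roi, axial = config$metrics$axial,
      min_chord_um = config$metrics$min_chord_um %||% 20))
    region_metrics_df(m, region = rg)
  })
  res$metrics <- do.call(rbind, met)

  seg_tab <- stage("metrics", segment_region_table(
    res$graph, res$maps, res$phantom, gf))
  res$segment_table <- seg_tab
  if (!is.null(out_dir)) {
    write_csv_det(res$metrics, file.path(out_dir, "metrics.csv"))
    write_csv_det(seg_tab, file.path(out_dir, "segment_metrics.csv"))
  }

  res$comparison <- stage("compare", {
    long <- segment_table_long(seg_tab)
    if (nrow(long)) compare_regions(long) else NULL
  })
  if (!is.null(out_dir) && !is.null(res$comparison)) {
    write_csv_det(res$comparison, file.path(out_dir, "comparison.csv"))
  }
  structure(res, class = "ulm_run")
}

#' @export
print.ulm_run <- function(x, ...) {
  cat("ulm_run:\n")
  cat(sprintf("  movie      %d frames, %d x %d px\n", dim(x$movie$frames)[3],
              dim(x$movie$frames)[1], dim(x$movie$frames)[2]))
  cat(sprintf("  filter     cutoff rank %d\n", x$spectrum$cutoff))
  cat(sprintf("  tracking   %d localizations -> %d tracks\n",
              nrow(x$localizations), length(x$tracks)))
  cat(sprintf("  graph      %d segments, %d branch points (Dice %.3f)\n",
              length(x$graph$segments),
              sum(x$graph$nodes$kind == "branch_point"), x$dice))
  cat(sprintf("  regions    %s\n", paste(x$metrics$region, collapse = ", ")))
  invisible(x)
}

# per-segment metric table with region assignment (majority of centerline)
segment_region_table <- function(graph, maps, phantom, grid_factor) {
  if (length(graph$segments) == 0L)
    return(data.frame(segment_id = integer(0), region = character(0),
                      curvature = numeric(0), diameter_um = numeric(0),
                      velocity_mm_s = numeric(0), flow_nl_s = numeric(0),
                      lc_um = numeric(0)))
  rois <- lapply(sort(unique(as.vector(phantom$region_map))),
                 function(rg) region_roi(phantom, rg, grid_factor))
  names(rois) <- sort(unique(as.vector(phantom$region_map)))
  do.call(rbind, lapply(graph$segments, function(s) {
    fr <- vapply(rois, function(roi) {
      ok <- s$pixels[, 1] >= 1 & s$pixels[, 1] <= nrow(roi) &
            s$pixels[, 2] >= 1 & s$pixels[, 2] <= ncol(roi)
      mean(roi[s$pixels[ok, , drop = FALSE]])
    }, numeric(1))
    v <- maps$velocity[s$pixels]
    v <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    d <- s$diameter_um %||% NA_real_
    data.frame(segment_id = s$id, region = names(which.max(fr)),
               curvature = if (s$l_um > 0) s$lc_um / s$l_um else NA_real_,
               diameter_um = d, velocity_mm_s = v,
               flow_nl_s = if (is.na(d) || is.na(v)) NA_real_ else flow_volume(d, v),
               lc_um = s$lc_um, stringsAsFactors = FALSE)
  }))
}

segment_table_long <- function(seg_tab) {
  pars <- c("curvature", "diameter_um", "velocity_mm_s", "flow_nl_s")
  out <- do.call(rbind, lapply(pars, function(p) {
    d <- seg_tab[!is.na(seg_tab[[p]]), c("region", p)]
    if (nrow(d) == 0L) return(NULL)
    data.frame(region = d$region, parameter = p, value = d[[p]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(region = character(0), parameter = character(0),
                      value = numeric(0))
  out
}
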