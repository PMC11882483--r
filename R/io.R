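#' Write a frame stack as multi-page TIFF with JSON sidecar
#'
#' TIFF samples are stored normalized to `[0, 1]` at 32-bit precision; the
#' affine offset/scale needed to restore physical amplitudes is recorded in
#' the sidecar together with pixel size and frame rate.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param seed optional seed recorded for provenance.
#' @export
write_frame_stack <- function(stack, path, seed = NULL) {
  f <- stack$frames
  lo <- min(f); hi <- max(f)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(f)[3]), function(t) (f[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_rate_hz = stack$frame_rate_hz,
               offset = lo, scale = scale, n_frames = dim(f)[3])
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#' @param path TIFF path with `<path>.json` sidecar.
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  f <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) f[, , t] <- pages[[t]] * meta$scale + meta$offset
  frame_stack(f, meta$pixel_size_um, meta$frame_rate_hz)
}

#' Write super-resolution maps (TIFFs plus JSON sidecar)
#' @param maps a `super_res_maps` object.
#' @param dir output directory (created if missing).
#' @export
write_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    v <- m; v[is.na(v)] <- 0
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((v - lo) / scale, file.path(dir, paste0(name, ".tiff")),
                    bits.per.sample = 32L, compression = "none")
    list(offset = lo, scale = scale)
  }
  meta <- list(grid_factor = maps$grid_factor,
               pixel_size_um = maps$pixel_size_um,
               density = wr(maps$density, "density"),
               velocity = wr(maps$velocity, "velocity"),
               direction = wr(maps$direction, "direction"))
  jsonlite::write_json(meta, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a binary mask as PNG
#' @param mask logical matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

# deterministic CSV writer (fixed 15-significant-digit formatting)
write_csv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE,
                                          scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
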