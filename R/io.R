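#' Write / read an SH stack as a multi-page TIFF with JSON metadata
#'
#' Counts are stored as 16-bit grayscale (scaled by `max_count`); frame
#' times, pixel size and other metadata go to a JSON sidecar file
#' (`<path>.json`).
#'
#' @param stack an [sh_stack()]
#' @param path TIFF output path
#' @param max_count full-scale count value mapped to 16-bit white
#' @return the path, invisibly
#' @export
write_stack_tiff <- function(stack, path, max_count = 65535) {
  stopifnot(inherits(stack, "sh_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(f) {
    pmin(pmax(stack$frames[, , f] / max_count, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(times_s = stack$times_s,
               pixel_size_um = stack$pixel_size_um,
               max_count = max_count,
               metadata = stack$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path TIFF path written by [write_stack_tiff()]
#' @rdname write_stack_tiff
#' @return [read_stack_tiff()] returns an [sh_stack()]
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) stop("stack not found: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * meta$max_count
  md <- meta$metadata
  if (!is.null(md$frame_windows)) {
    md$frame_windows <- lapply(md$frame_windows, as.integer)
  }
  sh_stack(frames, times_s = meta$times_s,
           pixel_size_um = meta$pixel_size_um,
           metadata = md)
}

#' Write a per-pixel potential map as 32-bit float TIFF
#'
#' @param map numeric matrix of potentials (V)
#' @param path output path
#' @return the path, invisibly
#' @export
write_potential_map_tiff <- function(map, path) {
  stopifnot(is.matrix(map))
  tiff::writeTIFF(map, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a domain catalog as CSV
#'
#' Columns `frame, x, y, area_um2, mean_intensity, mean_potential_V`
#' (pixel lists are dropped).
#'
#' @param catalog a `domain_catalog`
#' @param path output path
#' @return the path, invisibly
#' @export
write_domain_catalog_csv <- function(catalog, path) {
  stopifnot(is.data.frame(catalog))
  cols <- intersect(c("frame", "x", "y", "area_um2", "mean_intensity",
                      "mean_potential_V"), names(catalog))
  utils::write.csv(as.data.frame(catalog)[, cols, drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a tau/flux ROI grid as CSV
#'
#' Long format: `roi_row, roi_col, tau_min, flux_ions_per_s`.
#'
#' @param tmap a `tau_map`
#' @param path output path
#' @return the path, invisibly
#' @export
write_tau_map_csv <- function(tmap, path) {
  stopifnot(inherits(tmap, "tau_map"))
  g <- expand.grid(roi_row = seq_len(nrow(tmap$tau)),
                   roi_col = seq_len(ncol(tmap$tau)))
  g$tau_min <- tmap$tau[cbind(g$roi_row, g$roi_col)]
  g$flux_ions_per_s <- tmap$flux[cbind(g$roi_row, g$roi_col)]
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}
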