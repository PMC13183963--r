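# Readers and writers: images, 16-bit instance maps, experiment layouts
# and grouped result tables.

#' Load an image as an intensity grid in \[0,1\]
#'
#' Reads PNG/TIFF/JPEG via EBImage; 8- and 16-bit depths map to \[0,1\].
#' Grayscale images return a matrix, colour images an H x W x 3 array in
#' row (y) / column (x) order.
#'
#' @param path Image path.
#' @return Matrix or 3-channel array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores (x, y[, c]); transpose to (y, x[, c])
  if (length(dim(a)) == 2) out <- t(a)
  else {
    if (dim(a)[3] > 3) a <- a[, , 1:3]
    out <- aperm(a, c(2, 1, 3))
  }
  pmin(pmax(out, 0), 1)
}

#' Write an image
#' @param image Matrix or H x W x 3 array in \[0,1\].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @export
write_image <- function(image, path) {
  a <- if (length(dim(image)) == 2) t(image) else aperm(image, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a,
    colormode = if (length(dim(image)) == 3) "Color" else "Grayscale"),
    path)
  invisible(path)
}

#' Write an instance map as a 16-bit single-channel TIFF
#' @param instances Integer instance map (labels < 65536).
#' @param path Output `.tif` path.
#' @export
write_instance_map <- function(instances, path) {
  stopifnot(max(instances) < 65536)
  tiff::writeTIFF(instances / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an instance map written by [write_instance_map()]
#' @param path TIFF path.
#' @return Integer instance map.
#' @export
read_instance_map <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Summarize per-image results over an experiment layout
#'
#' Joins per-image measurements onto a layout table and reports the mean
#' and SD per group and timepoint, the exported summary format. Writes a
#' CSV (deterministic column order) and a JSON report when paths are
#' given; a read-back of the CSV equals the returned table.
#'
#' @param layout Data frame with columns `group`, `replicate`,
#'   `timepoint`, `image` (unique image identifiers/paths).
#' @param results Named numeric vector of per-image measurements, names
#'   matching `layout$image` exactly.
#' @param csv,json Optional output paths.
#' @return Data frame with `group`, `timepoint`, `n`, `mean`, `sd` (`sd`
#'   is NA for single images, flagged in the JSON report).
#' @export
write_results <- function(layout, results, csv = NULL, json = NULL) {
  stopifnot(all(c("group", "replicate", "timepoint", "image") %in%
                  names(layout)))
  if (anyDuplicated(layout$image)) stop("duplicate image paths in layout")
  missing <- setdiff(layout$image, names(results))
  if (length(missing))
    stop("missing results for: ", paste(missing, collapse = ", "))
  layout$value <- as.numeric(results[layout$image])
  agg <- do.call(rbind, lapply(
    split(layout, list(layout$group, layout$timepoint), drop = TRUE),
    function(d) data.frame(group = d$group[1], timepoint = d$timepoint[1],
                           n = nrow(d), mean = mean(d$value),
                           sd = if (nrow(d) > 1) stats::sd(d$value)
                                else NA_real_)))
  agg <- agg[order(agg$group, agg$timepoint), ]
  rownames(agg) <- NULL
  if (!is.null(csv)) utils::write.csv(agg, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(summary = agg,
                              single_image_groups = agg$n == 1),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  agg
}
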