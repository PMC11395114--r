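#' Well image container
#'
#' Light wrapper around an 8-bit pixel matrix carrying acquisition
#' metadata (worm id, imaging day, bit depth).
#'
#' @param pixels Integer pixel matrix.
#' @param worm_id,day,bit_depth Metadata.
#' @return A `well_image`.
#' @export
well_image <- function(pixels, worm_id = NA_character_, day = NA_integer_,
                       bit_depth = 8L) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, worm_id = worm_id, day = as.integer(day),
                 bit_depth = as.integer(bit_depth)),
            class = "well_image")
}

#' @export
print.well_image <- function(x, ...) {
  cat(sprintf("well image %dx%d (%d-bit)", nrow(x$pixels), ncol(x$pixels),
              x$bit_depth))
  if (!is.na(x$worm_id)) cat(sprintf("  worm %s", x$worm_id))
  if (!is.na(x$day)) cat(sprintf("  day %d", x$day))
  cat("\n")
  invisible(x)
}

#' Read and write well images
#'
#' PNG and TIFF I/O for 8-bit grayscale images; the format is chosen from
#' the file extension. Multichannel files are channel-averaged on read.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_well_image`: an integer 8-bit pixel matrix.
#' @export
read_well_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  as_u8(x * 255)
}

#' @rdname read_well_image
#' @param pixels 8-bit integer matrix (or `well_image`), or a 0/255 mask.
#' @export
write_well_image <- function(pixels, path) {
  px <- pixels_of(pixels)
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(px / 255, 0), 1)
  switch(ext,
         png = png::writePNG(x, path),
         tif = ,
         tiff = tiff::writeTIFF(x, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read and write dataset manifests
#'
#' CSV manifests with a declared header; reading validates that the
#' required columns are present (naming any missing ones) and preserves
#' unknown columns.
#'
#' @param path CSV file path.
#' @param required Character vector of required column names.
#' @return `read_manifest`: a data frame.
#' @export
read_manifest <- function(path,
                          required = c("worm_id", "well_id", "day",
                                       "age_days", "death_day")) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse manifest: ",
                                          conditionMessage(e)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Renders every manifest row and writes well images and masks as 8-bit
#' PNGs plus `manifest.csv` (with `image_path`/`mask_path` lineage
#' columns) and `survival.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return The manifest with path columns, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  man <- cohort$manifest
  man$image_path <- file.path("images", sprintf("%s_d%02d.png", man$worm_id,
                                                man$day))
  man$mask_path <- file.path("masks", sprintf("%s_d%02d.png", man$worm_id,
                                              man$day))
  for (i in seq_len(nrow(man))) {
    s <- cohort_sample(cohort, i)
    write_well_image(s$image, file.path(out_dir, man$image_path[i]))
    write_well_image(s$mask, file.path(out_dir, man$mask_path[i]))
  }
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  write.csv(cohort$survival, file.path(out_dir, "survival.csv"),
            row.names = FALSE)
  invisible(man)
}
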