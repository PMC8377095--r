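# Tiling: cut slides into a fixed non-overlapping grid and exclude
# background tiles by color thresholding.

#' Tiling configuration
#'
#' @param tile_px tile side length in pixels (224 at full scale, 64 in the
#'   desk profile).
#' @param background_brightness_min channel value (0-255) above which a
#'   pixel counts as background; a pixel is background when its *minimum*
#'   channel exceeds this, so saturated pink tissue is never background.
#' @param background_tissue_fraction_min minimum fraction of tissue
#'   (non-background) pixels required to keep a tile. A tile with exactly
#'   this tissue fraction is kept (the boundary counts as tissue).
#' @param microns_per_pixel metadata note about the source magnification
#'   (1 micron/pixel at 10x for real slides); not used in computation for
#'   plain images.
#' @return an object of class `tiling_config`.
#' @export
tiling_config <- function(tile_px = 64,
                          background_brightness_min = 220,
                          background_tissue_fraction_min = 0.5,
                          microns_per_pixel = 1.0) {
  cfg <- list(
    tile_px = check_count(tile_px, "tile_px", min = 1),
    background_brightness_min = background_brightness_min,
    background_tissue_fraction_min = check_proportion(
      background_tissue_fraction_min, "background_tissue_fraction_min"),
    microns_per_pixel = microns_per_pixel
  )
  if (!is.numeric(cfg$background_brightness_min) ||
      cfg$background_brightness_min < 0 || cfg$background_brightness_min > 255)
    stop("field 'background_brightness_min' must be in [0, 255]",
         call. = FALSE)
  class(cfg) <- "tiling_config"
  cfg
}

#' Read a slide image into a 0-255 RGB array
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array on the 0-255 scale.
#' @export
read_slide_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Classify a tile as background
#'
#' A pixel is background when its minimum RGB channel exceeds
#' `background_brightness_min` (near-white in every channel). The tile is
#' background when its tissue fraction (1 - background-pixel fraction)
#' falls *below* `background_tissue_fraction_min`; a tile exactly at the
#' threshold is tissue. Pure function of the pixels and config.
#'
#' @param patch tile_px x tile_px x 3 array, 0-255 scale.
#' @param config a [tiling_config()].
#' @return `TRUE` if the tile is background (to be excluded).
#' @export
is_background <- function(patch, config) {
  min_chan <- pmin(patch[, , 1], patch[, , 2], patch[, , 3])
  tissue_fraction <- mean(min_chan <= config$background_brightness_min)
  tissue_fraction < config$background_tissue_fraction_min
}

#' Tile one slide into a patch manifest
#'
#' Lays a non-overlapping grid of `tile_px`-sized tiles over the image
#' (0-based, top-left origin, half-open tiles `[x, x + tile_px)`), dropping
#' partial edge tiles, and flags each tile kept/excluded via
#' [is_background()].
#'
#' @param image H x W x 3 array (0-255) or a PNG path.
#' @param config a [tiling_config()].
#' @param patient_id,slide_id identifiers recorded in the manifest rows.
#' @return data.frame with columns patient_id, slide_id, x, y, kept; exactly
#'   `floor(H/tile_px) * floor(W/tile_px)` rows.
#' @export
tile_slide <- function(image, config, patient_id = "", slide_id = "") {
  if (is.character(image)) image <- read_slide_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]; tp <- config$tile_px
  if (h < tp || w < tp)
    stop(sprintf("image (%d x %d) is smaller than one %d-px tile", h, w, tp),
         call. = FALSE)
  nx <- w %/% tp; ny <- h %/% tp
  grid <- expand.grid(x = (seq_len(nx) - 1L) * tp,
                      y = (seq_len(ny) - 1L) * tp)
  kept <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows <- (grid$y[i] + 1L):(grid$y[i] + tp)
    cols <- (grid$x[i] + 1L):(grid$x[i] + tp)
    kept[i] <- !is_background(image[rows, cols, , drop = FALSE], config)
  }
  data.frame(patient_id = patient_id, slide_id = slide_id,
             x = grid$x, y = grid$y, kept = kept,
             stringsAsFactors = FALSE)
}

#' Build the cohort-wide patch manifest
#'
#' Tiles every PNG slide in a directory. Slide filenames must follow
#' `<patient_id>_<slide_idx>.png`; a slide whose patient is absent from the
#' clinical table is an error (naming the file), since downstream splitting
#' is patient-level.
#'
#' @param slide_dir directory of slide PNGs.
#' @param clinical clinical table with a `patient_id` column.
#' @param config a [tiling_config()].
#' @param out optional TSV path; written with a header comment documenting
#'   the 0-based half-open coordinate convention.
#' @return the manifest data.frame (one row per candidate tile).
#' @export
build_manifest <- function(slide_dir, clinical, config, out = NULL) {
  files <- sort(list.files(slide_dir, pattern = "\\.png$"))
  if (length(files) == 0) stop("no PNG slides found in ", slide_dir,
                               call. = FALSE)
  pids <- sub("_[0-9]+\\.png$", "", files)
  orphan <- !(pids %in% clinical$patient_id)
  if (any(orphan))
    stop("slide file(s) with no clinical row: ",
         paste(files[orphan], collapse = ", "), call. = FALSE)
  parts <- lapply(seq_along(files), function(i) {
    tile_slide(file.path(slide_dir, files[i]), config,
               patient_id = pids[i],
               slide_id = sub("\\.png$", "", files[i]))
  })
  manifest <- do.call(rbind, parts)
  n_kept <- sum(manifest$kept)
  message(sprintf("manifest: %d slides, %d candidate tiles, %d kept",
                  length(files), nrow(manifest), n_kept))
  if (n_kept == 0)
    warning("all tiles classified as background; 0 patches kept",
            call. = FALSE)
  if (!is.null(out)) write_manifest(manifest, out)
  manifest
}

#' Write / read a patch manifest TSV
#'
#' @param manifest manifest data.frame.
#' @param path TSV path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  writeLines(paste("# patch manifest; x, y are 0-based top-left pixel",
                   "coordinates; tiles are half-open [x, x+tile_px)"), con)
  utils::write.table(manifest, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
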