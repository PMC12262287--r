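# Image/mask data model, patch extraction, channel rescaling and the
# distortion protocol used for robustness testing.

CHANNEL_NAMES <- c("dapi", "target", "centromere", "rfp")

#' Construct a multi-channel fluorescence image
#'
#' Container for a raw 8-bit microscopy image with named channels. The pixel
#' grid is 0-based and row-major in all coordinate reporting; intensities are
#' integers in \[0, 255\].
#'
#' @param pixels numeric array, rows x cols x channels (a matrix is accepted
#'   for a single channel).
#' @param channels character vector of channel names, a subset of
#'   `c("dapi", "target", "centromere", "rfp")`, unique, one per slice.
#' @return An object of class `mc_image` with elements `pixels` (3-D array)
#'   and `channels`.
#' @export
mc_image <- function(pixels, channels) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == length(channels))
  if (anyDuplicated(channels)) stop("channel names must be unique")
  bad <- setdiff(channels, CHANNEL_NAMES)
  if (length(bad)) stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  dimnames(pixels) <- list(NULL, NULL, channels)
  structure(list(pixels = pixels, channels = channels), class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mc_image> %d x %d px, channels: %s\n", d[1], d[2],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Extract one named channel as a matrix
#' @param image an `mc_image`.
#' @param name channel name.
#' @return numeric matrix (rows x cols).
#' @export
get_channel <- function(image, name) {
  if (!name %in% image$channels) stop("channel not present: ", name)
  image$pixels[, , name]
}

#' Construct a nucleus instance mask
#'
#' @param labels integer matrix; 0 is background, k > 0 marks the pixels of
#'   nucleus instance k.
#' @return An object of class `nucleus_mask` (an integer matrix).
#' @export
nucleus_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (min(labels) < 0) stop("labels must be non-negative")
  storage.mode(labels) <- "integer"
  structure(labels, class = c("nucleus_mask", "matrix", "array"))
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d x %d px, %d instance(s)\n",
              nrow(x), ncol(x), length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

resize_bilinear <- function(m, nr, nc) {
  out <- EBImage::resize(m, w = nr, h = nc, filter = "bilinear")
  as.matrix(out)
}

resize_nearest <- function(m, nr, nc) {
  out <- EBImage::resize(m, w = nr, h = nc, filter = "none")
  as.matrix(out)
}

# Window starts along one axis: stride-`win`, non-overlapping, final window
# anchored at the far edge; a short axis yields a single full-extent window.
window_starts <- function(extent, win) {
  if (extent <= win) return(0L)
  n <- ceiling(extent / win)
  s <- (seq_len(n) - 1L) * win
  s[n] <- extent - win
  unique(s)
}

#' Crop per-nucleus patches from an image
#'
#' Draws the bounding box of every labeled nucleus, crops it and resizes the
#' crop to a fixed square patch (bilinear for intensities, nearest-neighbour
#' for the instance mask). Bounding boxes larger than the patch in either
#' dimension are tiled by non-overlapping windows of the patch size (stride
#' equal to the window, final window anchored at the bounding-box edge), one
#' patch per window with an incremented `window_index`. Pixels of neighbouring
#' nuclei inside the box are preserved as-is.
#'
#' Nuclei whose bounding box touches the image border are still cropped but
#' flagged `boundary = TRUE` so that downstream analyses relying on complete
#' nuclei (the tagging estimator) can exclude them.
#'
#' @param image an `mc_image`.
#' @param mask a `nucleus_mask` of the same spatial extent.
#' @param patch_size side of the output patch in pixels (default 256).
#' @param source_image_id identifier recorded in each patch.
#' @return list of `nucleus_patch` objects. Each holds `pixels`
#'   (patch_size x patch_size x channels, raw 8-bit scale), `nucleus`
#'   (logical matrix of this instance's pixels), `label`, `bbox` (half-open,
#'   0-based `c(row0, col0, row1, col1)` in source coordinates),
#'   `window_index`, `boundary`, `source_image_id`, and `rescaled = FALSE`.
#' @export
crop_patches <- function(image, mask, patch_size = 256L,
                         source_image_id = "image") {
  stopifnot(inherits(image, "mc_image"))
  if (!all(dim(mask) == dim(image$pixels)[1:2]))
    stop("mask extent must equal image extent")
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  if (!length(ids)) {
    warning("mask contains no nuclei; returning empty list")
    return(list())
  }
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list()
  for (id in ids) {
    px <- which(mask == id, arr.ind = TRUE)
    r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
    boundary <- r0 == 1L || c0 == 1L || r1 == nr || c1 == nc
    rs <- window_starts(r1 - r0 + 1L, patch_size)
    cs <- window_starts(c1 - c0 + 1L, patch_size)
    widx <- 0L
    for (wr in rs) for (wc in cs) {
      rr <- (r0 + wr):min(r0 + wr + patch_size - 1L, r1)
      cc <- (c0 + wc):min(c0 + wc + patch_size - 1L, c1)
      raw <- image$pixels[rr, cc, , drop = FALSE]
      chans <- vapply(seq_along(image$channels), function(k)
        resize_bilinear(raw[, , k], patch_size, patch_size),
        matrix(0, patch_size, patch_size))
      chans <- pmin(pmax(chans, 0), 255)
      dimnames(chans) <- list(NULL, NULL, image$channels)
      nuc <- resize_nearest((mask[rr, cc, drop = FALSE] == id) * 1,
                            patch_size, patch_size) > 0.5
      out[[length(out) + 1L]] <- structure(list(
        pixels = chans, nucleus = nuc, label = id,
        bbox = c(r0 - 1L, c0 - 1L, r1, c1),
        window_index = widx, boundary = boundary,
        source_image_id = source_image_id,
        channels = image$channels, rescaled = FALSE,
        flags = character(0)), class = "nucleus_patch")
      widx <- widx + 1L
    }
  }
  out
}

#' @export
print.nucleus_patch <- function(x, ...) {
  cat(sprintf("<nucleus_patch> label %d, window %d, %s scale%s\n", x$label,
              x$window_index, if (x$rescaled) "unit" else "raw 8-bit",
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Rescale patch channels to the unit interval
#'
#' The DAPI channel is divided by its own maximum over the patch; the target
#' and centromeric channels are divided by the shared maximum of the two, so
#' their relative brightness is preserved. The RFP channel is never rescaled:
#' tagging decisions are taken on the raw 0-255 scale. An all-zero channel is
#' left at zero and recorded in `flags` as `"empty_<channel>"`.
#'
#' @param patch a raw `nucleus_patch` from [crop_patches()].
#' @return the patch with intensity channels in \[0, 1\] and `rescaled = TRUE`.
#' @export
rescale_channels <- function(patch) {
  stopifnot(inherits(patch, "nucleus_patch"))
  if (patch$rescaled) stop("patch is already rescaled")
  px <- patch$pixels
  ix <- function(ch) match(ch, patch$channels)
  flag_empty <- function(ch) {
    patch$flags <<- c(patch$flags, paste0("empty_", ch))
  }
  if ("dapi" %in% patch$channels) {
    mx <- max(px[, , ix("dapi")])
    if (mx > 0) px[, , ix("dapi")] <- px[, , ix("dapi")] / mx
    else flag_empty("dapi")
  }
  tc <- intersect(c("target", "centromere"), patch$channels)
  if (length(tc)) {
    mx <- max(px[, , ix(tc)])
    for (ch in tc) {
      if (mx > 0) px[, , ix(ch)] <- px[, , ix(ch)] / mx
      if (max(patch$pixels[, , ix(ch)]) == 0) flag_empty(ch)
    }
  }
  patch$pixels <- px
  patch$rescaled <- TRUE
  patch
}

DISTORTION_KINDS <- c(shrink = 0.8, enlarge = 1.2, rotate = 45,
                      contrast_down = -0.4, contrast_up = 0.4)

#' Apply one of the fixed robustness distortions
#'
#' The protocol distorts an image in one of five fixed ways: shrink to 0.8x,
#' enlarge to 1.2x, rotate by 45 degrees, or change contrast by -40% / +40%.
#' Geometric operations resample bilinearly; rotation keeps the original
#' extent (corners falling outside are filled with 0). Contrast is a linear
#' scaling about the 8-bit midpoint 127.5 by a factor (1 + magnitude),
#' clipped to \[0, 255\].
#'
#' @param image an `mc_image`.
#' @param kind one of `"shrink"`, `"enlarge"`, `"rotate"`, `"contrast_down"`,
#'   `"contrast_up"`.
#' @param magnitude optional override of the fixed magnitude (scale factor,
#'   degrees, or signed contrast fraction depending on `kind`).
#' @return the distorted `mc_image`.
#' @export
distort_image <- function(image, kind, magnitude = NULL) {
  stopifnot(inherits(image, "mc_image"))
  kind <- match.arg(kind, names(DISTORTION_KINDS))
  if (is.null(magnitude)) magnitude <- DISTORTION_KINDS[[kind]]
  px <- image$pixels
  d <- dim(px)
  out <- switch(kind,
    shrink = ,
    enlarge = {
      nr <- max(1L, round(magnitude * d[1])); nc <- max(1L, round(magnitude * d[2]))
      arr <- array(0, c(nr, nc, d[3]))
      for (k in seq_len(d[3])) arr[, , k] <- resize_bilinear(px[, , k], nr, nc)
      arr
    },
    rotate = {
      arr <- array(0, d)
      for (k in seq_len(d[3]))
        arr[, , k] <- as.matrix(EBImage::rotate(px[, , k], magnitude,
                                                filter = "bilinear",
                                                output.dim = d[1:2], bg.col = 0))
      arr
    },
    contrast_down = ,
    contrast_up = 127.5 + (1 + magnitude) * (px - 127.5)
  )
  out <- round(pmin(pmax(out, 0), 255))
  mc_image(out, image$channels)
}

#' Naive Otsu-threshold nucleus mask (baseline stand-in)
#'
#' Thresholds the DAPI channel with Otsu's method and labels 4-connected
#' foreground components. A crude baseline for when no dedicated nucleus
#' segmenter output is available; real pipelines should supply a mask from a
#' proper segmenter.
#'
#' @param image an `mc_image` containing a `dapi` channel.
#' @param min_area components smaller than this many pixels are dropped.
#' @return a `nucleus_mask`.
#' @export
naive_nucleus_mask <- function(image, min_area = 50L) {
  dapi <- get_channel(image, "dapi") / 255
  thr <- EBImage::otsu(EBImage::Image(dapi), range = c(0, 1))
  lab <- as.matrix(EBImage::bwlabel(dapi > thr))
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  nucleus_mask(lab)
}

# ---- file I/O -------------------------------------------------------------

#' Read a multi-channel image from TIFF pages or per-channel PNG files
#'
#' `path` may be a multi-page TIFF (the channel map gives the page index per
#' channel name, 1-based) or a directory of PNGs (the channel map gives the
#' file name per channel). The channel map is a named list or the path of a
#' JSON sidecar.
#'
#' @param path TIFF file or directory of PNG files.
#' @param channel_map named list (`channel name -> page index or file name`)
#'   or path to a JSON file holding one.
#' @return an `mc_image` on the raw 0-255 scale.
#' @export
read_mc_image <- function(path, channel_map) {
  if (is.character(channel_map) && length(channel_map) == 1L)
    channel_map <- jsonlite::read_json(channel_map, simplifyVector = TRUE)
  channel_map <- as.list(channel_map)
  pages <- if (!dir.exists(path)) tiff::readTIFF(path, all = TRUE)
  read_one <- function(entry) {
    m <- if (dir.exists(path)) png::readPNG(file.path(path, entry))
         else pages[[as.integer(entry)]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round(m * 255)
  }
  mats <- lapply(channel_map, read_one)
  arr <- array(0, c(dim(mats[[1]]), length(mats)))
  for (k in seq_along(mats)) arr[, , k] <- mats[[k]]
  mc_image(arr, names(channel_map))
}

#' Write patches as TIFF stacks with a CSV manifest
#'
#' One multi-page TIFF per patch (one page per channel, raw intensities
#' divided by 255) plus a `manifest.csv` describing provenance.
#'
#' @param patches list of `nucleus_patch` objects.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest data frame.
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    fn <- sprintf("patch_%04d.tif", i)
    pages <- lapply(seq_along(p$channels), function(k) p$pixels[, , k] /
                      (if (p$rescaled) 1 else 255))
    tiff::writeTIFF(pages, file.path(dir, fn))
    data.frame(patch_id = fn, source_image = p$source_image_id,
               label = p$label,
               row0 = p$bbox[1], col0 = p$bbox[2], row1 = p$bbox[3],
               col1 = p$bbox[4], window_index = p$window_index,
               boundary = p$boundary)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a label mask from a TIFF file
#' @param path TIFF whose pixel values encode instance labels (stored as
#'   intensity / 65535).
#' @return a `nucleus_mask`.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  nucleus_mask(round(m * 65535))
}

#' Write a label mask to a 16-bit TIFF file
#' @param mask a `nucleus_mask`.
#' @param path output file.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(unclass(mask) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
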