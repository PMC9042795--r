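#' Physical-unit-aware image stack
#'
#' An `image_stack` bundles one or more co-registered channels (numeric
#' arrays sharing a grid) with the physical voxel size. It is the substrate
#' of every image operation in the package.
#'
#' Axis convention: 3D arrays are indexed `[z, y, x]`, 2D arrays `[y, x]`.
#' `voxel_size` gives the physical extent of one voxel along each axis in
#' nanometres, in the same axis order. All physical coordinates reported by
#' the package (centroids, ground truth) are measured in nm from the
#' `(0,0,0)` corner of the grid; the centre of voxel `i` lies at
#' `(i - 0.5) * voxel_size`.
#'
#' @param channels A numeric array (single channel) or named list of numeric
#'   arrays with identical dimensions.
#' @param voxel_size Numeric vector of nm per voxel per axis (length 2 or 3,
#'   matching the array dimensionality); all entries strictly positive.
#' @return An object of class `image_stack`.
#' @examples
#' img <- image_stack(array(0, c(8, 8, 8)), voxel_size = c(60, 40, 40))
#' dim(img)
#' @export
image_stack <- function(channels, voxel_size) {
  if (is.array(channels) || is.matrix(channels)) {
    channels <- list(ch1 = channels)
  }
  if (!is.list(channels) || length(channels) == 0) {
    stop("`channels` must be a numeric array or a non-empty list of arrays")
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("every channel must be a matrix or array")
  }
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1)))) {
    stop("all channels must share the same grid shape")
  }
  nd <- length(d0)
  if (!nd %in% c(2L, 3L)) stop("image stacks must be 2D or 3D")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != nd || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be strictly positive with one entry per axis (",
         nd, " expected)")
  }
  names(voxel_size) <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat("image_stack: ", paste(d, collapse = " x "), " voxels, ",
      length(x$channels), " channel(s) [",
      paste(names(x$channels), collapse = ", "), "]\n", sep = "")
  cat("voxel size (nm): ", paste(signif(x$voxel_size, 6), collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

#' Extract one channel of an image stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index; defaults to the first channel.
#' @return The channel's numeric array.
#' @export
get_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel) && !channel %in% names(stack$channels)) {
    stop("channel '", channel, "' not present (have: ",
         paste(names(stack$channels), collapse = ", "), ")")
  }
  if (is.numeric(channel) && (channel < 1 || channel > length(stack$channels))) {
    stop("channel index out of range")
  }
  stack$channels[[channel]]
}

#' Physical voxel volume
#'
#' @param stack An [image_stack()].
#' @return Volume of one voxel in cubic micrometres (area in square
#'   micrometres for 2D stacks).
#' @export
voxel_volume_um3 <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  prod(stack$voxel_size) / 1e3^length(stack$voxel_size)
}

#' Write an image stack to TIFF with a JSON metadata sidecar
#'
#' Voxels are stored as 32-bit float TIFF pages (page order: all z-slices of
#' channel 1, then channel 2, ...). Because baseline TIFF tags cannot carry
#' an anisotropic 3D voxel size, the voxel size, axis order, grid shape and
#' channel names are written to a JSON sidecar at `<path>.json`;
#' [read_image()] uses it to restore the stack. Storage is exact for
#' integer-valued intensities below 2^24 (e.g. photon counts) and for any
#' float32-representable value.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  nd <- length(d)
  # TIFF float samples are stored in [0, 1]; map intensities there with a
  # power-of-two scale (exact in float arithmetic) and an integer offset
  # for negative values, both recorded in the sidecar.
  all_v <- unlist(lapply(stack$channels, range))
  offset <- min(0, floor(min(all_v)))
  vmax <- max(all_v) - offset
  scale <- if (vmax <= 1) 1 else 2^ceiling(log2(vmax))
  pages <- list()
  for (ch in stack$channels) {
    ch <- (ch - offset) / scale
    if (nd == 2L) {
      pages <- c(pages, list(ch))
    } else {
      for (z in seq_len(d[1])) pages <- c(pages, list(ch[z, , ]))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    axes = if (nd == 3L) "zyx" else "yx",
    shape = as.integer(d),
    voxel_size_nm = as.numeric(stack$voxel_size),
    channels = names(stack$channels),
    intensity_scale = scale,
    intensity_offset = offset
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF image into an image stack
#'
#' Reads a (multi-page) TIFF written by [write_image()] or any plain TIFF.
#' The voxel size is taken from the JSON sidecar `<path>.json` when present;
#' otherwise it must be supplied via `voxel_size`. A missing voxel size is
#' an error, never a silent default.
#'
#' @param path TIFF path.
#' @param voxel_size Optional nm-per-axis override (required when no sidecar
#'   metadata exists).
#' @param shape Optional grid shape override `(z, y, x)` used to fold pages
#'   of a plain TIFF into z-slices and channels; defaults to sidecar info or,
#'   absent both, all pages are treated as z-slices of one channel.
#' @return An [image_stack()].
#' @export
read_image <- function(path, voxel_size = NULL, shape = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else NULL
  if (is.null(voxel_size)) voxel_size <- meta$voxel_size_nm
  if (is.null(voxel_size)) {
    stop("no voxel size: '", basename(path), "' has no metadata sidecar ",
         "and no `voxel_size` was supplied")
  }
  if (is.null(shape)) shape <- meta$shape
  ch_names <- meta$channels %||% NULL
  n_pages <- length(pages)
  if (is.null(shape)) {
    shape <- if (n_pages == 1L) dim(pages[[1]]) else
      c(n_pages, dim(pages[[1]]))
  }
  shape <- as.integer(shape)
  nd <- length(shape)
  n_per_ch <- if (nd == 3L) shape[1] else 1L
  if (n_pages %% n_per_ch != 0) {
    stop("page count (", n_pages, ") is not a multiple of z-slices (",
         n_per_ch, ")")
  }
  n_ch <- n_pages %/% n_per_ch
  scale <- meta$intensity_scale %||% 1
  offset <- meta$intensity_offset %||% 0
  chans <- vector("list", n_ch)
  for (c_i in seq_len(n_ch)) {
    if (nd == 2L) {
      chans[[c_i]] <- pages[[c_i]] * scale + offset
    } else {
      a <- array(0, shape)
      for (z in seq_len(shape[1])) {
        a[z, , ] <- pages[[(c_i - 1L) * n_per_ch + z]]
      }
      chans[[c_i]] <- a * scale + offset
    }
  }
  names(chans) <- if (!is.null(ch_names) && length(ch_names) == n_ch) {
    ch_names
  } else paste0("ch", seq_len(n_ch))
  image_stack(chans, voxel_size)
}
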