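#' Multi-channel 3D image stack
#'
#' @param channels Named list of 3D numeric arrays (all the same shape,
#'   non-negative intensities), e.g. DAPI, MYO7A, GFP, FLAG.
#' @param voxel_size Physical voxel spacing `(dx, dy, dz)` in micrometres.
#' @return An object of class `oto_stack`.
#' @export
oto_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    abort("`channels` must be a named list of arrays")
  }
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L || length(dims[[1]]) != 3L) {
    abort("all channels must be 3D arrays of the same shape")
  }
  if (any(vapply(channels, function(a) any(a < 0), logical(1)))) {
    abort("intensities must be non-negative")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive numbers")
  }
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size)),
            class = "oto_stack")
}

#' @export
print.oto_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<oto_stack> %d x %d x %d voxels, voxel %s um\n",
              d[1], d[2], d[3], paste(x$voxel_size, collapse = " x ")))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are written as 32-bit multi-page TIFF (pages ordered z-within-
#' channel, intensities rescaled to `[0, 1]`) with a JSON sidecar
#' (`<path>.json`) carrying channel names, dimensions, voxel size, and the
#' intensity scale, so a read round-trips the stack exactly.
#'
#' @param stack An [oto_stack()].
#' @param path Output TIFF path.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns an [oto_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "oto_stack"))
  d <- dim(stack$channels[[1]])
  scale <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (nm in names(stack$channels)) {
    arr <- stack$channels[[nm]] / scale
    for (z in seq_len(d[3])) {
      # TIFF pages are row-major (y rows): transpose the xy plane
      pages[[length(pages) + 1L]] <- t(arr[, , z])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = names(stack$channels), dim = d,
               voxel_size = stack$voxel_size, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  channels <- list()
  k <- 0L
  for (nm in meta$channels) {
    arr <- array(0, dim = d)
    for (z in seq_len(d[3])) {
      k <- k + 1L
      arr[, , z] <- t(pages[[k]])
    }
    channels[[nm]] <- arr * meta$intensity_scale
  }
  oto_stack(channels, meta$voxel_size)
}
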