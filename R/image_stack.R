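#' Multichannel 3D image stack
#'
#' Container for a multichannel 3D voxel volume with physical voxel spacing.
#' Array dimensions are ordered (x, y, z); voxel `(i, j, k)` (1-based) has its
#' centre at physical position `((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)`
#' micrometres, so the volume origin sits at the corner of the first voxel.
#' Every processing step appends an entry to the provenance log.
#'
#' @param channels named list of numeric 3D arrays, all with identical
#'   dimensions.
#' @param spacing_um numeric length-3 voxel spacing in micrometres (x, y, z).
#' @param log list of provenance entries (created empty by default).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, spacing_um, log = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("all channels must be 3D arrays")
  d1 <- dims[[1]]
  for (d in dims) if (!all(d == d1)) stop("all channels must share dimensions")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive values")
  structure(list(channels = channels, spacing_um = spacing_um, log = log),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat(sprintf("extent: %.1f x %.1f x %.1f um; %d processing steps logged\n",
              d[1] * x$spacing_um[1], d[2] * x$spacing_um[2], d[3] * x$spacing_um[3],
              length(x$log)))
  invisible(x)
}

#' Extract a channel array from a stack
#'
#' @param stack an [image_stack].
#' @param channel channel name.
#' @return The channel's 3D numeric array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")))
  stack$channels[[channel]]
}

#' Replace or add a channel in a stack
#'
#' @inheritParams get_channel
#' @param value 3D array with the stack's dimensions.
#' @return The modified stack.
#' @export
set_channel <- function(stack, channel, value) {
  stopifnot(inherits(stack, "image_stack"))
  if (!all(dim(value) == dim(stack$channels[[1]])))
    stop("channel dimensions do not match stack")
  stack$channels[[channel]] <- value
  stack
}

# Append a provenance entry (operation name plus its parameters).
log_op <- function(stack, op, params = list()) {
  stack$log[[length(stack$log) + 1L]] <- list(op = op, params = params)
  stack
}

#' Binary 3D mask
#'
#' A boolean voxel field with physical spacing, typically produced by
#' [binarize()]. Carries the threshold it was produced with so that
#' re-binarization at the recorded threshold is an identity.
#'
#' @param voxels logical 3D array.
#' @param spacing_um voxel spacing in micrometres (x, y, z).
#' @param source_threshold threshold used to produce the mask (or `NA`).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_um, source_threshold = NA_real_) {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive values")
  structure(list(voxels = voxels, spacing_um = spacing_um,
                 source_threshold = source_threshold),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_mask: %d x %d x %d voxels, %d foreground (%.2f%%), threshold %s\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels), format(x$source_threshold)))
  invisible(x)
}
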