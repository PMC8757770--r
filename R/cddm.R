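# Core CDDM data type and grid operations.
#
# A CDDM (current density distribution map) is a pair of same-shape real
# matrices over a rectangular grid: a magnitude field (current density,
# dimensionless, normalized so max = 1) and an angle field (direction of the
# current density vector, radians in (-pi, pi]). The computational grid is the
# vector grid on which stage-1 correlation operates; the default 10 x 10 grid
# yields the length-100 stage-1 vectors.

#' Grid configuration
#'
#' @param height,width Grid dimensions; both must be even integers >= 2 so
#'   that the quadrant split is exact. Default 10 x 10, giving length-100
#'   stage-1 vectors.
#' @return A list with `height`, `width` and `stage1_vector_length`.
#' @export
grid_config <- function(height = 10L, width = 10L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 2L || width < 2L)
    stop("grid dimensions must be >= 2", call. = FALSE)
  if (height %% 2L != 0L || width %% 2L != 0L)
    stop("grid dimensions must be even for an exact quadrant split",
         call. = FALSE)
  list(height = height, width = width,
       stage1_vector_length = height * width)
}

#' Wrap angles into (-pi, pi]
#'
#' @param x Numeric vector or matrix of angles in radians.
#' @return Same shape as `x`, every value in (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(2 * pi, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor() puts the result in [-pi, pi); fold the open end onto +pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

#' Normalize a magnitude map by its maximum
#'
#' Divides the map elementwise by its maximum so that the result has maximum
#' exactly 1. All-zero maps carry no current structure and are rejected.
#'
#' @param raw_magnitude Matrix of non-negative finite reals.
#' @return Matrix of the same shape with maximum 1.
#' @export
#' @examples
#' normalize_map(matrix(c(2, 4, 1, 0), 2, 2))
normalize_map <- function(raw_magnitude) {
  if (!is.matrix(raw_magnitude) || !is.numeric(raw_magnitude))
    stop("magnitude must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(raw_magnitude)))
    stop("magnitude contains non-finite values", call. = FALSE)
  if (any(raw_magnitude < 0))
    stop("magnitude contains negative values", call. = FALSE)
  mx <- max(raw_magnitude)
  if (mx == 0)
    stop("degenerate map: all magnitude values are zero", call. = FALSE)
  raw_magnitude / mx
}

#' Construct a CDDM
#'
#' @param magnitude Matrix of non-negative reals (H x W, both even, >= 2).
#' @param angle Matrix of angles in radians, same shape; wrapped to
#'   (-pi, pi] on construction.
#' @param label Optional heart-state label (canonical code or alias).
#' @param map_id Identifier string.
#' @param normalize If TRUE (default), magnitude is normalized by its maximum.
#'   If FALSE the magnitude must already have maximum 1.
#' @return An object of class `cddm`: list with `magnitude`, `angle`,
#'   `label` (or NA), `map_id`.
#' @export
cddm <- function(magnitude, angle, label = NULL, map_id = "",
                 normalize = TRUE) {
  if (!is.matrix(magnitude) || !is.matrix(angle))
    stop("magnitude and angle must be matrices", call. = FALSE)
  if (!identical(dim(magnitude), dim(angle)))
    stop("magnitude and angle must have identical shape; got ",
         paste(dim(magnitude), collapse = "x"), " vs ",
         paste(dim(angle), collapse = "x"), call. = FALSE)
  h <- nrow(magnitude); w <- ncol(magnitude)
  if (h < 2L || w < 2L || h %% 2L != 0L || w %% 2L != 0L)
    stop("CDDM grid must be even-sized in both dimensions and >= 2x2; got ",
         h, "x", w, call. = FALSE)
  if (any(!is.finite(angle)))
    stop("angle contains non-finite values", call. = FALSE)
  magnitude <- if (normalize) normalize_map(magnitude) else {
    if (any(!is.finite(magnitude)) || any(magnitude < 0))
      stop("magnitude must be finite and non-negative", call. = FALSE)
    if (abs(max(magnitude) - 1) > 1e-9)
      stop("magnitude is not normalized (max != 1)", call. = FALSE)
    magnitude
  }
  lab <- if (is.null(label) || (length(label) == 1 && is.na(label))) NA_character_
         else as_heart_state(label)
  structure(list(magnitude = magnitude, angle = wrap_angle(angle),
                 label = lab, map_id = as.character(map_id)),
            class = "cddm")
}

#' @export
print.cddm <- function(x, ...) {
  cat(sprintf("<cddm '%s' %dx%d label=%s>\n", x$map_id,
              nrow(x$magnitude), ncol(x$magnitude),
              ifelse(is.na(x$label), "<none>", x$label)))
  invisible(x)
}

#' Split a CDDM into four equal quadrants
#'
#' Quadrants are returned in fixed row-major order with row 1 at the top:
#' Q1 = top-left, Q2 = top-right, Q3 = bottom-left, Q4 = bottom-right. The
#' stage-2 feature layout depends on this order, which is therefore frozen.
#'
#' @param map A `cddm` object.
#' @return A list of 4 elements, each a list with `magnitude` and `angle`
#'   sub-matrices of shape (H/2) x (W/2).
#' @export
split_quadrants <- function(map) {
  stopifnot(inherits(map, "cddm"))
  h <- nrow(map$magnitude); w <- ncol(map$magnitude)
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("quadrant split requires even dimensions; got ", h, "x", w,
         call. = FALSE)
  hr <- seq_len(h / 2); lr <- (h / 2 + 1):h
  lc <- seq_len(w / 2); rc <- (w / 2 + 1):w
  idx <- list(Q1 = list(hr, lc), Q2 = list(hr, rc),
              Q3 = list(lr, lc), Q4 = list(lr, rc))
  lapply(idx, function(ii)
    list(magnitude = map$magnitude[ii[[1]], ii[[2]], drop = FALSE],
         angle     = map$angle[ii[[1]], ii[[2]], drop = FALSE]))
}

#' Flatten a CDDM to stage-1 vectors
#'
#' Row-major flattening of the magnitude and angle grids to the paired
#' vectors used by stage-1 correlation (length 100 on the default grid).
#' Flatten followed by reshape is the identity.
#'
#' @param map A `cddm` object.
#' @param grid A [grid_config()]; the map shape must match.
#' @return List with numeric vectors `magnitude` and `angle`, each of length
#'   `grid$stage1_vector_length`.
#' @export
flatten_for_stage1 <- function(map, grid = grid_config()) {
  stopifnot(inherits(map, "cddm"))
  if (nrow(map$magnitude) != grid$height || ncol(map$magnitude) != grid$width)
    stop("map shape ", nrow(map$magnitude), "x", ncol(map$magnitude),
         " does not match grid config ", grid$height, "x", grid$width,
         call. = FALSE)
  # row-major: walk row 1 left to right, then row 2, ...
  list(magnitude = as.vector(t(map$magnitude)),
       angle     = as.vector(t(map$angle)))
}
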