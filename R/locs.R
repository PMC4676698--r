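#' Build a localization table
#'
#' A localization table is the package's central data structure: one row per
#' detected molecule with coordinates in nanometres. It is an ordinary tibble
#' with columns `x`, `y`, `z`, `photons`, `precision` and `channel`, so every
#' dplyr/tidyr verb applies; row order carries no meaning and all analyses are
#' permutation-invariant.
#'
#' @param x,y Coordinates in nm.
#' @param z Axial coordinate in nm; 0 when the acquisition was 2-D.
#' @param photons Detected photon count per molecule (`NA` when not exported).
#' @param precision Per-molecule localization precision in nm (`NA` when not
#'   exported).
#' @param channel Colour-channel label.
#' @return A tibble with class `locs_tbl`.
#' @examples
#' locs(x = c(0, 100), y = c(0, 50), precision = 15)
#' @export
locs <- function(x, y, z = 0, photons = NA_real_, precision = NA_real_,
                 channel = "ch1") {
  out <- tibble::tibble(
    x = as.double(x), y = as.double(y), z = as.double(z),
    photons = as.double(photons), precision = as.double(precision),
    channel = as.character(channel)
  )
  validate_locs(out)
}

#' @rdname locs
#' @param data A data frame carrying at least `x` and `y` columns (nm).
#' @export
as_locs <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("x", "y") %in% names(data))) {
    stop("a localization table needs `x` and `y` columns (nm)", call. = FALSE)
  }
  locs(
    x = data$x, y = data$y,
    z = if ("z" %in% names(data)) data$z else 0,
    photons = if ("photons" %in% names(data)) data$photons else NA_real_,
    precision = if ("precision" %in% names(data)) data$precision else NA_real_,
    channel = if ("channel" %in% names(data)) data$channel else "ch1"
  )
}

validate_locs <- function(data) {
  if (nrow(data)) {
    if (!all(is.finite(data$x)) || !all(is.finite(data$y)) ||
        !all(is.finite(data$z))) {
      stop("localization coordinates must be finite", call. = FALSE)
    }
    if (any(data$photons < 0, na.rm = TRUE)) {
      stop("photon counts must be >= 0", call. = FALSE)
    }
    if (any(data$precision < 0, na.rm = TRUE)) {
      stop("localization precisions must be >= 0", call. = FALSE)
    }
  }
  class(data) <- unique(c("locs_tbl", class(data)))
  data
}

#' Coordinate matrix of a localization table
#'
#' @param data A localization table.
#' @param dims 2 for x/y, 3 for x/y/z.
#' @return A numeric matrix, one row per molecule.
#' @keywords internal
loc_coords <- function(data, dims = NULL) {
  if (is.null(dims)) dims <- if (any(data$z != 0)) 3L else 2L
  m <- cbind(x = data$x, y = data$y)
  if (dims == 3L) m <- cbind(m, z = data$z)
  m
}

#' Split a multi-channel localization table by channel
#'
#' @param data A localization table.
#' @return A named list of single-channel tables.
#' @export
split_channels <- function(data) {
  data <- as_locs(data)
  lapply(split(data, data$channel), validate_locs)
}

#' Mean per-channel localization precision
#'
#' Molecules lacking a precision value are excluded from the estimate; when no
#' molecule carries one the result is `NA` and a per-channel override must be
#' supplied wherever a colocalization distance criterion is needed.
#'
#' @param data A localization table (one or more channels).
#' @return A tibble with `channel`, `sigma` (nm) and `n_with_precision`.
#' @export
channel_precision <- function(data) {
  data <- as_locs(data)
  data |>
    dplyr::group_by(channel) |>
    dplyr::summarise(
      sigma = mean(precision, na.rm = TRUE),
      n_with_precision = sum(!is.na(precision)),
      .groups = "drop"
    ) |>
    dplyr::mutate(sigma = ifelse(n_with_precision == 0, NA_real_, sigma))
}
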