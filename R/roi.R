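#' Regions of interest
#'
#' An ROI is a simple (non-self-intersecting) polygon in nm, stored as a
#' tibble of vertices with class `roi`. `roi_rect()` is a convenience for
#' axis-aligned rectangles. ROIs bound the analysis area for cropping, for
#' uniform randomization of molecular positions, and for the area term of the
#' spatial statistics.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in nm.
#' @return An object of class `roi` (tibble of polygon vertices `x`, `y`).
#' @export
roi_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(is.finite(xmin), is.finite(xmax), is.finite(ymin), is.finite(ymax))
  if (xmax <= xmin || ymax <= ymin) {
    stop("ROI must have positive area", call. = FALSE)
  }
  out <- tibble::tibble(x = c(xmin, xmax, xmax, xmin),
                        y = c(ymin, ymin, ymax, ymax))
  structure(out, class = c("roi", class(out)), rectangular = TRUE,
            refined = FALSE)
}

#' @rdname roi_rect
#' @param x,y Polygon vertex coordinates in nm (not closed; the last vertex
#'   connects back to the first).
#' @param refined Flag marking a minimum-bounding-polygon refinement.
#' @export
roi_polygon <- function(x, y, refined = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  out <- tibble::tibble(x = as.double(x), y = as.double(y))
  if (roi_area_impl(out$x, out$y) <= 0) {
    stop("ROI must have positive area", call. = FALSE)
  }
  structure(out, class = c("roi", class(out)), rectangular = FALSE,
            refined = refined)
}

roi_area_impl <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of an ROI in nm^2
#' @param roi An `roi` object.
#' @export
roi_area <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  roi_area_impl(roi$x, roi$y)
}

#' Bounding rectangle of an ROI or localization table
#' @param obj An `roi` or localization table.
#' @return An `roi` rectangle.
#' @export
roi_bbox <- function(obj) {
  roi_rect(min(obj$x), max(obj$x), min(obj$y), max(obj$y))
}

#' Test molecules against an ROI (boundary-inclusive)
#' @param data A localization table.
#' @param roi An `roi`.
#' @return Logical vector, one entry per molecule.
#' @export
in_roi <- function(data, roi) {
  stopifnot(inherits(roi, "roi"))
  cpp_in_polygon(data$x, data$y, roi$x, roi$y)
}

#' Crop localization channels to an ROI
#'
#' All channels of `data` (or each element of a list of tables) are cropped
#' with the identical ROI; returned molecules lie inside or on the boundary.
#' A channel left empty by the crop raises a warning and is flagged in the
#' `empty_channels` attribute.
#'
#' @param data A localization table (possibly multi-channel) or list of
#'   tables.
#' @param roi An `roi` with positive area.
#' @return Cropped table(s) of the same shape as the input.
#' @export
crop_locs <- function(data, roi) {
  stopifnot(inherits(roi, "roi"))
  if (roi_area(roi) <= 0) stop("ROI must have positive area", call. = FALSE)
  if (is.list(data) && !is.data.frame(data)) {
    return(lapply(data, crop_locs, roi = roi))
  }
  data <- as_locs(data)
  out <- validate_locs(data[in_roi(data, roi), , drop = FALSE])
  empty <- setdiff(unique(data$channel), unique(out$channel))
  if (length(empty)) {
    warning("ROI contains zero molecules in channel(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  attr(out, "empty_channels") <- empty
  out
}

#' Minimum bounding polygon of a point set
#'
#' Returns the convex hull of the molecules as an ROI, flagged as refined.
#' Refining the randomization region to the hull avoids randomizing molecular
#' positions over a larger area than the molecules truly occupy, which would
#' otherwise inflate the apparent degree of association against the
#' randomized control.
#'
#' @param data A localization table with at least 3 non-collinear molecules.
#' @return An `roi` polygon flagged `refined`.
#' @export
minimum_bounding_polygon <- function(data) {
  data <- as_locs(data)
  if (nrow(data) < 3) {
    stop("need at least 3 points for a bounding polygon", call. = FALSE)
  }
  h <- grDevices::chull(data$x, data$y)
  if (length(h) < 3) {
    stop("points are collinear; bounding polygon is degenerate", call. = FALSE)
  }
  roi_polygon(data$x[h], data$y[h], refined = TRUE)
}

#' Filter molecules in low-density regions
#'
#' Keeps exactly the molecules whose distance to their k-th nearest
#' same-channel neighbour is at most `max_knn_distance`, removing sparse
#' background molecules to enhance analysis of clustered molecules. The k-th
#' nearest-neighbour distance is the same local density proxy OPTICS uses as
#' its core distance.
#'
#' @param data A single-channel localization table.
#' @param k Neighbour rank (>= 1, < number of molecules).
#' @param max_knn_distance Distance threshold in nm.
#' @return The filtered localization table (a subset of the input rows).
#' @export
density_filter <- function(data, k, max_knn_distance) {
  data <- as_locs(data)
  if (k < 1 || k >= nrow(data)) {
    stop("k must satisfy 1 <= k < number of molecules", call. = FALSE)
  }
  d <- cpp_kth_nn_dist(loc_coords(data, 3L), as.integer(k))
  validate_locs(data[d <= max_knn_distance, , drop = FALSE])
}

#' Rasterize a localization table to a count image
#'
#' Bins molecules into square pixels using half-open bins
#' `[i*s, (i+1)*s)` anchored at the origin (the minimum corner by default);
#' molecules on the maximum edge fall into the last pixel. The grid conserves
#' the molecule count; counts are clipped at 65535 (16-bit) with a warning.
#'
#' @param data A localization table.
#' @param pixel_size Pixel side in nm (default 20, the package's raster
#'   convention).
#' @param origin Numeric `c(x0, y0)`; defaults to the floor of the data
#'   minimum corner.
#' @param extent Optional `c(width, height)` in nm forcing the grid size.
#' @return A `raster_image`: integer count matrix (rows = y, cols = x) with
#'   `pixel_size` and `origin` attributes.
#' @export
rasterize_locs <- function(data, pixel_size = 20, origin = NULL,
                           extent = NULL) {
  data <- as_locs(data)
  stopifnot(pixel_size > 0)
  if (is.null(origin)) origin <- c(min(data$x), min(data$y))
  if (is.null(extent)) {
    extent <- c(max(data$x) - origin[1], max(data$y) - origin[2])
  }
  ncx <- max(1L, as.integer(ceiling(extent[1] / pixel_size)))
  ncy <- max(1L, as.integer(ceiling(extent[2] / pixel_size)))
  ix <- floor((data$x - origin[1]) / pixel_size)
  iy <- floor((data$y - origin[2]) / pixel_size)
  # molecules sitting exactly on the maximum edge fall into the last pixel
  ix[data$x - origin[1] == extent[1]] <- ncx - 1
  iy[data$y - origin[2] == extent[2]] <- ncy - 1
  keep <- ix >= 0 & ix < ncx & iy >= 0 & iy < ncy
  grid <- matrix(0L, nrow = ncy, ncol = ncx)
  if (any(keep)) {
    idx <- iy[keep] * ncx + ix[keep] + 1
    tab <- tabulate(idx, nbins = ncy * ncx)
    grid <- matrix(tab, nrow = ncy, ncol = ncx, byrow = TRUE)
  }
  if (any(grid > 65535L)) {
    warning("pixel counts clipped at 65535 (16-bit)", call. = FALSE)
    grid[grid > 65535L] <- 65535L
  }
  structure(grid, class = "raster_image", pixel_size = pixel_size,
            origin = origin, n_binned = sum(keep))
}

#' Write a raster image as 16-bit grayscale TIFF
#' @param img A `raster_image`.
#' @param path Output path.
#' @export
write_raster_tiff <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @export
print.raster_image <- function(x, ...) {
  cat("<raster_image> ", nrow(x), "x", ncol(x), " pixels, ",
      attr(x, "pixel_size"), " nm/pixel, ", sum(x), " counts\n", sep = "")
  invisible(x)
}
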