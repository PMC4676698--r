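#' @keywords internal
as_weighted_points <- function(obj) {
  if (inherits(obj, "raster_image")) {
    s <- attr(obj, "pixel_size")
    o <- attr(obj, "origin")
    nz <- which(obj > 0, arr.ind = TRUE)
    list(
      coords = cbind(x = o[1] + (nz[, 2] - 0.5) * s,
                     y = o[2] + (nz[, 1] - 0.5) * s),
      w = as.double(obj[nz])
    )
  } else {
    obj <- as_locs(obj)
    dims <- if (any(obj$z != 0)) 3L else 2L
    list(coords = loc_coords(obj, dims), w = rep(1, nrow(obj)))
  }
}

curve_region <- function(source, target, region) {
  if (is.null(region)) {
    pts <- dplyr::bind_rows(
      if (inherits(source, "raster_image")) NULL else as_locs(source),
      if (inherits(target, "raster_image")) NULL else as_locs(target)
    )
    if (nrow(pts) == 0) stop("supply `region` for raster inputs", call. = FALSE)
    region <- roi_bbox(pts)
  }
  region
}

check_radii <- function(radii, region) {
  stopifnot(length(radii) >= 2, all(diff(radii) > 0), radii[1] > 0)
  ext <- c(max(region$x) - min(region$x), max(region$y) - min(region$y))
  if (max(radii) > min(ext) / 2) {
    warning("radii exceed half the region's minimum extent; ",
            "large-r values are edge-dominated", call. = FALSE)
  }
}

new_spatial_curve <- function(df, kind, pair, ns, nt, area, toroidal) {
  structure(
    tibble::as_tibble(df),
    class = c("spatial_curve", class(tibble::tibble())),
    kind = kind, channel_pair = pair, n_source = ns, n_target = nt,
    region_area = area, toroidal = toroidal
  )
}

#' Cross-channel radial distribution function G(r)
#'
#' The pair-correlation (radial distribution) function counts target
#' molecules in an expanding annulus around each source molecule, normalized
#' by the count expected from the mean target density over the region.
#' Complete spatial randomness gives G = 1 at all radii; co-clustering shows
#' as G > 1 at radii up to the cluster scale. Cross-channel G is robust to
#' repeat detections (oversampling) because duplicated molecules inflate the
#' observed and expected counts alike.
#'
#' No edge correction is applied by default, so G decays below 1 as r
#' approaches the region size; `toroidal = TRUE` wraps distances on the
#' region rectangle, removing edge effects exactly (meant for synthetic
#' scenes). Inputs may also be `raster_image` objects, in which case pixel
#' centres weighted by counts are used (the raster parity path).
#'
#' @param source,target Localization tables (or raster images).
#' @param region `roi` rectangle defining the analysis area; defaults to the
#'   joint bounding box.
#' @param radii Annulus boundaries in nm (default 10 nm steps to 1000 nm,
#'   the package's radius cap).
#' @param toroidal Use periodic (wrapped) distances on the region rectangle.
#' @param exclude_self Skip identical row pairs (same-table usage).
#' @return A `spatial_curve` tibble with columns `r` (annulus midpoint) and
#'   `g`.
#' @export
cross_rdf <- function(source, target, region = NULL,
                      radii = seq(10, 1000, by = 10), toroidal = FALSE,
                      exclude_self = FALSE) {
  region <- curve_region(source, target, region)
  check_radii(radii, region)
  sp <- as_weighted_points(source)
  tp <- as_weighted_points(target)
  if (!nrow(sp$coords) || !nrow(tp$coords)) {
    stop("both channels must be non-empty", call. = FALSE)
  }
  reg <- c(min(region$x), min(region$y), max(region$x), max(region$y))
  counts <- cpp_pair_hist(sp$coords, tp$coords, radii, sp$w, tp$w,
                          exclude_self, toroidal, reg)
  ns <- sum(sp$w); nt <- sum(tp$w)
  area <- roi_area(region)
  rho <- (if (exclude_self) nt - 1 else nt) / area
  expected <- ns * rho * pi * diff(radii^2)
  new_spatial_curve(
    tibble::tibble(r = (radii[-length(radii)] + radii[-1]) / 2,
                   g = counts / expected),
    "rdf", c(source = "source", target = "target"), ns, nt, area, toroidal
  )
}

#' Cross-channel Ripley K, H and H' statistics
#'
#' Ripley's K counts target molecules within distance r of each source
#' molecule, normalized by density: K(r) = A / (n_s n_t) * sum_i c_i(r).
#' The variance-stabilized transform L = sqrt(K/pi) gives H(r) = L(r) - r,
#' which is ~0 at all radii for complete spatial randomness and rises to a
#' single peak for clustered data; the peak radius r_max tracks (but
#' overestimates) the mean cluster radius, and the peak height the degree of
#' clustering. H'(r) is the derivative of H by central differences on the
#' radius grid (one-sided at the ends). For 3-D tables K uses sphere counts
#' with L = (3K/(4 pi))^(1/3).
#'
#' Unlike cross-RDF, cross-Ripley statistics are cumulative and therefore
#' sensitive to sampling: undersampling lowers the H peak and oversampling
#' shrinks the apparent cluster size.
#'
#' @inheritParams cross_rdf
#' @param radii Radius grid in nm at which K is evaluated.
#' @return A `spatial_curve` tibble with columns `r`, `k`, `l`, `h`,
#'   `h_prime`.
#' @export
cross_ripley <- function(source, target, region = NULL,
                         radii = seq(10, 1000, by = 10), toroidal = FALSE,
                         exclude_self = FALSE) {
  region <- curve_region(source, target, region)
  check_radii(radii, region)
  sp <- as_weighted_points(source)
  tp <- as_weighted_points(target)
  if (!nrow(sp$coords) || !nrow(tp$coords)) {
    stop("both channels must be non-empty", call. = FALSE)
  }
  three_d <- ncol(sp$coords) == 3 || ncol(tp$coords) == 3
  reg <- c(min(region$x), min(region$y), max(region$x), max(region$y))
  counts <- cpp_pair_hist(sp$coords, tp$coords, c(0, radii), sp$w, tp$w,
                          exclude_self, toroidal, reg)
  cum <- cumsum(counts)
  ns <- sum(sp$w); nt <- sum(tp$w)
  area <- roi_area(region)
  k <- area * cum / (ns * (if (exclude_self) nt - 1 else nt))
  l <- if (three_d) (3 * k / (4 * pi))^(1 / 3) else sqrt(k / pi)
  h <- l - radii
  h_prime <- numeric(length(h))
  n <- length(h)
  h_prime[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / (radii[3:n] - radii[1:(n - 2)])
  h_prime[1] <- (h[2] - h[1]) / (radii[2] - radii[1])
  h_prime[n] <- (h[n] - h[n - 1]) / (radii[n] - radii[n - 1])
  new_spatial_curve(
    tibble::tibble(r = radii, k = k, l = l, h = h, h_prime = h_prime),
    "ripley", c(source = "source", target = "target"), ns, nt, area, toroidal
  )
}

#' Mean cluster radius from the H peak (r_max / 1.3)
#'
#' The radius of the H(r) maximum correlates roughly with mean cluster size
#' but overestimates it; dividing r_max by 1.3 gives a calibrated mean
#' cluster radius for biological point patterns.
#'
#' @param h_curve A `spatial_curve` from [cross_ripley()].
#' @return Estimated mean cluster radius in nm.
#' @seealso [cluster_radius_kiskowski()] for the H'-based alternative; both
#'   are exposed so either convention can be used.
#' @export
cluster_radius_lagache <- function(h_curve) {
  stopifnot(inherits(h_curve, "spatial_curve"),
            identical(attr(h_curve, "kind"), "ripley"))
  i <- which.max(h_curve$h)
  if (i == 1L || i == nrow(h_curve)) {
    stop("H(r) has no interior peak; data look unclustered at these radii",
         call. = FALSE)
  }
  h_curve$r[i] / 1.3
}

#' Mean cluster radius from the H' = -1 crossing
#'
#' The mean cluster radius equals one-half the radius at which the
#' derivative H'(r) first crosses -1 (downward), located by linear
#' interpolation between grid points.
#'
#' @param h_curve A `spatial_curve` from [cross_ripley()] (provides
#'   `h_prime`).
#' @return Estimated mean cluster radius in nm.
#' @export
cluster_radius_kiskowski <- function(h_curve) {
  stopifnot(inherits(h_curve, "spatial_curve"),
            identical(attr(h_curve, "kind"), "ripley"))
  hp <- h_curve$h_prime
  r <- h_curve$r
  cross <- which(hp[-length(hp)] > -1 & hp[-1] <= -1)
  if (!length(cross)) {
    stop("H'(r) never crosses -1 on this radius grid", call. = FALSE)
  }
  i <- cross[1]
  frac <- (hp[i] - (-1)) / (hp[i] - hp[i + 1])
  0.5 * (r[i] + frac * (r[i + 1] - r[i]))
}

#' Static-radius H-map segmentation
#'
#' Evaluates Ripley's H at a single radius `r0` on a pixel grid (each pixel
#' centre scores the molecule count within `r0`, normalized to the CSR
#' expectation), thresholds the resulting H map and labels 8-connected
#' components as clusters; per-molecule local H values are returned as well.
#' The resulting cluster map is highly dependent on the chosen `r0` and
#' threshold, which is why the density-based and reachability-based
#' segmentations are usually preferred; the method is retained for its
#' simplicity and for comparability.
#'
#' @param data A single-channel localization table.
#' @param r0 Static radius in nm.
#' @param threshold Local-H threshold; pixels at or above it are cluster
#'   pixels.
#' @param pixel_size Raster pixel size in nm.
#' @param region Optional `roi`; defaults to the bounding box.
#' @return An `hsegment_result`: per-molecule local H, the H raster, the
#'   binary mask, the component label matrix and `n_clusters`.
#' @export
h_segment <- function(data, r0, threshold, pixel_size = 20, region = NULL) {
  data <- as_locs(data)
  stopifnot(r0 > 0)
  if (is.null(region)) region <- roi_bbox(data)
  area <- roi_area(region)
  n <- nrow(data)
  m <- loc_coords(data, 2L)
  cnt <- cpp_count_within(m, m, r0, TRUE, FALSE, numeric(4))
  local_h <- sqrt(area * cnt / (pi * (n - 1))) - r0
  origin <- c(min(region$x), min(region$y))
  ext <- c(max(region$x), max(region$y)) - origin
  ncx <- max(1L, as.integer(ceiling(ext[1] / pixel_size)))
  ncy <- max(1L, as.integer(ceiling(ext[2] / pixel_size)))
  centres <- cbind(
    x = origin[1] + (rep(seq_len(ncx), each = ncy) - 0.5) * pixel_size,
    y = origin[2] + (rep(seq_len(ncy), times = ncx) - 0.5) * pixel_size
  )
  pix_cnt <- cpp_count_within(centres, m, r0, FALSE, FALSE, numeric(4))
  hmap <- matrix(sqrt(area * pix_cnt / (pi * n)) - r0, nrow = ncy, ncol = ncx)
  mask <- hmap >= threshold
  labels <- cpp_label8(mask)
  structure(
    list(local_h = local_h, h_map = hmap, mask = mask, labels = labels,
         n_clusters = max(labels), pixel_size = pixel_size, r0 = r0,
         threshold = threshold),
    class = "hsegment_result"
  )
}

#' @export
print.hsegment_result <- function(x, ...) {
  cat("<hsegment_result> r0 =", x$r0, "nm, threshold =", x$threshold,
      "->", x$n_clusters, "clusters\n")
  invisible(x)
}
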