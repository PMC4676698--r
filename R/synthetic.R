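#' @keywords internal
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))  # 2.3548

new_scene <- function(channels, truth, params, seed) {
  structure(list(channels = channels, truth = truth, params = params,
                 seed = seed),
            class = "smlm_scene")
}

#' @export
print.smlm_scene <- function(x, ...) {
  ns <- vapply(x$channels, nrow, 1L)
  cat("<smlm_scene> ", paste(names(ns), ns, sep = ": ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Synthetic fluorophore pair field
#'
#' Emulates a coverslip field of annealed dye-labeled oligonucleotide
#' duplexes: channel-A molecules are uniform over the square extent and each
#' paired channel-B molecule sits at exactly `separation` nm from its partner
#' at a uniform random angle. An optional fraction of unpaired (unannealed)
#' B molecules is added uniformly, reproducing the asymmetric-mixing
#' experiments. No localization error is applied here; jitter detection noise
#' with [jitter_locs()] to emulate the microscope.
#'
#' The default extent places same-channel molecules ~60 nm apart on average
#' (the density of the oligomer fields), scaling with `n_pairs`.
#'
#' @param n_pairs Number of A-B pairs.
#' @param separation True pair separation in nm (duplex lengths run from
#'   6.8 nm for a 20-mer to 20.4 nm for a 60-mer).
#' @param extent Side of the square field in nm; default gives ~60 nm mean
#'   same-channel nearest-neighbour spacing.
#' @param unpaired_b_fraction Extra unpaired B molecules as a fraction of
#'   `n_pairs` (>= 0).
#' @param precision Precision value (nm) stored on the molecules.
#' @param seed Integer seed.
#' @return An `smlm_scene` with channels `A` and `B` and a truth table of
#'   pair ids.
#' @export
make_pair_field <- function(n_pairs, separation, extent = NULL,
                            unpaired_b_fraction = 0, precision = 20,
                            seed = NULL) {
  stopifnot(separation >= 0, n_pairs >= 1)
  if (unpaired_b_fraction < 0) {
    stop("unpaired_b_fraction must be >= 0", call. = FALSE)
  }
  if (is.null(extent)) extent <- 120 * sqrt(n_pairs)
  run <- function() {
    ax <- stats::runif(n_pairs, 0, extent)
    ay <- stats::runif(n_pairs, 0, extent)
    ang <- stats::runif(n_pairs, 0, 2 * pi)
    bx <- ax + separation * cos(ang)
    by <- ay + separation * sin(ang)
    n_un <- round(unpaired_b_fraction * n_pairs)
    ux <- stats::runif(n_un, 0, extent)
    uy <- stats::runif(n_un, 0, extent)
    a <- locs(ax, ay, precision = precision, channel = "A")
    b <- locs(c(bx, ux), c(by, uy), precision = precision, channel = "B")
    truth <- tibble::tibble(
      channel = c(rep("A", n_pairs), rep("B", n_pairs + n_un)),
      index = c(seq_len(n_pairs), seq_len(n_pairs + n_un)),
      pair_id = c(seq_len(n_pairs), seq_len(n_pairs),
                  rep(NA_integer_, n_un))
    )
    new_scene(list(A = a, B = b), truth,
              list(extent = extent, n_pairs = n_pairs,
                   separation = separation,
                   unpaired_b_fraction = unpaired_b_fraction,
                   precision = precision),
              seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Synthetic clustered scene
#'
#' Generates a field of molecular clusters: cluster centres uniform over the
#' square extent; each cluster's molecule count is the maximum size minus a
#' uniform random integer on `[0, size_jitter]`, its radius the maximum
#' radius minus a uniform draw on `[0, radius_jitter]`; molecules are placed
#' at a uniform random angle and radius inside the cluster. Uniform noise
#' molecules are added as a fraction of the clustered count. With
#' `jitter_model = "gaussian"` sizes and radii are instead drawn as
#' mean +/- Gaussian jitter.
#'
#' Defaults reproduce the acquisition-model conditions: a 5000 x 5000 nm
#' field of 200 clusters of 100 +/- 10 molecules with radii 75 +/- 37.5 nm
#' and 10% noise. For co-clustering statistics, a variant with 50 clusters of
#' fixed 50 nm radius and 100 molecules is the standard configuration
#' (`preset = "rdf"`).
#'
#' @param n_clusters Number of clusters.
#' @param molecules_per_cluster Mean molecules per cluster.
#' @param cluster_radius Mean cluster radius in nm.
#' @param size_jitter Half-range of the uniform size jitter in molecules
#'   (max size = mean + size_jitter/... the generated size is
#'   `mean + size_jitter/2 - U{0..size_jitter}`).
#' @param radius_jitter Half-range span of the uniform radius jitter in nm
#'   (`radius = mean + radius_jitter/2 - U(0, radius_jitter)`).
#' @param extent Field side in nm.
#' @param noise_fraction Noise molecules as a fraction of the clustered
#'   count.
#' @param channel Channel label.
#' @param jitter_model `"uniform"` (max-minus-uniform) or `"gaussian"`.
#' @param preset `"acquisition"` (defaults above) or `"rdf"` (50 clusters,
#'   50 nm fixed radius, 100 molecules, no noise unless set).
#' @param precision Precision value (nm) stored on the molecules.
#' @param seed Integer seed.
#' @return An `smlm_scene` with one channel and a truth table of cluster
#'   ids (noise molecules have `NA`).
#' @export
make_clustered_scene <- function(n_clusters = 200,
                                 molecules_per_cluster = 100,
                                 cluster_radius = 75,
                                 size_jitter = 20, radius_jitter = 75,
                                 extent = 5000, noise_fraction = 0.1,
                                 channel = "A",
                                 jitter_model = c("uniform", "gaussian"),
                                 preset = NULL, precision = 20,
                                 seed = NULL) {
  jitter_model <- match.arg(jitter_model)
  if (!is.null(preset) && preset == "rdf") {
    n_clusters <- 50; molecules_per_cluster <- 100
    cluster_radius <- 50; size_jitter <- 0; radius_jitter <- 0
    noise_fraction <- 0
  }
  stopifnot(n_clusters >= 1, molecules_per_cluster >= 1, cluster_radius > 0,
            extent > 0, noise_fraction >= 0)
  run <- function() {
    cx <- stats::runif(n_clusters, 0, extent)
    cy <- stats::runif(n_clusters, 0, extent)
    if (jitter_model == "uniform") {
      sizes <- pmax(1L, as.integer(
        molecules_per_cluster + size_jitter / 2 -
          sample.int(size_jitter + 1L, n_clusters, replace = TRUE) + 1L))
      radii <- pmax(1e-6, cluster_radius + radius_jitter / 2 -
                      stats::runif(n_clusters, 0, radius_jitter))
    } else {
      sizes <- pmax(1L, round(stats::rnorm(n_clusters,
                                           molecules_per_cluster,
                                           size_jitter / 2)))
      radii <- pmax(1e-6, stats::rnorm(n_clusters, cluster_radius,
                                       radius_jitter / 2))
    }
    id <- rep.int(seq_len(n_clusters), sizes)
    ang <- stats::runif(length(id), 0, 2 * pi)
    rad <- stats::runif(length(id), 0, radii[id])
    x <- cx[id] + rad * cos(ang)
    y <- cy[id] + rad * sin(ang)
    n_noise <- round(noise_fraction * length(id))
    x <- c(x, stats::runif(n_noise, 0, extent))
    y <- c(y, stats::runif(n_noise, 0, extent))
    tab <- locs(x, y, precision = precision, channel = channel)
    truth <- tibble::tibble(
      channel = channel, index = seq_along(x),
      cluster_id = c(id, rep(NA_integer_, n_noise))
    )
    params <- list(extent = extent, n_clusters = n_clusters,
                   molecules_per_cluster = molecules_per_cluster,
                   cluster_radius = cluster_radius,
                   size_jitter = size_jitter, radius_jitter = radius_jitter,
                   noise_fraction = noise_fraction,
                   jitter_model = jitter_model, cluster_centres = cbind(cx, cy),
                   cluster_radii = radii, precision = precision)
    stats::setNames(list(tab), channel) |>
      new_scene(truth, params, seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Apply isotropic localization jitter
#'
#' Adds independent normal noise to x and y (and z for 3-D tables) with a
#' full-width-at-half-maximum of `0.5 * precision` — the detection-noise
#' model of stochastic localization: a 20 nm-precision microscope perturbs
#' each detection with FWHM 10 nm, i.e. sigma = 10 / 2.3548 = 4.25 nm.
#'
#' @param data A localization table.
#' @param precision Microscope precision in nm.
#' @param seed Integer seed.
#' @return The jittered table.
#' @export
jitter_locs <- function(data, precision = 20, seed = NULL) {
  data <- as_locs(data)
  run <- function() {
    s <- fwhm_to_sigma(0.5 * precision)
    out <- data
    out$x <- out$x + stats::rnorm(nrow(out), 0, s)
    out$y <- out$y + stats::rnorm(nrow(out), 0, s)
    if (any(out$z != 0)) out$z <- out$z + stats::rnorm(nrow(out), 0, s)
    validate_locs(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Emulate undersampling (missed detections)
#'
#' Randomly deletes a fraction of the molecules; to remove any repeat
#' detections of the deleted fluorophores as well, every same-channel
#' molecule within one CDC of a deleted molecule is also removed, so the
#' realized deletion count is at least `n * fraction_deleted`.
#'
#' @param data A single-channel localization table.
#' @param fraction_deleted Fraction in `[0, 1]`.
#' @param cdc Colocalization distance criterion in nm used for co-removal
#'   (0 disables it).
#' @param seed Integer seed.
#' @return The undersampled table.
#' @export
apply_undersampling <- function(data, fraction_deleted, cdc = 0,
                                seed = NULL) {
  data <- as_locs(data)
  stopifnot(fraction_deleted >= 0, fraction_deleted <= 1)
  if (fraction_deleted == 0) return(data)
  run <- function() {
    n <- nrow(data)
    sel <- sample.int(n, round(fraction_deleted * n))
    drop <- rep(FALSE, n)
    drop[sel] <- TRUE
    if (cdc > 0 && length(sel)) {
      m <- loc_coords(data, 3L)
      d <- cpp_nn_dist(m, m[sel, , drop = FALSE], FALSE, numeric(4))
      drop <- drop | d <= cdc
    }
    validate_locs(data[!drop, , drop = FALSE])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Emulate oversampling (repeat detections)
#'
#' Randomly selects a fraction of the molecules and duplicates each after
#' resampling its position uniformly within `cdc_diameter` of the original —
#' the signature artefact of stochastic blinking, where one fluorophore is
#' localized several times within its precision.
#'
#' @param data A single-channel localization table.
#' @param fraction_duplicated Fraction (>= 0; may exceed 1 for repeated
#'   duplication rounds).
#' @param cdc_diameter Resampling diameter in nm (default 21.27, one CDC
#'   diameter for a typical two-colour acquisition).
#' @param seed Integer seed.
#' @return The oversampled table (size `round(n * (1 + fraction))`).
#' @export
apply_oversampling <- function(data, fraction_duplicated,
                               cdc_diameter = 21.27, seed = NULL) {
  data <- as_locs(data)
  stopifnot(fraction_duplicated >= 0)
  if (fraction_duplicated == 0) return(data)
  run <- function() {
    n <- nrow(data)
    n_dup <- round(fraction_duplicated * n)
    # integer multiples duplicate every molecule equally (a 25x oversampled
    # image detects each fluorophore ~25 times); the remainder is drawn
    # without replacement
    rounds <- n_dup %/% n
    sel <- c(rep(seq_len(n), rounds),
             sample.int(n, n_dup - rounds * n))
    r <- (cdc_diameter / 2) * sqrt(stats::runif(n_dup))
    ang <- stats::runif(n_dup, 0, 2 * pi)
    dup <- data[sel, , drop = FALSE]
    dup$x <- dup$x + r * cos(ang)
    dup$y <- dup$y + r * sin(ang)
    validate_locs(dplyr::bind_rows(data, dup))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a stochastic super-resolution acquisition
#'
#' "Images" a ground-truth scene frame by frame: each frame activates a
#' uniform random subset of fluorophores (subset size uniform over
#' `active_range`) and records their positions perturbed by detection noise
#' with FWHM `0.5 * precision`. The concatenated frames reproduce the two
#' canonical sampling artefacts at once: molecules never activated are
#' missing (undersampling) while molecules activated repeatedly appear as
#' jittered repeat detections (oversampling). Optionally a fraction of
#' fluorophores is deleted up front, emulating incomplete labeling.
#'
#' @param scene An `smlm_scene` (first channel is imaged).
#' @param n_frames Number of frames (default 10000).
#' @param active_range Integer range of active fluorophores per frame
#'   (default 10-20).
#' @param precision Microscope precision in nm (default 20).
#' @param undersample_fraction Fraction of fluorophores deleted before
#'   imaging (default 0.1).
#' @param seed Integer seed.
#' @return An `acquisition_series`: tibble of detections with `frame`,
#'   `x`, `y`, `z`, `mol_id`, plus the retained ground truth in attributes.
#' @export
simulate_acquisition <- function(scene, n_frames = 10000,
                                 active_range = c(10, 20), precision = 20,
                                 undersample_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(scene, "smlm_scene"), n_frames >= 1)
  truth <- scene$channels[[1]]
  run <- function() {
    n0 <- nrow(truth)
    keep <- sort(sample.int(n0, round((1 - undersample_fraction) * n0)))
    pool <- truth[keep, , drop = FALSE]
    n <- nrow(pool)
    if (active_range[1] < 1 || active_range[2] > n) {
      stop("active_range must lie within [1, number of fluorophores]",
           call. = FALSE)
    }
    sizes <- seq(active_range[1], active_range[2])
    n_active <- sizes[sample.int(length(sizes), n_frames, replace = TRUE)]
    ids <- unlist(lapply(n_active, function(k) sample.int(n, k)))
    frame <- rep.int(seq_len(n_frames), n_active)
    s <- fwhm_to_sigma(0.5 * precision)
    det <- tibble::tibble(
      frame = frame,
      x = pool$x[ids] + stats::rnorm(length(ids), 0, s),
      y = pool$y[ids] + stats::rnorm(length(ids), 0, s),
      z = pool$z[ids],
      mol_id = keep[ids]
    )
    structure(det,
              class = c("acquisition_series", class(tibble::tibble())),
              ground_truth = truth, imaged_pool = pool,
              n_frames = n_frames, active_range = active_range,
              precision = precision,
              undersample_fraction = undersample_fraction, seed = seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Reconstruction autocorrelation and stop point
#'
#' Reconstructs the super-resolution image cumulatively, checkpointing every
#' `interval` frames, and computes the Pearson correlation of each
#' checkpoint raster against the raster from `interval` frames earlier. The
#' correlation climbs steeply while new fluorophores are still being added
#' and asymptotically approaches 1 once most detections are repeats; the
#' *stop frame* — the last checkpoint with correlation at or below
#' `stop_threshold` (default 0.990) — marks the reconstruction with the best
#' balance between under- and over-sampling.
#'
#' @param series An `acquisition_series`.
#' @param pixel_size Raster pixel size in nm (default 20).
#' @param interval Checkpoint spacing in frames (default 50).
#' @param stop_threshold Autocorrelation stop threshold (default 0.990).
#' @param extent Optional `c(width, height)` of the raster in nm; defaults
#'   to the ground-truth extent.
#' @return A `reconstruction_trace`: tibble with `frame` and
#'   `autocorrelation` per checkpoint, and attributes `stop_frame` and the
#'   raster origin/extent used.
#' @export
reconstruct_autocorrelation <- function(series, pixel_size = 20,
                                        interval = 50,
                                        stop_threshold = 0.990,
                                        extent = NULL) {
  stopifnot(inherits(series, "acquisition_series"), interval >= 1)
  truth <- attr(series, "ground_truth")
  origin <- c(min(truth$x), min(truth$y))
  if (is.null(extent)) {
    extent <- c(max(truth$x), max(truth$y)) - origin
  }
  n_frames <- attr(series, "n_frames")
  checkpoints <- seq(interval, n_frames, by = interval)
  if (length(checkpoints) < 2) {
    stop("need at least 2 checkpoints; lower `interval`", call. = FALSE)
  }
  ncx <- max(1L, as.integer(ceiling(extent[1] / pixel_size)))
  ncy <- max(1L, as.integer(ceiling(extent[2] / pixel_size)))
  ix <- pmin(pmax(floor((series$x - origin[1]) / pixel_size), 0), ncx - 1)
  iy <- pmin(pmax(floor((series$y - origin[2]) / pixel_size), 0), ncy - 1)
  pix <- iy * ncx + ix + 1
  acc <- numeric(ncx * ncy)
  prev <- NULL
  ord <- order(series$frame)
  pix <- pix[ord]
  frames <- series$frame[ord]
  autocor <- numeric(length(checkpoints))
  pos <- 1L
  for (ci in seq_along(checkpoints)) {
    hi <- checkpoints[ci]
    take <- if (pos > length(frames)) 0L else
      sum(frames[seq(pos, length(frames))] <= hi)
    if (take > 0) {
      block <- pix[seq(pos, pos + take - 1L)]
      tb <- tabulate(block, nbins = ncx * ncy)
      acc <- acc + tb
      pos <- pos + take
    }
    autocor[ci] <- if (is.null(prev)) NA_real_ else
      stats::cor(acc, prev)
    prev <- acc
  }
  below <- which(!is.na(autocor) & autocor <= stop_threshold)
  stop_frame <- if (length(below)) checkpoints[max(below)] else
    checkpoints[2]
  structure(
    tibble::tibble(frame = checkpoints, autocorrelation = autocor),
    class = c("reconstruction_trace", class(tibble::tibble())),
    stop_frame = stop_frame, stop_threshold = stop_threshold,
    pixel_size = pixel_size, origin = origin, extent = extent,
    interval = interval
  )
}

#' Match reconstruction checkpoints against the ground-truth H curve
#'
#' Evaluates, at a ladder of cumulative reconstruction checkpoints, how
#' closely the cross-Ripley H of the reconstruction (against the true
#' molecule set) matches the H of the ideally sampled image, and pairs each
#' checkpoint with its reconstruction autocorrelation. Early checkpoints are
#' undersampled (H too low) and late ones oversampled; the checkpoint with
#' the smallest H error marks the best reconstruction stop point, which
#' falls where the autocorrelation approaches the canonical 0.990 stop
#' threshold.
#'
#' The cumulative K statistics are accumulated incrementally from per-block
#' pair histograms, so the whole ladder costs a single pass over the
#' detections.
#'
#' @param series An `acquisition_series`.
#' @param trace A `reconstruction_trace` for the same series (defaults to
#'   computing one).
#' @param candidate_interval Spacing of candidate checkpoints in frames
#'   (default 500; must be a multiple of the trace interval).
#' @param radii Radius grid for the H comparison.
#' @return A tibble with one row per candidate: `frame`, `n_detections`,
#'   `h_rmse`, `autocorrelation`; the best row is flagged in `best`.
#' @export
match_reconstruction_h <- function(series, trace = NULL,
                                   candidate_interval = 500,
                                   radii = seq(10, 1000, by = 10)) {
  stopifnot(inherits(series, "acquisition_series"))
  if (is.null(trace)) trace <- reconstruct_autocorrelation(series)
  truth <- attr(series, "ground_truth")
  region <- roi_bbox(truth)
  area <- roi_area(region)
  reg <- c(min(region$x), min(region$y), max(region$x), max(region$y))
  tm <- loc_coords(truth, 2L)
  n_t <- nrow(tm)
  href <- cross_ripley(truth, truth, region, radii, exclude_self = TRUE)$h
  n_frames <- attr(series, "n_frames")
  cand <- seq(candidate_interval, n_frames, by = candidate_interval)
  breaks <- c(0, radii)
  block <- findInterval(series$frame, cand, left.open = TRUE) + 1
  counts <- matrix(0, nrow = length(breaks) - 1, ncol = length(cand))
  nsrc <- numeric(length(cand))
  for (b in sort(unique(block))) {
    sel <- block == b
    sm <- cbind(series$x[sel], series$y[sel])
    counts[, b] <- cpp_pair_hist(sm, tm, breaks, rep(1, nrow(sm)),
                                 rep(1, n_t), FALSE, FALSE, reg)
    nsrc[b] <- nrow(sm)
  }
  cum_counts <- t(apply(counts, 1, cumsum))
  cum_n <- cumsum(nsrc)
  rmse <- vapply(seq_along(cand), function(i) {
    k <- area * cumsum(cum_counts[, i]) / (cum_n[i] * n_t)
    h <- sqrt(k / pi) - radii
    sqrt(mean((h - href)^2))
  }, 1.0)
  ac <- trace$autocorrelation[match(cand, trace$frame)]
  out <- tibble::tibble(frame = cand, n_detections = cum_n, h_rmse = rmse,
                        autocorrelation = ac)
  out$best <- seq_along(cand) == which.min(rmse)
  out
}

#' Detections accumulated up to a frame
#'
#' @param series An `acquisition_series`.
#' @param frame Last frame to include.
#' @param channel Channel label for the resulting table.
#' @return A localization table of all detections in frames `1..frame`.
#' @export
reconstruct_at <- function(series, frame, channel = "recon") {
  stopifnot(inherits(series, "acquisition_series"))
  sel <- series$frame <= frame
  locs(series$x[sel], series$y[sel], z = series$z[sel],
       precision = attr(series, "precision"), channel = channel)
}
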