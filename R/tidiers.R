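#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SAA result
#'
#' One row per source molecule and direction with its nearest-neighbour
#' distance and whether it falls below the CDC.
#'
#' @param x An `saa_result`.
#' @param ... Unused.
#' @return A tibble with `direction`, `distance`, `below_cdc`.
#' @method tidy saa_result
#' @export
tidy.saa_result <- function(x, ...) {
  purrr::map_dfr(c("ab", "ba"), function(dir) {
    r <- x[[dir]]
    lab <- if (dir == "ab") {
      paste0(x$channels[1], "->", x$channels[2])
    } else {
      paste0(x$channels[2], "->", x$channels[1])
    }
    tibble::tibble(direction = lab, distance = r$nn_distances,
                   below_cdc = r$nn_distances <= x$cdc)
  })
}

#' Glance at an SAA result
#'
#' @param x An `saa_result`.
#' @param ... Unused.
#' @return One row per direction with the fraction below the CDC, its SRP
#'   control, their ratio, the distance mode and the CDC.
#' @method glance saa_result
#' @export
glance.saa_result <- function(x, ...) {
  purrr::map_dfr(c("ab", "ba"), function(dir) {
    r <- x[[dir]]
    lab <- if (dir == "ab") {
      paste0(x$channels[1], "->", x$channels[2])
    } else {
      paste0(x$channels[2], "->", x$channels[1])
    }
    tibble::tibble(
      direction = lab, n = length(r$nn_distances),
      fraction_below_cdc = r$fraction_below_cdc,
      srp_fraction_below_cdc = r$srp_fraction_below_cdc,
      enrichment = r$fraction_below_cdc / r$srp_fraction_below_cdc,
      mode_distance = r$mode_distance, cdc = x$cdc,
      n_randomizations = x$n_randomizations
    )
  })
}

#' @rdname tidy.saa_result
#' @method tidy saa3_result
#' @export
tidy.saa3_result <- function(x, ...) x$fractions

#' @rdname glance.saa_result
#' @method glance saa3_result
#' @export
glance.saa3_result <- function(x, ...) {
  tibble::tibble(cdc = x$cdc, n_randomizations = x$n_randomizations)
}

#' Tidy a cluster tree
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @method tidy cluster_tree
#' @export
tidy.cluster_tree <- function(x, ...) tibble::as_tibble(x)

#' @rdname glance.saa_result
#' @method glance cluster_tree
#' @export
glance.cluster_tree <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x), n_leaves = sum(x$leaf),
    max_depth = {
      depth <- integer(nrow(x))
      for (i in seq_len(nrow(x))) {
        d <- 0L; p <- x$parent[i]
        while (!is.na(p)) { d <- d + 1L; p <- x$parent[p] }
        depth[i] <- d
      }
      max(depth)
    },
    min_cluster_size = attr(x, "min_cluster_size"),
    split_significance = attr(x, "split_significance")
  )
}

#' Histogram plot of SAA nearest-neighbour distances
#'
#' Measured and randomized (SRP) distance histograms per direction, with the
#' CDC marked; the enrichment of counts left of the CDC line relative to the
#' SRP curve is the signature of molecular association.
#'
#' @param object An `saa_result`.
#' @param binwidth Histogram bin width in nm.
#' @param max_distance Upper display limit in nm.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saa_result
#' @export
autoplot.saa_result <- function(object, binwidth = NULL, max_distance = 200,
                                ...) {
  if (is.null(binwidth)) binwidth <- object$binwidth
  meas <- tidy(object)
  meas$kind <- "measured"
  srp <- purrr::map_dfr(c("ab", "ba"), function(dir) {
    r <- object[[dir]]
    lab <- if (dir == "ab") {
      paste0(object$channels[1], "->", object$channels[2])
    } else {
      paste0(object$channels[2], "->", object$channels[1])
    }
    tibble::tibble(direction = lab, distance = r$srp_nn_distances,
                   below_cdc = NA, kind = "SRP")
  })
  df <- dplyr::bind_rows(meas, srp) |>
    dplyr::filter(distance <= max_distance)
  ggplot2::ggplot(df, ggplot2::aes(distance, y = ggplot2::after_stat(density),
                                   colour = kind)) +
    ggplot2::geom_freqpoly(binwidth = binwidth, linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = object$cdc, linetype = "dashed") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "nearest-neighbour distance (nm)", y = "density",
                  colour = NULL,
                  caption = sprintf("dashed line: CDC = %.1f nm", object$cdc)) +
    ggplot2::theme_minimal()
}

#' Plot a spatial curve
#'
#' G(r) against its CSR reference of 1, or Ripley H(r) against 0.
#'
#' @param object A `spatial_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spatial_curve
#' @export
autoplot.spatial_curve <- function(object, ...) {
  if (identical(attr(object, "kind"), "rdf")) {
    ggplot2::ggplot(object, ggplot2::aes(r, g)) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "r (nm)", y = "G(r)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(r, h)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "r (nm)", y = "H(r)") +
      ggplot2::theme_minimal()
  }
}

#' Reachability (RD) plot with cluster segments
#'
#' The OPTICS reachability profile in order; valleys are clusters. When a
#' `cluster_tree` is supplied its leaf segments are underlaid.
#'
#' @param object A `reachability_profile`.
#' @param tree Optional `cluster_tree` from [hier_segment_rd()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reachability_profile
#' @export
autoplot.reachability_profile <- function(object, tree = NULL, ...) {
  df <- tibble::tibble(position = seq_len(nrow(object)),
                       rd = object$reachability)
  p <- ggplot2::ggplot(df, ggplot2::aes(position, rd)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "OPTICS order", y = "reachability distance (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(tree)) {
    leaves <- tibble::as_tibble(tree)[tree$leaf, ]
    p <- p + ggplot2::geom_rect(
      data = leaves,
      ggplot2::aes(xmin = start, xmax = end, ymin = 0, ymax = mean_rd),
      inherit.aes = FALSE, alpha = 0.25, fill = "steelblue"
    )
  }
  p
}

#' Scatter plot of clustered molecules
#'
#' @param object A `dbscan_labels` tibble.
#' @param ... Unused.
#' @return A ggplot; noise in grey, clusters coloured.
#' @method autoplot dbscan_labels
#' @export
autoplot.dbscan_labels <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cluster <- factor(df$.cluster)
  ggplot2::ggplot(df, ggplot2::aes(x, y, colour = cluster)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = c("0" = "grey80",
                 stats::setNames(grDevices::hcl.colors(
                   max(1, max(object$.cluster)), "Dark 3"),
                   as.character(seq_len(max(1, max(object$.cluster))))))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
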