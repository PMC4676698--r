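#' Run a batch analysis queue
#'
#' Processes a list of self-contained analysis jobs — the scripted
#' counterpart of an interactive per-ROI queue. Each job names 1-3 channel
#' position files, an optional ROI, the analyses to run with their
#' parameters, an output directory and a seed. One output folder is created
#' per job, holding the tables and a machine-readable JSON manifest
#' (parameters, seed, package version); a failing job is logged and does not
#' stop the queue. Re-running a job with the same configuration and seed
#' reproduces its numeric outputs exactly.
#'
#' A job is a list with fields:
#' \describe{
#'   \item{channels}{character vector of 1-3 position-file paths}
#'   \item{dialect}{optional [conversion_spec()] dialect (default
#'     `"standard"`)}
#'   \item{roi}{optional `list(xmin, xmax, ymin, ymax)` or
#'     `list(x = ..., y = ...)` polygon}
#'   \item{analyses}{named list; supported names `saa`, `rdf`, `ripley`,
#'     `dbscan`, `optics`, `hsegment`, each a (possibly empty) list of
#'     arguments for the corresponding function}
#'   \item{output_dir}{folder to create}
#'   \item{seed}{integer}
#' }
#'
#' @param jobs A list of job lists, or the path of a YAML/JSON queue file
#'   with a top-level `jobs` list.
#' @return Tibble with one row per job: `output_dir`, `status`, `message`.
#' @export
run_queue <- function(jobs) {
  if (is.character(jobs) && length(jobs) == 1) {
    cfg <- if (grepl("\\.ya?ml$", jobs)) yaml::read_yaml(jobs) else
      jsonlite::read_json(jobs, simplifyVector = FALSE)
    jobs <- cfg$jobs
  }
  if (is.null(jobs)) jobs <- list()
  # schema validation up front: a malformed queue fails before any job runs
  for (i in seq_along(jobs)) {
    j <- jobs[[i]]
    if (!is.list(j) || is.null(j$channels) || is.null(j$output_dir)) {
      stop("job ", i, " must name `channels` and `output_dir`", call. = FALSE)
    }
    if (length(j$channels) < 1 || length(j$channels) > 3) {
      stop("job ", i, " must list 1-3 channel files", call. = FALSE)
    }
    if (!is.null(j$analyses) && is.null(names(j$analyses))) {
      stop("job ", i, ": `analyses` must be a named list", call. = FALSE)
    }
    bad <- setdiff(names(j$analyses),
                   c("saa", "rdf", "ripley", "dbscan", "optics", "hsegment"))
    if (length(bad)) {
      stop("job ", i, ": unknown analysis ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  purrr::map_dfr(seq_along(jobs), function(i) {
    j <- jobs[[i]]
    res <- tryCatch({
      run_job(j)
      tibble::tibble(output_dir = j$output_dir, status = "ok", message = "")
    }, error = function(e) {
      tibble::tibble(output_dir = j$output_dir, status = "failed",
                     message = conditionMessage(e))
    })
    res
  })
}

job_roi <- function(roi_spec, channels) {
  if (is.null(roi_spec)) {
    return(roi_bbox(dplyr::bind_rows(channels)))
  }
  if (!is.null(roi_spec$xmin)) {
    roi_rect(roi_spec$xmin, roi_spec$xmax, roi_spec$ymin, roi_spec$ymax)
  } else {
    roi_polygon(unlist(roi_spec$x), unlist(roi_spec$y))
  }
}

run_job <- function(j) {
  spec <- conversion_spec(dialect = j$dialect %||% "standard")
  labels <- c("ch1", "ch2", "ch3")[seq_along(j$channels)]
  channels <- purrr::map2(j$channels, labels, ~read_locs(.x, spec,
                                                         channel = .y))
  roi <- job_roi(j$roi, channels)
  channels <- lapply(channels, crop_locs, roi = roi)
  dir.create(j$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- j$seed %||% 1L
  outp <- function(name) file.path(j$output_dir, name)
  for (nm in names(j$analyses)) {
    args <- j$analyses[[nm]]
    switch(nm,
      saa = {
        res <- do.call(saa_two_colour,
                       c(list(a = channels[[1]], b = channels[[2]],
                              region = roi, seed = seed), args))
        readr::write_csv(tidy(res), outp("saa_distances.csv"))
        readr::write_csv(glance(res), outp("saa_summary.csv"))
      },
      rdf = {
        res <- do.call(cross_rdf,
                       c(list(source = channels[[1]], target = channels[[2]],
                              region = roi), args))
        readr::write_csv(tibble::as_tibble(res), outp("rdf.csv"))
      },
      ripley = {
        res <- do.call(cross_ripley,
                       c(list(source = channels[[1]], target = channels[[2]],
                              region = roi), args))
        readr::write_csv(tibble::as_tibble(res), outp("ripley.csv"))
      },
      dbscan = {
        res <- do.call(dbscan_locs, c(list(data = channels[[1]]), args))
        readr::write_tsv(tibble::as_tibble(res), outp("dbscan_labels.tsv"))
        readr::write_csv(summarise_clusters(channels[[1]], res$.cluster),
                         outp("dbscan_clusters.csv"))
      },
      optics = {
        rd_threshold <- args$rd_threshold
        args$rd_threshold <- NULL
        prof <- do.call(optics_order, c(list(data = channels[[1]]), args))
        readr::write_csv(tibble::as_tibble(prof), outp("optics_profile.csv"))
        if (!is.null(rd_threshold)) {
          lab <- extract_clusters_static_rd(prof, rd_threshold)
        } else {
          lab <- tree_labels(hier_segment_rd(prof))
        }
        readr::write_tsv(lab, outp("optics_labels.tsv"))
      },
      hsegment = {
        res <- do.call(h_segment, c(list(data = channels[[1]]), args))
        readr::write_csv(
          tibble::tibble(molecule = seq_along(res$local_h),
                         local_h = res$local_h),
          outp("hsegment_local_h.csv"))
      }
    )
  }
  manifest <- list(
    channels = j$channels, roi = list(x = roi$x, y = roi$y),
    analyses = j$analyses, seed = seed,
    package_version = as.character(utils::packageVersion("smlmtools")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(j$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
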