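#' Full H-DAB quantification pipeline
#'
#' Stage order: color normalization -> stain deconvolution -> tissue masking
#' (hematoxylin channel) -> rotation search on the mask -> rotation and crop
#' of image, mask and DAB planes -> AP gate on the DAB grayscale -> (if
#' positive) k-means segmentation, DAB mask extraction and contour overlay.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Nested list of every module's tunables; unknown keys are rejected by
#' [validate_config()]. All defaults are documented here.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    normalization = list(enabled = TRUE, reference = NULL),
    stains = list(h_vector = hdab_stain_vectors()$h,
                  dab_vector = hdab_stain_vectors()$dab,
                  background = 255),
    mask = list(se_radius = 15L, min_tissue_fraction = 0.005),
    rotation = list(enabled = TRUE, angle_min = 1, angle_max = 180,
                    angle_step = 0.1, coarse_to_fine = FALSE, margin_px = 5L),
    gate = list(pixel_threshold = 30, ap_cutoff = 0.6),
    segment = list(k_min = 1L, k_max = 3L, seed = 0L, n_init = 5L),
    plastic_removal = list(enabled = FALSE),
    io = list(out_dir = "dabquant_out"),
    log = list(level = "warn")
  )
}

#' Validate and merge a (partial) configuration against the defaults
#'
#' @param config Nested list of overrides (possibly partial).
#' @return Completed configuration list; unknown keys raise an error.
#' @export
validate_config <- function(config = list()) {
  merge_into <- function(base, over, path = character()) {
    for (nm in names(over)) {
      here <- paste(c(path, nm), collapse = ".")
      if (!nm %in% names(base))
        stop("unknown config key: ", here, call. = FALSE)
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        if (!is.list(over[[nm]]))
          stop("config key ", here, " must be a list", call. = FALSE)
        base[[nm]] <- merge_into(base[[nm]], over[[nm]], c(path, nm))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(default_config(), config)
  if (!cfg$log$level %in% names(.log_levels))
    stop("unknown log level: ", cfg$log$level, call. = FALSE)
  cfg
}

#' Read a YAML pipeline configuration file
#'
#' @param path YAML file with (a subset of) the [default_config()] keys.
#' @return Completed configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

stage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
  dt <- proc.time()[["elapsed"]] - t0
  dq_log("info", "stage ", name, " done in ", sprintf("%.2f s", dt))
  timings[[name]] <- dt
  list(value = out, timings = timings)
}

#' Run the pipeline on a single image
#'
#' @param image H x W x 3 array in \[0,255\] (see [load_rgb_image()]).
#' @param config Configuration overrides (see [default_config()]).
#' @param image_id Identifier recorded in the result.
#' @param marker Optional marker label.
#' @param keep_intermediates Keep cropped image/mask/DAB planes and the
#'   segmentation object in the result (default `FALSE`).
#' @param plastic_hook Optional function `(image, mask) -> mask` applied
#'   after tissue masking; extension point for removal of stained plastic
#'   carrier membranes (disabled / identity by default).
#' @return A `dab_sample` result: the [sample_result()] fields plus
#'   `low_contrast`, per-stage `timings`, and (optionally) `intermediates`.
#' @export
run_pipeline <- function(image, config = list(), image_id = "sample",
                         marker = NA_character_, keep_intermediates = FALSE,
                         plastic_hook = NULL) {
  cfg <- validate_config(config)
  old_opt <- options(dabquant.log_level = cfg$log$level)
  on.exit(options(old_opt))
  validate_rgb_image(image)
  timings <- list()

  if (isTRUE(cfg$normalization$enabled)) {
    s <- stage("normalize", timings, {
      ref <- cfg$normalization$reference
      if (is.null(ref)) ref <- default_reference_stats()
      reinhard_normalize(image, ref)
    })
    norm <- s$value; timings <- s$timings
  } else {
    norm <- image
  }

  s <- stage("deconvolve", timings, {
    M <- build_stain_matrix(cfg$stains$h_vector, cfg$stains$dab_vector)
    deconvolve(rgb_to_od(norm, cfg$stains$background), M,
               cfg$stains$background)
  })
  maps <- s$value; timings <- s$timings

  s <- stage("tissue_mask", timings, {
    mask <- make_tissue_mask(maps$hema_gray, morphology_params(
      se_radius = cfg$mask$se_radius,
      min_tissue_fraction = cfg$mask$min_tissue_fraction))
    if (isTRUE(cfg$plastic_removal$enabled) && is.function(plastic_hook))
      mask <- plastic_hook(norm, mask)
    mask
  })
  mask <- s$value; timings <- s$timings

  if (isTRUE(cfg$rotation$enabled)) {
    s <- stage("rotation_search", timings, {
      find_horizontal_rotation(mask, rotation_search_params(
        angle_min = cfg$rotation$angle_min, angle_max = cfg$rotation$angle_max,
        angle_step = cfg$rotation$angle_step,
        coarse_to_fine = cfg$rotation$coarse_to_fine))
    })
    angle <- s$value$best_angle; timings <- s$timings
  } else {
    angle <- 0
  }

  s <- stage("rotate_crop", timings, {
    rotate_and_crop(norm, mask, angle, margin = cfg$rotation$margin_px,
                    extras = list(dab_gray = maps$dab_gray,
                                  dab_rgb = maps$dab_rgb))
  })
  rc <- s$value; timings <- s$timings

  s <- stage("gate", timings, {
    ap <- average_proportion(rc$extras$dab_gray, cfg$gate$pixel_threshold)
    list(ap = ap, positive = classify_sample(ap, cfg$gate$ap_cutoff))
  })
  gate <- s$value; timings <- s$timings

  seg <- NULL
  if (gate$positive) {
    s <- stage("segment", timings, {
      segment_dab(rc$extras$dab_rgb, rc$extras$dab_gray, rc$mask,
                  clustering_params(k_min = cfg$segment$k_min,
                                    k_max = cfg$segment$k_max,
                                    seed = cfg$segment$seed,
                                    n_init = cfg$segment$n_init))
    })
    seg <- s$value; timings <- s$timings
  }

  res <- sample_result(
    image_id = image_id, marker = marker, rotation_deg = angle,
    tissue_px = sum(rc$mask), ap_percent = gate$ap,
    is_positive = gate$positive,
    k_clusters = if (gate$positive) seg$k else 0L,
    dab_percent = if (gate$positive) seg$dab_percent else 0)
  out <- c(unclass(res),
           list(low_contrast = if (gate$positive) seg$low_contrast else FALSE,
                timings = timings, config = cfg))
  if (keep_intermediates) {
    out$intermediates <- list(image = rc$image, mask = rc$mask,
                              dab_gray = rc$extras$dab_gray,
                              dab_rgb = rc$extras$dab_rgb,
                              segmentation = seg)
  }
  structure(out, class = c("dab_sample", "sample_result"))
}

#' @export
print.dab_sample <- function(x, ...) {
  cat("H-DAB sample ", x$image_id,
      if (!is.na(x$marker)) paste0(" [", x$marker, "]"), "\n", sep = "")
  cat("  rotation: ", x$rotation_deg, " deg; tissue: ", x$tissue_px,
      " px\n", sep = "")
  cat("  AP: ", format(x$ap_percent, digits = 4), "% -> ",
      if (x$is_positive) "positive" else "negative", "\n", sep = "")
  if (x$is_positive)
    cat("  k = ", x$k_clusters, "; DAB occupancy = ",
        format(x$dab_percent, digits = 4), "% of tissue\n", sep = "")
  invisible(x)
}

#' Run the pipeline over a directory of images
#'
#' Processes every readable JPEG/PNG/TIFF in `input_dir`, writes per-image
#' outputs (DAB mask and contour overlay PNGs for positive samples) and the
#' batch CSV report under `out_dir`, plus a per-marker summary (count,
#' median, IQR of DAB occupancy among positives) when a marker map is given.
#' Unreadable or failing images are recorded and skipped, not fatal.
#'
#' @param input_dir Directory with >= 1 image.
#' @param config Configuration overrides.
#' @param out_dir Output directory (default from config `io.out_dir`).
#' @param marker_map Optional path to (or data frame of) a two-column CSV
#'   `file,marker` mapping file names to marker labels.
#' @return A `dab_batch` list: `results` (report data frame), `summary`
#'   (per-marker data frame or `NULL`), `failed` (character vector),
#'   `out_dir`.
#' @export
run_batch <- function(input_dir, config = list(), out_dir = NULL,
                      marker_map = NULL) {
  cfg <- validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$io$out_dir
  files <- list.files(input_dir, "\\.(jpe?g|png|tiff?)$", ignore.case = TRUE)
  if (length(files) == 0L)
    stop("no readable images in ", input_dir, call. = FALSE)
  markers <- NULL
  if (!is.null(marker_map)) {
    mm <- if (is.data.frame(marker_map)) marker_map else
      read.csv(marker_map, stringsAsFactors = FALSE)
    markers <- stats::setNames(as.character(mm[[2L]]), mm[[1L]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); failed <- character()
  for (f in files) {
    id <- tools::file_path_sans_ext(f)
    marker <- if (!is.null(markers) && f %in% names(markers))
      markers[[f]] else NA_character_
    res <- tryCatch({
      img <- load_rgb_image(file.path(input_dir, f))
      run_pipeline(img, cfg, image_id = id, marker = marker,
                   keep_intermediates = TRUE)
    }, error = function(e) {
      dq_log("warn", "sample ", id, " failed: ", conditionMessage(e))
      e
    })
    if (inherits(res, "error")) {
      failed <- c(failed, id)
      next
    }
    if (res$is_positive) {
      seg <- res$intermediates$segmentation
      sample_dir <- file.path(out_dir, id)
      dir.create(sample_dir, showWarnings = FALSE)
      write_mask_png(seg$dab_mask, file.path(sample_dir, "dab_mask.png"))
      write_image_png(draw_overlay(res$intermediates$image, seg$dab_mask),
                      file.path(sample_dir, "overlay.png"))
    }
    res$intermediates <- NULL
    rows[[id]] <- as.data.frame(res)
  }
  results <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else as.data.frame(stats::setNames(
      lapply(report_columns, function(x) character(0)), report_columns))
  write_report(results, file.path(out_dir, "report.csv"))
  summary_df <- NULL
  if (!is.null(markers) && nrow(results) > 0L) {
    summary_df <- do.call(rbind, lapply(split(results, results$marker),
      function(g) {
        pos <- g$dab_percent[g$is_positive]
        data.frame(marker = g$marker[1L], n = nrow(g), n_positive = length(pos),
                   median_dab_percent = if (length(pos)) median(pos) else NA_real_,
                   iqr_dab_percent = if (length(pos)) stats::IQR(pos) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  structure(list(results = results, summary = summary_df, failed = failed,
                 out_dir = out_dir),
            class = "dab_batch")
}

#' @export
print.dab_batch <- function(x, ...) {
  cat("H-DAB batch: ", nrow(x$results), " samples (",
      sum(x$results$is_positive), " positive), ",
      length(x$failed), " failed\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
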