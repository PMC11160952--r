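# End-to-end orchestration: images + annotations + metadata in, tidy
# metrics / intereye / stats files out. Also drives the synthetic mode.

#' Read an 8-bit grayscale angiogram image
#'
#' @param path PNG file path.
#' @param pixel_pitch mm per pixel.
#' @param eye_side,plexus,patient_id Labels attached to the image.
#' @return An [enface_image].
#' @export
read_enface_png <- function(path, pixel_pitch, eye_side, plexus,
                            patient_id = NA_character_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]  # grayscale channel
  enface_image(round(a * 255), pixel_pitch, eye_side, plexus, patient_id)
}

#' Write a grayscale image or binary mask as PNG
#'
#' Masks (logical matrices) are written as 0/255.
#'
#' @param x Numeric matrix in `[0, 255]`, logical matrix, or
#'   [enface_image].
#' @param path Output PNG path.
#' @export
write_enface_png <- function(x, path) {
  px <- if (inherits(x, "enface_image")) x$pixels else x
  if (is.logical(px)) px <- px * 255
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param manifest Path to the input manifest CSV (columns `patient_id,
#'   side, stage, plexus, image, faz_polygon, age, sex, hba1c`; the FAZ
#'   polygon applies to SCP rows), or `NULL` for synthetic mode.
#' @param output_dir Directory for `metrics.csv`, `intereye.csv`,
#'   `stats.json`, `run.log`.
#' @param pixel_pitch mm per pixel of the input images.
#' @param std_coeff_all,std_coeff_big Threshold coefficients for the
#'   all-vessel and big-vessel segmentations.
#' @param big_dilation Dilation radius (px) of the big-vessel exclusion
#'   mask.
#' @param dcp_exclude_projection Apply the SCP big-vessel mask to the DCP
#'   as a projection-artifact exclusion.
#' @param fd_offset_average Average box counts over grid offsets.
#' @param alpha Significance level of the cohort statistics.
#' @param synthetic Synthetic-mode settings: list with `n_patients`,
#'   `seed`, and optional overrides of [image_gen_params()] fields.
#' @param stats_metrics Metrics to model at the cohort level.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, output_dir = "octasym-out",
                            pixel_pitch = 0.012, std_coeff_all = 0.5,
                            std_coeff_big = 1.3, big_dilation = 0,
                            dcp_exclude_projection = FALSE,
                            fd_offset_average = FALSE, alpha = 0.05,
                            synthetic = NULL,
                            stats_metrics = "vd_total_SCP") {
  if (std_coeff_all <= 0 || std_coeff_big <= 0) {
    stop("threshold coefficients must be positive")
  }
  structure(
    list(manifest = manifest, output_dir = output_dir,
         pixel_pitch = pixel_pitch, std_coeff_all = std_coeff_all,
         std_coeff_big = std_coeff_big, big_dilation = big_dilation,
         dcp_exclude_projection = dcp_exclude_projection,
         fd_offset_average = fd_offset_average, alpha = alpha,
         synthetic = synthetic, stats_metrics = stats_metrics),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Quantify one eye: sector VD per plexus, FD per plexus, FAZ metrics (SCP).
# `images` is a named list SCP/DCP of enface_image; faz may be a faz_trace.
quantify_eye <- function(images, faz, config, scp_big = NULL) {
  out <- list()
  grids <- list()
  faz_center <- polygon_centroid(faz$polygon)
  for (plx in names(images)) {
    img <- images[[plx]]
    all_v <- binarize(img, config$std_coeff_all)
    big <- if (plx == "SCP") {
      big_vessel_mask(img, config$big_dilation, config$std_coeff_big)
    } else {
      scp_big
    }
    am <- analysis_mask(all_v, big, plexus = plx,
                        exclude_projection = config$dcp_exclude_projection)
    grid <- withCallingHandlers(
      build_grid(faz_center, img$pixel_pitch, nrow(img$pixels)),
      warning = function(w) {
        if (grepl("clipped", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    if (grid$clipped) out$qc_clipped <- TRUE
    grids[[plx]] <- grid
    vd <- vessel_density(am$capillary_mask, am$excluded_area_mask, grid)
    fd <- fractal_dimension(am$capillary_mask,
                            offset_average = config$fd_offset_average)
    out[[paste0("vd_total_", plx)]] <- vd$vd_total
    out[[paste0("vd_ir_", plx)]] <- vd$vd_ir
    out[[paste0("vd_or_", plx)]] <- vd$vd_or
    out[[paste0("fd_", plx)]] <- fd$fd
    if (plx == "SCP") out$scp_big <- big
  }
  fm <- faz_metrics(faz)
  out$faza <- fm$faza; out$fazp <- fm$fazp; out$fazc <- fm$fazc
  out
}

eye_metric_rows <- function(q, patient_id, side, stage) {
  metric_of <- function(name) sub("_(SCP|DCP)$", "", name)
  plexus_of <- function(name) {
    m <- regmatches(name, regexpr("(SCP|DCP)$", name))
    if (length(m)) m else ""
  }
  nm <- setdiff(names(q), c("scp_big", "qc_clipped"))
  do.call(rbind, lapply(nm, function(name) {
    data.frame(patient_id = patient_id, side = side, stage = stage,
               plexus = plexus_of(name),
               metric = metric_of(name),
               sector = if (grepl("^vd_ir", name)) "IR"
                        else if (grepl("^vd_or", name)) "OR"
                        else if (grepl("^vd_total", name)) "total" else "",
               value = q[[name]])
  }))
}

# Generate images + FAZ traces for one synthetic patient (both plexuses).
synthesize_patient <- function(pid, stage, config, seed) {
  syn <- config$synthetic
  base_args <- syn[intersect(names(syn), names(formals(image_gen_params)))]
  # stage-dependent capillary deficit mimicking capillary dropout
  stage_drop <- c(no = 0, mild = 0, moderate = 0.005, severe = 0.01,
                  PDR = 0.012)[[stage]]
  eyes <- list()
  for (plx in c("SCP", "DCP")) {
    args <- base_args
    args$seed <- derive_seed(seed, match(plx, c("SCP", "DCP")))
    base_cf <- if (!is.null(args$capillary_fraction)) args$capillary_fraction
               else if (plx == "SCP") 0.22 else 0.235
    args$capillary_fraction <- base_cf - stage_drop
    eyes[[plx]] <- generate_angiogram_pair(do.call(image_gen_params, args),
                                           plexus = plx, patient_id = pid)
  }
  eyes
}

#' Run the full intereye analysis pipeline
#'
#' Manifest mode reads en-face PNGs and FAZ polygon CSVs per the manifest;
#' synthetic mode generates a paired-eye image cohort instead. Both modes
#' then binarize, build the ETDRS grid from the FAZ centroid, measure
#' sector vessel densities, fractal dimensions and FAZ metrics, pair the
#' eyes, and run the cohort statistics, writing `metrics.csv`,
#' `intereye.csv`, `stats.json` and `run.log` to the output directory.
#' Floating outputs are rounded to 6 decimals so repeat runs are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, list with `metrics`, `intereye`, `stats`, and file
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("octasym %s", as.character(utils::packageVersion("octasym"))),
           sprintf("config: std_coeff_all=%g std_coeff_big=%g big_dilation=%g dcp_exclude_projection=%s alpha=%g",
                   config$std_coeff_all, config$std_coeff_big,
                   config$big_dilation, config$dcp_exclude_projection,
                   config$alpha))
  metrics <- list()

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    n_patients <- if (!is.null(syn$n_patients)) syn$n_patients else 6L
    seed <- if (!is.null(syn$seed)) syn$seed else 1L
    stages <- if (!is.null(syn$stages)) syn$stages else "no"
    log <- c(log, sprintf("synthetic mode: %d patients, seed %d", n_patients,
                          as.integer(seed)))
    for (i in seq_len(n_patients)) {
      pid <- sprintf("SYN%03d", i)
      stage <- stages[(i - 1L) %% length(stages) + 1L]
      eyes <- synthesize_patient(pid, stage, config, derive_seed(seed, i))
      set.seed(derive_seed(seed, 10000L + i))
      age <- round(stats::rnorm(1, 57.2, 13.1), 1)
      hba1c <- round(stats::rnorm(1, 7.34, 1.32), 2)
      sex <- if (stats::runif(1) < 0.66) "male" else "female"
      for (side in c("right", "left")) {
        imgs <- list(SCP = eyes$SCP[[side]], DCP = eyes$DCP[[side]])
        truth <- eyes$SCP[[paste0("truth_", side)]]
        faz <- faz_trace(truth$faz_polygon, config$pixel_pitch, check = FALSE)
        q <- quantify_eye(imgs, faz, config)
        if (isTRUE(q$qc_clipped)) {
          log <- c(log, sprintf("qc: grid clipped for %s/%s", pid, side))
        }
        rows <- eye_metric_rows(q, pid, side, stage)
        rows$age <- age; rows$sex <- sex; rows$hba1c <- hba1c
        metrics[[length(metrics) + 1L]] <- rows
      }
    }
  } else {
    if (is.null(config$manifest)) stop("either `manifest` or `synthetic` must be set")
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    req <- c("patient_id", "side", "stage", "plexus", "image")
    if (!all(req %in% names(man))) {
      stop("manifest lacks columns: ",
           paste(setdiff(req, names(man)), collapse = ", "))
    }
    for (i in seq_len(nrow(man))) {
      if (!file.exists(man$image[i])) {
        stop(sprintf("manifest row %d: image not found (%s)", i, man$image[i]))
      }
    }
    key <- with(man, paste(patient_id, side, plexus))
    if (anyDuplicated(key)) stop("duplicate (patient, side, plexus) in manifest")
    eyes <- split(man, with(man, paste(patient_id, side)))
    for (e in eyes) {
      pid <- e$patient_id[1]; side <- e$side[1]; stage <- e$stage[1]
      imgs <- list()
      faz <- NULL
      for (i in seq_len(nrow(e))) {
        imgs[[e$plexus[i]]] <- read_enface_png(e$image[i], config$pixel_pitch,
                                               side, e$plexus[i], pid)
        if (e$plexus[i] == "SCP") {
          if (is.null(e$faz_polygon) || !nzchar(e$faz_polygon[i])) {
            stop("SCP row without FAZ polygon for patient ", pid)
          }
          faz <- read_faz_trace(e$faz_polygon[i], config$pixel_pitch)
        }
      }
      if (is.null(faz)) {
        log <- c(log, sprintf("excluded %s/%s: no SCP image/FAZ trace", pid, side))
        next
      }
      imgs <- imgs[intersect(c("SCP", "DCP"), names(imgs))]
      q <- quantify_eye(imgs, faz, config)
      if (isTRUE(q$qc_clipped)) {
        log <- c(log, sprintf("qc: grid clipped for %s/%s", pid, side))
      }
      rows <- eye_metric_rows(q, pid, side, stage)
      rows$age <- if (!is.null(e$age)) e$age[1] else NA
      rows$sex <- if (!is.null(e$sex)) e$sex[1] else NA
      rows$hba1c <- if (!is.null(e$hba1c)) e$hba1c[1] else NA
      metrics[[length(metrics) + 1L]] <- rows
    }
  }

  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  pairs <- pair_eyes(metrics[, c("patient_id", "side", "stage", "metric",
                                 "sector", "plexus", "value")])
  for (u in attr(pairs, "unpaired")) log <- c(log, paste("unpaired:", u))

  stats_out <- list()
  covars <- unique(metrics[, c("patient_id", "age", "sex", "hba1c")])
  for (m in config$stats_metrics) {
    sub <- metrics[paste0(metrics$metric,
                          ifelse(nzchar(metrics$plexus), "_", ""),
                          metrics$plexus) == m &
                     metrics$sector %in% c("", "total"), ]
    if (nrow(sub) < 8L) {
      log <- c(log, sprintf("stats for %s skipped: too few eyes (%d)", m, nrow(sub)))
      next
    }
    dat <- merge(sub[, c("patient_id", "side", "stage", "value")], covars,
                 by = "patient_id")
    names(dat)[names(dat) == "value"] <- "response"
    res <- withCallingHandlers(
      try(fit_intereye_model(dat, alpha = config$alpha), silent = TRUE),
      warning = function(w) {
        log <<- c(log, sprintf("stats warning for %s: %s", m,
                               conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "try-error")) {
      log <- c(log, sprintf("stats for %s failed: %s", m,
                            conditionMessage(attr(res, "condition"))))
      next
    }
    rep <- branch_and_contrast(res)
    stats_out[[m]] <- list(
      side = res$side_marginal,
      side_coefficient = as.list(res$fixed[res$fixed$term == "sideleft",
                                           c("estimate", "ci_lower",
                                             "ci_upper", "p_value")]),
      stage_f_p = res$stage_f_p, interaction_f_p = res$interaction_f_p,
      stage_triggered = rep$stage_triggered,
      interaction_triggered = rep$interaction_triggered,
      variance_components = as.list(res$varcomp),
      notes = res$log)
  }

  metrics_out <- metrics
  metrics_out$value <- round(metrics_out$value, 6)
  pairs_out <- pairs
  for (cc in c("right", "left", "delta_abs", "asymmetry_index")) {
    pairs_out[[cc]] <- round(pairs_out[[cc]], 6)
  }
  paths <- list(metrics = file.path(config$output_dir, "metrics.csv"),
                intereye = file.path(config$output_dir, "intereye.csv"),
                stats = file.path(config$output_dir, "stats.json"),
                log = file.path(config$output_dir, "run.log"))
  utils::write.csv(metrics_out, paths$metrics, row.names = FALSE)
  utils::write.csv(pairs_out, paths$intereye, row.names = FALSE)
  jsonlite::write_json(stats_out, paths$stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(log, paste("finished", format(Sys.time()))), paths$log)
  invisible(list(metrics = metrics, intereye = pairs, stats = stats_out,
                 paths = paths, log = log))
}

#' Summary tables of a metrics table
#'
#' Produces the two standard cohort summaries: mean and SD per
#' stage x side x metric, and the median (Q1; Q3) of the asymmetry index
#' and absolute intereye difference per stage x metric (linear-interpolation
#' quantiles). Empty cells are reported as `NA`, not zero.
#'
#' @param metrics Long metrics data frame as written by [run_pipeline()].
#' @param pairs Optional intereye pair table ([pair_eyes()] output).
#' @return List with data frames `by_stage_side` and, when `pairs` is
#'   given, `asymmetry_by_stage`.
#' @export
summarize_metrics <- function(metrics, pairs = NULL) {
  key <- list(stage = metrics$stage, side = metrics$side,
              metric = metrics$metric, plexus = metrics$plexus,
              sector = metrics$sector)
  agg_m <- stats::aggregate(metrics$value, key, mean)
  agg_s <- stats::aggregate(metrics$value, key,
                            function(v) if (length(v) > 1) stats::sd(v) else 0)
  out <- agg_m
  names(out)[names(out) == "x"] <- "mean"
  out$sd <- agg_s$x
  res <- list(by_stage_side = out)
  if (!is.null(pairs) && nrow(pairs)) {
    q <- function(v, p) stats::quantile(v, p, type = 7, names = FALSE)
    key2 <- list(stage = pairs$stage, metric = pairs$metric,
                 plexus = pairs$plexus, sector = pairs$sector)
    sum_one <- function(col) {
      a <- stats::aggregate(pairs[[col]], key2, function(v)
        c(median = q(v, 0.5), q1 = q(v, 0.25), q3 = q(v, 0.75)))
      cbind(a[names(key2)], stats::setNames(as.data.frame(a$x),
        paste0(col, c("_median", "_q1", "_q3"))))
    }
    ai <- sum_one("asymmetry_index")
    da <- sum_one("delta_abs")
    res$asymmetry_by_stage <- cbind(ai, da[, -(1:4), drop = FALSE])
  }
  res
}
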