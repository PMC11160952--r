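#' Absolute intereye difference and asymmetry index
#'
#' The asymmetry index of a metric between fellow eyes is the absolute
#' right-left difference divided by the mean of the two eyes, times 100
#' (percent). It is scale-invariant and symmetric in its arguments.
#'
#' @param right,left Metric values of the right and left eye. Vectorized.
#' @return Data frame with `delta_abs` and `asymmetry_index` (percent).
#' @examples
#' asymmetry(0.22, 0.20)  # delta_abs 0.02, AI ~ 9.52
#' @export
asymmetry <- function(right, left) {
  if (length(right) != length(left)) stop("`right` and `left` lengths differ")
  m <- (right + left) / 2
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("asymmetry index undefined: nonpositive or missing two-eye mean")
  }
  d <- abs(right - left)
  data.frame(delta_abs = d, asymmetry_index = d / m * 100)
}

#' Pair fellow eyes and compute intereye asymmetry per metric
#'
#' Joins the right and left eye of each patient for every
#' (metric, plexus, sector) combination and attaches the absolute intereye
#' difference and asymmetry index. Patients lacking a fellow eye for a
#' metric are dropped and reported in the `unpaired` attribute.
#'
#' @param metrics Long data frame with columns `patient_id`, `side`
#'   (`"right"`/`"left"`), `stage`, `metric`, `value`, and optionally
#'   `plexus` and `sector` (filled with `""` when absent).
#' @return Data frame with one row per patient x metric:
#'   `patient_id, stage, metric, sector, plexus, right, left, delta_abs,
#'   asymmetry_index`; attribute `unpaired` lists dropped
#'   (patient, metric) combinations.
#' @export
pair_eyes <- function(metrics) {
  if (nrow(metrics) == 0L) {
    out <- data.frame(patient_id = character(), stage = character(),
                      metric = character(), sector = character(),
                      plexus = character(), right = numeric(),
                      left = numeric(), delta_abs = numeric(),
                      asymmetry_index = numeric())
    attr(out, "unpaired") <- character()
    return(out)
  }
  req <- c("patient_id", "side", "stage", "metric", "value")
  missing_cols <- setdiff(req, names(metrics))
  if (length(missing_cols)) {
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"plexus" %in% names(metrics)) metrics$plexus <- ""
  if (!"sector" %in% names(metrics)) metrics$sector <- ""
  key <- interaction(metrics$patient_id, metrics$side, metrics$metric,
                     metrics$plexus, metrics$sector, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, side, metric, plexus, sector) rows in metrics table")
  }
  # fellow eyes must carry the same stage label
  st <- tapply(metrics$stage, metrics$patient_id,
               function(s) length(unique(s)))
  if (any(st > 1L)) {
    stop("patients with conflicting stage labels between eyes: ",
         paste(names(st)[st > 1L], collapse = ", "))
  }
  mk <- interaction(metrics$patient_id, metrics$metric, metrics$plexus,
                    metrics$sector, drop = TRUE)
  pieces <- split(metrics, mk)
  paired <- list(); unpaired <- character()
  for (p in pieces) {
    r <- p$value[p$side == "right"]; l <- p$value[p$side == "left"]
    if (length(r) == 1L && length(l) == 1L) {
      a <- asymmetry(r, l)
      paired[[length(paired) + 1L]] <- data.frame(
        patient_id = p$patient_id[1], stage = p$stage[1],
        metric = p$metric[1], sector = p$sector[1], plexus = p$plexus[1],
        right = r, left = l, delta_abs = a$delta_abs,
        asymmetry_index = a$asymmetry_index)
    } else {
      unpaired <- c(unpaired,
                    sprintf("%s/%s/%s/%s: missing fellow eye", p$patient_id[1],
                            p$metric[1], p$plexus[1], p$sector[1]))
    }
  }
  out <- if (length(paired)) do.call(rbind, paired) else {
    data.frame(patient_id = character(), stage = character(),
               metric = character(), sector = character(),
               plexus = character(), right = numeric(), left = numeric(),
               delta_abs = numeric(), asymmetry_index = numeric())
  }
  rownames(out) <- NULL
  ord <- order(out$metric, out$plexus, out$sector, out$patient_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unpaired") <- unpaired
  out
}
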