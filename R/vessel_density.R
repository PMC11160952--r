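#' Vessel density per ETDRS sector
#'
#' Vessel density (VD) is the fraction of the measured area occupied by
#' flow-positive (vessel) pixels. For each sector the measured area is the
#' sector area minus any excluded pixels (big vessels, projection
#' artifacts); excluded pixels are removed from numerator and denominator
#' alike so that VD reflects the microcirculation of the remaining area.
#'
#' @param capillary_mask Logical matrix of capillary (vessel) pixels, e.g.
#'   from [analysis_mask()].
#' @param excluded_area_mask Logical matrix of pixels excluded from the
#'   measured area, or `NULL` for no exclusion.
#' @param grid An [build_grid()] ETDRS grid sharing the image shape.
#' @return Object of class `sector_vd`: list with fractions `vd_total`,
#'   `vd_ir`, `vd_or`, `vd_central`, and per-sector `measured_area_px` and
#'   `excluded_area_px`.
#' @export
vessel_density <- function(capillary_mask, excluded_area_mask = NULL, grid) {
  if (!inherits(grid, "etdrs_grid")) stop("`grid` must be an etdrs_grid")
  cm <- if (is.logical(capillary_mask)) capillary_mask else capillary_mask > 0
  if (!identical(dim(cm), dim(grid$total))) {
    stop("capillary mask and grid must share the image shape")
  }
  if (is.null(excluded_area_mask)) {
    ex <- matrix(FALSE, nrow(cm), ncol(cm))
  } else {
    ex <- if (is.logical(excluded_area_mask)) excluded_area_mask else excluded_area_mask > 0
    if (!identical(dim(ex), dim(cm))) {
      stop("exclusion mask and capillary mask must share the image shape")
    }
  }
  cm <- cm & !ex  # excluded pixels never count as capillaries
  sectors <- list(total = grid$total, ir = grid$ir, or_ = grid$or_,
                  central = grid$central)
  measured <- excluded <- numeric(4)
  vd <- numeric(4)
  names(vd) <- names(measured) <- names(excluded) <- names(sectors)
  for (s in names(sectors)) {
    sm <- sectors[[s]]
    excluded[[s]] <- sum(sm & ex)
    measured[[s]] <- sum(sm) - excluded[[s]]
    if (measured[[s]] <= 0) {
      stop("sector '", sub("_$", "", s), "' has zero measured area")
    }
    vd[[s]] <- sum(cm & sm) / measured[[s]]
  }
  structure(
    list(vd_total = vd[["total"]], vd_ir = vd[["ir"]], vd_or = vd[["or_"]],
         vd_central = vd[["central"]],
         measured_area_px = measured, excluded_area_px = excluded),
    class = "sector_vd"
  )
}

#' @export
print.sector_vd <- function(x, ...) {
  cat(sprintf("<sector_vd> total %.4f, IR %.4f, OR %.4f (central %.4f)\n",
              x$vd_total, x$vd_ir, x$vd_or, x$vd_central))
  invisible(x)
}
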