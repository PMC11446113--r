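#' @name roi
#' @title Intratumoral and peritumoral ROI derivation
#'
#' @description
#' Eight regions of interest are derived from a lesion mask by physical-
#' distance morphology: the intratumoral region (ITR), its 3 mm shrink
#' (`ITR-3mm`), 3 mm and 5 mm expansions (`ITR+3mm`, `ITR+5mm`), and four
#' peritumoral shells defined as set differences (`PTR0~+3mm`, `PTR0~+5mm`,
#' `PTR-3~+3mm`, `PTR-3~+5mm`). All offsets are Euclidean distances in mm,
#' computed via an exact anisotropic distance transform, so a "3 mm" margin
#' means 3 mm on any grid.
NULL

#' Canonical ROI names
#' @return character vector of the eight ROI names.
#' @export
roi_names <- function() {
  c("ITR", "ITR-3mm", "ITR+3mm", "ITR+5mm",
    "PTR0~+3mm", "PTR0~+5mm", "PTR-3~+3mm", "PTR-3~+5mm")
}

empty_roi_error <- function(roi, id = NULL) {
  structure(class = c("renorad_empty_roi", "error", "condition"),
            list(message = sprintf("ROI '%s' is empty%s", roi,
                                   if (is.null(id)) "" else
                                     sprintf(" for lesion '%s'", id)),
                 call = NULL, roi = roi, lesion_id = id))
}

#' Morphological offset of a mask in physical units
#'
#' Dilates (`offset_mm > 0`) or erodes (`offset_mm < 0`) a binary mask by a
#' Euclidean distance in mm via distance-transform thresholding. A dilation
#' keeps voxels within `offset_mm` of the mask; an erosion keeps mask voxels
#' farther than `|offset_mm|` from the background. `offset_mm = 0` returns
#' the input.
#'
#' @param mask 3-D logical array.
#' @param spacing voxel spacing in mm.
#' @param offset_mm signed offset in mm, `|offset_mm| <= max_offset_mm`.
#' @param max_offset_mm guard against runaway offsets (default 5).
#' @param lesion_id optional id carried in the empty-ROI error.
#' @return logical mask.
#' @export
morph_mm <- function(mask, spacing = voxel_spacing(mask), offset_mm,
                     max_offset_mm = 5, lesion_id = NULL) {
  stopifnot(all(spacing > 0))
  if (abs(offset_mm) > max_offset_mm + 1e-9)
    stop("offset exceeds configured maximum of ", max_offset_mm, " mm")
  if (offset_mm == 0) return(mask)
  if (offset_mm > 0) {
    out <- distance_to_mask(mask, spacing) <= offset_mm
  } else {
    out <- mask & (distance_to_mask(!mask, spacing) > -offset_mm)
    if (!any(out)) stop(empty_roi_error("erosion", lesion_id))
  }
  attr(out, "spacing") <- spacing
  out
}

#' Derive the eight ROIs from a lesion mask
#'
#' @param mask non-empty 3-D logical lesion mask (the ITR).
#' @param spacing voxel spacing in mm.
#' @param lesion_id optional id carried in error conditions.
#' @param on_empty `"error"` raises an empty-ROI condition when the 3 mm
#'   erosion empties (sub-6-mm lesions); `"flag"` keeps an all-`FALSE`
#'   `ITR-3mm` and records the name in the `flagged_empty` attribute so the
#'   case is excluded from that ROI's feature table rather than dropped.
#' @return named list of eight logical masks (class `roi_set`) satisfying
#'   `ITR-3mm` \eqn{\subseteq} `ITR` \eqn{\subseteq} `ITR+3mm`
#'   \eqn{\subseteq} `ITR+5mm`, with each PTR an exact set difference of the
#'   corresponding morphs.
#' @export
derive_rois <- function(mask, spacing = voxel_spacing(mask), lesion_id = NULL,
                        on_empty = c("error", "flag")) {
  on_empty <- match.arg(on_empty)
  if (!any(mask)) stop(empty_roi_error("ITR", lesion_id))
  itr <- mask
  flagged <- character()
  itr_m3 <- tryCatch(
    morph_mm(mask, spacing, -3, lesion_id = lesion_id),
    renorad_empty_roi = function(e) {
      if (on_empty == "error") stop(empty_roi_error("ITR-3mm", lesion_id))
      flagged <<- "ITR-3mm"
      structure(array(FALSE, dim(mask)), spacing = spacing)
    })
  itr_p3 <- morph_mm(mask, spacing, +3, lesion_id = lesion_id)
  itr_p5 <- morph_mm(mask, spacing, +5, lesion_id = lesion_id)
  rois <- list(
    "ITR"        = itr,
    "ITR-3mm"    = itr_m3,
    "ITR+3mm"    = itr_p3,
    "ITR+5mm"    = itr_p5,
    "PTR0~+3mm"  = itr_p3 & !itr,
    "PTR0~+5mm"  = itr_p5 & !itr,
    "PTR-3~+3mm" = itr_p3 & !itr_m3,
    "PTR-3~+5mm" = itr_p5 & !itr_m3)
  rois <- lapply(rois, function(m) { attr(m, "spacing") <- spacing; m })
  structure(rois, class = "roi_set", spacing = spacing, lesion_id = lesion_id,
            flagged_empty = flagged)
}
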