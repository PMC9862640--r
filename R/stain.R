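#' Stain detection profiles
#'
#' A stain profile is the fixed HSB threshold box and per-object area rule
#' used by one stain camera. A pixel is a stain candidate when its hue,
#' saturation and brightness each fall inside the profile's inclusive
#' interval (all on the 0-255 scale); a cocoon is called stained when any
#' single connected candidate object exceeds `min_object_area_px2` (strictly).
#'
#' The default profiles are the operating thresholds of the two stain
#' cameras, which differ because of their different illumination: the
#' top-view camera flags warm hues of at least moderate saturation
#' (H 0-80, S 60-255, B 0-255) and the bottom-view camera flags any strongly
#' saturated pixel (H 0-255, S 220-255, B 0-255); both use the 144 px^2
#' object-area rule.
#'
#' @param camera_id `"top"` or `"bottom"`.
#' @param h_range,s_range,b_range inclusive integer intervals on 0-255.
#' @param min_object_area_px2 strict per-object area threshold (default 144).
#' @return object of class `stain_profile`.
#' @export
stain_profile <- function(camera_id = c("top", "bottom"),
                          h_range = NULL, s_range = NULL, b_range = NULL,
                          min_object_area_px2 = 144) {
  camera_id <- match.arg(camera_id)
  defaults <- list(
    top    = list(h = c(0, 80),  s = c(60, 255),  b = c(0, 255)),
    bottom = list(h = c(0, 255), s = c(220, 255), b = c(0, 255))
  )[[camera_id]]
  h_range <- h_range %||% defaults$h
  s_range <- s_range %||% defaults$s
  b_range <- b_range %||% defaults$b
  for (rg in list(h_range, s_range, b_range)) {
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 0 || rg[2] > 255)
      stop_cocoon("stain_profile: ranges must be [lo, hi] within [0, 255]",
                  class = "parameter_error")
  }
  stopifnot(min_object_area_px2 > 0)
  structure(list(camera_id = camera_id, h_range = h_range, s_range = s_range,
                 b_range = b_range,
                 min_object_area_px2 = min_object_area_px2),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat(sprintf("<stain_profile %s: H %d-%d, S %d-%d, B %d-%d, object > %d px^2>\n",
              x$camera_id, x$h_range[1], x$h_range[2], x$s_range[1],
              x$s_range[2], x$b_range[1], x$b_range[2],
              x$min_object_area_px2))
  invisible(x)
}

#' Threshold an HSB image against a stain profile
#'
#' Flags every pixel whose H, S and B all fall inside the profile's intervals.
#' When a region of interest is supplied the filter is confined to it
#' (normally the segmented cocoon silhouette, so that background or cradle
#' pixels cannot trip the saturation thresholds).
#'
#' @param hsb an [hsb_image].
#' @param profile a [stain_profile].
#' @param roi optional [binary_mask] restricting the analysis.
#' @return a [binary_mask] of stain-candidate pixels.
#' @export
stain_filter <- function(hsb, profile, roi = NULL) {
  if (!inherits(hsb, "hsb_image")) hsb <- hsb_image(hsb)
  stopifnot(inherits(profile, "stain_profile"))
  m <- hsb[, , 1] >= profile$h_range[1] & hsb[, , 1] <= profile$h_range[2] &
       hsb[, , 2] >= profile$s_range[1] & hsb[, , 2] <= profile$s_range[2] &
       hsb[, , 3] >= profile$b_range[1] & hsb[, , 3] <= profile$b_range[2]
  m <- matrix(m, dim(hsb)[1], dim(hsb)[2])
  if (!is.null(roi)) {
    if (!identical(dim(m), dim(unclass(roi))))
      stop_cocoon("stain_filter: roi dimensions differ from image",
                  class = "parameter_error")
    m <- m & roi
  }
  binary_mask(m)
}

#' Stain verdict from a filtered mask
#'
#' Labels the 8-connected candidate objects and declares the cocoon stained
#' when any single object's area strictly exceeds the profile's
#' `min_object_area_px2` (144 px^2 by default); an object of exactly the
#' threshold area does not count, and several small objects are never summed
#' (summing would flag speckle noise).
#'
#' @param mask a [binary_mask] from [stain_filter()].
#' @param profile the [stain_profile] that produced it.
#' @param cocoon_id optional identifier carried into the verdict for pairing.
#' @return object of class `stain_verdict`: list with `stained`,
#'   `flagged_objects` (data frame: `area_px2`, `centroid_x`, `centroid_y`,
#'   `exceeds`), `view`, `cocoon_id`.
#' @export
stain_verdict <- function(mask, profile, cocoon_id = NA) {
  stopifnot(inherits(profile, "stain_profile"))
  lab <- label_components(mask)
  n <- attr(lab, "n")
  if (n == 0L) {
    objs <- data.frame(area_px2 = integer(0), centroid_x = numeric(0),
                       centroid_y = numeric(0), exceeds = logical(0))
  } else {
    idx <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[lab > 0L]
    area <- tabulate(l, nbins = n)
    cx <- tapply(idx[, 2] - 1, l, mean)
    cy <- tapply(idx[, 1] - 1, l, mean)
    objs <- data.frame(area_px2 = as.integer(area),
                       centroid_x = as.numeric(cx),
                       centroid_y = as.numeric(cy),
                       exceeds = area > profile$min_object_area_px2)
  }
  structure(list(stained = any(objs$exceeds),
                 flagged_objects = objs,
                 view = profile$camera_id,
                 cocoon_id = cocoon_id),
            class = "stain_verdict")
}

#' @export
print.stain_verdict <- function(x, ...) {
  cat(sprintf("<stain_verdict %s: %s (%d objects, largest %d px^2)>\n",
              x$view, if (x$stained) "STAINED" else "unstained",
              nrow(x$flagged_objects),
              if (nrow(x$flagged_objects)) max(x$flagged_objects$area_px2) else 0L))
  invisible(x)
}

#' Combine top and bottom stain verdicts
#'
#' A spot can sit on the face not framed by one camera, so the two views are
#' OR-combined: the cocoon is stained if either view says so.
#'
#' @param top,bottom [stain_verdict] objects for the same cocoon.
#' @return logical: combined stained verdict.
#' @export
combine_views <- function(top, bottom) {
  stopifnot(inherits(top, "stain_verdict"), inherits(bottom, "stain_verdict"))
  if (!is.na(top$cocoon_id) && !is.na(bottom$cocoon_id) &&
      !identical(top$cocoon_id, bottom$cocoon_id))
    stop_cocoon("combine_views: verdicts belong to different cocoons (",
                top$cocoon_id, " vs ", bottom$cocoon_id, ")",
                class = "pairing_error")
  isTRUE(top$stained) || isTRUE(bottom$stained)
}

#' Full stain check of one view
#'
#' Convenience wrapper: segment (or accept a precomputed ROI), filter, and
#' return the verdict.
#'
#' @param img an [rgb_image] from a stain camera.
#' @param profile a [stain_profile].
#' @param roi optional [binary_mask]; when `NULL` the cocoon is segmented
#'   from the image, and on segmentation failure the whole frame is used.
#' @param cocoon_id optional identifier.
#' @return a [stain_verdict].
#' @export
check_stains <- function(img, profile, roi = NULL, cocoon_id = NA) {
  hsb <- if (inherits(img, "hsb_image")) img else rgb_to_hsb(img)
  if (is.null(roi)) {
    roi <- tryCatch(segment_cocoon(hsb), cocoonsort_error = function(e) NULL)
  }
  stain_verdict(stain_filter(hsb, profile, roi), profile, cocoon_id = cocoon_id)
}
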