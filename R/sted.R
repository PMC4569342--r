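# STED image analysis: spot detection, FWHM sizing, active-zone definition
# from Bruchpilot rings, classification and group comparison.
#
# Pixel convention: 0-based indices, coordinates refer to pixel centers,
# distances are computed center-to-center in nm (row -> y, column -> x).

#' Construct a STED-style image object
#'
#' @param intensity numeric matrix of non-negative intensities (a.u.).
#' @param pixel_size nm per pixel (default 10).
#' @param channel `"syntaxin"` or `"brp"`.
#' @param mask optional logical membrane mask, same dimensions.
#' @return A [StedImage-class].
#' @export
stedImage <- function(intensity, pixel_size = 10,
                      channel = c("syntaxin", "brp"), mask = NULL) {
  channel <- match.arg(channel)
  if (is.null(mask)) mask <- matrix(logical(0), 0, 0)
  img <- new("StedImage", intensity = intensity, pixel_size = pixel_size,
             channel = channel, mask = mask)
  validObject(img)
  img
}

#' Read / write STED images as 16-bit TIFF
#'
#' Intensities are stored as 16-bit grayscale TIFF with 1 a.u. per gray
#' level (values are clipped at 65535); integer-valued images round-trip
#' exactly. An optional mask is stored as a second TIFF.
#'
#' @param path TIFF file path.
#' @param pixel_size nm per pixel.
#' @param channel `"syntaxin"` or `"brp"`.
#' @param mask_path optional path of a mask TIFF (non-zero = membrane).
#' @return `readStedImage` returns a [StedImage-class]; `writeStedImage`
#'   returns `path` invisibly.
#' @export
readStedImage <- function(path, pixel_size = 10,
                          channel = c("syntaxin", "brp"),
                          mask_path = NULL) {
  channel <- match.arg(channel)
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- tiff::readTIFF(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- m > 0
  }
  stedImage(round(arr * 65535), pixel_size, channel, mask)
}

#' @rdname readStedImage
#' @param image a [StedImage-class].
#' @export
writeStedImage <- function(image, path) {
  stopifnot(is(image, "StedImage"))
  tiff::writeTIFF(pmin(image@intensity, 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Constant-offset background subtraction
#'
#' Subtracts a constant offset (default: the median pixel intensity, a
#' robust background estimate when structures are sparse) and clips at
#' zero. Detection thresholds are conventionally applied after this step.
#'
#' @param image a [StedImage-class].
#' @param offset background level in a.u.; `NULL` uses the median.
#' @return the background-subtracted [StedImage-class].
#' @export
subtractBackground <- function(image, offset = NULL) {
  stopifnot(is(image, "StedImage"))
  if (is.null(offset)) offset <- median(image@intensity)
  image@intensity <- pmax(image@intensity - offset, 0)
  image
}

#' Detect intensity maxima in a circular sliding window
#'
#' A pixel is a cluster/spot center iff it is the maximum within the
#' circular window of `window_px` diameter centered on it and its
#' intensity strictly exceeds `min_intensity` (25 a.u.; a peak of exactly
#' 25 is not a center). Plateaus of equal-valued maxima collapse to their
#' centroid pixel. The default window is 9 px for the syntaxin channel and
#' 21 px for Bruchpilot (at 10 nm/px), so spots closer than 40 nm
#' (syntaxin) or 100 nm (Bruchpilot) merge.
#'
#' @param image a [StedImage-class].
#' @param window_px odd window diameter in pixels (>= 3); defaults by
#'   channel as above.
#' @param min_intensity detection threshold (a.u.).
#' @return data.frame with 0-based pixel coordinates `row`, `col`, metric
#'   coordinates `x_nm` (column direction), `y_nm` (row direction) and
#'   `peak` intensity.
#' @export
detectMaxima <- function(image, window_px = NULL, min_intensity = 25) {
  stopifnot(is(image, "StedImage"))
  if (is.null(window_px))
    window_px <- if (image@channel == "syntaxin") 9L else 21L
  cen <- .cpp_detect_maxima(image@intensity, as.integer(window_px),
                            min_intensity)
  data.frame(row = cen[, 1], col = cen[, 2],
             x_nm = cen[, 2] * image@pixel_size,
             y_nm = cen[, 1] * image@pixel_size,
             peak = image@intensity[cen + 1L])
}

#' Cluster size by full-width-half-maximum area
#'
#' Starting from a detected center, rings of equidistant pixels (integer
#' Euclidean radii) are scanned outward until the first ring whose average
#' intensity drops below half the center intensity. All scanned pixels
#' with intensity at or above the half-maximum form the cluster area; the
#' reported diameter is that of the circle of equal area. Scaling all
#' intensities leaves the result unchanged (the threshold is relative).
#' Centers whose scan reaches the image border are flagged and sized `NA`.
#'
#' @param image a [StedImage-class].
#' @param center length-2 vector: 0-based `(row, col)` of a detection.
#' @param max_radius_px scan limit (default: half the smaller image side).
#' @return list with `area_px2`, `area_nm2`, `diameter_nm`, `border`
#'   (logical flag).
#' @export
fwhmSize <- function(image, center, max_radius_px = NULL) {
  img <- image@intensity
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(max_radius_px)) max_radius_px <- floor(min(nr, nc) / 2)
  r0 <- center[1] + 1L; c0 <- center[2] + 1L
  half <- img[r0, c0] / 2
  area <- 1L  # the center pixel itself (>= half by construction)
  for (rad in seq_len(max_radius_px)) {
    dr <- -rad:rad
    offs <- expand.grid(dr = dr, dc = dr)
    d <- sqrt(offs$dr^2 + offs$dc^2)
    ring <- offs[d > rad - 0.5 & d <= rad + 0.5, ]
    rr <- r0 + ring$dr; cc <- c0 + ring$dc
    if (any(rr < 1 | cc < 1 | rr > nr | cc > nc))
      return(list(area_px2 = NA_real_, area_nm2 = NA_real_,
                  diameter_nm = NA_real_, border = TRUE))
    vals <- img[cbind(rr, cc)]
    area <- area + sum(vals >= half)
    if (mean(vals) < half) {
      ps <- image@pixel_size
      a_nm2 <- area * ps^2
      return(list(area_px2 = as.numeric(area), area_nm2 = a_nm2,
                  diameter_nm = 2 * sqrt(a_nm2 / pi), border = FALSE))
    }
  }
  list(area_px2 = NA_real_, area_nm2 = NA_real_, diameter_nm = NA_real_,
       border = TRUE)
}

#' @rdname fwhmSize
#' @param detections data.frame from [detectMaxima()].
#' @return `fwhmSizes` returns the detections with `area_px2`,
#'   `diameter_nm` and `border` columns appended.
#' @export
fwhmSizes <- function(image, detections, max_radius_px = NULL) {
  out <- lapply(seq_len(nrow(detections)), function(q)
    fwhmSize(image, c(detections$row[q], detections$col[q]), max_radius_px))
  detections$area_px2 <- vapply(out, `[[`, 0, "area_px2")
  detections$diameter_nm <- vapply(out, `[[`, 0, "diameter_nm")
  detections$border <- vapply(out, `[[`, TRUE, "border")
  detections
}

#' Define active zones from Bruchpilot spots
#'
#' Groups BRP spots by single-linkage clustering at `linkage_nm`; groups
#' with at least `min_spots` members whose radial spread around the group
#' centroid stays below `max_residual_nm` qualify as rings. Each ring
#' yields a filled circular active-zone mask of radius (mean
#' spot-to-centroid distance + `pad_nm`), the 25-nm padding covering the
#' ring structure inside and outside. Spots in no accepted ring contribute
#' no active zone.
#'
#' @param brp_centers data.frame from [detectMaxima()] on the BRP channel.
#' @param image a [StedImage-class] fixing the pixel grid for the masks.
#' @param pad_nm ring padding (default 25).
#' @param linkage_nm single-linkage grouping distance (default 150).
#' @param min_spots minimum ring membership (default 4).
#' @param max_residual_nm maximal radial RMS deviation from the mean ring
#'   radius (default 30).
#' @return An [ActiveZoneSet-class].
#' @export
defineActiveZones <- function(brp_centers, image, pad_nm = 25,
                              linkage_nm = 150, min_spots = 4,
                              max_residual_nm = 30) {
  stopifnot(nrow(brp_centers) >= 1)
  ps <- image@pixel_size
  xy <- cbind(brp_centers$x_nm, brp_centers$y_nm)
  groups <- if (nrow(xy) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(xy), method = "single"),
                  h = linkage_nm)
  rings <- list(); members <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < min_spots) next
    cen <- colMeans(xy[idx, , drop = FALSE])
    rad <- sqrt((xy[idx, 1] - cen[1])^2 + (xy[idx, 2] - cen[2])^2)
    resid <- sqrt(mean((rad - mean(rad))^2))
    if (resid >= max_residual_nm) next
    rings[[length(rings) + 1]] <-
      data.frame(cx_px = cen[1] / ps, cy_px = cen[2] / ps,
                 ring_radius_nm = mean(rad),
                 mask_radius_nm = mean(rad) + pad_nm,
                 n_spots = length(idx), fit_residual_nm = resid)
    members[[length(members) + 1]] <- idx
  }
  nr <- nrow(image@intensity); nc <- ncol(image@intensity)
  zone <- matrix(0L, nr, nc)
  if (length(rings)) {
    rings <- do.call(rbind, rings)
    rings <- cbind(az = seq_len(nrow(rings)), rings)
    # pixel-center coordinates in nm: x along columns, y along rows
    colx <- (seq_len(nc) - 1) * ps
    rowy <- (seq_len(nr) - 1) * ps
    for (k in seq_len(nrow(rings))) {
      d2 <- outer(rowy - rings$cy_px[k] * ps, colx - rings$cx_px[k] * ps,
                  function(a, b) a^2 + b^2)
      zone[d2 <= rings$mask_radius_nm[k]^2] <- k
    }
  } else {
    rings <- data.frame(az = integer(), cx_px = numeric(),
                        cy_px = numeric(), ring_radius_nm = numeric(),
                        mask_radius_nm = numeric(), n_spots = integer(),
                        fit_residual_nm = numeric())
  }
  new("ActiveZoneSet", rings = rings, members = members, zone_px = zone,
      pad_nm = pad_nm, pixel_size = ps)
}

#' Classify syntaxin clusters relative to active zones and summarize
#'
#' A cluster is `at_AZ` iff its center lies inside (or exactly on the edge
#' of, closed region) any active-zone mask. The distance of each cluster
#' to the active-zone scaffold is the minimum center-to-center distance to
#' any ring-member BRP spot. Densities are clusters per \eqn{\mu m^2}:
#' at-AZ counts over the summed AZ mask area, outside counts over
#' (membrane area - AZ area); without a membrane mask the outside density
#' is omitted with a warning. Sizes are additionally binned into 8
#' distance ranges of 50 nm (last bin open-ended).
#'
#' @param syx_detections data.frame from [fwhmSizes()] on the syntaxin
#'   channel.
#' @param az_set an [ActiveZoneSet-class].
#' @param brp_centers data.frame of BRP detections (ring members are taken
#'   from `az_set`).
#' @param membrane_mask optional logical matrix; defaults to the mask
#'   stored in `image` if given.
#' @param image optional [StedImage-class] supplying the membrane mask.
#' @return list with `detections` (input plus `at_AZ`, `dist_brp_nm`,
#'   `dist_bin`) and `summary` (counts, mean diameters and densities per
#'   group).
#' @export
classifyAndMeasure <- function(syx_detections, az_set, brp_centers,
                               membrane_mask = NULL, image = NULL) {
  stopifnot(is(az_set, "ActiveZoneSet"))
  ps <- az_set@pixel_size
  det <- syx_detections
  n <- nrow(det)
  if (is.null(membrane_mask) && !is.null(image) && length(image@mask) > 0)
    membrane_mask <- image@mask
  if (n == 0) {
    det$at_AZ <- logical(0); det$dist_brp_nm <- numeric(0)
    det$dist_bin <- factor(character(0))
    return(list(detections = det,
                summary = list(n_az = 0, n_outside = 0,
                               mean_diameter_az = NA, mean_diameter_out = NA,
                               density_az_um2 = 0, density_out_um2 = 0)))
  }
  det$at_AZ <- az_set@zone_px[cbind(det$row + 1, det$col + 1)] > 0
  ring_members <- unlist(az_set@members)
  if (length(ring_members)) {
    bx <- brp_centers$x_nm[ring_members]
    by <- brp_centers$y_nm[ring_members]
    det$dist_brp_nm <- vapply(seq_len(n), function(q)
      min(sqrt((bx - det$x_nm[q])^2 + (by - det$y_nm[q])^2)), 0)
  } else det$dist_brp_nm <- NA_real_
  breaks <- c(seq(0, 350, by = 50), Inf)
  det$dist_bin <- cut(det$dist_brp_nm, breaks = breaks, right = FALSE)

  px_um2 <- (ps / 1000)^2
  az_area_um2 <- sum(az_set@zone_px > 0) * px_um2
  density_az <- if (az_area_um2 > 0) sum(det$at_AZ) / az_area_um2 else 0
  if (is.null(membrane_mask)) {
    warning("no membrane mask supplied; outside density omitted")
    density_out <- NA_real_
  } else {
    out_area_um2 <- sum(membrane_mask & az_set@zone_px == 0) * px_um2
    density_out <- if (out_area_um2 > 0) sum(!det$at_AZ) / out_area_um2 else 0
  }
  ok <- !is.na(det$diameter_nm)
  list(detections = det,
       summary = list(
         n_az = sum(det$at_AZ), n_outside = sum(!det$at_AZ),
         mean_diameter_az = mean(det$diameter_nm[ok & det$at_AZ]),
         mean_diameter_out = mean(det$diameter_nm[ok & !det$at_AZ]),
         density_az_um2 = density_az, density_out_um2 = density_out))
}

#' Two-sample comparison of cluster sizes
#'
#' Two-sample t-test on the group means with the conventional significance
#' stars (* P<0.05, ** P<0.01, *** P<0.001). Degenerate inputs (zero
#' variance in both groups) are reported as non-significant with a
#' warning.
#'
#' @param sizes_a,sizes_b numeric vectors (>= 2 observations each).
#' @return list with `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
compareGroups <- function(sizes_a, sizes_b) {
  stopifnot(length(sizes_a) >= 2, length(sizes_b) >= 2)
  if (sd(sizes_a) == 0 && sd(sizes_b) == 0) {
    warning("zero variance in both groups; reporting non-significance")
    p <- 1
  } else {
    p <- t.test(sizes_a, sizes_b)$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(p_value = p, stars = stars, mean_a = mean(sizes_a),
       mean_b = mean(sizes_b))
}
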