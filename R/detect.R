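#' Detection parameters for microcolony quantification
#'
#' Parameters of the quantification pipeline: background subtraction,
#' intensity equalization, elliptic region-of-interest masking and automatic
#' segmentation of bright objects above an area cutoff.
#'
#' @param min_area_um2 area cutoff in um^2; objects must be strictly larger
#'   to be reported (default 4).
#' @param roi_ellipse_fraction fraction of the field spanned by the analysis
#'   ellipse (semi-axes = fraction x half-width/half-height); default 0.9,
#'   covering the brightly illuminated central area while excluding the
#'   poorly illuminated corners.
#' @param background_radius_um structuring-element radius of the
#'   morphological background estimate; must comfortably exceed the largest
#'   expected colony radius (default 25).
#' @param equalization `"stretch"` (percentile-clipped linear contrast
#'   stretch) or `"none"`.
#' @param threshold_method `"triangle"` (default; robust when bright objects
#'   occupy a tiny fraction of the frame) or `"otsu"`.
#' @param noise_floor_k lower bound on the segmentation threshold, expressed
#'   as robust standard deviations (MAD) above the median of the masked
#'   pixels: a bright object must stand out from the background noise. Keeps
#'   fields without any true signal from being segmented at a mid-noise
#'   threshold. Set to 0 to disable.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_area_um2 = 4,
                             roi_ellipse_fraction = 0.9,
                             background_radius_um = 25,
                             equalization = c("stretch", "none"),
                             threshold_method = c("triangle", "otsu"),
                             noise_floor_k = 6) {
  equalization <- match.arg(equalization)
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_area_um2 > 0, noise_floor_k >= 0)
  if (roi_ellipse_fraction <= 0 || roi_ellipse_fraction > 1)
    stop("roi_ellipse_fraction must lie in (0, 1]")
  stopifnot(background_radius_um > 0)
  structure(list(min_area_um2 = min_area_um2,
                 roi_ellipse_fraction = roi_ellipse_fraction,
                 background_radius_um = background_radius_um,
                 equalization = equalization,
                 threshold_method = threshold_method,
                 noise_floor_k = noise_floor_k),
            class = "detection_params")
}

#' Subtract the image background
#'
#' Estimates the background as the grayscale morphological opening of the
#' image with a disc structuring element whose radius is much larger than a
#' microcolony, then subtracts it. Bright objects smaller than the disc are
#' preserved by construction; smooth large-scale trends (illumination,
#' haze) are removed. The result is non-negative (opening never exceeds the
#' image).
#'
#' @param image 2-D intensity matrix.
#' @param params a [detection_params()].
#' @param pixel_scale_um micrometres per pixel.
#' @return Background-subtracted matrix, same dimensions, all values >= 0.
#' @export
subtract_background <- function(image, params = detection_params(),
                                pixel_scale_um = 1) {
  r_px <- params$background_radius_um / pixel_scale_um
  if (r_px <= 2)
    stop("background radius is <= 2 pixels at this pixel scale; degenerate filter")
  size <- 2L * as.integer(round(r_px)) + 1L
  bg <- EBImage::opening(image, EBImage::makeBrush(size, shape = "disc"))
  out <- image - as.matrix(bg)
  out[out < 0] <- 0
  out
}

#' Best-fit intensity equalization (linear contrast stretch)
#'
#' Linearly maps the intensity window between the `probs` quantiles to
#' [0, 1], clipping outside it. The default is a pure min-max stretch
#' (`probs = c(0, 1)`): it preserves pixel rank order exactly, is
#' idempotent, and keeps rare bright microcolonies as intensity outliers,
#' which the automatic segmentation threshold relies on. Percentile clipping
#' (e.g. `probs = c(0.001, 0.999)`) is available for images with hot pixels,
#' at the cost of clipping sparse signal into the noise range. A constant
#' image cannot be stretched and is returned unchanged with attribute
#' `equalize_warning = TRUE` plus a warning.
#'
#' @param image 2-D intensity matrix.
#' @param probs lower/upper stretch quantiles.
#' @return Equalized matrix with values in [0, 1].
#' @export
equalize <- function(image, probs = c(0, 1)) {
  q <- stats::quantile(image, probs, names = FALSE)
  if (q[2] <= q[1]) {
    warning("image intensity is constant; equalization skipped")
    attr(image, "equalize_warning") <- TRUE
    return(image)
  }
  out <- (image - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Central elliptic region-of-interest mask
#'
#' True exactly inside the axis-aligned ellipse centred in the image with
#' semi-axes `fraction` times the half-width and half-height. Pixel
#' membership is decided at the pixel centre.
#'
#' @param image_dim integer vector (nx, ny) or a matrix whose `dim` is used.
#' @param roi_ellipse_fraction fraction in (0, 1].
#' @return Logical matrix of dimensions (nx, ny).
#' @export
central_ellipse_mask <- function(image_dim, roi_ellipse_fraction = 0.9) {
  if (is.matrix(image_dim)) image_dim <- dim(image_dim)
  stopifnot(length(image_dim) == 2)
  if (roi_ellipse_fraction <= 0 || roi_ellipse_fraction > 1)
    stop("roi_ellipse_fraction must lie in (0, 1]")
  nx <- image_dim[1]; ny <- image_dim[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  a <- roi_ellipse_fraction * nx / 2
  b <- roi_ellipse_fraction * ny / 2
  outer(((seq_len(nx) - cx) / a)^2, ((seq_len(ny) - cy) / b)^2, `+`) <= 1
}

#' Triangle threshold of an intensity sample
#'
#' Geometric threshold on a 256-bin histogram: the threshold is the bin
#' farthest below the line joining the histogram peak to the far end of its
#' longest tail. Suited to images where bright objects occupy a small
#' fraction of pixels and the histogram is a single background peak with a
#' bright tail.
#'
#' @param values numeric vector of intensities.
#' @param n_bins histogram bins.
#' @return Threshold on the intensity scale.
#' @export
threshold_triangle <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(as.integer((values - rng[1]) / diff(rng) * n_bins) +
                            1L, 1L), n_bins), n_bins)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # mirror so the long tail is to the right of the peak; bright-object
  # histograms (background peak, high tail) are left as-is on ties
  flipped <- (peak - lo) > (hi - peak)
  if (flipped) {
    h <- rev(h)
    peak <- n_bins - peak + 1L
    hi <- n_bins - lo + 1L
  }
  if (hi <= peak || h[peak] == h[hi]) return(rng[2])
  bins <- peak:hi
  # distance of each histogram point below the peak-to-tail-end chord
  dx <- (bins - peak) / (hi - peak)
  dy <- (h[bins] - h[peak]) / (h[peak] - h[hi])  # note: decreasing 0 -> -1
  dist <- -dy - dx  # proportional to distance below the chord
  split <- bins[which.max(dist)]
  if (flipped) split <- n_bins - split + 1L
  rng[1] + (split - 0.5) / n_bins * diff(rng)
}

choose_threshold <- function(values, method) {
  if (diff(range(values)) == 0) return(Inf)  # featureless: nothing is bright
  switch(method,
         triangle = threshold_triangle(values),
         otsu = {
           v <- values
           rng <- range(v)
           v01 <- (v - rng[1]) / diff(rng)
           rng[1] + EBImage::otsu(matrix(v01, nrow = 1), range = c(0, 1)) *
             diff(rng)
         },
         stop("unknown threshold method: ", method))
}

#' Segment bright objects above an area cutoff
#'
#' Thresholds the image (threshold chosen automatically from the pixels
#' inside the mask), labels 8-connected components on the full frame, and
#' reports components whose area (pixel count x pixel_scale^2) is strictly
#' greater than `min_area_um2` and whose centroid lies inside the mask.
#' Objects are sorted by centroid (y, then x) for reproducibility.
#'
#' @param image background-subtracted, equalized 2-D intensity matrix.
#' @param mask logical region-of-interest matrix, same dimensions.
#' @param pixel_scale_um micrometres per pixel.
#' @param min_area_um2 area cutoff (strictly greater).
#' @param threshold_method `"triangle"` or `"otsu"`.
#' @param noise_floor_k see [detection_params()].
#' @return data.frame with columns `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity` (one row per reported object).
#' @export
segment_bright_objects <- function(image, mask, pixel_scale_um = 1,
                                   min_area_um2 = 4,
                                   threshold_method = "triangle",
                                   noise_floor_k = 6) {
  stopifnot(all(dim(image) == dim(mask)))
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  if (!any(mask)) return(empty)
  roi_px <- image[mask]
  thr <- choose_threshold(roi_px, threshold_method)
  if (noise_floor_k > 0) {
    floor_thr <- stats::median(roi_px) +
      noise_floor_k * stats::mad(roi_px)
    thr <- max(thr, floor_thr)
  }
  binary <- image > thr
  if (!any(binary)) return(empty)
  labels <- EBImage::bwlabel(EBImage::Image(binary * 1))
  lab <- as.matrix(EBImage::imageData(labels))
  n_obj <- max(lab)
  if (n_obj == 0) return(empty)
  idx <- which(lab > 0)
  l <- lab[idx]
  area_px <- tabulate(l, n_obj)
  xi <- ((idx - 1) %% nrow(image)) + 1
  yi <- ((idx - 1) %/% nrow(image)) + 1
  cx <- rowsum(xi, l)[, 1] / area_px
  cy <- rowsum(yi, l)[, 1] / area_px
  mi <- rowsum(image[idx], l)[, 1] / area_px
  area_um2 <- area_px * pixel_scale_um^2
  # centroid-in-mask rule for ROI membership
  in_roi <- mask[cbind(pmin(pmax(round(cx), 1), nrow(mask)),
                       pmin(pmax(round(cy), 1), ncol(mask)))]
  keep <- which(area_um2 > min_area_um2 & in_roi)
  keep <- keep[order(cy[keep], cx[keep])]
  data.frame(x_um = (cx[keep] - 0.5) * pixel_scale_um,
             y_um = (cy[keep] - 0.5) * pixel_scale_um,
             area_um2 = area_um2[keep],
             mean_intensity = mi[keep])
}

#' Count fluorescent microcolonies in one field
#'
#' Runs the full quantification chain per channel: background subtraction,
#' intensity equalization, central elliptic ROI masking and automatic
#' segmentation of bright objects strictly larger than the area cutoff.
#'
#' @param field a `field_image`.
#' @param params a [detection_params()].
#' @return List with `red_count`, `green_count` and `objects` (data.frame
#'   with `field_id`, `channel`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity`).
#' @export
count_field <- function(field, params = detection_params()) {
  stopifnot(inherits(field, "field_image"),
            all(dim(field$red) == dim(field$green)),
            field$pixel_scale_um > 0)
  mask <- central_ellipse_mask(dim(field$red), params$roi_ellipse_fraction)
  per_channel <- lapply(c(red = "red", green = "green"), function(ch) {
    img <- subtract_background(field[[ch]], params, field$pixel_scale_um)
    if (params$equalization == "stretch")
      img <- suppressWarnings(equalize(img))
    segment_bright_objects(img, mask, field$pixel_scale_um,
                           params$min_area_um2, params$threshold_method,
                           params$noise_floor_k)
  })
  objects <- do.call(rbind, lapply(names(per_channel), function(ch) {
    df <- per_channel[[ch]]
    if (!nrow(df)) return(NULL)
    cbind(field_id = field$field_id, channel = ch, df)
  }))
  if (is.null(objects))
    objects <- data.frame(field_id = character(0), channel = character(0),
                          x_um = numeric(0), y_um = numeric(0),
                          area_um2 = numeric(0), mean_intensity = numeric(0))
  rownames(objects) <- NULL
  list(red_count = nrow(per_channel$red),
       green_count = nrow(per_channel$green),
       objects = objects)
}

#' Quantify a set of fields
#'
#' Applies [count_field()] to each field and returns per-field counts plus
#' the combined object table.
#'
#' @param fields list of `field_image` objects.
#' @param params a [detection_params()].
#' @return List with `counts` (data.frame: field_id, red_count, green_count)
#'   and `objects`.
#' @export
quantify_fields <- function(fields, params = detection_params()) {
  res <- lapply(fields, count_field, params = params)
  counts <- data.frame(
    field_id = vapply(fields, `[[`, character(1), "field_id"),
    red_count = vapply(res, `[[`, numeric(1), "red_count"),
    green_count = vapply(res, `[[`, numeric(1), "green_count"))
  objects <- do.call(rbind, lapply(res, `[[`, "objects"))
  rownames(objects) <- NULL
  list(counts = counts, objects = objects)
}

#' Manual correction ledger for enumeration errors
#'
#' Records signed count corrections noted during manual control of the
#' automated enumeration.
#'
#' @param field_id character vector of field identifiers.
#' @param channel `"red"` or `"green"` per entry.
#' @param delta_count signed integer corrections.
#' @param note free-text justification per entry.
#' @return data.frame of class `correction_ledger`.
#' @export
correction_ledger <- function(field_id = character(0),
                              channel = character(0),
                              delta_count = integer(0),
                              note = character(0)) {
  stopifnot(length(field_id) == length(channel),
            length(field_id) == length(delta_count))
  if (!all(channel %in% c("red", "green")))
    stop("channel must be 'red' or 'green'")
  if (length(note) == 0) note <- rep("", length(field_id))
  structure(data.frame(field_id = field_id, channel = channel,
                       delta_count = as.integer(delta_count), note = note),
            class = c("correction_ledger", "data.frame"))
}

#' Apply manual corrections to per-field counts
#'
#' Adjusts the automated per-field counts by the ledger's signed deltas. A
#' correction that would drive a count below zero, or that references an
#' unknown field, is an error. The applied corrections are reported as an
#' audit trail attribute and via `message()`.
#'
#' @param counts data.frame with `field_id`, `red_count`, `green_count`.
#' @param ledger a [correction_ledger()].
#' @return Corrected counts data.frame with attribute `audit_trail`.
#' @export
apply_corrections <- function(counts, ledger) {
  stopifnot(is.data.frame(counts),
            all(c("field_id", "red_count", "green_count") %in% names(counts)))
  if (nrow(ledger) == 0) return(counts)
  audit <- character(0)
  for (k in seq_len(nrow(ledger))) {
    i <- match(ledger$field_id[k], counts$field_id)
    if (is.na(i))
      stop("correction references unknown field: ", ledger$field_id[k])
    col <- paste0(ledger$channel[k], "_count")
    new <- counts[[col]][i] + ledger$delta_count[k]
    if (new < 0)
      stop(sprintf("correction for %s/%s drives count below zero (%d %+d)",
                   ledger$field_id[k], ledger$channel[k],
                   counts[[col]][i], ledger$delta_count[k]))
    audit <- c(audit, sprintf("%s %s: %d -> %d (%s)", ledger$field_id[k],
                              ledger$channel[k], counts[[col]][i], new,
                              ledger$note[k]))
    counts[[col]][i] <- new
  }
  message("applied ", length(audit), " count correction(s)")
  attr(counts, "audit_trail") <- audit
  counts
}

#' Match detected objects to ground truth
#'
#' Greedy one-to-one matching by centroid distance: detection-truth pairs
#' are accepted in order of increasing distance while the distance is below
#' `truth radius + tol_um`. Used to score the detection pipeline on
#' synthetic experiments.
#'
#' @param truth per-colony ground-truth table (one channel) with `field_id`,
#'   `x_um`, `y_um`, `radius_um`, `area_um2`.
#' @param detections detected-object table (same channel) with `field_id`,
#'   `x_um`, `y_um`.
#' @param tol_um matching slack added to the truth radius.
#' @return List with `truth` (input plus logical `matched`) and `detections`
#'   (input plus `matched_area_um2`, `NA` where unmatched).
#' @export
match_detections <- function(truth, detections, tol_um = 3) {
  truth$matched <- rep(FALSE, nrow(truth))
  detections$matched_area_um2 <- rep(NA_real_, nrow(detections))
  for (fid in unique(detections$field_id)) {
    ti <- which(truth$field_id == fid)
    di <- which(detections$field_id == fid)
    if (!length(ti) || !length(di)) next
    d <- outer(detections$x_um[di], truth$x_um[ti], `-`)^2 +
         outer(detections$y_um[di], truth$y_um[ti], `-`)^2
    d <- sqrt(d)
    lim <- matrix(truth$radius_um[ti] + tol_um, nrow = length(di),
                  ncol = length(ti), byrow = TRUE)
    cand <- which(d <= lim, arr.ind = TRUE)
    if (!length(cand)) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_d <- logical(length(di)); used_t <- logical(length(ti))
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; b <- cand[r, 2]
      if (used_d[a] || used_t[b]) next
      used_d[a] <- TRUE; used_t[b] <- TRUE
      truth$matched[ti[b]] <- TRUE
      detections$matched_area_um2[di[a]] <- truth$area_um2[ti[b]]
    }
  }
  list(truth = truth, detections = detections)
}

#' Score green-channel detection against synthetic ground truth
#'
#' Recall is computed over true transconjugant colonies whose centre lies
#' inside the analysis ellipse and whose true area is at least
#' `recall_min_area_um2`; precision over all reported green objects (a
#' detection matching any true colony, inside or outside the ellipse, is a
#' true positive). Also reports how many detections were attributed to true
#' colonies of area at most `never_area_um2`, which the pipeline must not
#' report.
#'
#' @param experiment a `filter_experiment`.
#' @param objects detected object table from [quantify_fields()].
#' @param params the [detection_params()] used.
#' @param recall_min_area_um2 lower true-area bound for the recall set.
#' @param never_area_um2 upper true-area bound for the must-not-report set.
#' @return List with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `n_small_reported`.
#' @export
evaluate_detection <- function(experiment, objects, params,
                               recall_min_area_um2 = 6,
                               never_area_um2 = 2) {
  truth <- experiment$truth[experiment$truth$channel == "green", ]
  det <- objects[objects$channel == "green", ]
  W <- experiment$geometry$field_width_um
  H <- experiment$geometry$field_height_um
  fr <- params$roi_ellipse_fraction
  in_roi <- ((truth$x_um - W / 2) / (fr * W / 2))^2 +
            ((truth$y_um - H / 2) / (fr * H / 2))^2 <= 1
  m <- match_detections(truth, det)
  recall_set <- in_roi & truth$area_um2 >= recall_min_area_um2
  recall <- if (any(recall_set)) mean(m$truth$matched[recall_set]) else NA_real_
  precision <- if (nrow(det)) mean(!is.na(m$detections$matched_area_um2))
               else NA_real_
  n_small <- sum(!is.na(m$detections$matched_area_um2) &
                 m$detections$matched_area_um2 <= never_area_um2)
  list(recall = recall, precision = precision,
       n_truth = sum(recall_set), n_detected = nrow(det),
       n_small_reported = n_small)
}
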