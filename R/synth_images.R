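#' Ground-truth description of one synthetic microscope field
#'
#' Defines everything needed to render a two-channel (red = donor mCherry,
#' green = transconjugant GFP) stereomicroscope field deterministically:
#' colony positions, sizes and peak intensities per channel, the elliptic
#' illumination profile (bright centre, dark corners), background level,
#' additive noise and the pixel scale.
#'
#' Colonies are given as data.frames with columns `x_um`, `y_um`, `radius_um`
#' and `peak` (peak intensity, arbitrary units). Intensities are on an
#' arbitrary scale where a typical microcolony peak is 1.
#'
#' @param donors,transconjugants colony data.frames (possibly 0-row) for the
#'   red and green channel respectively.
#' @param field_width_um,field_height_um field dimensions in micrometres.
#' @param pixel_scale_um micrometres per pixel (> 0).
#' @param noise_sd standard deviation of additive Gaussian noise, intensity
#'   units.
#' @param shot_noise if `TRUE`, Poisson shot noise is applied to the clean
#'   signal before the additive noise.
#' @param background_level uniform background intensity, modulated by the
#'   illumination profile.
#' @param illumination list with elements `center` (fractions of field),
#'   `semi_axes` (fractions of field; the profile is zero outside this
#'   ellipse, which leaves the corners dark), `flat_fraction` (elliptic
#'   radius up to which illumination is flat at 1) and `falloff_power`
#'   (cosine-power exponent of the falloff between `flat_fraction` and 1).
#' @param blob_profile `"disk"` (antialiased hard disk; thresholded area is
#'   close to pi r^2 for any mid-range threshold) or `"gaussian"` (full width
#'   at half maximum equal to the colony diameter).
#' @param edge_width_px width in pixels of the disk profile's intensity edge.
#' @param seed integer seed; identical truth objects render bit-identical
#'   images.
#' @return An object of class `imaging_truth`.
#' @export
imaging_truth <- function(donors = empty_colonies(),
                          transconjugants = empty_colonies(),
                          field_width_um = 980,
                          field_height_um = 732,
                          pixel_scale_um = 1,
                          noise_sd = 0.05,
                          shot_noise = FALSE,
                          background_level = 0.1,
                          illumination = list(center = c(0.5, 0.5),
                                              semi_axes = c(0.5, 0.5),
                                              flat_fraction = 0.9,
                                              falloff_power = 2),
                          blob_profile = c("disk", "gaussian"),
                          edge_width_px = 0.5,
                          seed = 1L) {
  blob_profile <- match.arg(blob_profile)
  stopifnot(pixel_scale_um > 0, field_width_um > 0, field_height_um > 0,
            noise_sd >= 0, background_level >= 0, edge_width_px > 0)
  donors <- as_colonies(donors)
  transconjugants <- as_colonies(transconjugants)
  truth <- structure(list(
    donors = donors,
    transconjugants = transconjugants,
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    pixel_scale_um = pixel_scale_um,
    noise_sd = noise_sd,
    shot_noise = shot_noise,
    background_level = background_level,
    illumination = illumination,
    blob_profile = blob_profile,
    edge_width_px = edge_width_px,
    seed = as.integer(seed)
  ), class = "imaging_truth")
  check_colony_bounds(truth)
  truth
}

#' @rdname imaging_truth
#' @export
empty_colonies <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
             peak = numeric(0))
}

as_colonies <- function(df) {
  df <- as.data.frame(df)
  needed <- c("x_um", "y_um", "radius_um")
  if (!all(needed %in% names(df)))
    stop("colony table needs columns x_um, y_um, radius_um")
  if (is.null(df$peak)) df$peak <- rep(1, nrow(df))
  if (nrow(df) && any(df$radius_um <= 0))
    stop("colony radii must be positive")
  df[, c("x_um", "y_um", "radius_um", "peak")]
}

check_colony_bounds <- function(truth) {
  for (ch in c("donors", "transconjugants")) {
    df <- truth[[ch]]
    if (!nrow(df)) next
    bad <- which(df$x_um < 0 | df$x_um > truth$field_width_um |
                 df$y_um < 0 | df$y_um > truth$field_height_um)
    if (length(bad))
      stop(sprintf("%s colony %d lies outside the field bounds", ch, bad[1]))
  }
  invisible(TRUE)
}

#' Elliptic illumination profile of a field
#'
#' Flat at 1 inside `flat_fraction` of the illumination ellipse, cosine-power
#' falloff to 0 at the ellipse edge, 0 beyond (dark corners).
#'
#' @param truth an [imaging_truth()] object.
#' @return Matrix of illumination factors, dimensions (nx, ny) in pixels.
#' @export
illumination_profile <- function(truth) {
  nx <- round(truth$field_width_um / truth$pixel_scale_um)
  ny <- round(truth$field_height_um / truth$pixel_scale_um)
  il <- truth$illumination
  x <- ((seq_len(nx) - 0.5) * truth$pixel_scale_um) / truth$field_width_um
  y <- ((seq_len(ny) - 0.5) * truth$pixel_scale_um) / truth$field_height_um
  rho2 <- outer(((x - il$center[1]) / il$semi_axes[1])^2,
                ((y - il$center[2]) / il$semi_axes[2])^2, `+`)
  rho <- sqrt(rho2)
  flat <- il$flat_fraction
  prof <- matrix(0, nx, ny)
  prof[rho <= flat] <- 1
  ramp <- rho > flat & rho < 1
  prof[ramp] <- cos(pi / 2 * (rho[ramp] - flat) / (1 - flat))^il$falloff_power
  prof
}

render_colonies <- function(colonies, nx, ny, scale, profile, edge_width_px) {
  img <- matrix(0, nx, ny)
  if (!nrow(colonies)) return(img)
  for (k in seq_len(nrow(colonies))) {
    cx <- colonies$x_um[k] / scale + 0.5  # pixel-index coordinates
    cy <- colonies$y_um[k] / scale + 0.5
    r <- colonies$radius_um[k] / scale
    pk <- colonies$peak[k]
    if (profile == "gaussian") {
      s <- r / sqrt(2 * log(2))
      ext <- 4 * s
    } else {
      ext <- r + 2 * edge_width_px
    }
    i0 <- max(1L, floor(cx - ext)); i1 <- min(nx, ceiling(cx + ext))
    j0 <- max(1L, floor(cy - ext)); j1 <- min(ny, ceiling(cy + ext))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d <- sqrt(outer((ii - cx)^2, (jj - cy)^2, `+`))
    if (profile == "gaussian") {
      v <- pk * exp(-d^2 / (2 * s^2))
      v[d > ext] <- 0
    } else {
      v <- pk * pmin(1, pmax(0, 0.5 + (r - d) / edge_width_px))
    }
    img[ii, jj] <- img[ii, jj] + v
  }
  img
}

#' Render one synthetic two-channel field image
#'
#' Each channel is (background + colony blobs) times the elliptic
#' illumination profile, plus optional Poisson shot noise and additive
#' Gaussian noise, clipped at zero. Rendering is deterministic given
#' `truth$seed`.
#'
#' @param truth an [imaging_truth()] object.
#' @param field_id identifier attached to the rendered field.
#' @return A list with elements `field` (a `field_image`: `red` and `green`
#'   intensity matrices, `pixel_scale_um`, `field_id`) and `truth` (the input,
#'   unchanged).
#' @examples
#' tr <- imaging_truth(transconjugants = data.frame(x_um = 50, y_um = 40,
#'                                                  radius_um = 2, peak = 1),
#'                     field_width_um = 100, field_height_um = 80,
#'                     noise_sd = 0)
#' f <- generate_field(tr)$field
#' dim(f$green)
#' @export
generate_field <- function(truth, field_id = "field_1") {
  stopifnot(inherits(truth, "imaging_truth"))
  check_colony_bounds(truth)
  scale <- truth$pixel_scale_um
  nx <- round(truth$field_width_um / scale)
  ny <- round(truth$field_height_um / scale)
  prof <- illumination_profile(truth)
  set.seed(truth$seed)
  channels <- lapply(list(red = truth$donors, green = truth$transconjugants),
                     function(col) {
    clean <- (truth$background_level +
              render_colonies(col, nx, ny, scale, truth$blob_profile,
                              truth$edge_width_px)) * prof
    if (truth$shot_noise) {
      # shot noise on an arbitrary-unit scale: treat intensity 1 ~ 400 photons
      photons <- 400
      clean <- matrix(stats::rpois(length(clean), clean * photons) / photons,
                      nx, ny)
    }
    if (truth$noise_sd > 0)
      clean <- clean + matrix(stats::rnorm(length(clean), 0, truth$noise_sd),
                              nx, ny)
    pmax(clean, 0)
  })
  field <- structure(list(red = channels$red, green = channels$green,
                          pixel_scale_um = scale, field_id = field_id),
                     class = "field_image")
  list(field = field, truth = truth)
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image '%s': %d x %d px at %g um/px (red + green)\n",
              x$field_id, nrow(x$red), ncol(x$red), x$pixel_scale_um))
  invisible(x)
}

#' Place transconjugant colonies in direct proximity to donor colonies
#'
#' Each transconjugant centre is a uniform draw within `max_offset_um` of a
#' randomly sampled donor centre, clipped to the field bounds. Uses the
#' current RNG stream; seed beforehand for reproducibility.
#'
#' @param n number of transconjugants to place.
#' @param donors donor colony data.frame (must be non-empty when `n > 0`).
#' @param max_offset_um maximum distance to the parent donor centre.
#' @param field_width_um,field_height_um field bounds for clipping.
#' @param radius_um radii for the new colonies, recycled to length `n`.
#' @param peak peak intensities, recycled to length `n`.
#' @return Colony data.frame with `n` rows.
#' @export
place_transconjugants_near_donors <- function(n, donors, max_offset_um,
                                              field_width_um, field_height_um,
                                              radius_um = 1.5, peak = 1) {
  stopifnot(n >= 0, max_offset_um >= 0)
  if (n == 0) return(empty_colonies())
  donors <- as_colonies(donors)
  if (!nrow(donors))
    stop("cannot place transconjugants near donors: donor list is empty")
  idx <- sample.int(nrow(donors), n, replace = TRUE)
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- max_offset_um * sqrt(stats::runif(n))
  x <- pmin(pmax(donors$x_um[idx] + rad * cos(ang), 0), field_width_um)
  y <- pmin(pmax(donors$y_um[idx] + rad * sin(ang), 0), field_height_um)
  data.frame(x_um = x, y_um = y,
             radius_um = rep_len(radius_um, n), peak = rep_len(peak, n))
}

#' Random donor microcolony layout for one field
#'
#' Donors are scattered uniformly over the field with radii and peak
#' intensities drawn uniformly from the given ranges.
#'
#' @param n_donors number of donor microcolonies.
#' @param field_width_um,field_height_um field dimensions.
#' @param radius_range_um radius range (uniform draw).
#' @param peak_range peak intensity range (uniform draw).
#' @return Colony data.frame.
#' @export
random_donor_layout <- function(n_donors, field_width_um, field_height_um,
                                radius_range_um = c(4, 10),
                                peak_range = c(0.9, 1.1)) {
  stopifnot(n_donors >= 0)
  if (n_donors == 0) return(empty_colonies())
  data.frame(
    x_um = stats::runif(n_donors, 0, field_width_um),
    y_um = stats::runif(n_donors, 0, field_height_um),
    radius_um = stats::runif(n_donors, radius_range_um[1], radius_range_um[2]),
    peak = stats::runif(n_donors, peak_range[1], peak_range[2])
  )
}

#' Default imaging parameters for synthetic filter experiments
#'
#' The free knobs of the image model: microcolony peak intensity near 1 with
#' 10% spread, 5% additive noise, 10% uniform background, 200 donor
#' microcolonies of 4-10 um radius per field, transconjugant microcolony
#' areas spanning 1-20 um^2 (straddling the 4 um^2 detection cutoff), and
#' transconjugants placed within 20 um of a donor.
#'
#' @param noise_sd,background_level,pixel_scale_um,blob_profile,edge_width_px
#'   see [imaging_truth()].
#' @param donor_count donors per field.
#' @param donor_radius_range_um donor radius range.
#' @param tc_area_range_um2 transconjugant area range (uniform draw).
#' @param tc_max_offset_um maximum transconjugant-to-donor distance.
#' @param peak_range colony peak intensity range.
#' @param illumination see [imaging_truth()].
#' @return List of imaging defaults consumed by [generate_filter_experiment()].
#' @export
imaging_defaults <- function(noise_sd = 0.05,
                             background_level = 0.1,
                             pixel_scale_um = 1,
                             blob_profile = "disk",
                             edge_width_px = 0.5,
                             donor_count = 200,
                             donor_radius_range_um = c(4, 10),
                             tc_area_range_um2 = c(1, 20),
                             tc_max_offset_um = 20,
                             peak_range = c(0.9, 1.1),
                             illumination = list(center = c(0.5, 0.5),
                                                 semi_axes = c(0.5, 0.5),
                                                 flat_fraction = 0.9,
                                                 falloff_power = 2)) {
  list(noise_sd = noise_sd, background_level = background_level,
       pixel_scale_um = pixel_scale_um, blob_profile = blob_profile,
       edge_width_px = edge_width_px, donor_count = donor_count,
       donor_radius_range_um = donor_radius_range_um,
       tc_area_range_um2 = tc_area_range_um2,
       tc_max_offset_um = tc_max_offset_um, peak_range = peak_range,
       illumination = illumination)
}

#' Generate a full synthetic filter experiment (one scanning zone)
#'
#' Draws per-field transconjugant counts from a Poisson law with mean
#' `true_frequency * recipients_per_field(geometry) * detectable_fraction`,
#' scatters donor microcolonies, places transconjugants in proximity to
#' donors, and (optionally) renders every field. The exact ground truth is
#' recorded per colony and per field. Fully deterministic given `seed`.
#'
#' @param true_frequency true transfer frequency in T/R (0 <= f <= 1).
#' @param geometry an [experiment_geometry()].
#' @param imaging imaging parameter list from [imaging_defaults()].
#' @param seed integer seed.
#' @param render if `FALSE`, only counts and ground truth are generated
#'   (fast path for frequency-recovery studies).
#' @param detectable_fraction fraction of true transfer events that form a
#'   detectable microcolony (default 1).
#' @return An object of class `filter_experiment`: list with `fields` (list
#'   of `field_image` or `NULL`s), `truth` (per-colony table: field_id,
#'   channel, x_um, y_um, radius_um, area_um2, peak), `counts` (per-field
#'   table: field_id, n_donors, n_transconjugants), `total_true`,
#'   `true_frequency`, `geometry`, `imaging`, `seed`.
#' @export
generate_filter_experiment <- function(true_frequency, geometry,
                                       imaging = imaging_defaults(),
                                       seed = 1L, render = TRUE,
                                       detectable_fraction = 1) {
  if (is.na(true_frequency) || true_frequency < 0 || true_frequency > 1)
    stop("true_frequency must lie in [0, 1]")
  stopifnot(inherits(geometry, "experiment_geometry"))
  set.seed(as.integer(seed))
  n_fields <- geometry$n_fields
  W <- geometry$field_width_um
  H <- geometry$field_height_um
  lambda <- true_frequency * recipients_per_field(geometry) *
    detectable_fraction
  tc_counts <- stats::rpois(n_fields, lambda)
  field_seeds <- sample.int(2147483647L, n_fields)

  fields <- vector("list", n_fields)
  truth_rows <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    fid <- sprintf("field_%02d", f)
    donors <- random_donor_layout(imaging$donor_count, W, H,
                                  imaging$donor_radius_range_um,
                                  imaging$peak_range)
    n_tc <- tc_counts[f]
    areas <- if (n_tc > 0)
      stats::runif(n_tc, imaging$tc_area_range_um2[1],
                   imaging$tc_area_range_um2[2])
    else numeric(0)
    tcs <- place_transconjugants_near_donors(
      n_tc, donors, imaging$tc_max_offset_um, W, H,
      radius_um = sqrt(areas / pi),
      peak = stats::runif(max(n_tc, 1), imaging$peak_range[1],
                          imaging$peak_range[2])[seq_len(n_tc)])
    truth <- imaging_truth(donors = donors, transconjugants = tcs,
                           field_width_um = W, field_height_um = H,
                           pixel_scale_um = imaging$pixel_scale_um,
                           noise_sd = imaging$noise_sd,
                           background_level = imaging$background_level,
                           illumination = imaging$illumination,
                           blob_profile = imaging$blob_profile,
                           edge_width_px = imaging$edge_width_px,
                           seed = field_seeds[f])
    if (render) fields[[f]] <- generate_field(truth, field_id = fid)$field
    both <- rbind(
      if (nrow(donors)) cbind(channel = "red", donors) else NULL,
      if (nrow(tcs)) cbind(channel = "green", tcs) else NULL)
    if (!is.null(both) && nrow(both)) {
      both$field_id <- fid
      both$area_um2 <- pi * both$radius_um^2
      truth_rows[[f]] <- both[, c("field_id", "channel", "x_um", "y_um",
                                  "radius_um", "area_um2", "peak")]
    }
  }
  truth_tab <- do.call(rbind, truth_rows)
  if (is.null(truth_tab))
    truth_tab <- data.frame(field_id = character(0), channel = character(0),
                            x_um = numeric(0), y_um = numeric(0),
                            radius_um = numeric(0), area_um2 = numeric(0),
                            peak = numeric(0))
  rownames(truth_tab) <- NULL
  structure(list(
    fields = fields,
    truth = truth_tab,
    counts = data.frame(field_id = sprintf("field_%02d", seq_len(n_fields)),
                        n_donors = rep(imaging$donor_count, n_fields),
                        n_transconjugants = tc_counts),
    total_true = sum(tc_counts),
    true_frequency = true_frequency,
    geometry = geometry,
    imaging = imaging,
    seed = as.integer(seed)
  ), class = "filter_experiment")
}

#' @export
print.filter_experiment <- function(x, ...) {
  cat(sprintf(
    "filter_experiment: %d fields, true frequency %s T/R, %d true transconjugant microcolonies (seed %d)\n",
    x$geometry$n_fields, signif(x$true_frequency, 3), x$total_true, x$seed))
  invisible(x)
}

#' Write a field image as a two-page 16-bit TIFF
#'
#' Page 1 is the red (donor) channel, page 2 the green (transconjugant)
#' channel. Intensities are clipped to `[0, saturation]` and scaled to the
#' 16-bit range; [read_field_tiff()] reverses the scaling.
#'
#' @param field a `field_image`.
#' @param path output file path.
#' @param saturation intensity mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, saturation = 2) {
  stopifnot(inherits(field, "field_image"), saturation > 0)
  pages <- lapply(list(field$red, field$green),
                  function(m) t(pmin(pmax(m / saturation, 0), 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' @param path TIFF path (two pages: red, green).
#' @param pixel_scale_um micrometres per pixel of the stored image.
#' @param field_id identifier to attach.
#' @param saturation intensity scale used at write time.
#' @return A `field_image`.
#' @export
read_field_tiff <- function(path, pixel_scale_um = 1, field_id = NULL,
                            saturation = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2)
    stop("expected a two-page TIFF (red, green): ", path)
  if (is.null(field_id))
    field_id <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  structure(list(red = t(pages[[1]]) * saturation,
                 green = t(pages[[2]]) * saturation,
                 pixel_scale_um = pixel_scale_um, field_id = field_id),
            class = "field_image")
}

#' Write a filter experiment to disk (TIFFs + ground-truth TSV)
#'
#' @param experiment a `filter_experiment` with rendered fields.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the TIFF paths and the truth-table path.
#' @export
write_filter_experiment <- function(experiment, outdir) {
  stopifnot(inherits(experiment, "filter_experiment"))
  if (any(vapply(experiment$fields, is.null, logical(1))))
    stop("experiment was generated with render = FALSE; no images to write")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(experiment$fields, function(f) {
    p <- file.path(outdir, paste0(f$field_id, ".tiff"))
    write_field_tiff(f, p)
    p
  }, character(1))
  truth_path <- file.path(outdir, "ground_truth.tsv")
  utils::write.table(experiment$truth, truth_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  counts_path <- file.path(outdir, "true_counts.tsv")
  utils::write.table(experiment$counts, counts_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(tiffs = paths, truth = truth_path, counts = counts_path))
}
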