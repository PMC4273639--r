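#' Filter-mating experiment geometry
#'
#' Collects the constants that define the scaling from scanned-zone
#' microcolony counts to whole-filter transfer frequencies: the filter area,
#' the dimensions and number of microscope fields in the scanning zone, and
#' the initial cell load of the filter.
#'
#' Defaults describe the standard assay: a 270 mm^2 filter seeded at roughly
#' 30,000 bacteria per mm^2 at a 1:1 donor:recipient ratio, scanned as a
#' 7 x 7 grid of 980 x 732 um fields (about 13% of the filter).
#'
#' @param filter_area_mm2 total filter area in mm^2.
#' @param field_width_um,field_height_um dimensions of one microscope field
#'   in micrometres.
#' @param n_fields number of fields in the scanning zone.
#' @param initial_density_per_mm2 total cells (donors + recipients) deposited
#'   per mm^2 of filter.
#' @param recipient_fraction fraction of the deposited cells that are
#'   recipients; 0.5 for a 1:1 donor:recipient ratio.
#' @param suspension_density_per_ml cell density of the mating suspension
#'   (recorded metadata; not used in any calculation).
#' @return An object of class `experiment_geometry`.
#' @examples
#' geom <- experiment_geometry()
#' scanned_fraction(geom)       # ~0.13
#' recipients_on_filter(geom)   # 4.05e6
#' @export
experiment_geometry <- function(filter_area_mm2 = 270,
                                field_width_um = 980,
                                field_height_um = 732,
                                n_fields = 49,
                                initial_density_per_mm2 = 30000,
                                recipient_fraction = 0.5,
                                suspension_density_per_ml = 3e6) {
  stopifnot(filter_area_mm2 > 0, field_width_um > 0, field_height_um > 0,
            n_fields >= 0, initial_density_per_mm2 >= 0)
  if (recipient_fraction <= 0 || recipient_fraction >= 1)
    stop("recipient_fraction must lie strictly between 0 and 1")
  scanned_mm2 <- n_fields * field_width_um * field_height_um / 1e6
  if (scanned_mm2 > filter_area_mm2)
    stop(sprintf("scanned area (%.2f mm^2) exceeds the filter area (%.2f mm^2)",
                 scanned_mm2, filter_area_mm2))
  structure(list(
    filter_area_mm2 = filter_area_mm2,
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    n_fields = n_fields,
    initial_density_per_mm2 = initial_density_per_mm2,
    recipient_fraction = recipient_fraction,
    suspension_density_per_ml = suspension_density_per_ml
  ), class = "experiment_geometry")
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat("Filter-mating geometry\n")
  cat(sprintf("  filter area: %g mm^2; scanning zone: %d fields of %g x %g um (%.1f%%)\n",
              x$filter_area_mm2, x$n_fields, x$field_width_um, x$field_height_um,
              100 * scanned_fraction(x)))
  cat(sprintf("  initial density: %g cells/mm^2, recipient fraction %g (%.3g recipients on filter)\n",
              x$initial_density_per_mm2, x$recipient_fraction,
              recipients_on_filter(x)))
  invisible(x)
}

#' Fraction of the filter covered by the scanning zone
#'
#' @param geometry an [experiment_geometry()] object.
#' @return The scanned fraction on a 0-1 scale (about 0.13 for the defaults).
#' @export
scanned_fraction <- function(geometry) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  geometry$n_fields * geometry$field_width_um * geometry$field_height_um /
    1e6 / geometry$filter_area_mm2
}

#' Scale a scanned-zone count to the whole filter
#'
#' Assumes the scanning zone is representative of the filter, so the
#' whole-filter count is the scanned count divided by the scanned fraction.
#' The result is an expectation and need not be an integer.
#'
#' @param scanned_count non-negative microcolony count in the scanning zone.
#' @inheritParams scanned_fraction
#' @return Expected whole-filter count.
#' @export
scale_to_filter <- function(scanned_count, geometry) {
  stopifnot(all(scanned_count >= 0))
  frac <- scanned_fraction(geometry)
  if (frac == 0) stop("scanned fraction is zero; cannot scale to the filter")
  scanned_count / frac
}

#' Number of potential recipients initially placed on the filter
#'
#' The transfer-frequency denominator: cells initially deposited, not
#' recipients that later formed microcolonies.
#'
#' @inheritParams scanned_fraction
#' @return Recipient count (density x filter area x recipient fraction).
#' @export
recipients_on_filter <- function(geometry) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  geometry$initial_density_per_mm2 * geometry$filter_area_mm2 *
    geometry$recipient_fraction
}

#' Expected number of recipients within one microscope field
#'
#' @inheritParams scanned_fraction
#' @return Recipient count per field.
#' @export
recipients_per_field <- function(geometry) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  geometry$initial_density_per_mm2 * geometry$recipient_fraction *
    geometry$field_width_um * geometry$field_height_um / 1e6
}

#' Transfer frequency (transconjugants per recipient) from a scanned count
#'
#' Scales the scanned-zone transconjugant microcolony count to the whole
#' filter and divides by the number of potential recipients initially placed
#' on the filter.
#'
#' @inheritParams scale_to_filter
#' @return Transfer frequency in T/R.
#' @examples
#' transfer_frequency(3, experiment_geometry())  # ~5.69e-6
#' @export
transfer_frequency <- function(scanned_count, geometry) {
  recipients <- recipients_on_filter(geometry)
  if (recipients == 0) stop("no recipients on the filter; frequency undefined")
  scale_to_filter(scanned_count, geometry) / recipients
}

#' Aggregate replicate transfer frequencies
#'
#' Summarises replicate filters as mean and standard error of the mean
#' (sample sd / sqrt(n)). With a single replicate the SEM is undefined and
#' flagged as `NA`.
#'
#' @param frequencies numeric vector of per-replicate T/R values (n >= 1,
#'   all >= 0).
#' @return An object of class `frequency_estimate` with fields
#'   `per_replicate`, `mean`, `sem`, `n_replicates` and `sem_defined`.
#' @examples
#' aggregate_replicates(c(1, 2, 3) * 1e-4)
#' @export
aggregate_replicates <- function(frequencies) {
  if (length(frequencies) == 0) stop("no replicate frequencies supplied")
  if (any(!is.finite(frequencies)) || any(frequencies < 0))
    stop("replicate frequencies must be finite and non-negative")
  n <- length(frequencies)
  sem_defined <- n >= 2
  structure(list(
    per_replicate = as.numeric(frequencies),
    mean = mean(frequencies),
    sem = if (sem_defined) stats::sd(frequencies) / sqrt(n) else NA_real_,
    n_replicates = n,
    sem_defined = sem_defined
  ), class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("Transfer frequency: %s T/R (n = %d%s)\n",
              signif(x$mean, 3), x$n_replicates,
              if (x$sem_defined) sprintf(", SEM %s", signif(x$sem, 3))
              else ", SEM undefined"))
  invisible(x)
}
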