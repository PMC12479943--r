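#' Injection record for decay-corrected uptake quantification
#'
#' Carries everything needed to turn an ROI activity concentration into a
#' standardized uptake value: injected activity, isotope half-life, the
#' injection-to-measurement interval and the animal's body weight.
#'
#' The 18F half-life defaults to the physical constant 109.77 min; other
#' isotopes can be supplied.
#'
#' @param N0 injected activity at injection time (MBq), > 0.
#' @param half_life isotope half-life (min).
#' @param t interval between injection and measurement (min), >= 0.
#' @param w body weight (g), > 0.
#' @return an `injection_record` list with the decay constant `lambda`
#'   (1/min) derived as ln(2)/half_life.
#' @export
injection_record <- function(N0, half_life = 109.77, t = 0, w) {
  stopifnot(is.numeric(N0), is.numeric(half_life), is.numeric(t), is.numeric(w))
  if (N0 <= 0) stop("injected activity N0 must be positive")
  if (half_life <= 0) stop("half_life must be positive")
  if (t < 0) stop("interval t must be non-negative")
  if (w <= 0) stop("body weight w must be positive")
  lambda <- log(2) / half_life
  stopifnot(abs(lambda * half_life - log(2)) < 1e-12)
  structure(list(N0 = N0, half_life = half_life, t = t, w = w,
                 lambda = lambda),
            class = "injection_record")
}

#' Decay-correct the injected activity to the measurement time
#'
#' N(t) = N0 * exp(-lambda * t), with lambda = ln(2)/half_life.
#'
#' @param rec an [injection_record()].
#' @param t optional interval override (min); defaults to `rec$t`.
#' @return remaining activity N(t) in MBq.
#' @export
decay_correct <- function(rec, t = rec$t) {
  stopifnot(inherits(rec, "injection_record"))
  if (any(t < 0)) stop("interval t must be non-negative")
  rec$N0 * exp(-rec$lambda * t)
}

#' Standardized uptake value
#'
#' SUV = (r / N(t)) * w, with r the background-subtracted ROI activity
#' concentration (MBq/g), N(t) the decay-corrected injected activity (MBq)
#' and w the body weight (g). Negative post-subtraction concentrations are
#' physically meaningless and are clamped to zero; the clamp is flagged in
#' the `clamped` attribute.
#'
#' @param r ROI activity concentration, MBq/g.
#' @param rec an [injection_record()].
#' @return dimensionless SUV (vectorized over `r`).
#' @export
compute_suv <- function(r, rec) {
  stopifnot(inherits(rec, "injection_record"))
  Nt <- decay_correct(rec)
  if (Nt <= 0) stop("decay-corrected activity N(t) must be positive")
  clamped <- r < 0
  r2 <- pmax(r, 0)
  suv <- (r2 / Nt) * rec$w
  attr(suv, "clamped") <- clamped
  suv
}

#' SUV ratio to a reference region
#'
#' @param suv_region SUV of the target region.
#' @param suv_reference SUV of the reference region (here the brainstem);
#'   must be positive.
#' @return dimensionless SUVR; the reference against itself is exactly 1.
#' @export
compute_suvr <- function(suv_region, suv_reference) {
  if (any(suv_reference <= 0)) stop("reference SUV must be positive")
  as.numeric(suv_region) / as.numeric(suv_reference)
}

#' Autoradiogram image container
#'
#' A calibrated 2D intensity field (plate units) plus the acquisition
#' metadata needed to interpret it: pixel size, slice thickness, slice
#' position lateral to Bregma.
#'
#' @param intensity numeric matrix, plate units, all values >= 0
#'   (rows = y, columns = x).
#' @param pixel_size mm per pixel (default 0.025, i.e. 25 um).
#' @param slice_thickness_um section thickness in micrometres.
#' @param laterality_mm slice position lateral to Bregma (mm).
#' @export
autoradiogram_image <- function(intensity, pixel_size = 0.025,
                                slice_thickness_um = 20,
                                laterality_mm = NA_real_) {
  stopifnot(is.matrix(intensity))
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 slice_thickness_um = slice_thickness_um,
                 laterality_mm = laterality_mm),
            class = "autoradiogram_image")
}

#' Circular region-of-interest specification
#'
#' @param center_x_mm,center_y_mm ROI centre in image coordinates (mm,
#'   origin at the image's lower-left pixel corner).
#' @param diameter_mm ROI diameter (default 0.4 mm).
#' @param region_label one of the study's region labels.
#' @export
roi_spec <- function(center_x_mm, center_y_mm, diameter_mm = 0.4,
                     region_label = "unlabelled") {
  if (diameter_mm <= 0) stop("ROI diameter must be positive")
  structure(list(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
                 diameter_mm = diameter_mm, region_label = region_label),
            class = "roi_spec")
}

# logical pixel mask of a circular ROI; a pixel belongs to the ROI if its
# center lies within the radius
roi_mask <- function(image, roi) {
  px <- image$pixel_size
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  r <- roi$diameter_mm / 2
  if (roi$center_x_mm - r < 0 || roi$center_y_mm - r < 0 ||
      roi$center_x_mm + r > nc * px || roi$center_y_mm + r > nr * px) {
    stop("ROI '", roi$region_label, "' extends outside the image bounds")
  }
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  dx2 <- outer(rep(1, nr), (xc - roi$center_x_mm)^2)
  dy2 <- outer((yc - roi$center_y_mm)^2, rep(1, nc))
  (dx2 + dy2) <= r^2
}

roi_mean_intensity <- function(image, roi) {
  m <- roi_mask(image, roi)
  mean(image$intensity[m])
}

#' Fit the plate calibration from co-exposed activity standards
#'
#' Ordinary least squares mapping background-subtracted plate intensity to
#' activity concentration (MBq/g). Each standard contributes its mean
#' intensity and its known activity; activity is divided by the standard
#' section mass to give a concentration.
#'
#' @param standard_means data.frame with columns `intensity`
#'   (background-subtracted mean plate units) and `activity_MBq`.
#' @param standard_mass_g mass of one standard section (g). The default
#'   `NULL` requires the caller to supply it; see
#'   [standard_section_mass()] for the area x thickness x density
#'   computation.
#' @param intercept fit a free intercept (default TRUE; residual plate
#'   background may survive subtraction). Set FALSE to force the line
#'   through the origin.
#' @return a `calibration_curve` with `slope` ((MBq/g)/intensity-unit),
#'   `intercept` (MBq/g), `r_squared` and `standards_used`.
#' @export
fit_calibration <- function(standard_means, standard_mass_g,
                            intercept = TRUE) {
  stopifnot(is.data.frame(standard_means),
            all(c("intensity", "activity_MBq") %in% names(standard_means)))
  if (nrow(standard_means) < 2) stop("need at least 2 standards")
  if (standard_mass_g <= 0) stop("standard mass must be positive")
  if (length(unique(standard_means$intensity)) < 2) {
    stop("degenerate fit: all standards have identical intensities")
  }
  conc <- standard_means$activity_MBq / standard_mass_g
  x <- standard_means$intensity
  fit <- if (intercept) stats::lm(conc ~ x) else stats::lm(conc ~ x + 0)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((conc - mean(conc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(if (intercept) co[2] else co[1]),
                 intercept = unname(if (intercept) co[1] else 0),
                 r_squared = min(max(r2, 0), 1),
                 standards_used = nrow(standard_means)),
            class = "calibration_curve")
}

#' Mass of a homogenate standard section
#'
#' area x thickness x density; the standards are cut at the same thickness
#' as the brain sections.
#'
#' @param area_mm2 standard patch area (mm^2).
#' @param thickness_um section thickness (um), default 20.
#' @param density_g_per_ml tissue density, default 1.0.
#' @return mass in grams.
#' @export
standard_section_mass <- function(area_mm2, thickness_um = 20,
                                  density_g_per_ml = 1.0) {
  volume_mm3 <- area_mm2 * (thickness_um / 1000)
  volume_mm3 * 1e-3 * density_g_per_ml  # 1 mm^3 = 1e-3 mL
}

#' Background-subtracted ROI activity concentration
#'
#' Mean plate intensity over the circular pixel mask, minus the background
#' ROI mean, mapped through the calibration line. The result can be
#' negative only when background exceeds signal; this is flagged via the
#' `below_background` attribute, not silently clamped (the SUV step clamps).
#'
#' @param image an [autoradiogram_image()].
#' @param roi target [roi_spec()].
#' @param cal fitted `calibration_curve`.
#' @param background_roi [roi_spec()] placed over tissue-free plate.
#' @return activity concentration r in MBq/g.
#' @export
roi_activity <- function(image, roi, cal, background_roi) {
  stopifnot(inherits(cal, "calibration_curve"))
  sig <- roi_mean_intensity(image, roi)
  bg <- roi_mean_intensity(image, background_roi)
  r <- cal$slope * (sig - bg) + cal$intercept
  attr(r, "below_background") <- r < 0
  r
}

#' Aggregate per-slice SUVRs into a per-animal region summary
#'
#' The slice-sampling policy follows the sectioning scheme: every 10th
#' section between 2.44 and 1.44 mm lateral to Bregma gives 6 slices per
#' animal for hippocampus, striatum and brainstem, and 3 slices (1.84 to
#' 1.44 mm) for the thalamus. A nonstandard slice count warns but does not
#' fail, so partial series remain usable.
#'
#' @param per_slice_suvr numeric vector of per-slice SUVRs for one animal.
#' @param region_label region name; drives the expected slice count.
#' @param expected_n optional override of the policy slice count.
#' @return a [group_summary()] (mean, SEM = SD/sqrt(n), n).
#' @export
aggregate_region <- function(per_slice_suvr, region_label,
                             expected_n = NULL) {
  if (length(per_slice_suvr) == 0) stop("no slices supplied")
  if (is.null(expected_n)) {
    expected_n <- switch(region_label, thalamus = 3,
                         hippocampus = , striatum = , brainstem = 6,
                         NA_integer_)
  }
  if (!is.na(expected_n) && length(per_slice_suvr) != expected_n) {
    warning("region '", region_label, "': ", length(per_slice_suvr),
            " slices, policy expects ", expected_n)
  }
  group_summary(per_slice_suvr, label = region_label)
}
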