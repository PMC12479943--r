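#' Phantom autoradiogram specification
#'
#' Describes a synthetic slide: named brain-region polygons with programmed
#' SUVRs, a co-exposed ladder of activity standards, the plate background
#' level and additive Gaussian noise. The reference region ("brainstem")
#' must be programmed at exactly SUVR 1.
#'
#' @param region_polygons named list of 2-column matrices (mm); must
#'   include "brainstem" plus any target regions.
#' @param programmed_suvr named numeric vector, one entry per region;
#'   `programmed_suvr["brainstem"]` must equal 1.
#' @param background_level plate background intensity (plate units).
#' @param noise_sd additive Gaussian noise SD (plate units).
#' @param standards_activities ladder activities in MBq; defaults to the
#'   five-step 1.5/0.8/0.4/0.2/0.04 ladder.
#' @param pixel_size mm/pixel, default 0.025.
#' @param image_shape c(rows, cols) in pixels.
#' @param suv_reference true SUV programmed for the reference region;
#'   the default places all tissue concentrations inside the standards
#'   ladder so the calibration interpolates rather than extrapolates.
#' @param injection [injection_record()] embedded in the slide; defaults
#'   to 15 MBq injected, 120 min uptake, 25 g animal.
#' @param gain plate response in intensity units per MBq/g.
#' @param standard_side_mm side length of the square standard patches.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(region_polygons = NULL,
                         programmed_suvr = NULL,
                         background_level = 100,
                         noise_sd = 0,
                         standards_activities = c(1.5, 0.8, 0.4, 0.2, 0.04),
                         pixel_size = 0.025,
                         image_shape = c(320, 400),
                         suv_reference = 0.5,
                         injection = injection_record(N0 = 15, t = 120, w = 25),
                         gain = 300,
                         standard_side_mm = 1.2) {
  if (is.null(region_polygons)) {
    lay <- default_phantom_layout()
    region_polygons <- lay$region_polygons
  }
  if (is.null(programmed_suvr)) {
    programmed_suvr <- c(hippocampus = 2.09, thalamus = 5.45,
                         striatum = 1.79, brainstem = 1.0)
  }
  if (!"brainstem" %in% names(region_polygons)) {
    stop("region_polygons must include the reference region 'brainstem'")
  }
  if (!setequal(names(region_polygons), names(programmed_suvr))) {
    stop("programmed_suvr must name exactly the regions in region_polygons")
  }
  if (abs(programmed_suvr[["brainstem"]] - 1.0) > 0) {
    stop("the reference region 'brainstem' must be programmed at SUVR 1")
  }
  if (any(standards_activities <= 0)) stop("standard activities must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(region_polygons = region_polygons,
                 programmed_suvr = programmed_suvr,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 standards_activities = standards_activities,
                 pixel_size = pixel_size,
                 image_shape = image_shape,
                 suv_reference = suv_reference,
                 injection = injection,
                 gain = gain,
                 standard_side_mm = standard_side_mm),
            class = "phantom_spec")
}

# circular brain "regions" in the left part of the slide (mm); the right
# margin is reserved for the standards ladder
default_phantom_layout <- function() {
  list(region_polygons = list(
    hippocampus = circle_polygon(c(2.0, 6.0), 1.0),
    thalamus    = circle_polygon(c(4.5, 4.0), 1.2),
    striatum    = circle_polygon(c(2.0, 2.0), 1.0),
    brainstem   = circle_polygon(c(6.8, 1.8), 1.0)))
}

# axis-aligned polygon overlap test on rasterized masks
check_region_overlap <- function(polys, pixel_size, shape) {
  masks <- lapply(polys, rasterize_polygon, pixel_size = pixel_size,
                  shape = shape)
  nm <- names(polys)
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1)) {
      if (any(masks[[i]] & masks[[j]])) {
        stop("regions overlap: '", nm[j], "' and '", nm[i], "'")
      }
    }
  }
  invisible(masks)
}

rasterize_polygon <- function(poly, pixel_size, shape) {
  nr <- shape[1]; nc <- shape[2]
  xc <- (seq_len(nc) - 0.5) * pixel_size
  yc <- (seq_len(nr) - 0.5) * pixel_size
  g <- expand.grid(y = yc, x = xc)
  matrix(points_in_polygon(g$x, g$y, poly), nrow = nr, ncol = nc)
}

# standard ladder geometry: squares stacked in the right margin
standards_layout <- function(spec) {
  k <- length(spec$standards_activities)
  side <- spec$standard_side_mm
  w_mm <- spec$image_shape[2] * spec$pixel_size
  h_mm <- spec$image_shape[1] * spec$pixel_size
  x0 <- w_mm - side - 0.3
  gap <- (h_mm - k * side) / (k + 1)
  data.frame(
    standard = seq_len(k),
    activity_MBq = spec$standards_activities,
    xmin = x0, xmax = x0 + side,
    ymin = gap + (seq_len(k) - 1) * (side + gap),
    ymax = gap + (seq_len(k) - 1) * (side + gap) + side)
}

#' Generate a phantom autoradiogram with known ground truth
#'
#' Renders a synthetic slide: each brain region is painted at the plate
#' intensity consistent with its programmed SUVR given the embedded
#' injection record and plate gain, the standards ladder is painted at the
#' intensity consistent with each activity, and additive Gaussian noise is
#' applied on top. The zero-noise image round-trips exactly through
#' [quantify_phantom()].
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; all randomness flows from it.
#' @return list with `image` ([autoradiogram_image()]), `truth`
#'   (per-region programmed SUVR and true concentration r), `standards`
#'   (ladder geometry + activities), `standard_mass_g`, `injection`,
#'   `background_level` and the `spec`.
#' @export
generate_phantom_autoradiogram <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$image_shape
  masks <- check_region_overlap(spec$region_polygons, spec$pixel_size, shape)

  Nt <- decay_correct(spec$injection)
  suv_ref <- spec$suv_reference
  # r such that (r / N(t)) * w = SUVR * suv_ref
  r_true <- spec$programmed_suvr * suv_ref * Nt / spec$injection$w

  img <- matrix(spec$background_level, nrow = shape[1], ncol = shape[2])
  for (nm in names(masks)) {
    img[masks[[nm]]] <- spec$background_level + spec$gain * r_true[[nm]]
  }

  std <- standards_layout(spec)
  # the ladder values are incubation concentrations of the homogenate
  # (MBq per gram at unit density), so each patch is painted at the
  # intensity of that concentration directly
  mass <- 1.0
  for (i in seq_len(nrow(std))) {
    m <- rasterize_polygon(rect_polygon(std$xmin[i], std$ymin[i],
                                        std$xmax[i], std$ymax[i]),
                           spec$pixel_size, shape)
    img[m] <- spec$background_level +
      spec$gain * std$activity_MBq[i] / mass
  }

  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), sd = spec$noise_sd),
                        nrow = shape[1])
    img[img < 0] <- 0
  }

  centers <- t(vapply(spec$region_polygons, colMeans, numeric(2)))
  truth <- data.frame(region = names(spec$region_polygons),
                      suvr_true = as.numeric(spec$programmed_suvr[
                        names(spec$region_polygons)]),
                      r_true = as.numeric(r_true[
                        names(spec$region_polygons)]),
                      center_x_mm = centers[, 1],
                      center_y_mm = centers[, 2],
                      row.names = NULL)

  list(image = autoradiogram_image(img, pixel_size = spec$pixel_size),
       truth = truth, standards = std, standard_mass_g = mass,
       injection = spec$injection,
       background_level = spec$background_level, spec = spec)
}

# save/restore global RNG state so generators are seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Quantify a phantom autoradiogram end to end
#'
#' The full measurement chain on a (synthetic or real) slide: mean
#' intensity of each standard patch, background subtraction, calibration
#' fit, circular-ROI activity per region, decay-corrected SUV, and SUVR
#' against the brainstem reference.
#'
#' @param phantom output of [generate_phantom_autoradiogram()], or a list
#'   with the same `image` / `standards` / `standard_mass_g` / `injection`
#'   components for real data.
#' @param roi_diameter_mm circular ROI diameter, default 0.4 mm.
#' @param background_xy_mm centre of the background ROI (tissue-free
#'   plate); default picks a point in the lower-left free margin.
#' @param intercept passed to [fit_calibration()].
#' @return data.frame with one row per region: mean ROI intensity, r
#'   (MBq/g), SUV and SUVR.
#' @export
quantify_phantom <- function(phantom, roi_diameter_mm = 0.4,
                             background_xy_mm = c(6.5, 6.5),
                             intercept = TRUE) {
  image <- phantom$image
  std <- phantom$standards
  bg_roi <- roi_spec(background_xy_mm[1], background_xy_mm[2],
                     diameter_mm = roi_diameter_mm,
                     region_label = "background")
  bg_mean <- roi_mean_intensity(image, bg_roi)

  std_means <- vapply(seq_len(nrow(std)), function(i) {
    cx <- (std$xmin[i] + std$xmax[i]) / 2
    cy <- (std$ymin[i] + std$ymax[i]) / 2
    roi_mean_intensity(image, roi_spec(cx, cy, roi_diameter_mm,
                                       paste0("standard_", i)))
  }, numeric(1))
  cal <- fit_calibration(
    data.frame(intensity = std_means - bg_mean,
               activity_MBq = std$activity_MBq),
    standard_mass_g = phantom$standard_mass_g, intercept = intercept)

  truth <- phantom$truth
  res <- lapply(seq_len(nrow(truth)), function(i) {
    roi <- roi_spec(truth$center_x_mm[i], truth$center_y_mm[i],
                    roi_diameter_mm, truth$region[i])
    r <- roi_activity(image, roi, cal, bg_roi)
    suv <- compute_suv(as.numeric(r), phantom$injection)
    data.frame(region = truth$region[i], r = as.numeric(r),
               suv = as.numeric(suv))
  })
  res <- do.call(rbind, res)
  ref <- res$suv[res$region == "brainstem"]
  if (length(ref) != 1) stop("reference region 'brainstem' not quantified")
  res$suvr <- compute_suvr(res$suv, ref)
  attr(res, "calibration") <- cal
  res
}
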