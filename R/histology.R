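#' Fluorescence field container
#'
#' @param intensity numeric matrix, non-negative.
#' @param channel immunolabel ("NeuN", "GFAP", "CD11b", "DAPI", ...).
#' @param pixel_size_um um per pixel.
#' @param field region label ("VPM", "motor cortex", ...).
#' @export
fluorescence_image <- function(intensity, channel = "NeuN",
                               pixel_size_um = 1, field = NA_character_) {
  stopifnot(is.matrix(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(intensity = intensity, channel = channel,
                 pixel_size_um = pixel_size_um, field = field),
            class = "fluorescence_image")
}

# Otsu threshold on the image's own intensity range; constant images have
# no foreground
auto_threshold <- function(img, method = c("otsu", "percentile"),
                           percentile = 0.99) {
  method <- match.arg(method)
  rng <- range(img)
  if (diff(rng) == 0) return(Inf)
  if (method == "percentile") {
    return(stats::quantile(img, percentile))
  }
  e <- EBImage::Image(img / rng[2])
  EBImage::otsu(e, range = c(rng[1] / rng[2], 1)) * rng[2]
}

#' Count labelled cells in a single-channel field
#'
#' The segmentation chain mirrors a standard cell-counting pipeline:
#' automatic global threshold (Otsu on the image's own range, making the
#' count invariant to intensity rescaling), hole filling, splitting of
#' touching objects by distance-transform watershed, and a size filter.
#'
#' @param img a [fluorescence_image()] (single channel).
#' @param min_area,max_area object size window in pixels; defaults cover
#'   nuclei of roughly 4-8 um radius at 1 um/pixel.
#' @param threshold_method "otsu" (default) or "percentile".
#' @return a `quant_result`: `cell_count`, `threshold_used`,
#'   `objects_rejected_by_size`, `channel`.
#' @export
count_cells <- function(img, min_area = 40, max_area = 2500,
                        threshold_method = "otsu") {
  stopifnot(inherits(img, "fluorescence_image"))
  x <- img$intensity
  if (diff(range(x)) > 0 && mean(x >= max(x) * 0.999) > 0.5) {
    warning("image looks saturated; counts may be unreliable")
  }
  thr <- auto_threshold(x, threshold_method)
  mask <- x > thr
  if (!any(mask)) {
    return(structure(list(cell_count = 0L, ir_area_percent = NA_real_,
                          threshold_used = thr,
                          objects_rejected_by_size = 0L,
                          channel = img$channel),
                     class = "quant_result"))
  }
  m <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = 1)
  areas <- table(as.vector(EBImage::imageData(lab)))
  areas <- areas[names(areas) != "0"]
  keep <- areas >= min_area & areas <= max_area
  structure(list(cell_count = sum(keep),
                 ir_area_percent = NA_real_,
                 threshold_used = thr,
                 objects_rejected_by_size = sum(!keep),
                 channel = img$channel),
            class = "quant_result")
}

#' Immunoreactive area fraction of a field
#'
#' Percentage of field pixels above the automatic threshold. A constant
#' (all-background) field has no foreground and returns 0%.
#'
#' @param img a [fluorescence_image()].
#' @param threshold_method "otsu" (default) or "percentile".
#' @return a `quant_result` with `ir_area_percent`.
#' @export
ir_area_fraction <- function(img, threshold_method = "otsu") {
  stopifnot(inherits(img, "fluorescence_image"))
  x <- img$intensity
  thr <- auto_threshold(x, threshold_method)
  # a constant field carries no contrast: all-immunoreactive if bright,
  # empty if zero
  pct <- if (is.infinite(thr)) {
    if (max(x) > 0) 100 else 0
  } else {
    100 * mean(x > thr)
  }
  structure(list(cell_count = NA_integer_, ir_area_percent = pct,
                 threshold_used = thr,
                 objects_rejected_by_size = NA_integer_,
                 channel = img$channel),
            class = "quant_result")
}

#' Average per-slice quantifications into a per-animal summary
#'
#' The study averages 3-5 slices per animal. Mixing channels in one
#' average is refused.
#'
#' @param per_slice list of `quant_result`s for one animal.
#' @param what "cell_count" or "ir_area_percent".
#' @param label animal label.
#' @return a [group_summary()].
#' @export
per_animal_average <- function(per_slice, what = c("cell_count",
                                                   "ir_area_percent"),
                               label = NA_character_) {
  what <- match.arg(what)
  if (length(per_slice) == 0) stop("no slices supplied")
  ch <- unique(vapply(per_slice, `[[`, character(1), "channel"))
  if (length(ch) > 1) {
    stop("refusing to average across channels: ",
         paste(ch, collapse = ", "))
  }
  vals <- vapply(per_slice, function(q) as.numeric(q[[what]]), numeric(1))
  group_summary(vals, label = label)
}

#' Cell-field specification for the synthetic fluorescence generator
#'
#' @param n_cells number of disk cells, >= 0.
#' @param cell_radius disk radius, pixels.
#' @param image_shape c(rows, cols) pixels.
#' @param ir_fraction_target optional target immunoreactive fraction in %
#'   of the field area; when given, `cell_radius` is ignored and the disk
#'   radius is sized so `n_cells` disks approximately cover the target
#'   (the returned truth is always the exactly achieved fraction).
#' @param background,foreground background / disk intensity levels.
#' @param noise_sd additive Gaussian noise SD.
#' @export
cell_field_spec <- function(n_cells = 50, cell_radius = 6,
                            image_shape = c(256, 256),
                            ir_fraction_target = NULL,
                            background = 0.1, foreground = 0.9,
                            noise_sd = 0) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (!is.null(ir_fraction_target) &&
      (ir_fraction_target < 0 || ir_fraction_target > 100)) {
    stop("ir_fraction_target must lie in [0, 100]")
  }
  if (!is.null(ir_fraction_target) && n_cells > 0) {
    area <- prod(image_shape) * ir_fraction_target / 100
    cell_radius <- sqrt(area / n_cells / pi)
  }
  structure(list(n_cells = n_cells, cell_radius = cell_radius,
                 image_shape = image_shape,
                 ir_fraction_target = ir_fraction_target,
                 background = background, foreground = foreground,
                 noise_sd = noise_sd),
            class = "cell_field_spec")
}

#' Generate a synthetic fluorescence field of non-overlapping disk cells
#'
#' Disk centres are placed by seeded rejection sampling with a minimum
#' centre distance of 2 * radius + 2 px, so cells never touch; ground
#' truth is exact by construction (the immunoreactive fraction is the
#' exact pixel fraction of the rendered mask).
#'
#' @param spec a [cell_field_spec()].
#' @param seed integer seed.
#' @return list with `image` ([fluorescence_image()]), `truth`
#'   (`count`, `ir_area_percent`) and `centers`.
#' @export
generate_cell_field <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_field_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  r <- spec$cell_radius
  # feasibility: disks must fit with margin
  packing <- spec$n_cells * pi * (2 * r)^2 / 4
  if (spec$n_cells > 0 && packing > 0.5 * nr * nc) {
    stop("cannot place ", spec$n_cells, " non-overlapping cells of radius ",
         signif(r, 3), " px in a ", nr, "x", nc, " field")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < spec$n_cells) {
    cand <- c(runif(1, r + 1, nc - r - 1), runif(1, r + 1, nr - r - 1))
    ok <- nrow(centers) == 0 ||
      all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
            (2 * r + 2)^2)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > 20000 * max(1, spec$n_cells)) {
      stop("cannot place ", spec$n_cells, " non-overlapping cells in a ",
           nr, "x", nc, " field")
    }
  }

  img <- matrix(spec$background, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  if (spec$n_cells > 0) {
    xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    yg <- matrix(seq_len(nr), nr, nc)
    for (i in seq_len(nrow(centers))) {
      d2 <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2
      mask <- mask | (d2 <= r^2)
    }
    img[mask] <- spec$foreground
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    img[img < 0] <- 0
  }
  list(image = fluorescence_image(img, channel = "NeuN",
                                  pixel_size_um = 1),
       truth = list(count = spec$n_cells,
                    ir_area_percent = 100 * mean(mask)),
       centers = centers)
}
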