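#' Write an autoradiogram as 16-bit TIFF plus JSON sidecar
#'
#' Plate intensities are scaled into the 16-bit range; the scale factor,
#' pixel size and any injection record / standards layout travel in a
#' JSON sidecar next to the image so [read_autoradiogram()] can restore
#' calibrated units. Quantization to 16 bits limits the file round-trip
#' fidelity to about 1 part in 65535 of full scale; quantitative work
#' should stay with the in-memory image.
#'
#' @param image an [autoradiogram_image()].
#' @param path output TIFF path; the sidecar is written at `path` +
#'   ".json".
#' @param injection optional [injection_record()].
#' @param standards optional standards layout data.frame.
#' @param standard_mass_g optional standard section mass.
#' @export
write_autoradiogram <- function(image, path, injection = NULL,
                                standards = NULL, standard_mass_g = NULL) {
  stopifnot(inherits(image, "autoradiogram_image"))
  mx <- max(image$intensity)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(image$intensity / scale, path, bits.per.sample = 16,
                  compression = "none")
  side <- list(scale = scale, pixel_size_mm = image$pixel_size,
               slice_thickness_um = image$slice_thickness_um,
               laterality_mm = image$laterality_mm)
  if (!is.null(injection)) side$injection <- unclass(injection)
  if (!is.null(standards)) side$standards <- standards
  if (!is.null(standard_mass_g)) side$standard_mass_g <- standard_mass_g
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an autoradiogram written by [write_autoradiogram()]
#'
#' @param path TIFF path (sidecar expected at `path` + ".json").
#' @return list with `image`, and `injection` / `standards` /
#'   `standard_mass_g` when present in the sidecar.
#' @export
read_autoradiogram <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path)
  img <- autoradiogram_image(px * side$scale,
                             pixel_size = side$pixel_size_mm,
                             slice_thickness_um = side$slice_thickness_um,
                             laterality_mm = side$laterality_mm)
  out <- list(image = img)
  if (!is.null(side$injection)) {
    inj <- side$injection
    out$injection <- injection_record(inj$N0, inj$half_life, inj$t, inj$w)
  }
  if (!is.null(side$standards)) {
    out$standards <- as.data.frame(side$standards)
  }
  if (!is.null(side$standard_mass_g)) {
    out$standard_mass_g <- side$standard_mass_g
  }
  out
}

#' Write a sweep set as wide CSV
#'
#' Column 1 is time in seconds; one column per step, header = injected
#' current in pA. Step timing and QC metadata travel in a small JSON
#' sidecar, keeping the CSV a plain rectangular table.
#'
#' @param sweeps a `sweep_set`.
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  df <- data.frame(time_s = sweeps$time_s)
  for (k in seq_along(sweeps$current_pA)) {
    df[[paste0("I", sweeps$current_pA[k], "pA")]] <- sweeps$voltage[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(onset_s = sweeps$onset_s,
                            offset_s = sweeps$offset_s,
                            current_pA = sweeps$current_pA,
                            V_rest = sweeps$V_rest, R_S = sweeps$R_S),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sweep set written by [write_sweep_csv()]
#'
#' @param path CSV path (sidecar expected at `path` + ".json").
#' @return a `sweep_set`.
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  V <- as.matrix(df[, -1, drop = FALSE])
  dimnames(V) <- NULL
  structure(list(time_s = df[[1]], voltage = V,
                 current_pA = as.numeric(side$current_pA),
                 onset_s = side$onset_s, offset_s = side$offset_s,
                 dt_s = df[[1]][2] - df[[1]][1],
                 V_rest = side$V_rest, R_S = side$R_S,
                 ground_truth = NULL),
            class = "sweep_set")
}
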