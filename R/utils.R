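#' Standard error of the mean
#'
#' @param x numeric vector.
#' @return SD(x)/sqrt(n).
#' @export
sem <- function(x) {
  stats::sd(x) / sqrt(length(x))
}

#' Summarise a set of replicate values as mean, SEM and n
#'
#' The container used throughout the pipeline wherever per-group or
#' per-animal summaries feed downstream statistics.
#'
#' @param values numeric vector of replicate measurements.
#' @param label group / region label.
#' @return a `group_summary` list with `label`, `mean`, `sem`, `n`.
#' @export
group_summary <- function(values, label = NA_character_) {
  if (length(values) == 0) stop("cannot summarise an empty vector")
  structure(
    list(label = label,
         mean = mean(values),
         sem = if (length(values) > 1) sem(values) else 0,
         n = length(values)),
    class = "group_summary")
}

# vectorized even-odd ray casting; px/py are point coords, poly a 2-col matrix
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# circle approximated by a regular polygon (mm coordinates)
circle_polygon <- function(center, radius, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
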