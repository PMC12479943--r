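#' Open-field arena geometry
#'
#' A square arena divided into a border strip along the walls and a
#' central square; with the study's 44 x 44 cm arena and an 11 cm border
#' the centre is the middle 22 x 22 cm.
#'
#' @param side_cm arena side length, default 44.
#' @param border_cm border strip width, default 11.
#' @return an `arena_spec`; errors unless centre + 2 * border = side.
#' @export
arena_spec <- function(side_cm = 44, border_cm = 11) {
  if (side_cm <= 0 || border_cm <= 0) stop("arena dimensions must be positive")
  centre_cm <- side_cm - 2 * border_cm
  if (centre_cm <= 0) stop("border too wide for the arena")
  structure(list(side_cm = side_cm, border_cm = border_cm,
                 centre_cm = centre_cm),
            class = "arena_spec")
}

# TRUE when strictly inside the central square
in_centre <- function(x, y, arena) {
  b <- arena$border_cm; s <- arena$side_cm
  x > b & x < s - b & y > b & y < s - b
}

#' Zone occupancy, distance and velocity of an open-field trajectory
#'
#' Distance is the sum of segment lengths; each segment is assigned to the
#' zone of its midpoint (boundary points belong to the centre only when
#' strictly inside the central square). Time per zone sums the
#' inter-sample intervals the same way, so centre + border time equals the
#' total duration exactly. Velocity is total distance over total duration.
#'
#' @param traj data.frame with columns `t_s`, `x_cm`, `y_cm`; timestamps
#'   must be strictly increasing, >= 2 samples, all points inside the
#'   arena (0.5 cm tolerance).
#' @param arena an [arena_spec()].
#' @return list with `distance_cm`, `distance_centre_cm`,
#'   `distance_border_cm`, `time_centre_s`, `time_border_s`,
#'   `total_time_s`, `velocity_cm_s`.
#' @export
zone_metrics <- function(traj, arena) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(traj)))
  if (nrow(traj) < 2) stop("trajectory needs at least 2 samples")
  if (any(diff(traj$t_s) <= 0)) stop("timestamps must be strictly increasing")
  tol <- 0.5
  if (any(traj$x_cm < -tol | traj$x_cm > arena$side_cm + tol |
          traj$y_cm < -tol | traj$y_cm > arena$side_cm + tol)) {
    stop("trajectory leaves the arena")
  }
  dx <- diff(traj$x_cm); dy <- diff(traj$y_cm); dt <- diff(traj$t_s)
  seg <- sqrt(dx^2 + dy^2)
  mx <- (traj$x_cm[-1] + traj$x_cm[-nrow(traj)]) / 2
  my <- (traj$y_cm[-1] + traj$y_cm[-nrow(traj)]) / 2
  centre <- in_centre(mx, my, arena)
  total_t <- sum(dt)
  list(distance_cm = sum(seg),
       distance_centre_cm = sum(seg[centre]),
       distance_border_cm = sum(seg[!centre]),
       time_centre_s = sum(dt[centre]),
       time_border_s = sum(dt[!centre]),
       total_time_s = total_t,
       velocity_cm_s = sum(seg) / total_t)
}

#' Generate a synthetic arena trajectory
#'
#' Three modes: `stationary` (the animal sits at one point),
#' `centre_only` (a random walk confined to the central square) and
#' `random_walk` (a reflected Gaussian random walk over the whole arena;
#' wall-hugging behaviour emerges when `wall_bias` > 0 pulls the animal
#' toward the nearest wall, mimicking thigmotaxis).
#'
#' @param arena an [arena_spec()].
#' @param mode "stationary", "centre_only" or "random_walk".
#' @param duration_s session length (the study uses 20 min = 1200 s).
#' @param rate_hz sampling rate.
#' @param step_cm random-walk step scale per sample.
#' @param wall_bias 0..1, fraction of each step directed toward the
#'   nearest wall.
#' @param seed integer seed.
#' @return data.frame `t_s`, `x_cm`, `y_cm`.
#' @export
generate_trajectory <- function(arena, mode = c("random_walk",
                                                "stationary",
                                                "centre_only"),
                                duration_s = 1200, rate_hz = 25,
                                step_cm = 1.0, wall_bias = 0.6,
                                seed = 1L) {
  mode <- match.arg(mode)
  n <- round(duration_s * rate_hz) + 1
  t_s <- (seq_len(n) - 1) / rate_hz
  s <- arena$side_cm
  if (mode == "stationary") {
    return(data.frame(t_s = t_s, x_cm = rep(s / 2, n),
                      y_cm = rep(s / 2, n)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  b <- arena$border_cm
  lo <- if (mode == "centre_only") b + 1e-6 else 0
  hi <- if (mode == "centre_only") s - b - 1e-6 else s
  x <- numeric(n); y <- numeric(n)
  x[1] <- y[1] <- s / 2
  for (i in 2:n) {
    sx <- rnorm(1, sd = step_cm); sy <- rnorm(1, sd = step_cm)
    if (mode == "random_walk" && wall_bias > 0) {
      # pull toward the nearest wall (thigmotaxis)
      tx <- if (x[i - 1] < s / 2) 0 else s
      ty <- if (y[i - 1] < s / 2) 0 else s
      if (abs(x[i - 1] - tx) < abs(y[i - 1] - ty)) {
        sx <- sx + wall_bias * step_cm * sign(tx - x[i - 1])
      } else {
        sy <- sy + wall_bias * step_cm * sign(ty - y[i - 1])
      }
    }
    xn <- x[i - 1] + sx; yn <- y[i - 1] + sy
    # reflect at the allowed bounds
    xn <- reflect(xn, lo, hi); yn <- reflect(yn, lo, hi)
    x[i] <- xn; y[i] <- yn
  }
  data.frame(t_s = t_s, x_cm = x, y_cm = y)
}

reflect <- function(v, lo, hi) {
  rng <- hi - lo
  v <- (v - lo) %% (2 * rng)
  ifelse(v > rng, 2 * rng - v, v) + lo
}

#' Read / write trajectory CSV (columns t_s, x_cm, y_cm)
#' @param path CSV path.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(df)))
  df
}

#' @rdname read_trajectory_csv
#' @param traj trajectory data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
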