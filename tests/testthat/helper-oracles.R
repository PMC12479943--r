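# Independent brute-force oracles used across the suite. These never call
# the package's own implementations of the quantities they check.

# one-way ANOVA from raw data, from the sums-of-squares definition
oracle_oneway_F <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  grand <- mean(values)
  mns <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (mns - grand)^2)
  ssw <- sum((values - mns[groups])^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  U_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- U_of(a, b)
  m <- length(pooled)
  combs <- utils::combn(m, n)
  us <- apply(combs, 2, function(idx) U_of(pooled[idx], pooled[-idx]))
  mu <- n * (length(b)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# tree metrics by naive traversal over the SWC table (O(n^2) scans)
oracle_tree_metrics <- function(morph) {
  dend <- morph$type %in% c(3L, 4L)
  len <- 0
  n_primary <- 0
  n_bif <- 0
  n_term <- 0
  for (i in seq_len(nrow(morph))) {
    if (!dend[i]) next
    pid <- morph$parent[i]
    if (pid != -1) {
      j <- which(morph$id == pid)
      len <- len + sqrt(sum((unlist(morph[i, c("x", "y", "z")]) -
                             unlist(morph[j, c("x", "y", "z")]))^2))
      if (morph$type[j] == 1L) n_primary <- n_primary + 1
    }
    kids <- sum(morph$parent == morph$id[i] &
                  morph$type %in% c(3L, 4L))
    if (kids >= 2) n_bif <- n_bif + 1
    if (kids == 0) n_term <- n_term + 1
  }
  list(total_dendritic_length = len, n_primary_dendrites = n_primary,
       n_bifurcation_nodes = n_bif, n_terminal_endings = n_term)
}

# paint disks directly into a matrix (independent of the generator),
# allowing overlaps
paint_disks <- function(centers, radius, shape, background = 0.1,
                        foreground = 0.9) {
  img <- matrix(background, shape[1], shape[2])
  xg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  yg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    img[(xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= radius^2] <-
      foreground
  }
  img
}

# ideal RC sweep set built analytically (no simulator involved)
rc_sweep_set <- function(R_Mohm = 100, tau_ms = 20, amps = seq(-50, 50, 10),
                         EL = -65, dt_s = 1e-4, pre_s = 0.2, dur_s = 1,
                         post_s = 0.3) {
  n_pre <- round(pre_s / dt_s); n_dur <- round(dur_s / dt_s)
  n_post <- round(post_s / dt_s)
  n <- n_pre + n_dur + n_post
  t_step <- (seq_len(n_dur) - 1) * dt_s * 1000
  V <- sapply(amps, function(I) {
    dV <- I * R_Mohm / 1000  # pA * MOhm = uV*... (mV = pA*GOhm); R in MOhm
    c(rep(EL, n_pre),
      EL + dV * (1 - exp(-t_step / tau_ms)),
      rep(EL, n_post))
  })
  structure(list(time_s = (seq_len(n) - 1) * dt_s, voltage = V,
                 current_pA = amps, onset_s = pre_s,
                 offset_s = pre_s + dur_s, dt_s = dt_s,
                 V_rest = EL, R_S = 10, ground_truth = NULL),
            class = "sweep_set")
}
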