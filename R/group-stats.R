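#' One-way ANOVA reconstructed from group summaries
#'
#' Recomputes the one-way ANOVA F statistic from published per-group
#' means, SEMs and sample sizes, without the raw data. The between-group
#' sum of squares is taken about the n-weighted grand mean; the
#' within-group sum of squares is rebuilt from the SEMs via
#' SD_i = SEM_i * sqrt(n_i), i.e. SSW = sum over groups of
#' (n_i - 1) * n_i * SEM_i^2. When the summaries are error-free the
#' result equals the raw-data ANOVA exactly; from printed (rounded)
#' summaries it agrees within the rounding of the inputs.
#'
#' @param groups data.frame with columns `mean`, `sem`, `n` (and
#'   optionally `label`), or a list of [group_summary()] objects.
#' @return an `anova_result`: `F`, `df_between` (k-1), `df_within`
#'   (N-k), `p`, plus `ms_within` for post hoc use.
#' @export
anova_from_summary <- function(groups) {
  g <- as_group_df(groups)
  if (nrow(g) < 2) stop("need at least 2 groups")
  if (any(g$n < 2)) stop("every group needs n >= 2")
  if (any(is.na(g$sem))) stop("every group needs a SEM")
  N <- sum(g$n); k <- nrow(g)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$n * g$sem^2)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  Fv <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  structure(list(F = Fv, df_between = df1, df_within = df2,
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 ms_within = msw, grand_mean = grand),
            class = "anova_result")
}

as_group_df <- function(groups) {
  if (is.data.frame(groups)) return(groups)
  do.call(rbind, lapply(groups, function(s) {
    data.frame(label = s$label, mean = s$mean, sem = s$sem, n = s$n)
  }))
}

#' Pairwise post hoc comparisons from group summaries
#'
#' Fisher's LSD (unadjusted t tests on the pooled within-group mean
#' square) or Tukey's HSD (studentized range), both computed from the
#' reconstructed MSW of [anova_from_summary()] so they work when only
#' printed summaries exist.
#'
#' @param groups as in [anova_from_summary()].
#' @param method "lsd" or "tukey".
#' @return data.frame with one row per pair: difference, SE, statistic, p.
#' @export
posthoc_pairwise <- function(groups, method = c("lsd", "tukey")) {
  method <- match.arg(method)
  g <- as_group_df(groups)
  if (is.null(g$label)) g$label <- paste0("g", seq_len(nrow(g)))
  a <- anova_from_summary(g)
  pairs <- utils::combn(nrow(g), 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- g$mean[j] - g$mean[i]
    se <- sqrt(a$ms_within * (1 / g$n[i] + 1 / g$n[j]))
    tv <- d / se
    p <- if (method == "lsd") {
      2 * stats::pt(abs(tv), a$df_within, lower.tail = FALSE)
    } else {
      stats::ptukey(abs(tv) * sqrt(2), nrow(g), a$df_within,
                    lower.tail = FALSE)
    }
    data.frame(group_a = g$label[i], group_b = g$label[j],
               difference = d, se = se, statistic = tv, p = p)
  })
  do.call(rbind, out)
}

#' Absolute and relative change between two values
#'
#' Returns the magnitude of the change; the direction is reported
#' separately (the convention used when quoting e.g. a "7.8% increase"
#' against a negative-valued baseline).
#'
#' @param reference baseline value (non-zero).
#' @param comparison comparison value.
#' @return list with `absolute` (|comparison - reference|), `percent`
#'   (100 * absolute / |reference|) and `direction` (+1/-1/0 on the raw
#'   difference).
#' @export
percent_change <- function(reference, comparison) {
  if (reference == 0) stop("reference must be non-zero")
  d <- comparison - reference
  list(absolute = abs(d), percent = 100 * abs(d) / abs(reference),
       direction = sign(d))
}

#' Fold change comparison / reference
#'
#' @param reference baseline (> 0).
#' @param comparison comparison value.
#' @return the ratio comparison / reference.
#' @export
fold_change <- function(reference, comparison) {
  if (reference <= 0) stop("reference must be positive")
  comparison / reference
}

#' Wilcoxon-Mann-Whitney two-sample rank test
#'
#' Two-sided Mann-Whitney U. The exact null distribution is used for
#' untied samples with combined n <= `exact_max`; larger or tied samples
#' use the normal approximation with the tie correction.
#'
#' @param a,b numeric samples (each >= 3 values).
#' @param exact_max combined-size limit for the exact branch, default 12.
#' @return list with `U`, `p`, `method`.
#' @export
rank_test <- function(a, b, exact_max = 12) {
  if (length(a) < 3 || length(b) < 3) stop("both samples need >= 3 values")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Two-way mixed (repeated-measures) ANOVA
#'
#' Subjects are nested in genotype and measured at every timepoint; the
#' genotype main effect is tested against between-subject variation and
#' the timepoint and interaction terms against the within-subject
#' residual (classical univariate mixed ANOVA, delegated to `aov` with an
#' Error(subject) stratum). With a single timepoint the genotype test
#' collapses to the ordinary one-way ANOVA.
#'
#' @param data long-format data.frame with columns `subject`, `genotype`,
#'   `timepoint`, `value`.
#' @return data.frame with one row per effect: `effect`, `df`, `df_error`,
#'   `F`, `p`.
#' @export
two_way_rm_anova <- function(data) {
  needed <- c("subject", "genotype", "timepoint", "value")
  stopifnot(all(needed %in% names(data)))
  cross <- table(data$subject, data$genotype) > 0
  if (any(rowSums(cross) > 1)) {
    stop("design error: a subject appears in more than one genotype")
  }
  data$subject <- factor(data$subject)
  data$genotype <- factor(data$genotype)
  data$timepoint <- factor(data$timepoint)
  one_tp <- nlevels(data$timepoint) == 1

  if (one_tp) {
    fit <- stats::aov(value ~ genotype, data = data)
    s <- summary(fit)[[1]]
    return(data.frame(effect = "genotype",
                      df = s$Df[1], df_error = s$Df[2],
                      F = s$`F value`[1], p = s$`Pr(>F)`[1]))
  }
  fit <- stats::aov(value ~ genotype * timepoint + Error(subject),
                    data = data)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  out <- rbind(
    data.frame(effect = "genotype",
               df = between$Df[rn(between) == "genotype"],
               df_error = between$Df[rn(between) == "Residuals"],
               F = between$`F value`[rn(between) == "genotype"],
               p = between$`Pr(>F)`[rn(between) == "genotype"]),
    data.frame(effect = "timepoint",
               df = within$Df[rn(within) == "timepoint"],
               df_error = within$Df[rn(within) == "Residuals"],
               F = within$`F value`[rn(within) == "timepoint"],
               p = within$`Pr(>F)`[rn(within) == "timepoint"]),
    data.frame(effect = "genotype:timepoint",
               df = within$Df[rn(within) == "genotype:timepoint"],
               df_error = within$Df[rn(within) == "Residuals"],
               F = within$`F value`[rn(within) == "genotype:timepoint"],
               p = within$`Pr(>F)`[rn(within) == "genotype:timepoint"]))
  out
}
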