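test_that("summary ANOVA equals raw-data ANOVA for error-free summaries", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    ns <- sample(3:9, k, replace = TRUE)
    values <- unlist(lapply(seq_len(k), function(i) {
      rnorm(ns[i], mean = i * runif(1, 0, 3), sd = runif(1, 0.5, 2))
    }))
    groups <- rep(seq_len(k), ns)
    summ <- do.call(rbind, lapply(seq_len(k), function(i) {
      v <- values[groups == i]
      data.frame(mean = mean(v), sem = sd(v) / sqrt(length(v)),
                 n = length(v))
    }))
    got <- anova_from_summary(summ)
    want <- oracle_oneway_F(values, groups)
    expect_lt(abs(got$F / want - 1), 1e-10)
    expect_equal(got$df_between, k - 1)
    expect_equal(got$df_within, sum(ns) - k)
    # cross-check against aov as well
    fit <- summary(aov(values ~ factor(groups)))[[1]]
    expect_equal(got$F, fit$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p, fit$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("two groups give F equal to the squared pooled t statistic", {
  set.seed(11)
  a <- rnorm(8, 1); b <- rnorm(6, 2)
  summ <- data.frame(mean = c(mean(a), mean(b)),
                     sem = c(sd(a) / sqrt(8), sd(b) / sqrt(6)),
                     n = c(8, 6))
  got <- anova_from_summary(summ)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("equal group means give F = 0; validation errors", {
  summ <- data.frame(mean = c(5, 5, 5), sem = c(1, 2, 1), n = c(5, 5, 5))
  expect_equal(anova_from_summary(summ)$F, 0)
  expect_error(anova_from_summary(data.frame(mean = 1, sem = 1, n = 5)),
               "2 groups")
  expect_error(anova_from_summary(data.frame(mean = c(1, 2),
                                             sem = c(1, NA), n = c(5, 5))),
               "SEM")
})

test_that("printed-table reconstruction hits the published F values", {
  # microglia marker row: three genotypes of the thalamic VPM field
  cd11b <- data.frame(label = c("WT", "td", "ko"),
                      mean = c(3.4, 17, 29), sem = c(1.3, 2.0, 2.6),
                      n = c(10, 6, 6))
  a <- anova_from_summary(cd11b)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 19)
  expect_lt(abs(a$F / 50.77 - 1), 0.03)
  # astrocyte marker row
  gfap <- data.frame(mean = c(5, 24, 29), sem = c(0.7, 1.1, 3.6),
                     n = c(10, 6, 6))
  expect_lt(abs(anova_from_summary(gfap)$F / 51.89 - 1), 0.03)
})

test_that("post hoc pairwise comparisons behave sanely", {
  g <- data.frame(label = c("WT", "td", "ko"),
                  mean = c(3.4, 17, 29), sem = c(1.3, 2.0, 2.6),
                  n = c(10, 6, 6))
  lsd <- posthoc_pairwise(g, "lsd")
  tk <- posthoc_pairwise(g, "tukey")
  expect_equal(nrow(lsd), 3)
  expect_true(all(lsd$p <= tk$p + 1e-12))  # LSD is the more liberal test
  expect_lt(lsd$p[lsd$group_a == "WT" & lsd$group_b == "ko"], 1e-6)
})

test_that("percent and fold change reproduce the published deltas", {
  thr <- percent_change(-42.2, -38.9)
  expect_equal(thr$absolute, 3.3, tolerance = 1e-9)
  expect_equal(round(thr$percent, 1), 7.8)
  amp <- percent_change(93.1, 108.5)
  expect_equal(amp$absolute, 15.4, tolerance = 1e-9)
  expect_equal(round(amp$percent, 1), 16.5)
  ahp <- percent_change(12.3, 16.8)
  expect_equal(ahp$absolute, 4.5, tolerance = 1e-9)
  expect_equal(round(ahp$percent, 1), 36.6)
  expect_equal(percent_change(3, 3)$absolute, 0)
  expect_error(percent_change(0, 1), "non-zero")

  expect_equal(fold_change(5, 24), 4.8)
  expect_equal(round(fold_change(5, 24)), 5)
  expect_equal(fold_change(2, 2), 1)
  expect_equal(fold_change(2, 4), 2)
  expect_error(fold_change(0, 1), "positive")
})

test_that("scale invariance of percent and fold change", {
  for (c_ in c(0.5, 3, 100)) {
    expect_equal(percent_change(4 * c_, 7 * c_)$percent,
                 percent_change(4, 7)$percent, tolerance = 1e-12)
    expect_equal(fold_change(4 * c_, 7 * c_), fold_change(4, 7),
                 tolerance = 1e-12)
  }
})

test_that("rank test exact branch matches full enumeration", {
  r <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$p, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:15) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    got <- rank_test(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_mw_exact(a, b), tolerance = 1e-10)
  }
})

test_that("rank test p is invariant under monotone transforms", {
  a <- c(0.3, 1.2, 2.2, 4.1); b <- c(0.8, 2.9, 3.3, 5.0)
  p1 <- rank_test(a, b)$p
  p2 <- rank_test(exp(a), exp(b))$p
  p3 <- rank_test(a^3 + 2, b^3 + 2)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
  # near-identical samples give p close to 1
  expect_gt(rank_test(c(1, 3, 5, 7), c(2, 4, 6, 8))$p, 0.5)
})

test_that("repeated-measures ANOVA: design checks and collapse", {
  set.seed(21)
  df <- expand.grid(subject = paste0("s", 1:12),
                    timepoint = c("P20", "P30", "P40"))
  df$genotype <- ifelse(as.integer(sub("s", "", df$subject)) <= 6,
                        "WT", "td")
  df$value <- rnorm(nrow(df)) + (df$genotype == "td") * 2
  res <- two_way_rm_anova(df)
  expect_setequal(res$effect, c("genotype", "timepoint",
                                "genotype:timepoint"))
  expect_equal(res$df[res$effect == "genotype"], 1)
  expect_equal(res$df_error[res$effect == "genotype"], 10)

  # single timepoint collapses to the one-way ANOVA
  one <- df[df$timepoint == "P20", ]
  res1 <- two_way_rm_anova(one)
  raw <- summary(aov(value ~ genotype, one))[[1]]
  expect_equal(res1$F, raw$`F value`[1], tolerance = 1e-10)

  bad <- df
  bad$genotype[1] <- "ko"
  expect_error(two_way_rm_anova(bad), "more than one genotype")
})

test_that("repeated-measures interaction holds its type-I error", {
  set.seed(31)
  reject <- replicate(300, {
    df <- expand.grid(subject = paste0("s", 1:10),
                      timepoint = c("a", "b", "c"))
    df$genotype <- ifelse(as.integer(sub("s", "", df$subject)) <= 5,
                          "WT", "td")
    subj_eff <- rnorm(10)[as.integer(sub("s", "", df$subject))]
    df$value <- subj_eff + rnorm(nrow(df))
    res <- two_way_rm_anova(df)
    res$p[res$effect == "genotype:timepoint"] < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.035)
})
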