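# independent binomial log-likelihood oracle for the age deviance:
# 2 * (saturated-by-day log-lik - pooled log-lik)
age_deviance_oracle <- function(minor, major, day) {
  ll <- function(k, n, p) {
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    sum(k * log(p) + (n - k) * log(1 - p))
  }
  n <- minor + major
  p_day <- tapply(minor, day, sum) / tapply(n, day, sum)
  p_pool <- sum(minor) / sum(n)
  2 * (ll(minor, n, unname(p_day[as.character(day)])) -
         ll(minor, n, p_pool))
}

test_that("the age-factor GLM detects signal and matches a likelihood oracle", {
  # flat counts: no evidence of change
  flat <- do.call(rbind, lapply(c(2, 6, 10, 22), function(d) {
    locus_table(stats::setNames(list(list(R1 = c(50, 50), R2 = c(50, 50),
                                          R3 = c(50, 50))), d))
  }))
  res <- test_age_effect(flat)
  expect_gt(res$deviance_p, 0.999)
  expect_false(res$significant)
  # a complete day-2 -> day-22 reversal at depth 100 x 5 replicates
  reps <- function(major, minor) {
    stats::setNames(lapply(1:5, function(i) c(major, minor)),
                    paste0("R", 1:5))
  }
  strong <- rbind(locus_table(list(`2` = reps(90, 10))),
                  locus_table(list(`22` = reps(10, 90))))
  res <- test_age_effect(strong)
  expect_gt(res$deviance, 100)
  expect_lt(res$deviance_p, 1e-10)
  want <- age_deviance_oracle(strong$n_minor, strong$n_major, strong$day)
  expect_equal(res$deviance, want, tolerance = 1e-8)
})

test_that("BH adjustment across loci matches the step-up oracle", {
  sim <- simulate_pool_study(simulation_scenario(n_loci = 25, seed = 31,
                                                 scenario = "balanced"))
  res <- test_age_effect(sim$counts)
  # independent step-up arithmetic on the reported raw p-values
  m <- nrow(res)
  ord <- order(res$deviance_p)
  bh <- numeric(m)
  bh[ord] <- rev(cummin(rev(res$deviance_p[ord] * m / seq_len(m))))
  expect_equal(res$q_bh, pmin(bh, 1), tolerance = 1e-12)
  expect_true(all(res$q_bh >= res$deviance_p))
  expect_equal(res$significant, res$q_bh < 0.05)
})

test_that("loci with a single day of data are excluded with a warning", {
  tab <- rbind(
    locus_table(list(`2` = list(R1 = c(50, 50)))), # single day
    locus_table(list(`2` = list(R1 = c(80, 20)), `6` = list(R1 = c(20, 80))),
                locus_id = "L2", tag_id = "tag_2")
  )
  expect_warning(res <- test_age_effect(tab), "single day")
  expect_equal(res$locus_id, "L2")
})

test_that("sequential Tukey categorization separates G, UD and BD patterns", {
  days <- c(2, 6, 10, 14, 22)
  # flat trajectory, overall significant -> gradual
  g <- categorize_locus(maf_trajectory(rep(0.3, 5), days, seed = 1), TRUE)
  expect_equal(g$category, "G")
  # one abrupt step up -> UD with exactly one significant up-change
  ud <- categorize_locus(
    maf_trajectory(c(0.10, 0.10, 0.40, 0.40, 0.40), days, seed = 2), TRUE)
  expect_equal(ud$category, "UD")
  sig <- ud$intervals[ud$intervals$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$direction, "up")
  expect_equal(c(sig$day_from, sig$day_to), c(6, 10))
  # up then down -> BD
  bd <- categorize_locus(
    maf_trajectory(c(0.10, 0.10, 0.40, 0.10, 0.10), days, seed = 3), TRUE)
  expect_equal(bd$category, "BD")
  dirs <- bd$intervals$direction[bd$intervals$significant]
  expect_setequal(dirs, c("up", "down"))
  # non-significant loci are labelled NS and carry no interval calls
  ns <- categorize_locus(maf_trajectory(rep(0.3, 5), days), FALSE)
  expect_equal(ns$category, "NS")
  expect_null(ns$intervals)
})

test_that("a Tukey oracle confirms the single significant step", {
  # studentized-range check at alpha = 0.05 for the UD case above
  days <- c(2, 6, 10, 14, 22)
  tr <- maf_trajectory(c(0.10, 0.10, 0.40, 0.40, 0.40), days, seed = 2)
  fit <- aov(maf ~ factor(day), data = tr)
  ms <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfres <- summary(fit)[[1]]["Residuals", "Df"]
  crit <- qtukey(0.95, nmeans = 5, df = dfres)
  means <- tapply(tr$maf, tr$day, mean)
  qstat <- abs(diff(means)) / sqrt(ms / 5)
  expect_equal(as.vector(qstat > crit), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("monotone trajectories are never bi-directional", {
  days <- c(2, 6, 10, 14, 22)
  set.seed(99)
  for (i in 1:25) {
    means <- sort(runif(5, 0.05, 0.6)) # non-decreasing means
    res <- categorize_locus(maf_trajectory(means, days, sd = 0.004,
                                           seed = i), TRUE)
    expect_true(res$category %in% c("G", "UD"))
  }
})

test_that("categorization is invariant to flipping allele orientation", {
  days <- c(2, 6, 10, 14, 22)
  for (i in 1:10) {
    means <- runif(5, 0.1, 0.6)
    tr <- maf_trajectory(means, days, seed = 100 + i)
    a <- categorize_locus(tr, TRUE)
    tr_flip <- tr
    tr_flip$maf <- 1 - tr$maf
    b <- categorize_locus(tr_flip, TRUE)
    expect_equal(a$category, b$category)
    if (!is.null(a$intervals)) {
      flip_map <- c(up = "down", down = "up")
      expect_equal(unname(flip_map[a$intervals$direction]),
                   b$intervals$direction)
      expect_equal(a$intervals$significant, b$intervals$significant)
    }
  }
})

test_that("degenerate within-day variance is flagged, not fatal", {
  days <- c(2, 6)
  tr <- data.frame(replicate = rep(paste0("R", 1:3), 2),
                   day = rep(days, each = 3),
                   maf = rep(c(0.2, 0.4), each = 3))
  expect_warning(res <- categorize_locus(tr, TRUE), "degenerate")
  expect_equal(res$category, "UD")
})

test_that("day 0 (unreplicated) is excluded from sequential comparisons", {
  days <- c(0, 2, 6, 10)
  tr <- rbind(data.frame(replicate = "egg", day = 0, maf = 0.5),
              maf_trajectory(c(0.10, 0.10, 0.40), c(2, 6, 10), seed = 5))
  res <- categorize_locus(tr, TRUE)
  expect_false(0 %in% res$intervals$day_from)
  expect_equal(res$intervals$day_from, c(2, 6))
})

test_that("Tukey false positives on neutral data stay near the nominal level", {
  sim <- simulate_pool_study(simulation_scenario(n_loci = 500, seed = 37,
                                                 scenario = "neutral"))
  maf <- compute_maf(sim$counts)
  n_false <- 0L
  for (l in unique(maf$per_sample$locus_id)) {
    res <- suppressWarnings(categorize_locus(
      maf$per_sample[maf$per_sample$locus_id == l, ], TRUE))
    if (any(res$intervals$significant)) n_false <- n_false + 1L
  }
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lte(n_false / 500, 0.05 + 3 * se)
})
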