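#' Per-locus binomial GLM test of allele-frequency change over development
#'
#' For every locus, fits a binomial generalized linear model of the
#' minor-versus-major read counts on sampling day treated as a multi-level
#' factor, and tests the age effect with the deviance (likelihood-ratio)
#' test against the intercept-only model. P-values are adjusted across loci
#' with the Benjamini-Hochberg procedure and significance called at
#' adjusted p < `alpha`.
#'
#' Age enters as a factor rather than a continuous covariate because
#' genotype-dependent mortality need not be monotone in time: a locus whose
#' frequency rises and then falls would be invisible to a linear term.
#'
#' @param table Filtered allele-count data frame (columns `locus_id`,
#'   `replicate`, `day`, `n_major`, `n_minor`).
#' @param alpha False-discovery rate for the significance call.
#' @param quasi Use quasi-binomial overdispersion correction (off by
#'   default; the plain binomial is the reference analysis).
#' @return A data frame of class `"af_test"` with one row per tested locus:
#'   `locus_id`, `deviance`, `df`, `deviance_p`, `q_bh`, `significant`.
#'   Loci with a single day of data are dropped with a warning.
#' @examples
#' sim <- simulate_pool_study(simulation_scenario(n_loci = 8, seed = 4,
#'                                                scenario = "directional"))
#' res <- test_age_effect(sim$counts)
#' table(res$significant)
#' @export
test_age_effect <- function(table, alpha = 0.05, quasi = FALSE) {
  loci <- unique(table$locus_id)
  fam <- if (quasi) stats::quasibinomial() else stats::binomial()
  rows <- lapply(loci, function(l) {
    d <- table[table$locus_id == l, , drop = FALSE]
    if (length(unique(d$day)) < 2) return(NULL)
    fit <- glm(cbind(n_minor, n_major) ~ factor(day), family = fam, data = d)
    dev <- fit$null.deviance - fit$deviance
    df <- fit$df.null - fit$df.residual
    if (quasi) {
      disp <- sum(stats::residuals(fit, type = "pearson")^2) /
        fit$df.residual
      p <- stats::pf(dev / df / max(disp, 1e-12), df, fit$df.residual,
                     lower.tail = FALSE)
    } else {
      p <- pchisq(dev, df, lower.tail = FALSE)
    }
    data.frame(locus_id = l, deviance = dev, df = df, deviance_p = p,
               stringsAsFactors = FALSE)
  })
  dropped <- loci[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning(length(dropped),
            " locus/loci with a single day of data excluded from testing")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no locus has two or more days of data")
  out$q_bh <- p.adjust(out$deviance_p, method = "BH")
  out$significant <- out$q_bh < alpha
  rownames(out) <- NULL
  class(out) <- c("af_test", "data.frame")
  out
}

# Tukey studentized-range comparisons of replicate MAFs across days for one
# locus; returns per-pair estimates for all pairwise day comparisons
tukey_day_pairs <- function(maf_by_day, alpha = 0.05, arcsine = FALSE) {
  d <- maf_by_day
  d$day <- factor(d$day)
  y <- if (arcsine) asin(sqrt(pmin(pmax(d$maf, 0), 1))) else d$maf
  d$y <- y
  means <- tapply(d$y, d$day, mean)
  fit <- aov(y ~ day, data = d)
  res_ms <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  degenerate <- is.na(res_ms) || res_ms < 1e-16
  if (degenerate) {
    # zero within-day variance: any difference in means is a sure change
    warning("degenerate within-day variance; unequal day means treated as ",
            "significant changes")
    days <- levels(d$day)
    pairs <- t(utils::combn(days, 2))
    est <- means[pairs[, 2]] - means[pairs[, 1]]
    out <- data.frame(day_from = as.numeric(pairs[, 1]),
                      day_to = as.numeric(pairs[, 2]),
                      diff = as.numeric(est),
                      p_adj = ifelse(abs(est) > 1e-12, 0, 1))
    return(out)
  }
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$day
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(day_from = as.numeric(vapply(nm, `[`, "", 2)),
             day_to = as.numeric(vapply(nm, `[`, "", 1)),
             diff = tk[, "diff"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Categorize the temporal pattern of allele-frequency change at one locus
#'
#' Runs a one-way analysis of variance of replicate minor-allele
#' frequencies across sampling days followed by Tukey's studentized-range
#' pairwise comparisons. The Tukey family covers all pairwise day
#' comparisons, but only sequential-day pairs (day 2 to 6, 6 to 10, ...)
#' feed the categorization:
#'
#' * `"G"` (gradual): the locus changes significantly overall but no
#'   sequential pair differs significantly;
#' * `"UD"` (uni-directional): one or more significant sequential changes,
#'   all in the same direction;
#' * `"BD"` (bi-directional): two or more significant sequential changes in
#'   opposing directions.
#'
#' Days with fewer than two replicates (the unreplicated day-0 egg pool)
#' are excluded, so sequential comparisons start at the first replicated
#' day. Loci that failed the overall test are labelled `"NS"` and carry no
#' interval calls.
#'
#' @param maf_by_day Data frame with columns `replicate`, `day`, `maf` for
#'   one locus.
#' @param overall_significant Did the locus pass the per-locus GLM test?
#' @param alpha Family-wise level of the Tukey comparisons.
#' @param arcsine Apply the arcsine-square-root variance-stabilizing
#'   transform before the ANOVA (off by default; raw frequencies are the
#'   reference analysis).
#' @return A list of class `"change_category"`: `category`, and `intervals`
#'   (data frame `day_from`, `day_to`, `direction`, `significant`,
#'   `p_adj`).
#' @export
categorize_locus <- function(maf_by_day, overall_significant, alpha = 0.05,
                             arcsine = FALSE) {
  if (!isTRUE(overall_significant)) {
    return(structure(list(category = "NS",
                          intervals = NULL), class = "change_category"))
  }
  reps_per_day <- tapply(maf_by_day$replicate, maf_by_day$day,
                         function(x) length(unique(x)))
  keep_days <- as.numeric(names(reps_per_day)[reps_per_day >= 2])
  d <- maf_by_day[maf_by_day$day %in% keep_days, , drop = FALSE]
  if (length(keep_days) < 2) {
    stop("fewer than two replicated days; cannot categorize")
  }
  pairs <- tukey_day_pairs(d, alpha = alpha, arcsine = arcsine)
  days <- sort(keep_days)
  seq_idx <- match(
    paste(days[-length(days)], days[-1]),
    paste(pairs$day_from, pairs$day_to)
  )
  seq_pairs <- pairs[seq_idx, , drop = FALSE]
  seq_pairs$direction <- ifelse(seq_pairs$diff >= 0, "up", "down")
  seq_pairs$significant <- seq_pairs$p_adj < alpha
  sig <- seq_pairs[seq_pairs$significant, , drop = FALSE]
  category <- if (nrow(sig) == 0) {
    "G"
  } else if (length(unique(sig$direction)) == 1) {
    "UD"
  } else {
    "BD"
  }
  structure(list(category = category,
                 intervals = seq_pairs[, c("day_from", "day_to", "direction",
                                           "significant", "p_adj")]),
            class = "change_category")
}

#' Categorize every significant locus in a study
#'
#' @param per_sample Per-sample MAF table from [compute_maf()]
#'   (`$per_sample`).
#' @param test_result An `"af_test"` data frame from [test_age_effect()].
#' @param alpha,arcsine Passed to [categorize_locus()].
#' @return A list with `categories` (data frame `locus_id`, `category`) and
#'   `intervals` (data frame of sequential-interval calls for categorized
#'   loci).
#' @export
categorize_loci <- function(per_sample, test_result, alpha = 0.05,
                            arcsine = FALSE) {
  sig <- setNames(test_result$significant, test_result$locus_id)
  loci <- test_result$locus_id
  cats <- character(length(loci))
  ints <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    l <- loci[i]
    res <- categorize_locus(
      per_sample[per_sample$locus_id == l, , drop = FALSE],
      overall_significant = sig[[l]], alpha = alpha, arcsine = arcsine
    )
    cats[i] <- res$category
    if (!is.null(res$intervals)) {
      ints[[i]] <- cbind(locus_id = l, res$intervals)
    }
  }
  list(
    categories = data.frame(locus_id = loci, category = cats,
                            stringsAsFactors = FALSE),
    intervals = do.call(rbind, ints)
  )
}
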