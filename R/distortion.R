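#' Assemble per-genotype distortion records for the settled stage
#'
#' For each locus, pairs the forecasted (simulated) genotype frequencies at
#' the final, settled-juvenile ("spat") stage with two candidate
#' expectations: the genotype composition of the fertilized egg pool, and
#' the Hardy-Weinberg expectation computed from the spat-pool minor allele
#' frequency. The record's `residual` is simulated minus the HWE
#' expectation.
#'
#' @param spat_states Matrix (loci x 3) of simulated spat genotype
#'   frequencies (e.g. forecaster ensemble means at the last day),
#'   rownames = locus ids.
#' @param spat_maf Per-locus MAF of the spat pool (empirical, same order).
#' @param egg_states Matrix (loci x 3) of egg-pool genotype frequencies.
#' @param initial_maf Per-locus egg-pool MAF (reporting stratifier).
#' @return Data frame with one row per locus x genotype: `locus_id`,
#'   `genotype`, `sim_freq`, `hwe_freq`, `egg_freq`, `residual`,
#'   `initial_maf`.
#' @export
distortion_records <- function(spat_states, spat_maf, egg_states,
                               initial_maf) {
  n <- nrow(spat_states)
  stopifnot(length(spat_maf) == n, nrow(egg_states) == n,
            length(initial_maf) == n)
  ids <- rownames(spat_states)
  if (is.null(ids)) ids <- sprintf("L%04d", seq_len(n))
  hwe <- hwe_expected(spat_maf)
  if (n == 1) hwe <- matrix(hwe, 1)
  gt <- c("AA", "AB", "BB")
  out <- do.call(rbind, lapply(1:3, function(g) {
    data.frame(locus_id = ids, genotype = gt[g],
               sim_freq = spat_states[, g], hwe_freq = hwe[, g],
               egg_freq = egg_states[, g],
               residual = spat_states[, g] - hwe[, g],
               initial_maf = initial_maf, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$locus_id, out$genotype), ]
  rownames(out) <- NULL
  out
}

#' Fit and compare the two genotype-distortion model formulations
#'
#' Two linear-model formulations of how spat-stage genotype frequencies
#' arise, each fitted separately per genotype class (AA, AB, BB):
#'
#' * model `egg`: simulated spat frequency regressed on the egg-pool
#'   frequency of the same genotype (change relative to the start);
#' * model `hwe`: simulated spat frequency regressed on the Hardy-Weinberg
#'   expectation from the spat-pool MAF (the null that final genotype
#'   frequencies reflect only final allele frequencies).
#'
#' Goodness of fit is compared by F-statistics and by Akaike and Bayesian
#' information criterion scores summed across genotype classes; the
#' formulation with the better (lower) information criteria is selected.
#'
#' @param records Data frame from [distortion_records()].
#' @return A list of class `"distortion_fit"`: `models` (nested list
#'   `[egg|hwe][[genotype]]` of `lm` fits), `comparison` (data frame of
#'   F, AIC, BIC per model and genotype plus totals), `selected`
#'   (`"egg"` or `"hwe"`), `records`.
#' @export
fit_distortion_models <- function(records) {
  n_loci <- length(unique(records$locus_id))
  if (n_loci < 10) {
    stop("need at least 10 loci to fit distortion models (got ",
         n_loci, ")")
  }
  gt <- c("AA", "AB", "BB")
  preds <- c(egg = "egg_freq", hwe = "hwe_freq")
  models <- list(egg = list(), hwe = list())
  comp <- list()
  for (m in names(preds)) {
    for (g in gt) {
      d <- records[records$genotype == g, , drop = FALSE]
      if (var(d[[preds[[m]]]]) < 1e-14) {
        warning("degenerate predictor (zero variance) for model '", m,
                "', genotype ", g, "; model skipped")
        next
      }
      fit <- lm(stats::reformulate(preds[[m]], "sim_freq"), data = d)
      fstat <- summary(fit)$fstatistic
      models[[m]][[g]] <- fit
      comp[[length(comp) + 1L]] <- data.frame(
        model = m, genotype = g,
        f_statistic = unname(fstat[1]), r_squared = summary(fit)$r.squared,
        aic = AIC(fit), bic = BIC(fit), stringsAsFactors = FALSE
      )
    }
  }
  comparison <- do.call(rbind, comp)
  totals <- aggregate(cbind(aic, bic) ~ model, data = comparison, FUN = sum)
  # lower AIC and BIC win; if they disagree, AIC decides
  sel <- totals$model[order(totals$aic + totals$bic, totals$aic)][1]
  structure(list(models = models, comparison = comparison,
                 totals = totals, selected = sel, records = records),
            class = "distortion_fit")
}

#' @export
print.distortion_fit <- function(x, ...) {
  cat("Genotype-distortion model comparison (per-genotype linear models)\n")
  print(x$totals, row.names = FALSE)
  cat("selected formulation:", x$selected, "\n")
  invisible(x)
}

#' Flag genotypes outside the model's prediction interval
#'
#' A locus-genotype record is an outlier when its simulated frequency lies
#' outside the two-sided prediction interval of the selected linear model
#' (fitted for its genotype class) at the stated level.
#'
#' @param fit A `"distortion_fit"`.
#' @param level Prediction-interval coverage (default 0.95).
#' @return The records data frame with added columns `fitted`, `pi_lo`,
#'   `pi_hi`, `outlier`.
#' @export
flag_outliers <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "distortion_fit"))
  records <- fit$records
  records$fitted <- NA_real_
  records$pi_lo <- NA_real_
  records$pi_hi <- NA_real_
  for (g in names(fit$models[[fit$selected]])) {
    ix <- which(records$genotype == g)
    m <- fit$models[[fit$selected]][[g]]
    pr <- predict(m, newdata = records[ix, , drop = FALSE],
                  interval = "prediction", level = level)
    records$fitted[ix] <- pr[, "fit"]
    records$pi_lo[ix] <- pr[, "lwr"]
    records$pi_hi[ix] <- pr[, "upr"]
  }
  records$outlier <- records$sim_freq < records$pi_lo |
    records$sim_freq > records$pi_hi
  records
}

#' Classify the distortion mode of loci with outlier genotypes
#'
#' A locus whose flagged genotypes show the major homozygote up and the
#' heterozygote/minor homozygote not up (`AA` residual > 0, `AB`/`BB`
#' residuals <= 0) is skewed towards fixation of the major allele
#' (`"fixation_skew"`, the signature of selection against a deleterious
#' minor allele). The opposite pattern centred on the heterozygote (`AB`
#' residual > 0, `AA`/`BB` <= 0) is `"heterozygote_excess"`; anything else
#' is `"other"`. Loci are also stratified by their initial (egg-pool) MAF
#' against `maf_threshold` — a reporting threshold, not a model input.
#'
#' @param flagged Records from [flag_outliers()].
#' @param maf_threshold Initial-MAF stratification boundary (default 0.20).
#' @return Data frame, one row per locus with at least one outlier
#'   genotype: `locus_id`, `class`, `stratum` (`"low_maf"`/`"high_maf"`),
#'   `initial_maf`.
#' @export
classify_distortions <- function(flagged, maf_threshold = 0.20) {
  stopifnot("outlier" %in% names(flagged))
  loci <- unique(flagged$locus_id[flagged$outlier])
  rows <- lapply(loci, function(l) {
    d <- flagged[flagged$locus_id == l, , drop = FALSE]
    r <- setNames(d$residual, d$genotype)
    cls <- if (r[["AA"]] > 0 && r[["AB"]] <= 0 && r[["BB"]] <= 0) {
      "fixation_skew"
    } else if (r[["AB"]] > 0 && r[["AA"]] <= 0 && r[["BB"]] <= 0) {
      "heterozygote_excess"
    } else {
      "other"
    }
    maf0 <- d$initial_maf[1]
    data.frame(locus_id = l, class = cls,
               stratum = if (maf0 < maf_threshold) "low_maf" else "high_maf",
               initial_maf = maf0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(locus_id = character(), class = character(),
                      stratum = character(), initial_maf = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}
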