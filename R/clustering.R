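#' Inter-interval allele-frequency changes for one locus
#'
#' First differences of the mean MAF trajectory in day order. A single
#' missing interior mean is imputed by linear interpolation between the
#' flanking days (and flagged); more than one consecutive missing time
#' point makes the locus unusable for clustering.
#'
#' @param maf Mean MAF per day (may contain `NA`).
#' @param days Sampling days, same length as `maf`.
#' @return A list with `delta` (named vector of changes, one per sequential
#'   interval), `imputed` (days whose mean was interpolated), or `NULL`
#'   with a warning when more than one consecutive time point is missing.
#' @examples
#' compute_delta_af(c(0.20, 0.30, 0.25), c(2, 6, 10))$delta
#' @export
compute_delta_af <- function(maf, days) {
  stopifnot(length(maf) == length(days), length(maf) >= 2)
  ord <- order(days)
  maf <- maf[ord]
  days <- days[ord]
  miss <- which(is.na(maf))
  imputed <- numeric(0)
  if (length(miss)) {
    if (any(diff(miss) == 1) || 1L %in% miss || length(maf) %in% miss) {
      warning("more than one consecutive missing time point (or a missing ",
              "endpoint); locus excluded from clustering")
      return(NULL)
    }
    for (j in miss) {
      w <- (days[j] - days[j - 1]) / (days[j + 1] - days[j - 1])
      maf[j] <- (1 - w) * maf[j - 1] + w * maf[j + 1]
    }
    imputed <- days[miss]
  }
  delta <- diff(maf)
  names(delta) <- paste0("d", days[-length(days)], "_", days[-1])
  list(delta = delta, imputed = imputed)
}

#' Build the matrix of allele-frequency-change vectors for clustering
#'
#' @param per_day Per-day mean MAF table (`locus_id`, `day`, `maf`), e.g.
#'   from [compute_maf()].
#' @param loci Loci to include (default: all in `per_day`).
#' @param include_day0 Include the day-0 to first-replicated-day interval
#'   (off by default; day 0 is a single unreplicated egg-pool sample).
#' @return A numeric matrix (loci x intervals) with rownames `locus_id`;
#'   loci with uncomputable change vectors are dropped with a warning.
#' @export
delta_af_matrix <- function(per_day, loci = NULL, include_day0 = FALSE) {
  if (is.null(loci)) loci <- unique(per_day$locus_id)
  if (!include_day0) per_day <- per_day[per_day$day > 0, , drop = FALSE]
  days <- sort(unique(per_day$day))
  rows <- lapply(loci, function(l) {
    d <- per_day[per_day$locus_id == l, , drop = FALSE]
    maf <- d$maf[match(days, d$day)]
    res <- suppressWarnings(compute_delta_af(maf, days))
    if (is.null(res)) NULL else res$delta
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " locus/loci dropped from the change matrix")
  }
  out <- do.call(rbind, rows[keep])
  rownames(out) <- loci[keep]
  out
}

# k-means whose result does not depend on input row order: rows are put in
# a canonical (lexicographic) order before seeded restarts, and assignments
# are mapped back; labels are renumbered by descending cluster size
canonical_kmeans <- function(x, k, seed, nstart = 25) {
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct rows (", n_distinct, ")")
  }
  ord <- do.call(order, as.data.frame(x))
  xs <- x[ord, , drop = FALSE]
  set.seed(seed)
  fit <- suppressWarnings(kmeans(xs, centers = k, nstart = nstart,
                                 iter.max = 100))
  cl_sorted <- fit$cluster
  cl <- integer(nrow(x))
  cl[ord] <- cl_sorted
  # relabel by descending membership; ties keep first-seen order
  sizes <- table(cl)
  new_lab <- setNames(rank(-as.numeric(sizes), ties.method = "first"),
                      names(sizes))
  relab <- as.integer(new_lab[as.character(cl)])
  centers <- fit$centers[as.integer(names(sizes))[order(new_lab)], ,
                         drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(cluster = relab, centers = centers,
       sizes = as.integer(sort(table(relab), decreasing = TRUE)))
}

# internal validity indices for a given partition
index_silhouette <- function(x, cl, dmat) {
  if (length(unique(cl)) < 2) return(NA_real_)
  mean(cluster::silhouette(cl, dmat)[, "sil_width"])
}

index_calinski_harabasz <- function(x, cl) {
  n <- nrow(x)
  k <- length(unique(cl))
  if (k < 2) return(NA_real_)
  grand <- colMeans(x)
  w <- 0
  b <- 0
  for (g in unique(cl)) {
    xg <- x[cl == g, , drop = FALSE]
    cg <- colMeans(xg)
    w <- w + sum(sweep(xg, 2, cg)^2)
    b <- b + nrow(xg) * sum((cg - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

index_davies_bouldin <- function(x, cl) {
  labs <- sort(unique(cl))
  k <- length(labs)
  if (k < 2) return(NA_real_)
  cents <- t(vapply(labs, function(g) colMeans(x[cl == g, , drop = FALSE]),
                    numeric(ncol(x))))
  s <- vapply(seq_along(labs), function(i) {
    xg <- x[cl == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xg, 2, cents[i, ])^2)))
  }, 0)
  db <- 0
  for (i in seq_len(k)) {
    r <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      m <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      r <- max(r, (s[i] + s[j]) / m)
    }
    db <- db + r
  }
  db / k
}

#' Choose the number of clusters by majority vote of validity indices
#'
#' Runs seeded k-means over a range of candidate `k` and scores each
#' partition with three internal validity indices: mean silhouette width
#' computed on a Manhattan dissimilarity matrix, the Calinski-Harabasz
#' criterion, and the Davies-Bouldin index. Each index votes for its best
#' `k` (silhouette and Calinski-Harabasz maximal, Davies-Bouldin minimal)
#' and the majority wins, ties broken toward smaller `k`. Validity indices
#' are undefined for a single cluster, so the candidate range starts at 2;
#' `k = 1` is returned (flagged degenerate) only when all rows are
#' identical.
#'
#' @param x Matrix of allele-frequency-change vectors (loci x intervals).
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed.
#' @param nstart Random restarts per k-means run.
#' @return A list of class `"k_selection"`: `k`, `votes` (per-index best
#'   k), `scores` (index values per candidate k), `degenerate`.
#' @export
select_k <- function(x, k_range = 2:20, seed = 1, nstart = 25) {
  if (nrow(unique(x)) == 1) {
    return(structure(list(k = 1L, votes = NULL, scores = NULL,
                          degenerate = TRUE), class = "k_selection"))
  }
  if (nrow(x) < max(k_range) + 1) {
    stop("need at least max(k_range) + 1 loci to scan k_range")
  }
  dmat <- dist(x, method = "manhattan")
  scores <- data.frame(k = k_range, silhouette = NA_real_,
                       calinski_harabasz = NA_real_,
                       davies_bouldin = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- canonical_kmeans(x, k, seed = seed + k, nstart = nstart)
    scores$silhouette[i] <- index_silhouette(x, fit$cluster, dmat)
    scores$calinski_harabasz[i] <- index_calinski_harabasz(x, fit$cluster)
    scores$davies_bouldin[i] <- index_davies_bouldin(x, fit$cluster)
  }
  votes <- c(
    silhouette = scores$k[which.max(scores$silhouette)],
    calinski_harabasz = scores$k[which.max(scores$calinski_harabasz)],
    davies_bouldin = scores$k[which.min(scores$davies_bouldin)]
  )
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  structure(list(k = min(winners), votes = votes, scores = scores,
                 degenerate = FALSE), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  if (x$degenerate) {
    cat("k selection: degenerate input (identical rows); k = 1\n")
  } else {
    cat("k selection: chosen k =", x$k, "\n  votes:",
        paste(names(x$votes), x$votes, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cluster allele-frequency-change trajectories with k-means
#'
#' Plain (Euclidean) k-means with seeded random restarts; cluster labels
#' are renumbered by descending membership so cluster 1 is always the
#' largest. The result is independent of input row order.
#'
#' @param x Matrix of change vectors (loci x intervals, rownames =
#'   locus ids).
#' @param k Number of clusters (`"auto"` to pick via [select_k()]).
#' @param seed Integer seed.
#' @param nstart Random restarts.
#' @return A list of class `"af_clustering"`: `k`, `assignments` (named
#'   integer vector), `centers`, `sizes`, and `selection` (the
#'   `"k_selection"` when `k = "auto"`).
#' @examples
#' m <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
#' rownames(m) <- paste0("L", 1:40)
#' cluster_trajectories(m, k = 2, seed = 1)$sizes
#' @export
cluster_trajectories <- function(x, k = "auto", seed = 1, nstart = 25) {
  sel <- NULL
  if (identical(k, "auto")) {
    sel <- select_k(x, seed = seed, nstart = nstart)
    k <- sel$k
  }
  stopifnot(k >= 1)
  if (k == 1) {
    fit <- list(cluster = rep(1L, nrow(x)),
                centers = matrix(colMeans(x), 1), sizes = nrow(x))
  } else {
    fit <- canonical_kmeans(x, k, seed = seed, nstart = nstart)
  }
  structure(
    list(k = as.integer(k),
         assignments = setNames(fit$cluster, rownames(x)),
         centers = fit$centers, sizes = fit$sizes, selection = sel),
    class = "af_clustering"
  )
}

#' @export
print.af_clustering <- function(x, ...) {
  cat("Trajectory clustering: k =", x$k, "| sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}
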