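#' Assign SNPs to linkage-group positions via shared scaffolds
#'
#' Each SNP inherits the centimorgan position of the mapped marker on its
#' genomic scaffold; when several markers share the scaffold, the one
#' nearest by base-pair distance wins (ties toward the smaller base-pair
#' position). SNPs on scaffolds absent from the map, or on scaffolds whose
#' markers span multiple linkage groups, are omitted with a reason code —
#' omissions are data, not errors.
#'
#' @param snps Data frame with columns `locus_id`, `scaffold`, `position`.
#' @param map Linkage-map data frame with columns `scaffold`, `lg`, `cM`,
#'   `marker_bp`.
#' @return Data frame, one row per input SNP: `locus_id`, `scaffold`,
#'   `position`, `lg`, `cM`, `assigned`, `reason` (`NA` when assigned,
#'   else `"scaffold_unmapped"` or `"multi_lg_scaffold"`).
#' @export
bridge_to_map <- function(snps, map) {
  lg_per_scaffold <- tapply(map$lg, map$scaffold,
                            function(x) length(unique(x)))
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    sc <- snps$scaffold[i]
    base <- data.frame(locus_id = snps$locus_id[i], scaffold = sc,
                       position = snps$position[i], lg = NA_character_,
                       cM = NA_real_, assigned = FALSE,
                       reason = NA_character_, stringsAsFactors = FALSE)
    m <- map[map$scaffold == sc, , drop = FALSE]
    if (nrow(m) == 0) {
      base$reason <- "scaffold_unmapped"
      return(base)
    }
    if (lg_per_scaffold[[sc]] > 1) {
      base$reason <- "multi_lg_scaffold"
      return(base)
    }
    d <- abs(m$marker_bp - snps$position[i])
    best <- m[order(d, m$marker_bp), , drop = FALSE][1, ]
    base$lg <- as.character(best$lg)
    base$cM <- best$cM
    base$assigned <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# mean adjacent centimorgan gap per linkage group
lg_mean_gaps <- function(assignments) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  gaps <- tapply(a$cM, a$lg, function(x) {
    x <- sort(x)
    if (length(x) < 2) return(NA_real_)
    mean(diff(x))
  })
  gaps[!is.na(gaps)]
}

#' Inter-marker distances within linkage groups
#'
#' Within each linkage group, assigned markers are sorted by centimorgan
#' position and adjacent gaps averaged; the group-level summary is the
#' mean of these per-LG means with the standard deviation taken among LGs.
#' With `clusters` supplied, the statistic is recomputed per trajectory
#' cluster on that cluster's markers only.
#'
#' @param assignments Output of [bridge_to_map()].
#' @param clusters Optional named vector (locus id -> cluster label).
#' @param all_pairs Use all within-LG pairwise distances instead of
#'   adjacent gaps.
#' @return Data frame with `group`, `mean_cM`, `sd_among_lg`, `n_lg`,
#'   `n_markers`; one row (`group = "all"`) without `clusters`, one per
#'   cluster otherwise. Groups without two markers in any LG get `NA`.
#' @examples
#' m <- data.frame(scaffold = "s1", lg = "LG1", cM = c(0, 10, 20),
#'                 marker_bp = c(100, 200, 300))
#' s <- data.frame(locus_id = c("a", "b", "c"), scaffold = "s1",
#'                 position = c(90, 210, 310))
#' intermarker_distances(bridge_to_map(s, m))
#' @export
intermarker_distances <- function(assignments, clusters = NULL,
                                  all_pairs = FALSE) {
  gap_stat <- function(a) {
    a <- a[a$assigned, , drop = FALSE]
    per_lg <- tapply(a$cM, a$lg, function(x) {
      x <- sort(x)
      if (length(x) < 2) return(NA_real_)
      if (all_pairs) mean(dist(x)) else mean(diff(x))
    })
    per_lg <- per_lg[!is.na(per_lg)]
    if (length(per_lg) == 0) {
      return(data.frame(mean_cM = NA_real_, sd_among_lg = NA_real_,
                        n_lg = 0L, n_markers = sum(a$assigned)))
    }
    data.frame(mean_cM = mean(per_lg),
               sd_among_lg = if (length(per_lg) > 1) sd(per_lg) else NA_real_,
               n_lg = length(per_lg), n_markers = sum(a$assigned))
  }
  if (is.null(clusters)) {
    return(cbind(group = "all", gap_stat(assignments)))
  }
  labs <- sort(unique(clusters))
  out <- do.call(rbind, lapply(labs, function(cl) {
    ids <- names(clusters)[clusters == cl]
    cbind(group = as.character(cl),
          gap_stat(assignments[assignments$locus_id %in% ids, ,
                               drop = FALSE]))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a linkage-map table for synthetic studies
#'
#' Emits mapped markers for a configurable fraction of scaffolds so the
#' bridging step is exercisable on synthetic data: each mapped scaffold
#' gets 1-3 markers on one linkage group at uniform centimorgan positions.
#'
#' @param scaffolds Character vector of scaffold names.
#' @param n_lg Number of linkage groups.
#' @param mapped_fraction Fraction of scaffolds carrying a mapped marker.
#' @param seed Integer seed.
#' @return Data frame `scaffold`, `lg`, `cM`, `marker_bp`.
#' @export
simulate_linkage_map <- function(scaffolds, n_lg = 10,
                                 mapped_fraction = 0.3, seed = 1) {
  set.seed(seed)
  scaffolds <- unique(scaffolds)
  mapped <- sample(scaffolds, ceiling(mapped_fraction * length(scaffolds)))
  rows <- lapply(mapped, function(sc) {
    k <- sample(1:3, 1)
    data.frame(scaffold = sc,
               lg = paste0("LG", sample.int(n_lg, 1)),
               cM = round(runif(k, 0, 100), 2),
               marker_bp = sort(sample.int(1e6, k)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
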