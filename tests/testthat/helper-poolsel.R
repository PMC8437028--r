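# shared fixtures, built in code at test time

# random point on the 2-simplex
random_state <- function() {
  u <- runif(3)
  u / sum(u)
}

# independent hand-arithmetic oracle for the Hardy-Weinberg fitness update
hw_update_oracle <- function(state, w) {
  wbar <- state[1] * w[1] + state[2] * w[2] + state[3] * w[3]
  new <- c(state[1] * w[1], state[2] * w[2], state[3] * w[3]) / wbar
  list(state = new, w_bar = wbar, maf = new[2] / 2 + new[3])
}

# count table for a single locus with fully controlled counts:
# counts = list(day = list(replicate = c(major, minor)))
locus_table <- function(counts, locus_id = "L1", tag_id = "tag_1") {
  rows <- list()
  for (day in names(counts)) {
    for (rep in names(counts[[day]])) {
      cnt <- counts[[day]][[rep]]
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = locus_id, scaffold = "s1", position = 100L,
        tag_id = tag_id, replicate = rep, day = as.numeric(day),
        n_major = cnt[1], n_minor = cnt[2], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# replicate MAF table for one locus: means named by day, common within-day sd
maf_trajectory <- function(means, days, n_rep = 5, sd = 0.005, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(days), function(j) {
    data.frame(replicate = paste0("R", seq_len(n_rep)), day = days[j],
               maf = rnorm(n_rep, means[j], sd), stringsAsFactors = FALSE)
  }))
}

# well-separated gaussian blobs on a delta-AF-like scale
make_blobs <- function(n_per, centres, sd = 0.01, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centres), 0, sd), n_per), 2,
          centres[i, ], "+")
  }))
  rownames(x) <- sprintf("L%04d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(nrow(centres)), each = n_per))
}

# best-match label agreement between a clustering and ground truth
label_agreement <- function(assigned, truth) {
  tab <- table(assigned, truth)
  sum(apply(tab, 2, max)) / length(truth)
}
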