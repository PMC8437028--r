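base_day <- function(major, minor, n_rep = 3) {
  stats::setNames(lapply(seq_len(n_rep), function(i) c(major, minor)),
                  paste0("R", seq_len(n_rep)))
}

# a minimal table that passes every rule: day 0 egg + two replicated days
clean_table <- function(locus_id = "L1", tag_id = "tag_1",
                        egg = c(90, 10)) {
  rbind(
    locus_table(list(`0` = list(egg = egg)), locus_id, tag_id),
    locus_table(list(`2` = base_day(80, 20), `6` = base_day(70, 30)),
                locus_id, tag_id)
  )
}

test_that("depth boundaries follow the stated rule exactly", {
  tab <- clean_table()
  extra <- locus_table(list(`2` = list(R4 = c(39, 10), R5 = c(40, 10))))
  res <- apply_filters(rbind(tab, extra), filter_config())
  depth <- res$table$n_major + res$table$n_minor
  # depth 49 removed, depth 50 retained
  expect_false(any(depth == 49))
  expect_true(any(depth == 50))
  expect_equal(res$report$depth_samples_removed, 1L)
})

test_that("tags carrying more than one SNP are excluded entirely", {
  tab <- rbind(clean_table("L1", "tagA"), clean_table("L2", "tagA"),
               clean_table("L3", "tagB"))
  res <- apply_filters(tab, filter_config())
  expect_setequal(unique(res$table$locus_id), "L3")
  expect_equal(res$report$multi_snp_tag_loci_removed, 2L)
})

test_that("the egg-pool MAF filter is strict and day-0 based", {
  tab <- rbind(clean_table("L1", "tag_1", egg = c(995, 5)),   # 0.005
               clean_table("L2", "tag_2", egg = c(980, 20)))  # 0.02
  res <- apply_filters(tab, filter_config())
  expect_setequal(unique(res$table$locus_id), "L2")
  expect_equal(res$report$egg_maf_loci_removed, 1L)
  # exactly 1% is not "greater than 1%"
  tab3 <- clean_table("L3", "tag_3", egg = c(99, 1))
  res3 <- apply_filters(tab3, filter_config())
  expect_equal(nrow(res3$table), 0L)
})

test_that("a table without day-0 samples is an explicit error", {
  tab <- locus_table(list(`2` = base_day(80, 20), `6` = base_day(70, 30)))
  expect_error(apply_filters(tab, filter_config()), "day-0")
})

test_that("the presence rule drops loci missing replicates at any day", {
  tab <- rbind(
    clean_table("L1", "tag_1"),
    # L2 has only 2 replicates on day 6
    rbind(locus_table(list(`0` = list(egg = c(90, 10))), "L2", "tag_2"),
          locus_table(list(`2` = base_day(80, 20),
                           `6` = base_day(70, 30, n_rep = 2)),
                      "L2", "tag_2"))
  )
  res <- apply_filters(tab, filter_config())
  expect_setequal(unique(res$table$locus_id), "L1")
  expect_equal(res$report$presence_loci_removed, 1L)
})

test_that("filtering is idempotent and the report sums are consistent", {
  sim <- simulate_pool_study(simulation_scenario(n_loci = 40, seed = 21,
                                                 depth_range = c(30, 1200)))
  res1 <- apply_filters(sim$counts, filter_config())
  res2 <- apply_filters(res1$table, filter_config())
  expect_identical(res1$table, res2$table)
  rep1 <- res1$report
  # locus removals per rule account exactly for the locus attrition
  expect_equal(rep1$loci_in - rep1$loci_out,
               rep1$multiallelic_loci_removed +
                 rep1$multi_snp_tag_loci_removed +
                 rep1$presence_loci_removed + rep1$egg_maf_loci_removed)
  # sample attrition = depth removals + samples of removed loci
  depth_ok <- with(sim$counts, n_major + n_minor >= 50 &
                     n_major + n_minor <= 1000)
  dropped_locus_samples <- sum(depth_ok &
                                 !(sim$counts$locus_id %in%
                                     res1$table$locus_id))
  expect_equal(rep1$samples_in - rep1$samples_out,
               rep1$depth_samples_removed + dropped_locus_samples)
  # a table built to pass every rule goes through unchanged
  clean <- simulate_pool_study(simulation_scenario(n_loci = 20, seed = 22,
                                                   initial_maf = runif(20, 0.2, 0.5)))
  resc <- apply_filters(clean$counts, filter_config())
  expect_identical(resc$table, clean$counts)
})

test_that("MAF designation is fixed globally and not re-flipped per day", {
  expect_equal(compute_maf(data.frame(
    locus_id = "L1", replicate = "R1", day = 2,
    n_major = 90, n_minor = 10))$per_sample$maf, 0.10)
  expect_equal(compute_maf(data.frame(
    locus_id = "L1", replicate = "R1", day = 2,
    n_major = 50, n_minor = 50))$per_sample$maf, 0.50)
  # allele 2 globally rarer but above 0.5 on the final day
  tab <- locus_table(list(`2` = list(R1 = c(90, 10), R2 = c(88, 12)),
                          `6` = list(R1 = c(85, 15), R2 = c(87, 13)),
                          `22` = list(R1 = c(40, 60), R2 = c(42, 58))))
  maf <- compute_maf(tab)
  # oracle: global mean per-sample fraction of allele 2 decides designation
  frac2 <- tab$n_minor / (tab$n_major + tab$n_minor)
  expect_lt(mean(frac2), 0.5) # allele 2 is globally minor...
  d22 <- maf$per_day[maf$per_day$day == 22, ]
  expect_equal(d22$maf, mean(c(0.60, 0.58))) # ...and day-22 values stay > 0.5
  expect_false(any(maf$per_sample$flipped))
  # mirrored counts give the mirrored (flipped) designation
  tab_m <- tab
  tab_m$n_major <- tab$n_minor
  tab_m$n_minor <- tab$n_major
  maf_m <- compute_maf(tab_m)
  expect_true(all(maf_m$per_sample$flipped))
  expect_equal(maf_m$per_day$maf, maf$per_day$maf)
})

test_that("zero-depth samples are excluded from means and flagged", {
  tab <- locus_table(list(`2` = list(R1 = c(50, 50), R2 = c(0, 0))))
  expect_warning(maf <- compute_maf(tab), "zero-depth")
  expect_true(maf$per_sample$zero_depth[2])
  expect_equal(maf$per_day$maf, 0.5)
  expect_equal(maf$per_day$n_replicates, 1L)
})
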