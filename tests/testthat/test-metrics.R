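make_headline_table <- function(scale = 1) {
  count_table(data.frame(
    disk = 1,
    section = rep(c("E", "C", "A"), 2),
    cell_class = rep(c("WBC", "RBC"), each = 3),
    count = scale * c(9515, 100, 385, 2000, 8000, 990000)))
}

test_that("count tables are validated row by row", {
  expect_error(count_table(data.frame(disk = 1, section = "E",
                                      cell_class = "WBC", count = -1)),
               "non-negative")
  expect_error(count_table(data.frame(disk = 1, section = "E",
                                      cell_class = "WBC", count = 1.5)),
               "row")
  expect_error(count_table(data.frame(disk = c(1, 1), section = c("E", "E"),
                                      cell_class = c("WBC", "WBC"),
                                      count = c(1, 2))),
               "duplicate")
  expect_error(count_table(data.frame(disk = 1, count = 3)), "lacks column")
})

test_that("retention/exclusion/enrichment match hand arithmetic", {
  m <- partition_metrics(make_headline_table(), "WBC", "RBC", "E")
  expect_equal(m$retention_pct, 95.15)
  expect_equal(m$exclusion_pct, 99.8)
  # enrichment: (9515/2000) / (10000/1e6)
  expect_equal(m$enrichment_fold, (9515 / 2000) / (10000 / 1e6))
  # perfect separation
  perfect <- count_table(data.frame(
    disk = 1, section = rep(c("E", "A"), 2),
    cell_class = rep(c("WBC", "RBC"), each = 2),
    count = c(500, 0, 0, 800)))
  mp <- partition_metrics(perfect, "WBC", "RBC", "E")
  expect_equal(mp$retention_pct, 100)
  expect_equal(mp$exclusion_pct, 100)
})

test_that("metrics are invariant under count rescaling", {
  m1 <- partition_metrics(make_headline_table(1), "WBC", "RBC", "E")
  m10 <- partition_metrics(make_headline_table(10), "WBC", "RBC", "E")
  expect_equal(m1$retention_pct, m10$retention_pct)
  expect_equal(m1$exclusion_pct, m10$exclusion_pct)
  expect_equal(m1$enrichment_fold, m10$enrichment_fold)
})

test_that("retention over all sections partitions to 100 percent", {
  tab <- make_headline_table()
  for (cls in c("WBC", "RBC")) {
    tot <- sum(vapply(unique(tab$section), function(s)
      partition_metrics(tab, cls, cls, s)$retention_pct, numeric(1)))
    expect_equal(tot, 100, tolerance = 1e-12)
  }
})

test_that("zero class totals yield missing metrics, never 0 or 100", {
  tab <- count_table(data.frame(
    disk = 1, section = rep(c("E", "A"), 2),
    cell_class = rep(c("WBC", "RBC"), each = 2),
    count = c(0, 0, 10, 90)))
  expect_warning(m <- partition_metrics(tab, "WBC", "RBC", "E"), "zero total")
  expect_true(is.na(m$retention_pct))
  expect_false(is.na(m$exclusion_pct))
})

test_that("across-disk summaries use mean and sample sd", {
  tab <- count_table(data.frame(
    disk = rep(1:3, each = 2),
    section = rep(c("E", "A"), 3),
    cell_class = "WBC",
    count = c(9400, 600, 9500, 500, 9645, 355)))
  per_disk <- partition_metrics(tab, "WBC", "WBC", "E")
  expect_equal(per_disk$retention_pct, c(94, 95, 96.45))
  smry <- summarize_disks(tab, "WBC", "WBC", "E")
  ret <- smry[smry$metric == "retention_pct", ]
  expect_equal(ret$mean, 95.15)
  expect_equal(ret$sd, sd(c(94, 95, 96.45)))
  # permutation invariance over disk order
  tab_perm <- count_table(tab[order(-tab$disk, tab$section), ])
  expect_equal(summarize_disks(tab_perm, "WBC", "WBC", "E")$mean, smry$mean)
  # identical disks have zero dispersion
  same <- count_table(data.frame(disk = rep(1:2, each = 2),
                                 section = rep(c("E", "A"), 2),
                                 cell_class = "WBC",
                                 count = rep(c(95, 5), 2)))
  expect_equal(summarize_disks(same, "WBC", "WBC", "E")$sd[1], 0)
  # single disk: mean only
  single <- summarize_disks(make_headline_table(), "WBC", "RBC", "E")
  expect_equal(single$mean[1], 95.15)
  expect_true(all(is.na(single$sd)))
})
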