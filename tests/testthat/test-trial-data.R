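test_that("long and wide layouts parse to the same dataset", {
  ds <- tiny_rcbd()
  long_path <- withr::local_tempfile(fileext = ".csv")
  write_trial(ds, long_path)
  got_long <- read_trial(long_path)
  expect_equal(got_long, ds)

  wide <- tidyr::pivot_wider(ds, names_from = trait, values_from = value)
  wide_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wide, wide_path)
  got_wide <- read_trial(wide_path, layout = "wide")
  expect_equal(got_wide, ds)
  expect_equal(length(unique(got_long$family)), 3)
  expect_equal(length(unique(got_long$replicate)), 2)
})

test_that("round-trip write/read preserves values and identifier order", {
  ds <- random_trial(7, g = 4, r = 2)
  # deliberately scramble family labels so order-preservation is visible
  ds$family <- paste0("fam_", rev(LETTERS)[as.integer(factor(ds$family))])
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(ds, path)
  expect_equal(read_trial(path), validate_trial(ds))
  expect_equal(unique(read_trial(path)$family), unique(ds$family))
})

test_that("validation rejects exactly the unbalanced datasets", {
  ds <- tiny_rcbd()
  expect_silent(validate_trial(ds))
  # one missing cell, named in the error
  expect_error(validate_trial(ds[-2, ]), "B, r2|A, r2",
               class = "mahp_balance_error")
  # duplicated cell
  expect_error(validate_trial(rbind(ds, ds[1, ])),
               class = "mahp_balance_error")
  # property: any dataset whose cell count matches the Cartesian product of
  # its identifier sets passes; dropping any single row fails
  for (seed in 1:3) {
    full <- random_trial(seed, g = 3, r = 2)
    expect_silent(validate_trial(full))
    drop <- sample(nrow(full), 1)
    expect_error(validate_trial(full[-drop, ]), class = "mahp_balance_error")
  }
})

test_that("read errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(family = "a", replicate = "r1",
                              condition = "normal", value = 1), path)
  expect_error(read_trial(path), "trait", class = "mahp_format_error")
  writeLines(c("family,replicate,condition,trait,value",
               "a,r1,normal,t,1.5", "a,r2,normal,t,oops"), path)
  expect_error(read_trial(path), "row 2", class = "mahp_parse_error")
  writeLines(c("family,replicate,condition,trait,value",
               "a,r1,weird,t,1"), path)
  expect_error(read_trial(path), "weird", class = "mahp_format_error")
})

test_that("family means average replicates and ignore replicate order", {
  ds <- tiny_rcbd()
  m <- family_means(ds, "normal")
  expect_equal(m$family, c("A", "B", "C"))
  expect_equal(m$t1, c(5, 9, 7))
  # permuting replicate labels (and their row order) leaves means alone
  swapped <- ds
  swapped$replicate <- c(r1 = "r2", r2 = "r1")[ds$replicate]
  swapped <- swapped[order(swapped$replicate), ]
  expect_equal(family_means(swapped, "normal"), m)
  expect_error(family_means(ds, "stress"), class = "mahp_lookup_error")
  # constant dataset
  const <- ds; const$value <- 3.5
  expect_equal(family_means(const, "normal")$t1, rep(3.5, 3))
})

test_that("condition_average is the elementwise mean of per-condition means", {
  ds <- random_trial(11, g = 4, r = 3)
  avg <- condition_average(ds)
  mn <- family_means(ds, "normal")
  ms <- family_means(ds, "stress")
  for (tr in unique(ds$trait)) {
    expect_equal(avg[[tr]], (mn[[tr]] + ms[[tr]]) / 2)
  }
  expect_error(condition_average(ds[ds$condition == "normal", ]),
               class = "mahp_precondition_error")
  # identical conditions reduce to family_means of either
  dup <- ds[ds$condition == "normal", ]
  dup2 <- dup; dup2$condition <- "stress"
  both <- rbind(dup, dup2)
  expect_equal(condition_average(both)[-1], family_means(both, "normal")[-1])
})
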