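test_that("inclusion rule follows the activity/concentration scoring", {
  expect_false(include_record(0, 4))
  expect_true(include_record(1, 2))
  expect_false(include_record(1, 1))
  expect_true(include_record(4, 4))
  expect_false(include_record(2, 0))
  # vectorized, and the filter can only shrink a sample
  a <- sample(0:4, 50, replace = TRUE); c_ <- sample(0:4, 50, replace = TRUE)
  expect_lte(sum(include_record(a, c_)), 50)
  expect_error(include_record(5, 1))
})

test_that("fat classification splits at score 3", {
  expect_equal(fat_class(2), "lean")
  expect_equal(fat_class(3), "fat")
  expect_equal(fat_class(0), "lean")
  expect_equal(fat_class(c(9, 1)), c("fat", "lean"))
  expect_error(fat_class(10), "0-9")
})

test_that("each bird enters each diagram once, keeping the first test", {
  rec <- make_records(3, c(100, 150, 200))
  rec$group <- "g1"
  twice <- rbind(rec, transform(rec[1, ], bearing = 355, date = "2005-08-20"))
  out <- dedupe_per_group(twice)
  expect_equal(nrow(out), 3)
  expect_equal(out$bearing[out$bird_id == "B001"], 100)  # earlier date kept
  # same bird in two different cells stays in both
  both <- rbind(rec, transform(rec[1, ], group = "g2"))
  expect_equal(nrow(dedupe_per_group(both)), 4)
  empty <- rec[0, ]
  expect_equal(nrow(dedupe_per_group(empty)), 0)
})

test_that("pipeline on printed-parameter synthetic data reproduces the group structure", {
  d <- generate_study(1)
  a <- suppressWarnings(run_analysis(d))
  expect_s3_class(a, "cage_analysis")
  expect_equal(nrow(a$groups), 7)
  expect_equal(a$groups$n[a$groups$group == "adult_clear"], 16)
  expect_equal(a$groups$n[a$groups$group == "all_juv_clear"], 43)
  expect_equal(a$groups$n[a$groups$group == "all_juv_overcast"], 45)
  expect_lt(a$groups$rayleigh_p[a$groups$group == "adult_clear"], 0.05)
  expect_lt(abs(a$groups$r[a$groups$group == "all_juv_clear"] - 0.25), 0.1)
  # activity contrasts built into the generator are recovered
  expect_lt(a$activity_tests$sky$p_value, 0.05)
})

test_that("pipeline output is deterministic", {
  d <- generate_study(7)
  a1 <- suppressWarnings(run_analysis(d))
  a2 <- suppressWarnings(run_analysis(d))
  expect_identical(a1$groups, a2$groups)
  expect_identical(a1$comparisons, a2$comparisons)
})

test_that("no duplicated (bird, group) pairs survive the pipeline", {
  for (s in c(2, 3)) {
    a <- suppressWarnings(run_analysis(generate_study(s)))
    expect_false(any(duplicated(a$included[, c("group", "bird_id")])))
    expect_lte(sum(a$groups$n[1:3]), nrow(generate_study(s)))
  }
})

test_that("test selection: Watson U2 is used when either sample is unoriented", {
  set.seed(121)
  oriented <- make_records(20, round(rvonmises(20, 113, 3) / 5) * 5,
                           capture_window = "early", bird_prefix = "E")
  uniform <- make_records(20, round(runif(20, 0, 360) / 5) * 5,
                          capture_window = "late", bird_prefix = "L")
  a <- suppressWarnings(run_analysis(rbind(oriented, uniform)))
  cmp <- a$comparisons[a$comparisons$group_a == "late_juv_clear" &
                         a$comparisons$group_b == "early_juv_clear", ]
  expect_equal(cmp$test, "watson_u2")
  # both oriented: Mardia F reported with the concentration test alongside
  set.seed(122)
  oriented2 <- make_records(20, round(rvonmises(20, 150, 3) / 5) * 5,
                            capture_window = "late", bird_prefix = "M")
  a2 <- suppressWarnings(run_analysis(rbind(oriented, oriented2)))
  cmp2 <- a2$comparisons[a2$comparisons$group_a == "late_juv_clear" &
                           a2$comparisons$group_b == "early_juv_clear", ]
  expect_equal(cmp2$test, "mardia_f")
  expect_false(is.na(cmp2$conc_p))
})

test_that("single-group data still yields group statistics with comparisons skipped", {
  set.seed(123)
  one <- make_records(15, round(rvonmises(15, 100, 2) / 5) * 5)
  a <- suppressWarnings(run_analysis(one))
  expect_equal(a$groups$n[a$groups$group == "early_juv_clear"], 15)
  expect_true(all(a$comparisons$test == "skipped"))
})

test_that("malformed records are rejected with the offending row named", {
  bad <- make_records(3, c(100, 150, 200))
  bad$bearing[2] <- 101  # not a multiple of 5
  expect_error(run_analysis(bad), "row 2")
  bad2 <- make_records(3, c(100, 150, 200))
  bad2$sky[3] <- "foggy"
  expect_error(run_analysis(bad2), "row 3")
})

test_that("decisive groups keep their published significance in most replicates", {
  # groups printed far from the 5% threshold land on the printed side in a
  # clear majority of seeds; borderline groups (printed p 0.059/0.065) split
  seeds <- 1:25
  sig <- sapply(seeds, function(s) {
    a <- suppressWarnings(run_analysis(generate_study(s)))
    stats::setNames(a$groups$rayleigh_p < 0.05, a$groups$group)
  })
  expect_gte(mean(sig["adult_clear", ]), 0.7)         # printed P < 0.002
  expect_gte(mean(sig["all_juv_overcast", ]), 0.6)    # printed P = 0.01
  expect_gte(mean(sig["early_juv_clear", ]), 0.6)     # printed P = 0.007
  expect_gte(mean(sig["early_juv_overcast", ]), 0.6)  # printed P = 0.024
  expect_gte(mean(sig["late_juv_overcast", ]), 0.6)   # printed P = 0.021
  for (borderline in c("all_juv_clear", "late_juv_clear")) {
    expect_gt(mean(sig[borderline, ]), 0.1)
    expect_lt(mean(sig[borderline, ]), 0.9)
  }
})

test_that("externally supplied per-individual bearing tables run through the pipeline", {
  # replication hook: a supplement-style table of per-individual bearings is
  # accepted via the same CSV contract and analysed verbatim
  set.seed(321)
  supp <- rbind(
    make_records(16, round(rvonmises(16, 114, vonmises_kappa(0.61)) / 5) * 5,
                 age = "adult", bird_prefix = "A"),
    make_records(22, round(rvonmises(22, 113, vonmises_kappa(0.47)) / 5) * 5,
                 bird_prefix = "J")
  )
  path <- tempfile(fileext = ".csv")
  utils::write.csv(supp, path, row.names = FALSE)
  a <- suppressWarnings(run_analysis(read_cage_records(path)))
  expect_equal(a$groups$n[a$groups$group == "adult_clear"], 16)
  cmp <- a$comparisons[a$comparisons$group_a == "adult_clear", ]
  expect_true(cmp$test %in% c("mardia_f", "watson_u2"))
  unlink(path)
})
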