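# Data model: reading, validation, aggregation, plant-top totals.

test_that("a well-formed table round-trips losslessly through CSV", {
  rec <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rec, path)
  back <- read_measurements(path, default_design())
  expect_equal(back, rec)
  expect_identical(nrow(validate_measurements(rec, default_design(),
                                              action = "report")), 0L)
})

test_that("schema, value and integrity violations are rejected with row ids", {
  d <- default_design()
  rec <- tiny_records()

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec[, setdiff(names(rec), "abundance_15n")], path,
                   row.names = FALSE)
  expect_error(read_measurements(path, d), class = "fixn_schema_error")

  dup <- rbind(rec, rec[3, ])
  expect_error(validate_measurements(dup, d),
               class = "fixn_integrity_error")
  expect_match(tryCatch(validate_measurements(dup, d),
                        error = conditionMessage),
               "Control/1/50/stalk")

  neg <- rec
  neg$dry_biomass[2] <- -1
  expect_error(validate_measurements(neg, d), class = "fixn_value_error")

  early_ear <- rec
  early_ear$part[early_ear$part == "stalk" & early_ear$block == 1 &
                   early_ear$treatment == "Trt" &
                   early_ear$harvest_day == 50][1] <- "ear"
  rep <- validate_measurements(early_ear, d, action = "report")
  expect_true("part_not_available" %in% rep$rule)
  expect_match(rep$detail[rep$rule == "part_not_available"][1],
               "before anthesis")
})

test_that("%N concentration input converts to total N on load", {
  rec <- tiny_records()
  alt <- rec
  alt$percent_n <- alt$total_n / (alt$dry_biomass * 10)
  alt$total_n <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(alt, path, row.names = FALSE)
  back <- read_measurements(path, default_design())
  expect_equal(back$total_n, rec$total_n)
})

test_that("summaries report the arithmetic mean and SEM over blocks", {
  d <- default_design()
  rec <- do.call(rbind, lapply(1:4, function(b) {
    data.frame(treatment = c("Control", "Trt"), block = b,
               harvest_day = 50L, part = "stalk",
               dry_biomass = c(2, b), total_n = c(100, 10 * b),
               abundance_15n = 1.0, stringsAsFactors = FALSE)
  }))
  s <- summarise_parts(rec, d)
  trt_n <- s[s$response == "total_n" & s$treatment == "Trt", ]
  expect_equal(trt_n$mean, 25)                       # mean(10,20,30,40)
  expect_equal(trt_n$sem, sd(c(10, 20, 30, 40)) / 2) # 12.9099/2 ~ 6.455
  ctl_b <- s[s$response == "dry_biomass" & s$treatment == "Control", ]
  expect_equal(ctl_b$sem, 0)                          # identical values
  expect_equal(unique(s$n_replicates), 4L)
})

test_that("single-replicate cells yield SEM 0 with a warning", {
  d <- default_design()
  rec <- tiny_records()[1:3, ]
  expect_warning(s <- summarise_parts(rec, d), "single replicate")
  expect_true(all(s$sem == 0))
})

test_that("group means of a large simulated trial recover generator truth", {
  sc <- trial_scenario(treatments = c("Control", "Trt"),
                       ndfa = c(Control = 0, Trt = 0.2),
                       parts = c("stalk", "old_leaves"),
                       blocks = 200, seed = 11)
  rec <- simulate_trial(sc)
  s <- summarise_parts(rec, default_design())
  bm <- s[s$response == "dry_biomass" & s$part == "stalk" &
            s$harvest_day == 50, ]
  truth <- sc$biomass_mean[["50"]][["stalk"]]
  expect_true(all(abs(bm$mean - truth) <= 3 * bm$sem))
})

test_that("plant-top totals sum the above-ground parts per replicate", {
  d <- default_design()
  # one 'block' per tabulated mean reproduces the printed plant-top sums
  mk <- function(treatment, harvest, n_by_part) {
    data.frame(treatment = treatment, block = 1L, harvest_day = harvest,
               part = names(n_by_part), dry_biomass = 1,
               total_n = unname(n_by_part), abundance_15n = 1,
               stringsAsFactors = FALSE)
  }
  ctl <- mk("Control", 50L, c(tassel = 121, young_leaves = 104,
                              ear_leaves = 104, old_leaves = 81,
                              stalk = 206))
  s1 <- mk("S1r1", 65L, c(tassel = 124, young_leaves = 234,
                          ear_leaves = 182, old_leaves = 168,
                          stalk = 391, ear = 223))
  tot <- suppressWarnings(plant_top_totals(rbind(ctl, s1), d))
  expect_equal(tot$top_n[tot$treatment == "Control"], 616)  # printed: 617
  expect_equal(tot$top_n[tot$treatment == "S1r1"], 1322)    # printed: 1321
  expect_false(any(tot$incomplete))

  gap <- plant_top_totals(ctl[ctl$part != "stalk", ], d)
  expect_true(gap$incomplete)
  expect_match(attr(gap, "gaps")$missing, "stalk")
})

test_that("aggregating then totalling commutes with totalling then aggregating", {
  rec <- simulate_trial(trial_scenario(seed = 4))
  d <- default_design()
  tot <- plant_top_totals(rec, d)
  # mean over blocks of per-replicate totals
  agg1 <- tapply(tot$top_n, paste(tot$treatment, tot$harvest_day), mean)
  # totals of per-cell means (balanced data)
  s <- summarise_parts(rec, d)
  tn <- s[s$response == "total_n", ]
  agg2 <- tapply(tn$mean, paste(tn$treatment, tn$harvest_day), sum)
  expect_equal(agg1[names(agg2)], agg2, tolerance = 1e-10)
})
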