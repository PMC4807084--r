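# Atom excess, WAE, %Ndfa, fixed N, rates, per-area scaling, pipeline.

test_that("atom excess is measured abundance minus natural background", {
  expect_equal(atom_excess(0.3663), 0)
  expect_equal(atom_excess(1.4663), 1.1)
  expect_equal(atom_excess(0.3000), -0.0663)   # below background, kept
  expect_error(atom_excess(NaN), class = "fixn_value_error")
  expect_error(atom_excess(0), class = "fixn_value_error")
})

test_that("WAE is the total-N-weighted mean of part excesses", {
  # constant excess: weights are irrelevant
  w <- weighted_atom_excess(c(a = 1, b = 1, c = 1), c(a = 5, b = 99, c = 1))
  expect_equal(w$wae, 1)
  # single part passes through
  w1 <- weighted_atom_excess(c(stalk = 0.823), c(stalk = 500))
  expect_equal(w1$wae, 0.823)
  # five-part worked example; direct arithmetic oracle
  ae <- c(tassel = 0.815, young_leaves = 0.808, ear_leaves = 0.797,
          old_leaves = 1.056, stalk = 0.924)
  tn <- c(tassel = 186, young_leaves = 176, ear_leaves = 169,
          old_leaves = 147, stalk = 280)
  w5 <- weighted_atom_excess(ae, tn)
  expect_equal(w5$wae, sum(ae * tn) / sum(tn))
  expect_equal(w5$wae, 0.8794, tolerance = 1e-4)
  expect_equal(w5$total_n_mg, 958)
})

test_that("WAE rejects mismatched keys, roots and zero total N", {
  expect_error(weighted_atom_excess(c(a = 1), c(b = 1)),
               class = "fixn_key_error")
  expect_error(weighted_atom_excess(c(root = 1), c(root = 1)),
               class = "fixn_key_error")
  expect_error(weighted_atom_excess(c(a = 1, b = 2), c(a = 0, b = 0)),
               class = "fixn_value_error")
})

test_that("WAE is convex in part excesses and invariant to N rescaling", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    ae <- setNames(runif(k, -0.1, 2), paste0("p", 1:k))
    tn <- setNames(runif(k, 1, 500), names(ae))
    w <- weighted_atom_excess(ae, tn)
    expect_gte(w$wae, min(ae) - 1e-12)
    expect_lte(w$wae, max(ae) + 1e-12)
    w2 <- weighted_atom_excess(ae, tn * runif(1, 0.01, 100))
    expect_equal(w$wae, w2$wae, tolerance = 1e-12)
  }
})

test_that("%Ndfa follows the isotope-dilution formula", {
  expect_equal(round(ndfa_percent(0.875, 1.259), 1), 30.5)
  expect_equal(round(ndfa_percent(0.651, 0.885), 1), 26.4)
  expect_equal(ndfa_percent(0.7, 0.7), 0)
  expect_equal(ndfa_percent(0, 0.885), 100)
  expect_lt(ndfa_percent(1.3, 1.0), 0)   # above-reference: negative, kept
  expect_error(ndfa_percent(0.5, 0), class = "fixn_reference_error")
  expect_error(ndfa_percent(0.5, -0.1), class = "fixn_reference_error")
})

test_that("%Ndfa is decreasing in sample excess, increasing in reference", {
  set.seed(7)
  s <- sort(runif(50, 0, 2))
  expect_true(all(diff(ndfa_percent(s, 1.1)) < 0))
  r <- sort(runif(50, 0.05, 2))
  expect_true(all(diff(ndfa_percent(0.8, r)) > 0))
})

test_that("fixed N, fixation rate and per-hectare scaling", {
  expect_equal(round(n_fixed(26.4, 223), 1), 58.9)   # printed 58.8
  expect_equal(n_fixed(0, 500), 0)
  expect_equal(n_fixed(50, 100), 50)
  expect_equal(round(fixation_rate(175.7, 50), 1), 3.5)
  expect_equal(round(fixation_rate(198.4, 65), 1), 3.1)
  expect_equal(fixation_rate(0, 50), 0)
  expect_error(fixation_rate(10, 0), class = "fixn_value_error")
  expect_equal(round(scale_per_area(304, 53333), 1), 16.2)
  expect_equal(round(scale_per_area(262, 53333), 1), 14.0)
  expect_equal(scale_per_area(0, 53333), 0)
})

test_that("part-level fixed N sums to plant-top fixed N under a common reference", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    ae <- setNames(runif(k, 0, 1.5), paste0("p", 1:k))
    tn <- setNames(runif(k, 10, 400), names(ae))
    ref <- runif(1, 1.6, 2.5)
    by_part <- sum(n_fixed(ndfa_percent(ae, ref), tn))
    w <- weighted_atom_excess(ae, tn)
    by_top <- n_fixed(ndfa_percent(w$wae, ref), w$total_n_mg)
    expect_equal(by_part, by_top, tolerance = 1e-9)
  }
})

test_that("pipeline recovers construction truth and zeroes on self-reference", {
  d <- default_design()
  rec <- tiny_records(ndfa_trt = 0.30)
  for (agg in c("mean_first", "replicate_first")) {
    nd <- ndfa_pipeline(rec, d, aggregation = agg)
    trt <- nd[nd$treatment == "Trt", ]
    expect_equal(trt$ndfa_pct, rep(30, nrow(trt)), tolerance = 1e-9)
    ctl <- nd[nd$treatment == "Control", ]
    expect_equal(ctl$ndfa_pct, rep(0, nrow(ctl)), tolerance = 1e-9)
  }
})

test_that("mean_first equals replicate_first when every block is identical", {
  d <- default_design()
  rec <- tiny_records(ndfa_trt = 0.22)   # blocks are exact copies
  a <- ndfa_pipeline(rec, d, aggregation = "mean_first")
  b <- ndfa_pipeline(rec, d, aggregation = "replicate_first")
  key <- function(x) paste(x$treatment, x$harvest_day, x$part)
  expect_equal(a$ndfa_pct, b$ndfa_pct[match(key(a), key(b))],
               tolerance = 1e-12)
})

test_that("negative estimates are flagged, and clipped only on request", {
  d <- default_design()
  rec <- tiny_records(ndfa_trt = 0.30)
  # make the sample more enriched than the reference
  hot <- rec
  hot$abundance_15n[hot$treatment == "Trt"] <- 1.9
  nd <- ndfa_pipeline(hot, d)
  expect_true(all(nd$ndfa_pct[nd$treatment == "Trt"] < 0))
  expect_true(all(grepl("negative_ndfa",
                        nd$flags[nd$treatment == "Trt"])))
  cl <- ndfa_pipeline(hot, d, clip_negative = TRUE)
  expect_true(all(cl$ndfa_pct[cl$treatment == "Trt"] == 0))
  expect_true(all(grepl("clipped", cl$flags[cl$treatment == "Trt"])))
})

test_that("a missing reference part names the offending cell", {
  d <- default_design()
  rec <- tiny_records()
  rec <- rec[!(rec$treatment == "Control" & rec$part == "stalk"), ]
  err <- tryCatch(ndfa_pipeline(rec, d), error = identity)
  expect_s3_class(err, "fixn_reference_error")
  expect_match(conditionMessage(err), "stalk")
})

test_that("summary-table estimation reproduces tabulated plant-top estimates", {
  s <- trial_summary_tables()
  nd <- ndfa_from_summary(s, default_design())
  top <- nd[nd$scope == "plant_top", ]
  g <- function(tr, h) top$ndfa_pct[top$treatment == tr &
                                      top$harvest_day == h]
  expect_equal(round(g("S1r1", 50), 1), 30.5)
  expect_equal(round(g("S1r1", 65), 1), 25.5)
  expect_equal(round(g("UPMB10", 50), 1), 21.7)
  ear <- nd[nd$part == "ear" & nd$treatment == "S1r1", ]
  expect_equal(round(ear$ndfa_pct, 1), 26.4)
})
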