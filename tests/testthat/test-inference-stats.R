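# ANOVA, Duncan's multiple range test, letter displays, correlations.

test_that("one-way ANOVA handles flat and degenerate inputs", {
  set.seed(1)
  y <- rnorm(30, 10, 1)                     # equal means, nonzero spread
  g <- rep(letters[1:3], 10)
  fit <- one_way_anova(y, g)
  expect_lt(fit$table$statistic[1], 4)
  expect_gt(fit$table$p_value[1], 0.01)
  flat <- one_way_anova(rep(5, 12), rep(letters[1:3], 4))
  expect_equal(flat$table$statistic[1], 0)
  expect_equal(flat$table$p_value[1], 1)
  expect_error(one_way_anova(y, rep("a", 30)),
               class = "fixn_design_error")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(6, 10, 2); b <- rnorm(6, 12, 2)
    fit <- one_way_anova(c(a, b), rep(c("a", "b"), each = 6))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(fit$table$statistic[1], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(fit$table$p_value[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("a large injected treatment effect is detected at four blocks", {
  set.seed(5)
  hits <- replicate(20, {
    y <- c(rnorm(4, 10, 1), rnorm(4, 16, 1))
    one_way_anova(y, rep(c("ctl", "trt"), each = 4))$table$p_value[1] < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("two-way ANOVA needs two levels per factor and full cells", {
  set.seed(3)
  y <- rnorm(16)
  s <- rep(c("a", "b"), each = 8)
  h <- rep(rep(c("d50", "d65"), each = 4), 2)
  fit <- two_way_anova(y, s, h)
  expect_identical(fit$table$term,
                   c("strain", "harvest", "strain:harvest", "residual"))
  expect_error(two_way_anova(y, s, rep("d50", 16)),
               class = "fixn_design_error")
  err <- tryCatch(two_way_anova(y[1:12], s[1:12],
                                c(h[1:8], rep("d50", 4))),
                  error = identity)
  expect_s3_class(err, "fixn_design_error")
  expect_match(conditionMessage(err), "b:d65")
})

test_that("crossed harvest slopes produce a detectable interaction", {
  set.seed(8)
  hits <- replicate(30, {
    g <- expand.grid(strain = c("a", "b"), harvest = c(50, 65), rep = 1:4)
    mu <- with(g, ifelse(strain == "a", 1, -1) * ifelse(harvest == 50, 2, -2))
    y <- mu + rnorm(nrow(g))
    two_way_anova(y, g$strain, g$harvest)$table$p_value[3] < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("DMRT letter displays behave at the extremes", {
  ld <- duncan_mrt(c(a = 5, b = 5, c = 5), ms_error = 1, df_error = 9,
                   n_per_group = 4)
  expect_true(all(ld$groups$letters == "a"))
  ld2 <- duncan_mrt(c(lo = 1, hi = 100), ms_error = 0.5, df_error = 6,
                    n_per_group = 4)
  expect_equal(sort(ld2$groups$letters), c("a", "b"))
  expect_equal(ld2$groups$letters[ld2$groups$mean == 100], "a")
  expect_error(duncan_mrt(c(a = 1, b = 2), 1, 6, n_per_group = c(3, 5)),
               class = "fixn_design_error")
})

test_that("an auxin-assay-like instance reproduces the published pattern", {
  # five strains, means 12.99 / 10.70 / 10.55 / 10.10 / 4.91, small spread
  set.seed(7)
  means <- c(Fr1 = 12.99, S3r2 = 10.70, S1r1 = 10.55, UPMB10 = 10.10,
             Br1 = 4.91)
  vals <- unlist(lapply(means, function(m) rnorm(3, m, 0.35)))
  ld <- dmrt_letters(vals, rep(names(means), each = 3))
  lett <- setNames(ld$groups$letters, ld$groups$group)
  expect_equal(lett[["Fr1"]], "a")
  expect_equal(unname(lett[c("S3r2", "S1r1", "UPMB10")]),
               c("b", "b", "b"))
  expect_equal(lett[["Br1"]], "c")
})

test_that("letter displays match the brute-force all-pairs oracle", {
  set.seed(20)
  for (i in 1:150) {
    k <- sample(2:6, 1)
    means <- setNames(runif(k, 0, 10), paste0("g", 1:k))
    ms <- runif(1, 0.05, 4); df <- sample(4:30, 1); n <- sample(2:6, 1)
    ld <- duncan_mrt(means, ms, df, n)
    got <- letters_nonsig(ld, names(means))
    want <- oracle_duncan_nonsig(means, ms, df, n)
    expect_identical(got, want)
  }
})

test_that("DMRT at two groups collapses to Fisher's LSD", {
  set.seed(21)
  for (i in 1:100) {
    means <- setNames(runif(2, 0, 5), c("a", "b"))
    ms <- runif(1, 0.1, 3); df <- sample(3:25, 1); n <- sample(2:8, 1)
    ld <- duncan_mrt(means, ms, df, n)
    differ <- ld$groups$letters[1] != ld$groups$letters[2]
    lsd <- abs(diff(means)) / sqrt(2 * ms / n) > qt(0.975, df)
    expect_identical(differ, unname(lsd))
  }
})

test_that("letter displays are invariant to input order", {
  set.seed(22)
  means <- setNames(runif(5, 0, 8), paste0("g", 1:5))
  ld1 <- duncan_mrt(means, 0.5, 12, 4)
  perm <- sample(5)
  ld2 <- duncan_mrt(means[perm], 0.5, 12, 4)
  expect_equal(ld1$groups, ld2$groups)
})

test_that("within/between-harvest letters mirror the trial table layout", {
  rec <- tiny_records(ndfa_trt = 0.5)   # big separation on abundance
  lt <- trial_letters(rec, "abundance_15n", default_design())
  stalk50 <- lt[lt$part == "stalk" & lt$harvest_day == 50, ]
  # Control is more enriched: letter a; the diluted treatment: letter b
  expect_equal(stalk50$letter_within[stalk50$treatment == "Control"], "a")
  expect_equal(stalk50$letter_within[stalk50$treatment == "Trt"], "b")
  # identical values across harvests: shared uppercase letter
  expect_true(all(lt$letter_between[lt$part == "stalk"] == "A"))
})

test_that("Pearson matrices match hand-computed correlations", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 2 * x + 1
  z <- -x
  w <- c(2.1, 1.8, 3.9, 3.1, 5.4, 4.9)
  cm <- pearson_matrix(data.frame(x = x, y = y, z = z, w = w))
  expect_equal(unname(cm$r["x", "y"]), 1)
  expect_equal(unname(cm$r["x", "z"]), -1)
  hand <- sum((x - mean(x)) * (w - mean(w))) /
    sqrt(sum((x - mean(x))^2) * sum((w - mean(w))^2))
  expect_equal(unname(cm$r["x", "w"]), hand)
  expect_equal(unname(cm$p["x", "w"]),
               cor.test(x, w)$p.value)
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
})

test_that("zero-variance variables are reported missing with a diagnostic", {
  cm <- pearson_matrix(data.frame(a = 1:6, b = rep(2, 6)))
  expect_true(is.na(cm$r["a", "b"]))
  expect_match(cm$diagnostics, "zero-variance")
})
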