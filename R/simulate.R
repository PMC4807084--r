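#' Define a synthetic trial scenario
#'
#' Describes a randomised-complete-block, multi-harvest isotope-dilution
#' trial to be simulated by [simulate_trial()]. The isotope model is the
#' three-pool mixing implied by the tracer design: plant N is drawn from
#' labelled fertiliser (enrichment `fertilizer_enrichment`), unlabelled
#' soil N and atmospheric N2. Only the fertiliser pool carries excess 15N,
#' so the true tissue excess is
#' \deqn{AE = f_{fert} \, E_{fert} \, (1 - Ndfa)}
#' where `f_fert` is the fertiliser-derived fraction of the non-atmospheric
#' plant N at each harvest and `Ndfa` the true atmospheric fraction
#' (identically 0 for the reference treatment). Measured abundance adds the
#' natural background and Gaussian instrument noise.
#'
#' Defaults reproduce the conditions of a greenhouse maize trial: six
#' treatments (an uninoculated reference plus five rhizobacterial
#' inoculants), four blocks, destructive harvests at 50 and 65 days after
#' planting, urea tracer at 4.72 atom % excess, and part biomass and N
#' concentration at agronomically realistic levels with ~10% biological
#' CVs.
#'
#' @param treatments treatment labels; the first is the reference unless
#'   `reference_treatment` says otherwise.
#' @param reference_treatment label of the non-fixing reference; its true
#'   Ndfa is forced to 0.
#' @param ndfa named numeric vector of true Ndfa fractions (0 <= x < 1) per
#'   treatment, recycled over parts and harvests; or a data.frame with
#'   columns `treatment`, `part`, `harvest_day`, `ndfa` for full control.
#' @param parts plant parts to simulate (ear only at the final harvest).
#' @param biomass_mean named list: per harvest (as character day), named
#'   vector of part biomass means, g/plant.
#' @param biomass_cv coefficient of variation of biomass (lognormal).
#' @param ncon_mean named vector of part N concentrations, % of dry matter.
#' @param ncon_cv coefficient of variation of N concentration (lognormal).
#' @param block_sd standard deviation (log scale) of the multiplicative
#'   block effect on biomass.
#' @param instrument_sd additive Gaussian noise on measured abundance,
#'   atom %.
#' @param f_fert named numeric vector per harvest (character day): the
#'   fertiliser-derived fraction of non-atmospheric plant N.
#' @param fertilizer_enrichment,natural_abundance,harvest_days,blocks
#'   trial constants; see [design_config()].
#' @param seed mandatory integer seed making the scenario reproducible.
#' @return object of class `trial_scenario`.
#' @export
trial_scenario <- function(
    treatments = c("Control", "UPMB10", "Br1", "Fr1", "S1r1", "S3r2"),
    reference_treatment = treatments[1L],
    ndfa = c(Control = 0, UPMB10 = 0.20, Br1 = 0.12, Fr1 = 0.25,
             S1r1 = 0.29, S3r2 = 0.10),
    parts = setdiff(plant_parts(), "root"),
    biomass_mean = list(
      `50` = c(tassel = 6.0, young_leaves = 4.9, ear_leaves = 5.5,
               old_leaves = 4.7, stalk = 16.1, ear = NA),
      `65` = c(tassel = 5.5, young_leaves = 6.2, ear_leaves = 5.5,
               old_leaves = 5.0, stalk = 23.5, ear = 10.0)),
    biomass_cv = 0.10,
    ncon_mean = c(tassel = 2.4, young_leaves = 2.9, ear_leaves = 2.7,
                  old_leaves = 2.7, stalk = 1.5, ear = 1.9),
    ncon_cv = 0.10,
    block_sd = 0.05,
    instrument_sd = 0.02,
    f_fert = c(`50` = 0.267, `65` = 0.234),
    fertilizer_enrichment = 4.72,
    natural_abundance = 0.3663,
    harvest_days = c(50L, 65L),
    blocks = 4L,
    seed = 1L) {
  if (is.data.frame(ndfa)) {
    stopifnot(all(c("treatment", "part", "harvest_day", "ndfa") %in%
                    names(ndfa)))
    bad <- ndfa$ndfa < 0 | ndfa$ndfa >= 1
  } else {
    stopifnot(!is.null(names(ndfa)), all(treatments %in% names(ndfa)))
    bad <- ndfa < 0 | ndfa >= 1
  }
  if (any(bad)) {
    fixn_error("fixn_value_error", "true Ndfa must lie in [0, 1)")
  }
  stopifnot(biomass_cv >= 0, ncon_cv >= 0, block_sd >= 0,
            instrument_sd >= 0, blocks >= 1,
            all(as.character(harvest_days) %in% names(f_fert)),
            all(f_fert > 0), all(f_fert <= 1),
            reference_treatment %in% treatments,
            is.numeric(seed), length(seed) == 1L)
  # the reference fixes nothing, by definition of the method
  if (is.data.frame(ndfa)) {
    ndfa$ndfa[ndfa$treatment == reference_treatment] <- 0
  } else {
    ndfa[reference_treatment] <- 0
  }
  structure(
    list(treatments = treatments,
         reference_treatment = reference_treatment,
         ndfa = ndfa, parts = parts,
         biomass_mean = biomass_mean, biomass_cv = biomass_cv,
         ncon_mean = ncon_mean, ncon_cv = ncon_cv,
         block_sd = block_sd, instrument_sd = instrument_sd,
         f_fert = f_fert,
         fertilizer_enrichment = fertilizer_enrichment,
         natural_abundance = natural_abundance,
         harvest_days = as.integer(harvest_days),
         blocks = as.integer(blocks),
         seed = as.integer(seed)),
    class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("synthetic isotope-dilution trial scenario\n")
  cat("  ", length(x$treatments), "treatments x", x$blocks, "blocks x",
      length(x$harvest_days), "harvests;",
      length(x$parts), "plant parts\n")
  cat("  reference:", x$reference_treatment,
      "| tracer:", x$fertilizer_enrichment, "atom % excess",
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' True tissue atom excess implied by a scenario
#'
#' The noise-free three-pool prediction `f_fert * E_fert * (1 - Ndfa)` for
#' every treatment x part x harvest cell.
#'
#' @param scenario a [trial_scenario()].
#' @return data.frame `treatment`, `part`, `harvest_day`, `ndfa_true`,
#'   `excess_true`.
#' @export
scenario_truth <- function(scenario) {
  grid <- expand.grid(treatment = scenario$treatments,
                      part = scenario$parts,
                      harvest_day = scenario$harvest_days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[!(grid$part == "ear" &
                   grid$harvest_day < max(scenario$harvest_days)), ]
  if (is.data.frame(scenario$ndfa)) {
    key <- paste(scenario$ndfa$treatment, scenario$ndfa$part,
                 scenario$ndfa$harvest_day)
    grid$ndfa_true <- scenario$ndfa$ndfa[
      match(paste(grid$treatment, grid$part, grid$harvest_day), key)]
    if (any(is.na(grid$ndfa_true))) {
      fixn_error("fixn_key_error",
                 "ndfa data.frame does not cover every simulated cell")
    }
  } else {
    grid$ndfa_true <- unname(scenario$ndfa[grid$treatment])
  }
  ff <- scenario$f_fert[as.character(grid$harvest_day)]
  grid$excess_true <- unname(ff) * scenario$fertilizer_enrichment *
    (1 - grid$ndfa_true)
  rownames(grid) <- NULL
  grid
}

#' Simulate a replicate-level trial table
#'
#' Draws a complete randomised-complete-block measurement table from a
#' [trial_scenario()]: biomass is lognormal around its part mean with the
#' scenario CV times a multiplicative lognormal block effect; N
#' concentration is lognormal; total N is their product; tissue excess
#' follows the three-pool model ([scenario_truth()]); measured abundance
#' adds the natural background and Gaussian instrument noise and is
#' truncated below at a hair above zero (an emission spectrometer cannot
#' report a negative abundance). Byte-identical output under the same
#' seed; the caller's RNG state is left untouched.
#'
#' @param scenario a [trial_scenario()].
#' @param seed overrides `scenario$seed` when given.
#' @return measurement data.frame (see [read_measurements()]).
#' @export
simulate_trial <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "trial_scenario"))
  # force the seed before touching the RNG state: a caller may pass a
  # freshly drawn seed, whose draw must not be rolled back on exit
  seed <- as.integer(seed)
  truth <- scenario_truth(scenario)
  key <- paste(truth$treatment, truth$part, truth$harvest_day)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)

  lnorm_cv <- function(n, mean, cv) {
    if (cv == 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
  }
  block_eff <- if (scenario$block_sd == 0) rep(1, scenario$blocks) else
    stats::rlnorm(scenario$blocks, -scenario$block_sd^2 / 2,
                  scenario$block_sd)

  rows <- vector("list", nrow(truth) * scenario$blocks)
  idx <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth$treatment[i]; p <- truth$part[i]; h <- truth$harvest_day[i]
    bm_mean <- scenario$biomass_mean[[as.character(h)]][[p]]
    if (is.null(bm_mean) || is.na(bm_mean)) next
    nc_mean <- scenario$ncon_mean[[p]]
    for (b in seq_len(scenario$blocks)) {
      bm <- lnorm_cv(1L, bm_mean, scenario$biomass_cv) * block_eff[b]
      nc <- lnorm_cv(1L, nc_mean, scenario$ncon_cv)
      ab <- truth$excess_true[i] + scenario$natural_abundance +
        stats::rnorm(1L, 0, scenario$instrument_sd)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        treatment = tr, block = b, harvest_day = h, part = p,
        dry_biomass = bm,
        total_n = bm * nc * 10,       # g x % -> mg N
        abundance_15n = max(ab, 1e-6),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(idx)])
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Parameter-recovery report
#'
#' Joins an estimated [ndfa_pipeline()] table against the simulating
#' scenario's truth and reports bias, RMSE and (when SEMs are available)
#' the coverage of mean +/- 2 SEM intervals, across part-level cells.
#'
#' @param estimates an `ndfa_table` from [ndfa_pipeline()].
#' @param scenario the [trial_scenario()] that generated the data.
#' @return object of class `recovery_metrics`: list with `cells` (per-cell
#'   truth and estimate), `bias`, `rmse`, `coverage` (NA without SEMs).
#' @export
recovery_report <- function(estimates, scenario) {
  truth <- scenario_truth(scenario)
  est <- estimates[estimates$scope == "part", , drop = FALSE]
  key_t <- paste(truth$treatment, truth$part, truth$harvest_day)
  key_e <- paste(est$treatment, est$part, est$harvest_day)
  m <- match(key_e, key_t)
  if (any(is.na(m))) {
    fixn_error("fixn_key_error",
               "estimates contain cells the scenario does not define")
  }
  cells <- data.frame(
    treatment = est$treatment, part = est$part,
    harvest_day = est$harvest_day,
    ndfa_true = 100 * truth$ndfa_true[m],
    ndfa_est = est$ndfa_pct,
    ndfa_sem = est$ndfa_sem,
    stringsAsFactors = FALSE)
  err <- cells$ndfa_est - cells$ndfa_true
  coverage <- if (all(is.na(cells$ndfa_sem))) NA_real_ else
    mean(abs(err) <= 2 * cells$ndfa_sem, na.rm = TRUE)
  structure(list(cells = cells,
                 bias = mean(err),
                 rmse = sqrt(mean(err^2)),
                 coverage = coverage),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("Ndfa recovery over %d cells: bias %+.2f, RMSE %.2f",
              nrow(x$cells), x$bias, x$rmse))
  if (!is.na(x$coverage)) {
    cat(sprintf(", +/-2 SEM coverage %.0f%%", 100 * x$coverage))
  }
  cat("\n")
  invisible(x)
}

#' Scenario parameterised from the packaged trial summaries
#'
#' Builds a [trial_scenario()] whose cell means equal the packaged
#' two-harvest maize trial's tabulated means: per-treatment part biomass
#' and N concentration are back-computed from the biomass and total-N
#' tables, CVs from the tabulated SEMs (CV = SEM * sqrt(n) / mean), and
#' the true Ndfa per treatment x part x harvest from the atom-excess table
#' via the isotope-dilution estimator (reference treatment forced to 0).
#'
#' @param seed scenario seed.
#' @return a `trial_scenario` whose grid matches the packaged tables; the
#'   per-treatment mean structure is carried in the `cell_means` element
#'   used by [simulate_trial()] via the `ndfa` data.frame and per-part
#'   means.
#' @export
reference_trial_scenario <- function(seed = 1L) {
  s <- trial_summary_tables()
  design <- design_config("Control")
  ae <- s[s$response == "atom_excess" & s$treatment != "harvest_mean", ]
  tn <- s[s$response == "total_n" & s$treatment != "harvest_mean", ]
  bm <- s[s$response == "dry_biomass" & s$treatment != "harvest_mean", ]
  parts <- setdiff(plant_parts(), "root")

  # true Ndfa per treatment x part x harvest from the tabulated means
  nd <- ndfa_from_summary(s[s$treatment != "harvest_mean", ], design)
  nd <- nd[nd$scope == "part", c("treatment", "part", "harvest_day",
                                 "ndfa_pct")]
  nd$ndfa <- pmin(pmax(nd$ndfa_pct / 100, 0), 0.999)
  nd$ndfa_pct <- NULL

  # pooled (across treatments) part means for biomass / N concentration
  harvests <- sort(unique(bm$harvest_day))
  biomass_mean <- lapply(harvests, function(h) {
    v <- vapply(parts, function(p) {
      x <- bm$mean[bm$part == p & bm$harvest_day == h]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
    v
  })
  names(biomass_mean) <- as.character(harvests)
  ncon_mean <- vapply(parts, function(p) {
    tnp <- tn[tn$part == p, ]
    bmp <- bm[bm$part == p, ]
    m <- match(paste(tnp$treatment, tnp$harvest_day),
               paste(bmp$treatment, bmp$harvest_day))
    mean(tnp$mean / (bmp$mean[m] * 10))   # mg N / (g * 10) -> %N
  }, numeric(1))
  # CVs back-computed from tabulated SEMs (n = 4)
  biomass_cv <- stats::median(bm$sem * sqrt(bm$n_replicates) / bm$mean)
  ncon_cv <- stats::median(tn$sem * sqrt(tn$n_replicates) / tn$mean)

  # fertiliser-derived fraction implied by the reference's plant-top excess
  ref_top <- ae[ae$treatment == "Control" & ae$part == "plant_top", ]
  f_fert <- stats::setNames(ref_top$mean / design$fertilizer_enrichment,
                            as.character(ref_top$harvest_day))

  trial_scenario(
    treatments = unique(tn$treatment),
    reference_treatment = "Control",
    ndfa = nd,
    parts = parts,
    biomass_mean = biomass_mean,
    biomass_cv = biomass_cv,
    ncon_mean = ncon_mean,
    ncon_cv = ncon_cv,
    f_fert = f_fert,
    harvest_days = harvests,
    seed = seed)
}
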