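#' Atom percent excess
#'
#' Corrects a measured 15N abundance for the natural 15N background. A
#' non-positive result means the tissue is at or below background (an
#' unlabelled or anomalous sample); it is returned as-is, never clipped --
#' downstream estimators flag such values.
#'
#' @param measured_abundance measured 15N abundance, atom % (0 < x < 100).
#' @param natural_abundance natural background, atom % (default 0.3663).
#' @return numeric vector of atom % 15N excess.
#' @examples
#' atom_excess(1.4663)           # 1.1
#' atom_excess(0.3663)           # exactly at background: 0
#' @export
atom_excess <- function(measured_abundance, natural_abundance = 0.3663) {
  if (any(!is.finite(measured_abundance))) {
    fixn_error("fixn_value_error", "non-finite measured abundance")
  }
  if (any(measured_abundance <= 0 | measured_abundance >= 100)) {
    fixn_error("fixn_value_error",
               "measured abundance must lie in (0, 100) atom %")
  }
  measured_abundance - natural_abundance
}

#' Total-N-weighted plant-top atom excess (WAE)
#'
#' The plant-top enrichment is the convex combination of part-level atom
#' excesses weighted by each part's total N:
#' \deqn{WAE = \sum_i AE_i TN_i / \sum_i TN_i}
#' so it always lies between the smallest and largest part excess, and is
#' invariant to rescaling all N weights by a constant.
#'
#' @param part_excess named numeric vector of atom % excess per part.
#' @param part_n named numeric vector of total N (mg/plant) per part; must
#'   carry exactly the same part names. Roots are not analysed for 15N and
#'   may not appear.
#' @return an object of class `wae_result`: list with elements `wae`,
#'   `total_n_mg`, `parts_used`.
#' @examples
#' weighted_atom_excess(c(stalk = 0.9, ear = 0.6), c(stalk = 300, ear = 200))
#' @export
weighted_atom_excess <- function(part_excess, part_n) {
  if (is.null(names(part_excess)) || is.null(names(part_n)) ||
      anyDuplicated(names(part_excess)) || anyDuplicated(names(part_n)) ||
      !setequal(names(part_excess), names(part_n))) {
    fixn_error("fixn_key_error",
               "part_excess and part_n must carry the same unique part names")
  }
  if ("root" %in% names(part_excess)) {
    fixn_error("fixn_key_error",
               "roots are excluded from isotope computations")
  }
  part_n <- part_n[names(part_excess)]
  if (any(part_n < 0) || sum(part_n) <= 0) {
    fixn_error("fixn_value_error",
               "total N weights must be non-negative with a positive sum")
  }
  structure(
    list(wae = sum(part_excess * part_n) / sum(part_n),
         total_n_mg = sum(part_n),
         parts_used = names(part_excess)),
    class = "wae_result"
  )
}

#' @export
print.wae_result <- function(x, ...) {
  cat(sprintf("plant-top WAE %.3f atom %% excess over %.0f mg N (%s)\n",
              x$wae, x$total_n_mg, paste(x$parts_used, collapse = ", ")))
  invisible(x)
}

#' Proportion of nitrogen derived from the atmosphere
#'
#' The isotope-dilution estimator: a fixing plant dilutes the fertiliser
#' label with unlabelled atmospheric N, so
#' \deqn{%Ndfa = 100 (1 - AE_{fixing} / AE_{reference})}
#' where the reference is the non-fixing treatment's excess for the same
#' part (or WAE for the plant top) at the same harvest. Values are not
#' clipped: a sample more enriched than its reference yields a negative
#' estimate, which downstream tables flag.
#'
#' @param sample_excess atom % excess of the (potentially) fixing sample.
#' @param reference_excess atom % excess of the non-fixing reference;
#'   must be strictly positive.
#' @return %Ndfa, numeric (vectorised).
#' @examples
#' ndfa_percent(0.875, 1.259)   # 30.5
#' ndfa_percent(0.651, 0.885)   # 26.4
#' @export
ndfa_percent <- function(sample_excess, reference_excess) {
  if (any(!is.finite(sample_excess)) || any(!is.finite(reference_excess))) {
    fixn_error("fixn_value_error", "non-finite atom excess")
  }
  if (any(reference_excess <= 0)) {
    fixn_error("fixn_reference_error",
               "reference excess must be strictly positive")
  }
  100 * (1 - sample_excess / reference_excess)
}

#' Amount of N2 fixed
#'
#' @param ndfa_pct %Ndfa.
#' @param total_n total N of the same scope, mg/plant.
#' @return mg N fixed per plant (vectorised).
#' @examples
#' n_fixed(26.4, 223)
#' @export
n_fixed <- function(ndfa_pct, total_n) {
  stopifnot(all(total_n >= 0))
  ndfa_pct / 100 * total_n
}

#' Mean N2 fixation rate since planting
#'
#' @param n_fixed mg N fixed per plant (cumulative at the harvest).
#' @param days_after_planting harvest day (> 0).
#' @return mg N per plant per day.
#' @examples
#' fixation_rate(175.7, 50)   # 3.5
#' @export
fixation_rate <- function(n_fixed, days_after_planting) {
  if (any(days_after_planting <= 0)) {
    fixn_error("fixn_value_error", "days_after_planting must be positive")
  }
  n_fixed / days_after_planting
}

#' Per-hectare extrapolation of fixed N
#'
#' @param n_fixed mg N fixed per plant.
#' @param planting_density plants per hectare.
#' @return kg N per hectare.
#' @examples
#' scale_per_area(304, 53333)  # 16.2
#' @export
scale_per_area <- function(n_fixed, planting_density) {
  stopifnot(all(planting_density > 0))
  n_fixed * planting_density * 1e-6
}

#' Full %Ndfa estimation pipeline
#'
#' Estimates %Ndfa and mg N2 fixed for every treatment x harvest, both per
#' part (each part compared against the reference treatment's same part and
#' harvest) and for the whole plant top (WAE compared against the
#' reference's WAE).
#'
#' Two aggregation paths are provided. `replicate_first` (default)
#' estimates per block -- pairing each block's excess with the reference
#' treatment's mean excess -- then averages across blocks and reports the
#' SEM; this is the path that produces per-cell standard errors.
#' `mean_first` computes a single estimate from the cell means and carries
#' no SEM; it is the only path reproducible from published summary tables.
#'
#' @param records validated measurement data.frame.
#' @param design a [design_config()].
#' @param aggregation `"replicate_first"` or `"mean_first"`.
#' @param clip_negative if `TRUE`, negative %Ndfa estimates are clipped to
#'   zero (and flagged `clipped`); default reports them as-is with a
#'   `negative_ndfa` flag.
#' @return data.frame of class `ndfa_table` with columns `treatment`,
#'   `harvest_day`, `scope` (`part`/`plant_top`), `part`, `ndfa_pct`,
#'   `ndfa_sem`, `n_fixed_mg`, `n_fixed_sem`, `sample_excess`,
#'   `reference_excess`, `n`, `flags`.
#' @export
ndfa_pipeline <- function(records, design,
                          aggregation = c("replicate_first", "mean_first"),
                          clip_negative = FALSE) {
  aggregation <- match.arg(aggregation)
  records <- validate_measurements(records, design)
  records$atom_excess <- atom_excess(records$abundance_15n,
                                     design$natural_abundance)
  ref_lab <- design$reference_treatment
  harvests <- sort(unique(records$harvest_day))
  treatments <- unique(records$treatment)
  out <- list()

  for (h in harvests) {
    dh <- records[records$harvest_day == h, , drop = FALSE]
    parts <- intersect(isotope_parts(h, design), unique(dh$part))
    refh <- dh[dh$treatment == ref_lab, , drop = FALSE]

    ref_part_mean <- vapply(parts, function(p) {
      x <- refh$atom_excess[refh$part == p]
      if (!length(x)) {
        fixn_error("fixn_reference_error", paste0(
          "reference part missing for cell (", ref_lab, ", D", h, ", ", p,
          ")"))
      }
      mean(x)
    }, numeric(1))
    if (any(ref_part_mean <= 0)) {
      fixn_error("fixn_reference_error", paste0(
        "non-positive reference excess at D", h, " for part(s): ",
        paste(parts[ref_part_mean <= 0], collapse = ", ")))
    }

    # per-block plant-top WAE of the reference
    ref_wae_blocks <- .block_wae(refh, parts)
    ref_wae <- if (aggregation == "mean_first") {
      ref_tn <- vapply(parts, function(p) mean(refh$total_n[refh$part == p]),
                       numeric(1))
      sum(ref_part_mean * ref_tn) / sum(ref_tn)
    } else {
      mean(ref_wae_blocks$wae)
    }

    for (tr in treatments) {
      dt <- dh[dh$treatment == tr, , drop = FALSE]
      if (!nrow(dt)) next
      # part scope ------------------------------------------------------
      for (p in intersect(parts, unique(dt$part))) {
        ae <- dt$atom_excess[dt$part == p]
        tn <- dt$total_n[dt$part == p]
        out[[length(out) + 1L]] <- .ndfa_row(
          tr, h, "part", p, ae, tn, ref_part_mean[[p]],
          aggregation, clip_negative)
      }
      # plant-top scope --------------------------------------------------
      if (all(parts %in% dt$part)) {
        if (aggregation == "mean_first") {
          ae_m <- vapply(parts, function(p) mean(dt$atom_excess[dt$part == p]),
                         numeric(1))
          tn_m <- vapply(parts, function(p) mean(dt$total_n[dt$part == p]),
                         numeric(1))
          w <- weighted_atom_excess(ae_m, tn_m)
          out[[length(out) + 1L]] <- .ndfa_row(
            tr, h, "plant_top", "plant_top", w$wae, w$total_n_mg, ref_wae,
            "mean_first", clip_negative)
        } else {
          wb <- .block_wae(dt, parts)
          out[[length(out) + 1L]] <- .ndfa_row(
            tr, h, "plant_top", "plant_top", wb$wae, wb$total_n, ref_wae,
            "replicate_first", clip_negative)
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ndfa_table", "data.frame")
  out
}

# per-block WAE for one treatment's records at one harvest
.block_wae <- function(d, parts) {
  blocks <- sort(unique(d$block))
  wae <- tn <- rep(NA_real_, length(blocks))
  for (i in seq_along(blocks)) {
    db <- d[d$block == blocks[i] & d$part %in% parts, , drop = FALSE]
    if (!setequal(db$part, parts)) {
      fixn_error("fixn_integrity_error", paste0(
        "block ", blocks[i], " of treatment ", d$treatment[1L],
        " is missing part(s): ",
        paste(setdiff(parts, db$part), collapse = ", ")))
    }
    w <- weighted_atom_excess(
      stats::setNames(db$atom_excess, db$part),
      stats::setNames(db$total_n, db$part))
    wae[i] <- w$wae
    tn[i] <- w$total_n_mg
  }
  data.frame(block = blocks, wae = wae, total_n = tn)
}

# one output row; ae/tn are per-block vectors (replicate_first) or scalars
.ndfa_row <- function(treatment, harvest_day, scope, part, ae, tn,
                      ref_excess, aggregation, clip_negative) {
  sem <- function(x) if (length(x) < 2L) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  if (aggregation == "mean_first") {
    ae <- mean(ae); tn <- mean(tn)
    nd <- ndfa_percent(ae, ref_excess)
    nf <- n_fixed(nd, tn)
    nd_m <- nd; nd_s <- NA_real_; nf_m <- nf; nf_s <- NA_real_
    s_exc <- ae; n_obs <- 1L
  } else {
    nd <- ndfa_percent(ae, ref_excess)
    nf <- n_fixed(nd, tn)
    nd_m <- mean(nd); nd_s <- sem(nd)
    nf_m <- mean(nf); nf_s <- sem(nf)
    s_exc <- mean(ae); n_obs <- length(ae)
  }
  flags <- character()
  if (any(ae <= 0)) flags <- c(flags, "below_background")
  if (nd_m < 0) flags <- c(flags, "negative_ndfa")
  if (clip_negative && nd_m < 0) {
    nd_m <- 0; nf_m <- 0; flags <- c(flags, "clipped")
  }
  data.frame(treatment = treatment, harvest_day = harvest_day,
             scope = scope, part = part,
             ndfa_pct = nd_m, ndfa_sem = nd_s,
             n_fixed_mg = nf_m, n_fixed_sem = nf_s,
             sample_excess = s_exc, reference_excess = ref_excess,
             n = n_obs, flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' %Ndfa from published-style summary tables
#'
#' Mean-first estimation directly from a long-format summary table (as
#' returned by [summarise_parts()] or [trial_summary_tables()]): each
#' part's mean excess is compared with the reference treatment's same part
#' and harvest, and the plant top uses the tabulated plant-top WAE when a
#' `part == "plant_top"` atom-excess row is present (the usual case for
#' published tables, whose WAE was computed from raw replicates), falling
#' back to the WAE of the tabulated part means otherwise.
#'
#' @param summary long summary data.frame with columns `response`,
#'   `treatment`, `part`, `harvest_day`, `mean` (and optionally `sem`).
#' @param design a [design_config()].
#' @param use_printed_top use tabulated plant-top WAE rows when present
#'   (default `TRUE`).
#' @param clip_negative clip negative estimates to zero.
#' @return an `ndfa_table` data.frame (see [ndfa_pipeline()]); SEMs are
#'   `NA` because cell means carry no replicate information.
#' @export
ndfa_from_summary <- function(summary, design, use_printed_top = TRUE,
                              clip_negative = FALSE) {
  ae <- summary[summary$response == "atom_excess", , drop = FALSE]
  tn <- summary[summary$response == "total_n", , drop = FALSE]
  if (!nrow(ae)) {
    fixn_error("fixn_schema_error", "no atom_excess rows in summary")
  }
  ref_lab <- design$reference_treatment
  pick <- function(d, tr, p, h) {
    v <- d$mean[d$treatment == tr & d$part == p & d$harvest_day == h]
    if (length(v) == 1L) v else NA_real_
  }
  out <- list()
  harvests <- sort(unique(ae$harvest_day))
  treatments <- setdiff(unique(ae$treatment), "harvest_mean")
  for (h in harvests) {
    parts <- intersect(isotope_parts(h, design),
                       unique(ae$part[ae$harvest_day == h]))
    ref_part <- vapply(parts, function(p) pick(ae, ref_lab, p, h),
                       numeric(1))
    if (any(is.na(ref_part))) {
      fixn_error("fixn_reference_error", paste0(
        "reference part missing for cell (", ref_lab, ", D", h, ", ",
        paste(parts[is.na(ref_part)], collapse = ", "), ")"))
    }
    if (any(ref_part <= 0)) {
      fixn_error("fixn_reference_error",
                 "non-positive reference excess in summary")
    }
    ref_top <- pick(ae, ref_lab, "plant_top", h)
    if (!use_printed_top || is.na(ref_top)) {
      ref_tn <- vapply(parts, function(p) pick(tn, ref_lab, p, h),
                       numeric(1))
      ref_top <- sum(ref_part * ref_tn) / sum(ref_tn)
    }
    for (tr in treatments) {
      for (p in parts) {
        s <- pick(ae, tr, p, h)
        if (is.na(s)) next
        out[[length(out) + 1L]] <- .ndfa_row(
          tr, h, "part", p, s, pick(tn, tr, p, h), ref_part[[p]],
          "mean_first", clip_negative)
      }
      s_top <- pick(ae, tr, "plant_top", h)
      tn_parts <- vapply(parts, function(p) pick(tn, tr, p, h), numeric(1))
      top_n <- pick(tn, tr, "plant_top", h)
      if (is.na(top_n)) top_n <- sum(tn_parts)
      if (!use_printed_top || is.na(s_top)) {
        ae_parts <- vapply(parts, function(p) pick(ae, tr, p, h), numeric(1))
        if (any(is.na(ae_parts)) || any(is.na(tn_parts))) next
        s_top <- sum(ae_parts * tn_parts) / sum(tn_parts)
      }
      out[[length(out) + 1L]] <- .ndfa_row(
        tr, h, "plant_top", "plant_top", s_top, top_n, ref_top,
        "mean_first", clip_negative)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ndfa_table", "data.frame")
  out
}

#' @export
print.ndfa_table <- function(x, digits = 1, ...) {
  cat("%Ndfa estimates (", nrow(x), " cells)\n", sep = "")
  y <- x
  y$ndfa_pct <- round(y$ndfa_pct, digits)
  y$n_fixed_mg <- round(y$n_fixed_mg, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
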