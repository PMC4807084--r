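#' Format a "mean +/- SEM letterLETTER" table cell
#'
#' Renders cells the way multi-harvest trial tables print them:
#' `"5.43±0.45 bA"`, with the lowercase letter comparing treatments within
#' a harvest and the uppercase letter comparing harvests. A missing mean
#' renders as `"N/A"` (a structurally absent part, e.g. the ear before
#' anthesis); missing letters are simply omitted.
#'
#' @param mean,sem cell mean and SEM.
#' @param letter_within,letter_between compact letters (may be `NA`).
#' @param digits decimals to print (vectorised over cells).
#' @return character vector of formatted cells.
#' @examples
#' render_cell(5.43, 0.45, "b", "A")
#' @export
render_cell <- function(mean, sem, letter_within = NA,
                        letter_between = NA, digits = 2) {
  n <- max(length(mean), length(sem))
  mean <- rep_len(mean, n); sem <- rep_len(sem, n)
  letter_within <- rep_len(letter_within, n)
  letter_between <- rep_len(letter_between, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(mean[i])) {
      out[i] <- "N/A"
      next
    }
    cell <- sprintf("%.*f±%.*f", digits, mean[i], digits, sem[i])
    lw <- if (!is.na(letter_within[i]) && nzchar(letter_within[i]))
      letter_within[i] else ""
    lb <- if (!is.na(letter_between[i]) && nzchar(letter_between[i]))
      letter_between[i] else ""
    if (nzchar(lw) || nzchar(lb)) cell <- paste0(cell, " ", lw, lb)
    out[i] <- cell
  }
  out
}

#' Render a treatment x (part, harvest) character table
#'
#' @param summary long summary table (columns `response`, `treatment`,
#'   `part`, `harvest_day`, `mean`, `sem`, optionally `letter_within`,
#'   `letter_between`).
#' @param response which response to render.
#' @param digits decimals per cell.
#' @return character matrix, one row per treatment, one column per
#'   part x harvest; structurally absent cells read `"N/A"`.
#' @export
render_summary_table <- function(summary, response, digits = 2) {
  d <- summary[summary$response == response, , drop = FALSE]
  if (!nrow(d)) {
    fixn_error("fixn_schema_error",
               paste0("no rows for response '", response, "'"))
  }
  if (!("letter_within" %in% names(d))) d$letter_within <- NA_character_
  if (!("letter_between" %in% names(d))) d$letter_between <- NA_character_
  treatments <- unique(d$treatment)
  # full part x harvest cross: structurally absent cells render as N/A
  parts <- unique(d$part)
  parts <- parts[order(match(parts, c(plant_parts(), "plant_top",
                                      "whole_plant")))]
  cols <- expand.grid(harvest_day = sort(unique(d$harvest_day)),
                      part = parts, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("part", "harvest_day")]
  out <- matrix("N/A", nrow = length(treatments), ncol = nrow(cols),
                dimnames = list(treatments,
                                paste0(cols$part, "_D", cols$harvest_day)))
  for (i in seq_len(nrow(d))) {
    cn <- paste0(d$part[i], "_D", d$harvest_day[i])
    out[d$treatment[i], cn] <- render_cell(
      d$mean[i], d$sem[i], d$letter_within[i], d$letter_between[i], digits)
  }
  out
}

#' Run the full trial analysis pipeline
#'
#' Reads and validates a replicate-level measurement table, then writes a
#' report bundle to `out_dir`: per-part summaries with Duncan letters
#' (`summary.csv`), the %Ndfa table (`ndfa.csv`), the between-harvest
#' flux table (`flux.csv`), Pearson correlations of the per-replicate
#' plant-top totals (`correlations.csv`), headline derived quantities
#' (`derived_claims.csv`) and provenance metadata (`provenance.json`:
#' input hash, configuration, package version, seed). Outputs are
#' deterministic: identical input and configuration give byte-identical
#' files. On any stage failure the partial bundle is removed.
#'
#' @param input path to the replicate-level CSV.
#' @param design a [design_config()].
#' @param out_dir output directory (created if needed).
#' @param aggregation %Ndfa aggregation path, see [ndfa_pipeline()].
#' @param alpha level for the letter displays.
#' @param seed recorded in provenance (the pipeline itself draws no random
#'   numbers).
#' @param col_map forwarded to [read_measurements()].
#' @return invisible named list of the files written.
#' @export
run_full_pipeline <- function(input, design, out_dir,
                              aggregation = "replicate_first",
                              alpha = 0.05, seed = NULL, col_map = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written))

  records <- read_measurements(input, design, col_map = col_map)
  if (!nrow(records)) {
    fixn_error("fixn_value_error", "input contains no measurement rows")
  }

  summary <- summarise_parts(records, design)
  summary$letter_within <- NA_character_
  summary$letter_between <- NA_character_
  for (resp in c("dry_biomass", "total_n", "atom_excess")) {
    lt <- trial_letters(records, resp, design, alpha = alpha)
    m <- match(paste(summary$treatment, summary$part, summary$harvest_day),
               paste(lt$treatment, lt$part, lt$harvest_day))
    sel <- summary$response == resp
    summary$letter_within[sel] <- lt$letter_within[m][sel]
    summary$letter_between[sel] <- lt$letter_between[m][sel]
  }

  ndfa <- ndfa_pipeline(records, design, aggregation = aggregation)
  flux <- flux_table(summary)

  totals <- plant_top_totals(records, design)
  wide <- NULL
  for (h in sort(unique(totals$harvest_day))) {
    th <- totals[totals$harvest_day == h,
                 c("treatment", "block", "top_biomass", "top_n")]
    names(th)[3:4] <- paste0(c("top_biomass_D", "top_n_D"), h)
    wide <- if (is.null(wide)) th else
      merge(wide, th, by = c("treatment", "block"))
  }
  corr <- pearson_matrix(wide[, setdiff(names(wide),
                                        c("treatment", "block"))])

  claims <- derived_claims(summary, ndfa, design)

  paths <- file.path(out_dir, c(
    summary = "summary.csv", ndfa = "ndfa.csv", flux = "flux.csv",
    correlations = "correlations.csv", claims = "derived_claims.csv",
    provenance = "provenance.json"))
  names(paths) <- c("summary", "ndfa", "flux", "correlations", "claims",
                    "provenance")
  utils::write.csv(summary, paths["summary"], row.names = FALSE)
  written <- paths["summary"]
  utils::write.csv(as.data.frame(ndfa), paths["ndfa"], row.names = FALSE)
  written <- c(written, paths["ndfa"])
  utils::write.csv(as.data.frame(flux), paths["flux"], row.names = FALSE)
  written <- c(written, paths["flux"])
  corr_df <- data.frame(variable = rownames(corr$r),
                        round(corr$r, 6), check.names = FALSE)
  utils::write.csv(corr_df, paths["correlations"], row.names = FALSE)
  written <- c(written, paths["correlations"])
  utils::write.csv(claims, paths["claims"], row.names = FALSE)
  written <- c(written, paths["claims"])
  prov <- list(
    input = basename(input),
    input_md5 = unname(tools::md5sum(input)),
    package_version = as.character(utils::packageVersion("fixntrace")),
    aggregation = aggregation, alpha = alpha,
    seed = if (is.null(seed)) NA else seed,
    design = unclass(design))
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, paths["provenance"])
  ok <- TRUE
  invisible(as.list(paths))
}

#' Headline derived quantities of a trial
#'
#' Computes, per inoculated treatment and harvest, the plant-top %Ndfa
#' and fixed N with its per-hectare equivalent and mean daily fixation
#' rate, the percent increase of plant-top N (and of final-harvest ear
#' biomass) over the reference treatment, and the fraction of final
#' plant-top N already accumulated at the first harvest.
#'
#' @param summary long summary table with `total_n` / `dry_biomass` rows.
#' @param ndfa an `ndfa_table`.
#' @param design a [design_config()].
#' @return data.frame, one row per treatment x harvest.
#' @export
derived_claims <- function(summary, ndfa, design) {
  ref <- design$reference_treatment
  top <- ndfa[ndfa$scope == "plant_top", , drop = FALSE]
  tn <- summary[summary$response == "total_n" & summary$part == "plant_top", ]
  bm <- summary[summary$response == "dry_biomass" & summary$part == "ear", ]
  harvests <- sort(unique(top$harvest_day))
  h_last <- max(harvests)
  pick <- function(d, tr, h) {
    v <- d$mean[d$treatment == tr & d$harvest_day == h]
    if (length(v) == 1L) v else NA_real_
  }
  rows <- list()
  for (tr in unique(top$treatment)) {
    for (h in harvests) {
      r <- top[top$treatment == tr & top$harvest_day == h, ]
      if (!nrow(r)) next
      top_n <- pick(tn, tr, h)
      ref_n <- pick(tn, ref, h)
      n1 <- pick(tn, tr, min(harvests)); n2 <- pick(tn, tr, h_last)
      ear_tr <- pick(bm, tr, h_last); ear_ref <- pick(bm, ref, h_last)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, harvest_day = h,
        ndfa_pct = r$ndfa_pct,
        n_fixed_mg = r$n_fixed_mg,
        n_fixed_kg_ha = scale_per_area(r$n_fixed_mg,
                                       design$planting_density),
        fixation_rate_mg_day = fixation_rate(r$n_fixed_mg, h),
        top_n_increase_pct = if (tr == ref || is.na(top_n) || is.na(ref_n))
          NA_real_ else percent_increase(top_n, ref_n),
        ear_biomass_increase_pct =
          if (tr == ref || h != h_last || is.na(ear_tr) || is.na(ear_ref))
            NA_real_ else percent_increase(ear_tr, ear_ref),
        pre_anthesis_fraction_pct =
          if (is.na(n1) || is.na(n2)) NA_real_ else
            pre_anthesis_fraction(n1, n2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
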