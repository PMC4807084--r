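#' Read replicate-level trial measurements
#'
#' Reads a tidy long-format CSV/TSV with one row per replicate x plant part
#' and validates it against the trial design. Expected columns (matched
#' case-insensitively, remappable through `col_map`):
#' `treatment`, `block`, `harvest_day`, `part`, `dry_biomass` (g/plant),
#' `abundance_15n` (measured atom % 15N, uncorrected) and either
#' `total_n` (mg N/plant) or `percent_n` (Kjeldahl N concentration, % of
#' dry matter), from which `total_n = dry_biomass * percent_n * 10` is
#' computed on load.
#'
#' @param path path to a delimited text file (UTF-8, dot decimal).
#' @param design a [design_config()].
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(dry_biomass = "dw_g")`.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return a `data.frame` of validated measurement records with columns
#'   `treatment`, `block`, `harvest_day`, `part`, `dry_biomass`,
#'   `total_n`, `abundance_15n`.
#' @seealso [validate_measurements()], [write_measurements()]
#' @export
read_measurements <- function(path, design, col_map = NULL, sep = ",") {
  if (!file.exists(path)) {
    fixn_error("fixn_io_error", paste0("file not found: ", path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      from <- tolower(col_map[[canon]])
      if (from %in% names(raw)) names(raw)[names(raw) == from] <- canon
    }
  }
  needed <- c("treatment", "block", "harvest_day", "part",
              "dry_biomass", "abundance_15n")
  missing_cols <- setdiff(needed, names(raw))
  if (!("total_n" %in% names(raw)) && !("percent_n" %in% names(raw))) {
    missing_cols <- c(missing_cols, "total_n (or percent_n)")
  }
  if (length(missing_cols)) {
    fixn_error("fixn_schema_error",
               paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!("total_n" %in% names(raw))) {
    # Kjeldahl concentration path: g dry matter * %N -> mg N
    raw$total_n <- raw$dry_biomass * raw$percent_n * 10
  }
  records <- raw[, c("treatment", "block", "harvest_day", "part",
                     "dry_biomass", "total_n", "abundance_15n")]
  records$treatment   <- as.character(records$treatment)
  records$block       <- as.integer(records$block)
  records$harvest_day <- as.integer(records$harvest_day)
  records$part        <- as.character(records$part)
  validate_measurements(records, design)
}

#' Validate measurement records
#'
#' Checks the structural invariants of a replicate-level measurement table:
#' known plant parts, non-negative biomass and N, measured abundance in
#' (0, 100), uniqueness of (treatment, block, harvest_day, part), the ear
#' only at the ear-bearing harvest, and presence of the reference
#' treatment. Violations raise classed errors (`fixn_schema_error`,
#' `fixn_value_error`, `fixn_integrity_error`) whose messages list the
#' offending rows; with `action = "report"` a diagnostics data frame is
#' returned instead and nothing is raised.
#'
#' @param records data.frame of measurement records (see
#'   [read_measurements()] for columns).
#' @param design a [design_config()].
#' @param action `"error"` (default) to stop at the first violated rule,
#'   `"report"` to return all row-level diagnostics.
#' @return `records` (invisibly validated) for `action = "error"`; a
#'   data.frame with columns `row`, `rule`, `detail` for
#'   `action = "report"` (zero rows when clean).
#' @export
validate_measurements <- function(records, design,
                                  action = c("error", "report")) {
  action <- match.arg(action)
  needed <- c("treatment", "block", "harvest_day", "part",
              "dry_biomass", "total_n", "abundance_15n")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    fixn_error("fixn_schema_error",
               paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  diags <- list()
  note <- function(rows, rule, detail) {
    if (length(rows)) {
      diags[[length(diags) + 1L]] <<- data.frame(
        row = rows, rule = rule, detail = detail,
        stringsAsFactors = FALSE)
    }
  }

  bad_part <- which(!(records$part %in% plant_parts()))
  note(bad_part, "unknown_part",
       paste0("unknown part '", records$part[bad_part], "'"))

  early_ear <- which(part_unavailable(records$part, records$harvest_day,
                                      design))
  note(early_ear, "part_not_available",
       "part not available before anthesis")

  neg <- which(records$dry_biomass < 0 | records$total_n < 0)
  note(neg, "negative_value", "negative biomass or total N")

  bad_ab <- which(!is.finite(records$abundance_15n) |
                    records$abundance_15n <= 0 |
                    records$abundance_15n >= 100)
  note(bad_ab, "abundance_out_of_range",
       "measured 15N abundance must lie in (0, 100) atom %")

  key <- paste(records$treatment, records$block, records$harvest_day,
               records$part, sep = "/")
  dup <- which(duplicated(key))
  note(dup, "duplicate_key",
       paste0("duplicate record for (", key[dup], ")"))

  diags <- if (length(diags)) do.call(rbind, diags) else
    data.frame(row = integer(), rule = character(), detail = character(),
               stringsAsFactors = FALSE)

  if (action == "report") {
    return(diags)
  }
  if (nrow(diags)) {
    rule <- diags$rule[1L]
    klass <- switch(rule,
                    duplicate_key = "fixn_integrity_error",
                    unknown_part = "fixn_schema_error",
                    "fixn_value_error")
    shown <- diags[diags$rule == rule, , drop = FALSE]
    fixn_error(klass, paste0(
      rule, " in row(s) ", paste(shown$row, collapse = ", "), ": ",
      shown$detail[1L]))
  }
  if (!(design$reference_treatment %in% records$treatment)) {
    fixn_error("fixn_schema_error",
               paste0("reference treatment '", design$reference_treatment,
                      "' absent from the data"))
  }
  records
}

#' Write measurement records to CSV
#'
#' Round-trip companion to [read_measurements()]; values are written in
#' full precision so write -> read is lossless.
#'
#' @param records measurement data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate replicate records into per-cell summaries
#'
#' Computes the mean and standard error of the mean (SEM = sample SD /
#' sqrt(n)) of dry biomass, total N and background-corrected atom excess
#' for every treatment x harvest x part cell, across blocks. A cell with a
#' single replicate gets SEM 0 with a warning.
#'
#' @param records measurement data.frame (validated).
#' @param design a [design_config()]; supplies the natural abundance used
#'   to derive atom excess from measured abundance.
#' @return a long-format summary data.frame with columns `response`
#'   (`dry_biomass`, `total_n`, `atom_excess`), `treatment`, `part`,
#'   `harvest_day`, `mean`, `sem`, `n_replicates`.
#' @export
summarise_parts <- function(records, design) {
  records$atom_excess <- atom_excess(records$abundance_15n,
                                     design$natural_abundance)
  sem <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  out <- list()
  for (resp in c("dry_biomass", "total_n", "atom_excess")) {
    grp <- interaction(records$treatment, records$part,
                       records$harvest_day, drop = TRUE)
    pieces <- split(records, grp)
    rows <- lapply(pieces, function(d) {
      data.frame(response = resp,
                 treatment = d$treatment[1L],
                 part = d$part[1L],
                 harvest_day = d$harvest_day[1L],
                 mean = mean(d[[resp]]),
                 sem = sem(d[[resp]]),
                 n_replicates = nrow(d),
                 stringsAsFactors = FALSE)
    })
    out[[resp]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (any(out$n_replicates == 1L)) {
    warning("cells with a single replicate: SEM reported as 0",
            call. = FALSE)
  }
  out[order(out$response, out$treatment, out$part, out$harvest_day), ]
}

#' Plant-top and whole-plant totals per replicate
#'
#' Sums dry biomass and total N over the above-ground parts (everything
#' except the root) for each treatment x block x harvest; whole-plant
#' biomass additionally includes the root. A replicate missing one of the
#' parts the design expects at that harvest is flagged `incomplete` and the
#' gaps are reported in the `"gaps"` attribute.
#'
#' @param records measurement data.frame.
#' @param design a [design_config()].
#' @return data.frame with columns `treatment`, `block`, `harvest_day`,
#'   `top_biomass`, `top_n`, `whole_biomass`, `incomplete`; attribute
#'   `"gaps"` lists missing parts per replicate.
#' @export
plant_top_totals <- function(records, design) {
  grp <- interaction(records$treatment, records$block,
                     records$harvest_day, drop = TRUE)
  pieces <- split(records, grp)
  gaps <- list()
  rows <- lapply(pieces, function(d) {
    h <- d$harvest_day[1L]
    expected <- isotope_parts(h, design)
    top <- d[d$part != "root", , drop = FALSE]
    missing_parts <- setdiff(expected, top$part)
    if (length(missing_parts)) {
      gaps[[length(gaps) + 1L]] <<- data.frame(
        treatment = d$treatment[1L], block = d$block[1L], harvest_day = h,
        missing = paste(missing_parts, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    data.frame(treatment = d$treatment[1L],
               block = d$block[1L],
               harvest_day = h,
               top_biomass = sum(top$dry_biomass),
               top_n = sum(top$total_n),
               whole_biomass = sum(d$dry_biomass[d$part != "whole_plant"]),
               incomplete = length(missing_parts) > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$treatment, out$harvest_day, out$block), ]
  attr(out, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else NULL
  out
}
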