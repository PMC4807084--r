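#' Between-harvest nitrogen flux table
#'
#' Balance-remobilisation accounting on treatment means: for every
#' treatment x part present at two harvests, the change in total N, dry
#' biomass and atom excess from the earlier to the later harvest, and a
#' sink/source classification on the N change. Because the two harvests
#' destroy different plants, fluxes are computed on means, never on
#' within-plant pairs.
#'
#' A part is a `source` when its N significantly decreased and a `sink`
#' when it significantly increased; everything else (including any
#' non-significant change) is `neutral`. Significance is taken from the
#' between-harvest letter display of the total-N response (two cells
#' sharing no letter differ); with `raw = TRUE` classification uses the
#' sign alone.
#'
#' @param summary long summary data.frame (columns `response`, `treatment`,
#'   `part`, `harvest_day`, `mean`, optionally `letter_between`).
#' @param harvests length-2 integer vector; defaults to the two smallest
#'   harvest days present.
#' @param raw ignore significance gating and classify on sign only.
#' @return data.frame of class `flux_table`: `treatment`, `part`,
#'   `delta_n`, `delta_biomass`, `delta_excess`, `significant`, `role`.
#' @export
flux_table <- function(summary, harvests = NULL, raw = FALSE) {
  if (is.null(harvests)) {
    harvests <- sort(unique(summary$harvest_day))[1:2]
  }
  stopifnot(length(harvests) == 2L)
  h1 <- harvests[1L]; h2 <- harvests[2L]
  if (is.na(h1) || is.na(h2)) {
    fixn_error("fixn_value_error", "two harvests are required for fluxes")
  }
  pick <- function(resp, tr, p, h, col = "mean") {
    v <- summary[[col]][summary$response == resp & summary$treatment == tr &
                          summary$part == p & summary$harvest_day == h]
    if (length(v) == 1L) v else NA
  }
  has_letters <- "letter_between" %in% names(summary)
  combos <- unique(summary[summary$response == "total_n",
                           c("treatment", "part")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$treatment[i]; p <- combos$part[i]
    n1 <- pick("total_n", tr, p, h1); n2 <- pick("total_n", tr, p, h2)
    if (is.na(n1) || is.na(n2)) next  # e.g. ear absent before anthesis
    d_n <- n2 - n1
    d_b <- pick("dry_biomass", tr, p, h2) - pick("dry_biomass", tr, p, h1)
    d_e <- pick("atom_excess", tr, p, h2) - pick("atom_excess", tr, p, h1)
    sig <- NA
    if (has_letters) {
      l1 <- pick("total_n", tr, p, h1, "letter_between")
      l2 <- pick("total_n", tr, p, h2, "letter_between")
      if (!is.na(l1) && !is.na(l2) && nzchar(l1) && nzchar(l2)) {
        sig <- !letters_share(l1, l2)
      }
    }
    gate <- if (raw) TRUE else isTRUE(sig)
    role <- if (gate && d_n < 0) "source" else if (gate && d_n > 0) "sink"
            else "neutral"
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = tr, part = p, delta_n = d_n, delta_biomass = d_b,
      delta_excess = d_e, significant = sig, role = role,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("flux_table", "data.frame")
  out
}

# do two compact-letter strings share at least one letter?
letters_share <- function(a, b) {
  length(intersect(strsplit(a, "")[[1L]], strsplit(b, "")[[1L]])) > 0L
}

#' Fraction of final plant-top N present before anthesis
#'
#' @param n_top_first plant-top N at the earlier harvest, mg.
#' @param n_top_second plant-top N at the later harvest, mg (> 0).
#' @return percentage (vectorised). Can exceed 100 if plant-top N declined.
#' @examples
#' pre_anthesis_fraction(617, 880)   # 70.1
#' @export
pre_anthesis_fraction <- function(n_top_first, n_top_second) {
  if (any(n_top_second <= 0)) {
    fixn_error("fixn_value_error", "later-harvest plant-top N must be > 0")
  }
  100 * n_top_first / n_top_second
}

#' Percentage increase over a control
#'
#' @param treated treated quantity.
#' @param control control quantity (> 0).
#' @return percentage change (vectorised).
#' @examples
#' percent_increase(957, 617)    # 55.1
#' @export
percent_increase <- function(treated, control) {
  if (any(control <= 0)) {
    fixn_error("fixn_value_error", "control quantity must be > 0")
  }
  100 * (treated - control) / control
}

#' Fold change over a control
#'
#' Satisfies `fold_change(x, y) == 1 + percent_increase(x, y) / 100`.
#'
#' @inheritParams percent_increase
#' @return fold (vectorised).
#' @examples
#' fold_change(726.77, 0.96)     # ~757
#' @export
fold_change <- function(treated, control) {
  if (any(control <= 0)) {
    fixn_error("fixn_value_error", "control quantity must be > 0")
  }
  treated / control
}

#' Delayed-senescence indicator from tassel N flux
#'
#' A significantly negative between-harvest change in tassel N marks
#' continued remobilisation out of a still-living tassel: the operational
#' sign of delayed dehiscence/senescence. A tassel whose N did not change
#' significantly shed its N early (dehisced) and is not flagged.
#'
#' @param flux a [flux_table()].
#' @return named logical vector, one element per treatment with a tassel
#'   flux record.
#' @export
senescence_delayed <- function(flux) {
  t_rows <- flux[flux$part == "tassel", , drop = FALSE]
  stats::setNames(
    isTRUE_each(t_rows$significant) & t_rows$delta_n < 0,
    t_rows$treatment)
}

isTRUE_each <- function(x) !is.na(x) & x
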