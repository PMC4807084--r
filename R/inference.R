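#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition via [stats::lm()]/[stats::anova()],
#' returned in a tidy shape together with the residual mean square and
#' degrees of freedom needed by [duncan_mrt()]. Data in which every
#' observation is identical (zero spread, equal means) return F = 0,
#' p = 1 rather than an error.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor, >= 2 levels).
#' @return object of class `fixn_anova`: list with `table` (term, df,
#'   sumsq, meansq, statistic, p_value), `ms_error`, `df_error`,
#'   `n_per_group` (NA if unbalanced).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) {
    fixn_error("fixn_design_error", "at least two groups are required")
  }
  stopifnot(length(values) == length(groups))
  fit <- stats::lm(values ~ groups)
  a <- quiet_perfect_fit(stats::anova(fit))
  tab <- data.frame(
    term = c("groups", "residual"),
    df = a$Df, sumsq = a$`Sum Sq`, meansq = a$`Mean Sq`,
    statistic = a$`F value`, p_value = a$`Pr(>F)`,
    stringsAsFactors = FALSE)
  # degenerate all-constant input: define the F = 0 path
  if (all(abs(values - mean(values)) < 1e-12)) {
    tab$statistic[1L] <- 0
    tab$p_value[1L] <- 1
  }
  ns <- table(groups)
  structure(
    list(table = tab,
         ms_error = tab$meansq[2L],
         df_error = tab$df[2L],
         n_per_group = if (length(unique(ns)) == 1L) unname(ns[1L])
                       else NA_integer_),
    class = "fixn_anova")
}

# zero-residual fits are a defined degenerate path, not a user concern
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Two-way crossed analysis of variance with interaction
#'
#' Fits `values ~ a * b` (for a strain x harvest layout) and returns main
#' effects and the interaction. Requires at least two levels per factor
#' and no empty cells.
#'
#' @param values numeric response vector.
#' @param strain,harvest factor labels of the two crossed factors.
#' @return object of class `fixn_anova` (see [one_way_anova()]); `table`
#'   has rows `strain`, `harvest`, `strain:harvest`, `residual`.
#' @export
two_way_anova <- function(values, strain, harvest) {
  strain <- factor(strain); harvest <- factor(harvest)
  if (nlevels(strain) < 2L || nlevels(harvest) < 2L) {
    fixn_error("fixn_design_error",
               "both factors need at least two levels")
  }
  cells <- table(strain, harvest)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    fixn_error("fixn_design_error", paste0(
      "empty design cell(s): ",
      paste(rownames(cells)[empty[, 1L]], colnames(cells)[empty[, 2L]],
            sep = ":", collapse = ", ")))
  }
  fit <- stats::lm(values ~ strain * harvest)
  a <- quiet_perfect_fit(stats::anova(fit))
  tab <- data.frame(
    term = c("strain", "harvest", "strain:harvest", "residual"),
    df = a$Df, sumsq = a$`Sum Sq`, meansq = a$`Mean Sq`,
    statistic = a$`F value`, p_value = a$`Pr(>F)`,
    stringsAsFactors = FALSE)
  structure(
    list(table = tab, ms_error = tab$meansq[4L], df_error = tab$df[4L],
         n_per_group = NA_integer_),
    class = "fixn_anova")
}

#' @export
print.fixn_anova <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Duncan's multiple range test with compact letter display
#'
#' Ranks the group means in descending order and tests every stretch of
#' `p` adjacent ranked means against the critical range
#' \deqn{R_p = q(\alpha_p, p, df_e) \sqrt{MS_e / n}}
#' where `q` is the studentized-range quantile at Duncan's protection
#' level \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}}. A stretch whose range does
#' not exceed \eqn{R_p} is declared homogeneous together with everything
#' it contains (the containment rule). Letters are assigned to the maximal
#' homogeneous stretches; the largest mean always holds letter `a`. At two
#' groups the protection level collapses to \eqn{\alpha} and the decision
#' coincides with Fisher's LSD.
#'
#' @param group_means named numeric vector of group means (or unnamed with
#'   `labels`).
#' @param ms_error residual mean square of the underlying ANOVA.
#' @param df_error residual degrees of freedom (>= 1).
#' @param n_per_group common replicate count per group; unbalanced designs
#'   must opt in to the harmonic-mean approximation via
#'   `harmonic = TRUE` and pass the vector of group sizes.
#' @param alpha test level (default 0.05).
#' @param labels optional group labels.
#' @param harmonic allow unbalanced `n_per_group` via its harmonic mean.
#' @return object of class `letter_display`: data.frame `groups` with
#'   `group`, `mean`, `letters` (sorted by descending mean), plus
#'   attributes `alpha` and `critical_ranges`.
#' @examples
#' duncan_mrt(c(A = 10, B = 9.8, C = 5), ms_error = 0.1, df_error = 9,
#'            n_per_group = 4)
#' @export
duncan_mrt <- function(group_means, ms_error, df_error, n_per_group,
                       alpha = 0.05, labels = names(group_means),
                       harmonic = FALSE) {
  k <- length(group_means)
  stopifnot(k >= 2L, ms_error >= 0, df_error >= 1)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  if (length(unique(n_per_group)) > 1L) {
    if (!harmonic) {
      fixn_error("fixn_design_error", paste0(
        "unbalanced group sizes; set harmonic = TRUE to use the ",
        "harmonic-mean approximation"))
    }
    n_per_group <- length(n_per_group) / sum(1 / n_per_group)
  } else {
    n_per_group <- n_per_group[1L]
  }
  ord <- order(group_means, decreasing = TRUE)
  m <- group_means[ord]
  lab <- labels[ord]

  # critical ranges R_p for stretches of p = 2..k ranked means
  p_seq <- 2:k
  alpha_p <- 1 - (1 - alpha)^(p_seq - 1)
  r_crit <- stats::qtukey(1 - alpha_p, p_seq, df_error) *
    sqrt(ms_error / n_per_group)
  names(r_crit) <- p_seq

  # containment sweep, widest stretch first
  nonsig <- diag(k) > 0
  if (k >= 2L) {
    for (p in rev(p_seq)) {
      for (i in seq_len(k - p + 1L)) {
        j <- i + p - 1L
        if (nonsig[i, j]) next   # inherited from a wider homogeneous stretch
        if ((m[i] - m[j]) <= r_crit[[as.character(p)]]) {
          nonsig[i:j, i:j] <- TRUE
        }
      }
    }
  }

  # letters = maximal homogeneous stretches (intervals in ranked order)
  reach <- vapply(seq_len(k), function(i) max(which(nonsig[i, ])), integer(1))
  reach <- cummax(reach)  # containment makes this monotone; enforce anyway
  intervals <- list()
  i <- 1L
  repeat {
    j <- reach[i]
    intervals[[length(intervals) + 1L]] <- c(i, j)
    if (j >= k) break
    nxt <- which(reach > j)[1L]
    i <- nxt
  }
  lett <- character(k)
  for (s in seq_along(intervals)) {
    idx <- intervals[[s]][1L]:intervals[[s]][2L]
    lett[idx] <- paste0(lett[idx], letters[s])
  }

  out <- data.frame(group = lab, mean = unname(m), letters = lett,
                    stringsAsFactors = FALSE)
  structure(list(groups = out),
            class = "letter_display",
            alpha = alpha, critical_ranges = r_crit)
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", attr(x, "alpha"), ")\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Letter display straight from raw data
#'
#' Convenience wrapper: one-way ANOVA on `values ~ groups`, then
#' [duncan_mrt()] on the group means with the fit's residual mean square.
#'
#' @inheritParams one_way_anova
#' @inheritParams duncan_mrt
#' @return a `letter_display`.
#' @export
dmrt_letters <- function(values, groups, alpha = 0.05, harmonic = FALSE) {
  groups <- factor(groups)
  fit <- one_way_anova(values, groups)
  means <- tapply(values, groups, mean)
  ns <- as.integer(table(groups))
  duncan_mrt(as.numeric(means), fit$ms_error, fit$df_error,
             n_per_group = ns, alpha = alpha, labels = names(means),
             harmonic = harmonic)
}

#' Within- and between-harvest letter displays for a trial
#'
#' Reproduces the two letter systems of multi-harvest trial tables:
#' lowercase letters compare treatments within each part x harvest cell
#' column, uppercase letters compare the two harvests within each
#' treatment x part row. Each part is fitted separately (no pooling of
#' error terms across parts).
#'
#' @param records validated measurement data.frame.
#' @param response one of `"dry_biomass"`, `"total_n"`, `"abundance_15n"`
#'   or `"atom_excess"`.
#' @param design a [design_config()] (needed for `atom_excess`).
#' @param alpha test level.
#' @return data.frame with columns `treatment`, `part`, `harvest_day`,
#'   `letter_within` (lowercase), `letter_between` (uppercase).
#' @export
trial_letters <- function(records, response, design, alpha = 0.05) {
  if (response == "atom_excess") {
    records$atom_excess <- atom_excess(records$abundance_15n,
                                       design$natural_abundance)
  }
  y <- records[[response]]
  key <- paste(records$treatment, records$part, records$harvest_day,
               sep = "\r")
  out <- unique(data.frame(treatment = records$treatment,
                           part = records$part,
                           harvest_day = records$harvest_day,
                           stringsAsFactors = FALSE))
  out$letter_within <- NA_character_
  out$letter_between <- NA_character_

  # lowercase: treatments within part x harvest
  for (p in unique(out$part)) {
    for (h in unique(out$harvest_day[out$part == p])) {
      sel <- records$part == p & records$harvest_day == h
      if (length(unique(records$treatment[sel])) < 2L) next
      ld <- dmrt_letters(y[sel], records$treatment[sel], alpha = alpha)
      for (r in seq_len(nrow(ld$groups))) {
        tgt <- out$part == p & out$harvest_day == h &
          out$treatment == ld$groups$group[r]
        out$letter_within[tgt] <- ld$groups$letters[r]
      }
    }
  }
  # uppercase: harvests within treatment x part
  for (tr in unique(out$treatment)) {
    for (p in unique(out$part[out$treatment == tr])) {
      sel <- records$treatment == tr & records$part == p
      hs <- unique(records$harvest_day[sel])
      if (length(hs) < 2L) next
      ld <- dmrt_letters(y[sel], records$harvest_day[sel], alpha = alpha)
      for (r in seq_len(nrow(ld$groups))) {
        tgt <- out$treatment == tr & out$part == p &
          out$harvest_day == as.integer(ld$groups$group[r])
        out$letter_between[tgt] <- toupper(ld$groups$letters[r])
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson correlations across the columns of a numeric table,
#' with two-sided p-values from the t transform ([stats::cor.test()]).
#' Variables with zero variance get `NA` correlations and a diagnostic.
#'
#' @param table data.frame or matrix, observations in rows, variables in
#'   columns (>= 3 complete observations per pair).
#' @return object of class `correlation_matrix`: list with matrices `r`
#'   and `p`, the common `n` per pair, and `diagnostics`.
#' @export
pearson_matrix <- function(table) {
  x <- as.data.frame(table)
  stopifnot(ncol(x) >= 2L)
  vars <- names(x)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(NA_integer_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  degenerate <- vars[vapply(x, function(v) stats::var(v, na.rm = TRUE) == 0,
                            logical(1))]
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- stats::complete.cases(x[[i]], x[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L) {
        fixn_error("fixn_design_error", paste0(
          "fewer than 3 complete observations for ", vars[i], " vs ",
          vars[j]))
      }
      if (vars[i] %in% degenerate || vars[j] %in% degenerate) next
      ct <- stats::cor.test(x[[i]][ok], x[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n,
                 diagnostics = if (length(degenerate))
                   paste0("zero-variance variable(s): ",
                          paste(degenerate, collapse = ", "))
                 else NULL),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  stars <- ifelse(is.na(x$p), "",
                  ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", "")))
  disp <- matrix(paste0(format(round(x$r, digits)), stars),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  disp[upper.tri(disp)] <- ""
  print(as.data.frame(disp), ...)
  cat("Levels of significance: *p<0.05, **p<0.01. n =",
      max(x$n, na.rm = TRUE), "\n")
  if (!is.null(x$diagnostics)) cat(x$diagnostics, "\n")
  invisible(x)
}
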