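# Fixture builders and independent oracles shared across tests.

default_design <- function() design_config("Control")

# A tiny balanced two-treatment, two-block, two-harvest trial built in code.
# Atom excesses are exact three-pool values so %Ndfa is known by construction.
tiny_records <- function(ndfa_trt = 0.30, ref_excess = 1.0,
                         natural = 0.3663) {
  parts50 <- c("tassel", "young_leaves", "stalk")
  parts65 <- c(parts50, "ear")
  rows <- list()
  for (trt in c("Control", "Trt")) {
    exc <- if (trt == "Control") ref_excess else ref_excess * (1 - ndfa_trt)
    for (b in 1:2) {
      for (h in c(50L, 65L)) {
        for (p in if (h == 50L) parts50 else parts65) {
          rows[[length(rows) + 1L]] <- data.frame(
            treatment = trt, block = b, harvest_day = h, part = p,
            dry_biomass = 5, total_n = 100,
            abundance_15n = exc + natural, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Independent brute-force Duncan's-MRT oracle: recursive all-pairs testing
# with the containment rule, returning the pairwise non-significance matrix
# in the original group order.
oracle_duncan_nonsig <- function(means, ms_error, df_error, n_per_group,
                                 alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nonsig <- diag(k) > 0
  r_p <- function(p) {
    a_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - a_p, p, df_error) * sqrt(ms_error / n_per_group)
  }
  test <- function(i, j) {
    if (j <= i || nonsig[i, j]) return(invisible(NULL))
    if ((m[i] - m[j]) <= r_p(j - i + 1)) {
      nonsig[i:j, i:j] <<- TRUE
    } else {
      test(i, j - 1L)
      test(i + 1L, j)
    }
    invisible(NULL)
  }
  test(1L, k)
  out <- matrix(FALSE, k, k)
  out[ord, ord] <- nonsig
  out
}

# pairwise "share a letter" matrix implied by a letter display, in the
# order of the supplied labels
letters_nonsig <- function(display, labels) {
  lets <- display$groups$letters[match(labels, display$groups$group)]
  k <- length(labels)
  out <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- length(intersect(strsplit(lets[i], "")[[1]],
                                    strsplit(lets[j], "")[[1]])) > 0
    }
  }
  out
}
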