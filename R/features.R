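# Structural feature screen: intragenic vs intergenic L1s. Categorical
# features get a Pearson chi-square on the 2x2 presence table (counted per
# L1 and per host gene); numeric features get a homoscedastic (pooled
# variance) two-sample t-test.

feature_result <- function(feature_name, test_kind, counting_mode,
                           statistic, p_value, direction,
                           degenerate = FALSE) {
  tibble(
    feature = feature_name, test = test_kind, mode = counting_mode,
    statistic = statistic, p = p_value, direction = direction,
    degenerate = degenerate
  )
}

#' Chi-square test of a categorical L1 feature
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table of
#' feature presence in intragenic vs intergenic L1s. Direction compares the
#' present-fractions of the two groups. A zero row or column margin makes
#' the result degenerate (p = 1, direction `"none"`).
#'
#' @param feature Feature name.
#' @param intragenic_counts,intergenic_counts Length-2 integer vectors
#'   `c(present, absent)`.
#' @param counting_mode Label recorded in the result (`"per_l1"` or
#'   `"per_gene"`).
#' @return One-row tibble: `feature`, `test`, `mode`, `statistic`, `p`,
#'   `direction`, `degenerate`.
#' @export
categorical_feature_test <- function(feature, intragenic_counts,
                                     intergenic_counts,
                                     counting_mode = "per_l1") {
  stopifnot(length(intragenic_counts) == 2, length(intergenic_counts) == 2,
            all(intragenic_counts >= 0), all(intergenic_counts >= 0),
            sum(intragenic_counts) > 0, sum(intergenic_counts) > 0)
  res <- chisq_or(contingency_2x2(
    intragenic_counts[1], intragenic_counts[2],
    intergenic_counts[1], intergenic_counts[2],
    row_labels = c("intragenic", "intergenic"),
    col_labels = c("present", "absent")
  ))
  frac_intra <- intragenic_counts[1] / sum(intragenic_counts)
  frac_inter <- intergenic_counts[1] / sum(intergenic_counts)
  direction <- if (res$degenerate || frac_intra == frac_inter) {
    "none"
  } else if (frac_intra > frac_inter) "intragenic_higher" else "intergenic_higher"
  feature_result(feature, "chi_square", counting_mode,
                 res$chi_square, res$p_value, direction,
                 degenerate = res$degenerate)
}

#' Homoscedastic t-test of a numeric L1 feature
#'
#' Two-sample pooled-variance (equal variance) two-sided t-test comparing a
#' numeric feature between intragenic and intergenic L1s.
#'
#' @param feature Feature name.
#' @param intragenic_values,intergenic_values Numeric vectors (>= 2 values
#'   each; `NA`s dropped).
#' @return One-row tibble as in [categorical_feature_test()] with
#'   `test = "t_test_homoscedastic"`.
#' @export
numeric_feature_test <- function(feature, intragenic_values,
                                 intergenic_values) {
  x <- intragenic_values[!is.na(intragenic_values)]
  y <- intergenic_values[!is.na(intergenic_values)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 non-missing values.")
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- FALSE
  if (se == 0) {
    if (m1 == m2) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(m1 - m2) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    tstat <- (m1 - m2) / se
    p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  direction <- if (m1 == m2) "none" else if (m1 > m2) "intragenic_higher" else "intergenic_higher"
  feature_result(feature, "t_test_homoscedastic", "not_applicable",
                 tstat, p, direction, degenerate = degenerate)
}

#' Screen all registered L1 features
#'
#' Runs [categorical_feature_test()] for every categorical feature in both
#' counting modes (`per_l1`: each L1 is one observation; `per_gene`: each
#' host gene counts once, "present" when any of its L1s has the feature —
#' intergenic L1s are counted per L1 in both modes since they have no host
#' gene) and [numeric_feature_test()] for every numeric feature.
#' Multi-category features (e.g. subfamily) are decomposed into one-vs-rest
#' presence tests per observed level.
#'
#' @param l1s Classified L1 tibble ([classify_l1_locations()] output) whose
#'   columns include the registered features.
#' @param registry List with character vectors `categorical` and `numeric`
#'   naming feature columns of `l1s`. Logical/binary categorical columns are
#'   tested as-is; factors/characters one-vs-rest.
#' @param max_missing Features missing in more than this fraction of L1s are
#'   excluded with a warning (default 0.5).
#' @return Tibble of feature test results, one row per (feature x mode) and
#'   per numeric feature; a `bonferroni_p` column is appended for
#'   convenience (the screen itself is reported uncorrected).
#' @export
run_feature_screen <- function(l1s, registry, max_missing = 0.5) {
  l1s <- as_tibble(l1s)
  if (!"location_class" %in% names(l1s)) {
    abort("`l1s` must be classified first: run classify_l1_locations().")
  }
  intra <- dplyr::filter(l1s, .data$location_class == "intragenic")
  inter <- dplyr::filter(l1s, .data$location_class == "intergenic")
  if (nrow(intra) == 0 || nrow(inter) == 0) {
    abort("need both intragenic and intergenic L1s to run the screen.")
  }

  usable <- function(nm) {
    if (!nm %in% names(l1s)) {
      warn(sprintf("feature '%s' not found; skipped.", nm))
      return(FALSE)
    }
    frac_na <- mean(is.na(l1s[[nm]]))
    if (frac_na > max_missing) {
      warn(sprintf("feature '%s' missing for %.0f%% of L1s; excluded.",
                   nm, 100 * frac_na))
      return(FALSE)
    }
    TRUE
  }

  results <- list()
  for (nm in registry$categorical %||% character(0)) {
    if (!usable(nm)) next
    vals <- l1s[[nm]]
    levels_tested <- if (is.logical(vals) ||
                         all(stats::na.omit(vals) %in% c(0, 1, TRUE, FALSE))) {
      list(stats::setNames(TRUE, nm))
    } else {
      lv <- sort(unique(as.character(stats::na.omit(vals))))
      lapply(lv, function(l) stats::setNames(l, paste0(nm, ":", l)))
    }
    for (lev in levels_tested) {
      label <- names(lev)
      present <- !is.na(vals) & as.character(vals) == as.character(lev[[1]])
      for (cm in c("per_l1", "per_gene")) {
        cnt <- feature_counts(l1s, present, counting_mode = cm)
        results[[length(results) + 1]] <- categorical_feature_test(
          label, cnt$intragenic, cnt$intergenic, counting_mode = cm
        )
      }
    }
  }
  for (nm in registry$numeric %||% character(0)) {
    if (!usable(nm)) next
    results[[length(results) + 1]] <- numeric_feature_test(
      nm,
      intra[[nm]],
      inter[[nm]]
    )
  }
  if (length(results) == 0) abort("no usable features in the registry.")
  out <- dplyr::bind_rows(results)
  out$bonferroni_p <- pmin(out$p * nrow(out), 1)
  out
}

# presence/absence counts for the two classes under a counting mode.
# per_l1: one observation per L1. per_gene: intragenic observations collapse
# to host genes (a gene is "present" if any of its L1s has the feature);
# intergenic L1s stay per-L1 (no host gene to collapse on).
feature_counts <- function(l1s, present, counting_mode) {
  is_intra <- l1s$location_class == "intragenic"
  ok <- !is.na(present)
  if (counting_mode == "per_l1") {
    intra <- c(sum(present & is_intra & ok), sum(!present & is_intra & ok))
    inter <- c(sum(present & !is_intra & ok), sum(!present & !is_intra & ok))
  } else {
    hosts <- l1s$host_genes[is_intra & ok]
    pres <- present[is_intra & ok]
    gene_present <- tapply(
      rep(pres, lengths(hosts)), unlist(hosts), any
    )
    intra <- c(sum(gene_present), sum(!gene_present))
    inter <- c(sum(present & !is_intra & ok), sum(!present & !is_intra & ok))
  }
  list(intragenic = intra, intergenic = inter)
}
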