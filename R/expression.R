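# Two-group expression calling. Each probe gets a pair of one-sided
# pooled-variance Student t-tests (test > control for "up", test < control
# for "down"); genes are then called from their probes: one significant
# unique probe suffices, while a gene represented only by homologous probes
# (probes mapping to more than one gene) needs at least two significant
# homologous probes in the same direction.

#' Construct a two-group expression experiment
#'
#' @param matrix Numeric probe x sample matrix with probe row names.
#' @param groups Named character vector mapping sample -> `"test"` /
#'   `"control"`; names must match the matrix columns.
#' @param probe_map Tibble with columns `probe`, `gene_id`; probes mapping to
#'   more than one gene (several rows) are *homologous*, probes mapping to
#'   exactly one gene are *unique*.
#' @param design `"unpaired"` (default) or `"paired"`; a paired design
#'   requires equal group sizes and pairs samples by their order within each
#'   group.
#' @param ip_derived Was the mRNA prepared by immunoprecipitation? (Affects
#'   the default significance threshold; see [select_alpha()].)
#' @param experiment_id Optional identifier carried through to call sets.
#' @return An `expression_experiment` list.
#' @export
expression_experiment <- function(matrix, groups, probe_map,
                                  design = c("unpaired", "paired"),
                                  ip_derived = FALSE, experiment_id = "exp") {
  design <- match.arg(design)
  if (is.null(rownames(matrix))) abort("`matrix` must have probe row names.")
  if (is.null(names(groups)) || !all(colnames(matrix) %in% names(groups))) {
    abort("`groups` must be a named vector covering every sample column.")
  }
  groups <- groups[colnames(matrix)]
  if (!all(groups %in% c("test", "control"))) {
    abort("group labels must be 'test' or 'control'.")
  }
  n_test <- sum(groups == "test"); n_control <- sum(groups == "control")
  if (n_test < 2 || n_control < 2) {
    abort("need at least 2 samples per group.")
  }
  if (design == "paired" && n_test != n_control) {
    abort("paired design requires equal group sizes.")
  }
  probe_map <- dplyr::distinct(as_tibble(probe_map)[, c("probe", "gene_id")])
  structure(
    list(matrix = matrix, groups = groups, probe_map = probe_map,
         design = design, ip_derived = ip_derived,
         experiment_id = experiment_id),
    class = "expression_experiment"
  )
}

#' Significance threshold for gene calling
#'
#' Returns 0.05 when either group has exactly two samples or the mRNA was
#' prepared by immunoprecipitation; 0.01 otherwise.
#'
#' @param n_test,n_control Samples per group (each >= 2).
#' @param ip_derived Immunoprecipitation-derived mRNA?
#' @return 0.05 or 0.01.
#' @export
select_alpha <- function(n_test, n_control, ip_derived = FALSE) {
  if (n_test < 2 || n_control < 2) {
    abort("t-test undefined: need at least 2 samples per group.")
  }
  if (min(n_test, n_control) == 2 || isTRUE(ip_derived)) 0.05 else 0.01
}

#' Per-probe one-sided t-tests
#'
#' For every probe, two one-sided pooled-variance Student t-tests:
#' `p_up` tests test > control, `p_down` tests test < control. With a paired
#' design the test is a paired t-test on per-pair differences. Probes with
#' zero pooled variance and equal means get `p_up = p_down = 1`; zero
#' variance with unequal means gives 0/1 according to the sign. Probes with
#' missing values are tested on the available samples when at least two per
#' group remain, otherwise skipped (`NA`).
#'
#' @param experiment An `expression_experiment`.
#' @param mode `"one_sided"` (default, two independent one-sided tests) or
#'   `"two_sided"` (a single two-sided test whose p is assigned to the side
#'   matching the sign of the mean difference; the other side gets 1).
#' @return Tibble with columns `probe`, `p_up`, `p_down`, `t`, `df`,
#'   `mean_test`, `mean_control`.
#' @export
probe_tests <- function(experiment, mode = c("one_sided", "two_sided")) {
  mode <- match.arg(mode)
  stopifnot(inherits(experiment, "expression_experiment"))
  mat <- experiment$matrix
  test_idx <- which(experiment$groups == "test")
  ctrl_idx <- which(experiment$groups == "control")

  if (experiment$design == "paired") {
    diffs <- mat[, test_idx, drop = FALSE] - mat[, ctrl_idx, drop = FALSE]
    n <- rowSums(!is.na(diffs))
    m <- rowMeans(diffs, na.rm = TRUE)
    s <- apply(diffs, 1, sd, na.rm = TRUE)
    df <- n - 1
    se <- s / sqrt(n)
    tstat <- m / se
    usable <- n >= 2
    mean_test <- rowMeans(mat[, test_idx, drop = FALSE], na.rm = TRUE)
    mean_ctrl <- rowMeans(mat[, ctrl_idx, drop = FALSE], na.rm = TRUE)
  } else {
    xt <- mat[, test_idx, drop = FALSE]
    xc <- mat[, ctrl_idx, drop = FALSE]
    n1 <- rowSums(!is.na(xt)); n2 <- rowSums(!is.na(xc))
    m1 <- rowMeans(xt, na.rm = TRUE); m2 <- rowMeans(xc, na.rm = TRUE)
    v1 <- row_var(xt); v2 <- row_var(xc)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    usable <- n1 >= 2 & n2 >= 2
    mean_test <- m1; mean_ctrl <- m2
  }

  delta <- mean_test - mean_ctrl
  p_up <- pt(tstat, df = df, lower.tail = FALSE)
  p_down <- pt(tstat, df = df, lower.tail = TRUE)
  # zero-variance probes: se = 0 -> t is +/-Inf or NaN
  zero_se <- usable & (is.nan(tstat) | is.infinite(tstat))
  eq <- zero_se & abs(delta) < .Machine$double.eps^0.5
  p_up[eq] <- 1; p_down[eq] <- 1
  gt <- zero_se & !eq & delta > 0
  lt <- zero_se & !eq & delta < 0
  p_up[gt] <- 0; p_down[gt] <- 1
  p_up[lt] <- 1; p_down[lt] <- 0

  if (mode == "two_sided") {
    p2 <- 2 * pmin(p_up, p_down)
    p2 <- pmin(p2, 1)
    new_up <- if_else(delta > 0, p2, 1)
    new_down <- if_else(delta < 0, p2, 1)
    keep <- eq | gt | lt
    p_up <- if_else(keep, p_up, new_up)
    p_down <- if_else(keep, p_down, new_down)
  }

  p_up[!usable] <- NA_real_
  p_down[!usable] <- NA_real_

  tibble(
    probe = rownames(mat), p_up = unname(p_up), p_down = unname(p_down),
    t = unname(tstat), df = unname(df),
    mean_test = unname(mean_test), mean_control = unname(mean_ctrl)
  )
}

row_var <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
}

#' Call genes up/down from probe-level tests
#'
#' A gene is called in a direction when at least one *unique* probe is
#' significant in that direction, or, if the gene is represented only by
#' *homologous* probes, when at least two homologous probes are significant
#' in that same direction. A gene qualifying in both directions is resolved
#' to the direction with the smaller best p-value and flagged
#' (`conflict = TRUE`); genes without mapped probes are excluded from the
#' call set.
#'
#' @param experiment An `expression_experiment`.
#' @param alpha Significance threshold; defaults to [select_alpha()] applied
#'   to the experiment's group sizes and `ip_derived` flag.
#' @param mode Passed to [probe_tests()].
#' @param probe_p Optionally, a precomputed [probe_tests()] tibble.
#' @return A `gene_calls` tibble with columns `gene_id`, `up_call`
#'   (`"up"`/`"not_up"`), `down_call` (`"down"`/`"not_down"`), `best_p_up`,
#'   `best_p_down`, `n_probes_significant_up`, `n_probes_significant_down`,
#'   `conflict`; attributes `experiment_id` and `alpha`.
#' @export
call_genes <- function(experiment, alpha = NULL,
                       mode = c("one_sided", "two_sided"), probe_p = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(experiment, "expression_experiment"))
  if (is.null(alpha)) {
    alpha <- select_alpha(sum(experiment$groups == "test"),
                          sum(experiment$groups == "control"),
                          experiment$ip_derived)
  }
  if (is.null(probe_p)) probe_p <- probe_tests(experiment, mode = mode)

  map <- experiment$probe_map
  n_genes_per_probe <- table(map$probe)
  map$is_unique <- as.integer(n_genes_per_probe[map$probe]) == 1L
  map <- dplyr::filter(map, .data$probe %in% probe_p$probe)
  dat <- dplyr::inner_join(map, probe_p, by = "probe")
  dat <- dplyr::filter(dat, !is.na(.data$p_up) & !is.na(.data$p_down))
  if (nrow(dat) == 0) abort("no testable probes map to any gene.")

  per_gene <- dat |>
    group_by(.data$gene_id) |>
    summarise(
      has_unique = any(.data$is_unique),
      n_sig_up_unique = sum(.data$is_unique & .data$p_up < alpha),
      n_sig_down_unique = sum(.data$is_unique & .data$p_down < alpha),
      n_sig_up_homol = sum(!.data$is_unique & .data$p_up < alpha),
      n_sig_down_homol = sum(!.data$is_unique & .data$p_down < alpha),
      best_p_up = min(.data$p_up),
      best_p_down = min(.data$p_down),
      .groups = "drop"
    )

  up_ok <- per_gene$n_sig_up_unique >= 1 |
    (!per_gene$has_unique & per_gene$n_sig_up_homol >= 2)
  down_ok <- per_gene$n_sig_down_unique >= 1 |
    (!per_gene$has_unique & per_gene$n_sig_down_homol >= 2)

  conflict <- up_ok & down_ok
  keep_up <- conflict & per_gene$best_p_up <= per_gene$best_p_down
  up_ok[conflict] <- keep_up[conflict]
  down_ok[conflict] <- !keep_up[conflict]

  out <- tibble(
    gene_id = per_gene$gene_id,
    up_call = if_else(up_ok, "up", "not_up"),
    down_call = if_else(down_ok, "down", "not_down"),
    best_p_up = per_gene$best_p_up,
    best_p_down = per_gene$best_p_down,
    n_probes_significant_up = per_gene$n_sig_up_unique + per_gene$n_sig_up_homol,
    n_probes_significant_down = per_gene$n_sig_down_unique + per_gene$n_sig_down_homol,
    conflict = conflict
  )
  attr(out, "experiment_id") <- experiment$experiment_id
  attr(out, "alpha") <- alpha
  class(out) <- c("gene_calls", class(out))
  out
}
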