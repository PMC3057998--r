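# Cross-experiment regulation concordance (CU-DREAM): genes present in two
# experiments are cross-tabulated into regulated-in-both / in-one / in-
# neither and tested by chi-square with an odds ratio; plus a multi-
# experiment commonality score comparing how often L1 genes vs other genes
# are commonly down-regulated.

regulated_in <- function(calls, direction) {
  switch(direction,
    up = calls$up_call == "up",
    down = calls$down_call == "down",
    not_up = calls$up_call != "up",
    not_down = calls$down_call != "down",
    abort(sprintf("unknown direction '%s'.", direction))
  )
}

#' Cross-tabulate regulation calls of two experiments
#'
#' Over the shared gene universe (genes carrying calls in both experiments),
#' builds the 2x2 table `a` = regulated in both, `b` = regulated in B only,
#' `c` = regulated in A only, `d` = regulated in neither, and applies
#' [chisq_or()]. A significantly non-random table indicates the two
#' conditions regulate a shared gene set.
#'
#' @param calls_a,calls_b Gene call tibbles from [call_genes()].
#' @param direction_a,direction_b Regulation category per experiment:
#'   `"up"`, `"down"`, or the complements `"not_up"` / `"not_down"` (used
#'   for mixed analyses such as up-in-knockdown vs not-up-in-cancer).
#' @return An `l1_xexp` object: fields `experiment_a`, `experiment_b`,
#'   `direction_a`, `direction_b`, `table` (`contingency_2x2`),
#'   `association` (`l1_assoc`), `n_shared_genes`.
#' @export
intersect_experiments <- function(calls_a, calls_b,
                                  direction_a = "down", direction_b = "down") {
  calls_a <- as_tibble(calls_a); calls_b <- as_tibble(calls_b)
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) abort("empty call set.")
  shared <- intersect(calls_a$gene_id, calls_b$gene_id)
  if (length(shared) == 0) abort("shared gene universe is empty.")
  a_tab <- calls_a[match(shared, calls_a$gene_id), ]
  b_tab <- calls_b[match(shared, calls_b$gene_id), ]
  reg_a <- regulated_in(a_tab, direction_a)
  reg_b <- regulated_in(b_tab, direction_b)
  tab <- contingency_2x2(
    a = sum(reg_a & reg_b), b = sum(!reg_a & reg_b),
    c = sum(reg_a & !reg_b), d = sum(!reg_a & !reg_b),
    row_labels = c(paste0("B_", direction_b), paste0("B_not_", direction_b)),
    col_labels = c(paste0("A_", direction_a), paste0("A_not_", direction_a))
  )
  structure(
    list(
      experiment_a = attr(calls_a, "experiment_id") %||% "A",
      experiment_b = attr(calls_b, "experiment_id") %||% "B",
      direction_a = direction_a, direction_b = direction_b,
      table = tab, association = chisq_or(tab),
      n_shared_genes = length(shared)
    ),
    class = "l1_xexp"
  )
}

#' @export
print.l1_xexp <- function(x, ...) {
  cat(sprintf("CU-DREAM: %s (%s) x %s (%s), %d shared genes\n",
              x$experiment_a, x$direction_a, x$experiment_b, x$direction_b,
              x$n_shared_genes))
  print(x$association)
  invisible(x)
}

#' @rdname intersect_experiments
#' @param x An `l1_xexp` object.
#' @param ... Unused.
#' @method tidy l1_xexp
#' @export
tidy.l1_xexp <- function(x, ...) {
  dplyr::mutate(
    tidy(x$association),
    experiment_a = x$experiment_a, experiment_b = x$experiment_b,
    direction_a = x$direction_a, direction_b = x$direction_b,
    n_shared_genes = x$n_shared_genes,
    .before = 1
  )
}

#' @rdname intersect_experiments
#' @method glance l1_xexp
#' @export
glance.l1_xexp <- function(x, ...) tidy(x, ...)

#' CU-DREAM stratified by a gene set
#'
#' Runs [intersect_experiments()] separately on the shared universe
#' restricted to a gene set (e.g. L1-hosting genes) and on its complement.
#' Strata smaller than 10 genes are flagged `low_n`.
#'
#' @inheritParams intersect_experiments
#' @param gene_set Character vector of gene ids defining the stratum.
#' @return List with elements `within_set` and `outside_set`, each an
#'   `l1_xexp` with an added `low_n` flag.
#' @export
stratified_intersect <- function(calls_a, calls_b, gene_set,
                                 direction_a = "down", direction_b = "down") {
  calls_a <- as_tibble(calls_a); calls_b <- as_tibble(calls_b)
  shared <- intersect(calls_a$gene_id, calls_b$gene_id)
  if (length(shared) == 0) abort("shared gene universe is empty.")
  inside <- intersect(shared, gene_set)
  outside <- setdiff(shared, gene_set)
  run_stratum <- function(ids) {
    if (length(ids) == 0) abort("stratum is empty.")
    res <- intersect_experiments(
      calls_a[calls_a$gene_id %in% ids, ],
      calls_b[calls_b$gene_id %in% ids, ],
      direction_a, direction_b
    )
    res$low_n <- length(ids) < 10
    res
  }
  list(within_set = run_stratum(inside), outside_set = run_stratum(outside))
}

#' Commonality of down-regulation across experiments
#'
#' For every gene in the universe (present in all call sets by default, or
#' in any), counts the experiments in which it is down-regulated, then
#' compares mean counts between a gene set (L1-hosting genes) and its
#' complement with a homoscedastic t-test.
#'
#' @param call_sets List of gene call tibbles ([call_genes()] outputs),
#'   length >= 2.
#' @param gene_set Character vector of gene ids.
#' @param universe `"all"` (genes called in every experiment, default) or
#'   `"any"` (genes called in at least one; absent calls count as not-down).
#' @param direction Regulation category counted per experiment (default
#'   `"down"`).
#' @return A `commonality_score` list: `per_gene` tibble (`gene_id`,
#'   `n_down`, `in_set`), `mean_in_set`, `mean_out_set`, `t`, `p_value`,
#'   `n_experiments`.
#' @export
commonality_score <- function(call_sets, gene_set,
                              universe = c("all", "any"),
                              direction = "down") {
  universe <- match.arg(universe)
  if (length(call_sets) < 2) abort("need at least 2 call sets.")
  ids <- lapply(call_sets, function(x) as_tibble(x)$gene_id)
  genes <- if (universe == "all") Reduce(intersect, ids) else Reduce(union, ids)
  if (length(genes) == 0) abort("gene universe is empty.")
  counts <- rep(0L, length(genes))
  for (cs in call_sets) {
    cs <- as_tibble(cs)
    idx <- match(genes, cs$gene_id)
    hit <- !is.na(idx) & regulated_in(cs[replace(idx, is.na(idx), 1L), ],
                                      direction)
    counts <- counts + as.integer(hit)
  }
  in_set <- genes %in% gene_set
  if (!any(in_set) || all(in_set)) {
    abort("`gene_set` must split the universe into two non-empty groups.")
  }
  tt <- numeric_feature_test("commonality", counts[in_set], counts[!in_set])
  structure(
    list(
      per_gene = tibble(gene_id = genes, n_down = counts, in_set = in_set),
      mean_in_set = mean(counts[in_set]),
      mean_out_set = mean(counts[!in_set]),
      t = tt$statistic, p_value = tt$p,
      n_experiments = length(call_sets)
    ),
    class = "commonality_score"
  )
}

#' @export
print.commonality_score <- function(x, ...) {
  cat(sprintf(
    "Commonality over %d experiments: mean %s = %.4f (in set) vs %.4f (out), t = %.3f, p = %.3g\n",
    x$n_experiments, "down-count", x$mean_in_set, x$mean_out_set, x$t, x$p_value
  ))
  invisible(x)
}

#' @rdname commonality_score
#' @param x A `commonality_score` object.
#' @param ... Unused.
#' @method glance commonality_score
#' @export
glance.commonality_score <- function(x, ...) {
  tibble(
    mean_in_set = x$mean_in_set, mean_out_set = x$mean_out_set,
    t = x$t, p_value = x$p_value, n_experiments = x$n_experiments,
    n_genes = nrow(x$per_gene)
  )
}
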