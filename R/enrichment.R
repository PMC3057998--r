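# 2x2 contingency statistics: Pearson chi-square (df = 1, no continuity
# correction), odds ratio, and Woolf (log-scale) 95% confidence interval.
# This is the statistic behind the enrichment tables ("genes containing L1s"
# x "regulated") and the cross-experiment concordance tables.

#' Build a labeled 2x2 contingency table
#'
#' Cell layout: `a` = row 1 / col 1, `b` = row 1 / col 2, `c` = row 2 /
#' col 1, `d` = row 2 / col 2.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param row_labels,col_labels Length-2 character labels.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d,
                            row_labels = c("row1", "row2"),
                            col_labels = c("col1", "col2")) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    abort("all four cells must be non-negative integers.")
  }
  if (sum(counts) <= 0) abort("table total must be positive.")
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         d = as.numeric(d),
         row_labels = row_labels, col_labels = col_labels),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(x$row_labels, x$col_labels))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2, 2,
         dimnames = list(x$row_labels, x$col_labels))
}

#' Chi-square test, odds ratio and Woolf CI for a 2x2 table
#'
#' Computes the Pearson chi-square statistic on the raw counts
#' (df = 1, no continuity correction by default), the odds ratio
#' OR = (a d)/(b c) and its Woolf 95% confidence interval
#' exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero,
#' 0.5 is added to every cell for the OR and CI only (Haldane-Anscombe
#' correction, flagged via `zero_cell_corrected`); the chi-square always uses
#' the raw counts. A zero row or column margin makes the test degenerate:
#' p = 1, OR undefined.
#'
#' @param table A `contingency_2x2`, or a 2x2 matrix, or a length-4 numeric
#'   vector `c(a, b, c, d)`.
#' @param continuity_correction Apply the Yates correction to the chi-square
#'   (off by default; the large-table analyses this package reproduces use
#'   the uncorrected statistic).
#' @return An `l1_assoc` object with fields `table`, `chi_square`, `p_value`,
#'   `odds_ratio`, `ci95_low`, `ci95_high`, `zero_cell_corrected`,
#'   `degenerate`.
#'
#' @examples
#' chisq_or(contingency_2x2(30, 70, 10, 90))
#' @export
chisq_or <- function(table, continuity_correction = FALSE) {
  tab <- as_contingency(table)
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  n <- a + b + c + d
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d

  degenerate <- any(c(row1, row2, col1, col2) == 0)
  if (degenerate) {
    chi2 <- 0
    p <- 1
    or <- NA_real_
    ci <- c(NA_real_, NA_real_)
    corrected <- FALSE
  } else {
    delta <- abs(a * d - b * c)
    if (continuity_correction) delta <- max(delta - n / 2, 0)
    chi2 <- n * delta^2 / (row1 * row2 * col1 * col2)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    corrected <- any(c(a, b, c, d) == 0)
    if (corrected) {
      a2 <- a + 0.5; b2 <- b + 0.5; c2 <- c + 0.5; d2 <- d + 0.5
    } else {
      a2 <- a; b2 <- b; c2 <- c; d2 <- d
    }
    or <- (a2 * d2) / (b2 * c2)
    se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
    ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  }

  structure(
    list(
      table = tab,
      chi_square = chi2,
      p_value = p,
      odds_ratio = or,
      ci95_low = ci[1],
      ci95_high = ci[2],
      zero_cell_corrected = corrected,
      degenerate = degenerate,
      continuity_correction = continuity_correction
    ),
    class = "l1_assoc"
  )
}

as_contingency <- function(table) {
  if (inherits(table, "contingency_2x2")) return(table)
  if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    return(contingency_2x2(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  }
  if (is.numeric(table) && length(table) == 4) {
    return(contingency_2x2(table[1], table[2], table[3], table[4]))
  }
  abort("`table` must be a contingency_2x2, a 2x2 matrix, or c(a, b, c, d).")
}

#' @export
print.l1_assoc <- function(x, ...) {
  cat("2x2 association\n")
  print(x$table)
  cat(sprintf("chi-square = %.4g (df = 1), p = %.3g\n", x$chi_square, x$p_value))
  if (x$degenerate) {
    cat("degenerate margin: odds ratio undefined\n")
  } else {
    cat(sprintf("OR = %.4g (95%% CI %.4g-%.4g)%s\n",
                x$odds_ratio, x$ci95_low, x$ci95_high,
                if (x$zero_cell_corrected) " [0.5 zero-cell correction]" else ""))
  }
  invisible(x)
}

#' @rdname chisq_or
#' @param x An `l1_assoc` object.
#' @param ... Unused.
#' @method tidy l1_assoc
#' @export
tidy.l1_assoc <- function(x, ...) {
  tibble(
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    chi_square = x$chi_square, p_value = x$p_value,
    odds_ratio = x$odds_ratio, ci95_low = x$ci95_low, ci95_high = x$ci95_high,
    zero_cell_corrected = x$zero_cell_corrected, degenerate = x$degenerate
  )
}

#' @rdname chisq_or
#' @method glance l1_assoc
#' @export
glance.l1_assoc <- function(x, ...) tidy(x, ...)

#' Membership table: regulated calls x gene-set membership
#'
#' Cross-tabulates the regulation status of the genes in a call set against
#' membership in a gene set (typically the genes hosting intragenic L1s):
#' `a` = regulated and in the set, `b` = not regulated and in the set,
#' `c` = regulated outside the set, `d` = not regulated outside the set.
#' The universe is the set of genes carrying calls; gene-set members without
#' calls are ignored.
#'
#' @param calls A gene call tibble from [call_genes()].
#' @param gene_set Character vector of gene ids (e.g. L1-hosting genes).
#' @param direction `"up"` or `"down"`: which regulation direction defines
#'   the "regulated" column.
#' @return A `contingency_2x2`.
#' @export
build_membership_table <- function(calls, gene_set, direction = c("down", "up")) {
  direction <- match.arg(direction)
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) abort("`calls` is empty.")
  gene_set <- unique(as.character(gene_set))
  if (length(intersect(calls$gene_id, gene_set)) == 0) {
    abort("no overlap between the call universe and `gene_set`.")
  }
  reg <- if (direction == "up") calls$up_call == "up" else calls$down_call == "down"
  in_set <- calls$gene_id %in% gene_set
  contingency_2x2(
    a = sum(reg & in_set), b = sum(!reg & in_set),
    c = sum(reg & !in_set), d = sum(!reg & !in_set),
    row_labels = c("in_set", "not_in_set"),
    col_labels = c(paste0(direction, "_regulated"), "not_regulated")
  )
}

#' Enrichment of a gene set among regulated genes
#'
#' Convenience wrapper: builds the membership table with
#' [build_membership_table()] and applies [chisq_or()].
#'
#' @inheritParams build_membership_table
#' @inheritParams chisq_or
#' @return An `l1_assoc`.
#' @export
enrichment_test <- function(calls, gene_set, direction = c("down", "up"),
                            continuity_correction = FALSE) {
  direction <- match.arg(direction)
  chisq_or(build_membership_table(calls, gene_set, direction),
           continuity_correction = continuity_correction)
}
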