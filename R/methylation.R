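# COBRA (combined bisulfite restriction analysis) methylation quantification
# and methylation-expression correlation.

#' COBRA methylation percentage
#'
#' Methylation percentage from band intensities: the methylated (TaqI-cut,
#' 80-bp band) intensity divided by the sum of methylated and unmethylated
#' (TasI-cut, 97-bp band) intensities, times 100.
#'
#' @param taqI Intensity of the methylation-dependent (TaqI) band(s);
#'   non-negative, vectorised.
#' @param tasI Intensity of the methylation-independent (TasI) band(s).
#' @return Percentage in `[0, 100]`.
#' @examples
#' cobra_percent(30, 10) # 75
#' @export
cobra_percent <- function(taqI, tasI) {
  if (any(taqI < 0) || any(tasI < 0)) abort("intensities must be non-negative.")
  total <- taqI + tasI
  if (any(total == 0)) abort("taqI + tasI must be positive.")
  100 * taqI / total
}

#' COBRA percentages for a band-intensity table
#'
#' @param bands Tibble with columns `sample_id`, `locus_id`, `taqI`, `tasI`.
#' @return `bands` with a `percent_methylation` column added.
#' @export
cobra_table <- function(bands) {
  bands <- as_tibble(bands)
  needed <- c("sample_id", "locus_id", "taqI", "tasI")
  if (!all(needed %in% names(bands))) {
    abort(sprintf("`bands` needs columns: %s.", paste(needed, collapse = ", ")))
  }
  dplyr::mutate(bands,
                percent_methylation = cobra_percent(.data$taqI, .data$tasI))
}

#' Pearson correlation of methylation with expression
#'
#' Product-moment correlation between per-sample methylation percentages and
#' expression (or RNA) levels, with the two-sided p-value from the
#' t-transform of r.
#'
#' @param x,y Paired numeric vectors (>= 3 finite pairs).
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
methylation_expression_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired finite observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in one of the vectors.")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
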