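# AGO2 binding-site analyses: site length filtering (CLIP sites > 18 bp),
# gene-level association between L1 hosting and site presence among
# up-regulated genes, and the signed-distance proximity histogram of sites
# around intragenic L1s (25-kb bins spanning +/- 600 kb).

#' Filter binding sites by length
#'
#' Keeps sites strictly longer than `min_bp` (default 18 bp, so an 18-bp
#' site is excluded and a 19-bp site kept). Idempotent.
#'
#' @param sites Tibble with `site_id`, `chrom`, `start`, `end` (BED
#'   convention).
#' @param min_bp Exclusive lower bound on site length.
#' @return The filtered tibble with a `length_bp` column added.
#' @export
filter_sites <- function(sites, min_bp = 18) {
  sites <- validate_intervals(as_tibble(sites), "site_id", "sites")
  sites$length_bp <- as.integer(sites$end - sites$start)
  dplyr::filter(sites, .data$length_bp > min_bp)
}

#' Association between L1 hosting and AGO2 site presence
#'
#' Among up-regulated genes, cross-tabulates whether a gene hosts an
#' intragenic L1 against whether its transcript span overlaps at least one
#' (filtered) binding site, and applies [chisq_or()].
#'
#' @param sites Filtered binding-site tibble (see [filter_sites()]).
#' @param genes Gene tibble as in [classify_l1_locations()].
#' @param l1_genes Character vector of L1-hosting gene ids.
#' @param upregulated Character vector of up-regulated gene ids (the
#'   universe of the test).
#' @return List with `table` (`contingency_2x2`) and `association`
#'   (`l1_assoc`).
#' @export
ago2_l1_association <- function(sites, genes, l1_genes, upregulated) {
  genes <- validate_intervals(as_tibble(genes), "gene_id", "genes")
  upregulated <- intersect(unique(upregulated), genes$gene_id)
  if (length(upregulated) == 0) abort("empty up-regulated gene set.")
  uni <- genes[genes$gene_id %in% upregulated, , drop = FALSE]

  has_site <- rep(FALSE, nrow(uni))
  if (nrow(sites) > 0) {
    hits <- GenomicRanges::findOverlaps(
      intervals_to_granges(uni), intervals_to_granges(as_tibble(sites)),
      ignore.strand = TRUE
    )
    has_site[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  has_l1 <- uni$gene_id %in% l1_genes
  tab <- contingency_2x2(
    a = sum(has_l1 & has_site), b = sum(has_l1 & !has_site),
    c = sum(!has_l1 & has_site), d = sum(!has_l1 & !has_site),
    row_labels = c("L1_gene", "no_L1"),
    col_labels = c("has_site", "no_site")
  )
  list(table = tab, association = chisq_or(tab))
}

#' Signed-distance histogram of binding sites around intragenic L1s
#'
#' For every (intragenic L1, site) pair on the same chromosome, the signed
#' distance from the L1 anchor to the site midpoint is binned into
#' fixed-width bins spanning `[-range_bp, +range_bp)` (defaults: 25-kb bins
#' over +/- 600 kb, i.e. 48 bins). Sign convention: positive = downstream of
#' the L1 in the host gene's transcription direction. Anchoring uses the L1
#' 5' edge in host-gene orientation by default. L1s are first restricted to
#' the requested orientation of the L1 strand relative to its host gene
#' strand; a site within range of several L1s counts once per pair.
#'
#' @param sites Filtered binding-site tibble.
#' @param l1s Classified L1 tibble; intragenic rows must carry
#'   `host_strand` (host gene strand) — see [host_strand_table()].
#' @param orientation `"antisense"` (default) or `"sense"`: L1 strand
#'   relative to the host gene strand.
#' @param bin_width_bp Bin width (default 25000).
#' @param range_bp Half-range (default 600000); must be a multiple of
#'   `bin_width_bp`.
#' @param anchor `"five_prime"` (default), `"three_prime"` or `"midpoint"`
#'   of the L1, taken in host-gene orientation.
#' @return An `l1_prox_hist` object: tibble of `bin_start`, `bin_end`
#'   (signed bp), `count`, with attributes `n_sites_in_range`, `n_anchors`,
#'   `orientation`, `bin_width_bp`, `range_bp`, `anchor`.
#' @export
l1_proximity_histogram <- function(sites, l1s,
                                   orientation = c("antisense", "sense"),
                                   bin_width_bp = 25000, range_bp = 600000,
                                   anchor = c("five_prime", "three_prime",
                                              "midpoint")) {
  orientation <- match.arg(orientation)
  anchor <- match.arg(anchor)
  if (range_bp %% bin_width_bp != 0) {
    abort("`range_bp` must be a multiple of `bin_width_bp`.")
  }
  l1s <- as_tibble(l1s)
  if (!"location_class" %in% names(l1s)) {
    abort("`l1s` must be classified first: run classify_l1_locations().")
  }
  intra <- dplyr::filter(l1s, .data$location_class == "intragenic")
  if (!"host_strand" %in% names(intra)) {
    abort("`l1s` must carry a `host_strand` column; see host_strand_table().")
  }
  no_strand <- is.na(intra$host_strand) | !(intra$host_strand %in% c("+", "-"))
  if (any(no_strand)) {
    warn(sprintf("%d intragenic L1(s) lack host gene strand; skipped.",
                 sum(no_strand)))
    intra <- intra[!no_strand, , drop = FALSE]
  }
  want_sense <- orientation == "sense"
  is_sense <- intra$strand == intra$host_strand
  intra <- intra[if (want_sense) is_sense else !is_sense, , drop = FALSE]

  n_bins <- 2L * as.integer(range_bp / bin_width_bp)
  bin_start <- seq(-range_bp, range_bp - bin_width_bp, by = bin_width_bp)
  counts <- rep(0L, n_bins)
  n_in_range <- 0L

  sites <- as_tibble(sites)
  if (nrow(intra) > 0 && nrow(sites) > 0) {
    plus <- intra$host_strand == "+"
    anchor_pos <- switch(anchor,
      five_prime = if_else(plus, intra$start, intra$end),
      three_prime = if_else(plus, intra$end, intra$start),
      midpoint = (intra$start + intra$end) / 2
    )
    site_mid <- (sites$start + sites$end) / 2
    for (i in seq_len(nrow(intra))) {
      on_chrom <- sites$chrom == intra$chrom[i]
      if (!any(on_chrom)) next
      d <- site_mid[on_chrom] - anchor_pos[i]
      if (!plus[i]) d <- -d
      d <- d[d >= -range_bp & d < range_bp]
      if (length(d) == 0) next
      bin_idx <- floor(d / bin_width_bp) + range_bp / bin_width_bp + 1
      tabulated <- tabulate(bin_idx, nbins = n_bins)
      counts <- counts + tabulated
      n_in_range <- n_in_range + length(d)
    }
  }

  out <- tibble(
    bin_start = bin_start,
    bin_end = bin_start + bin_width_bp,
    count = counts
  )
  attr(out, "n_sites_in_range") <- n_in_range
  attr(out, "n_anchors") <- nrow(intra)
  attr(out, "orientation") <- orientation
  attr(out, "bin_width_bp") <- bin_width_bp
  attr(out, "range_bp") <- range_bp
  attr(out, "anchor") <- anchor
  class(out) <- c("l1_prox_hist", class(out))
  out
}

#' Host gene strand per intragenic L1
#'
#' Adds a `host_strand` column to a classified L1 tibble: the strand of the
#' (first) host gene of each intragenic L1, `NA` for intergenic L1s or when
#' host genes disagree in strand (ambiguous anchoring).
#'
#' @param l1s Classified L1 tibble.
#' @param genes Gene tibble.
#' @return `l1s` with `host_strand` added.
#' @export
host_strand_table <- function(l1s, genes) {
  genes <- as_tibble(genes)
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  l1s <- as_tibble(l1s)
  l1s$host_strand <- vapply(l1s$host_genes, function(g) {
    if (length(g) == 0) return(NA_character_)
    s <- unique(unname(strand_of[g]))
    if (length(s) == 1 && s %in% c("+", "-")) s else NA_character_
  }, character(1))
  l1s
}

#' @rdname l1_proximity_histogram
#' @param object An `l1_prox_hist`.
#' @param ... Unused.
#' @method autoplot l1_prox_hist
#' @export
autoplot.l1_prox_hist <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2e3, y = .data$count
  )) +
    ggplot2::geom_col(width = attr(object, "bin_width_bp") / 1e3,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "distance from L1 anchor (kb, downstream positive)",
      y = "binding sites",
      title = sprintf("AGO2 binding sites around %s L1s",
                      attr(object, "orientation"))
    ) +
    ggplot2::theme_minimal()
}
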