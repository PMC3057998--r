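# Genome annotation: intragenic/intergenic classification of L1 elements and
# identification of intergenic L1s flanking gene termini.
#
# All interval tibbles use BED conventions: 0-based, half-open [start, end),
# with columns chrom / start / end / strand. Strand is "+", "-" or "*"
# (unknown). Genes carry gene_id (unique) and optionally symbol; L1s carry
# l1_id.

validate_intervals <- function(x, id_col, what) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals.", what))
  }
  x <- as_tibble(x)
  needed <- c(id_col, "chrom", "start", "end")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"strand" %in% names(x)) x$strand <- "*"
  x$strand <- as.character(x$strand)
  x$strand[is.na(x$strand) | !(x$strand %in% c("+", "-"))] <- "*"
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    abort(sprintf("`%s` has empty chromosome names.", what))
  }
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)) ||
      any(x$start >= x$end) || any(x$start < 0)) {
    abort(sprintf(
      "`%s` has invalid intervals: require 0 <= start < end.", what
    ))
  }
  if (anyDuplicated(x[[id_col]])) {
    abort(sprintf("`%s` has duplicated %s values.", what, id_col))
  }
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand
  )
}

#' Classify L1 elements as intragenic or intergenic
#'
#' An L1 element is *intragenic* when its interval overlaps the transcript
#' span of at least one gene by one or more base pairs (the weakest defensible
#' reading of a location-based classification against a RefSeq-style
#' annotation); otherwise it is *intergenic*. A stricter containment mode
#' requires the L1 to lie entirely within a gene span.
#'
#' @param l1s Tibble of L1 intervals with columns `l1_id`, `chrom`, `start`,
#'   `end` and optionally `strand` (BED conventions: 0-based half-open).
#' @param genes Tibble of gene intervals with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param mode `"overlap"` (default: any >= 1 bp overlap makes an L1
#'   intragenic) or `"containment"` (the L1 must lie fully inside a gene span).
#'
#' @return The input `l1s` tibble with three added columns:
#'   `location_class` (`"intragenic"` / `"intergenic"`), `host_genes`
#'   (list-column of host `gene_id`s, empty unless intragenic) and
#'   `n_host_genes`. An L1 overlapping several genes is intragenic once and
#'   lists every host gene.
#'
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0,
#'                         end = 1000, strand = "+")
#' l1s <- tibble::tibble(l1_id = c("L1a", "L1b"), chrom = "chr1",
#'                       start = c(100, 5000), end = c(200, 6000),
#'                       strand = "+")
#' classify_l1_locations(l1s, genes)
#' @export
classify_l1_locations <- function(l1s, genes, mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  l1s <- validate_intervals(l1s, "l1_id", "l1s")
  genes <- validate_intervals(genes, "gene_id", "genes")

  shared <- intersect(unique(l1s$chrom), unique(genes$chrom))
  if (length(shared) == 0) {
    abort(sprintf(
      "No shared chromosomes between L1s (%s) and genes (%s): mismatched chromosome namespaces.",
      paste(head(unique(l1s$chrom), 3), collapse = ","),
      paste(head(unique(genes$chrom), 3), collapse = ",")
    ))
  }

  gr_l1 <- intervals_to_granges(l1s)
  gr_gene <- intervals_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(
    gr_l1, gr_gene,
    type = if (mode == "containment") "within" else "any",
    ignore.strand = TRUE
  )
  host <- vector("list", nrow(l1s))
  for (i in seq_along(host)) host[[i]] <- character(0)
  if (length(hits) > 0) {
    by_l1 <- split(
      genes$gene_id[S4Vectors::subjectHits(hits)],
      S4Vectors::queryHits(hits)
    )
    idx <- as.integer(names(by_l1))
    host[idx] <- lapply(by_l1, function(g) sort(unique(g)))
  }
  n_host <- lengths(host)
  l1s$location_class <- if_else(n_host > 0, "intragenic", "intergenic")
  l1s$host_genes <- host
  l1s$n_host_genes <- as.integer(n_host)
  l1s
}

#' Find intergenic L1s flanking gene termini
#'
#' For every intergenic L1 whose nearest edge lies within `window_bp` of a
#' gene's 5' or 3' terminus (outside the gene body), emits one assignment per
#' (L1, gene, end). Orientation is `"sense"` when the L1 strand equals the
#' gene strand, `"antisense"` otherwise; pairs where either strand is unknown
#' are skipped with a warning.
#'
#' @param l1s Classified L1 tibble, i.e. the output of
#'   [classify_l1_locations()]. Only intergenic L1s receive assignments.
#' @param genes Gene tibble as in [classify_l1_locations()]; strand required.
#' @param window_bp Flank window in base pairs, typically 1000 or 2000.
#'
#' @return Tibble with columns `l1_id`, `gene_id`, `gene_end`
#'   (`"five_prime"` / `"three_prime"`), `window_bp`, `orientation`
#'   (`"sense"` / `"antisense"`) and `distance_bp` (0 <= distance <= window).
#' @export
find_flanking_l1s <- function(l1s, genes, window_bp = 1000) {
  if (!("location_class" %in% names(l1s))) {
    abort("`l1s` must be classified first: run classify_l1_locations().")
  }
  stopifnot(is.numeric(window_bp), length(window_bp) == 1, window_bp > 0)
  genes <- validate_intervals(genes, "gene_id", "genes")
  inter <- dplyr::filter(as_tibble(l1s), .data$location_class == "intergenic")
  if (nrow(inter) == 0 || nrow(genes) == 0) {
    return(empty_flank_tbl())
  }

  n_unknown <- sum(inter$strand == "*") + sum(genes$strand == "*")
  if (n_unknown > 0) {
    warn(sprintf(
      "%d element(s) with unknown strand: their (L1, gene) pairs are skipped.",
      n_unknown
    ))
    inter <- dplyr::filter(inter, .data$strand != "*")
    genes <- dplyr::filter(genes, .data$strand != "*")
    if (nrow(inter) == 0 || nrow(genes) == 0) return(empty_flank_tbl())
  }

  # gene termini in genome coordinates: for "+" genes 5' = start, 3' = end;
  # reversed for "-" genes.
  termini <- dplyr::bind_rows(
    tibble(
      gene_id = genes$gene_id, chrom = genes$chrom,
      gene_strand = genes$strand, gene_end = "five_prime",
      pos = if_else(genes$strand == "+", genes$start, genes$end),
      side = if_else(genes$strand == "+", "left", "right")
    ),
    tibble(
      gene_id = genes$gene_id, chrom = genes$chrom,
      gene_strand = genes$strand, gene_end = "three_prime",
      pos = if_else(genes$strand == "+", genes$end, genes$start),
      side = if_else(genes$strand == "+", "right", "left")
    )
  )

  # GRanges of the outward window at each terminus; L1s overlapping the
  # window are candidates, exact edge distance computed afterwards.
  win_start <- if_else(termini$side == "right", termini$pos,
                       pmax(termini$pos - window_bp - 1, 0))
  win_end <- if_else(termini$side == "right", termini$pos + window_bp + 1,
                     termini$pos)
  keep <- win_end > win_start
  termini <- termini[keep, , drop = FALSE]
  gr_win <- GenomicRanges::GRanges(
    termini$chrom, IRanges::IRanges(win_start[keep] + 1L, win_end[keep])
  )
  gr_l1 <- intervals_to_granges(inter)
  hits <- GenomicRanges::findOverlaps(gr_l1, gr_win, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty_flank_tbl())

  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # distance from the terminus point to the nearest L1 edge, measured on the
  # outward (intergenic) side; an L1 edge exactly at the terminus has
  # distance 0.
  dist <- if_else(
    termini$side[si] == "right",
    inter$start[qi] - termini$pos[si],
    termini$pos[si] - inter$end[qi]
  )
  # an L1 straddling the window edge can overlap the window while its nearest
  # outward edge lies inside: clamp negatives (edge at/behind terminus) to 0
  # only when the L1 actually reaches the terminus side; intergenic L1s never
  # overlap gene bodies, so a negative distance means the L1 crosses the
  # terminus point itself, which cannot happen for a true terminus window.
  ok <- dist >= 0 & dist <= window_bp
  if (!any(ok)) return(empty_flank_tbl())
  qi <- qi[ok]; si <- si[ok]; dist <- dist[ok]

  out <- tibble(
    l1_id = inter$l1_id[qi],
    gene_id = termini$gene_id[si],
    gene_end = termini$gene_end[si],
    window_bp = as.integer(window_bp),
    orientation = if_else(inter$strand[qi] == termini$gene_strand[si],
                          "sense", "antisense"),
    distance_bp = as.integer(dist)
  )
  dplyr::arrange(out, .data$gene_id, .data$gene_end, .data$l1_id)
}

empty_flank_tbl <- function() {
  tibble(
    l1_id = character(0), gene_id = character(0), gene_end = character(0),
    window_bp = integer(0), orientation = character(0),
    distance_bp = integer(0)
  )
}
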