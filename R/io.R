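# Readers and writers for the pipeline's plain-text interchange formats.
# Standard genomic formats go through rtracklayer; tabular sidecars through
# readr. All interval tibbles leave these functions in BED convention
# (0-based, half-open).

granges_to_tibble <- function(gr, id_col, ids = NULL) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "*"
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand
  )
  if (is.null(ids)) {
    nm <- gr$name %||% as.character(seq_along(gr))
    nm[is.na(nm) | !nzchar(nm)] <- as.character(which(is.na(nm) | !nzchar(nm)))
    ids <- nm
  }
  out[[id_col]] <- ids
  dplyr::select(out, dplyr::all_of(id_col), "chrom", "start", "end", "strand")
}

#' Read a BED file of intervals
#'
#' @param path BED3/BED6 file.
#' @param id_col Name for the identifier column (`"gene_id"`, `"l1_id"`,
#'   `"site_id"`, ...); taken from the BED name field when present.
#' @return Tibble with `id_col`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`.
#' @export
read_bed <- function(path, id_col = "id") {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_tibble(gr, id_col)
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features (or all features when none are typed `gene`) and
#' converts to BED-convention coordinates.
#'
#' @param path GFF3 file.
#' @return Tibble with `gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(as.character(gr$type) == "gene")) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  ids <- gr$ID %||% gr$gene_id %||% as.character(seq_along(gr))
  out <- granges_to_tibble(gr, "gene_id", ids = as.character(ids))
  out$symbol <- as.character(gr$Name %||% out$gene_id)
  dplyr::select(out, "gene_id", "symbol", "chrom", "start", "end", "strand")
}

#' Read an L1 feature sidecar table
#'
#' Per-L1 structural attributes keyed by `l1_id`: categorical columns
#' (presence/absence of conserved sequence, CpG island, subfamily, ...) and
#' numeric columns (G-C content, intactness score, ...).
#'
#' @param path TSV with an `l1_id` column.
#' @return Tibble keyed by `l1_id`.
#' @export
read_l1_features <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"l1_id" %in% names(x)) abort("feature table must have an `l1_id` column.")
  x
}

#' Read a two-group expression experiment from plain-text files
#'
#' @param matrix_path TSV whose first column is the probe id and whose header
#'   names the samples.
#' @param groups_path CSV/TSV with columns `sample`, `group` (values `test`
#'   and `control`).
#' @param probe_map_path TSV with columns `probe`, `gene_id`; a probe mapping
#'   to several genes appears on several rows (or gene ids separated by
#'   commas in one row).
#' @param design `"unpaired"` or `"paired"`.
#' @param ip_derived Was the mRNA prepared by immunoprecipitation?
#' @return An `expression_experiment` list (see [expression_experiment()]).
#' @export
read_expression_experiment <- function(matrix_path, groups_path, probe_map_path,
                                       design = "unpaired", ip_derived = FALSE) {
  mat_tbl <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  probes <- as.character(mat_tbl[[1]])
  mat <- as.matrix(mat_tbl[, -1, drop = FALSE])
  rownames(mat) <- probes

  delim <- if (grepl("\\.tsv$", groups_path)) "\t" else ","
  groups_tbl <- readr::read_delim(groups_path, delim = delim,
                                  show_col_types = FALSE, progress = FALSE)
  groups <- setNames(as.character(groups_tbl$group), groups_tbl$sample)

  map_tbl <- readr::read_tsv(probe_map_path, show_col_types = FALSE,
                             progress = FALSE)
  map_tbl <- tidyr::separate_rows(map_tbl, "gene_id", sep = ",")
  probe_map <- dplyr::distinct(
    tibble(probe = as.character(map_tbl$probe),
           gene_id = trimws(as.character(map_tbl$gene_id)))
  )

  expression_experiment(mat, groups, probe_map, design = design,
                        ip_derived = ip_derived)
}

#' Write a tibble as TSV
#' @param x Tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  x <- as_tibble(x)
  list_cols <- vapply(x, is.list, logical(1))
  for (col in names(x)[list_cols]) {
    x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ",")
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#' @param x Interval tibble (BED convention) with an id column.
#' @param path Output file.
#' @param id_col Column holding the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, id_col = "id") {
  strand <- x$strand %||% rep("*", nrow(x))
  strand[!(strand %in% c("+", "-"))] <- "."
  bed <- tibble(
    chrom = x$chrom, start = as.integer(x$start), end = as.integer(x$end),
    name = as.character(x[[id_col]]), score = 0L, strand = strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
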