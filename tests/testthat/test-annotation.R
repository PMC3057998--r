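test_that("containment and non-overlap classify as expected", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0,
                          end = 1000, strand = "+")
  l1s <- tibble::tibble(
    l1_id = c("in", "out", "other_chrom"),
    chrom = c("chr1", "chr1", "chr9"),
    start = c(100, 5000, 10), end = c(200, 6000, 500),
    strand = "+"
  )
  res <- classify_l1_locations(l1s, genes)
  expect_equal(res$location_class, c("intragenic", "intergenic", "intergenic"))
  expect_equal(res$host_genes[[1]], "g1")
  expect_equal(res$host_genes[[2]], character(0))
  expect_equal(res$n_host_genes, c(1L, 0L, 0L))
})

test_that("a single-bp overlap is intragenic; containment mode is stricter", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100,
                          end = 200, strand = "+")
  edge <- tibble::tibble(l1_id = "e", chrom = "chr1", start = 199, end = 300,
                         strand = "+")
  expect_equal(classify_l1_locations(edge, genes)$location_class, "intragenic")
  expect_equal(classify_l1_locations(edge, genes, mode = "containment")$location_class,
               "intergenic")
  adjacent <- tibble::tibble(l1_id = "a", chrom = "chr1", start = 200,
                             end = 300, strand = "+")
  expect_equal(classify_l1_locations(adjacent, genes)$location_class,
               "intergenic")
})

test_that("disjoint chromosome namespaces are a hard error", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "1", start = 0, end = 10,
                          strand = "+")
  l1s <- tibble::tibble(l1_id = "x", chrom = "chr1", start = 0, end = 10,
                        strand = "+")
  expect_error(classify_l1_locations(l1s, genes), "chromosome namespaces")
})

test_that("random layouts match the brute-force all-pairs oracle", {
  set.seed(11)
  for (rep in 1:3) {
    l1s <- random_intervals(200, "l1")
    genes <- random_intervals(50, "gene")
    res <- classify_l1_locations(l1s, genes)
    ora <- oracle_classify(l1s, genes)
    expect_equal(res$location_class, ora$location_class)
    expect_equal(res$host_genes, ora$host_genes)
    # partition invariant
    expect_equal(sum(res$location_class == "intragenic") +
                   sum(res$location_class == "intergenic"), nrow(l1s))
    # order invariance
    perm <- sample(nrow(l1s))
    res2 <- classify_l1_locations(l1s[perm, ], genes[sample(nrow(genes)), ])
    expect_equal(res2$location_class, res$location_class[perm])
  }
})

test_that("flanking assignment handles the canonical downstream case", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1000,
                          end = 5000, strand = "+")
  l1s <- tibble::tibble(
    l1_id = c("near", "far"),
    chrom = "chr1", start = c(5500, 8000), end = c(6500, 9000), strand = "+"
  )
  cls <- classify_l1_locations(l1s, genes)
  fl <- find_flanking_l1s(cls, genes, window_bp = 1000)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$l1_id, "near")
  expect_equal(fl$gene_end, "three_prime")
  expect_equal(fl$orientation, "sense")
  expect_equal(fl$distance_bp, 500L)
  # 3,000 bp away with window 2000 -> still nothing
  fl2 <- find_flanking_l1s(cls[cls$l1_id == "far", ], genes, window_bp = 2000)
  expect_equal(nrow(fl2), 0)
})

test_that("flank assignments match brute-force enumeration and nest by window", {
  set.seed(23)
  for (rep in 1:3) {
    genes <- random_intervals(30, "gene", max_pos = 60000)
    l1s <- random_intervals(80, "l1", max_pos = 60000, max_len = 2000)
    cls <- classify_l1_locations(l1s, genes)
    for (w in c(1000, 2000)) {
      fl <- find_flanking_l1s(cls, genes, window_bp = w)
      ora <- oracle_flanks(cls, genes, w)
      expect_equal(nrow(fl), nrow(ora))
      expect_equal(as.data.frame(fl), ora, ignore_attr = TRUE)
    }
    f1 <- find_flanking_l1s(cls, genes, window_bp = 1000)
    f2 <- find_flanking_l1s(cls, genes, window_bp = 2000)
    key <- function(x) paste(x$l1_id, x$gene_id, x$gene_end)
    expect_true(all(key(f1) %in% key(f2)))
  }
})

test_that("unknown strands are skipped with a warning", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1000,
                          end = 2000, strand = "+")
  l1s <- tibble::tibble(l1_id = "u", chrom = "chr1", start = 2100, end = 2400,
                        strand = "*")
  cls <- classify_l1_locations(l1s, genes)
  expect_warning(fl <- find_flanking_l1s(cls, genes, 1000), "unknown strand")
  expect_equal(nrow(fl), 0)
})
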