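mk_sites <- function(start, len, chrom = "chr1") {
  tibble::tibble(
    site_id = sprintf("s%03d", seq_along(start)),
    chrom = chrom, start = start, end = start + len, strand = "*"
  )
}

test_that("site filter keeps only sites longer than 18 bp and is idempotent", {
  s <- mk_sites(c(0, 100, 200, 300), c(18, 19, 10, 40))
  kept <- filter_sites(s)
  expect_equal(kept$site_id, c("s002", "s004"))
  expect_equal(kept$length_bp, c(19L, 40L))
  expect_equal(filter_sites(kept), kept)
  expect_equal(nrow(filter_sites(mk_sites(numeric(0), numeric(0)))), 0)

  set.seed(101)
  r <- mk_sites(seq(0, 9900, by = 100), sample(1:40, 100, TRUE))
  expect_equal(filter_sites(r)$site_id,
               r$site_id[r$end - r$start > 18])
})

test_that("L1/site association builds the expected 2x2 over up-regulated genes", {
  genes <- tibble::tibble(
    gene_id = c("gL1a", "gL1b", "gA", "gB"),
    chrom = "chr1", start = c(0, 1000, 2000, 3000),
    end = c(500, 1500, 2500, 3500), strand = "+"
  )
  sites <- mk_sites(c(100, 2100), c(30, 30))
  res <- ago2_l1_association(sites, genes, l1_genes = c("gL1a", "gL1b"),
                             upregulated = genes$gene_id)
  expect_equal(c(res$table$a, res$table$b, res$table$c, res$table$d),
               c(1, 1, 1, 1))
  # no sites at all -> zero column margin, degenerate
  none <- ago2_l1_association(mk_sites(numeric(0), numeric(0)), genes,
                              c("gL1a"), genes$gene_id)
  expect_true(none$association$degenerate)
  expect_error(ago2_l1_association(sites, genes, c("gL1a"), character(0)),
               "empty up-regulated")
})

test_that("sites planted in L1 genes raise the association OR", {
  set.seed(111)
  cfg <- sim_config(seed = 7, n_genes = 300, chrom_count = 2,
                    n_intergenic_l1 = 100, ago2_fold_excess = 12,
                    ago2_site_density_per_mb = 3)
  st <- simulate_study(cfg)
  kept <- filter_sites(st$sites)
  res <- ago2_l1_association(kept, st$genes, st$l1_gene_set,
                             upregulated = st$genes$gene_id)
  expect_gt(res$association$odds_ratio, 1)
})

mk_hist_l1 <- function(start, end, strand, host_strand, chrom = "chr1") {
  tibble::tibble(
    l1_id = sprintf("L%02d", seq_along(start)),
    chrom = chrom, start = start, end = end, strand = strand,
    location_class = "intragenic",
    host_genes = replicate(length(start), "g1", simplify = FALSE),
    host_strand = host_strand
  )
}

test_that("proximity histogram bins a coincident site at [0, 25000)", {
  l1 <- mk_hist_l1(100000, 105000, "-", "+")
  site <- mk_sites(100000 - 15, 30)       # midpoint exactly at the 5' edge
  h <- l1_proximity_histogram(site, l1, orientation = "antisense")
  expect_equal(nrow(h), 48)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$bin_start == 0], 1)
  expect_equal(attr(h, "n_sites_in_range"), 1)
  # downstream site on a - strand host maps to a negative bin
  l1_minus <- mk_hist_l1(1e6, 1e6 + 5000, "+", "-")
  site2 <- mk_sites(1e6 + 5000 + 30000, 30)
  h2 <- l1_proximity_histogram(site2, l1_minus, orientation = "antisense")
  expect_equal(sum(h2$count[h2$bin_start < 0]), 1)
})

test_that("histogram equals brute-force binning and mirrors under strand flip", {
  set.seed(121)
  for (rep in 1:3) {
    anchors_start <- floor(runif(50, 6e5, 4e6))
    strand <- sample(c("+", "-"), 50, TRUE)
    host <- sample(c("+", "-"), 50, TRUE)
    l1s <- mk_hist_l1(anchors_start, anchors_start + 3000, strand, host)
    sites <- mk_sites(floor(runif(1000, 0, 5e6)), 25)
    h <- l1_proximity_histogram(sites, l1s, orientation = "antisense",
                                anchor = "five_prime")
    sel <- l1s$strand != l1s$host_strand
    anchors <- tibble::tibble(
      chrom = l1s$chrom[sel],
      pos = ifelse(l1s$host_strand[sel] == "+", l1s$start[sel], l1s$end[sel]),
      host_strand = l1s$host_strand[sel]
    )
    expect_equal(h$count, oracle_hist(sites, anchors))
    expect_equal(sum(h$count), attr(h, "n_sites_in_range"))
    # permutation invariance of the total
    h_perm <- l1_proximity_histogram(sites[sample(nrow(sites)), ], l1s)
    expect_equal(sum(h_perm$count), sum(h$count))
    # flipping every strand mirrors the histogram (midpoint anchor, which
    # is strand-invariant; edge anchors move under the flip)
    h_mid <- l1_proximity_histogram(sites, l1s, orientation = "antisense",
                                    anchor = "midpoint")
    flipped <- l1s
    flipped$host_strand <- ifelse(l1s$host_strand == "+", "-", "+")
    flipped$strand <- ifelse(l1s$strand == "+", "-", "+")
    h_flip <- l1_proximity_histogram(sites, flipped, orientation = "antisense",
                                     anchor = "midpoint")
    # fractional site midpoints never sit on a bin edge, so the flip is an
    # exact mirror
    expect_equal(h_flip$count, rev(h_mid$count))
  }
})

test_that("sites beyond 600 kb never contribute", {
  l1 <- mk_hist_l1(2e6, 2e6 + 1000, "-", "+")
  far <- mk_sites(c(2e6 + 700000, 2e6 - 700000), c(30, 30))
  h <- l1_proximity_histogram(far, l1)
  expect_equal(sum(h$count), 0)
})

test_that("a site near two L1s counts once per anchor pair", {
  l1s <- mk_hist_l1(c(1e6, 1e6 + 50000), c(1e6 + 1000, 1e6 + 51000),
                    c("-", "-"), c("+", "+"))
  site <- mk_sites(1e6 + 20000, 30)
  h <- l1_proximity_histogram(site, l1s)
  expect_equal(sum(h$count), 2)
})
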