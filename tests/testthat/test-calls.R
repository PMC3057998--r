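test_that("alpha selection follows the group-size and IP rules", {
  expect_equal(select_alpha(5, 5, FALSE), 0.01)
  expect_equal(select_alpha(2, 6, FALSE), 0.05)
  expect_equal(select_alpha(6, 2, FALSE), 0.05)
  expect_equal(select_alpha(8, 8, TRUE), 0.05)
  expect_error(select_alpha(1, 5), "at least 2")
})

test_that("probe tests match per-probe t.test and handle flat probes", {
  set.seed(3)
  mat <- rbind(
    flat = rep(5, 10),
    up = c(rnorm(5, 10), rnorm(5, 5)),
    dn = c(rnorm(5, 2), rnorm(5, 7))
  )
  map <- tibble::tibble(probe = rownames(mat), gene_id = c("g1", "g2", "g3"))
  ex <- make_micro_experiment(mat, 5, 5, map)
  pp <- probe_tests(ex)

  expect_equal(pp$p_up[pp$probe == "flat"], 1)
  expect_equal(pp$p_down[pp$probe == "flat"], 1)

  ref_up <- t.test(mat["up", 1:5], mat["up", 6:10],
                   alternative = "greater", var.equal = TRUE)
  expect_equal(pp$p_up[pp$probe == "up"], ref_up$p.value, tolerance = 1e-12)
  ref_dn <- t.test(mat["up", 1:5], mat["up", 6:10],
                   alternative = "less", var.equal = TRUE)
  expect_equal(pp$p_down[pp$probe == "up"], ref_dn$p.value, tolerance = 1e-12)
  expect_gt(pp$p_down[pp$probe == "up"], 0.99)
  expect_lt(pp$p_up[pp$probe == "dn"], 1)

  # for non-degenerate probes one side is always favored and the two
  # one-sided p-values are complementary (flat probes get 1/1 by contract)
  live <- pp$probe != "flat"
  expect_true(all(pmin(pp$p_up, pp$p_down)[live] <= 0.5 + 1e-12))
  expect_equal(pp$p_up[live] + pp$p_down[live], rep(1, 2), tolerance = 1e-12)
})

test_that("paired design matches paired t.test", {
  set.seed(4)
  mat <- matrix(rnorm(40), nrow = 4)
  rownames(mat) <- paste0("p", 1:4)
  map <- tibble::tibble(probe = rownames(mat), gene_id = paste0("g", 1:4))
  ex <- make_micro_experiment(mat, 5, 5, map, design = "paired")
  pp <- probe_tests(ex)
  for (i in 1:4) {
    ref <- t.test(mat[i, 1:5], mat[i, 6:10], paired = TRUE,
                  alternative = "greater")
    expect_equal(pp$p_up[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("unique and homologous probe rules drive gene calls", {
  # g_unique: one unique significant probe -> up
  # g_homol1: only homologous probes, one significant -> not called
  # g_homol2: only homologous probes, two significant -> up
  set.seed(9)
  up_vals <- function() c(rnorm(5, 12, 0.2), rnorm(5, 5, 0.2))
  null_vals <- function() rnorm(10, 5, 0.2)
  mat <- rbind(
    u1 = up_vals(),
    h1 = up_vals(), h2 = null_vals(),
    h3 = up_vals(), h4 = up_vals()
  )
  map <- tibble::tibble(
    probe = c("u1", "h1", "h1", "h2", "h2", "h3", "h3", "h4", "h4"),
    gene_id = c("g_unique",
                "g_homol1", "other1", "g_homol1", "other1",
                "g_homol2", "other2", "g_homol2", "other2")
  )
  ex <- make_micro_experiment(mat, 5, 5, map)
  calls <- call_genes(ex, alpha = 0.01)
  get <- function(g, col) calls[[col]][calls$gene_id == g]
  expect_equal(get("g_unique", "up_call"), "up")
  expect_equal(get("g_homol1", "up_call"), "not_up")
  expect_equal(get("g_homol1", "down_call"), "not_down")
  expect_equal(get("g_homol2", "up_call"), "up")
  # mutual exclusivity
  expect_false(any(calls$up_call == "up" & calls$down_call == "down"))
})

test_that("genes without probes are excluded and alpha is monotone", {
  set.seed(10)
  mat <- rbind(a = c(rnorm(5, 8), rnorm(5, 5)), b = rnorm(10))
  map <- tibble::tibble(probe = c("a", "b", "zz"),
                        gene_id = c("g1", "g2", "g_unprobed"))
  ex <- make_micro_experiment(mat, 5, 5, map)
  calls <- call_genes(ex, alpha = 0.01)
  expect_false("g_unprobed" %in% calls$gene_id)

  loose <- call_genes(ex, alpha = 0.05)
  up_strict <- calls$gene_id[calls$up_call == "up"]
  up_loose <- loose$gene_id[loose$up_call == "up"]
  expect_true(all(up_strict %in% up_loose))
})

test_that("calls equal the brute-force rule on synthetic experiments", {
  cfg <- sim_config(seed = 31, n_genes = 80, chrom_count = 2,
                    n_intergenic_l1 = 40, n_samples_per_group = 3,
                    frac_homologous = 0.3)
  gen <- simulate_genome(cfg)
  for (off in 0:19) {
    sim <- simulate_expression(cfg, gen$genes, gen$l1_gene_set,
                               seed_offset = off)
    ex <- sim$experiment
    pp <- probe_tests(ex)
    calls <- call_genes(ex, alpha = 0.05, probe_p = pp)
    ora <- oracle_call_genes(pp, ex$probe_map, 0.05)
    got <- as.data.frame(calls[order(calls$gene_id),
                               c("gene_id", "up_call", "down_call")])
    rownames(got) <- NULL
    expect_equal(got, ora, ignore_attr = TRUE)
  }
})

test_that("null data call rate matches the analytic probe-rule rate", {
  # genes with a single unique probe under the null are called up with
  # probability alpha; aggregate over replicates and compare
  set.seed(55)
  alpha <- 0.05
  n_rep <- 200
  n_genes <- 40
  hits <- 0
  for (i in seq_len(n_rep)) {
    mat <- matrix(rnorm(n_genes * 8), nrow = n_genes)
    rownames(mat) <- sprintf("p%02d", seq_len(n_genes))
    map <- tibble::tibble(probe = rownames(mat),
                          gene_id = sprintf("g%02d", seq_len(n_genes)))
    ex <- make_micro_experiment(mat, 4, 4, map)
    calls <- call_genes(ex, alpha = alpha)
    hits <- hits + sum(calls$up_call == "up")
  }
  rate <- hits / (n_rep * n_genes)
  se <- sqrt(alpha * (1 - alpha) / (n_rep * n_genes))
  expect_lt(abs(rate - alpha), 4 * se)
})

test_that("two-sided mode assigns the doubled p to the favoured side", {
  set.seed(6)
  mat <- rbind(x = c(rnorm(5, 9), rnorm(5, 5)))
  map <- tibble::tibble(probe = "x", gene_id = "g")
  ex <- make_micro_experiment(mat, 5, 5, map)
  pp <- probe_tests(ex, mode = "two_sided")
  ref <- t.test(mat[1, 1:5], mat[1, 6:10], var.equal = TRUE)
  expect_equal(pp$p_up, ref$p.value, tolerance = 1e-12)
  expect_equal(pp$p_down, 1)
})
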