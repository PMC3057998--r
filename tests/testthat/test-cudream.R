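mk_calls <- function(ids, down, up = NULL, id = "exp") {
  out <- tibble::tibble(
    gene_id = ids,
    up_call = ifelse(ids %in% (up %||% character(0)), "up", "not_up"),
    down_call = ifelse(ids %in% down, "down", "not_down")
  )
  attr(out, "experiment_id") <- id
  out
}

test_that("perfect concordance yields the 0.5-corrected OR of 121", {
  ids <- sprintf("g%02d", 1:10)
  calls <- mk_calls(ids, down = ids[1:5])
  res <- intersect_experiments(calls, calls, "down", "down")
  expect_equal(c(res$table$a, res$table$b, res$table$c, res$table$d),
               c(5, 0, 0, 5))
  expect_true(res$association$zero_cell_corrected)
  expect_equal(res$association$odds_ratio, 121)
  expect_equal(res$n_shared_genes, 10)
})

test_that("cross-tabulation is a transpose under experiment swap", {
  set.seed(41)
  ids <- sprintf("g%03d", 1:200)
  a <- mk_calls(ids, down = sample(ids, 60), id = "A")
  b <- mk_calls(sample(ids, 150), down = sample(ids, 50), id = "B")
  ab <- intersect_experiments(a, b, "down", "down")
  ba <- intersect_experiments(b, a, "down", "down")
  expect_equal(ab$table$a, ba$table$a)
  expect_equal(ab$table$b, ba$table$c)
  expect_equal(ab$table$c, ba$table$b)
  expect_equal(ab$table$d, ba$table$d)
  expect_equal(ab$association$odds_ratio, ba$association$odds_ratio)
  # shared-universe conservation
  tot <- ab$table$a + ab$table$b + ab$table$c + ab$table$d
  expect_equal(tot, ab$n_shared_genes)
  expect_equal(ab$n_shared_genes, length(intersect(a$gene_id, b$gene_id)))
})

test_that("independent experiments give OR near 1 and ~5% significance", {
  set.seed(61)
  n_seed <- 120
  n <- 1500
  ids <- sprintf("g%04d", seq_len(n))
  ors <- numeric(n_seed); sig <- logical(n_seed)
  for (s in seq_len(n_seed)) {
    a <- mk_calls(ids, down = sample(ids, 300))
    b <- mk_calls(ids, down = sample(ids, 300))
    res <- intersect_experiments(a, b, "down", "down")
    ors[s] <- res$association$odds_ratio
    sig[s] <- res$association$p_value < 0.05
  }
  expect_lt(abs(median(ors) - 1), 0.15)
  expect_lt(mean(sig), 0.15)
  expect_gt(mean(sig), 0.005)
})

test_that("planted concordance odds ratios are recovered", {
  set.seed(71)
  n <- 2000
  ids <- sprintf("g%04d", seq_len(n))
  for (omega in c(1, 4)) {
    ors <- numeric(60)
    for (s in seq_len(60)) {
      down_a <- runif(n) < 0.25
      # concordance planted through the conditional odds of down-in-B
      p_b_given_a <- omega * 0.25 / (1 + (omega - 1) * 0.25)
      p_b_given_not <- 0.25
      down_b <- runif(n) < ifelse(down_a, p_b_given_a, p_b_given_not)
      a <- mk_calls(ids, down = ids[down_a])
      b <- mk_calls(ids, down = ids[down_b])
      ors[s] <- intersect_experiments(a, b)$association$odds_ratio
    }
    expect_lt(abs(median(ors) - omega) / omega, 0.10)
  }
})

test_that("stratified analysis splits the universe correctly", {
  set.seed(81)
  ids <- sprintf("g%03d", 1:300)
  set <- sample(ids, 100)
  a <- mk_calls(ids, down = sample(ids, 90))
  b <- mk_calls(ids, down = sample(ids, 90))
  st <- stratified_intersect(a, b, set, "down", "down")
  expect_equal(st$within_set$n_shared_genes, 100)
  expect_equal(st$outside_set$n_shared_genes, 200)
  # stratum tables add up to the unstratified table
  full <- intersect_experiments(a, b, "down", "down")
  expect_equal(st$within_set$table$a + st$outside_set$table$a, full$table$a)
  # whole-universe set reproduces the unstratified result; complement errors
  st_all <- tryCatch(stratified_intersect(a, b, ids), error = identity)
  expect_s3_class(st_all, "error")
  expect_false(st$within_set$low_n)
})

test_that("mixed direction categories (up vs not_up) are supported", {
  ids <- sprintf("g%02d", 1:20)
  a <- mk_calls(ids, down = character(0), up = ids[1:8])
  b <- mk_calls(ids, down = ids[5:12])
  res <- intersect_experiments(a, b, "up", "not_down")
  expect_equal(res$table$a + res$table$b + res$table$c + res$table$d, 20)
  expect_equal(res$table$a + res$table$c,
               sum(a$up_call == "up"))
})

test_that("commonality score counts experiments and compares groups", {
  ids <- sprintf("g%02d", 1:40)
  set <- ids[1:20]
  # L1 genes down in 3 of 4 experiments, others down in 1 of 4
  css <- lapply(1:4, function(i) {
    down <- c(if (i <= 3) set else character(0),
              if (i == 1) setdiff(ids, set) else character(0))
    mk_calls(ids, down = down, id = paste0("e", i))
  })
  cs <- commonality_score(css, set)
  expect_equal(cs$per_gene$n_down[cs$per_gene$in_set], rep(3, 20))
  expect_equal(cs$per_gene$n_down[!cs$per_gene$in_set], rep(1, 20))
  expect_equal(cs$mean_in_set, 3)
  expect_equal(cs$mean_out_set, 1)
  expect_true(all(cs$per_gene$n_down <= cs$n_experiments))
  g <- glance(cs)
  expect_equal(g$n_experiments, 4)

  # null: no group difference on random calls
  set.seed(91)
  css0 <- lapply(1:4, function(i) mk_calls(ids, down = sample(ids, 10)))
  cs0 <- commonality_score(css0, set)
  expect_gt(cs0$p_value, 1e-4)
})
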