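# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: a genome of non-overlapping gene spans with a configurable
# fraction hosting intragenic L1s, class-specific L1 feature prevalences,
# two-group expression with Gaussian probe noise and mean-shift effects
# where the down-regulated gene set is sampled so that the (L1, down) 2x2
# table has a planted expected odds ratio, and binding sites with a
# configurable fold-excess near intragenic L1s.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's recovery experiments: 2,000 genes, 20% hosting an intragenic
#' L1, a 2-standard-deviation expression shift in affected genes, 5 samples
#' per group, and a planted odds ratio of 3 linking L1 hosting to
#' down-regulation.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_genes Number of genes.
#' @param gene_length_range_bp Gene span lengths, uniform in this range.
#' @param intergenic_gap_range_bp Gap lengths between consecutive genes.
#' @param chrom_count Number of chromosomes (genes split evenly).
#' @param frac_l1_genes Fraction of genes receiving >= 1 intragenic L1.
#' @param n_intergenic_l1 Number of intergenic L1s placed in gene gaps.
#' @param l1_length_range_bp L1 element lengths.
#' @param l1_feature_spec List with `categorical` (per feature:
#'   `c(intragenic = prevalence, intergenic = prevalence)`) and `numeric`
#'   (per feature: `c(intragenic = mean, intergenic = mean, sd = sd)`).
#' @param n_samples_per_group Samples per group (test and control).
#' @param probe_per_gene_probs Probability of a gene having 1, 2, 3 ...
#'   unique probes.
#' @param frac_homologous Homologous probes (each mapping to a random pair
#'   of genes) as a fraction of `n_genes`.
#' @param baseline_expression_mean,baseline_expression_sd Per-probe baseline
#'   level distribution (log-scale units).
#' @param noise_sd Within-probe Gaussian noise standard deviation.
#' @param de_effect_size Standardised shift (in units of `noise_sd`) applied
#'   to regulated genes in the test group.
#' @param frac_down Overall fraction of genes planted down-regulated.
#' @param frac_up Overall fraction of genes planted up-regulated
#'   (independent of L1 status).
#' @param planted_or_down Target odds ratio of the (L1 hosting) x
#'   (down-regulated) 2x2 table, enforced in expectation.
#' @param ago2_site_density_per_mb Background binding-site density.
#' @param ago2_fold_excess Fold-excess of site density within
#'   `ago2_flank_bp` of intragenic L1 anchors (1 = no excess).
#' @param ago2_flank_bp Half-width of the near-L1 excess window.
#' @param site_length_range_bp Lengths of generated binding sites.
#' @param frac_short_sites Fraction of sites drawn at <= 18 bp (removed by
#'   the length filter).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000,
                       gene_length_range_bp = c(5000, 50000),
                       intergenic_gap_range_bp = c(5000, 30000),
                       chrom_count = 5,
                       frac_l1_genes = 0.2,
                       n_intergenic_l1 = 1500,
                       l1_length_range_bp = c(1000, 6000),
                       l1_feature_spec = default_feature_spec(),
                       n_samples_per_group = 5,
                       probe_per_gene_probs = c(0.5, 0.3, 0.2),
                       frac_homologous = 0.1,
                       baseline_expression_mean = 8,
                       baseline_expression_sd = 1,
                       noise_sd = 1,
                       de_effect_size = 2,
                       frac_down = 0.15,
                       frac_up = 0.05,
                       planted_or_down = 3,
                       ago2_site_density_per_mb = 5,
                       ago2_fold_excess = 10,
                       ago2_flank_bp = 12500,
                       site_length_range_bp = c(20, 40),
                       frac_short_sites = 0.2) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$frac_l1_genes >= 0, cfg$frac_l1_genes <= 1,
    cfg$frac_down > 0, cfg$frac_down < 1,
    cfg$frac_up >= 0, cfg$frac_up < 1,
    cfg$planted_or_down > 0,
    cfg$n_samples_per_group >= 2,
    cfg$ago2_fold_excess >= 1
  )
  structure(cfg, class = "sim_config")
}

default_feature_spec <- function() {
  list(
    categorical = list(
      conserved_seq = c(intragenic = 0.6, intergenic = 0.3),
      cpg_island = c(intragenic = 0.5, intergenic = 0.25)
    ),
    numeric = list(
      gc_content = c(intragenic = 0.47, intergenic = 0.41, sd = 0.03),
      intactness = c(intragenic = 0.8, intergenic = 0.6, sd = 0.1)
    )
  )
}

#' Simulate a genome of genes and L1 elements
#'
#' Genes are laid out left to right on each chromosome with random lengths
#' and gaps, so spans never overlap. A round(`frac_l1_genes` * `n_genes`)
#' subset of genes receives one intragenic L1 placed fully inside the gene
#' span; `n_intergenic_l1` L1s are placed inside intergenic gaps (never
#' overlapping a gene). Categorical and numeric features are drawn at the
#' class-specific prevalences/means of `l1_feature_spec`.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble), `l1s` (tibble with feature columns),
#'   `l1_gene_set` (character: planted L1-hosting gene ids) and
#'   `truth` (planted `location_class` per L1).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  per_chrom <- rep(ceiling(n / config$chrom_count), config$chrom_count)
  per_chrom[config$chrom_count] <- n - sum(per_chrom[-config$chrom_count])
  if (any(per_chrom <= 0)) abort("more chromosomes than genes.")

  glen <- round(runif(n, config$gene_length_range_bp[1],
                      config$gene_length_range_bp[2]))
  ggap <- round(runif(n, config$intergenic_gap_range_bp[1],
                      config$intergenic_gap_range_bp[2]))
  chrom <- rep(paste0("chr", seq_len(config$chrom_count)), per_chrom)
  start <- numeric(n); pos <- 0; cur <- ""
  for (i in seq_len(n)) {
    if (chrom[i] != cur) { pos <- 0; cur <- chrom[i] }
    pos <- pos + ggap[i]
    start[i] <- pos
    pos <- pos + glen[i]
  }
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    symbol = sprintf("GENE%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + glen,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )

  n_l1_genes <- round(config$frac_l1_genes * n)
  l1_gene_idx <- if (n_l1_genes > 0) sort(sample.int(n, n_l1_genes)) else integer(0)

  l1_rows <- list()
  make_l1 <- function(id, chrom, lo, hi, planted) {
    # place an L1 of a feasible length fully inside [lo, hi)
    max_len <- hi - lo
    if (max_len < 50) return(NULL)
    len <- round(runif(1, min(config$l1_length_range_bp[1], max_len - 1),
                       min(config$l1_length_range_bp[2], max_len)))
    len <- max(len, 50)
    s <- round(runif(1, lo, hi - len))
    tibble(l1_id = id, chrom = chrom, start = s, end = s + len,
           strand = sample(c("+", "-"), 1), planted_class = planted)
  }
  for (k in seq_along(l1_gene_idx)) {
    g <- l1_gene_idx[k]
    l1_rows[[length(l1_rows) + 1]] <- make_l1(
      sprintf("L1intra%04d", k), genes$chrom[g],
      genes$start[g] + 1, genes$end[g] - 1, "intragenic"
    )
  }
  # intergenic L1s: inside the gap upstream of a random gene, kept clear of
  # both flanking gene spans
  gap_ok <- which(ggap >= 200)
  if (config$n_intergenic_l1 > 0) {
    if (length(gap_ok) == 0) abort("genome too small: no usable intergenic gaps.")
    picks <- sample(gap_ok, config$n_intergenic_l1, replace = TRUE)
    for (k in seq_along(picks)) {
      g <- picks[k]
      gap_hi <- genes$start[g]
      gap_lo <- gap_hi - ggap[g]
      l1_rows[[length(l1_rows) + 1]] <- make_l1(
        sprintf("L1inter%04d", k), genes$chrom[g],
        gap_lo + 1, gap_hi - 1, "intergenic"
      )
    }
  }
  l1s <- dplyr::bind_rows(l1_rows)
  if (nrow(l1s) > 0) {
    spec <- config$l1_feature_spec
    is_intra <- l1s$planted_class == "intragenic"
    for (nm in names(spec$categorical %||% list())) {
      pr <- spec$categorical[[nm]]
      p <- if_else(is_intra, pr[["intragenic"]], pr[["intergenic"]])
      l1s[[nm]] <- rbinom(nrow(l1s), 1, p) == 1
    }
    for (nm in names(spec$numeric %||% list())) {
      pr <- spec$numeric[[nm]]
      mu <- if_else(is_intra, pr[["intragenic"]], pr[["intergenic"]])
      l1s[[nm]] <- rnorm(nrow(l1s), mu, pr[["sd"]])
    }
  }

  list(
    genes = genes,
    l1s = dplyr::select(l1s, -"planted_class"),
    l1_gene_set = genes$gene_id[l1_gene_idx],
    truth = dplyr::select(l1s, "l1_id", "planted_class")
  )
}

# Solve per-class down probabilities (p_l1, p_other) so that the expected
# (L1, down) table has odds ratio `or` and the overall down fraction is
# `frac_down`, given the fraction `q` of L1 genes.
planted_down_probs <- function(frac_down, q, or) {
  p1_of <- function(p2) or * p2 / (1 + (or - 1) * p2)
  g <- function(p2) q * p1_of(p2) + (1 - q) * p2 - frac_down
  if (q <= 0 || q >= 1) return(c(p_l1 = frac_down, p_other = frac_down))
  if (g(1e-12) > 0 || g(1 - 1e-12) < 0) {
    abort(sprintf(
      "planted OR %.3g infeasible for frac_down = %.3g, frac_l1 = %.3g.",
      or, frac_down, q
    ))
  }
  p2 <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(p_l1 = p1_of(p2), p_other = p2)
}

#' Simulate a two-group expression experiment with planted effects
#'
#' Probe values are Gaussian around a per-probe baseline; planted
#' down-regulated genes are shifted by `-de_effect_size * noise_sd` in the
#' test group (up-regulated genes by the positive shift). The down-regulated
#' gene set is sampled with class-conditional probabilities solved in closed
#' form so that the expected (L1 hosting) x (down) 2x2 table has odds ratio
#' `planted_or_down`. Homologous probes map to two genes and carry the mean
#' of their hosts' shifts.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble from [simulate_genome()].
#' @param l1_gene_set Character vector of L1-hosting gene ids.
#' @param experiment_id Identifier for the resulting experiment.
#' @param seed_offset Added to `config$seed` so several experiments can be
#'   drawn from one config.
#' @param truth Optional planted-truth tibble from a previous call; when
#'   given, the same planted regulated gene sets are reused with fresh
#'   noise, emulating two experiments probing the same regulatory
#'   mechanism.
#' @return List with `experiment` (an [expression_experiment()]) and `truth`
#'   (tibble: `gene_id`, `is_l1_gene`, `planted_down`, `planted_up`).
#' @export
simulate_expression <- function(config, genes, l1_gene_set,
                                experiment_id = "sim", seed_offset = 0L,
                                truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + seed_offset)
  n <- nrow(genes)
  is_l1 <- genes$gene_id %in% l1_gene_set
  if (is.null(truth)) {
    q <- mean(is_l1)
    pr <- planted_down_probs(config$frac_down, q, config$planted_or_down)
    p_down <- if_else(is_l1, pr[["p_l1"]], pr[["p_other"]])
    planted_down <- rbinom(n, 1, p_down) == 1
    planted_up <- !planted_down & rbinom(n, 1, config$frac_up) == 1
  } else {
    stopifnot(identical(truth$gene_id, genes$gene_id))
    planted_down <- truth$planted_down
    planted_up <- truth$planted_up
  }

  shift <- numeric(n)
  shift[planted_down] <- -config$de_effect_size * config$noise_sd
  shift[planted_up] <- config$de_effect_size * config$noise_sd
  names(shift) <- genes$gene_id

  n_probes <- sample(seq_along(config$probe_per_gene_probs), n,
                     replace = TRUE, prob = config$probe_per_gene_probs)
  probe_gene <- rep(genes$gene_id, n_probes)
  probe_ids <- sprintf("P%05d", seq_along(probe_gene))
  probe_map <- tibble(probe = probe_ids, gene_id = probe_gene)

  n_homol <- round(config$frac_homologous * n)
  if (n_homol > 0 && n >= 2) {
    hp_ids <- sprintf("H%05d", seq_len(n_homol))
    g1 <- sample(genes$gene_id, n_homol, replace = TRUE)
    g2 <- vapply(g1, function(g) sample(setdiff(genes$gene_id, g), 1),
                 character(1))
    probe_map <- dplyr::bind_rows(
      probe_map,
      tibble(probe = rep(hp_ids, 2), gene_id = c(g1, unname(g2)))
    )
  }

  all_probes <- unique(probe_map$probe)
  probe_shift <- vapply(
    split(probe_map$gene_id, probe_map$probe)[all_probes],
    function(gs) mean(shift[gs]), numeric(1)
  )
  ns <- config$n_samples_per_group
  baseline <- rnorm(length(all_probes), config$baseline_expression_mean,
                    config$baseline_expression_sd)
  mat <- matrix(
    rnorm(length(all_probes) * 2 * ns, mean = 0, sd = config$noise_sd),
    nrow = length(all_probes)
  ) + baseline
  mat[, seq_len(ns)] <- mat[, seq_len(ns)] + probe_shift
  rownames(mat) <- all_probes
  colnames(mat) <- c(sprintf("test_%d", seq_len(ns)),
                     sprintf("ctrl_%d", seq_len(ns)))
  groups <- setNames(rep(c("test", "control"), each = ns), colnames(mat))

  exp <- expression_experiment(mat, groups, probe_map,
                               experiment_id = experiment_id)
  truth <- tibble(
    gene_id = genes$gene_id, is_l1_gene = is_l1,
    planted_down = planted_down, planted_up = planted_up
  )
  list(experiment = exp, truth = truth)
}

#' Simulate AGO2 binding sites
#'
#' Background sites are uniform over each chromosome; additional sites are
#' placed within `ago2_flank_bp` of every intragenic L1 anchor so that local
#' density is `ago2_fold_excess` times background. Site lengths are drawn
#' from `site_length_range_bp`, with `frac_short_sites` of sites at <= 18 bp
#' (removed later by [filter_sites()]).
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble (defines chromosome extents).
#' @param l1s Classified L1 tibble ([classify_l1_locations()] output).
#' @param seed_offset Added to `config$seed`.
#' @return Binding-site tibble: `site_id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_ago2_sites <- function(config, genes, l1s, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 17L + seed_offset)
  chrom_len <- genes |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$end) + 10000, .groups = "drop")

  draw_len <- function(k) {
    short <- rbinom(k, 1, config$frac_short_sites) == 1
    len <- round(runif(k, config$site_length_range_bp[1],
                       config$site_length_range_bp[2]))
    len[short] <- sample(10:18, sum(short), replace = TRUE)
    len
  }

  density_bp <- config$ago2_site_density_per_mb / 1e6
  rows <- list()
  for (i in seq_len(nrow(chrom_len))) {
    k <- stats::rpois(1, density_bp * chrom_len$len[i])
    if (k == 0) next
    s <- round(runif(k, 0, chrom_len$len[i] - 50))
    len <- draw_len(k)
    rows[[length(rows) + 1]] <- tibble(
      chrom = chrom_len$chrom[i], start = s, end = s + len
    )
  }
  if (config$ago2_fold_excess > 1 && "location_class" %in% names(l1s)) {
    intra <- dplyr::filter(as_tibble(l1s), .data$location_class == "intragenic")
    if (nrow(intra) > 0) {
      lam <- density_bp * 2 * config$ago2_flank_bp * (config$ago2_fold_excess - 1)
      extra <- stats::rpois(nrow(intra), lam)
      for (i in which(extra > 0)) {
        anchor <- if (intra$strand[i] == "-") intra$end[i] else intra$start[i]
        s <- round(runif(extra[i], max(anchor - config$ago2_flank_bp, 0),
                         anchor + config$ago2_flank_bp))
        len <- draw_len(extra[i])
        rows[[length(rows) + 1]] <- tibble(
          chrom = intra$chrom[i], start = s, end = s + len
        )
      }
    }
  }
  sites <- dplyr::bind_rows(rows)
  if (nrow(sites) == 0) {
    return(tibble(site_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), strand = character(0)))
  }
  sites <- dplyr::arrange(sites, .data$chrom, .data$start)
  sites$site_id <- sprintf("S%06d", seq_len(nrow(sites)))
  sites$strand <- "*"
  dplyr::select(sites, "site_id", "chrom", "start", "end", "strand")
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper: genome, classified L1s, one expression experiment
#' and binding sites from a single config.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `l1s` (classified), `l1_gene_set`,
#'   `experiment`, `truth`, `sites`, `config`.
#' @export
simulate_study <- function(config) {
  gen <- simulate_genome(config)
  l1s <- host_strand_table(classify_l1_locations(gen$l1s, gen$genes),
                           gen$genes)
  expr <- simulate_expression(config, gen$genes, gen$l1_gene_set)
  sites <- simulate_ago2_sites(config, gen$genes, l1s)
  list(
    genes = gen$genes, l1s = l1s, l1_gene_set = gen$l1_gene_set,
    l1_truth = gen$truth,
    experiment = expr$experiment, truth = expr$truth,
    sites = sites, config = config
  )
}
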