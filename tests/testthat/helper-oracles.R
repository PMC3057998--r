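# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and textbook formulas only.

# all-pairs interval overlap scan (0-based half-open)
oracle_classify <- function(l1s, genes) {
  out_class <- character(nrow(l1s))
  out_hosts <- vector("list", nrow(l1s))
  for (i in seq_len(nrow(l1s))) {
    hosts <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (l1s$chrom[i] == genes$chrom[j] &&
          l1s$start[i] < genes$end[j] && genes$start[j] < l1s$end[i]) {
        hosts <- c(hosts, genes$gene_id[j])
      }
    }
    out_class[i] <- if (length(hosts) > 0) "intragenic" else "intergenic"
    out_hosts[[i]] <- sort(unique(hosts))
  }
  list(location_class = out_class, host_genes = out_hosts)
}

# enumeration over all (L1, gene, end) triples
oracle_flanks <- function(l1s, genes, window_bp) {
  rows <- list()
  for (i in seq_len(nrow(l1s))) {
    if (l1s$location_class[i] != "intergenic") next
    if (!(l1s$strand[i] %in% c("+", "-"))) next
    for (j in seq_len(nrow(genes))) {
      if (!(genes$strand[j] %in% c("+", "-"))) next
      if (l1s$chrom[i] != genes$chrom[j]) next
      for (end_kind in c("five_prime", "three_prime")) {
        left_end <- (genes$strand[j] == "+") == (end_kind == "five_prime")
        if (left_end) {
          pos <- genes$start[j]
          d <- pos - l1s$end[i]          # L1 fully left of the terminus
        } else {
          pos <- genes$end[j]
          d <- l1s$start[i] - pos        # L1 fully right of the terminus
        }
        if (d >= 0 && d <= window_bp) {
          rows[[length(rows) + 1]] <- data.frame(
            l1_id = l1s$l1_id[i], gene_id = genes$gene_id[j],
            gene_end = end_kind, window_bp = as.integer(window_bp),
            orientation = if (l1s$strand[i] == genes$strand[j]) "sense" else "antisense",
            distance_bp = as.integer(d),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(l1_id = character(0), gene_id = character(0),
                      gene_end = character(0), window_bp = integer(0),
                      orientation = character(0), distance_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$gene_end, out$l1_id), , drop = FALSE]
}

# direct Pearson chi-square sum((O-E)^2/E) and ad/bc with 0.5 correction
oracle_chisq_or <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  chi2 <- sum((obs - expd)^2 / expd)
  if (any(obs == 0)) obs <- obs + 0.5
  or <- (obs[1, 1] * obs[2, 2]) / (obs[1, 2] * obs[2, 1])
  se <- sqrt(sum(1 / obs))
  list(chi_square = chi2, p = pchisq(chi2, 1, lower.tail = FALSE), or = or,
       ci = exp(log(or) + c(-1, 1) * qnorm(0.975) * se))
}

# loop-based reapplication of the gene-calling rule to per-probe p-values
oracle_call_genes <- function(probe_p, probe_map, alpha) {
  genes <- unique(probe_map$gene_id)
  gene_count_per_probe <- table(probe_map$probe)
  res <- list()
  for (g in genes) {
    probes <- probe_map$probe[probe_map$gene_id == g]
    probes <- probes[probes %in% probe_p$probe]
    pp <- probe_p[match(probes, probe_p$probe), ]
    ok <- !is.na(pp$p_up) & !is.na(pp$p_down)
    pp <- pp[ok, , drop = FALSE]; probes <- probes[ok]
    if (length(probes) == 0) next
    uniq <- as.integer(gene_count_per_probe[probes]) == 1L
    call_dir <- function(p) {
      sig <- p < alpha
      any(uniq & sig) || (!any(uniq) && sum(!uniq & sig) >= 2)
    }
    up <- call_dir(pp$p_up)
    down <- call_dir(pp$p_down)
    if (up && down) {
      if (min(pp$p_up) <= min(pp$p_down)) down <- FALSE else up <- FALSE
    }
    res[[g]] <- data.frame(
      gene_id = g,
      up_call = if (up) "up" else "not_up",
      down_call = if (down) "down" else "not_down",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

# O(n * m) signed-distance binning around anchors
oracle_hist <- function(sites, anchors, bin_width = 25000, range_bp = 600000) {
  n_bins <- 2 * range_bp / bin_width
  counts <- rep(0L, n_bins)
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(sites))) {
      if (sites$chrom[j] != anchors$chrom[i]) next
      mid <- (sites$start[j] + sites$end[j]) / 2
      d <- mid - anchors$pos[i]
      if (anchors$host_strand[i] == "-") d <- -d
      if (d >= -range_bp && d < range_bp) {
        k <- floor(d / bin_width) + range_bp / bin_width + 1
        counts[k] <- counts[k] + 1L
      }
    }
  }
  counts
}

# random interval layouts for property tests
random_intervals <- function(n, id_prefix, chroms = c("chr1", "chr2"),
                             max_pos = 100000, max_len = 5000) {
  start <- floor(runif(n, 0, max_pos))
  len <- floor(runif(n, 1, max_len))
  df <- tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
  df[[paste0(id_prefix, "_id")]] <- sprintf("%s%04d", id_prefix, seq_len(n))
  df[, c(paste0(id_prefix, "_id"), "chrom", "start", "end", "strand")]
}

# micro expression experiment built directly from a value matrix
make_micro_experiment <- function(mat, n_test, n_control, probe_map,
                                  ip_derived = FALSE, design = "unpaired") {
  colnames(mat) <- c(sprintf("t%d", seq_len(n_test)),
                     sprintf("c%d", seq_len(n_control)))
  groups <- stats::setNames(rep(c("test", "control"), c(n_test, n_control)),
                            colnames(mat))
  expression_experiment(mat, groups, probe_map, design = design,
                        ip_derived = ip_derived)
}
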