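# End-to-end orchestration: annotate -> call -> enrich -> cross-experiment
# -> AGO2 -> report. Every emitted statistic carries its 2x2 table and the
# parameters that produced it, so each report number is recomputable from
# the intermediate files.

known_config_keys <- c("seed", "simulate", "inputs", "params", "outdir")
known_param_keys <- c("direction", "flank_window", "orientation", "anchor",
                      "alpha", "mode", "classification_mode",
                      "continuity_correction")

#' Pipeline configuration
#'
#' @param seed Integer seed (used when simulating).
#' @param simulate `NULL` to run from files, or a (possibly empty) list of
#'   [sim_config()] overrides to run on synthetic data.
#' @param inputs For file-driven runs: list with `genes` (BED or GFF3 path),
#'   `l1` (BED), `l1_features` (TSV, optional), `sites` (BED, optional) and
#'   `experiments`, a list of lists with `matrix`, `groups`, `probe_map`,
#'   and optional `paired`, `ip`, `id`.
#' @param params List of analysis parameters: `direction` (`"down"`/`"up"`,
#'   default `"down"`), `flank_window` (1000), `orientation`
#'   (`"antisense"`), `anchor` (`"five_prime"`), `alpha` (`NULL` = rule
#'   based), `mode` (`"one_sided"`), `classification_mode` (`"overlap"`),
#'   `continuity_correction` (FALSE). Unknown keys are rejected.
#' @param outdir Output directory for the report bundle.
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, simulate = list(), inputs = NULL,
                            params = list(), outdir = tempfile("l1run")) {
  cfg <- list(seed = seed, simulate = simulate, inputs = inputs,
              params = params, outdir = outdir)
  unknown <- setdiff(names(params), known_param_keys)
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter key(s): %s.", paste(unknown, collapse = ", ")))
  }
  defaults <- list(direction = "down", flank_window = 1000,
                   orientation = "antisense", anchor = "five_prime",
                   alpha = NULL, mode = "one_sided",
                   classification_mode = "overlap",
                   continuity_correction = FALSE)
  cfg$params <- modifyList(defaults, params)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are those of
#'   [pipeline_config()]; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), known_config_keys)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

assoc_record <- function(assoc, ...) {
  c(list(
    table = list(a = assoc$table$a, b = assoc$table$b,
                 c = assoc$table$c, d = assoc$table$d,
                 rows = assoc$table$row_labels, cols = assoc$table$col_labels),
    chi_square = assoc$chi_square, p_value = assoc$p_value,
    odds_ratio = assoc$odds_ratio,
    ci95 = c(assoc$ci95_low, assoc$ci95_high),
    zero_cell_corrected = assoc$zero_cell_corrected,
    degenerate = assoc$degenerate
  ), list(...))
}

#' Run the full analysis pipeline
#'
#' Runs annotation, feature screening, gene calling, L1 enrichment,
#' cross-experiment concordance (when two or more experiments are given),
#' AGO2 association and proximity histograms, and writes a report bundle
#' (`report.json` plus TSV intermediates) to `config$outdir`.
#'
#' @param config A [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return The report, invisibly, as a named list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = p[!vapply(p, is.null, logical(1))],
                 seed = config$seed)

  # ---- load or simulate inputs ------------------------------------------
  if (!is.null(config$simulate)) {
    dat <- stage("simulate", {
      sc <- do.call(sim_config, modifyList(list(seed = config$seed),
                                           config$simulate))
      gen <- simulate_genome(sc)
      exp_a <- simulate_expression(sc, gen$genes, gen$l1_gene_set,
                                   experiment_id = "simA", seed_offset = 0L)
      # second experiment: same planted regulation, fresh noise, so the
      # cross-experiment concordance stage has signal to find
      exp_b <- simulate_expression(sc, gen$genes, gen$l1_gene_set,
                                   experiment_id = "simB", seed_offset = 1L,
                                   truth = exp_a$truth)
      exps <- list(exp_a, exp_b)
      list(genes = gen$genes, l1s_raw = gen$l1s,
           experiments = lapply(exps, `[[`, "experiment"),
           sites = NULL, sim = list(gen = gen, sc = sc))
    })
  } else {
    if (is.null(config$inputs)) abort("config needs either `simulate` or `inputs`.")
    dat <- stage("load_inputs", {
      ins <- config$inputs
      for (f in c("genes", "l1")) {
        if (is.null(ins[[f]]) || !file.exists(ins[[f]])) {
          abort(sprintf("input '%s' missing or not found: %s",
                        f, ins[[f]] %||% "<unset>"))
        }
      }
      genes <- if (grepl("\\.gff3?$", ins$genes)) {
        read_gff_genes(ins$genes)
      } else {
        read_bed(ins$genes, id_col = "gene_id")
      }
      l1s <- read_bed(ins$l1, id_col = "l1_id")
      if (!is.null(ins$l1_features)) {
        l1s <- left_join(l1s, read_l1_features(ins$l1_features), by = "l1_id")
      }
      exps <- lapply(ins$experiments %||% list(), function(e) {
        for (f in c("matrix", "groups", "probe_map")) {
          if (is.null(e[[f]]) || !file.exists(e[[f]])) {
            abort(sprintf("experiment input '%s' missing or not found: %s",
                          f, e[[f]] %||% "<unset>"))
          }
        }
        ex <- read_expression_experiment(
          e$matrix, e$groups, e$probe_map,
          design = if (isTRUE(e$paired)) "paired" else "unpaired",
          ip_derived = isTRUE(e$ip)
        )
        ex$experiment_id <- e$id %||% basename(e$matrix)
        ex
      })
      sites <- if (!is.null(ins$sites)) read_bed(ins$sites, id_col = "site_id")
      list(genes = genes, l1s_raw = l1s, experiments = exps, sites = sites,
           sim = NULL)
    })
  }

  # ---- annotation -------------------------------------------------------
  l1s <- stage("annotate", {
    x <- classify_l1_locations(dat$l1s_raw, dat$genes,
                               mode = p$classification_mode)
    host_strand_table(x, dat$genes)
  })
  l1_gene_set <- sort(unique(unlist(l1s$host_genes)))
  flanks <- stage("flanks", find_flanking_l1s(l1s, dat$genes,
                                              window_bp = p$flank_window))
  write_tsv_out(dplyr::select(l1s, -dplyr::any_of("host_genes")) |>
                  mutate(host_genes = vapply(l1s$host_genes, paste,
                                             character(1), collapse = ",")),
                file.path(config$outdir, "l1_annotated.tsv"))
  write_tsv_out(flanks, file.path(config$outdir, "flanks.tsv"))
  report$annotation <- list(
    n_l1 = nrow(l1s),
    n_intragenic = sum(l1s$location_class == "intragenic"),
    n_intergenic = sum(l1s$location_class == "intergenic"),
    n_l1_genes = length(l1_gene_set),
    n_flank_assignments = nrow(flanks)
  )

  # ---- feature screen ---------------------------------------------------
  feature_cols <- setdiff(
    names(l1s),
    c("l1_id", "chrom", "start", "end", "strand", "location_class",
      "host_genes", "n_host_genes", "host_strand")
  )
  if (length(feature_cols) > 0 &&
      sum(l1s$location_class == "intragenic") > 0 &&
      sum(l1s$location_class == "intergenic") > 0) {
    screen <- stage("feature_screen", {
      is_num <- vapply(l1s[feature_cols], is.numeric, logical(1))
      run_feature_screen(l1s, list(categorical = feature_cols[!is_num],
                                   numeric = feature_cols[is_num]))
    })
    write_tsv_out(screen, file.path(config$outdir, "feature_screen.tsv"))
    report$feature_screen <- list(
      n_tests = nrow(screen),
      n_significant_p001 = sum(screen$p < 0.001)
    )
  }

  # ---- gene calling + enrichment ---------------------------------------
  calls <- stage("call_genes", lapply(dat$experiments, function(ex) {
    call_genes(ex, alpha = p$alpha, mode = p$mode)
  }))
  if (length(calls) > 0) {
    for (i in seq_along(calls)) {
      write_tsv_out(calls[[i]], file.path(
        config$outdir, sprintf("calls_%s.tsv",
                               attr(calls[[i]], "experiment_id") %||% i)
      ))
    }
    report$enrichment <- stage("enrich", lapply(calls, function(cl) {
      res <- enrichment_test(cl, l1_gene_set, direction = p$direction,
                             continuity_correction = p$continuity_correction)
      assoc_record(res,
                   experiment = attr(cl, "experiment_id") %||% "exp",
                   direction = p$direction,
                   alpha = attr(cl, "alpha"))
    }))
  }

  # ---- cross-experiment (CU-DREAM) -------------------------------------
  if (length(calls) >= 2) {
    report$cudream <- stage("cudream", {
      xe <- intersect_experiments(calls[[1]], calls[[2]],
                                  p$direction, p$direction)
      strat <- stratified_intersect(calls[[1]], calls[[2]], l1_gene_set,
                                    p$direction, p$direction)
      cs <- commonality_score(calls, l1_gene_set, direction = "down")
      list(
        overall = assoc_record(xe$association,
                               n_shared_genes = xe$n_shared_genes),
        within_l1 = assoc_record(strat$within_set$association,
                                 n_shared_genes = strat$within_set$n_shared_genes,
                                 low_n = strat$within_set$low_n),
        outside_l1 = assoc_record(strat$outside_set$association,
                                  n_shared_genes = strat$outside_set$n_shared_genes,
                                  low_n = strat$outside_set$low_n),
        commonality = list(mean_l1 = cs$mean_in_set,
                           mean_no_l1 = cs$mean_out_set,
                           t = cs$t, p_value = cs$p_value)
      )
    })
  }

  # ---- AGO2 sites -------------------------------------------------------
  if (is.null(dat$sites) && !is.null(dat$sim)) {
    dat$sites <- stage("simulate_sites",
                       simulate_ago2_sites(dat$sim$sc, dat$genes, l1s))
  }
  if (!is.null(dat$sites) && length(calls) > 0) {
    report$ago2 <- stage("ago2", {
      kept <- filter_sites(dat$sites)
      up <- calls[[1]]$gene_id[calls[[1]]$up_call == "up"]
      rec <- list(n_sites = nrow(dat$sites), n_sites_kept = nrow(kept))
      if (length(up) > 0) {
        asc <- ago2_l1_association(kept, dat$genes, l1_gene_set, up)
        rec$association <- assoc_record(asc$association,
                                        n_upregulated = length(up))
      }
      for (ori in c("antisense", "sense")) {
        h <- l1_proximity_histogram(kept, l1s, orientation = ori,
                                    anchor = p$anchor)
        write_tsv_out(as_tibble(h),
                      file.path(config$outdir, sprintf("hist_%s.tsv", ori)))
        rec[[paste0("hist_", ori)]] <- list(
          n_bins = nrow(h),
          n_sites_in_range = attr(h, "n_sites_in_range"),
          n_anchors = attr(h, "n_anchors")
        )
      }
      rec
    })
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
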