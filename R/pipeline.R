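#' Build a pipeline configuration
#'
#' The configuration drives [run_pipeline()] end to end. Two input modes are
#' supported: `simulate` (a list of [synthetic_spec()] arguments; the
#' compendium, sequences, weight table and annotations are generated) or
#' explicit paths (`matrix_tsv` + `meta_tsv`, `weights_tsv`, and optionally
#' `labels_tsv` / `terms_tsv` / `fasta`).
#'
#' @param outdir output directory for all stage results.
#' @param simulate `NULL`, or a list of arguments for [synthetic_spec()].
#' @param matrix_tsv,meta_tsv,weights_tsv,labels_tsv,terms_tsv,fasta input
#'   paths (ignored in simulate mode except `weights_tsv`, which overrides
#'   the generated table).
#' @param min_alignment alignment-score threshold for [filter_conditions()].
#' @param prune_to number of conditions for the sparse subset, or `NULL` to
#'   skip pruning.
#' @param p_max,q_max enrichment thresholds for [enrich()].
#' @param top_k number of top enrichment rows reported.
#' @param metric codon-bias metric, `"cai"` or `"tai"`.
#' @param duplicate_policy `"drop_both"` or `"drop_one"` for duplicated
#'   conditions.
#' @param exclude_ALE,exclude_mutants restrict to neutral condition subsets
#'   before the per-gene analyses.
#' @param seed master integer seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulate = list(),
                            matrix_tsv = NULL, meta_tsv = NULL,
                            weights_tsv = NULL, labels_tsv = NULL,
                            terms_tsv = NULL, fasta = NULL,
                            min_alignment = 80, prune_to = 30,
                            p_max = 0.04, q_max = 0.05, top_k = 15,
                            metric = c("cai", "tai"),
                            duplicate_policy = c("drop_both", "drop_one"),
                            exclude_ALE = FALSE, exclude_mutants = FALSE,
                            seed = 1L) {
  structure(list(
    outdir = outdir, simulate = simulate,
    matrix_tsv = matrix_tsv, meta_tsv = meta_tsv, weights_tsv = weights_tsv,
    labels_tsv = labels_tsv, terms_tsv = terms_tsv, fasta = fasta,
    min_alignment = min_alignment, prune_to = prune_to,
    p_max = p_max, q_max = q_max, top_k = top_k,
    metric = match.arg(metric),
    duplicate_policy = match.arg(duplicate_policy),
    exclude_ALE = exclude_ALE, exclude_mutants = exclude_mutants,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' Checks types, ranges and path existence without running anything.
#'
#' @param config a [pipeline_config()].
#' @return A character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (!inherits(config, "pipeline_config")) {
    return("not a pipeline_config object")
  }
  if (!is.character(config$outdir) || !nzchar(config$outdir)) {
    add("outdir must be a non-empty path")
  }
  if (!is.numeric(config$seed) || !is.finite(config$seed) || config$seed < 0) {
    add("seed must be a non-negative integer")
  }
  if (config$min_alignment < 0) add("min_alignment must be >= 0")
  if (!is.null(config$prune_to) && config$prune_to < 2) {
    add("prune_to must be >= 2")
  }
  for (thr in c("p_max", "q_max")) {
    v <- config[[thr]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      add(paste(thr, "must be in (0, 1]"))
    }
  }
  if (config$top_k < 0) add("top_k must be >= 0")
  sim_mode <- !is.null(config$simulate)
  if (!sim_mode) {
    for (p in c("matrix_tsv", "meta_tsv", "weights_tsv")) {
      if (is.null(config[[p]])) {
        add(paste(p, "is required when simulate is disabled"))
      }
    }
  }
  if (sim_mode && length(config$simulate)) {
    ok <- tryCatch({
      do.call(synthetic_spec, config$simulate); TRUE
    }, error = function(e) e$message)
    if (!isTRUE(ok)) add(ok)
  }
  for (p in c("matrix_tsv", "meta_tsv", "weights_tsv", "labels_tsv",
              "terms_tsv", "fasta")) {
    path <- config[[p]]
    if (!is.null(path) && !file.exists(path)) {
      add(paste0(p, ": path does not exist: ", path))
    }
  }
  errs
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the compendium (simulate or load), score codon usage bias,
#' process expression (condition filters, replicate averaging, duplicate
#' removal, optional neutral subsets), condition-level structure (all-by-all
#' correlations, per-condition predictivity, growth trend, optional sparse
#' pruning), per-gene GCI with permutation null, the four nested
#' codon-bias models with VIF, and gene-set statistics when labels/terms are
#' available. Each stage writes TSV outputs into `outdir`; a manifest
#' (parameters, seeds, md5 checksums) and a plain-text report of the
#' headline statistics are written at the end.
#'
#' @param config a [pipeline_config()]; it is validated first and any
#'   problem aborts before a stage runs.
#' @return Invisibly, a list of in-memory stage results (`dataset`,
#'   `scores`, `corr`, `profile`, `trend`, `gci`, `null`, `gci_summary`,
#'   `gci_vs_expr`, `models`, `vif`, `groups`, `enrichment_pos`,
#'   `enrichment_neg`, `outdir`).
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list(outdir = config$outdir)
  written <- character()
  seed <- config$seed
  opath <- function(f) file.path(config$outdir, f)

  # --- inputs -------------------------------------------------------------
  labels <- NULL; mapping <- NULL
  if (!is.null(config$simulate)) {
    stage("simulate", {
      spec <- do.call(synthetic_spec,
                      utils::modifyList(list(seed = seed), config$simulate))
      sim <- generate_dataset(spec)
      out$dataset <- sim$dataset
      out$truth <- sim$truth
      out$table <- if (is.null(config$weights_tsv)) {
        random_weight_table(metric = if (config$metric == "tai") "tAI" else "CAI",
                            seed = seed + 1L)
      } else {
        read_weight_table(config$weights_tsv)
      }
      out$cds <- generate_sequences(out$truth, out$table, seed = seed + 2L)
      ann <- generate_annotations(out$truth, seed = seed + 3L)
      labels <- ann$labels
      mapping <- ann$mapping
      write_expression_tsv(out$dataset, opath("expression.tsv"),
                           opath("conditions.tsv"))
      write_tsv(out$truth, opath("truth.tsv"))
      write_cds_fasta(out$cds, opath("sequences.fasta"))
      written <- c(written, opath("expression.tsv"), opath("conditions.tsv"),
                   opath("truth.tsv"), opath("sequences.fasta"))
    })
  } else {
    stage("load", {
      out$dataset <- read_expression_tsv(config$matrix_tsv, config$meta_tsv)
      out$table <- read_weight_table(config$weights_tsv)
      if (!is.null(config$fasta)) out$cds <- read_cds_fasta(config$fasta)
      if (!is.null(config$labels_tsv)) labels <- read_gene_labels(config$labels_tsv)
      if (!is.null(config$terms_tsv)) mapping <- read_term_mapping(config$terms_tsv)
    })
  }

  # --- codon bias ----------------------------------------------------------
  stage("cub", {
    if (!is.null(out$cds)) {
      filt <- filter_cds(out$cds)
      out$scores <- score_genes(filt$kept, out$table, metric = config$metric)
      written <- c(written, write_tsv(out$scores, opath("cub_scores.tsv")))
    }
  })

  # --- expression processing ----------------------------------------------
  stage("process_expression", {
    ds <- filter_conditions(out$dataset, min_alignment = config$min_alignment)
    ds <- average_replicates(ds)
    ds <- drop_duplicate_conditions(ds, policy = config$duplicate_policy)
    ds <- filter_complete_genes(ds)
    if (config$exclude_ALE || config$exclude_mutants) {
      ds <- subset_conditions(ds, exclude_ALE = config$exclude_ALE,
                              exclude_mutants = config$exclude_mutants)
    }
    out$processed <- ds
    writeLines(ds$log, opath("processing_log.txt"))
    written <- c(written, opath("processing_log.txt"))
  })
  ds <- out$processed

  # --- condition-level structure ------------------------------------------
  stage("conditions", {
    corr <- condition_correlation_matrix(ds)
    out$corr <- corr
    written <- c(written, write_tsv(
      data.frame(condition = corr$condition_ids, corr$R2, check.names = FALSE),
      opath("condition_r2.tsv")))
    if (!is.null(out$scores)) {
      prof <- per_condition_cub_r2(ds, out$scores)
      out$profile <- prof
      out$trend <- growth_predictivity_trend(prof)
      written <- c(written, write_tsv(prof, opath("predictivity.tsv")))
    }
    if (!is.null(config$prune_to) && config$prune_to < ncol(ds$X)) {
      pruned <- prune_redundant_conditions(ds, config$prune_to,
                                           seed = seed + 4L)
      out$sparse <- pruned
      written <- c(written, write_tsv(attr(pruned, "prune_log"),
                                      opath("prune_log.tsv")))
    }
  })

  # --- GCI ------------------------------------------------------------------
  stage("gci", {
    out$gci <- compute_gci(ds)
    out$null <- permuted_gci(ds, seed = seed + 5L)
    out$gci_summary <- gci_summary(out$gci, out$null)
    out$gci_vs_expr <- gci_vs_mean_expression(out$gci, ds)
    written <- c(written,
                 write_tsv(out$gci, opath("gci.tsv")),
                 write_tsv(out$null$values, opath("gci_null.tsv")))
  })

  # --- models ---------------------------------------------------------------
  stage("models", {
    if (!is.null(out$scores)) {
      mean_expr <- rowMeans(ds$X)
      fits <- fit_models(out$scores, mean_expr, out$gci)
      out$models <- fits
      out$vif <- vif(mean_expr, out$gci)
      written <- c(written,
                   write_tsv(fits$summary, opath("models.tsv")),
                   write_tsv(fits$coefficients, opath("model_coefficients.tsv")),
                   write_tsv(out$vif, opath("vif.tsv")))
    }
  })

  # --- gene sets ------------------------------------------------------------
  stage("genesets", {
    if (!is.null(labels)) {
      out$groups <- compare_groups(out$gci, labels)
    }
    if (!is.null(mapping)) {
      sets <- split_by_gci_sign(out$gci)
      universe <- intersect(out$gci$gene[out$gci$defined],
                            unique(mapping$gene))
      for (side in c("positive", "negative")) {
        genes <- intersect(sets[[side]], universe)
        if (length(genes) == 0) next
        rows <- enrich(genes, universe, mapping,
                       p_max = config$p_max, q_max = config$q_max)
        top <- top_by_odds_ratio(rows, k = config$top_k)
        out[[paste0("enrichment_", substr(side, 1, 3))]] <- top
        written <- c(written, write_tsv(
          top, opath(paste0("enrichment_", side, ".tsv"))))
      }
    }
  })

  # --- manifest and report --------------------------------------------------
  manifest <- list(
    parameters = config[setdiff(names(config), "simulate")],
    simulate = config$simulate,
    seed = seed,
    outputs = lapply(stats::setNames(nm = basename(written)), function(f) {
      unname(tools::md5sum(file.path(config$outdir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(pipeline_report(out), file.path(config$outdir, "report.txt"))
  invisible(out)
}

# plain-text headline report
pipeline_report <- function(out) {
  lines <- c("gcicub pipeline report", strrep("=", 40))
  ds <- out$processed
  lines <- c(lines, sprintf("processed dataset: %d genes x %d conditions",
                            nrow(ds$X), ncol(ds$X)))
  if (!is.null(out$profile)) {
    lines <- c(lines, sprintf(
      "expression-CUB predictivity R2 range: %.3f-%.3f",
      min(out$profile$r2), max(out$profile$r2)))
  }
  if (!is.null(out$trend)) {
    lines <- c(lines, sprintf(
      "growth vs predictivity Spearman rho = %.3f (p = %.3g)",
      out$trend$rho, out$trend$p))
  }
  if (!is.null(out$gci_summary)) {
    s <- out$gci_summary
    lines <- c(lines, sprintf(
      "GCI: range %.3f-%.3f, mean %.3f, mode %.3f, skewness %.3f",
      s$min, s$max, s$mean, s$mode, s$skewness),
      sprintf("GCI null: mean %.4f, sd %.4f; %.1f%% of |GCI| beyond 2 null SD",
              s$null_mean, s$null_sd, 100 * s$frac_beyond_2sd))
  }
  if (!is.null(out$gci_vs_expr)) {
    lines <- c(lines, sprintf("GCI vs mean expression: R2 = %.3f (p = %.3g)",
                              out$gci_vs_expr$r2, out$gci_vs_expr$p))
  }
  if (!is.null(out$models)) {
    m <- out$models$summary
    lines <- c(lines, "model adjusted R2:",
               sprintf("  %-12s %.4f", m$model, m$adj_r2))
  }
  if (!is.null(out$vif)) {
    lines <- c(lines, sprintf("additive-model VIF: %.3f",
                              max(out$vif$vif)))
  }
  if (!is.null(out$groups)) {
    g <- out$groups
    lines <- c(lines, sprintf(
      "group mean GCI: %s = %.3f, %s = %.3f (t = %.2f, p = %.3g)",
      names(g$means)[1], g$means[1], names(g$means)[2], g$means[2], g$t, g$p))
  }
  for (side in c("enrichment_pos", "enrichment_neg")) {
    if (!is.null(out[[side]]) && nrow(out[[side]])) {
      lines <- c(lines, paste0(side, " top terms: ",
                               paste(utils::head(out[[side]]$term, 5),
                                     collapse = ", ")))
    }
  }
  lines
}
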