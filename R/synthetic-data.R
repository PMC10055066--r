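#' Specify a synthetic expression compendium
#'
#' The generator emulates a condition-level expression compendium: per-gene
#' baseline expression (lognormal on the natural scale, stored on the log
#' scale), per-gene growth-rate slopes drawn from a sign-constrained
#' two-component mixture (a negative-mode majority and a positive minority),
#' growth rates uniform over `growth_range`, Gaussian measurement noise, and
#' optional replicate columns sharing a condition's growth rate.
#'
#' Defaults mirror a bacterial RNA-seq compendium: 103 conditions with growth
#' rates spanning roughly 0.1-1.5 /hr, about a quarter of genes upregulated
#' under rapid growth, and slope magnitudes placing the mode of the
#' theoretical growth-correlation distribution near -0.3 at unit noise.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_conditions number of distinct conditions (>= 3).
#' @param growth_range `c(min, max)` growth rates in 1/hr, min > 0.
#' @param slope_mix fraction of genes with positive growth slope, in `[0, 1]`.
#' @param slope_scale spread (SD) of slope magnitudes around `slope_mode`.
#' @param slope_mode typical slope magnitude (log-expression per unit growth
#'   rate) of each mixture component.
#' @param noise_sd SD of Gaussian noise in log-expression units (>= 0).
#' @param baseline_mean,baseline_sd mean and SD of per-gene baseline
#'   log-expression.
#' @param n_replicates replicate columns per condition (>= 1).
#' @param p_ale probability a condition is flagged as an
#'   adaptive-laboratory-evolution (ALE) strain.
#' @param p_mutant probability a non-ALE condition is flagged as a mutant or
#'   knock-out strain.
#' @param coupling strength of the coupling between the per-gene latent
#'   score and the codon-bias sampling exponent (see [generate_sequences()]).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_conditions = 103,
                           growth_range = c(0.1, 1.5),
                           slope_mix = 0.25, slope_scale = 0.4,
                           slope_mode = 0.8, noise_sd = 1,
                           baseline_mean = 5, baseline_sd = 1.5,
                           n_replicates = 1, p_ale = 55 / 103,
                           p_mutant = 20 / 48, coupling = 1, seed = 1L) {
  spec <- list(n_genes = n_genes, n_conditions = n_conditions,
               growth_range = growth_range, slope_mix = slope_mix,
               slope_scale = slope_scale, slope_mode = slope_mode,
               noise_sd = noise_sd, baseline_mean = baseline_mean,
               baseline_sd = baseline_sd, n_replicates = n_replicates,
               p_ale = p_ale, p_mutant = p_mutant, coupling = coupling,
               seed = as.integer(seed))
  check <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid synthetic_spec field '", field, "': ", msg)
  }
  check(is.numeric(n_genes) && n_genes >= 2, "n_genes", "must be >= 2")
  check(is.numeric(n_conditions) && n_conditions >= 3, "n_conditions",
        "must be >= 3")
  check(length(growth_range) == 2 && growth_range[1] > 0 &&
          growth_range[2] >= growth_range[1], "growth_range",
        "must be (min, max) with min > 0")
  check(slope_mix >= 0 && slope_mix <= 1, "slope_mix", "must be in [0, 1]")
  check(slope_scale >= 0, "slope_scale", "must be >= 0")
  check(noise_sd >= 0, "noise_sd", "must be >= 0")
  check(baseline_sd >= 0, "baseline_sd", "must be >= 0")
  check(n_replicates >= 1, "n_replicates", "must be >= 1")
  check(p_ale >= 0 && p_ale <= 1, "p_ale", "must be in [0, 1]")
  check(p_mutant >= 0 && p_mutant <= 1, "p_mutant", "must be in [0, 1]")
  check(is.finite(spec$seed), "seed", "must be a finite integer")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Growth rates are drawn uniformly on the spec's range; gene `g` in
#' condition `c` has log expression `baseline_g + b_g * mu_c + eps` with
#' `eps ~ N(0, noise_sd^2)` drawn independently per replicate column.
#' Slopes `b_g` are positive for a fraction `slope_mix` of genes and negative
#' otherwise, with magnitudes `|N(slope_mode, slope_scale)|`.
#'
#' The returned truth records, per gene, the slope, the theoretical
#' growth-correlation `b * sd(mu) / sqrt(b^2 * var(mu) + noise_sd^2)`
#' (computed from the realized growth rates), a latent score combining
#' standardized baseline and theoretical correlation, and the codon-bias
#' coupling exponent `beta = exp(coupling * score)` used by
#' [generate_sequences()].
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (data frame: `gene`, `baseline`, `slope`, `gci_theory`,
#'   `score`, `beta`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    conds <- sprintf("cond_%03d", seq_len(spec$n_conditions))
    mu <- stats::runif(spec$n_conditions, spec$growth_range[1],
                       spec$growth_range[2])
    sign_pos <- stats::runif(spec$n_genes) < spec$slope_mix
    mag <- abs(stats::rnorm(spec$n_genes, spec$slope_mode, spec$slope_scale))
    slope <- ifelse(sign_pos, mag, -mag)
    baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)

    nrep <- spec$n_replicates
    col_cond <- rep(seq_len(spec$n_conditions), each = nrep)
    col_ids <- if (nrep == 1) conds else
      paste0(conds[col_cond], "_r", rep(seq_len(nrep), spec$n_conditions))
    signal <- outer(slope, mu[col_cond]) + baseline
    noise <- matrix(stats::rnorm(length(signal), 0, spec$noise_sd),
                    nrow = spec$n_genes)
    X <- signal + noise
    rownames(X) <- genes
    colnames(X) <- col_ids

    is_ale <- stats::runif(spec$n_conditions) < spec$p_ale
    is_mut <- !is_ale & stats::runif(spec$n_conditions) < spec$p_mutant
    meta <- data.frame(
      condition_id = col_ids,
      alignment_score = 100,
      replicate_group = conds[col_cond],
      is_ALE = is_ale[col_cond],
      is_mutant_or_KO = is_mut[col_cond]
    )
    ds <- expression_dataset(X, mu[col_cond], meta, scale = "logTPM")
    ds$log <- sprintf("generate_dataset: seed %d, %d genes x %d conditions x %d replicate(s)",
                      spec$seed, spec$n_genes, spec$n_conditions, nrep)

    vmu <- stats::var(mu)
    denom <- sqrt(slope^2 * vmu + spec$noise_sd^2)
    gci_theory <- ifelse(denom > 0, slope * sqrt(vmu) / denom, 0)
    score <- as.numeric(scale(baseline)) + as.numeric(scale(gci_theory))
    truth <- data.frame(
      gene = genes, baseline = baseline, slope = slope,
      gci_theory = gci_theory, score = score,
      beta = exp(spec$coupling * score)
    )
    list(dataset = ds, truth = truth)
  })
}

#' Generate coding sequences with planted codon usage bias
#'
#' For each gene, internal codon positions draw an amino acid uniformly from
#' the families represented in the weight table, then a synonymous codon with
#' probability proportional to `w^beta_g`. `beta = 0` gives uniform codon use
#' within each family; large `beta` concentrates on the highest-weight codon.
#' Sequences start with ATG, end with a stop codon (TAA), and have length
#' `3 * n_codons`.
#'
#' @param truth truth data frame from [generate_dataset()] (columns `gene`
#'   and `beta`), or any data frame with those columns.
#' @param table a [codon_weight_table()] covering all sense codons.
#' @param n_codons total codons per sequence including start and stop
#'   (>= 10).
#' @param seed integer seed.
#' @return A `coding_sequences` data frame (see [coding_sequences()]).
#' @export
generate_sequences <- function(truth, table, n_codons = 300, seed = 1L) {
  stopifnot(inherits(table, "codon_weight_table"))
  if (n_codons < 10) stop("n_codons must be >= 10")
  if (length(table$weights) == 0) stop("empty weight table")
  gc <- Biostrings::GENETIC_CODE
  avail <- names(table$weights)
  fam <- split(avail, gc[avail])
  if (length(fam) == 0) stop("weight table covers no amino-acid family")
  n_internal <- n_codons - 2L
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(seq_len(nrow(truth)), function(g) {
      beta <- truth$beta[g]
      aa_idx <- sample.int(length(fam), n_internal, replace = TRUE)
      codons <- character(n_internal)
      for (a in unique(aa_idx)) {
        pos <- which(aa_idx == a)
        cods <- fam[[a]]
        if (length(cods) == 1) {
          codons[pos] <- cods
        } else {
          lw <- beta * log(table$weights[cods])
          p <- exp(lw - max(lw))
          codons[pos] <- cods[sample.int(length(cods), length(pos),
                                         replace = TRUE, prob = p)]
        }
      }
      paste0("ATG", paste(codons, collapse = ""), "TAA")
    }, character(1))
    coding_sequences(id = truth$gene, seq = seqs)
  })
}

#' Random codon weight table for simulations
#'
#' Draws one weight per sense codon uniformly on `(w_min, 1)`; continuous
#' draws make the optimal codon of each synonymous family unique almost
#' surely. The table is max-normalized on construction.
#'
#' @param metric `"CAI"` or `"tAI"`.
#' @param w_min lower bound of the raw weights (> 0).
#' @param seed integer seed.
#' @return A [codon_weight_table()].
#' @export
random_weight_table <- function(metric = "CAI", w_min = 0.05, seed = 1L) {
  stopifnot(w_min > 0, w_min < 1)
  withr::with_seed(as.integer(seed), {
    cods <- sense_codons()
    w <- stats::runif(length(cods), w_min, 1)
    names(w) <- cods
    codon_weight_table(w, metric = metric,
                       provenance = sprintf("random_weight_table(seed = %d)", seed))
  })
}

#' Synthetic gene labelings and term mappings coupled to ground truth
#'
#' Produces a binary essential/non-essential labeling whose probability of
#' "essential" increases with the theoretical growth-correlation of the gene,
#' and a gene-to-term mapping in which `n_planted` terms are enriched (by
#' factor `enrichment` on the sampling odds) among genes with positive
#' theoretical growth-correlation. Used for recovery tests of the gene-set
#' statistics.
#'
#' @param truth truth data frame from [generate_dataset()].
#' @param n_terms number of terms.
#' @param term_size expected genes per term.
#' @param n_planted number of terms planted with positive-set enrichment.
#' @param enrichment odds multiplier applied to positive-correlation genes
#'   for planted terms (> 1).
#' @param label_intercept,label_slope logistic model for the essential label:
#'   `P(essential) = plogis(label_intercept + label_slope * gci_theory)`.
#' @param seed integer seed.
#' @return A list with `labels` (data frame `gene`, `label`) and `mapping`
#'   (data frame `gene`, `term`).
#' @export
generate_annotations <- function(truth, n_terms = 40, term_size = 60,
                                 n_planted = 5, enrichment = 4,
                                 label_intercept = -2.8, label_slope = 3,
                                 seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- nrow(truth)
    p_ess <- stats::plogis(label_intercept + label_slope * truth$gci_theory)
    labels <- data.frame(
      gene = truth$gene,
      label = ifelse(stats::runif(n) < p_ess, "essential", "non_essential")
    )
    pos <- truth$gci_theory > 0
    base_p <- term_size / n
    rows <- list()
    for (t in seq_len(n_terms)) {
      p <- rep(base_p, n)
      if (t <= n_planted) {
        odds <- base_p / (1 - base_p) * ifelse(pos, enrichment, 1)
        p <- odds / (1 + odds)
      }
      members <- truth$gene[stats::runif(n) < p]
      if (length(members)) {
        rows[[t]] <- data.frame(gene = members,
                                term = sprintf("T%03d", t))
      }
    }
    list(labels = labels, mapping = do.call(rbind, rows))
  })
}

#' Write a coding-sequence set to FASTA
#' @param cds a `coding_sequences` data frame.
#' @param path output path.
#' @return Invisibly, `cds`.
#' @export
write_cds_fasta <- function(cds, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(cds$seq, cds$id))
  Biostrings::writeXStringSet(x, path)
  invisible(cds)
}

#' Read coding sequences from FASTA
#' @param path FASTA path.
#' @return A `coding_sequences` data frame.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  coding_sequences(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}
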