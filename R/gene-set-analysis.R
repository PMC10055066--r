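#' Compare mean GCI between two labeled gene groups
#'
#' Two-sided Student's t-test (pooled variance by default, Welch behind a
#' flag) for a difference in mean GCI between the two label groups, over
#' genes with defined GCI.
#'
#' @param gci a `gci_result` from [compute_gci()] or a data frame with
#'   `gene` and `r` columns.
#' @param labels data frame with columns `gene` and `label` (exactly two
#'   label values among the genes with defined GCI).
#' @param welch use the Welch (unequal-variance) test instead of the pooled
#'   Student's test.
#' @return A list with `means` (named by label), `t`, `df`, `p`, `n`
#'   (per-group counts).
#' @export
compare_groups <- function(gci, labels, welch = FALSE) {
  if (!all(c("gene", "label") %in% names(labels))) {
    stop("labels must have 'gene' and 'label' columns")
  }
  if (anyDuplicated(labels$gene)) stop("labeled gene ids must be unique")
  keep <- if ("defined" %in% names(gci)) gci$defined else is.finite(gci$r)
  d <- merge(gci[keep, c("gene", "r")], labels, by = "gene")
  groups <- sort(unique(d$label))
  if (length(groups) != 2) {
    stop("need exactly 2 label groups among defined-GCI genes, got ",
         length(groups))
  }
  x <- d$r[d$label == groups[1]]
  y <- d$r[d$label == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 genes with defined GCI")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(
    means = stats::setNames(c(mean(x), mean(y)), groups),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    n = stats::setNames(c(length(x), length(y)), groups)
  )
}

#' Split genes by the sign of their GCI
#'
#' Genes with exactly zero GCI belong to neither set and are reported
#' separately; undefined genes are excluded.
#'
#' @param gci a `gci_result` from [compute_gci()].
#' @return A list with character vectors `positive`, `negative` and `zero`.
#' @export
split_by_gci_sign <- function(gci) {
  keep <- if ("defined" %in% names(gci)) gci$defined else is.finite(gci$r)
  d <- gci[keep, , drop = FALSE]
  list(positive = d$gene[d$r > 0],
       negative = d$gene[d$r < 0],
       zero = d$gene[d$r == 0])
}

#' Over-representation analysis of a gene set
#'
#' One-sided hypergeometric test per term: the probability of observing at
#' least the seen overlap between the gene set and the term's annotated
#' genes, given the universe. P-values are Benjamini-Hochberg adjusted over
#' all tested terms, and rows are filtered by the dual threshold
#' `p <= p_max` and `q <= q_max`. Odds ratios use the cross-product
#' `(a*d)/(b*c)` with a Haldane 0.5 correction (flagged) when any
#' contingency cell is zero.
#'
#' @param set character vector of gene ids (must be a subset of `universe`).
#' @param universe character vector of background gene ids.
#' @param mapping data frame with columns `gene` and `term` (multiple rows
#'   per gene allowed).
#' @param p_max,q_max significance thresholds applied jointly.
#' @param filter_significant return only rows passing both thresholds; set
#'   to `FALSE` to get every tested term.
#' @return Data frame with columns `term`, `a` (set genes in term),
#'   `b` (set genes not in term), `c` (non-set universe genes in term),
#'   `d` (remainder), `p`, `q`, `odds_ratio`, `haldane` (whether the 0.5
#'   correction was applied). Cells always satisfy
#'   `a + b + c + d = length(universe)`.
#' @export
enrich <- function(set, universe, mapping, p_max = 0.04, q_max = 0.05,
                   filter_significant = TRUE) {
  set <- unique(as.character(set))
  universe <- unique(as.character(universe))
  if (length(set) == 0 || length(universe) == 0) {
    stop("gene set and universe must be non-empty")
  }
  if (!all(set %in% universe)) {
    stop("gene set must be a subset of the universe")
  }
  mapping <- mapping[mapping$gene %in% universe, , drop = FALSE]
  if (nrow(mapping) == 0) {
    stop("term mapping covers no universe gene")
  }
  terms <- split(mapping$gene, mapping$term)
  N <- length(universe)
  n_set <- length(set)
  rows <- lapply(names(terms), function(tm) {
    members <- unique(terms[[tm]])
    K <- length(members)
    a <- sum(set %in% members)
    b <- n_set - a
    cc <- K - a
    dd <- N - K - b
    p <- stats::phyper(a - 1, K, N - K, n_set, lower.tail = FALSE)
    data.frame(term = tm, a = a, b = b, c = cc, d = dd, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  zero_cell <- with(out, a == 0 | b == 0 | c == 0 | d == 0)
  out$odds_ratio <- ifelse(
    zero_cell,
    (out$a + 0.5) * (out$d + 0.5) / ((out$b + 0.5) * (out$c + 0.5)),
    out$a * out$d / (out$b * out$c)
  )
  out$haldane <- zero_cell
  rownames(out) <- NULL
  if (filter_significant) {
    out <- out[out$p <= p_max & out$q <= q_max, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Rank enrichment rows by odds ratio
#'
#' Descending odds ratio; ties broken by ascending p-value, then term id.
#'
#' @param rows output of [enrich()].
#' @param k number of rows to return (the `min(k, nrow)` top rows).
#' @return The top rows.
#' @export
top_by_odds_ratio <- function(rows, k = 15) {
  if (k < 0) stop("k must be >= 0")
  ord <- order(-rows$odds_ratio, rows$p, rows$term)
  rows[ord[seq_len(min(k, nrow(rows)))], , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order. Wraps [stats::p.adjust()] after validating the inputs.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return The adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Read a two-column gene labeling TSV
#' @param path TSV with columns `gene` and `label`.
#' @return Data frame with `gene`, `label`.
#' @export
read_gene_labels <- function(path) {
  tab <- utils::read.delim(path)
  names(tab)[1:2] <- c("gene", "label")
  tab[, c("gene", "label")]
}

#' Read a gene-to-term mapping TSV
#' @param path TSV with columns `gene` and `term` (multiple rows per gene).
#' @return Data frame with `gene`, `term`.
#' @export
read_term_mapping <- function(path) {
  tab <- utils::read.delim(path)
  names(tab)[1:2] <- c("gene", "term")
  tab[, c("gene", "term")]
}
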