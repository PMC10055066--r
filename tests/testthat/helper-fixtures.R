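# Shared fixtures and independent brute-force oracles.

# --- weight tables ----------------------------------------------------------

# toy two-codon contrast plus neutral weights for everything else
toy_weight_table <- function() {
  cods <- gcicub:::sense_codons()
  w <- stats::setNames(rep(0.5, length(cods)), cods)
  w["AAA"] <- 1
  w["AAG"] <- 0.25
  codon_weight_table(w, metric = "CAI")
}

uniform_weight_table <- function() {
  cods <- gcicub:::sense_codons()
  codon_weight_table(stats::setNames(rep(1, length(cods)), cods),
                     metric = "CAI")
}

# random table renormalized so every synonymous family has max weight 1
# (the classic relative-adaptiveness convention)
family_normalized_table <- function(seed = 1) {
  tab <- random_weight_table(seed = seed)
  gc <- Biostrings::GENETIC_CODE
  w <- tab$weights
  for (aa in unique(gc[names(w)])) {
    cods <- names(w)[gc[names(w)] == aa]
    w[cods] <- w[cods] / max(w[cods])
  }
  codon_weight_table(w, metric = "CAI")
}

# --- datasets ---------------------------------------------------------------

make_ds <- function(X, growth, meta = NULL, scale = "logTPM") {
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  expression_dataset(X, growth, meta, scale = scale)
}

random_ds <- function(n_genes, n_conditions, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_genes * n_conditions), n_genes)
    make_ds(X, growth = runif(n_conditions, 0.1, 1.5))
  })
}

# --- GenBank toy records ----------------------------------------------------

# writes a minimal single-record GenBank flat file and returns its path
write_toy_genbank <- function(sequence, cds_features) {
  path <- withr::local_tempfile(fileext = ".gbk",
                                .local_envir = parent.frame())
  n <- nchar(sequence)
  lines <- c(
    sprintf("LOCUS       TOY%18d bp    DNA     circular BCT 01-JAN-2000", n),
    "DEFINITION  toy record.",
    "ACCESSION   TOY001",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  for (f in cds_features) {
    lines <- c(lines,
               sprintf("     CDS             %s", f$location),
               sprintf("                     /locus_tag=\"%s\"", f$locus_tag))
    if (!is.null(f$gene)) {
      lines <- c(lines, sprintf("                     /gene=\"%s\"", f$gene))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(sequence)
  pos <- seq(1, n, 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}

bf_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# --- brute-force oracles ----------------------------------------------------

# product-then-root geometric mean over the scored codons
bf_geom_score <- function(seq, table, extra_excluded = character()) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
  excl <- union(table$excluded_codons, extra_excluded)
  codons <- codons[!(codons %in% excl)]
  prod(table$weights[codons])^(1 / length(codons))
}

# two-column Pearson from first principles
bf_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Benjamini-Hochberg step-up by direct construction
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# OLS through the normal equations
bf_ols <- function(X, y) {
  X <- cbind(1, X)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# two predictors with exact sample correlation rho, n observations
correlated_predictors <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    z1 <- rnorm(n)
    z1 <- (z1 - mean(z1)) / sd(z1)
    z2 <- rnorm(n)
    z2 <- z2 - mean(z2)
    z2 <- z2 - z1 * sum(z1 * z2) / sum(z1^2)  # orthogonal to z1, mean 0
    z2 <- z2 / sd(z2)
    list(x1 = z1, x2 = rho * z1 + sqrt(1 - rho^2) * z2)
  })
}
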