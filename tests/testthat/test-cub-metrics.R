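test_that("forward-strand CDS equals the genomic slice", {
  genome <- paste(rep("ACGTTGCAAC", 12), collapse = "")
  path <- write_toy_genbank(genome, list(
    list(location = "11..31", locus_tag = "t0001", gene = "abc")
  ))
  rec <- read_genbank(path)
  expect_equal(rec$accession, "TOY001")
  expect_equal(rec$sequence, genome)
  cds <- extract_cds(rec)
  expect_equal(nrow(cds), 1)
  expect_equal(cds$seq, substr(genome, 11, 31))
  expect_equal(cds$id, "t0001")
  expect_equal(cds$gene_name, "abc")
  expect_equal(cds$strand, "+")
})

test_that("minus-strand CDS is reverse-complemented", {
  genome <- paste(rep("ACGTTGCAAC", 12), collapse = "")
  path <- write_toy_genbank(genome, list(
    list(location = "complement(19..36)", locus_tag = "t0002")
  ))
  cds <- extract_cds(read_genbank(path))
  expect_equal(cds$strand, "-")
  expect_equal(cds$seq, bf_revcomp(substr(genome, 19, 36)))
})

test_that("joined multi-exon CDS is spliced in annotation order", {
  genome <- paste(rep("ACGTTGCAAC", 12), collapse = "")
  path <- write_toy_genbank(genome, list(
    list(location = "join(4..12,31..45)", locus_tag = "t0003")
  ))
  cds <- extract_cds(read_genbank(path))
  expect_equal(cds$seq,
               paste0(substr(genome, 4, 12), substr(genome, 31, 45)))
  expect_equal(cds$intervals[[1]], cbind(c(4, 31), c(12, 45)))
})

test_that("out-of-range CDS features are skipped with a warning", {
  genome <- paste(rep("ACGTTGCAAC", 3), collapse = "")
  path <- write_toy_genbank(genome, list(
    list(location = "5..400", locus_tag = "bad"),
    list(location = "1..9", locus_tag = "good")
  ))
  expect_warning(cds <- extract_cds(read_genbank(path)), "out-of-range")
  expect_equal(cds$id, "good")
})

test_that("CDS filters apply the divisibility, span and length rules", {
  mk <- function(lens) {
    coding_sequences(id = sprintf("g%d", seq_along(lens)),
                     seq = vapply(lens, function(n) {
                       paste(rep("A", n), collapse = "")
                     }, ""))
  }
  # not divisible by 3
  f <- filter_cds(mk(c(100, 99)))
  expect_equal(f$kept$id, "g2")
  expect_match(f$removed$reason, "divisible")
  # median rule: lengths {30,30,30,30,201}, median 30, threshold 150
  f <- filter_cds(mk(c(30, 30, 30, 30, 201)))
  expect_equal(nrow(f$kept), 4)
  expect_equal(f$removed$id, "g5")
  expect_match(f$removed$reason, "median")
  # all equal and divisible: all kept
  f <- filter_cds(mk(rep(30, 6)))
  expect_equal(nrow(f$removed), 0)
  # annotated span disagreeing with the sequence length
  cds <- mk(c(30, 30))
  cds$intervals[[1]] <- cbind(1, 29)
  f <- filter_cds(cds)
  expect_equal(f$removed$id, "g1")
  expect_match(f$removed$reason, "span")
  expect_error(filter_cds(mk(integer(0))), "empty")
})

test_that("geometric mean score matches hand and brute-force computation", {
  tab <- toy_weight_table()
  out <- geometric_mean_score("AAAAAGAAA", tab)
  expect_equal(out$score, 0.25^(1 / 3), tolerance = 1e-12)
  expect_equal(out$n_codons_scored, 3)
  # brute-force product-then-root oracle on short random sequences
  set.seed(20)
  rtab <- random_weight_table(seed = 21)
  cods <- names(rtab$weights)
  for (i in 1:20) {
    s <- paste(sample(cods, sample(2:10, 1), replace = TRUE), collapse = "")
    got <- geometric_mean_score(s, rtab)
    expect_equal(got$score, bf_geom_score(s, rtab), tolerance = 1e-12)
  }
})

test_that("score is invariant under codon order and monotone in weights", {
  rtab <- random_weight_table(seed = 22)
  set.seed(23)
  cods <- sample(names(rtab$weights), 30, replace = TRUE)
  s1 <- paste(cods, collapse = "")
  s2 <- paste(sample(cods), collapse = "")
  expect_equal(geometric_mean_score(s1, rtab)$score,
               geometric_mean_score(s2, rtab)$score, tolerance = 1e-12)
  # replacing a codon by a higher-weight synonym never decreases the score
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(rtab$weights), gc[names(rtab$weights)])
  fam <- fam[lengths(fam) > 1][[1]]
  lo <- fam[which.min(rtab$weights[fam])]
  hi <- fam[which.max(rtab$weights[fam])]
  base <- paste(cods, collapse = "")
  s_lo <- paste0(base, lo)
  s_hi <- paste0(base, hi)
  expect_gte(geometric_mean_score(s_hi, rtab)$score,
             geometric_mean_score(s_lo, rtab)$score)
})

test_that("exclusions, unknown codons and ambiguity are handled", {
  tab <- toy_weight_table()
  # stop codon at the end is never scored
  expect_equal(geometric_mean_score("AAATAA", tab)$n_codons_scored, 1)
  # weight-1 codons only
  expect_equal(geometric_mean_score("AAAAAA", tab)$score, 1)
  # everything excluded
  expect_error(geometric_mean_score("TAATGA", tab), "no scorable codons")
  # unknown codon names the codon
  small <- codon_weight_table(
    stats::setNames(rep(1, 61), gcicub:::sense_codons()), metric = "CAI")
  small$weights <- small$weights[names(small$weights) != "GGG"]
  expect_error(geometric_mean_score("AAAGGG", small), "GGG")
  # ambiguous bases are skipped with a warning, not an error
  expect_warning(out <- geometric_mean_score("AAANNNAAG", tab), "ambiguous")
  expect_equal(out$n_codons_scored, 2)
})

test_that("cai wrapper applies the single-codon-family policy", {
  tab <- toy_weight_table()
  # default: ATG and TGG excluded from scoring
  expect_equal(cai("ATGAAATGG", tab)$n_codons_scored, 1)
  expect_equal(cai("ATGAAATGG", tab, exclude_single_codon_families = FALSE)$n_codons_scored,
               3)
  # wrapper identity with the policy disabled
  expect_equal(cai("AAAAAGAAA", tab, exclude_single_codon_families = FALSE)$score,
               geometric_mean_score("AAAAAGAAA", tab)$score)
})

test_that("tai zero-weight policy substitutes the geometric mean", {
  cods <- gcicub:::sense_codons()
  w <- stats::setNames(rep(0.5, length(cods)), cods)
  w["AAA"] <- 1
  w["GGG"] <- 0  # codon with no decoding tRNA
  tab <- codon_weight_table(w, metric = "tAI")
  out <- tai("AAAGGGAAA", tab)
  expect_true(is.finite(out$score))
  # hand computation with the substituted weight
  sub_w <- exp(mean(log(w[w > 0] / max(w))))
  expect_equal(out$score, (1 * sub_w * 1)^(1 / 3), tolerance = 1e-12)
  expect_error(tai("AAAGGGAAA", tab, zero_policy = "error"), "zero-weight")
})

test_that("weight tables normalize and round-trip through TSV", {
  cods <- gcicub:::sense_codons()
  w <- stats::setNames(seq(0.2, 4, length.out = length(cods)), cods)
  tab <- codon_weight_table(w, metric = "CAI")
  expect_equal(max(tab$weights), 1)
  expect_equal(unname(tab$weights), unname(w / max(w)))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(codon = names(tab$weights),
                                cai = tab$weights),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_weight_table(path)
  expect_equal(back$metric, "CAI")
  expect_equal(back$weights, tab$weights)
  # incomplete table is rejected
  expect_error(codon_weight_table(w[1:10], metric = "CAI"),
               "neither weighted nor excluded")
})
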