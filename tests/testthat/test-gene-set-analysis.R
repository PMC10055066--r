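fake_gci <- function(r, prefix = "g") {
  data.frame(gene = paste0(prefix, seq_along(r)), r = r,
             n_conditions = 10, defined = is.finite(r))
}

test_that("group comparison is a pooled two-sided Student's t-test", {
  gci <- fake_gci(c(0, 1, 2, 3))
  labels <- data.frame(gene = gci$gene,
                       label = c("a", "a", "b", "b"))
  out <- compare_groups(gci, labels)
  expect_equal(unname(out$means), c(0.5, 2.5))
  expect_equal(out$t, -2.828427, tolerance = 1e-6)
  expect_equal(out$df, 2)
  expect_equal(out$p, 0.105573, tolerance = 1e-5)
  # identical groups: t = 0, p = 1
  gci2 <- fake_gci(c(1, 2, 3, 1, 2, 3))
  labels2 <- data.frame(gene = gci2$gene,
                        label = rep(c("a", "b"), each = 3))
  out2 <- compare_groups(gci2, labels2)
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  expect_equal(unname(diff(out2$means)), 0)
  # empty group after the defined-GCI filter
  gci3 <- fake_gci(c(1, 2, NA, NA))
  expect_error(compare_groups(gci3, labels), "2 label groups|at least 2")
})

test_that("welch variant relaxes the equal-variance assumption", {
  withr::with_seed(60, {
    gci <- fake_gci(c(rnorm(30, 0, 0.1), rnorm(30, 0.3, 0.6)))
  })
  labels <- data.frame(gene = gci$gene, label = rep(c("a", "b"), each = 30))
  pooled <- compare_groups(gci, labels)
  welch <- compare_groups(gci, labels, welch = TRUE)
  expect_equal(pooled$df, 58)
  expect_lt(welch$df, 58)
  expect_equal(pooled$means, welch$means)
})

test_that("splitting by GCI sign partitions the defined genes", {
  gci <- fake_gci(c(0.5, -0.2, 0, 0.1, NA, -0.9))
  s <- split_by_gci_sign(gci)
  expect_setequal(s$positive, c("g1", "g4"))
  expect_setequal(s$negative, c("g2", "g6"))
  expect_equal(s$zero, "g3")
  expect_equal(length(s$positive) + length(s$negative) + length(s$zero),
               sum(gci$defined))
  all_pos <- split_by_gci_sign(fake_gci(c(0.1, 0.2)))
  expect_length(all_pos$negative, 0)
})

test_that("enrichment reproduces hypergeometric and odds-ratio hand cases", {
  # universe of 10, one term annotating 5, set of 2 both annotated:
  # p = C(5,2)/C(10,2) = 10/45
  universe <- paste0("g", 1:10)
  mapping <- data.frame(gene = paste0("g", 1:5), term = "T1")
  rows <- enrich(paste0("g", 1:2), universe, mapping,
                 filter_significant = FALSE)
  expect_equal(rows$p, 10 / 45, tolerance = 1e-12)
  expect_equal(rows$a + rows$b + rows$c + rows$d, 10)
  # cross-product odds ratio: a=10, b=90, c=50, d=850 -> 1.8889
  universe2 <- sprintf("u%04d", 1:1000)
  set2 <- universe2[1:100]
  term2 <- c(universe2[1:10], universe2[101:150])
  mapping2 <- data.frame(gene = term2, term = "T2")
  rows2 <- enrich(set2, universe2, mapping2, filter_significant = FALSE)
  expect_equal(rows2[, c("a", "b", "c", "d")],
               data.frame(a = 10, b = 90, c = 50, d = 850))
  expect_equal(rows2$odds_ratio, 17 / 9, tolerance = 1e-12)
  expect_equal(round(rows2$odds_ratio, 4), 1.8889)
  expect_false(rows2$haldane)
  # annotation proportions identical inside and outside the set: OR = 1
  # (a=4, b=16, c=16, d=64 gives a*d = b*c)
  universe3 <- sprintf("v%03d", 1:100)
  mapping3 <- data.frame(gene = universe3[1:20], term = "T3")
  rows3 <- enrich(universe3[c(1:4, 21:36)], universe3,
                  mapping3, filter_significant = FALSE)
  expect_equal(rows3$odds_ratio, 1, tolerance = 1e-12)
  # zero cell triggers the flagged Haldane correction
  mapping4 <- data.frame(gene = c("g1", "g2"), term = "T4")
  rows4 <- enrich(c("g1", "g2"), universe, mapping4,
                  filter_significant = FALSE)
  expect_true(rows4$haldane)
  expect_equal(rows4$odds_ratio,
               (2 + 0.5) * (8 + 0.5) / (0.5 * 0.5), tolerance = 1e-12)
  expect_error(enrich(character(), universe, mapping), "non-empty")
  expect_error(enrich("zz", universe, mapping), "subset")
})

test_that("the dual p/q threshold filters the returned rows", {
  withr::with_seed(61, {
    universe <- sprintf("g%04d", 1:400)
    set <- universe[1:80]
    # one strongly planted term + many random ones
    rows <- list(data.frame(gene = c(set[1:40], universe[301:310]),
                            term = "PLANTED"))
    for (t in 1:20) {
      rows[[t + 1]] <- data.frame(gene = sample(universe, 30),
                                  term = sprintf("R%02d", t))
    }
    mapping <- do.call(rbind, rows)
  })
  all_rows <- enrich(set, universe, mapping, filter_significant = FALSE)
  sig <- enrich(set, universe, mapping)
  expect_true("PLANTED" %in% sig$term)
  expect_true(all(sig$p <= 0.04 & sig$q <= 0.05))
  expect_true(nrow(sig) < nrow(all_rows))
})

test_that("planted enrichment is recovered near its implied odds ratio", {
  # membership odds multiplied by f for set genes: the sample OR estimates f
  f <- 4
  withr::with_seed(62, {
    universe <- sprintf("g%05d", 1:20000)
    in_set <- rep(c(TRUE, FALSE), each = 10000)
    base_odds <- 0.1 / 0.9
    p_term <- ifelse(in_set, f * base_odds / (1 + f * base_odds), 0.1)
    member <- runif(20000) < p_term
  })
  mapping <- data.frame(gene = universe[member], term = "T")
  rows <- enrich(universe[in_set], universe, mapping,
                 filter_significant = FALSE)
  expect_equal(rows$odds_ratio, f, tolerance = 0.15)
})

test_that("odds-ratio ranking breaks ties by p then term id", {
  rows <- data.frame(term = c("t4", "t1", "t3", "t2"),
                     odds_ratio = c(2, 5, 5, 1),
                     p = c(0.01, 0.02, 0.01, 0.001))
  top <- top_by_odds_ratio(rows, k = 3)
  expect_equal(top$term, c("t3", "t1", "t4"))
  expect_equal(nrow(top_by_odds_ratio(rows, k = 10)), 4)
  expect_equal(nrow(top_by_odds_ratio(rows, k = 0)), 0)
  # equal OR and equal p falls back to term id
  rows2 <- data.frame(term = c("b", "a"), odds_ratio = c(3, 3),
                      p = c(0.5, 0.5))
  expect_equal(top_by_odds_ratio(rows2, k = 2)$term, c("a", "b"))
})

test_that("BH adjustment matches the brute-force step-up exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(63, {
    for (i in 1:10) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-15)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("labelings and mappings round-trip through TSV", {
  labels <- data.frame(gene = paste0("g", 1:4),
                       label = c("core", "core", "accessory", "accessory"))
  mapping <- data.frame(gene = c("g1", "g1", "g2"),
                        term = c("T1", "T2", "T1"))
  lp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(labels, lp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mapping, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_labels(lp), labels)
  expect_equal(read_term_mapping(mp), mapping)
})
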