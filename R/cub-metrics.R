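STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 sense codons, from the standard genetic code
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Read a GenBank flat file
#'
#' A minimal reader for GenBank records: parses the LOCUS line, the feature
#' table (feature key, location, qualifiers) and the ORIGIN sequence. Only
#' what CDS extraction needs is retained; compound locations
#' (`join(...)`, `complement(...)`) are supported.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return A list of class `genbank_record` with elements `accession`,
#'   `length`, `sequence` (uppercase character string) and `features`
#'   (a list of `list(key, location, qualifiers)`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  accession <- NA_character_
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    accession <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else if (length(locus)) {
    accession <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  }
  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  if (length(feat_start) == 0 || length(origin) == 0) {
    stop("not a GenBank flat file (missing FEATURES or ORIGIN): ", path)
  }
  feat_lines <- lines[(feat_start[1] + 1):(origin[1] - 1)]
  end <- grep("^//", lines)
  end <- if (length(end)) end[1] - 1 else length(lines)
  seq_lines <- lines[(origin[1] + 1):end]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- list()
  cur <- NULL
  in_qualifiers <- FALSE
  for (ln in feat_lines) {
    if (!nzchar(trimws(ln))) next
    key_field <- substr(ln, 1, 20)
    body <- trimws(substr(ln, 21, nchar(ln)))
    if (nzchar(trimws(key_field))) {
      if (!is.null(cur)) features[[length(features) + 1]] <- cur
      cur <- list(key = trimws(key_field), location = body,
                  qualifiers = character())
      in_qualifiers <- FALSE
    } else if (startsWith(body, "/")) {
      cur$qualifiers <- c(cur$qualifiers, body)
      in_qualifiers <- TRUE
    } else if (!is.null(cur)) {
      if (in_qualifiers) {
        n <- length(cur$qualifiers)
        cur$qualifiers[n] <- paste0(cur$qualifiers[n], body)
      } else {
        cur$location <- paste0(cur$location, body)
      }
    }
  }
  if (!is.null(cur)) features[[length(features) + 1]] <- cur
  features <- lapply(features, function(f) {
    f$qualifiers <- parse_qualifiers(f$qualifiers)
    f
  })
  structure(list(accession = accession, length = nchar(sequence),
                 sequence = sequence, features = features),
            class = "genbank_record")
}

parse_qualifiers <- function(quals) {
  out <- list()
  for (q in quals) {
    q <- sub("^/", "", q)
    eq <- regexpr("=", q, fixed = TRUE)
    if (eq == -1) {
      out[[q]] <- TRUE
    } else {
      key <- substr(q, 1, eq - 1)
      val <- substr(q, eq + 1, nchar(q))
      val <- gsub("^\"|\"$", "", val)
      out[[key]] <- val
    }
  }
  out
}

# parse a GenBank location string into intervals (1-based inclusive) + strand;
# returns NULL for locations this package does not support (e.g. mixed-strand
# joins or remote references)
parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (any(grepl("[():]", parts))) return(NULL)
  iv <- t(vapply(parts, function(p) {
    nums <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    if (anyNA(nums)) return(c(NA_real_, NA_real_))
    if (length(nums) == 1) nums <- c(nums, nums)
    nums
  }, numeric(2)))
  if (anyNA(iv)) return(NULL)
  list(intervals = unname(iv), strand = strand)
}

#' Extract coding sequences from a GenBank record
#'
#' One entry is returned per CDS feature. Multi-interval (joined) CDS are
#' spliced in annotation order; minus-strand CDS are reverse-complemented so
#' that `seq` is always the coding strand. Coordinates are kept 1-based
#' inclusive as in the source record. Features with out-of-range or
#' unsupported locations are skipped with a warning.
#'
#' @param record a `genbank_record` from [read_genbank()].
#' @return A `coding_sequences` data frame with columns `id` (locus tag),
#'   `gene_name`, `strand`, `length`, `seq` and a list-column `intervals`
#'   (two-column matrices of start/end).
#' @export
extract_cds <- function(record) {
  stopifnot(inherits(record, "genbank_record"))
  feats <- Filter(function(f) f$key == "CDS", record$features)
  rows <- list()
  skipped <- 0L
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    loc <- parse_location(f$location)
    if (is.null(loc) ||
        any(loc$intervals < 1) || any(loc$intervals > record$length) ||
        any(loc$intervals[, 2] < loc$intervals[, 1])) {
      warning("skipping CDS with unsupported or out-of-range location: ",
              f$location)
      skipped <- skipped + 1L
      next
    }
    pieces <- apply(loc$intervals, 1, function(iv) {
      substr(record$sequence, iv[1], iv[2])
    })
    s <- paste(pieces, collapse = "")
    if (loc$strand == "-") s <- revcomp(s)
    id <- f$qualifiers$locus_tag
    if (is.null(id)) id <- f$qualifiers$gene
    if (is.null(id)) id <- sprintf("CDS_%04d", i)
    gene <- f$qualifiers$gene
    rows[[length(rows) + 1L]] <- list(id = id, gene_name = gene %||% NA_character_,
                                      strand = loc$strand, seq = s,
                                      intervals = loc$intervals)
  }
  coding_sequences(
    id = vapply(rows, `[[`, "", "id"),
    seq = vapply(rows, `[[`, "", "seq"),
    gene_name = vapply(rows, `[[`, "", "gene_name"),
    strand = vapply(rows, `[[`, "", "strand"),
    intervals = lapply(rows, `[[`, "intervals")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Construct a table of coding sequences
#'
#' @param id character vector of locus tags (unique).
#' @param seq nucleotide sequences on the coding strand.
#' @param gene_name optional gene names.
#' @param strand `"+"` or `"-"` per entry.
#' @param intervals optional list of two-column start/end matrices in source
#'   coordinates; defaults to a single interval covering each sequence.
#' @return A data frame of class `coding_sequences`.
#' @export
coding_sequences <- function(id, seq, gene_name = NA_character_,
                             strand = "+", intervals = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  gene_name <- rep_len(gene_name, length(id))
  strand <- rep_len(strand, length(id))
  if (anyDuplicated(id)) {
    warning("duplicated CDS ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.null(intervals)) {
    intervals <- lapply(nchar(seq), function(n) cbind(1, n))
  }
  out <- data.frame(id = id, gene_name = gene_name, strand = strand,
                    length = nchar(seq), seq = seq,
                    stringsAsFactors = FALSE)
  out$intervals <- intervals
  class(out) <- c("coding_sequences", "data.frame")
  out
}

#' Filter coding sequences by basic quality rules
#'
#' Keeps entries whose length is divisible by 3, equals the summed width of
#' the annotated intervals (catching malformed joins), and is at most five
#' times the median length of the full input set. The median is computed over
#' all input entries before any removal.
#'
#' @param cds a `coding_sequences` data frame.
#' @param max_median_fold length cutoff as a multiple of the median length.
#' @return A list with elements `kept` and `removed`; `removed` carries a
#'   `reason` column.
#' @export
filter_cds <- function(cds, max_median_fold = 5) {
  stopifnot(inherits(cds, "coding_sequences"))
  if (nrow(cds) == 0) stop("empty coding-sequence set")
  len <- nchar(cds$seq)
  span <- vapply(cds$intervals, function(iv) sum(iv[, 2] - iv[, 1] + 1), 0)
  med <- stats::median(len)
  reason <- rep(NA_character_, nrow(cds))
  reason[len %% 3 != 0] <- "length not divisible by 3"
  reason[is.na(reason) & len != span] <- "length differs from annotated interval span"
  reason[is.na(reason) & len > max_median_fold * med] <-
    sprintf("longer than %g x median length (%g)", max_median_fold, med)
  removed <- cds[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = cds[is.na(reason), , drop = FALSE], removed = removed)
}

#' Construct a codon weight table
#'
#' Weights are normalized so the maximum is 1 (both CAI and tAI are defined
#' relative to the optimal codon). Every sense codon must either carry a
#' weight or be listed in `excluded_codons`; stop codons are always excluded.
#'
#' @param weights named numeric vector, names are codons (DNA alphabet; `U`
#'   is accepted and converted to `T`). Weights must be non-negative; zero
#'   weights are permitted at construction and handled by the metric's zero
#'   policy (see [tai()]).
#' @param metric `"CAI"` or `"tAI"`.
#' @param excluded_codons codons never scored (stop codons are added
#'   automatically).
#' @param provenance free-text description of where the weights come from.
#' @return An object of class `codon_weight_table`.
#' @export
codon_weight_table <- function(weights, metric = c("CAI", "tAI"),
                               excluded_codons = character(),
                               provenance = "") {
  metric <- match.arg(metric)
  if (length(weights) == 0) stop("empty weight table")
  names(weights) <- chartr("Uu", "Tt", toupper(names(weights)))
  excluded_codons <- unique(c(chartr("U", "T", toupper(excluded_codons)),
                              STOP_CODONS))
  bad <- setdiff(names(weights), names(Biostrings::GENETIC_CODE))
  if (length(bad)) stop("not codons: ", paste(bad, collapse = ", "))
  if (any(!is.finite(weights) | weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  weights <- weights[!(names(weights) %in% excluded_codons)]
  missing <- setdiff(sense_codons(), c(names(weights), excluded_codons))
  if (length(missing)) {
    stop("sense codons neither weighted nor excluded: ",
         paste(missing, collapse = ", "))
  }
  if (max(weights) <= 0) stop("all weights are zero")
  weights <- weights / max(weights)
  structure(list(metric = metric, weights = weights,
                 excluded_codons = excluded_codons, provenance = provenance),
            class = "codon_weight_table")
}

#' Read a codon weight table from a two-column TSV
#'
#' The file has a header whose second column names the metric (e.g.
#' `codon<TAB>cai`), followed by one `codon<TAB>weight` row per codon.
#'
#' @param path path to the TSV.
#' @param metric override the metric named in the header.
#' @param ... passed to [codon_weight_table()].
#' @return A [codon_weight_table()].
#' @export
read_weight_table <- function(path, metric = NULL, ...) {
  tab <- utils::read.delim(path)
  if (ncol(tab) < 2) stop("weight table must have two columns (codon, weight)")
  if (is.null(metric)) {
    metric <- switch(toupper(names(tab)[2]),
                     CAI = "CAI", TAI = "tAI",
                     stop("header does not name a known metric (cai/tai): ",
                          names(tab)[2]))
  }
  codon_weight_table(stats::setNames(tab[[2]], tab[[1]]), metric = metric,
                     provenance = path, ...)
}

#' Geometric-mean codon usage score of one sequence
#'
#' The score is `exp(mean(log w))` over all scored codons. Codons listed in
#' the table's `excluded_codons` are skipped and not counted; codons
#' containing ambiguous bases (anything outside ACGT) are skipped with a
#' warning. A codon that is neither excluded nor present in the table is an
#' error.
#'
#' @param seq nucleotide string, length divisible by 3.
#' @param table a [codon_weight_table()].
#' @return A list with `score`, `n_codons_scored` and `metric`.
#' @export
geometric_mean_score <- function(seq, table) {
  stopifnot(inherits(table, "codon_weight_table"))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3 || n %% 3 != 0) {
    stop("sequence length must be a positive multiple of 3, got ", n)
  }
  codons <- substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
  codons <- codons[!(codons %in% table$excluded_codons)]
  ambiguous <- grepl("[^ACGT]", codons)
  if (any(ambiguous)) {
    warning(sum(ambiguous), " codon(s) with ambiguous bases skipped")
    codons <- codons[!ambiguous]
  }
  if (length(codons) == 0) stop("no scorable codons left after exclusions")
  unknown <- setdiff(unique(codons), names(table$weights))
  if (length(unknown)) {
    stop("codon(s) absent from the weight table: ",
         paste(unknown, collapse = ", "))
  }
  w <- table$weights[codons]
  if (any(w == 0)) {
    stop("zero-weight codon(s) scored: ",
         paste(unique(codons[w == 0]), collapse = ", "),
         "; use tai() with zero_policy = \"geomean\" for tAI-style tables")
  }
  list(score = exp(mean(log(w))), n_codons_scored = length(codons),
       metric = table$metric)
}

#' Codon adaptation index of one sequence
#'
#' Geometric mean of reference codon weights. Stop codons are never scored;
#' the single-codon families ATG (Met) and TGG (Trp), which carry no
#' synonymous choice, are excluded by default.
#'
#' @inheritParams geometric_mean_score
#' @param exclude_single_codon_families exclude ATG and TGG from scoring.
#' @return As [geometric_mean_score()].
#' @export
cai <- function(seq, table, exclude_single_codon_families = TRUE) {
  if (exclude_single_codon_families) {
    table <- codon_weight_table(
      table$weights, metric = table$metric,
      excluded_codons = union(table$excluded_codons, c("ATG", "TGG")),
      provenance = table$provenance)
  }
  out <- geometric_mean_score(seq, table)
  out$metric <- "CAI"
  out
}

#' tRNA adaptation index of one sequence
#'
#' Geometric mean of tRNA-availability weights. Published tAI tables can
#' assign zero weight to codons with no decoding tRNA; under the default
#' policy such codons receive the geometric mean of the non-zero weights.
#'
#' @inheritParams geometric_mean_score
#' @param zero_policy `"geomean"` substitutes the geometric mean of non-zero
#'   weights for zero-weight codons; `"error"` refuses to score them.
#' @return As [geometric_mean_score()].
#' @export
tai <- function(seq, table, zero_policy = c("geomean", "error")) {
  zero_policy <- match.arg(zero_policy)
  w <- table$weights
  if (any(w == 0) && zero_policy == "geomean") {
    w[w == 0] <- exp(mean(log(w[w > 0])))
    table <- codon_weight_table(w, metric = table$metric,
                                excluded_codons = table$excluded_codons,
                                provenance = table$provenance)
  }
  out <- geometric_mean_score(seq, table)
  out$metric <- "tAI"
  out
}

#' Score a set of coding sequences
#'
#' @param cds a `coding_sequences` data frame (see [coding_sequences()]).
#' @param table a [codon_weight_table()].
#' @param metric `"cai"` or `"tai"`; dispatches to the corresponding scorer.
#' @param ... passed to [cai()] or [tai()].
#' @return Data frame with columns `id`, `metric`, `score`, `n_codons`.
#' @export
score_genes <- function(cds, table, metric = c("cai", "tai"), ...) {
  metric <- match.arg(metric)
  fun <- if (metric == "cai") cai else tai
  res <- lapply(cds$seq, fun, table = table, ...)
  data.frame(
    id = cds$id,
    metric = vapply(res, `[[`, "", "metric"),
    score = vapply(res, `[[`, 0, "score"),
    n_codons = vapply(res, `[[`, 0L, "n_codons_scored")
  )
}

#' Write per-gene scores as TSV
#' @param scores output of [score_genes()].
#' @param path output path.
#' @return Invisibly, `scores`.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scores)
}
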