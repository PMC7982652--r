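# Ortholog detection: best bidirectional hits with ties, from either the
# built-in Smith-Waterman aligner or externally supplied tabular hits.

#' Construct a pairwise hit table
#'
#' One row per (query, subject) pair after best-row reduction, carrying the
#' E-value and bit score of the best-scoring HSP. `direction` records which
#' proteome played query: `"forward"` means source-query against target-db.
#'
#' @param query,subject Character vectors of protein ids.
#' @param evalue Non-negative E-values (compared exactly as parsed; ties are
#'   real, e.g. exact gene duplications).
#' @param bitscore Bit scores.
#' @param direction `"forward"` or `"reverse"`.
#' @param reduce Reduce multiple rows per (query, subject) to the one with
#'   minimal E-value (ties broken by maximal bit score).
#' @return A `data.frame` of class `hit_table`.
#' @export
hit_table <- function(query = character(), subject = character(),
                      evalue = numeric(), bitscore = numeric(),
                      direction = c("forward", "reverse"), reduce = FALSE) {
  direction <- match.arg(direction)
  if (any(evalue < 0)) stop("E-values must be >= 0", call. = FALSE)
  df <- data.frame(query = as.character(query),
                   subject = as.character(subject),
                   evalue = as.numeric(evalue),
                   bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  if (reduce) df <- reduce_best_rows(df)
  df <- df[order(df$query, df$subject), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("query", "subject")]))
    stop("hit table has multiple rows per (query, subject); use reduce = TRUE",
         call. = FALSE)
  structure(df, direction = direction, class = c("hit_table", "data.frame"))
}

reduce_best_rows <- function(df) {
  if (nrow(df) == 0L) return(df)
  # best HSP per (query, subject): minimal E-value, then maximal bitscore
  o <- order(df$query, df$subject, df$evalue, -df$bitscore)
  df <- df[o, , drop = FALSE]
  keep <- !duplicated(df[c("query", "subject")])
  df[keep, , drop = FALSE]
}

#' Load external tabular alignment hits (12-column dialect)
#'
#' Reads the common 12-column tab-separated alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Multiple HSPs per (query, subject) are reduced to the
#' row with minimal E-value (ties by maximal bit score). Ids are preserved
#' verbatim.
#'
#' @param path File path; an empty file yields an empty table.
#' @param direction `"forward"` (source-query vs target-db) or `"reverse"`.
#' @return A `hit_table`.
#' @export
load_tabular_hits <- function(path, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L || all(is.na(nf)))
    return(hit_table(direction = direction))
  bad <- which(nf != 12L)
  if (length(bad))
    stop("expected 12 tab-separated columns but found ", nf[bad[1L]],
         " on line ", bad[1L], " of '", path, "'", call. = FALSE)
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", rep("numeric", 10)))
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hit_table(df$qseqid, df$sseqid, df$evalue, df$bitscore,
            direction = direction, reduce = TRUE)
}

#' Best hits per query under an E-value cutoff
#'
#' For each query, returns every subject achieving the minimal E-value among
#' that query's rows, provided that minimum is strictly below the cutoff.
#' All ties are returned (multiple subjects can share the same minimal
#' E-value, as with exact gene duplications). E-values are compared exactly
#' as parsed; no epsilon.
#'
#' @param hits A `hit_table` (already best-row reduced).
#' @param evalue_cutoff Strict upper bound on the best E-value (default
#'   `1e-3`).
#' @return Named list: query id -> character vector of best subject ids.
#'   Queries whose best E-value is not below the cutoff are absent.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-3) {
  if (nrow(hits) == 0L) return(structure(list(), names = character()))
  out <- lapply(split(hits[c("subject", "evalue")], hits$query), function(h) {
    m <- min(h$evalue)
    if (m < evalue_cutoff) sort(h$subject[h$evalue == m]) else NULL
  })
  drop_null(out)
}

#' Bidirectional best-hit ortholog pairs
#'
#' A pair (A, B) is an ortholog pair iff B is among A's best forward hits
#' and A is among B's best reverse hits, with both best E-values below the
#' cutoff. A protein may appear in multiple pairs (ties are retained in both
#' directions). The P-value of a pair is the arithmetic mean of its two
#' E-values. Paralogs are never called.
#'
#' @param fwd Forward `hit_table` (source proteins as queries).
#' @param rev Reverse `hit_table` (target proteins as queries).
#' @param evalue_cutoff Strict E-value cutoff for both directions.
#' @return A `data.frame` of class `ortholog_pairs` with columns
#'   `source_protein`, `target_protein`, `e_forward`, `e_reverse`, `p_value`
#'   and `tie_group` (shared identifier for targets with several co-best
#'   source partners, `NA` otherwise), sorted by source then target id.
#' @export
bidirectional_orthologs <- function(fwd, rev, evalue_cutoff = 1e-3) {
  bh_f <- best_hits(fwd, evalue_cutoff)
  bh_r <- best_hits(rev, evalue_cutoff)
  src <- character(); tgt <- character(); ef <- numeric(); er <- numeric()
  fkey <- paste(fwd$query, fwd$subject, sep = "\r")
  rkey <- paste(rev$query, rev$subject, sep = "\r")
  for (a in names(bh_f)) {
    for (b in bh_f[[a]]) {
      if (a %in% (bh_r[[b]] %||% character())) {
        src <- c(src, a); tgt <- c(tgt, b)
        ef <- c(ef, fwd$evalue[match(paste(a, b, sep = "\r"), fkey)])
        er <- c(er, rev$evalue[match(paste(b, a, sep = "\r"), rkey)])
      }
    }
  }
  df <- data.frame(source_protein = src, target_protein = tgt,
                   e_forward = ef, e_reverse = er,
                   p_value = (ef + er) / 2, stringsAsFactors = FALSE)
  df <- df[order(df$source_protein, df$target_protein), , drop = FALSE]
  rownames(df) <- NULL
  multi <- names(which(table(df$target_protein) > 1L))
  df$tie_group <- ifelse(df$target_protein %in% multi, df$target_protein,
                         NA_character_)
  structure(df, class = c("ortholog_pairs", "data.frame"))
}

# ---- built-in all-vs-all aligner ----------------------------------------

get_score_matrix <- function(name) {
  if (is.null(pgdbprop_env$matrices)) pgdbprop_env$matrices <- list()
  if (is.null(pgdbprop_env$matrices[[name]])) {
    e <- new.env()
    data(list = name, package = "Biostrings", envir = e)
    pgdbprop_env$matrices[[name]] <- get(name, envir = e)
  }
  pgdbprop_env$matrices[[name]]
}

shared_kmer_count <- function(qkmers, skmers) {
  length(intersect(qkmers, skmers))
}

seq_kmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
}

#' All-vs-all local alignment scored as E-values
#'
#' Desk-scale substitute for an external similarity search: Smith-Waterman
#' local alignment (BLOSUM matrix, affine gaps) with raw scores converted to
#' E-values through the Karlin-Altschul form `E = K * m * n * exp(-lambda *
#' S)`, where `m` is the query length and `n` the summed subject-set length.
#' Parity with an external search engine's E-values is not promised -- only
#' rank behavior within each query; externally supplied tabular hits are the
#' fidelity path. A shared-4-mer seed prefilter skips subject sequences that
#' could not reach the reporting ceiling anyway (sequences shorter than 8
#' residues bypass the prefilter). Output is deterministic and invariant
#' under input order.
#'
#' @param proteome_query,proteome_db Named character vectors of amino-acid
#'   sequences (or anything [Biostrings::AAStringSet()] accepts).
#' @param config A [prop_config()]; uses `matrix`, `gap_open`, `gap_ext`,
#'   `karlin_k`, `karlin_lambda`, `min_seed_kmers`.
#' @param direction Direction label stored on the returned table.
#' @return A `hit_table` with one row per aligned (query, subject) pair.
#' @export
align_all_vs_all <- function(proteome_query, proteome_db,
                             config = prop_config(),
                             direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  q <- toupper(as.character(proteome_query))
  s <- toupper(as.character(proteome_db))
  names(q) <- names(proteome_query); names(s) <- names(proteome_db)
  if (!length(q) || !length(s)) stop("proteomes must be non-empty", call. = FALSE)
  bad <- c(names(q)[!grepl(AA_ALPHABET_RE, q)], names(s)[!grepl(AA_ALPHABET_RE, s)])
  if (length(bad))
    stop("illegal sequence characters in record(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  q <- q[order(names(q))]; s <- s[order(names(s))]
  mat <- get_score_matrix(config$matrix)
  K <- config$karlin_k; lambda <- config$karlin_lambda
  n_total <- sum(nchar(s))

  # seed prefilter, then one batched elementwise alignment call
  skmers <- lapply(s, seq_kmers)
  qi <- integer(0); si <- integer(0)
  for (i in seq_along(q)) {
    qk <- seq_kmers(q[[i]])
    cand <- if (nchar(q[[i]]) < 8L) seq_along(s) else
      which(vapply(skmers, shared_kmer_count, integer(1), qkmers = qk) >=
              config$min_seed_kmers | nchar(s) < 8L)
    qi <- c(qi, rep.int(i, length(cand))); si <- c(si, cand)
  }
  if (length(qi)) {
    scores <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(s[si]),
      subject = Biostrings::AAStringSet(q[qi]),
      type = "local", substitutionMatrix = mat,
      gapOpening = config$gap_open, gapExtension = config$gap_ext,
      scoreOnly = TRUE)
    ev <- K * nchar(q[qi]) * n_total * exp(-lambda * scores)
    df <- data.frame(query = names(q)[qi], subject = names(s)[si],
                     evalue = unname(ev), bitscore = (lambda * scores - log(K)) / log(2),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(query = character(), subject = character(),
                     evalue = numeric(), bitscore = numeric())
  }
  hit_table(df$query, df$subject, df$evalue, df$bitscore,
            direction = direction)
}
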