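# In-code fixtures: compact builders for small hand-crafted genome databases.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

rand_aa <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")

# Build a PGDB from compact per-gene specs. Each gene spec is a list with:
#   id; seq (NULL => RNA gene); name; syn; pname; psyn;
#   go = list(c(term, code) or c(term, code, with_ref)); rx; ev (protein
#   evidence); gev (gene evidence); strand.
fixture_db <- function(id, genes, topology = "linear", complexes = list(),
                       reactions = character(), replicon = "chr1") {
  gene_recs <- list(); prot_recs <- list(); pos <- 1L
  order_ids <- vapply(genes, function(g) g$id, character(1))
  for (g in genes) {
    pid <- if (!is.null(g$seq)) paste0("p-", g$id)
    w <- if (!is.null(g$seq)) nchar(g$seq) * 3L else 90L
    gene_recs[[g$id]] <- gene_record(
      g$id, replicon, pos, pos + w - 1L, strand = g$strand %||% "+",
      name = g$name, synonyms = g$syn %||% character(),
      product = pid, evidence = g$gev %||% character())
    if (!is.null(pid)) {
      go <- lapply(g$go %||% list(), function(a)
        go_annotation(a[[1]], a[[2]], if (length(a) > 2) a[[3]]))
      prot_recs[[pid]] <- protein_record(
        pid, g$id, g$seq, name = g$pname, synonyms = g$psyn %||% character(),
        go_annotations = go, reactions = g$rx %||% character(),
        evidence = g$ev %||% character())
    }
    pos <- pos + w + 10L
  }
  rxn_ids <- unique(c(reactions,
                      unlist(lapply(genes, function(g) g$rx)),
                      unlist(lapply(complexes, function(cx) cx$reactions))))
  cx_recs <- lapply(complexes, function(cx)
    complex_record(cx$id, cx$components, name = cx$name,
                   reactions = cx$reactions %||% character(),
                   evidence = cx$ev %||% character()))
  new_pgdb(id,
           replicons = list(replicon_record(replicon, topology, order_ids)),
           genes = gene_recs, proteins = prot_recs, complexes = cx_recs,
           reactions = lapply(rxn_ids, reaction_record))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pgdb_json_string <- function(db) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_pgdb(db, f)
  paste(readLines(f), collapse = "\n")
}

# hand-built ortholog pair table (no alignment involved)
pairs_of <- function(...) {
  rows <- list(...)
  df <- data.frame(
    source_protein = vapply(rows, `[[`, character(1), 1L),
    target_protein = vapply(rows, `[[`, character(1), 2L),
    stringsAsFactors = FALSE)
  df$e_forward <- vapply(rows, function(r)
    if (length(r) > 2) as.numeric(r[[3]]) else 1e-50, numeric(1))
  df$e_reverse <- vapply(rows, function(r)
    if (length(r) > 3) as.numeric(r[[4]]) else 1e-50, numeric(1))
  df$p_value <- (df$e_forward + df$e_reverse) / 2
  df$tie_group <- NA_character_
  structure(df, class = c("ortholog_pairs", "data.frame"))
}
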