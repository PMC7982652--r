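# Domain model for annotated genome databases ("PGDB-lite") and its JSON /
# FASTA readers and writers.

AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"
GO_TERM_RE <- "^GO:[0-9]{7}$"

#' Construct a replicon record
#'
#' A replicon (chromosome or plasmid) holds the ordered list of its genes,
#' which defines gene adjacency for the synteny test. `gene_order` is ordered
#' by start coordinate (ties broken by end, then id); adjacency is always
#' taken from this list, never recomputed from raw coordinates, so
#' overlapping genes still have a defined order.
#'
#' @param id Replicon identifier.
#' @param topology `"circular"` (adjacency wraps around) or `"linear"`.
#' @param gene_order Character vector of gene ids in coordinate order.
#' @return A list of class `pgdb_replicon`.
#' @export
replicon_record <- function(id, topology = c("circular", "linear"),
                            gene_order = character()) {
  topology <- match.arg(topology)
  structure(list(id = as.character(id), topology = topology,
                 gene_order = as.character(gene_order)),
            class = "pgdb_replicon")
}

#' Construct a gene record
#'
#' Coordinates are 1-based inclusive (GenBank convention). RNA genes simply
#' have no `product`. The primary `name` is kept out of `synonyms`.
#'
#' @param id Gene identifier.
#' @param replicon Id of the replicon carrying the gene.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param name Primary gene name, or `NULL` if unnamed.
#' @param synonyms Character vector of alternative names.
#' @param product Protein id of the gene product, or `NULL` for RNA genes.
#' @param evidence Evidence codes attached directly to the gene.
#' @return A list of class `pgdb_gene`.
#' @export
gene_record <- function(id, replicon, start, end, strand = "+", name = NULL,
                        synonyms = character(), product = NULL,
                        evidence = character()) {
  name <- opt_chr(name)
  structure(list(id = as.character(id), name = name,
                 synonyms = setdiff(chr_set(synonyms), name),
                 replicon = as.character(replicon),
                 start = as.integer(start), end = as.integer(end),
                 strand = as.character(strand),
                 product = opt_chr(product),
                 evidence = chr_set(evidence)),
            class = "pgdb_gene")
}

#' Construct a protein record
#'
#' @param id Protein identifier.
#' @param gene Id of the encoding gene.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus X.
#' @param name Product function name, or `NULL`.
#' @param synonyms Alternative product names.
#' @param go_annotations List of [go_annotation()] records.
#' @param reactions Character vector of reaction ids catalyzed/assigned.
#' @param evidence Evidence codes attached directly to the protein.
#' @return A list of class `pgdb_protein`.
#' @export
protein_record <- function(id, gene, sequence, name = NULL,
                           synonyms = character(), go_annotations = list(),
                           reactions = character(), evidence = character()) {
  name <- opt_chr(name)
  structure(list(id = as.character(id), gene = as.character(gene),
                 sequence = toupper(as.character(sequence)),
                 name = name,
                 synonyms = setdiff(chr_set(synonyms), name),
                 go_annotations = unname(go_annotations),
                 reactions = chr_set(reactions),
                 evidence = chr_set(evidence)),
            class = "pgdb_protein")
}

#' Construct a GO annotation
#'
#' @param term GO identifier matching `GO:\\d{7}`.
#' @param evidence_code GO evidence code string (e.g. IDA, IMP, ISO, IEA).
#' @param with_ref Identifier of the supporting object (for ISO annotations,
#'   the source ortholog protein id), or `NULL`.
#' @return A list of class `pgdb_go_annotation`.
#' @export
go_annotation <- function(term, evidence_code, with_ref = NULL) {
  structure(list(term = as.character(term),
                 evidence_code = as.character(evidence_code),
                 with_ref = opt_chr(with_ref)),
            class = "pgdb_go_annotation")
}

#' Construct a protein complex record
#'
#' Components are a stoichiometric multiset referencing proteins, other
#' complexes (sub-complexes), or genes without a protein product (RNA
#' components). Whether the complex is heteromultimeric (>= 2 distinct
#' flattened component species) and whether it contains RNA are derived,
#' never stored authoritatively; see [complex_is_heteromultimeric()].
#'
#' @param id Complex identifier.
#' @param components Named numeric vector: component id -> stoichiometric
#'   coefficient (>= 1).
#' @param name Optional complex name.
#' @param reactions Reaction ids assigned to the complex.
#' @param evidence Evidence codes attached to the complex.
#' @return A list of class `pgdb_complex`.
#' @export
complex_record <- function(id, components, name = NULL,
                           reactions = character(), evidence = character()) {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("complex components must be a named numeric vector (id -> coefficient)")
  comp <- setNames(as.integer(components), names(components))
  comp <- comp[order(names(comp))]
  structure(list(id = as.character(id), name = opt_chr(name),
                 components = comp, reactions = chr_set(reactions),
                 evidence = chr_set(evidence)),
            class = "pgdb_complex")
}

#' Construct a reaction record
#' @param id Reaction identifier (unique within the PGDB).
#' @param ec_number Optional EC number string.
#' @param name Optional reaction name.
#' @return A list of class `pgdb_reaction`.
#' @export
reaction_record <- function(id, ec_number = NULL, name = NULL) {
  structure(list(id = as.character(id), ec_number = opt_chr(ec_number),
                 name = opt_chr(name)),
            class = "pgdb_reaction")
}

named_by_id <- function(records) {
  if (length(records) == 0L) return(structure(list(), names = character()))
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    abort_validation(paste0("duplicate record ids: ",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                     ids = unique(ids[duplicated(ids)]))
  records <- setNames(records, ids)
  records[order(ids)]
}

#' Assemble a PGDB
#'
#' Builds a fully cross-linked annotated genome database and (by default)
#' validates all structural invariants: resolvable cross-references, one gene
#' per protein, coordinate sanity, gene-order completeness, sequence
#' alphabet, GO term syntax, and acyclic complex composition.
#'
#' @param id Database identifier.
#' @param replicons,genes,proteins,complexes,reactions Lists of the
#'   corresponding record types (see [gene_record()] and friends).
#' @param provenance Named list of free-form provenance metadata (strings).
#' @param propagation_records List of propagation history records attached by
#'   [run_propagation()].
#' @param validate Run [validate_pgdb()] before returning (default `TRUE`).
#' @return A list of class `pgdb`; collections are named by record id and
#'   kept sorted by id so serialization is canonical.
#' @export
new_pgdb <- function(id, replicons = list(), genes = list(), proteins = list(),
                     complexes = list(), reactions = list(),
                     provenance = list(), propagation_records = list(),
                     validate = TRUE) {
  db <- structure(list(id = as.character(id),
                       provenance = provenance,
                       replicons = named_by_id(replicons),
                       genes = named_by_id(genes),
                       proteins = named_by_id(proteins),
                       complexes = named_by_id(complexes),
                       reactions = named_by_id(reactions),
                       propagation_records = unname(propagation_records)),
                  class = "pgdb")
  if (validate) validate_pgdb(db)
  db
}

#' @export
print.pgdb <- function(x, ...) {
  cat(sprintf("PGDB '%s': %d replicon(s), %d genes, %d proteins, %d complexes, %d reactions\n",
              x$id, length(x$replicons), length(x$genes), length(x$proteins),
              length(x$complexes), length(x$reactions)))
  if (length(x$propagation_records))
    cat(sprintf("  %d propagation record(s)\n", length(x$propagation_records)))
  invisible(x)
}

# ---- complex structure helpers -------------------------------------------

flatten_complex_components <- function(db, complex_id, seen = character()) {
  if (complex_id %in% seen)
    abort_validation(paste0("cyclic complex composition involving '", complex_id, "'"),
                     ids = complex_id)
  cx <- db$complexes[[complex_id]]
  out <- numeric(0)
  for (ref in names(cx$components)) {
    coef <- cx$components[[ref]]
    if (!is.null(db$complexes[[ref]])) {
      sub <- flatten_complex_components(db, ref, c(seen, complex_id))
      sub <- sub * coef
      for (sid in names(sub)) out[sid] <- (out[sid] %||% 0) + sub[[sid]]
      out[is.na(out)] <- 0
    } else {
      cur <- if (ref %in% names(out)) out[[ref]] else 0
      out[ref] <- cur + coef
    }
  }
  out
}

#' Complex classification helpers
#'
#' `complex_is_heteromultimeric()` is true when the flattened component
#' multiset has at least two distinct species; `complex_contains_rna()` is
#' true when any flattened component references a gene with no protein
#' product (an RNA component). `complexes_containing()` lists the complexes
#' whose flattened components include the given protein.
#'
#' @param db A `pgdb`.
#' @param complex_id Complex identifier.
#' @return Logical scalar.
#' @export
complex_is_heteromultimeric <- function(db, complex_id) {
  length(names(flatten_complex_components(db, complex_id))) >= 2L
}

#' @rdname complex_is_heteromultimeric
#' @export
complex_contains_rna <- function(db, complex_id) {
  refs <- names(flatten_complex_components(db, complex_id))
  any(vapply(refs, function(r) {
    is.null(db$proteins[[r]]) && !is.null(db$genes[[r]]) &&
      is.null(db$genes[[r]]$product)
  }, logical(1)))
}

#' @rdname complex_is_heteromultimeric
#' @param protein_id Protein identifier.
#' @export
complexes_containing <- function(db, protein_id) {
  hits <- vapply(names(db$complexes), function(cid) {
    protein_id %in% names(flatten_complex_components(db, cid))
  }, logical(1))
  names(db$complexes)[hits]
}

# ---- validation ----------------------------------------------------------

#' Validate a PGDB's structural invariants
#'
#' Raises a condition of class `pgdb_validation_error` naming the offending
#' record(s) on the first violated invariant; returns the database invisibly
#' when everything checks out.
#'
#' @param db A `pgdb`.
#' @return `db`, invisibly.
#' @export
validate_pgdb <- function(db) {
  genes <- db$genes; proteins <- db$proteins

  for (r in db$replicons) {
    if (anyDuplicated(r$gene_order))
      abort_validation(paste0("replicon '", r$id, "' lists a gene more than once"),
                       ids = r$id)
    missing <- setdiff(r$gene_order, names(genes))
    if (length(missing))
      abort_validation(paste0("replicon '", r$id, "' orders unknown gene(s): ",
                              paste(missing, collapse = ", ")), ids = missing)
    for (gid in r$gene_order)
      if (!identical(genes[[gid]]$replicon, r$id))
        abort_validation(paste0("gene '", gid, "' is ordered on replicon '", r$id,
                                "' but references replicon '",
                                genes[[gid]]$replicon, "'"), ids = gid)
  }

  for (g in genes) {
    if (is.null(db$replicons[[g$replicon]]))
      abort_validation(paste0("gene '", g$id, "' references missing replicon '",
                              g$replicon, "'"), ids = g$id)
    if (!g$id %in% db$replicons[[g$replicon]]$gene_order)
      abort_validation(paste0("gene '", g$id, "' absent from gene_order of replicon '",
                              g$replicon, "'"), ids = g$id)
    if (is.na(g$start) || is.na(g$end) || g$start > g$end)
      abort_validation(paste0("gene '", g$id, "' has start > end"), ids = g$id)
    if (!g$strand %in% c("+", "-"))
      abort_validation(paste0("gene '", g$id, "' has invalid strand"), ids = g$id)
    if (!is.null(g$name) && g$name %in% g$synonyms)
      abort_validation(paste0("gene '", g$id, "' repeats its name in synonyms"),
                       ids = g$id)
    if (!is.null(g$product)) {
      p <- proteins[[g$product]]
      if (is.null(p))
        abort_validation(paste0("gene '", g$id, "' references missing protein '",
                                g$product, "'"), ids = g$id)
      if (!identical(p$gene, g$id))
        abort_validation(paste0("protein '", p$id, "' and gene '", g$id,
                                "' disagree on their link"), ids = c(g$id, p$id))
    }
  }

  for (p in proteins) {
    g <- genes[[p$gene]]
    if (is.null(g))
      abort_validation(paste0("protein '", p$id, "' references missing gene '",
                              p$gene, "'"), ids = p$id)
    if (!identical(g$product, p$id))
      abort_validation(paste0("protein '", p$id, "' is not the product of its gene '",
                              p$gene, "'"), ids = p$id)
    if (!nzchar(p$sequence) || !grepl(AA_ALPHABET_RE, p$sequence))
      abort_validation(paste0("protein '", p$id,
                              "' has an empty or non-amino-acid sequence"),
                       ids = p$id)
    if (!is.null(p$name) && p$name %in% p$synonyms)
      abort_validation(paste0("protein '", p$id, "' repeats its name in synonyms"),
                       ids = p$id)
    for (ann in p$go_annotations)
      if (!grepl(GO_TERM_RE, ann$term))
        abort_validation(paste0("protein '", p$id, "' has malformed GO term '",
                                ann$term, "'"), ids = p$id)
    missing_rxn <- setdiff(p$reactions, names(db$reactions))
    if (length(missing_rxn))
      abort_validation(paste0("protein '", p$id, "' references missing reaction(s): ",
                              paste(missing_rxn, collapse = ", ")), ids = p$id)
  }

  for (cx in db$complexes) {
    for (ref in names(cx$components)) {
      known <- !is.null(proteins[[ref]]) || !is.null(db$complexes[[ref]]) ||
        !is.null(genes[[ref]])
      if (!known)
        abort_validation(paste0("complex '", cx$id,
                                "' references unknown component '", ref, "'"),
                         ids = cx$id)
      if (is.null(proteins[[ref]]) && is.null(db$complexes[[ref]]) &&
          !is.null(genes[[ref]]$product))
        abort_validation(paste0("complex '", cx$id, "' references gene '", ref,
                                "' that has a protein product; use the protein id"),
                         ids = cx$id)
    }
    if (any(cx$components < 1))
      abort_validation(paste0("complex '", cx$id, "' has non-positive stoichiometry"),
                       ids = cx$id)
    flatten_complex_components(db, cx$id)  # raises on cycles
    missing_rxn <- setdiff(cx$reactions, names(db$reactions))
    if (length(missing_rxn))
      abort_validation(paste0("complex '", cx$id, "' references missing reaction(s): ",
                              paste(missing_rxn, collapse = ", ")), ids = cx$id)
  }

  for (rec in db$propagation_records)
    if (is.null(genes[[rec$target_gene]]))
      abort_validation(paste0("propagation record targets missing gene '",
                              rec$target_gene, "'"), ids = rec$target_gene)

  invisible(db)
}

# ---- accessors -----------------------------------------------------------

#' Proteome accessors
#'
#' `protein_coding_genes()` lists gene ids with a protein product;
#' `proteome_sequences()` returns the named amino-acid sequence vector of
#' all proteins.
#'
#' @param db A `pgdb`.
#' @return Character vector.
#' @export
protein_coding_genes <- function(db) {
  ids <- names(db$genes)
  ids[vapply(db$genes, function(g) !is.null(g$product), logical(1))]
}

#' @rdname protein_coding_genes
#' @export
proteome_sequences <- function(db) {
  vapply(db$proteins, function(p) p$sequence, character(1))
}

# ---- PGDB-lite JSON I/O --------------------------------------------------

replicon_to_json <- function(r) {
  list(id = j_str(r$id), topology = j_str(r$topology),
       gene_order = as.character(r$gene_order))
}

gene_to_json <- function(r) {
  drop_null(list(
    id = j_str(r$id),
    name = if (!is.null(r$name)) j_str(r$name),
    synonyms = if (length(r$synonyms)) r$synonyms,
    replicon = j_str(r$replicon),
    start = j_int(r$start), end = j_int(r$end), strand = j_str(r$strand),
    product = if (!is.null(r$product)) j_str(r$product),
    evidence = if (length(r$evidence)) r$evidence,
    propagated_from = if (!is.null(r$propagated_from)) j_str(r$propagated_from)))
}

protein_to_json <- function(r) {
  drop_null(list(
    id = j_str(r$id), gene = j_str(r$gene), sequence = j_str(r$sequence),
    name = if (!is.null(r$name)) j_str(r$name),
    synonyms = if (length(r$synonyms)) r$synonyms,
    go_annotations = if (length(r$go_annotations))
      lapply(r$go_annotations, function(a) drop_null(list(
        term = j_str(a$term), evidence_code = j_str(a$evidence_code),
        with_ref = if (!is.null(a$with_ref)) j_str(a$with_ref)))),
    reactions = if (length(r$reactions)) r$reactions,
    evidence = if (length(r$evidence)) r$evidence))
}

complex_to_json <- function(r) {
  drop_null(list(
    id = j_str(r$id),
    name = if (!is.null(r$name)) j_str(r$name),
    components = lapply(names(r$components), function(ref)
      list(ref = j_str(ref), coefficient = j_int(r$components[[ref]]))),
    reactions = if (length(r$reactions)) r$reactions,
    evidence = if (length(r$evidence)) r$evidence))
}

reaction_to_json <- function(r) {
  drop_null(list(
    id = j_str(r$id),
    ec_number = if (!is.null(r$ec_number)) j_str(r$ec_number),
    name = if (!is.null(r$name)) j_str(r$name)))
}

PROP_SET_FIELDS <- c("gene_synonyms", "product_synonyms", "go_terms",
                     "reactions", "complex_membership")

prop_record_to_json <- function(rec) {
  priors <- lapply(rec$changed_fields, function(f) {
    v <- rec$prior_values[[f]]
    if (f %in% PROP_SET_FIELDS) as.character(v %||% character())
    else j_str(v %||% "")
  })
  names(priors) <- rec$changed_fields
  list(target_gene = j_str(rec$target_gene),
       source_gene = j_str(rec$source_gene),
       changed_fields = as.character(rec$changed_fields),
       prior_values = priors,
       timestamp = j_str(rec$timestamp))
}

pgdb_to_json <- function(db) {
  # derived complex booleans are written for readers but recomputed on read
  drop_null(list(
    id = j_str(db$id),
    provenance = if (length(db$provenance))
      lapply(db$provenance, function(v) jsonlite::unbox(v)),
    replicons = lapply(unname(db$replicons), replicon_to_json),
    genes = lapply(unname(db$genes), gene_to_json),
    proteins = lapply(unname(db$proteins), protein_to_json),
    complexes = if (length(db$complexes))
      lapply(unname(db$complexes), function(cx) {
        out <- complex_to_json(cx)
        out$heteromultimeric <- j_bool(complex_is_heteromultimeric(db, cx$id))
        out$contains_rna <- j_bool(complex_contains_rna(db, cx$id))
        out
      }),
    reactions = if (length(db$reactions))
      lapply(unname(db$reactions), reaction_to_json),
    propagation_records = if (length(db$propagation_records))
      lapply(db$propagation_records, prop_record_to_json)))
}

#' Write a PGDB to PGDB-lite JSON
#'
#' Serialization is canonical: collections sorted by id, fixed key order,
#' empty optional fields omitted (never `null`), full numeric precision.
#' Writing the same database twice yields byte-identical files.
#'
#' @param db A valid `pgdb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgdb <- function(db, path) {
  validate_pgdb(db)
  write_json_file(pgdb_to_json(db), path)
  invisible(path)
}

lchr <- function(x) if (is.null(x)) character() else unlist(x, use.names = FALSE)

#' Read a PGDB from PGDB-lite JSON
#'
#' @param path Path to a PGDB-lite JSON file (see the schema shipped at
#'   `system.file("extdata", "pgdb-lite-schema.json", package = "pgdbprop")`).
#' @return A validated `pgdb`. Malformed JSON raises a parse error; dangling
#'   references and other invariant violations raise a
#'   `pgdb_validation_error` naming the offending record ids.
#' @export
read_pgdb <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(errorCondition(
                      paste0("malformed PGDB-lite JSON in '", path, "': ",
                             conditionMessage(e)),
                      class = c("pgdb_parse_error", "error", "condition"))))
  pgdb_from_list(raw)
}

pgdb_from_list <- function(raw) {
  replicons <- lapply(raw$replicons %||% list(), function(r)
    replicon_record(r$id, r$topology %||% "linear", lchr(r$gene_order)))
  genes <- lapply(raw$genes %||% list(), function(g) {
    rec <- gene_record(g$id, g$replicon, g$start, g$end, g$strand %||% "+",
                       name = g$name, synonyms = lchr(g$synonyms),
                       product = g$product, evidence = lchr(g$evidence))
    if (!is.null(g$propagated_from))
      rec$propagated_from <- as.character(g$propagated_from)
    rec
  })
  proteins <- lapply(raw$proteins %||% list(), function(p)
    protein_record(p$id, p$gene, p$sequence, name = p$name,
                   synonyms = lchr(p$synonyms),
                   go_annotations = lapply(p$go_annotations %||% list(),
                                           function(a) go_annotation(a$term, a$evidence_code, a$with_ref)),
                   reactions = lchr(p$reactions), evidence = lchr(p$evidence)))
  complexes <- lapply(raw$complexes %||% list(), function(cx) {
    comp <- setNames(vapply(cx$components, function(c) as.numeric(c$coefficient),
                            numeric(1)),
                     vapply(cx$components, function(c) as.character(c$ref),
                            character(1)))
    complex_record(cx$id, comp, name = cx$name, reactions = lchr(cx$reactions),
                   evidence = lchr(cx$evidence))
  })
  reactions <- lapply(raw$reactions %||% list(), function(r)
    reaction_record(r$id, ec_number = r$ec_number, name = r$name))
  records <- lapply(raw$propagation_records %||% list(), function(rec) {
    fields <- lchr(rec$changed_fields)
    priors <- lapply(fields, function(f) {
      v <- rec$prior_values[[f]]
      if (f %in% PROP_SET_FIELDS) lchr(v) else as.character(v %||% "")
    })
    names(priors) <- fields
    list(target_gene = as.character(rec$target_gene),
         source_gene = as.character(rec$source_gene),
         changed_fields = fields, prior_values = priors,
         timestamp = as.character(rec$timestamp %||% ""))
  })
  provenance <- lapply(raw$provenance %||% list(), function(v) v)
  new_pgdb(raw$id %||% "pgdb", replicons = replicons, genes = genes,
           proteins = proteins, complexes = complexes, reactions = reactions,
           provenance = provenance, propagation_records = records)
}

# ---- FASTA ---------------------------------------------------------------

#' Read a proteome FASTA
#'
#' Sequences are uppercased and a single terminal stop (`*`) is stripped.
#' Record ids are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @param db Optional `pgdb`; ids absent from its proteins are collected into
#'   one warning (not fatal).
#' @return Named character vector of sequences. Duplicate ids are an error.
#' @export
read_proteome_fasta <- function(path, db = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- ids
  if (!is.null(db)) {
    unknown <- setdiff(ids, names(db$proteins))
    if (length(unknown))
      warning("FASTA id(s) absent from PGDB '", db$id, "': ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write a PGDB's proteome as FASTA
#' @param db A `pgdb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(db, path) {
  seqs <- proteome_sequences(db)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 70L)
  invisible(path)
}

# ---- evidence codes ------------------------------------------------------

# GO evidence-code inventory, reduced to the classes the filters care
# about: experimental / literature / computational / none-assigned.
# BioCyc-style codes map by prefix. The table is a documented choice,
# overridable via evidence_code_table().
GO_EXPERIMENTAL <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                     "HTP", "HDA", "HMP", "HGI", "HEP")
GO_LITERATURE <- c("TAS", "IC", "NAS")
GO_COMPUTATIONAL <- c("IEA", "ISS", "ISO", "ISA", "ISM", "IGC",
                      "IBA", "IBD", "IKR", "IRD", "RCA")

#' Evidence-code class table and classifier
#'
#' `evidence_code_table()` returns the shipped mapping of evidence codes to
#' classes; `evidence_code_class()` classifies codes, mapping BioCyc-style
#' codes by prefix (`EV-EXP*` experimental, `EV-AS*` literature, `EV-COMP*`
#' computational). Unknown codes are treated as computational and logged once
#' per code per session.
#'
#' @param code Character vector of evidence codes.
#' @param table Optional override table as returned by
#'   `evidence_code_table()` (a named list of character vectors with entries
#'   `experimental`, `literature`, `computational`, `none`).
#' @return For `evidence_code_class()`, a character vector over
#'   `{experimental, literature, computational, none-assigned}`.
#' @export
evidence_code_table <- function() {
  list(experimental = GO_EXPERIMENTAL, literature = GO_LITERATURE,
       computational = GO_COMPUTATIONAL, none = "ND")
}

#' @rdname evidence_code_table
#' @export
evidence_code_class <- function(code, table = evidence_code_table()) {
  vapply(as.character(code), function(cd) {
    if (cd %in% table$experimental) return("experimental")
    if (cd %in% table$literature) return("literature")
    if (cd %in% table$computational) return("computational")
    if (cd %in% table$none) return("none-assigned")
    if (startsWith(cd, "EV-EXP")) return("experimental")
    if (startsWith(cd, "EV-AS")) return("literature")
    if (startsWith(cd, "EV-COMP")) return("computational")
    if (!cd %in% pgdbprop_env$warned_codes) {
      pgdbprop_env$warned_codes <- c(pgdbprop_env$warned_codes, cd)
      message("unknown evidence code '", cd, "' treated as computational")
    }
    "computational"
  }, character(1), USE.NAMES = FALSE)
}

#' Aggregate evidence class of a gene/protein and its associated objects
#'
#' Scans the gene's own evidence codes, its product's, the product's GO
#' annotations, and (optionally) complexes containing the product, and
#' reduces them to one of `"experimental-or-literature"` (any experimental or
#' literature code present), `"computational-only"` (codes present but none
#' experimental/literature), or `"none"` (no codes anywhere). Adding an
#' experimental code can never downgrade the result.
#'
#' @param db A `pgdb`.
#' @param id A gene id or protein id.
#' @param scope Which associated objects to scan; any subset of
#'   `c("gene", "protein", "go")`.
#' @param include_complexes Also scan complexes containing the product.
#' @param table Evidence-code table override (see [evidence_code_table()]).
#' @return One of `"experimental-or-literature"`, `"computational-only"`,
#'   `"none"`.
#' @export
evidence_class <- function(db, id, scope = c("gene", "protein", "go"),
                           include_complexes = FALSE,
                           table = evidence_code_table()) {
  gene <- db$genes[[id]]
  prot <- db$proteins[[id]]
  if (is.null(gene) && is.null(prot))
    stop("'", id, "' is neither a gene nor a protein of PGDB '", db$id, "'",
         call. = FALSE)
  if (is.null(gene) && !is.null(prot)) gene <- db$genes[[prot$gene]]
  if (is.null(prot) && !is.null(gene) && !is.null(gene$product))
    prot <- db$proteins[[gene$product]]

  codes <- character()
  if ("gene" %in% scope && !is.null(gene)) codes <- c(codes, gene$evidence)
  if ("protein" %in% scope && !is.null(prot)) codes <- c(codes, prot$evidence)
  if ("go" %in% scope && !is.null(prot))
    codes <- c(codes, vapply(prot$go_annotations, function(a) a$evidence_code,
                             character(1)))
  if (include_complexes && !is.null(prot))
    for (cid in complexes_containing(db, prot$id))
      codes <- c(codes, db$complexes[[cid]]$evidence)

  if (!length(codes)) return("none")
  cls <- evidence_code_class(codes, table)
  if (any(cls %in% c("experimental", "literature"))) "experimental-or-literature"
  else "computational-only"
}
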