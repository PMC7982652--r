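# Attribute propagation from a resolved source protein/gene to its target
# ortholog: names, GO terms (ISO), reaction assignments (replacement
# semantics), heteromultimeric complexes, with change detection and
# history-note provenance.

PROPAGATED_FIELDS <- c("gene_name", "gene_synonyms", "product_name",
                       "product_synonyms", "go_terms", "reactions",
                       "complex_membership")

new_change_set <- function() list(changed = character(), priors = list())

note_change <- function(ch, field, prior) {
  ch$changed <- union(ch$changed, field)
  ch$priors[[field]] <- prior
  ch
}

# merge a name + synonyms pair from source onto target; the target's prior
# primary name (if displaced) is demoted to a synonym, never discarded
merge_names <- function(t_name, t_syn, s_name, s_syn) {
  new_name <- t_name
  if (!is.null(s_name)) new_name <- s_name
  new_syn <- chr_set(c(t_syn, s_syn))
  if (!is.null(t_name) && !identical(t_name, new_name))
    new_syn <- chr_set(c(new_syn, t_name))
  if (!is.null(new_name)) new_syn <- setdiff(new_syn, new_name)
  list(name = new_name, synonyms = new_syn)
}

#' Propagate gene and product names and synonyms
#'
#' The target gene takes the source gene's primary name; the target's prior
#' name, if different, is demoted to a synonym, and the source's synonyms
#' are unioned into the target's. The same scheme applies to the product
#' function name. A primary name is never duplicated among the synonyms,
#' and an absent source name never blanks an existing target name. Changes
#' are recorded only when a value actually differs.
#'
#' @param target_db Target `pgdb` (a modified copy is returned).
#' @param source_db Source `pgdb`.
#' @param source_protein,target_protein The resolved pair's protein ids.
#' @return `list(db = updated target, changed = character of field names,
#'   priors = named list of prior values)`.
#' @export
propagate_names <- function(target_db, source_db, source_protein,
                            target_protein) {
  sp <- source_db$proteins[[source_protein]]
  tp <- target_db$proteins[[target_protein]]
  sg <- source_db$genes[[sp$gene]]
  tg <- target_db$genes[[tp$gene]]
  ch <- new_change_set()

  gn <- merge_names(tg$name, tg$synonyms, sg$name, sg$synonyms)
  if (!identical(gn$name, tg$name))
    ch <- note_change(ch, "gene_name", tg$name %||% "")
  if (!set_equal(gn$synonyms, tg$synonyms))
    ch <- note_change(ch, "gene_synonyms", tg$synonyms)
  tg$name <- gn$name; tg$synonyms <- gn$synonyms

  pn <- merge_names(tp$name, tp$synonyms, sp$name, sp$synonyms)
  if (!identical(pn$name, tp$name))
    ch <- note_change(ch, "product_name", tp$name %||% "")
  if (!set_equal(pn$synonyms, tp$synonyms))
    ch <- note_change(ch, "product_synonyms", tp$synonyms)
  tp$name <- pn$name; tp$synonyms <- pn$synonyms

  target_db$genes[[tg$id]] <- tg
  target_db$proteins[[tp$id]] <- tp
  list(db = target_db, changed = ch$changed, priors = ch$priors)
}

#' Propagate GO annotations with ISO evidence
#'
#' Only source GO terms carrying an experimental evidence code are
#' propagated, unless the two protein sequences are identical (exact string
#' equality after normalization), in which case all source terms are
#' propagated. Every propagated term is attached to the target with
#' evidence code `ISO` ("inferred from sequence orthology") and a `with_ref`
#' pointing at the source protein. Terms the target already holds are
#' deduplicated by term id; a change is recorded only if the target's term
#' set actually grew.
#'
#' @inheritParams propagate_names
#' @param table Evidence-code table (see [evidence_code_table()]).
#' @return As [propagate_names()].
#' @export
propagate_go <- function(target_db, source_db, source_protein, target_protein,
                         table = evidence_code_table()) {
  sp <- source_db$proteins[[source_protein]]
  tp <- target_db$proteins[[target_protein]]
  identical_seqs <- identical(sp$sequence, tp$sequence)

  src_terms <- vapply(sp$go_annotations, function(a) a$term, character(1))
  if (!identical_seqs) {
    keep <- vapply(sp$go_annotations, function(a)
      evidence_code_class(a$evidence_code, table) == "experimental", logical(1))
    src_terms <- src_terms[keep]
  }
  src_terms <- unique(src_terms)

  have <- vapply(tp$go_annotations, function(a) a$term, character(1))
  add <- setdiff(src_terms, have)
  ch <- new_change_set()
  if (length(add)) {
    ch <- note_change(ch, "go_terms", sort(have))
    for (term in sort(add))
      tp$go_annotations <- c(tp$go_annotations,
                             list(go_annotation(term, "ISO",
                                                with_ref = source_protein)))
    target_db$proteins[[tp$id]] <- tp
  }
  list(db = target_db, changed = ch$changed, priors = ch$priors)
}

#' Propagate reaction assignments (replacement semantics)
#'
#' The target protein's reaction set becomes exactly the source protein's:
#' new assignments are added *and* spurious prior assignments are removed
#' (union semantics could not express removals such as a wrongly assigned
#' transport reaction). Reactions referenced by the source but absent from
#' the target database are created from the source's reaction records. A
#' change is recorded only if the sets differ.
#'
#' @inheritParams propagate_names
#' @return As [propagate_names()].
#' @export
propagate_reactions <- function(target_db, source_db, source_protein,
                                target_protein) {
  sp <- source_db$proteins[[source_protein]]
  tp <- target_db$proteins[[target_protein]]
  ch <- new_change_set()
  if (!set_equal(sp$reactions, tp$reactions)) {
    ch <- note_change(ch, "reactions", tp$reactions)
    for (rid in setdiff(sp$reactions, names(target_db$reactions)))
      target_db$reactions[[rid]] <- source_db$reactions[[rid]]
    target_db$reactions <- target_db$reactions[order(names(target_db$reactions))]
    tp$reactions <- chr_set(sp$reactions)
    target_db$proteins[[tp$id]] <- tp
  }
  list(db = target_db, changed = ch$changed, priors = ch$priors)
}

map_component <- function(ref, source_db, target_db, source_to_target) {
  if (!is.null(source_db$proteins[[ref]])) return(source_to_target[[ref]] %||% NA_character_)
  NA_character_
}

# find an existing target complex with the same direct-component multiset
find_equivalent_complex <- function(target_db, components) {
  key <- paste(names(components), components, sep = ":", collapse = ";")
  for (cx in target_db$complexes) {
    k <- paste(names(cx$components), cx$components, sep = ":", collapse = ";")
    if (identical(k, key)) return(cx$id)
  }
  NULL
}

#' Propagate heteromultimeric complex membership
#'
#' For every heteromultimeric complex containing the source protein (the
#' complex filter guarantees all protein components have orthologs), the
#' complex is instantiated in the target with components mapped through the
#' ortholog map, preserving stoichiometry, together with the complex's
#' reaction assignments and name. Sub-complex components are instantiated
#' recursively. The operation is idempotent: an existing target complex with
#' the same mapped component multiset is reused, never duplicated.
#'
#' @inheritParams propagate_names
#' @param source_to_target Named character vector mapping source protein ids
#'   to their resolved/most-plausible target ortholog.
#' @return As [propagate_names()].
#' @export
propagate_complexes <- function(target_db, source_db, source_protein,
                                source_to_target) {
  ch <- new_change_set()
  created <- FALSE
  t_protein <- source_to_target[[source_protein]]
  prior_membership <- if (!is.null(t_protein))
    complexes_containing(target_db, t_protein) else character()

  instantiate <- function(cid) {
    cx <- source_db$complexes[[cid]]
    mapped <- integer(0)
    for (ref in names(cx$components)) {
      coef <- cx$components[[ref]]
      if (!is.null(source_db$complexes[[ref]])) {
        sub_id <- instantiate(ref)
        if (is.na(sub_id)) return(NA_character_)
        mapped[sub_id] <- (if (sub_id %in% names(mapped)) mapped[[sub_id]] else 0L) + coef
      } else {
        t_ref <- map_component(ref, source_db, target_db, source_to_target)
        if (is.na(t_ref)) return(NA_character_)  # unmappable (e.g. RNA)
        mapped[t_ref] <- (if (t_ref %in% names(mapped)) mapped[[t_ref]] else 0L) + coef
      }
    }
    mapped <- mapped[order(names(mapped))]
    existing <- find_equivalent_complex(target_db, mapped)
    if (!is.null(existing)) return(existing)
    new_id <- cid
    if (!is.null(target_db$complexes[[new_id]])) new_id <- paste0(cid, "-PROP")
    for (rid in setdiff(cx$reactions, names(target_db$reactions)))
      target_db$reactions[[rid]] <<- source_db$reactions[[rid]]
    target_db$reactions <<- target_db$reactions[order(names(target_db$reactions))]
    target_db$complexes[[new_id]] <<-
      complex_record(new_id, mapped, name = cx$name, reactions = cx$reactions)
    target_db$complexes <<- target_db$complexes[order(names(target_db$complexes))]
    created <<- TRUE
    new_id
  }

  for (cid in complexes_containing(source_db, source_protein)) {
    if (!complex_is_heteromultimeric(source_db, cid)) next
    instantiate(cid)
  }
  if (created)
    ch <- note_change(ch, "complex_membership", prior_membership)
  list(db = target_db, changed = ch$changed, priors = ch$priors)
}

#' Propagate all whitelisted attributes for one resolved pair
#'
#' Applies name, GO, reaction and complex propagation, assembles the
#' propagation record (the history note's data: source gene, fields changed,
#' prior values, timestamp), stores the source gene id on the target gene
#' (`propagated_from`, so a renderer can surface the source's summary), and
#' attaches the record to the target database when any field changed. A
#' record with no changed fields is still returned, flagged as a no-op.
#'
#' @inheritParams propagate_names
#' @param source_to_target Source-to-target ortholog map (see
#'   [propagate_complexes()]).
#' @param config A [prop_config()] (supplies the history-note timestamp).
#' @return `list(db = updated target, record = propagation record, noop =
#'   logical)`.
#' @export
propagate_gene <- function(target_db, source_db, source_protein,
                           target_protein, source_to_target = NULL,
                           config = prop_config()) {
  if (is.null(source_to_target))
    source_to_target <- setNames(target_protein, source_protein)
  sp <- source_db$proteins[[source_protein]]
  tp <- target_db$proteins[[target_protein]]

  changed <- character(); priors <- list()
  step <- function(res) {
    target_db <<- res$db
    changed <<- union(changed, res$changed)
    priors[res$changed] <<- res$priors[res$changed]
  }
  step(propagate_names(target_db, source_db, source_protein, target_protein))
  step(propagate_go(target_db, source_db, source_protein, target_protein))
  step(propagate_reactions(target_db, source_db, source_protein, target_protein))
  step(propagate_complexes(target_db, source_db, source_protein,
                           source_to_target))

  tg <- target_db$genes[[tp$gene]]
  tg$propagated_from <- sp$gene
  target_db$genes[[tg$id]] <- tg

  changed <- intersect(PROPAGATED_FIELDS, changed)  # canonical order
  record <- list(target_gene = tp$gene, source_gene = sp$gene,
                 changed_fields = changed, prior_values = priors[changed],
                 timestamp = config$timestamp)
  if (length(changed))
    target_db$propagation_records <- c(target_db$propagation_records,
                                       list(record))
  list(db = target_db, record = record, noop = !length(changed))
}

#' Format a propagation record as a human-readable history note
#'
#' @param record A propagation record (element of
#'   `pgdb$propagation_records`).
#' @return A single string.
#' @export
format_history_note <- function(record) {
  fields <- if (length(record$changed_fields)) {
    parts <- vapply(record$changed_fields, function(f) {
      prior <- record$prior_values[[f]]
      prior <- if (length(prior)) paste(prior, collapse = ", ") else "(none)"
      sprintf("%s (was: %s)", f, prior)
    }, character(1))
    paste(parts, collapse = "; ")
  } else "no fields (no-op)"
  sprintf("[%s] Data propagated from ortholog %s: %s.",
          record$timestamp, record$source_gene, fields)
}

#' Run ortholog-based propagation of a whole database pair
#'
#' Orchestrates the full method over every protein-coding gene of the
#' target: ortholog mapping (built-in aligner or supplied hit tables),
#' candidate resolution by synteny then gene name, the five quality
#' filters, and attribute propagation with provenance. The source database
#' is never modified; the returned target is a mutated copy carrying all
#' propagation records. Gene and protein counts of the target are unchanged
#' (only attributes, reactions and complexes change), and re-running on the
#' output is a no-op.
#'
#' @param source_db,target_db Validated `pgdb`s (the run aborts before any
#'   mutation otherwise).
#' @param config A [prop_config()].
#' @param hits Optional `list(fwd = , rev = )` of `hit_table`s (e.g. from
#'   [load_tabular_hits()]); when omitted, the built-in aligner computes
#'   both directions.
#' @return A list of class `propagation_run`: `target` (updated `pgdb`),
#'   `report` (a `run_report`), `pairs` (the `ortholog_pairs` table),
#'   `decisions` (per-gene decision data frame) and `config`.
#' @export
run_propagation <- function(source_db, target_db, config = prop_config(),
                            hits = NULL) {
  validate_pgdb(source_db)
  validate_pgdb(target_db)

  if (is.null(hits)) {
    src_seqs <- proteome_sequences(source_db)
    tgt_seqs <- proteome_sequences(target_db)
    hits <- list(
      fwd = align_all_vs_all(src_seqs, tgt_seqs, config, "forward"),
      rev = align_all_vs_all(tgt_seqs, src_seqs, config, "reverse"))
  }
  pairs <- bidirectional_orthologs(hits$fwd, hits$rev, config$evalue_cutoff)

  # resolve every target protein-coding gene (RNA genes are never candidates)
  t_genes <- sort(protein_coding_genes(target_db))
  resolutions <- list()
  for (gid in t_genes) {
    pid <- target_db$genes[[gid]]$product
    cand <- pairs[pairs$target_protein == pid, , drop = FALSE]
    resolutions[[gid]] <- if (nrow(cand) == 0L) NULL
    else resolve_ortholog(source_db, target_db, pid, cand, pairs)
  }

  # source -> target ortholog map for complex instantiation: prefer targets
  # that resolved to the source; fall back to the lexicographically first
  # paired target for components that were not themselves resolved
  source_to_target <- list()
  for (res in drop_null(resolutions))
    if (!is.na(res$chosen)) source_to_target[[res$chosen]] <- res$target_protein
  for (spid in sort(unique(pairs$source_protein)))
    if (is.null(source_to_target[[spid]]))
      source_to_target[[spid]] <-
        min(pairs$target_protein[pairs$source_protein == spid])

  decisions <- list(); verdicts <- list(); records <- list()
  for (gid in t_genes) {
    pid <- target_db$genes[[gid]]$product
    res <- resolutions[[gid]]
    if (is.null(res)) {
      decisions[[gid]] <- list(gene = gid, status = "rejected",
                               reason = "no-ortholog",
                               failed = character(), source_gene = NA_character_,
                               resolution = NA_character_)
      next
    }
    if (res$resolution == "rejected") {
      decisions[[gid]] <- list(gene = gid, status = "rejected",
                               reason = "ambiguous-ortholog",
                               failed = character(), source_gene = NA_character_,
                               resolution = "rejected")
      next
    }
    spid <- res$chosen
    prow <- pairs[pairs$source_protein == spid & pairs$target_protein == pid, ]
    verdict <- evaluate_filters(source_db, target_db, spid, pid,
                                prow$p_value[1L], pairs, config)
    verdicts[[gid]] <- verdict
    s_gene <- source_db$proteins[[spid]]$gene
    if (verdict$passed_all) {
      out <- propagate_gene(target_db, source_db, spid, pid,
                            source_to_target, config)
      target_db <- out$db
      records[[gid]] <- out$record
      decisions[[gid]] <- list(gene = gid, status = "propagated",
                               reason = NA_character_, failed = character(),
                               source_gene = s_gene,
                               resolution = res$resolution)
    } else {
      failed <- names(verdict$results)[verdict$results == "fail"]
      decisions[[gid]] <- list(gene = gid, status = "rejected",
                               reason = failure_reason(failed),
                               failed = failed, source_gene = s_gene,
                               resolution = res$resolution)
    }
  }

  report <- build_report(decisions, verdicts, records, target_db, config)
  structure(list(target = target_db, report = report, pairs = pairs,
                 decisions = decisions, config = config),
            class = "propagation_run")
}

# canonical rejection-reason label for a set of failed filters
failure_reason <- function(failed) {
  lab <- c(target_evidence = "target-evidence", source_evidence = "source-evidence",
           p_value = "p-value", length = "length", complex = "complex")
  failed <- sort(unname(lab[failed]))
  if (length(failed) == 1L) failed
  else paste0("multiple:", paste(failed, collapse = "+"))
}
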