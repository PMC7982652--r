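# Resolution of target proteins that map to multiple source orthologs:
# synteny first, then gene name; otherwise the target is rejected.

#' Genes directly adjacent to a gene
#'
#' Immediate predecessor and successor in the replicon's `gene_order`.
#' Circular replicons wrap around; ends of linear replicons yield a single
#' neighbor; a two-gene circular replicon yields the other gene once
#' (deduplicated); strand is ignored. Genes on different replicons are never
#' adjacent.
#'
#' @param db A `pgdb`.
#' @param gene_id Gene identifier.
#' @return Character vector of up to two gene ids.
#' @export
adjacent_genes <- function(db, gene_id) {
  g <- db$genes[[gene_id]]
  if (is.null(g)) stop("gene '", gene_id, "' not found", call. = FALSE)
  rep <- db$replicons[[g$replicon]]
  ord <- rep$gene_order
  i <- match(gene_id, ord)
  if (is.na(i)) stop("gene '", gene_id, "' not in any replicon's gene order",
                     call. = FALSE)
  n <- length(ord)
  if (rep$topology == "circular") {
    nb <- ord[c((i - 2L) %% n + 1L, i %% n + 1L)]
  } else {
    nb <- ord[c(i - 1L, i + 1L)]
    nb <- nb[!is.na(nb)]
  }
  setdiff(unique(nb), gene_id)
}

pair_exists <- function(pairs, source_protein, target_protein) {
  any(pairs$source_protein == source_protein &
        pairs$target_protein == target_protein)
}

#' Local synteny test for an ortholog candidate pair
#'
#' Passes iff the product of either of the two genes directly adjacent to
#' the source gene is an ortholog (member of `pairs`) of the product of
#' either of the two genes directly adjacent to the target gene. Neighbors
#' without protein products (RNA genes) are skipped; strand is ignored.
#'
#' @param source_db,target_db The two `pgdb`s.
#' @param source_gene,target_gene Gene ids with replicon placement.
#' @param pairs An `ortholog_pairs` table from [bidirectional_orthologs()].
#' @return Logical scalar.
#' @export
synteny_pass <- function(source_db, target_db, source_gene, target_gene, pairs) {
  flank_products <- function(db, gid) {
    prods <- vapply(adjacent_genes(db, gid),
                    function(n) db$genes[[n]]$product %||% NA_character_,
                    character(1))
    prods[!is.na(prods)]
  }
  sp <- flank_products(source_db, source_gene)
  tp <- flank_products(target_db, target_gene)
  for (a in sp) for (b in tp) if (pair_exists(pairs, a, b)) return(TRUE)
  FALSE
}

#' Resolve a target protein's source-ortholog candidates
#'
#' A single candidate is accepted outright (`resolution = "unique"`). With
#' several candidates, the synteny test is applied to each: exactly one pass
#' selects that candidate (`"synteny"`); if none pass, candidates whose
#' source gene name equals the target gene's name exactly (case-sensitive,
#' primary names only, synonyms ignored) are considered, and exactly one
#' match selects it (`"gene-name"`). Everything else -- several synteny
#' passes, several or zero name matches, an unnamed target -- rejects the
#' target (`"rejected"`): when no single best source can be determined, no
#' data is propagated at all rather than risking overwriting correct
#' information.
#'
#' The outcome is independent of candidate order, and the chosen source is
#' always among the input candidates.
#'
#' @param source_db,target_db The two `pgdb`s.
#' @param target_protein Target protein id.
#' @param candidate_pairs Subset of `pairs` rows whose `target_protein` is
#'   this protein (>= 1 row).
#' @param pairs Full `ortholog_pairs` table (used by the synteny test).
#' @return A list of class `ortholog_candidate` with elements
#'   `target_protein`, `source_candidates`, `resolution` (one of `"unique"`,
#'   `"synteny"`, `"gene-name"`, `"rejected"`) and `chosen` (source protein
#'   id, or `NA` iff rejected).
#' @export
resolve_ortholog <- function(source_db, target_db, target_protein,
                             candidate_pairs, pairs) {
  cands <- sort(unique(candidate_pairs$source_protein))
  if (!length(cands)) stop("at least one candidate pair required", call. = FALSE)
  t_gene <- target_db$proteins[[target_protein]]$gene

  result <- function(resolution, chosen = NA_character_) {
    structure(list(target_protein = target_protein,
                   source_candidates = cands,
                   resolution = resolution, chosen = chosen),
              class = "ortholog_candidate")
  }

  if (length(cands) == 1L) return(result("unique", cands))

  synt <- vapply(cands, function(sp) {
    synteny_pass(source_db, target_db, source_db$proteins[[sp]]$gene, t_gene,
                 pairs)
  }, logical(1))
  if (sum(synt) == 1L) return(result("synteny", cands[synt]))
  if (sum(synt) == 0L) {
    t_name <- target_db$genes[[t_gene]]$name
    if (!is.null(t_name)) {
      name_match <- vapply(cands, function(sp) {
        s_name <- source_db$genes[[source_db$proteins[[sp]]$gene]]$name
        !is.null(s_name) && identical(s_name, t_name)
      }, logical(1))
      if (sum(name_match) == 1L) return(result("gene-name", cands[name_match]))
    }
  }
  result("rejected")
}
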