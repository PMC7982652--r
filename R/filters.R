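# The five propagation quality filters. All five are always evaluated for a
# resolved (S, T) pair so single- vs multiple-failure statistics are
# computable.

FILTER_NAMES <- c("target_evidence", "source_evidence", "p_value", "length",
                  "complex")

#' Run configuration and thresholds
#'
#' Defaults follow the method's published settings: orthologs require both
#' E-values strictly below `1e-3`; the pair P-value (arithmetic mean of the
#' two E-values) must not exceed `1e-10`; the two sequences must not differ
#' in length by more than 10% (relative to the longer sequence). Both the
#' P-value and length thresholds are configurable.
#'
#' @param evalue_cutoff Strict E-value cutoff for best-hit calls.
#' @param p_value_threshold Inclusive upper bound on the pair P-value.
#' @param length_threshold Inclusive upper bound on relative length
#'   difference `|len_S - len_T| / max(len_S, len_T)`.
#' @param target_evidence_scope Associated objects scanned when testing the
#'   target for prior curation; subset of `c("gene", "protein", "go")`.
#' @param target_scan_complexes Also scan complexes containing the target
#'   product for evidence (off by default; uncurated targets rarely carry
#'   curated complexes).
#' @param matrix Substitution matrix name for the built-in aligner.
#' @param gap_open,gap_ext Affine gap penalties.
#' @param karlin_k,karlin_lambda Karlin-Altschul parameters used to convert
#'   raw local-alignment scores to E-values (defaults are the standard
#'   gapped BLOSUM62/11/1 values).
#' @param min_seed_kmers Shared 4-mers required before a sequence pair is
#'   aligned by the built-in aligner.
#' @param timestamp Timestamp string recorded on history notes; defaults to
#'   the run's UTC date. Pass a fixed value for byte-reproducible outputs.
#' @return A list of class `prop_config`.
#' @export
prop_config <- function(evalue_cutoff = 1e-3,
                        p_value_threshold = 1e-10,
                        length_threshold = 0.10,
                        target_evidence_scope = c("gene", "protein", "go"),
                        target_scan_complexes = FALSE,
                        matrix = "BLOSUM62",
                        gap_open = 11, gap_ext = 1,
                        karlin_k = 0.041, karlin_lambda = 0.267,
                        min_seed_kmers = 2L,
                        timestamp = NULL) {
  stopifnot(evalue_cutoff > 0, p_value_threshold >= 0,
            length_threshold >= 0, length_threshold <= 1)
  structure(list(evalue_cutoff = evalue_cutoff,
                 p_value_threshold = p_value_threshold,
                 length_threshold = length_threshold,
                 target_evidence_scope = target_evidence_scope,
                 target_scan_complexes = target_scan_complexes,
                 matrix = matrix, gap_open = gap_open, gap_ext = gap_ext,
                 karlin_k = karlin_k, karlin_lambda = karlin_lambda,
                 min_seed_kmers = as.integer(min_seed_kmers),
                 timestamp = timestamp %||%
                   format(Sys.Date(), "%Y-%m-%d")),
            class = "prop_config")
}

#' Individual propagation filters
#'
#' `target_evidence_filter()`: passes iff the target gene and its associated
#' objects (per `config$target_evidence_scope`) carry no experimental or
#' literature-based evidence code -- any such code signals prior curation
#' that must not be overwritten.
#'
#' `source_evidence_filter()`: passes iff the source side *does* carry an
#' experimental or literature-based evidence code, so that only first-hand
#' knowledge is propagated and transitive annotation errors are avoided.
#'
#' `p_value_filter()`: the pair P-value (arithmetic mean of the two best-hit
#' E-values) must not exceed the threshold; exactly at the threshold passes.
#'
#' `length_filter()`: the sequences must not differ in length by more than
#' the threshold fraction of the longer sequence; exactly at the threshold
#' passes.
#'
#' `complex_filter()`: if the source protein is a component (directly or
#' through sub-complexes) of a heteromultimeric complex, every other protein
#' component of that complex must have at least one ortholog pair; any RNA
#' component (a gene without a protein product) fails the filter outright,
#' since RNA is excluded from the ortholog computation.
#'
#' All return `"pass"` or `"fail"`.
#'
#' @param target_db,source_db The two `pgdb`s.
#' @param target_protein,source_protein Protein ids.
#' @param config A [prop_config()].
#' @param p_value Pair P-value.
#' @param threshold Filter-specific threshold override.
#' @param len_source,len_target Residue counts.
#' @param pairs An `ortholog_pairs` table.
#' @return `"pass"` or `"fail"`.
#' @export
target_evidence_filter <- function(target_db, target_protein,
                                   config = prop_config()) {
  cls <- evidence_class(target_db, target_protein,
                        scope = config$target_evidence_scope,
                        include_complexes = isTRUE(config$target_scan_complexes))
  if (cls == "experimental-or-literature") "fail" else "pass"
}

#' @rdname target_evidence_filter
#' @export
source_evidence_filter <- function(source_db, source_protein,
                                   config = prop_config()) {
  cls <- evidence_class(source_db, source_protein)
  if (cls == "experimental-or-literature") "pass" else "fail"
}

#' @rdname target_evidence_filter
#' @export
p_value_filter <- function(p_value, threshold = 1e-10) {
  if (p_value > threshold) "fail" else "pass"
}

#' @rdname target_evidence_filter
#' @export
length_filter <- function(len_source, len_target, threshold = 0.10) {
  rel <- abs(len_source - len_target) / max(len_source, len_target)
  if (rel > threshold) "fail" else "pass"
}

#' @rdname target_evidence_filter
#' @export
complex_filter <- function(source_db, source_protein, pairs) {
  for (cid in complexes_containing(source_db, source_protein)) {
    if (!complex_is_heteromultimeric(source_db, cid)) next
    comps <- names(flatten_complex_components(source_db, cid))
    for (ref in comps) {
      if (identical(ref, source_protein)) next
      if (is.null(source_db$proteins[[ref]])) return("fail")  # RNA component
      if (!any(pairs$source_protein == ref)) return("fail")
    }
  }
  "pass"
}

#' Evaluate all five propagation filters for a resolved pair
#'
#' Every filter is computed regardless of earlier failures, so multi-failure
#' statistics remain available. Loosening the P-value or length threshold
#' can never flip a pass to a fail, and each filter's result depends only on
#' its own inputs.
#'
#' @param source_db,target_db The two `pgdb`s.
#' @param source_protein,target_protein The resolved protein pair.
#' @param p_value Pair P-value (mean of the two best-hit E-values).
#' @param pairs Full `ortholog_pairs` table (for the complex filter).
#' @param config A [prop_config()].
#' @return A list of class `filter_verdict`: `pair`, `results` (named
#'   character over the five filters, values `"pass"`/`"fail"`) and
#'   `passed_all`.
#' @export
evaluate_filters <- function(source_db, target_db, source_protein,
                             target_protein, p_value, pairs,
                             config = prop_config()) {
  res <- c(
    target_evidence = target_evidence_filter(target_db, target_protein, config),
    source_evidence = source_evidence_filter(source_db, source_protein, config),
    p_value = p_value_filter(p_value, config$p_value_threshold),
    length = length_filter(nchar(source_db$proteins[[source_protein]]$sequence),
                           nchar(target_db$proteins[[target_protein]]$sequence),
                           config$length_threshold),
    complex = complex_filter(source_db, source_protein, pairs))
  structure(list(pair = c(source = source_protein, target = target_protein),
                 results = res,
                 passed_all = all(res == "pass")),
            class = "filter_verdict")
}
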