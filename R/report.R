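# The three-part run report: summary statistics, fields propagated per
# protein, and the reasons why not -- plus the histogram-ready breakdowns
# and the unknown/vague/specific function-name classifier.

#' Function-name pattern lists
#'
#' Loads the shipped (or a user-supplied) set of case-insensitive regular
#' expressions that classify product names as corresponding to unknown
#' function (e.g. "hypothetical protein", "orf") or to a vague, non-specific
#' function (e.g. "transporter", "oxidoreductase", "regulatory protein").
#' The shipped lists are seeded from well-known annotation boilerplate and
#' are editable data, not fixed truth.
#'
#' @param path Optional path to a JSON file with `unknown` and `vague`
#'   arrays of regular expressions.
#' @return List with character vectors `unknown` and `vague`.
#' @export
function_name_patterns <- function(path = NULL) {
  path <- path %||% system.file("extdata", "function-name-patterns.json",
                                package = "pgdbprop")
  raw <- jsonlite::fromJSON(path)
  list(unknown = as.character(raw$unknown), vague = as.character(raw$vague))
}

#' Classify a product function name as unknown, vague or specific
#'
#' Case-insensitive regex match against the pattern lists; `unknown` takes
#' precedence over `vague`; a name matching neither is `specific`; an
#' absent/empty name is `unknown`. Total over arbitrary strings.
#'
#' @param name Character vector of product names (NA/empty allowed).
#' @param patterns Pattern lists from [function_name_patterns()].
#' @return Character vector over `{"unknown", "vague", "specific"}`.
#' @export
classify_function_name <- function(name, patterns = function_name_patterns()) {
  vapply(as.character(name), function(nm) {
    if (is.na(nm) || !nzchar(trimws(nm))) return("unknown")
    for (p in patterns$unknown)
      if (grepl(p, nm, ignore.case = TRUE, perl = TRUE)) return("unknown")
    for (p in patterns$vague)
      if (grepl(p, nm, ignore.case = TRUE, perl = TRUE)) return("vague")
    "specific"
  }, character(1), USE.NAMES = FALSE)
}

#' Count function upgrades among propagated proteins
#'
#' An upgrade is a propagated protein whose product name classified as
#' unknown or vague before propagation and as specific after -- i.e. the
#' propagation added genuinely new functional information.
#'
#' @param before,after Equal-length character vectors of product names.
#' @param patterns Pattern lists from [function_name_patterns()].
#' @return Integer count.
#' @export
count_function_upgrades <- function(before, after,
                                    patterns = function_name_patterns()) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length", call. = FALSE)
  if (!length(before)) return(0L)
  b <- classify_function_name(before, patterns)
  a <- classify_function_name(after, patterns)
  changed <- !mapply(identical, as.character(before), as.character(after))
  sum(b %in% c("unknown", "vague") & a == "specific" & changed)
}

#' Assemble the run report
#'
#' Computes the three-part report from per-gene decisions, filter verdicts
#' and propagation records: (a) summary statistics, (b) the fields
#' propagated for every propagated protein, and (c) the rejection reason for
#' every protein not propagated (multi-filter failures are recorded once,
#' with the full failing set). Propagated and rejected genes partition the
#' candidate set (all protein-coding target genes).
#'
#' @param decisions Named list of per-gene decisions (from
#'   [run_propagation()]).
#' @param verdicts Named list of `filter_verdict`s.
#' @param records Named list of propagation records.
#' @param target_db The post-run target `pgdb`.
#' @param config The run's [prop_config()].
#' @param patterns Function-name pattern lists.
#' @return A list of class `run_report`.
#' @export
build_report <- function(decisions, verdicts, records, target_db,
                         config = prop_config(),
                         patterns = function_name_patterns()) {
  decisions <- drop_null(decisions)
  genes <- sort(names(decisions))
  status <- vapply(decisions, function(d) d$status, character(1))[genes]

  prop_genes <- genes[status == "propagated"]
  rej_genes <- genes[status == "rejected"]

  propagated <- data.frame(
    target_gene = prop_genes,
    source_gene = vapply(decisions[prop_genes], function(d) d$source_gene,
                         character(1)),
    resolution = vapply(decisions[prop_genes], function(d) d$resolution,
                        character(1)),
    fields = vapply(prop_genes, function(g)
      paste(records[[g]]$changed_fields, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rejected <- data.frame(
    target_gene = rej_genes,
    reason = vapply(decisions[rej_genes], function(d) d$reason, character(1)),
    failed_filters = vapply(decisions[rej_genes], function(d)
      paste(sort(d$failed), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(propagated) <- rownames(rejected) <- NULL

  attribute_counts <- setNames(integer(length(PROPAGATED_FIELDS)),
                               PROPAGATED_FIELDS)
  for (g in prop_genes)
    for (f in records[[g]]$changed_fields)
      attribute_counts[[f]] <- attribute_counts[[f]] + 1L

  # function upgrades: before-name from the record's prior value when the
  # product name changed, else the (unchanged) current name
  before <- after <- character(length(prop_genes))
  for (i in seq_along(prop_genes)) {
    g <- prop_genes[i]
    pid <- target_db$genes[[g]]$product
    after[i] <- target_db$proteins[[pid]]$name %||% ""
    rec <- records[[g]]
    before[i] <- if ("product_name" %in% rec$changed_fields)
      rec$prior_values[["product_name"]] %||% "" else after[i]
  }
  upgrades <- count_function_upgrades(before, after, patterns)

  n_fail <- vapply(decisions[rej_genes], function(d) length(d$failed), integer(1))
  reason_tab <- table(rejected$reason)
  res_tab <- table(vapply(decisions[prop_genes], function(d) d$resolution,
                          character(1)))

  structure(list(
    summary = list(
      candidates = length(genes),
      propagated = length(prop_genes),
      rejected = length(rej_genes),
      resolutions = as.list(res_tab),
      rejected_by_reason = as.list(reason_tab),
      filter_failures = list(
        any = sum(n_fail >= 1L),
        single = sum(n_fail == 1L),
        multiple = sum(n_fail >= 2L)),
      function_upgrades = upgrades,
      thresholds = list(evalue_cutoff = config$evalue_cutoff,
                        p_value_threshold = config$p_value_threshold,
                        length_threshold = config$length_threshold)),
    propagated = propagated,
    rejected = rejected,
    attribute_counts = attribute_counts,
    function_upgrades = upgrades),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Propagation report: %d candidate genes, %d propagated, %d rejected\n",
              s$candidates, s$propagated, s$rejected))
  if (length(s$rejected_by_reason)) {
    cat("  rejections:\n")
    for (r in names(s$rejected_by_reason))
      cat(sprintf("    %-28s %d\n", r, s$rejected_by_reason[[r]]))
  }
  cat("  attributes propagated:\n")
  for (f in names(x$attribute_counts))
    if (x$attribute_counts[[f]] > 0)
      cat(sprintf("    %-28s %d\n", f, x$attribute_counts[[f]]))
  cat(sprintf("  function upgrades (unknown/vague -> specific): %d\n",
              x$function_upgrades))
  invisible(x)
}

#' Write the report files
#'
#' Emits `summary.json` (machine-readable summary), `propagated.tsv`,
#' `rejected.tsv` and a human-readable `report.txt`, all deterministically
#' ordered by gene id; regenerating from the same records is byte-identical.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  js <- list(
    candidates = j_int(s$candidates), propagated = j_int(s$propagated),
    rejected = j_int(s$rejected),
    resolutions = lapply(s$resolutions, j_int),
    rejected_by_reason = lapply(s$rejected_by_reason, j_int),
    filter_failures = lapply(s$filter_failures, j_int),
    function_upgrades = j_int(s$function_upgrades),
    attribute_counts = lapply(as.list(report$attribute_counts), j_int),
    thresholds = lapply(s$thresholds, j_num))
  write_json_file(js, file.path(dir, "summary.json"))

  write_tsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
  }
  write_tsv(report$propagated, file.path(dir, "propagated.tsv"))
  write_tsv(report$rejected, file.path(dir, "rejected.tsv"))

  txt <- c(
    "Ortholog-based annotation propagation report",
    "============================================",
    "",
    sprintf("Candidate protein-coding genes: %d", s$candidates),
    sprintf("Propagated:                     %d", s$propagated),
    sprintf("Rejected:                       %d", s$rejected),
    "",
    "Rejections by reason:",
    if (length(s$rejected_by_reason))
      sprintf("  %-32s %d", names(s$rejected_by_reason),
              unlist(s$rejected_by_reason)) else "  (none)",
    "",
    sprintf("Filter failures: %d total (%d single-filter, %d multiple-filter)",
            s$filter_failures$any, s$filter_failures$single,
            s$filter_failures$multiple),
    "",
    "Attributes propagated:",
    sprintf("  %-32s %d", names(report$attribute_counts),
            report$attribute_counts),
    "",
    sprintf("Function upgrades (unknown/vague -> specific): %d",
            s$function_upgrades),
    "",
    sprintf("Thresholds: E-value < %g, P-value <= %g, length diff <= %g%%",
            s$thresholds$evalue_cutoff, s$thresholds$p_value_threshold,
            100 * s$thresholds$length_threshold))
  con <- file(file.path(dir, "report.txt"), open = "wb")
  writeLines(txt, con, useBytes = TRUE)
  close(con)
  invisible(dir)
}

#' Rebuild a run report from a propagated PGDB's embedded records
#'
#' Reconstructs parts (a) and (b) of the report from the propagation
#' records stored in a database (rejection reasons are only known to the
#' run that produced them and are reported as unavailable).
#'
#' @param db A `pgdb` carrying `propagation_records`.
#' @param config A [prop_config()] (thresholds echoed into the summary).
#' @param patterns Function-name pattern lists.
#' @return A `run_report`.
#' @export
report_from_records <- function(db, config = prop_config(),
                                patterns = function_name_patterns()) {
  records <- db$propagation_records
  decisions <- list(); recs <- list()
  for (rec in records) {
    g <- rec$target_gene
    decisions[[g]] <- list(gene = g, status = "propagated",
                           reason = NA_character_, failed = character(),
                           source_gene = rec$source_gene,
                           resolution = "recorded")
    recs[[g]] <- rec
  }
  build_report(decisions, list(), recs, db, config, patterns)
}
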