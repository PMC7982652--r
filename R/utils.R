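# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

pgdbprop_env <- new.env(parent = emptyenv())

# normalized string set: unique, sorted, no NA/empty
chr_set <- function(x) {
  x <- as.character(x %||% character())
  sort(unique(x[!is.na(x) & nzchar(x)]))
}

set_equal <- function(a, b) identical(chr_set(a), chr_set(b))

opt_chr <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L]) || !nzchar(x[1L])) NULL
  else as.character(x[1L])
}

abort_validation <- function(msg, ids = character()) {
  stop(errorCondition(paste0("PGDB validation: ", msg),
                      ids = ids,
                      class = c("pgdb_validation_error", "error", "condition")))
}

# canonical JSON: scalars are explicitly unboxed when structures are built,
# so serialization is fully deterministic (fixed key order, no auto-unbox
# heuristics, full numeric precision).
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA, null = "null",
                   na = "null", pretty = 2)
}

write_json_file <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(canonical_json(x), con, useBytes = TRUE)
  invisible(path)
}

# unboxed scalar helpers for canonical serialization
j_str <- function(x) jsonlite::unbox(as.character(x))
j_int <- function(x) jsonlite::unbox(as.integer(x))
j_num <- function(x) jsonlite::unbox(as.numeric(x))
j_bool <- function(x) jsonlite::unbox(as.logical(x))

# drop NULL entries from a list, preserving order
drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
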