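test_that("a minimal database assembles with the expected counts", {
  db <- fixture_db("mini", list(list(id = "g1", seq = "MKV", name = "abcA")))
  expect_s3_class(db, "pgdb")
  expect_length(db$replicons, 1L)
  expect_length(db$genes, 1L)
  expect_length(db$proteins, 1L)
})

test_that("dangling references raise validation errors naming the record", {
  db <- fixture_db("bad", list(list(id = "g1", seq = "MKV")))
  db$proteins[["p-g1"]]$gene <- "missing-gene"
  expect_error(validate_pgdb(db), class = "pgdb_validation_error",
               regexp = "p-g1")

  db2 <- fixture_db("bad2", list(list(id = "g1", seq = "MKV")))
  db2$genes[["g1"]]$product <- "nope"
  expect_error(validate_pgdb(db2), class = "pgdb_validation_error",
               regexp = "nope")

  db3 <- fixture_db("bad3", list(list(id = "g1", seq = "MKV")))
  db3$proteins[["p-g1"]]$sequence <- "MKB*"
  expect_error(validate_pgdb(db3), class = "pgdb_validation_error",
               regexp = "p-g1")
})

test_that("malformed JSON raises a parse error", {
  f <- tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(read_pgdb(f), class = "pgdb_parse_error")
  expect_error(read_pgdb(tempfile()), "no such file")
})

test_that("write/read round-trips generated databases exactly", {
  set.seed(42)
  for (seed in c(3, 14)) {
    pair <- generate_pair(strain_pair_spec(
      n_genes = 15, duplication_rate = 0.2, loss_rate = 0.1,
      substitution_rate = 0.02, name_dropout = 0.3, n_complexes = 2,
      n_rna_complexes = 1, vague_name_rate = 0.2,
      spurious_reaction_rate = 0.2, seed = seed))
    for (db in list(pair$source, pair$target)) {
      f <- tempfile(fileext = ".json")
      write_pgdb(db, f)
      back <- read_pgdb(f)
      expect_identical(pgdb_json_string(back), pgdb_json_string(db))
      # canonical serialization: writing twice is byte-identical
      f2 <- tempfile(fileext = ".json")
      write_pgdb(back, f2)
      expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))
    }
  }
})

test_that("empty optional fields are omitted from the JSON, never null", {
  db <- fixture_db("opt", list(list(id = "g1", seq = "MKV")))
  txt <- pgdb_json_string(db)
  expect_false(grepl("null", txt, fixed = TRUE))
  expect_false(grepl('"synonyms"', txt, fixed = TRUE))
  expect_false(grepl('"name"', txt, fixed = TRUE))
})

test_that("proteome FASTA reading normalizes case and strips terminal stops", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "mkvlaw", ">p2", "MKV*"), f)
  seqs <- read_proteome_fasta(f)
  expect_identical(seqs, c(p1 = "MKVLAW", p2 = "MKV"))

  writeLines(c(">p1", "MKV", ">p1", "MML"), f)
  expect_error(read_proteome_fasta(f), "duplicate")

  db <- fixture_db("fa", list(list(id = "g1", seq = "MKVLAW")))
  writeLines(c(">p-g1", "MKVLAW", ">stray", "MML"), f)
  expect_warning(read_proteome_fasta(f, db), "stray")
})

test_that("FASTA write/read round-trips a proteome", {
  pair <- generate_pair(strain_pair_spec(n_genes = 8, seed = 5))
  f <- tempfile(fileext = ".fasta")
  write_proteome_fasta(pair$source, f)
  seqs <- read_proteome_fasta(f, pair$source)
  expect_identical(seqs[order(names(seqs))], proteome_sequences(pair$source))
})

test_that("evidence classes follow the code table and BioCyc prefixes", {
  db <- fixture_db("ev", list(
    list(id = "g1", seq = "MKV", ev = "IDA"),
    list(id = "g2", seq = "MKV", go = list(c("GO:0000001", "IEA"))),
    list(id = "g3", seq = "MKV"),
    list(id = "g4", seq = "MKV", ev = "EV-EXP-IDA"),
    list(id = "g5", seq = "MKV", ev = "TAS"),
    list(id = "g6", seq = "MKV", gev = "EV-COMP-AINF")))
  expect_identical(evidence_class(db, "g1"), "experimental-or-literature")
  expect_identical(evidence_class(db, "g2"), "computational-only")
  expect_identical(evidence_class(db, "g3"), "none")
  expect_identical(evidence_class(db, "g4"), "experimental-or-literature")
  expect_identical(evidence_class(db, "g5"), "experimental-or-literature")
  expect_identical(evidence_class(db, "g6"), "computational-only")
  # protein id and gene id give the same answer
  expect_identical(evidence_class(db, "p-g1"), evidence_class(db, "g1"))
})

test_that("unknown evidence codes degrade to computational and log once", {
  expect_message(cls <- evidence_code_class("WEIRD-CODE-XYZ"), "WEIRD-CODE-XYZ")
  expect_identical(cls, "computational")
  expect_silent(evidence_code_class("WEIRD-CODE-XYZ"))
})

test_that("adding an experimental code never downgrades the class", {
  set.seed(99)
  pool <- c("IEA", "ISS", "ISO", "TAS", "ND", "EV-COMP-HINF")
  rank <- c(none = 0L, `computational-only` = 1L,
            `experimental-or-literature` = 2L)
  for (i in 1:20) {
    codes <- sample(pool, sample(0:3, 1L))
    db <- fixture_db("mono", list(list(id = "g1", seq = "MKV", ev = codes)))
    base <- evidence_class(db, "g1")
    db2 <- fixture_db("mono", list(list(id = "g1", seq = "MKV",
                                        ev = c(codes, "IDA"))))
    expect_gte(rank[[evidence_class(db2, "g1")]], rank[[base]])
    expect_identical(evidence_class(db2, "g1"), "experimental-or-literature")
  }
})

test_that("complex classification: heteromultimeric and RNA content are derived", {
  db <- fixture_db("cx", list(
    list(id = "g1", seq = "MKVLAW"),
    list(id = "g2", seq = "MMLPRT"),
    list(id = "rna1", seq = NULL)),
    complexes = list(
      list(id = "homo", components = c(`p-g1` = 4)),
      list(id = "hetero", components = c(`p-g1` = 2, `p-g2` = 1)),
      list(id = "rnp", components = c(`p-g1` = 1, rna1 = 1))))
  expect_false(complex_is_heteromultimeric(db, "homo"))
  expect_true(complex_is_heteromultimeric(db, "hetero"))
  expect_true(complex_is_heteromultimeric(db, "rnp"))
  expect_false(complex_contains_rna(db, "hetero"))
  expect_true(complex_contains_rna(db, "rnp"))
  # every RNA-containing complex has a component gene with no product
  for (cid in names(db$complexes)) {
    if (!complex_contains_rna(db, cid)) next
    refs <- names(db$complexes[[cid]]$components)
    expect_true(any(vapply(refs, function(r)
      !is.null(db$genes[[r]]) && is.null(db$genes[[r]]$product), logical(1))))
  }
})

test_that("cyclic complex composition is rejected", {
  db <- fixture_db("cyc", list(list(id = "g1", seq = "MKV"),
                               list(id = "g2", seq = "MML")))
  db$complexes <- list(
    cA = complex_record("cA", c(`p-g1` = 1, cB = 1)),
    cB = complex_record("cB", c(`p-g2` = 1, cA = 1)))
  expect_error(validate_pgdb(db), class = "pgdb_validation_error",
               regexp = "cyclic")
})
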