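# Hand-built (S, T) pairs exercising the propagation semantics, including
# the published renaming / reaction-replacement behaviors in fixture form.

name_fixture <- function(t_name, t_syn = character(), s_name = "btsR",
                         s_syn = character()) {
  seqx <- strrep("MKVLAWPR", 20)
  src <- fixture_db("S", list(list(id = "sg", seq = seqx, name = s_name,
                                   syn = s_syn, pname = "sensory kinase",
                                   ev = "IDA")))
  tgt <- fixture_db("T", list(list(id = "tg", seq = seqx, name = t_name,
                                   syn = t_syn, pname = "sensory kinase")))
  list(src = src, tgt = tgt)
}

test_that("a renamed gene demotes the target's prior name to a synonym", {
  fx <- name_fixture(t_name = "yehT", s_syn = "yehT")
  out <- propagate_names(fx$tgt, fx$src, "p-sg", "p-tg")
  tg <- out$db$genes[["tg"]]
  expect_identical(tg$name, "btsR")
  expect_true("yehT" %in% tg$synonyms)
  expect_false("btsR" %in% tg$synonyms)
  expect_true(all(c("gene_name", "gene_synonyms") %in% out$changed))
  expect_identical(out$priors$gene_name, "yehT")
})

test_that("identical names record no change; unnamed targets gain a name only", {
  fx <- name_fixture(t_name = "btsR")
  out <- propagate_names(fx$tgt, fx$src, "p-sg", "p-tg")
  expect_length(out$changed, 0L)

  fx2 <- name_fixture(t_name = NULL)
  out2 <- propagate_names(fx2$tgt, fx2$src, "p-sg", "p-tg")
  expect_identical(out2$db$genes[["tg"]]$name, "btsR")
  expect_identical(out2$changed, "gene_name")
  expect_length(out2$db$genes[["tg"]]$synonyms, 0L)
})

go_fixture <- function(identical_seqs) {
  s_seq <- strrep("MKVLAWPR", 20)
  t_seq <- if (identical_seqs) s_seq else strrep("MKVLAWPS", 20)
  src <- fixture_db("S", list(list(
    id = "sg", seq = s_seq, ev = "IDA",
    go = list(c("GO:0016301", "IDA"), c("GO:0005737", "IEA")))))
  tgt <- fixture_db("T", list(list(id = "tg", seq = t_seq)))
  list(src = src, tgt = tgt)
}

test_that("GO propagation keeps experimental terms only for divergent sequences", {
  fx <- go_fixture(identical_seqs = FALSE)
  out <- propagate_go(fx$tgt, fx$src, "p-sg", "p-tg")
  anns <- out$db$proteins[["p-tg"]]$go_annotations
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$term, "GO:0016301")
  expect_identical(anns[[1]]$evidence_code, "ISO")
  expect_identical(anns[[1]]$with_ref, "p-sg")
  expect_identical(out$changed, "go_terms")
})

test_that("identical sequences propagate all GO terms, still as ISO", {
  fx <- go_fixture(identical_seqs = TRUE)
  out <- propagate_go(fx$tgt, fx$src, "p-sg", "p-tg")
  anns <- out$db$proteins[["p-tg"]]$go_annotations
  expect_identical(sort(vapply(anns, `[[`, character(1), "term")),
                   c("GO:0005737", "GO:0016301"))
  expect_true(all(vapply(anns, `[[`, character(1), "evidence_code") == "ISO"))
})

test_that("GO terms already held by the target produce no change", {
  fx <- go_fixture(identical_seqs = FALSE)
  tgt <- fixture_db("T", list(list(
    id = "tg", seq = strrep("MKVLAWPS", 20),
    go = list(c("GO:0016301", "IEA")))))
  out <- propagate_go(tgt, fx$src, "p-sg", "p-tg")
  expect_length(out$changed, 0L)
  expect_length(out$db$proteins[["p-tg"]]$go_annotations, 1L)
})

test_that("reaction propagation replaces: additions and removals both happen", {
  seqx <- strrep("MKVLAWPR", 20)
  # misannotated dehalogenase reactions replaced by the curated phosphatase one
  src <- fixture_db("S", list(list(id = "sg", seq = seqx, ev = "IDA",
                                   rx = "SUGAR-PHOSPHATASE-RXN")))
  tgt <- fixture_db("T", list(list(id = "tg", seq = seqx,
                                   rx = c("DEHALOGENASE-RXN-1",
                                          "DEHALOGENASE-RXN-2"))))
  out <- propagate_reactions(tgt, src, "p-sg", "p-tg")
  expect_identical(out$db$proteins[["p-tg"]]$reactions, "SUGAR-PHOSPHATASE-RXN")
  expect_true("SUGAR-PHOSPHATASE-RXN" %in% names(out$db$reactions))
  expect_identical(sort(out$priors$reactions),
                   c("DEHALOGENASE-RXN-1", "DEHALOGENASE-RXN-2"))

  # secondary activities: the target gains the source's extra reactions
  extra <- sprintf("NDPK-RXN-%d", 1:7)
  src2 <- fixture_db("S", list(list(id = "sg", seq = seqx, ev = "IDA",
                                    rx = c("ADENYL-KIN-RXN", extra))))
  tgt2 <- fixture_db("T", list(list(id = "tg", seq = seqx,
                                    rx = "ADENYL-KIN-RXN")))
  out2 <- propagate_reactions(tgt2, src2, "p-sg", "p-tg")
  expect_identical(out2$db$proteins[["p-tg"]]$reactions,
                   sort(c("ADENYL-KIN-RXN", extra)))

  # a regulator with no catalytic activity: spurious assignment removed
  src3 <- fixture_db("S", list(list(id = "sg", seq = seqx, ev = "IDA")))
  tgt3 <- fixture_db("T", list(list(id = "tg", seq = seqx,
                                    rx = "PHOSPHATE-TRANSPORT-RXN")))
  out3 <- propagate_reactions(tgt3, src3, "p-sg", "p-tg")
  expect_length(out3$db$proteins[["p-tg"]]$reactions, 0L)
  expect_identical(out3$changed, "reactions")
})

complex_pair <- function() {
  s1 <- strrep("MKVLAWPR", 20); s2 <- strrep("CCDEFGHI", 20)
  src <- fixture_db("S", list(
    list(id = "sa", seq = s1, ev = "IDA"),
    list(id = "sb", seq = s2, ev = "IDA")),
    complexes = list(list(id = "CPLX-AB",
                          components = c(`p-sa` = 2, `p-sb` = 1),
                          reactions = "CPLX-RXN")))
  tgt <- fixture_db("T", list(
    list(id = "ta", seq = s1),
    list(id = "tb", seq = s2)))
  pairs <- pairs_of(c("p-sa", "p-ta"), c("p-sb", "p-tb"))
  list(src = src, tgt = tgt, pairs = pairs,
       s2t = c(`p-sa` = "p-ta", `p-sb` = "p-tb"))
}

test_that("complex propagation maps components, keeps stoichiometry, is idempotent", {
  fx <- complex_pair()
  out <- propagate_complexes(fx$tgt, fx$src, "p-sa", fx$s2t)
  cx <- out$db$complexes[["CPLX-AB"]]
  expect_identical(cx$components, c(`p-ta` = 2L, `p-tb` = 1L))
  expect_identical(cx$reactions, "CPLX-RXN")
  expect_true("CPLX-RXN" %in% names(out$db$reactions))
  expect_identical(out$changed, "complex_membership")

  out2 <- propagate_complexes(out$db, fx$src, "p-sa", fx$s2t)
  expect_length(out2$changed, 0L)
  expect_length(out2$db$complexes, 1L)
})

test_that("whole-gene propagation assembles a history record with priors", {
  fx <- name_fixture(t_name = "yehT", s_syn = "yehT")
  out <- propagate_gene(fx$tgt, fx$src, "p-sg", "p-tg",
                        config = prop_config(timestamp = "2026-02-01"))
  rec <- out$record
  expect_false(out$noop)
  expect_identical(rec$source_gene, "sg")
  expect_identical(rec$target_gene, "tg")
  expect_identical(sort(names(rec$prior_values)), sort(rec$changed_fields))
  expect_identical(rec$timestamp, "2026-02-01")
  expect_identical(out$db$genes[["tg"]]$propagated_from, "sg")
  expect_match(format_history_note(rec), "sg")
  # every changed field really differs from its prior value
  expect_true("gene_name" %in% rec$changed_fields)
  expect_false(identical(rec$prior_values$gene_name,
                         out$db$genes[["tg"]]$name))

  # second application is a no-op for names/reactions
  out2 <- propagate_gene(out$db, fx$src, "p-sg", "p-tg",
                         config = prop_config(timestamp = "2026-02-01"))
  expect_true(out2$noop)
})

test_that("a clone run propagates everything eligible and only adds GO", {
  spec <- strain_pair_spec(n_genes = 20, source_evidence_fraction = 1,
                           n_complexes = 2, seed = 31)
  pair <- generate_pair(spec)
  run <- run_propagation(pair$source, pair$target,
                         prop_config(timestamp = "2026-02-01"))
  expect_identical(run$report$summary$propagated, 20L)
  fields <- unique(unlist(lapply(run$target$propagation_records,
                                 function(r) r$changed_fields)))
  expect_identical(fields, "go_terms")
  # conservation: gene and protein counts unchanged
  expect_identical(length(run$target$genes), length(pair$target$genes))
  expect_identical(length(run$target$proteins), length(pair$target$proteins))
})

test_that("rerunning propagation on its own output changes nothing", {
  spec <- strain_pair_spec(n_genes = 15, source_evidence_fraction = 1,
                           n_complexes = 1, vague_name_rate = 0.3,
                           spurious_reaction_rate = 0.3, name_dropout = 0.3,
                           complex_dropout = 1, seed = 8)
  pair <- generate_pair(spec)
  cfg <- prop_config(timestamp = "2026-02-01")
  run1 <- run_propagation(pair$source, pair$target, cfg)
  run2 <- run_propagation(pair$source, run1$target, cfg)
  expect_identical(run2$report$summary$propagated +
                     run2$report$summary$rejected, 15L)
  new_changes <- setdiff(seq_along(run2$target$propagation_records),
                         seq_along(run1$target$propagation_records))
  expect_length(new_changes, 0L)
  expect_true(all(run2$report$attribute_counts == 0L))
  # and the serialized databases are byte-identical
  expect_identical(pgdb_json_string(run2$target), pgdb_json_string(run1$target))
})

test_that("the source database is never modified by a run", {
  spec <- strain_pair_spec(n_genes = 12, source_evidence_fraction = 1,
                           substitution_rate = 0.02, seed = 77)
  pair <- generate_pair(spec)
  f <- tempfile(fileext = ".json")
  write_pgdb(pair$source, f)
  before <- unname(tools::md5sum(f))
  run <- run_propagation(pair$source, pair$target,
                         prop_config(timestamp = "2026-02-01"))
  f2 <- tempfile(fileext = ".json")
  write_pgdb(pair$source, f2)
  expect_identical(before, unname(tools::md5sum(f2)))
})

test_that("disjoint proteomes yield zero propagations but a complete report", {
  set.seed(4)
  src <- fixture_db("S", lapply(1:5, function(i)
    list(id = paste0("s", i), seq = rand_aa(150), ev = "IDA")))
  tgt <- fixture_db("T", lapply(1:5, function(i)
    list(id = paste0("t", i), seq = rand_aa(150))))
  run <- run_propagation(src, tgt, prop_config(timestamp = "2026-02-01"))
  expect_identical(run$report$summary$propagated, 0L)
  expect_identical(run$report$summary$rejected, 5L)
  expect_true(all(run$report$rejected$reason == "no-ortholog"))
})

test_that("every ISO annotation written carries a resolvable source reference", {
  spec <- strain_pair_spec(n_genes = 15, source_evidence_fraction = 0.8,
                           substitution_rate = 0.02, seed = 21)
  pair <- generate_pair(spec)
  run <- run_propagation(pair$source, pair$target,
                         prop_config(timestamp = "2026-02-01"))
  n_iso <- 0L
  for (p in run$target$proteins) {
    for (a in p$go_annotations) {
      if (a$evidence_code != "ISO") next
      n_iso <- n_iso + 1L
      expect_false(is.null(a$with_ref))
      expect_true(a$with_ref %in% names(pair$source$proteins))
    }
  }
  expect_gt(n_iso, 0L)
})
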