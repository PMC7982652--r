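# Shared fixtures: a source genome with a duplicated gene family and a
# target genome whose gene order controls which candidate (if any) is
# syntenic. Ortholog pair tables are hand-built; no alignment involved.

three_gene_db <- function(id, topology = "linear", order = c("g1", "g2", "g3")) {
  genes <- lapply(order, function(g) list(id = g, seq = strrep("MKVLAW", 5)))
  fixture_db(id, genes, topology = topology)
}

test_that("adjacency follows gene order, topology and replicon boundaries", {
  lin <- three_gene_db("lin")
  expect_identical(sort(adjacent_genes(lin, "g2")), c("g1", "g3"))
  expect_identical(adjacent_genes(lin, "g1"), "g2")
  expect_identical(adjacent_genes(lin, "g3"), "g2")

  circ <- three_gene_db("circ", topology = "circular")
  expect_identical(sort(adjacent_genes(circ, "g1")), c("g2", "g3"))

  two <- fixture_db("two", list(list(id = "gA", seq = "MKV"),
                                list(id = "gB", seq = "MML")),
                    topology = "circular")
  expect_identical(adjacent_genes(two, "gA"), "gB")  # deduplicated

  expect_error(adjacent_genes(lin, "nope"), "not found")
})

test_that("synteny passes for conserved neighborhoods and fails for shuffled ones", {
  src <- three_gene_db("S")
  tgt <- three_gene_db("T")
  pairs <- pairs_of(c("p-g1", "p-g1"), c("p-g2", "p-g2"), c("p-g3", "p-g3"))
  expect_true(synteny_pass(src, tgt, "g2", "g2", pairs))
  # target neighborhood shuffled: g2's flanks pair with nothing
  pairs_shuf <- pairs_of(c("p-g2", "p-g2"))
  expect_false(synteny_pass(src, tgt, "g2", "g2", pairs_shuf))
})

test_that("synteny agrees with the exhaustive 2x2 flank oracle on inverted blocks", {
  set.seed(9)
  for (rep in 1:6) {
    n <- 10L
    genes <- lapply(seq_len(n), function(i)
      list(id = sprintf("g%02d", i), seq = rand_aa(40)))
    src <- fixture_db("S", genes)
    # target: same genes, one inverted block of 4
    ord <- seq_len(n)
    s <- sample(1:(n - 3), 1L)
    ord[s:(s + 3)] <- rev(ord[s:(s + 3)])
    tgt <- fixture_db("T", genes[ord])
    pairs <- do.call(pairs_of, lapply(seq_len(n), function(i)
      rep(sprintf("p-g%02d", i), 2)))
    for (g in sprintf("g%02d", seq_len(n))) {
      expect_identical(synteny_pass(src, tgt, g, g, pairs),
                       oracle_synteny(src, tgt, g, g, pairs),
                       info = paste("gene", g, "rep", rep))
    }
  }
})

# Disambiguation fixture: source carries duplicates s1a/s1b of the target
# gene t1; s1a sits in t1's conserved neighborhood, s1b elsewhere.
dis_fixture <- function(t1_name = "abcA", s1a_name = "abcA", s1b_name = "abcA") {
  seq_dup <- strrep("MKVLAWPRTQ", 6)
  seq_nb1 <- strrep("CCDEFGHIKL", 6)
  seq_nb2 <- strrep("MNPQRSTVWY", 6)
  src <- fixture_db("S", list(
    list(id = "s0", seq = seq_nb1),
    list(id = "s1a", seq = seq_dup, name = s1a_name),
    list(id = "s2", seq = seq_nb2),
    list(id = "s3", seq = strrep("AWAWMKML", 8)),
    list(id = "s1b", seq = seq_dup, name = s1b_name)))
  tgt <- fixture_db("T", list(
    list(id = "t0", seq = seq_nb1),
    list(id = "t1", seq = seq_dup, name = t1_name),
    list(id = "t2", seq = seq_nb2),
    list(id = "t3", seq = strrep("AWAWMKML", 8))))
  pairs <- pairs_of(c("p-s0", "p-t0"), c("p-s2", "p-t2"), c("p-s3", "p-t3"),
                    c("p-s1a", "p-t1"), c("p-s1b", "p-t1"))
  list(src = src, tgt = tgt, pairs = pairs)
}

test_that("a single candidate resolves as unique", {
  fx <- dis_fixture()
  cand <- fx$pairs[fx$pairs$source_protein == "p-s1a" &
                     fx$pairs$target_protein == "p-t1", ]
  res <- resolve_ortholog(fx$src, fx$tgt, "p-t1", cand, fx$pairs)
  expect_identical(res$resolution, "unique")
  expect_identical(res$chosen, "p-s1a")
})

test_that("synteny is preferred and selects the neighborhood-conserved duplicate", {
  fx <- dis_fixture()
  cand <- fx$pairs[fx$pairs$target_protein == "p-t1", ]
  res <- resolve_ortholog(fx$src, fx$tgt, "p-t1", cand, fx$pairs)
  expect_identical(res$resolution, "synteny")
  expect_identical(res$chosen, "p-s1a")
  # determinism: candidate order must not matter
  res2 <- resolve_ortholog(fx$src, fx$tgt, "p-t1",
                           cand[rev(seq_len(nrow(cand))), ], fx$pairs)
  expect_identical(res2$chosen, res$chosen)
})

test_that("gene names break ties only when synteny fails, and only uniquely", {
  # remove flank pairs so neither duplicate is syntenic
  no_flank <- function(fx) {
    fx$pairs <- fx$pairs[fx$pairs$target_protein == "p-t1", ]
    fx
  }
  # exactly one name match -> gene-name resolution
  fx <- no_flank(dis_fixture(t1_name = "abcA", s1a_name = "abcA",
                             s1b_name = "xyzB"))
  cand <- fx$pairs
  res <- resolve_ortholog(fx$src, fx$tgt, "p-t1", cand, fx$pairs)
  expect_identical(res$resolution, "gene-name")
  expect_identical(res$chosen, "p-s1a")

  # both named identically to the target -> rejected
  fx2 <- no_flank(dis_fixture())
  res2 <- resolve_ortholog(fx2$src, fx2$tgt, "p-t1", fx2$pairs, fx2$pairs)
  expect_identical(res2$resolution, "rejected")
  expect_true(is.na(res2$chosen))

  # unnamed target cannot fall through to name matching
  fx3 <- no_flank(dis_fixture(t1_name = NULL))
  res3 <- resolve_ortholog(fx3$src, fx3$tgt, "p-t1", fx3$pairs, fx3$pairs)
  expect_identical(res3$resolution, "rejected")
})

test_that("a multi-way synteny pass rejects rather than falling back to names", {
  fx <- dis_fixture(s1b_name = "xyzB")
  # make s1b syntenic too: its flank s3 pairs with t1's flank t2
  fx$pairs <- rbind(fx$pairs, pairs_of(c("p-s3", "p-t2")))
  cand <- fx$pairs[fx$pairs$target_protein == "p-t1", ]
  res <- resolve_ortholog(fx$src, fx$tgt, "p-t1", cand, fx$pairs)
  expect_identical(res$resolution, "rejected")
})

test_that("the chosen source is always among the candidates", {
  set.seed(55)
  fx <- dis_fixture()
  for (i in 1:5) {
    cand <- fx$pairs[sample(nrow(fx$pairs), sample(2:nrow(fx$pairs), 1L)), ]
    cand <- cand[cand$target_protein == "p-t1", , drop = FALSE]
    if (!nrow(cand)) next
    res <- resolve_ortholog(fx$src, fx$tgt, "p-t1", cand, fx$pairs)
    if (!is.na(res$chosen))
      expect_true(res$chosen %in% cand$source_protein)
  }
})
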