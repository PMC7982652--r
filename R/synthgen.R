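# Synthetic strain-pair generator: pairs of related annotated genomes with
# known ortholog ground truth, plus an analytic replay of the propagation
# rules that serves as an end-to-end oracle independent of the pipeline.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

UNKNOWN_NAME_POOL <- c("hypothetical protein", "uncharacterized protein",
                       "ORF, conserved", "DUF1234 domain-containing protein")
VAGUE_NAME_POOL <- c("MFS transporter", "oxidoreductase", "regulatory protein",
                     "transporter", "hydrolase", "membrane protein")

SUBSTRATE_POOL <- c("L-arabinose", "N-acetylneuraminate", "D-xylulose",
                    "glycerol-3-phosphate", "shikimate", "L-rhamnose",
                    "putrescine", "trehalose-6-phosphate", "chorismate",
                    "maltodextrin", "N4-acetylcytidine", "adenylosuccinate",
                    "phosphoenolpyruvate", "UDP-glucose", "L-threonine",
                    "succinyl-CoA", "dihydroorotate", "sn-glycerol",
                    "thiamine diphosphate", "2-oxoglutarate")
ENZYME_POOL <- c("isomerase subunit", "aminohydrolase", "dehydratase",
                 "synthase subunit alpha", "decarboxylase", "epimerase",
                 "mutase", "carboxykinase", "aldolase", "thiolase",
                 "aminotransferase", "cyclase")

#' Specification of a synthetic related-strain genome pair
#'
#' Defines the events separating a curated "source" genome from a degraded
#' "target" derived from it. The seed fixes all randomness; with all event
#' rates at zero the target is a curation-stripped clone of the source.
#'
#' Duplications come in two modes, chosen with equal probability per event:
#' `target-copy` (the gene is present once in the source and twice in the
#' target, so each copy has a unique source candidate) and `source-paralog`
#' (the source gains an identical paralog and the single target copy is
#' relocated, so neither candidate can win the synteny test and the shared
#' gene name cannot discriminate -- the expected outcome is rejection as
#' ambiguous). Duplicated sequences are exact copies; duplicated genes are
#' excluded from complex membership.
#'
#' @param n_genes Number of protein-coding genes in the source genome.
#' @param duplication_rate,loss_rate Per-gene event probabilities.
#' @param substitution_rate Per-residue substitution probability applied to
#'   target sequences.
#' @param indel_rate Per-gene probability of one insertion or deletion.
#' @param indel_mean_length Mean indel length (geometric distribution).
#' @param n_inversions Number of local inversion blocks (3-6 genes) applied
#'   to the target gene order.
#' @param name_dropout Probability a target gene loses its gene name.
#' @param source_evidence_fraction Fraction of source genes carrying an
#'   experimental evidence code (the propagation-eligible set).
#' @param target_evidence_fraction Fraction of target genes carrying prior
#'   curation (experimental evidence), which blocks propagation.
#' @param n_complexes Number of heteromultimeric protein complexes.
#' @param complex_size_range Inclusive range of complex sizes (distinct
#'   protein species).
#' @param n_rna_complexes Number of complexes that additionally contain an
#'   RNA component (their protein members can never be propagated).
#' @param complex_dropout Probability a (complete) source complex is absent
#'   from the target database.
#' @param spurious_reaction_rate Probability a target protein's reactions
#'   are replaced by decoy reactions (mimicking mis-assignment).
#' @param vague_name_rate Probability a target product name is replaced by
#'   unknown/vague annotation boilerplate.
#' @param gene_length_range Inclusive range of protein lengths (residues).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `strain_pair_spec`.
#' @export
strain_pair_spec <- function(n_genes = 40L,
                             duplication_rate = 0,
                             loss_rate = 0,
                             substitution_rate = 0,
                             indel_rate = 0,
                             indel_mean_length = 10,
                             n_inversions = 0L,
                             name_dropout = 0,
                             source_evidence_fraction = 0.65,
                             target_evidence_fraction = 0,
                             n_complexes = 0L,
                             complex_size_range = c(2L, 4L),
                             n_rna_complexes = 0L,
                             complex_dropout = 0,
                             spurious_reaction_rate = 0,
                             vague_name_rate = 0,
                             gene_length_range = c(120L, 300L),
                             seed = 1L) {
  rates <- c(duplication_rate, loss_rate, substitution_rate, indel_rate,
             name_dropout, source_evidence_fraction, target_evidence_fraction,
             complex_dropout, spurious_reaction_rate, vague_name_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (n_genes < 4L) stop("n_genes must be >= 4", call. = FALSE)
  if (max(complex_size_range) > n_genes)
    stop("complex size exceeds n_genes: inconsistent spec", call. = FALSE)
  if ((n_complexes + n_rna_complexes) * max(complex_size_range) > n_genes)
    stop("complexes require more distinct genes than n_genes provides",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_mean_length = indel_mean_length,
                 n_inversions = as.integer(n_inversions),
                 name_dropout = name_dropout,
                 source_evidence_fraction = source_evidence_fraction,
                 target_evidence_fraction = target_evidence_fraction,
                 n_complexes = as.integer(n_complexes),
                 complex_size_range = as.integer(complex_size_range),
                 n_rna_complexes = as.integer(n_rna_complexes),
                 complex_dropout = complex_dropout,
                 spurious_reaction_rate = spurious_reaction_rate,
                 vague_name_rate = vague_name_rate,
                 gene_length_range = as.integer(gene_length_range),
                 seed = as.integer(seed)),
            class = "strain_pair_spec")
}

rand_seq <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

mutate_seq <- function(s, sub_rate, indel_rate, indel_mean) {
  aa <- strsplit(s, "")[[1]]
  if (sub_rate > 0) {
    hit <- which(runif(length(aa)) < sub_rate)
    for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  }
  if (indel_rate > 0 && runif(1) < indel_rate) {
    len <- rgeom(1, 1 / indel_mean) + 1L
    if (runif(1) < 0.5) {
      # deletion, truncating at most half the protein so that the conserved
      # remainder still aligns far below any plausible P-value threshold
      len <- min(len, length(aa) %/% 2L)
      if (len > 0) {
        at <- sample(length(aa) - len, 1L)
        aa <- aa[-(at:(at + len - 1L))]
      }
    } else {                          # insertion
      at <- sample(length(aa), 1L)
      aa <- append(aa, sample(AA20, len, replace = TRUE), after = at)
    }
  }
  paste(aa, collapse = "")
}

unique_gene_names <- function(n) {
  pool <- character(0)
  while (length(pool) < n) {
    nm <- paste0(paste(sample(letters, 3L, replace = TRUE), collapse = ""),
                 sample(LETTERS, 1L))
    pool <- unique(c(pool, nm))
  }
  pool[seq_len(n)]
}

layout_genes <- function(order_ids, widths, replicon_id) {
  pos <- 1L
  out <- list()
  for (gid in order_ids) {
    w <- widths[[gid]]
    out[[gid]] <- c(start = pos, end = pos + w - 1L)
    pos <- pos + w + 49L
  }
  out
}

insert_at <- function(vec, value, pos) append(vec, value, after = pos - 1L)

#' Generate a related synthetic genome pair with ground truth
#'
#' Builds a curated source genome (names, synonyms, GO annotations with
#' experimental codes on the curated fraction, reaction assignments,
#' heteromultimeric complexes, optional RNA-containing complexes) and a
#' target genome derived from it by the spec's events (loss, duplication,
#' substitution, indels, inversions, name dropout, annotation degradation:
#' GO and evidence stripped, vague/unknown product names, spurious decoy
#' reactions). The ground truth maps every target gene to its true source
#' gene and labels the events that shaped it.
#'
#' @param spec A [strain_pair_spec()].
#' @return List of class `strain_pair`: `source` and `target` (`pgdb`s) and
#'   `truth` (list with `map`, `events`, `families`, `lost`, `spec`).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "strain_pair_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gids <- sprintf("g%03d", seq_len(n))
  pids <- sprintf("p%03d", seq_len(n))
  names(pids) <- gids

  lens <- setNames(sample(spec$gene_length_range[1]:spec$gene_length_range[2],
                          n, replace = TRUE), gids)
  seqs <- setNames(vapply(lens, rand_seq, character(1)), gids)
  gnames <- setNames(unique_gene_names(n), gids)
  pnames <- setNames(paste(sample(SUBSTRATE_POOL, n, replace = TRUE),
                           sample(ENZYME_POOL, n, replace = TRUE)), gids)
  has_gsyn <- runif(n) < 0.25
  gsyns <- setNames(ifelse(has_gsyn, paste0(gnames, "_alt"), NA), gids)

  go_pool <- sprintf("GO:%07d", sample(1:9999999, 300L))
  go_sets <- setNames(lapply(seq_len(n), function(i)
    sample(go_pool, sample(1:3, 1L))), gids)

  rxn_pool <- sprintf("RXN-%04d", seq_len(n + 20L))
  rxn_sets <- setNames(lapply(seq_len(n), function(i)
    sample(rxn_pool, sample(1:2, 1L))), gids)
  decoy_pool <- sprintf("DECOY-RXN-%02d", 1:20)

  curated <- setNames(runif(n) < spec$source_evidence_fraction, gids)

  # ---- event decisions --------------------------------------------------
  lost <- gids[runif(n) < spec$loss_rate]
  dup_candidates <- setdiff(gids, lost)
  dup <- dup_candidates[runif(length(dup_candidates)) < spec$duplication_rate]
  dup_mode <- setNames(sample(c("target-copy", "source-paralog"),
                              length(dup), replace = TRUE), dup)

  # complexes among non-duplicated genes; lost members are allowed (they
  # break the complex filter for the surviving members, as intended)
  cx_pool <- setdiff(gids, dup)
  n_cx <- spec$n_complexes + spec$n_rna_complexes
  cx_members <- list()
  if (n_cx > 0L) {
    sizes <- sample(spec$complex_size_range[1]:spec$complex_size_range[2],
                    n_cx, replace = TRUE)
    avail <- sample(cx_pool)
    take <- 0L
    for (i in seq_len(n_cx)) {
      cx_members[[i]] <- avail[(take + 1L):(take + sizes[i])]
      take <- take + sizes[i]
    }
  }
  rna_ids <- if (spec$n_rna_complexes > 0L)
    sprintf("rr%02d", seq_len(spec$n_rna_complexes)) else character()

  # ---- source genome ----------------------------------------------------
  paralog_of <- dup[dup_mode == "source-paralog"]
  src_order <- gids
  families <- character()
  src_extra <- list()
  for (g in paralog_of) {
    pg <- paste0(g, "-par"); pp <- paste0(pids[[g]], "-par")
    src_order <- insert_at(src_order, pg, sample(length(src_order) + 1L, 1L))
    src_extra[[pg]] <- pp
    families[c(g, pg)] <- g
  }
  src_order <- c(src_order, rna_ids)

  src_widths <- c(setNames(as.integer(3L * lens + 3L), gids),
                  if (length(paralog_of))
                    setNames(as.integer(3L * lens[paralog_of] + 3L),
                             paste0(paralog_of, "-par")),
                  setNames(rep(120L, length(rna_ids)), rna_ids))
  coords <- layout_genes(src_order, src_widths, "chr")

  src_genes <- list(); src_prots <- list()
  mk_source_gene <- function(gid, base, pid) {
    syn <- if (!is.na(gsyns[[base]])) gsyns[[base]] else character()
    go <- lapply(seq_along(go_sets[[base]]), function(k) {
      code <- if (curated[[base]] && k == 1L) "IDA"
      else if (curated[[base]] && runif(1) < 0.3) "TAS" else "IEA"
      go_annotation(go_sets[[base]][k], code)
    })
    ev <- if (curated[[base]]) "IDA" else character()
    list(gene = gene_record(gid, "chr", coords[[gid]][["start"]],
                            coords[[gid]][["end"]],
                            strand = sample(c("+", "-"), 1L),
                            name = gnames[[base]], synonyms = syn,
                            product = pid, evidence = character()),
         protein = protein_record(pid, gid, seqs[[base]],
                                  name = pnames[[base]],
                                  go_annotations = go,
                                  reactions = rxn_sets[[base]],
                                  evidence = ev))
  }
  for (gid in gids) {
    rec <- mk_source_gene(gid, gid, pids[[gid]])
    src_genes[[gid]] <- rec$gene; src_prots[[pids[[gid]]]] <- rec$protein
  }
  for (pg in names(src_extra)) {
    base <- sub("-par$", "", pg)
    rec <- mk_source_gene(pg, base, src_extra[[pg]])
    src_genes[[pg]] <- rec$gene; src_prots[[src_extra[[pg]]]] <- rec$protein
  }
  for (rid in rna_ids)
    src_genes[[rid]] <- gene_record(rid, "chr", coords[[rid]][["start"]],
                                    coords[[rid]][["end"]], strand = "+",
                                    name = sub("rr", "rrs", rid))

  src_rxns <- lapply(rxn_pool, function(r)
    reaction_record(r, ec_number = sprintf("%d.%d.%d.%d", sample(6, 1),
                                           sample(20, 1), sample(30, 1),
                                           sample(99, 1))))
  src_cx <- list()
  src_pid_of <- c(pids, setNames(unlist(src_extra) %||% character(),
                                 names(src_extra)))
  for (i in seq_along(cx_members)) {
    cid <- sprintf("CPLX-%02d", i)
    comp <- setNames(sample(1:2, length(cx_members[[i]]), replace = TRUE),
                     unname(src_pid_of[cx_members[[i]]]))
    if (i > spec$n_complexes) {           # RNA-containing complex
      rna <- rna_ids[i - spec$n_complexes]
      comp <- c(comp, setNames(1L, rna))
    }
    src_cx[[cid]] <- complex_record(cid, comp,
                                    name = sprintf("synthetic complex %d", i),
                                    reactions = sample(rxn_pool, 1L))
  }

  source_db <- new_pgdb("SRC-PGDB",
                        replicons = list(replicon_record("chr", "circular",
                                                         src_order)),
                        genes = src_genes, proteins = src_prots,
                        complexes = src_cx, reactions = src_rxns,
                        provenance = list(generator = "pgdbprop synthgen",
                                          seed = spec$seed))

  # ---- target genome ----------------------------------------------------
  tid <- function(g) paste0("t", g)

  kept <- setdiff(gids, lost)
  tgt_order <- vapply(kept, tid, character(1))
  truth_map <- setNames(gids, vapply(gids, tid, character(1)))[tgt_order]
  events <- setNames(vector("list", length(tgt_order)), tgt_order)

  for (g in dup) {
    if (dup_mode[[g]] == "target-copy") {
      cp <- paste0(tid(g), "-dup")
      tgt_order <- insert_at(tgt_order, cp, sample(length(tgt_order) + 1L, 1L))
      truth_map[[cp]] <- g
      events[[cp]] <- c(events[[cp]], "duplicated")
      events[[tid(g)]] <- c(events[[tid(g)]], "duplicated")
      families[c(g, tid(g), cp)] <- g
    } else {
      # source-paralog mode: relocate the single target copy
      tgt_order <- setdiff(tgt_order, tid(g))
      tgt_order <- insert_at(tgt_order, tid(g),
                             sample(length(tgt_order) + 1L, 1L))
      events[[tid(g)]] <- c(events[[tid(g)]], "duplicated-ambiguous",
                            "relocated")
      families[tid(g)] <- g
    }
  }

  # inversions: reverse non-overlapping blocks of 3-6 genes
  if (spec$n_inversions > 0L && length(tgt_order) >= 8L) {
    used <- rep(FALSE, length(tgt_order))
    for (k in seq_len(spec$n_inversions)) {
      blen <- sample(3:6, 1L)
      starts <- which(!vapply(seq_len(length(tgt_order) - blen + 1L),
                              function(s) any(used[s:(s + blen - 1L)]),
                              logical(1)))
      if (!length(starts)) break
      s <- sample(rep(starts, 2L), 1L)   # rep() guards length-1 sample()
      idx <- s:(s + blen - 1L)
      tgt_order[idx] <- rev(tgt_order[idx])
      used[idx] <- TRUE
      for (g in tgt_order[idx]) events[[g]] <- c(events[[g]], "inverted")
    }
  }
  t_rna <- vapply(rna_ids, tid, character(1))
  tgt_order <- c(tgt_order, t_rna)

  # sequences: exact copies within duplication families, mutated otherwise
  tgt_seq <- list()
  for (tg in setdiff(tgt_order, t_rna)) {
    base <- truth_map[[tg]]
    tgt_seq[[tg]] <- if (base %in% dup) seqs[[base]]
    else mutate_seq(seqs[[base]], spec$substitution_rate, spec$indel_rate,
                    spec$indel_mean_length)
    rel <- abs(nchar(tgt_seq[[tg]]) - lens[[base]]) /
      max(nchar(tgt_seq[[tg]]), lens[[base]])
    if (rel > 0.10)
      events[[tg]] <- c(events[[tg]], "diverged-beyond-length-threshold")
  }

  tgt_widths <- setNames(c(as.integer(3L * vapply(tgt_seq, nchar, integer(1)) + 3L),
                           rep(120L, length(t_rna))),
                         c(names(tgt_seq), t_rna))
  tcoords <- layout_genes(tgt_order, tgt_widths, "chr")

  tgt_genes <- list(); tgt_prots <- list()
  for (tg in setdiff(tgt_order, t_rna)) {
    base <- truth_map[[tg]]
    keep_name <- runif(1) >= spec$name_dropout
    if (!keep_name) events[[tg]] <- c(events[[tg]], "name-dropped")
    vague <- runif(1) < spec$vague_name_rate
    prod_name <- if (vague) {
      events[[tg]] <- c(events[[tg]], "name-degraded")
      sample(c(UNKNOWN_NAME_POOL, VAGUE_NAME_POOL), 1L)
    } else pnames[[base]]
    spurious <- runif(1) < spec$spurious_reaction_rate
    rxns <- if (spurious) {
      events[[tg]] <- c(events[[tg]], "spurious-reactions")
      sample(decoy_pool, sample(1:2, 1L))
    } else rxn_sets[[base]]
    cur <- runif(1) < spec$target_evidence_fraction
    if (cur) events[[tg]] <- c(events[[tg]], "target-curated")
    pid <- paste0("t", unname(src_pid_of[[base]]),
                  if (endsWith(tg, "-dup")) "-dup" else "")
    tgt_genes[[tg]] <- gene_record(tg, "chr", tcoords[[tg]][["start"]],
                                   tcoords[[tg]][["end"]],
                                   strand = sample(c("+", "-"), 1L),
                                   name = if (keep_name) gnames[[base]],
                                   synonyms = if (!is.na(gsyns[[base]]))
                                     gsyns[[base]] else character(),
                                   product = pid)
    tgt_prots[[pid]] <- protein_record(pid, tg, tgt_seq[[tg]],
                                       name = prod_name,
                                       reactions = rxns,
                                       evidence = if (cur) "IDA" else character())
  }
  for (tr in t_rna) {
    base <- sub("^t", "", tr)
    tgt_genes[[tr]] <- gene_record(tr, "chr", tcoords[[tr]][["start"]],
                                   tcoords[[tr]][["end"]], strand = "+",
                                   name = sub("rr", "rrs", base))
    truth_map[[tr]] <- base
  }

  tgt_rxns <- c(src_rxns, lapply(decoy_pool, function(r) reaction_record(r)))
  tgt_cx <- list()
  for (cid in names(src_cx)) {
    comp <- src_cx[[cid]]$components
    base_genes <- vapply(names(comp), function(ref) {
      if (!is.null(src_prots[[ref]])) src_prots[[ref]]$gene else ref
    }, character(1))
    if (any(base_genes %in% lost)) next
    if (runif(1) < spec$complex_dropout) next
    t_comp <- setNames(comp, vapply(names(comp), function(ref) {
      if (!is.null(src_prots[[ref]])) paste0("t", ref) else tid(ref)
    }, character(1)))
    tgt_cx[[paste0("t", cid)]] <- complex_record(paste0("t", cid), t_comp,
                                                 name = src_cx[[cid]]$name,
                                                 reactions = src_cx[[cid]]$reactions)
  }

  target_db <- new_pgdb("TGT-PGDB",
                        replicons = list(replicon_record("chr", "circular",
                                                         tgt_order)),
                        genes = tgt_genes, proteins = tgt_prots,
                        complexes = tgt_cx, reactions = tgt_rxns,
                        provenance = list(generator = "pgdbprop synthgen",
                                          seed = spec$seed,
                                          derived_from = "SRC-PGDB"))

  truth <- list(map = truth_map, events = events, families = families,
                lost = lost, dup_mode = dup_mode, spec = spec)
  structure(list(source = source_db, target = target_db, truth = truth),
            class = "strain_pair")
}

# ---- analytic replay (end-to-end oracle) ---------------------------------

# neighbor lookup used by the replay only; intentionally local so the
# oracle does not call the pipeline's adjacency code
replay_neighbors <- function(db, gid) {
  rep <- db$replicons[[db$genes[[gid]]$replicon]]
  ord <- rep$gene_order; n <- length(ord); i <- match(gid, ord)
  if (rep$topology == "circular") nb <- ord[c((i - 2L) %% n + 1L, i %% n + 1L)]
  else { nb <- ord[c(i - 1L, i + 1L)]; nb <- nb[!is.na(nb)] }
  setdiff(unique(nb), gid)
}

replay_has_explit <- function(db, gid, table = evidence_code_table()) {
  g <- db$genes[[gid]]
  codes <- g$evidence
  if (!is.null(g$product)) {
    p <- db$proteins[[g$product]]
    codes <- c(codes, p$evidence,
               vapply(p$go_annotations, function(a) a$evidence_code,
                      character(1)))
  }
  any(codes %in% c(table$experimental, table$literature) |
        startsWith(codes, "EV-EXP") | startsWith(codes, "EV-AS"))
}

#' Analytic replay of the propagation rules over a generated pair
#'
#' Predicts, for every protein-coding target gene, whether the pipeline
#' should propagate it or reject it (and for which reasons), using only the
#' emitted pair and its ground truth: ortholog candidates come from the
#' truth's duplication families, the synteny and gene-name disambiguation is
#' replayed over the actual gene orders with the truth map as the ortholog
#' relation, and the evidence/length/complex filters are recomputed directly
#' from the annotations and sequences. True ortholog pairs are assumed to
#' pass the P-value filter (the generator's divergence keeps similarity far
#' below that threshold). The replay never invokes the alignment, best-hit
#' or filter code of the pipeline, so it serves as an independent
#' end-to-end oracle.
#'
#' @param pair A `strain_pair` from [generate_pair()].
#' @param config A [prop_config()] (length threshold).
#' @return `data.frame` with columns `target_gene`, `expected_status`
#'   (`"propagated"`/`"rejected"`) and `expected_reason` (canonical reason
#'   label, `NA` when propagated), sorted by gene id.
#' @export
expected_outcomes <- function(pair, config = prop_config()) {
  src <- pair$source; tgt <- pair$target; truth <- pair$truth
  fam <- truth$families

  fam_of <- function(g) if (!is.null(fam[g][[1]]) && !is.na(fam[g][[1]]))
    fam[[g]] else NA_character_
  related <- function(s_gene, t_gene) {
    base <- truth$map[t_gene][[1]] %||% NA_character_
    if (is.na(base)) return(FALSE)
    identical(s_gene, base) ||
      (!is.na(fam_of(s_gene)) && identical(fam_of(s_gene), fam_of(base)))
  }
  # a source gene has a target ortholog iff some target gene maps into its
  # family (or to it directly)
  has_target_ortholog <- function(s_gene) {
    for (tg in names(truth$map))
      if (!is.null(tgt$genes[[tg]]$product) && related(s_gene, tg))
        return(TRUE)
    FALSE
  }

  t_genes <- sort(names(tgt$genes)[vapply(tgt$genes,
                                          function(g) !is.null(g$product),
                                          logical(1))])
  out <- lapply(t_genes, function(tg) {
    base <- truth$map[tg][[1]] %||% NA_character_
    reject <- function(reason)
      data.frame(target_gene = tg, expected_status = "rejected",
                 expected_reason = reason, stringsAsFactors = FALSE)
    if (is.na(base) || base %in% truth$lost) return(reject("no-ortholog"))

    f <- fam_of(base)
    cands <- if (is.na(f)) base
    else sort(names(src$genes)[vapply(names(src$genes), function(g)
      !is.na(fam_of(g)) && identical(fam_of(g), f) &&
        !is.null(src$genes[[g]]$product), logical(1))])

    chosen <- cands[1]
    if (length(cands) > 1L) {
      syn_ok <- vapply(cands, function(sg) {
        s_fl <- Filter(function(g) !is.null(src$genes[[g]]$product),
                       replay_neighbors(src, sg))
        t_fl <- Filter(function(g) !is.null(tgt$genes[[g]]$product),
                       replay_neighbors(tgt, tg))
        for (a in s_fl) for (b in t_fl) if (related(a, b)) return(TRUE)
        FALSE
      }, logical(1))
      if (sum(syn_ok) == 1L) chosen <- cands[syn_ok]
      else if (sum(syn_ok) > 1L) return(reject("ambiguous-ortholog"))
      else {
        t_name <- tgt$genes[[tg]]$name
        nm <- if (is.null(t_name)) logical(length(cands))
        else vapply(cands, function(sg)
          identical(src$genes[[sg]]$name, t_name), logical(1))
        if (sum(nm) == 1L) chosen <- cands[nm]
        else return(reject("ambiguous-ortholog"))
      }
    }

    failed <- character()
    if (replay_has_explit(tgt, tg)) failed <- c(failed, "target_evidence")
    if (!replay_has_explit(src, chosen)) failed <- c(failed, "source_evidence")
    len_s <- nchar(src$proteins[[src$genes[[chosen]]$product]]$sequence)
    len_t <- nchar(tgt$proteins[[tgt$genes[[tg]]$product]]$sequence)
    if (abs(len_s - len_t) / max(len_s, len_t) > config$length_threshold)
      failed <- c(failed, "length")
    # complex completeness over the source's heteromultimeric complexes
    s_pid <- src$genes[[chosen]]$product
    for (cid in names(src$complexes)) {
      comp <- names(src$complexes[[cid]]$components)
      if (!s_pid %in% comp || length(comp) < 2L) next
      for (ref in setdiff(comp, s_pid)) {
        if (is.null(src$proteins[[ref]])) { failed <- c(failed, "complex"); break }
        if (!has_target_ortholog(src$proteins[[ref]]$gene)) {
          failed <- c(failed, "complex"); break
        }
      }
    }
    failed <- unique(failed)
    if (length(failed)) reject(failure_reason(failed))
    else data.frame(target_gene = tg, expected_status = "propagated",
                    expected_reason = NA_character_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a pair together with its expected per-gene outcomes
#'
#' Convenience wrapper combining [generate_pair()] and the independent
#' analytic replay [expected_outcomes()].
#'
#' @param spec A [strain_pair_spec()].
#' @param config A [prop_config()].
#' @return The `strain_pair` with an extra element `expected`.
#' @export
generate_pair_with_expected_outcomes <- function(spec, config = prop_config()) {
  pair <- generate_pair(spec)
  pair$expected <- expected_outcomes(pair, config)
  pair
}

#' Write a generated pair to disk
#'
#' Emits `source.json`, `target.json`, `source.fasta`, `target.fasta` and
#' `truth.json` into a directory.
#'
#' @param pair A `strain_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pgdb(pair$source, file.path(dir, "source.json"))
  write_pgdb(pair$target, file.path(dir, "target.json"))
  write_proteome_fasta(pair$source, file.path(dir, "source.fasta"))
  write_proteome_fasta(pair$target, file.path(dir, "target.fasta"))
  tr <- pair$truth
  write_json_file(list(
    map = lapply(as.list(tr$map), j_str),
    events = lapply(tr$events, function(e) as.character(e %||% character())),
    families = lapply(as.list(tr$families), j_str),
    lost = as.character(tr$lost),
    seed = j_int(tr$spec$seed)), file.path(dir, "truth.json"))
  invisible(dir)
}
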