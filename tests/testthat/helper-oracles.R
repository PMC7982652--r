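# Independent oracles, implemented by exhaustive enumeration so they stay
# structurally unlike the code paths they check.

# best hits per query by a literal scan over all rows
oracle_best_hits <- function(df, cutoff = 1e-3) {
  out <- list()
  for (q in sort(unique(df$query))) {
    rows <- df[df$query == q, , drop = FALSE]
    m <- min(rows$evalue)
    if (m < cutoff) out[[q]] <- sort(unique(rows$subject[rows$evalue == m]))
  }
  out
}

# exhaustive double loop over all (query, subject) combinations
oracle_bbh <- function(fwd, rev, cutoff = 1e-3) {
  as <- sort(unique(fwd$query)); bs <- sort(unique(rev$query))
  fwd_by_q <- split(fwd, fwd$query); rev_by_q <- split(rev, rev$query)
  src <- character(); tgt <- character(); ef <- numeric(); er <- numeric()
  for (a in as) for (b in bs) {
    fa <- fwd_by_q[[a]]; rb <- rev_by_q[[b]]
    e_ab <- fa$evalue[fa$subject == b]
    e_ba <- rb$evalue[rb$subject == a]
    if (!length(e_ab) || !length(e_ba)) next
    if (e_ab == min(fa$evalue) && e_ab < cutoff &&
        e_ba == min(rb$evalue) && e_ba < cutoff) {
      src <- c(src, a); tgt <- c(tgt, b); ef <- c(ef, e_ab); er <- c(er, e_ba)
    }
  }
  df <- data.frame(source_protein = src, target_protein = tgt,
                   e_forward = ef, e_reverse = er,
                   p_value = (ef + er) / 2, stringsAsFactors = FALSE)
  df[order(df$source_protein, df$target_protein), , drop = FALSE]
}

# random hit-table pair over two id sets; coarse E-value grid makes exact
# ties (including at the minimum and at the cutoff boundary) common
random_hit_fixture <- function(n_a, n_b) {
  a_ids <- sprintf("a%02d", seq_len(n_a))
  b_ids <- sprintf("b%02d", seq_len(n_b))
  mk <- function(qs, ss, direction) {
    q <- character(); s <- character(); e <- numeric()
    for (qq in qs) for (ss2 in ss) {
      if (runif(1) < 0.35) {
        q <- c(q, qq); s <- c(s, ss2)
        e <- c(e, 10^(-sample(0:25, 1L)))
      }
    }
    hit_table(q, s, e, bitscore = -log10(e + 1e-300), direction = direction)
  }
  list(fwd = mk(a_ids, b_ids, "forward"), rev = mk(b_ids, a_ids, "reverse"))
}

# exhaustive 2x2 flank-combination synteny check
oracle_synteny <- function(source_db, target_db, s_gene, t_gene, pairs) {
  flanks <- function(db, gid) {
    rep <- db$replicons[[db$genes[[gid]]$replicon]]
    ord <- rep$gene_order; i <- match(gid, ord); n <- length(ord)
    idx <- if (rep$topology == "circular") c((i - 2L) %% n + 1L, i %% n + 1L)
    else c(i - 1L, i + 1L)
    idx <- idx[idx >= 1L & idx <= n]
    setdiff(unique(ord[idx]), gid)
  }
  found <- FALSE
  for (sn in flanks(source_db, s_gene)) for (tn in flanks(target_db, t_gene)) {
    sp <- source_db$genes[[sn]]$product
    tp <- target_db$genes[[tn]]$product
    if (is.null(sp) || is.null(tp)) next
    if (any(pairs$source_protein == sp & pairs$target_protein == tp))
      found <- TRUE
  }
  found
}
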