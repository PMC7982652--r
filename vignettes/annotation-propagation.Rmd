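---
title: "Ortholog-based propagation of curated annotations between strain databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-based propagation of curated annotations between strain databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgdbprop)
```

## The problem

Manual curation of an annotated genome database is slow and expensive, so it
is typically concentrated on a single gold-standard strain while databases
for hundreds of related strains remain at the quality of their original
automated annotation. Those automated annotations carry characteristic
defects: missing or outdated gene names, vague product descriptions
("hypothetical protein", "MFS transporter"), spurious or missing reaction
assignments, and no protein complexes. Because strains of one species are
phylogenetically close, most of the curated knowledge for one strain applies
verbatim to its orthologs in the others — provided the transfer is gated
carefully enough that it cannot overwrite correct information or launder
computational guesses into apparent facts.

`pgdbprop` implements such a curation-propagation method as a reusable
library plus a small command-line tool. It is deliberately conservative:
when in doubt about the right source gene for a target, it propagates
nothing at all.

## The method

### Ortholog mapping

Orthologs are operationalized as **best bidirectional hits (BBH)** between
the two proteomes. For a source protein $A$ and target proteome $P_B$, the
best hits of $A$ are all subjects achieving the minimal E-value among $A$'s
hits, provided that minimum is strictly below the cutoff (default
$10^{-3}$). Ties are retained — they are real, arising from exact gene
duplications — so a protein can participate in several pairs. $(A, B)$ is an
ortholog pair iff $B$ is among $A$'s best forward hits **and** $A$ is among
$B$'s best reverse hits. Paralogs are never called, and RNA genes never
participate (they have no protein product).

Each pair carries a similarity $P$-value defined as the arithmetic mean of
its two E-values,

$$P = \frac{E_{\mathrm{fwd}} + E_{\mathrm{rev}}}{2},$$

which the filters below test against a configurable threshold.

E-values are compared **exactly as parsed**, with no epsilon. Search engines
print coarse E-values, so exact ties are genuine; an epsilon would turn the
tie semantics into an arbitrary clustering.

### Disambiguation: synteny, then gene name

When a target protein maps to several source candidates, the method tries to
pick a single best one:

1. **Synteny (preferred).** A candidate pair $(S, T)$ passes if the product
   of either of the two genes directly adjacent to $S$ is an ortholog of the
   product of either of the two genes directly adjacent to $T$. Adjacency is
   taken from each replicon's gene order (strand-agnostic, wrapping on
   circular replicons, never across replicons); neighbors without protein
   products are skipped. Exactly one passing candidate wins.
2. **Gene name.** Only if *no* candidate passes synteny, candidates whose
   source gene name equals the target's name exactly (case-sensitive,
   primary names only) are considered; exactly one match wins.
3. Otherwise the target is **rejected as ambiguous**.

Two design points were genuinely open and are resolved here as follows. A
*multi-way* synteny pass rejects rather than falling back to names: the name
test is specified as a fallback for zero synteny passes, and no stated
discriminator exists between two syntenic candidates, so the conservative
reading wins. Synonyms are ignored in the name test because they are noisy
and directional; only primary names are compared.

### The five quality filters

All five filters are always evaluated for a resolved pair, so
single-versus-multiple failure statistics stay available:

| filter | passes when | default |
|---|---|---|
| target evidence | the target gene, its product and the product's GO annotations carry **no** experimental or literature-based evidence code (prior curation must not be overwritten) | scope: gene + protein + GO |
| source evidence | the source side **does** carry an experimental or literature-based code (no transitive annotation errors) | — |
| P-value | $P \le$ threshold (inclusive: "must not exceed") | $10^{-10}$ |
| length | $\lvert \mathrm{len}_S - \mathrm{len}_T \rvert / \max(\mathrm{len}_S, \mathrm{len}_T) \le$ threshold (inclusive) | 10 % |
| complex | if $S$ belongs to a heteromultimeric complex (directly or through sub-complexes), every other protein component has at least one ortholog pair; any RNA component fails outright | — |

The length denominator is the **longer** sequence: the rule itself names
only a percentage, and the max denominator is the symmetric, conservative
reading (it flags slightly more pairs than a min denominator would). Complexes are excluded from the target-side evidence scan by default
because uncurated targets essentially never carry curated complexes; the
scope is configurable.

Evidence codes are classified by a shipped, overridable table: the GO
experimental set (`EXP IDA IPI IMP IGI IEP HTP HDA HMP HGI HEP`), a
literature set (`TAS IC NAS`), the computational set (`IEA ISS ISO ...`),
and BioCyc-style codes by prefix (`EV-EXP*`, `EV-AS*`, `EV-COMP*`). Unknown
codes degrade to computational (never upward) and are logged once per code.

### What is propagated, and how

Only attributes unlikely to be strain-specific cross over: gene name and
synonyms, product name and synonyms, GO terms, reaction assignments, and
heteromultimeric complex membership (with the complex's reactions). Kinetic
data, regulation and textual summaries never do; instead the source gene id
is stored on the target gene (`propagated_from`) so a renderer can display
the source's summary alongside.

* **Names.** The target takes the source's primary name; a displaced target
  name is demoted to a synonym rather than discarded, and source synonyms
  are unioned in. A primary name never appears among the synonyms, and an
  absent source name never blanks an existing target name.
* **GO terms.** Only source terms with an *experimental* evidence code are
  transferred — unless the two sequences are identical (exact string
  equality after normalization), in which case all terms transfer. Every
  transferred term gets evidence code `ISO` with a `with_ref` to the source
  protein. Terms the target already holds are deduplicated by term id.
* **Reactions.** Full **replacement**, not union: the target's assignment
  set becomes exactly the source's. Replacement is the only semantics that
  can express the removal of spurious assignments (a mis-annotated
  transport reaction) as well as the addition of secondary activities.
  Reaction records missing from the target database are created from the
  source's.
* **Complexes.** Each heteromultimeric source complex is instantiated in
  the target with components mapped through the ortholog map, preserving
  stoichiometry, plus the complex's reactions and name. The operation is
  idempotent: an existing target complex with the same mapped component
  multiset is reused.

An attribute counts as propagated only when the new value actually differs
from the old one. Every change is recorded in a structured **history
record** (source gene, changed fields, prior values, timestamp) embedded in
the output database; `format_history_note()` renders the human-readable
note.

### The report

Every run produces a three-part report: (a) summary statistics, (b) the
fields propagated for each propagated protein, and (c) the reason each
remaining protein was not propagated — `no-ortholog`, `ambiguous-ortholog`,
a single filter name, or `multiple:<sorted failing set>` recorded once per
gene so single- versus multi-filter failures partition cleanly. A
function-name classifier (case-insensitive regex lists, shipped as editable
data) grades product names as *unknown* ("hypothetical protein", "orf"),
*vague* ("transporter", "oxidoreductase", "regulatory protein") or
*specific*, and the report counts **function upgrades**: propagated proteins
whose name class improved from unknown/vague to specific.

## Similarity backends and numerical choices

External 12-column tabular hits (`load_tabular_hits()`) are the fidelity
path; multiple HSPs per pair are reduced to the minimal-E-value row (ties by
bit score). The built-in aligner (`align_all_vs_all()`) is a desk-scale
substitute: Smith–Waterman local alignment (BLOSUM62, gap open 11 / extend
1) with raw scores converted through the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ using the standard gapped-BLOSUM62 parameters
$K = 0.041$, $\lambda = 0.267$, $m$ the query length and $n$ the summed
subject lengths (no edge correction). Parity with an external engine's
E-values is *not* promised — only rank behavior within a query. A
shared-4-mer seed prefilter skips subject sequences that could not reach the
reporting range anyway (two random 200-residue sequences share $\ge 2$
distinct 4-mers only a few percent of the time, and an unseeded pair's best
possible E-value sits orders of magnitude above the $10^{-3}$ cutoff);
sequences shorter than 8 residues bypass the prefilter. Output is
deterministic and invariant under input order.

Other numerical choices: the BBH cutoff is strict (`<`), both filter
thresholds are inclusive (`<=`); all collections are sorted by id and JSON
serialization is canonical (fixed key order, empty optionals omitted, full
numeric precision), so identical runs produce byte-identical outputs; the
history-note timestamp defaults to the run's UTC date and can be pinned via
`prop_config(timestamp =)` for reproducible pipelines.

## The synthetic strain-pair generator

Real inputs for this method are proprietary curated databases, so the
package ships a first-class generator (`generate_pair()`) that emulates the
study design: a curated source genome (specific product names, GO terms
with experimental codes on a configurable fraction of genes — default 0.65,
matching the roughly two-thirds of a well-curated genome that carries
experimental evidence — reactions, heteromultimeric complexes, optionally
with RNA components) and a target derived from it by seeded events: gene
loss, duplication, per-residue substitution, indels, local inversions, gene
name dropout, product-name degradation to unknown/vague boilerplate,
spurious decoy reactions, and full curation stripping (no GO, no evidence
codes).

Duplications come in two modes, equally likely per event. *Target-copy*
leaves one source gene with two target copies; each copy has a unique
source candidate and both may propagate. *Source-paralog* gives the source
an identical paralog while the single target copy is relocated; neither
candidate then usually passes synteny and the shared gene name cannot
discriminate, so the expected outcome is rejection as ambiguous — unless
the relocation happens to land the gene back in a syntenic spot, in which
case resolution by synteny is the correct outcome. Duplicated sequences are
exact copies (the classic tie case), and duplicated genes are excluded from
complexes so component mapping stays single-valued.

`expected_outcomes()` replays the propagation rules *analytically* over the
emitted pair: candidates come from the truth's duplication families, the
synteny/name decision is recomputed from the actual gene orders with the
truth map as the ortholog relation, and the evidence, length and complex
filters are recomputed directly from the annotations and sequences. It
never calls the alignment, best-hit, filter or propagation code, so it
serves as an independent end-to-end oracle. Its one assumption is that true
ortholog pairs pass the P-value filter; the generator guarantees the margin
structurally (minimum protein length 120 residues, deletions truncate at
most half a protein), keeping every true pair's E-value many orders of
magnitude below $10^{-10}$.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: amino-acid composition and substitution-matrix
structure (sequences are uniform-background; only the rank structure of
similarity matters for BBH), phylogenetic or codon-level realism, horizontal
transfer and mobile elements, pseudogenes and partial gene models, biased
annotation error modes of real pipelines, and multi-replicon genomes.
Conclusions about real strain collections must rest on external hit tables
from a production search engine and real curated inputs.

## Validation scale

The shipped tests and the acceptance script run the whole method at desk
scale, chosen so the full suite completes in well under a minute of compute
per property: 100 random hit-table fixtures (up to 50 proteins a side) for
the BBH-versus-enumeration check, clone genomes of 40 genes for the
identity run, 20 seeded 40-gene strain pairs (~780 per-gene decisions) for
pipeline-versus-replay agreement, and a 60-gene study-style pair for the
attribute statistics. The properties being checked are size-independent;
the sizes are a compute choice, not a methodological one.

## Known limitations

* The built-in aligner is for fixtures and small genomes; real proteomes
  should come with externally computed hit tables.
* PGDB-lite JSON is the only native format; importing GenBank/GFF or a
  production database export requires external conversion.
* Pathway re-inference after reaction updates is out of scope; the output
  database is the natural input for a downstream pathway predictor (run it
  after `run_propagation()` — the reaction complement is final at that
  point).
* Complexes containing RNA components are never propagated and their
  protein members are always rejected by the complex filter; no workaround
  is attempted, matching the method's conservative stance.

## A worked micro-example

```{r example, eval = FALSE}
library(pgdbprop)

spec <- strain_pair_spec(n_genes = 30, source_evidence_fraction = 0.8,
                         name_dropout = 0.4, vague_name_rate = 0.3,
                         spurious_reaction_rate = 0.25, n_complexes = 2,
                         complex_dropout = 1, seed = 101)
pair <- generate_pair(spec)
run <- run_propagation(pair$source, pair$target,
                       prop_config(timestamp = "2026-03-01"))
print(run$report)
cat(format_history_note(run$target$propagation_records[[1]]), "\n")
write_report(run$report, "report")
```
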