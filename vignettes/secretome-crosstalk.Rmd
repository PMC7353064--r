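---
title: "Secretome, surfaceome and crosstalk prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secretome, surfaceome and crosstalk prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretalk)
```

This vignette is the package's own account of the methods it implements:
the classification rules and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate, the
numerical and design choices made where the procedure was genuinely
open, and the known limitations.

## The classification model

All cross-dataset operations key on the **canonical gene symbol**
(uppercased, trimmed). Accessions are carried as provenance only, and
duplicate accessions mapping to one symbol collapse to one record, so a
"proteome" here is a set of unique symbols per tissue. This matches how
heterogeneous proteomics lists are usually reconciled, at the cost of
conflating genuinely distinct isoforms that share a symbol.

### Secretome: two disjoint routes

The classical route models export through the endoplasmic
reticulum/Golgi, marked by an N-terminal signal peptide. A protein
qualifies when, simultaneously:

* it has **no transmembrane segment** (α-helix count + β-barrel count
  = 0) — single-pass and multi-pass membrane proteins also carry signal
  anchors and would otherwise flood the call set;
* its SignalP-style discrimination score satisfies **D > 0.5**, a
  *strict* inequality (a protein at exactly 0.5 is negative); and
* its TargetP **reliability class RC ≤ 2** on the 1–5 scale
  (1 = most reliable).

The non-classical route captures signal-peptide-independent export:
TargetP class **"other"** (neither secretory-signal nor mitochondrial),
**RC ≤ 2**, and **at least one GO annotation under an extracellular
root**. It is evaluated *only on classical-route negatives*, so the two
call sets are disjoint and the secretome size is exactly the sum of the
route counts.

Two readings in these rules were genuinely open and are worth spelling
out. First, the "TargetP score ≤ 2" criterion is interpreted as the
reliability class RC ∈ {1, 2}: RC is the only 1–5 integer quantity
TargetP emits, and a bound of "≤ 2" is only meaningful on a scale where
lower is better. Second, "other secretory pathway" is read as TargetP
location class "other": proteins on this route lack signal peptides by
construction, so the secretory-signal class cannot be required. The
TargetP class "S" is deliberately *not* required for the classical
route; the stated criteria (noTM, D-score, RC) are applied literally.
UniProt subcellular-location strings, when supplied, are recorded as
corroborating evidence but never required — they are curated text, not
a predictor output, and making them mandatory would silently penalize
poorly annotated proteins.

Proteins whose feature rows are missing are reported in a dedicated
*unevaluated* list rather than silently counted as negatives, so the
accounting `secretome + negatives + unevaluated = proteome` always
holds.

### The ontology predicates

"Related to an extracellular location" is operationalized as *reflexive
`is_a` descendant* of {extracellular region `GO:0005576`, extracellular
space `GO:0005615`, extracellular exosome `GO:0070062`} — configurable,
since no canonical term list exists for this notion. Likewise the
plasma-membrane predicate accepts `GO:0005886` or any `is_a` descendant,
because annotation practice places proteins on specific children
("external side of plasma membrane") rather than the root; a
strict-exact mode (`plasma_membrane_exact = TRUE`) is available. Only
`is_a` edges are traversed. `part_of` would arguably widen both
predicates (e.g. terms that are parts of the plasma membrane), and its
omission is a documented limitation rather than a claim of correctness.
The ancestor closure is precomputed in topological order at DAG
construction, which also serves as the acyclicity check.

### Surfaceome: feature rules union atlas

The feature rule is a conjunction: an *anchoring feature* (≥ 1
transmembrane α-helix or β-barrel, or a GPI anchor) **and** the
plasma-membrane annotation. Either alone is insufficient — a TM helix
may thread an internal membrane, and a bare plasma-membrane annotation
may describe peripheral association with no exposed residue. The second
strategy intersects the tissue proteome with a reference **atlas**
compendium merged from contributed cell-surface gene lists
(deduplicated, with per-symbol source provenance). The final call set is
the union; each call records its basis, and the predicted-vs-atlas Venn
partition is attached for reporting. Membership never depends on basis
ordering.

### Crosstalk networks

Interaction records are filtered in a fixed order, and each rejected
record is tallied by the *first* filter it fails: self-interaction →
compartment (one endpoint secreted in A, the other surface in B) →
experimental evidence → tissue expression. Retained pairs are oriented
`secreted → surface` (the ligand→receptor reading) even though the
underlying records are unordered; a pair satisfiable in both
orientations yields one edge per orientation, deduplicated. Evidence
classes are derived from the PSI-MITAB detection-method text through a
keyword table (prediction/inference vocabulary → `predicted`; empty or
unspecified → `unknown`; otherwise `experimental`), because interaction
databases encode "proven by experiment" in free vocabulary rather than
a flag; the table is an argument of `read_mitab()` and can be replaced.
Expression lookups answer `TRUE`/`FALSE`/`NA` and never throw; an `NA`
(unknown) endpoint passes with a warning under the default policy and is
dropped under `unknown_expression = "drop"`. The permissive default
reflects that expression catalogues are incomplete, whereas a `FALSE` is
a positive claim of absence and always rejects the edge.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `signalp_threshold` | 0.5 | D-score in (0,1), strict `>` | classical route |
| `targetp_rc_max` | 2 | RC, 1–5 | both secretion routes |
| `bh_alpha` | 0.01 | adjusted p | enrichment reporting |
| `min_annotated` | 2 | proteins | enrichment reporting |
| `extracellular_roots` | 0005576/0005615/0070062 | GO ids | non-classical route |
| `plasma_membrane_root` | GO:0005886 | GO id | surfaceome rule |
| `require_experimental_ppi` | TRUE | — | crosstalk filter |
| `require_expression_check` | TRUE | — | crosstalk filter |
| `unknown_expression` | "pass" | pass/drop | unknown-endpoint policy |
| `signalp_sensitivity_cutoff` | 0.34 | D-cutoff | metadata only |

Every numeric criterion lives in `criteria_config()`; no stage hard-codes
a threshold. `signalp_sensitivity_cutoff` records the cleavage-site
sensitivity setting of the upstream signal-peptide predictor; it is
deliberately *not* applied as a classification threshold — the
classification bound is the explicit `D > 0.5`.

## Enrichment statistics

Over-representation of a study set against a background is tested with
the upper-tail hypergeometric probability `P(X ≥ k)` for
`X ~ Hypergeom(N, K, n)` — equivalently a one-tailed Fisher exact test —
computed via `stats::phyper()` in stable log-space. Adjustment uses
Benjamini–Hochberg step-up over *all* terms tested in one run (not per
GO namespace), since a single adjusted threshold is applied to the
report. Reported terms must satisfy `p_BH < 0.01` **and** annotate ≥ 2
study proteins; the unfiltered table is kept as an attribute. The
background defaults to every symbol in the annotation file and is
overridable. Annotations propagate to `is_a` ancestors when a DAG is
supplied (the true-path rule). The test suite validates the tail
against exhaustive enumeration of all urns with `N ≤ 12`, the adjustment
against a brute-force step-up oracle, and the empirical type-I rate
under the null against `α + 3·SE` over 2000 simulated studies.

## The synthetic-data generator

`generate_bundle()` emits a complete, internally consistent input
bundle: two tissue proteomes with a configurable overlap, a feature
table, GAF and mini-ontology, an atlas, two PPI tables with planted
true edges and decoys, an expression table, and an ortholog map —
together with a ground-truth manifest. Design points:

* **Planted classes are exact, not probabilistic.** Each symbol belongs
  to exactly one class (classical, non-classical, surface-TM,
  surface-GPI, background), and its features are sampled *uniformly from
  the region satisfying exactly that class's criteria* (e.g. classical
  D-scores from U(0.51, 0.99), background from U(0, 0.5)), so boundaries
  are exercised and the deterministic classifiers must recover the
  planted memberships exactly for every seed. Any misclassification is a
  bug, never noise.
* **Default dimensions** mirror the fetal bovine study conditions: 750
  adipose and 531 muscle proteins, with route fractions (9% classical,
  2.5% non-classical) chosen so the planted secretomes land near the
  published tallies, a 30% cross-tissue overlap, and a few planted
  crosstalk edges per direction. Unit tests scale `n_proteins` down to
  60–130 per tissue, a size chosen to keep planted counts per class
  comfortably non-zero while the full suite stays fast.
* **Decoy soundness.** Every decoy PPI record violates exactly one
  filter (predicted-only evidence, both endpoints in the same
  compartment, or a non-member endpoint), and the manifest records the
  expected rejection reason, which tests verify verbatim.
* **Namespace hygiene.** Generated symbols use a reserved `SYN` prefix
  so synthetic data can never collide with published gene symbols.
* **Determinism.** The same spec yields byte-identical on-disk bundles;
  generation saves and restores the caller's RNG state.

What the generator does *not* emulate: protein abundances, missing or
contradictory predictor rows (real SignalP/TargetP outputs disagree near
their decision boundaries), annotation noise and evidence-code
stratification in GAFs, isoform-level identifiers, or the heavy-tailed
degree distribution of real interaction databases. Passing the planted
recovery tests therefore demonstrates that the *rules* are implemented
exactly, not that the rules are robust to noisy real-world inputs.

## Reference fixtures

The packaged fixtures encode the published fetal bovine gene lists: the
77 classical-route and 22 non-classical-route proteins with their
tissue memberships, the crosstalk endpoint names for both directions,
and the per-tissue surfaceome cardinalities (7 predicted / 21 atlas / 26
union for adipose; 4 / 11 / 13 for muscle). Three constructions deserve
explicit flags:

* The **predicted-vs-atlas overlap** per tissue is not published; the
  value 2 is forced by inclusion–exclusion on the published counts
  (7 + 21 − 26 and 4 + 11 − 13), and the overlap identities are set to
  PSMC1 and F3, the two proteins reported as feature-predicted in both
  tissues. Derived, not observed.
* The **11-edge muscle→adipose pairing** is constructed: only the 9 + 7
  endpoint names and three narrative links (HPX–CDC42, PLG–ENO1,
  APOA1–KRT1) are published. The planted pairing includes HPX–CDC42 and
  covers all 16 endpoints. The APOA1–KRT1 attribution of the
  adipose→muscle direction is likewise inferred (PLG–ENO1 being the
  directly supported link).
* Where no member identity was published (atlas fillers, decoy
  proteins), names use the `SYN` synthetic namespace.

One quirk preserved deliberately: the non-classical adipose column of
the source lists prints `SPET5` where the accompanying text discusses
`SEPT5`; the fixture encodes the printed list verbatim, since fixtures
promise fidelity to the published table rather than to its probable
intent.

The compendium counts themselves (750/531 unique proteins merged from
the new and previously published lists) are reproduced only as
properties of `merge_proteomes()` — the per-study overlaps needed for a
count-exact reconstruction were not published. Similarly, the ortholog
translation counts and the enriched-term lists depend on external
database versions (orthology links, GO release, atlas supplements) and
are validated by bookkeeping invariants and statistical properties
rather than exact counts.

## Numerical and degenerate-input choices

* The hypergeometric tail is delegated to `phyper(..., lower.tail =
  FALSE)` rather than summing densities, avoiding cancellation for
  large urns; `k = 0` returns exactly 1.
* BH adjustment preserves input order, caps at 1, and is validated
  against the step-up definition to 1e-12.
* Venn partitions and merges are pure set operations on canonical
  symbols; empty sets are legal everywhere.
* DAG construction fails fast on cycles (naming an offending edge) and
  on undefined parents; a term is always its own ancestor.
* Ties in enrichment output are broken by term id after adjusted p, so
  output order is total and reproducible.
* Readers default to strict mode; lenient mode skips malformed rows,
  warns, and exposes the skipped count so `records + skipped = rows`
  is checkable.

## Interface

The package is function-first: `run_pipeline()` chains all stages over
an input bundle (in-memory or a directory of standard-format files) and
returns a report whose counts are recomputable from the stage outputs;
each stage is independently callable, and `scripts/acceptance.R` is a
thin script over the installed package that recomputes the headline
numbers. No shell subcommand layer is shipped — users of an analysis
package like this one work from R.
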