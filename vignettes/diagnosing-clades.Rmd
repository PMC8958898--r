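---
title: "Diagnosing clades with genomic DNA characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing clades with genomic DNA characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxodiag)
```

## The problem

Genomic revisions of taxa — increasingly built on whole-genome shotgun data
from fresh and museum specimens, including century-old primary types — need
taxon diagnoses that other workers can check against sequence data. The
practical currency for such diagnoses is the position-level **diagnostic
character**: an alignment position where every member of a clade carries one
base while essentially all other specimens carry another. `taxodiag`
implements the discovery, ranking, verification and reporting of such
characters from annotated multi-locus exon alignments, together with the
COI-barcode divergence summaries and monophyly tests that accompany rank
decisions.

## Character model

All computation happens on an *annotated alignment*: a specimen × column
matrix over `A/C/G/T`, IUPAC ambiguity codes, `N` and `-`, partitioned into
named loci (`cne<scaffold>.<gene>.<exon>` for nuclear exons in the reference
coordinate system; the reserved id `COI` for the mitochondrial barcode
locus). Positions are 1-based within their locus; `N`, `-` and input
ambiguity codes all count as missing data.

A column is diagnostic for a clade (members *M* vs all other specimens *O*)
under these rules, with `f` the allowed outside mismatch fraction
(default 0.05):

* **direct** (`T789C`): all members with data share one state `der`; the
  outside specimens have a modal state `anc != der`; at most `f` of the
  non-missing outsiders deviate from `anc`; and *no* outsider carries `der`.
  The outside modal state is reported as the ancestral state — the notation
  treats the predominant outside base as ancestral.
* **state_only** (`145A`): members are invariant and no outsider carries
  their state, but outside variation is too high for a modal state to pass
  the `f` threshold, so the ancestral state is left unstated.
* **ambiguous** (`T281R`): the clade is polymorphic with exactly two states
  whose IUPAC union is reported as the derived state; no outsider carries
  either member state and the outside modal passes the threshold. Enabled
  only where requested — by default the pipeline allows it on the COI
  barcode, where such characters are conventional, and not in nuclear lists.

Two boundary decisions are worth stating. When no outsider has data at a
column there is nothing to be different from, and the column classifies as
`none`. And the zero-tolerance rule for the clade state (no outsider may
carry `der`, even within the `f` budget) is applied to the two-state
ambiguous case as well: both member states must be absent outside. This
keeps every emitted character strictly diagnostic while `f` only absorbs
scattered third-state noise such as sequencing error.

## Ranking and the small-clade procedure

Candidate characters are ranked by ascending number of clade members with
missing data, then descending minimum read depth, then descending mean depth
over members with data, with `(locus, position)` as a final deterministic
tie-break; the top `k_report` (default 5) are reported. The order of keys
mirrors the discovery procedure: a character present in every sequenced
member is worth more than a better-covered one seen in fewer, and coverage
then guards against base-calling artefacts in degraded specimens.

Clades of one or two specimens are never diagnosed by their private states —
a private base in a single specimen is indistinguishable from a random
substitution or a sequencing error. Instead `diagnose_small_clade()`
assembles the neighbourhood evidence: the sister clade's direct
synapomorphies restated from the focal side (`G82G (not A)` — the focal taxon
*retains* G where the sister changed to A), plus the direct synapomorphies of
the parent clade (members plus sister) against everything else. Each scope is
ranked and truncated separately, and the union diagnoses the taxon. With the
outside-mismatch budget at zero this union provably separates the focal
clade from every other specimen whenever both scopes yield characters.

## Barcode formulas

Where a clade is polymorphic at every barcode position, no single character
separates it, but a small disjunction can: `G506A or G38A & T283A`.
`find_barcode_formula()` searches the bounded DNF space — at most 2 terms of
at most 2 literals, the shape such published formulas take — and returns a
formula with the fewest literals, then fewest terms, then lexicographically
least positions. The search screens single literals and conjunction pairs
with vectorised matrix products, and for two-term formulas enumerates only
terms that no outsider satisfies and at least one member satisfies
(a minimal formula can contain no other term), deduplicated by their
member-coverage pattern. A specimen satisfies a term only when it has data
at all of the term's positions; members with no data at any complete term
are exempt from coverage. Bounds above 2×2 are capped: the space beyond is
combinatorially explosive and diagnoses never print such formulas.

## Divergence, trees, monophyly

Barcode comparisons use the standard 658-position COI window
(`extract_barcode()`, renumbered 1..658) and uncorrected p-distances with
pairwise deletion; input ambiguity codes are excluded like missing data
(conservative, and immaterial at barcode scale). Clade-vs-clade divergence is
reported as min/mean/max percent over defined cross pairs, because printed
"% difference" values may be either a minimum or a mean when clades hold
several specimens — both bracket the comparison with genus-level (≈8–9%) and
subgenus-level (≈6–7%) bands. Pairs with no comparable sites are flagged
`NA`, never zeroed.

`nj_tree()` is a standard neighbor-joining implementation with one addition:
among pairs minimising the Q criterion it joins the pair whose subtrees
contain the lexicographically least tip labels, so output is bit-identical
across runs; negative branch lengths are clamped to zero with a warning. It
exists for desk-scale topology checks (additive distances are recovered
exactly), not as a substitute for likelihood inference, which is out of
scope. `check_monophyly()` tests MRCA-tip-set equality on a rooted tree and
reports intruders; `root_with_outgroup()` places the root on the branch
separating a (separable) outgroup.

## The simulator and what passing tests show

`simulate_dataset()` generates the study conditions end to end: a fixed
20-specimen tree (clades of 5, 5 and 4 specimens; a doubleton sister to the
4-clade; a singleton sister to the ingroup; a 3-specimen outgroup), 10
nuclear exons of 500 bp plus a 700 bp COI locus, unit branch lengths with a
background substitution probability of 0.01 per site per unit branch
(yielding COI divergences of roughly 4–12%, the range of interest), five
planted nuclear synapomorphies on each multi-specimen clade, three on the
branches feeding the small-clade procedure, three COI characters per
multi-specimen clade, per-specimen missing fractions drawn uniformly from
[0, 0.2] (museomics-style degraded specimens), and read depth at covered
cells of 1 + NegBin(mu = 24, size = 1.5) so that depth 0 coincides exactly
with masked cells.

Ground truth is kept exact by construction: planted columns are exempt from
background substitution anywhere in the tree, and the missing mask never
blanks all members of a clade at one of its planted columns (one member is
kept observed). Recovery tests need unambiguous truth; the cost is that
planted columns are slightly cleaner than an average column.

The substitution model is deliberately minimal — i.i.d. replacement, no
rate heterogeneity, no indels, no paralogy or contamination. Passing
recovery tests therefore show that the discovery logic is sound under
clade-structured noise and missing data; they do not show robustness to
alignment error or systematic base-calling bias, which real museomics data
add on top.

## Problem sizes and numerical choices

The test suite exercises: oracle equivalence of the column classifier
against a literal brute-force scan on 200 random alignments (≤12 specimens ×
≤50 columns); planted recovery on 50 simulated replicates at the default
conditions; complement soundness on 20 zero-noise small-clade diagnoses;
formula minimality against exhaustive enumeration on 100 instances (≤8
specimens × ≤12 columns); NJ topology recovery on 100 random additive trees
(n ≤ 10); 1,000 notation round-trips; and 100 monophyly comparisons against
a naive traversal. These sizes keep each property statistically meaningful
while the whole suite stays fast.

Ties everywhere are broken deterministically (alphabetically first modal
base; lexicographic literal order in formulas; lexicographic tip pairs in
NJ), so every pipeline artifact is reproducible bit for bit from a config
and seed.

## Limitations

Diagnostic characters are only as stable as the comparison set: adding new
outside specimens can demote a character, which is why `verify_characters()`
re-evaluates every emitted diagnosis against the current data. The package
does not infer ancestral states probabilistically (the outside modal state
stands in), does not correct distances for multiple hits, and treats locus
identifiers as opaque keys inherited from the reference exon set.
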