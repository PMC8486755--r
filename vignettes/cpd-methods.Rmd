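---
title: "Methods: scanning for compensated pathogenic deviations in Complex I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for compensated pathogenic deviations in Complex I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdscan)
```

## The problem

A human mtDNA variant that is unambiguously pathogenic can occur as the
normal allele of another metazoan. The usual interpretation is epistasis:
the foreign sequence background contains *compensating* (masking,
permissive) differences that neutralise the deleterious effect. `cpdscan`
implements a desk-scale version of the comparative analysis behind this
idea for the seven mtDNA-encoded Complex I subunits: find the species
carrying human pathogenic amino acids (compensated pathogenic deviations,
CPDs), count how often the pathogenic state arose independently on the
phylogeny, and interrogate the residues in structural contact with the CPD
site for candidate masking substitutions.

## Coordinate mapping

Catalogue entries use rCRS nucleotide coordinates. For heavy-strand genes
the in-gene offset is `nt - start + 1`; ND6 is encoded on the light strand,
so its frame runs backward and the offset is `end - nt + 1`. The protein
position is `ceiling(offset / 3)`. The packaged gene spans are validated at
every access against three fixed mappings (m.3481→ND1:59, m.10158→ND3:34,
m.14487→ND6:63); if the constants were ever corrupted, loading fails rather
than silently mis-mapping.

## Pathogenicity rubric

Published pathogenicity scoring for mtDNA variants weighs independent
reports, heteroplasmy, segregation, biochemical defect, cybrid transfer,
single-fibre analysis and an in-silico prediction category, with functional
laboratory evidence most persuasive. The exact point schedule used in the
literature is not published as numbers, so `default_rubric()` ships an
explicit assumption: cybrid and single-fibre evidence 7 points each,
biochemical defect 4, the remaining criteria 2 each, with class cut-offs
possibly ≥ 5, probably ≥ 11, definitely ≥ 18 (so that *definitely* is
unreachable without functional evidence). The rubric is plain configuration:
any non-negative weights and thresholds can be supplied, and classification
is guaranteed monotone in evidence. LHON variants systematically score low
(incomplete penetrance, homoplasmy in unaffected carriers); they are
carried as their own status class taken from the catalogue rather than
forced through the score.

## CPD scanning conventions

Alignment columns are located through the human reference row (the column
holding the *k*-th non-gap human character). Prevalence denominators are
always the *covered* species at that column: gaps and `X` are excluded from
counts, never silently treated as mismatches, and every exclusion is
tallied. Reports are 1-based throughout. Columns covered in fewer than half
the species are flagged; this is an automated stand-in for manual alignment
inspection and deliberately conservative.

## Ancestral states and event counting

Substitution counts use Fitch parsimony under uniform costs. The bottom-up
pass yields candidate state sets and the parsimony score; the top-down pass
resolves ties deterministically (inherit the parent state when possible,
otherwise the alphabetically first candidate; the root likewise, flagged
when ambiguous). The score is independent of the tie rule, and the suite
verifies it against an exhaustive minimum over all internal labelings on
trees of up to 8 tips. Users with precomputed ancestral states (e.g. from a
likelihood method) can supply them directly to `count_events_to()` /
`count_reversions()`; parsimony is the reproducible default, not a claim
that the original reconstructions were parsimony-based, and exact
reproduction of published per-variant event counts is therefore not
promised. A *reversion* is counted only on branches below an earlier
forward event on the same root path — `count_reversions(fit, "T", "A")`
counts T→A branches below an A→T gain, the pattern seen at ND5:398
(pathogenic A ancestral, T gained in primates, A restored twice).

Tips with missing states are pruned before reconstruction; pruning can only
lower the parsimony score (property-tested).

## Contacts

A residue's representative atom is its C-beta (C-alpha for glycine);
non-glycine residues lacking a C-beta fall back to C-alpha with a warning,
and residues with neither are omitted and counted as unassessable rather
than treated as non-contacts. Two residues are in contact when their
representative atoms are strictly closer than 8 Å, the conventional
contact definition; the threshold is a parameter. No minimum sequence
separation is applied by default because near-in-sequence neighbours are
part of the analysis. Structure numbering is assumed to equal catalogue
numbering up to a per-gene integer offset; a sequence cross-check between
structure residue identities and the human alignment row fails loudly above
5% mismatch, which catches off-by-one numbering errors immediately. Only
intra-chain contacts are considered: inter-subunit masking is out of scope.
Alternate locations resolve to the highest-occupancy record (ties: first
encountered); insertion codes are rejected rather than guessed at.

## Masking classification

For each contact site of a CPD, the states of the CPD-carrying species are
inspected at the mapped column. The site is classified `all` when every
covered CPD species carries a non-human amino acid, `none` when all carry
the human one, `some` otherwise. CPD species with missing data at the
contact site do not veto `all`: they are excluded from the determination
and their count is reported, because silent vetoing would hide signal and
silent inclusion would fabricate it. The scope rule is honoured as
configuration: for definitely pathogenic variants all CPD species are
searched, for probably pathogenic and LHON-class variants the search is
restricted to a clade (primates by default), driven by the taxonomy table
rather than hard-coded species lists.

## Sequence statistics

*dN/dS.* Pairwise rates use the Nei–Gojobori (1986) counting method:
synonymous site fractions by enumeration of the nine single-nucleotide
neighbours of each codon (changes to stops count as nonsynonymous),
differences averaged over all orderings of single-step paths with
stop-passing paths excluded, Jukes–Cantor correction
d = −¾·ln(1 − 4p/3). Saturation (p ≥ ¾) and an undefined ratio (no
synonymous divergence) are explicit signals, never division errors. The
default code is vertebrate mitochondrial with invertebrate mitochondrial
and standard tables selectable per comparison, since a metazoan-wide
dataset spans codes. A counting method and a maximum-likelihood method
(codeml) will not agree numerically; published ML values are treated as
order-of-magnitude reference points only.

*Conservation probability.* The chance that all *k* contact sites of a
residue fall on identical positions of a protein pair with identity
fraction *q* is computed without replacement with K = round(q·N):
P = Π (K−i)/(N−i). For ND6 (N = 174, q = 0.59, k = 7) this gives 0.023,
i.e. 0.02 at two decimals. The binomial approximation q^k is exposed for
comparison. The exact intermediate K is not published for the reference
computation; any K in a sensible band rounds to the same two decimals, so
the choice of `round()` is documented rather than fitted.

*Miyata ranks.* The packaged Miyata et al. (1979) distance matrix is built
exactly as published: Grantham (1974) polarity and volume, each pairwise
difference scaled by the standard deviation of the 190 pairwise
differences, combined in quadrature. The construction reproduces published
entries at their printed precision (P–A 0.06, L–I 0.14, K–R 0.40, C–P
1.33). `miyata_rank(ref, q)` ranks the 19 non-reference amino acids by
ascending distance with alphabetical tie-break. Under this matrix the rank
of Ala for Val is 9 and the rank of Val for Ala is 7 (the six nearer
neighbours of Ala being P, S, T, G, C, N — with d(A,N) = 1.77 just inside
d(A,V) = 1.84); no normalisation convention we examined (sample vs
population standard deviation, 20 values vs 190 pairs) reorders that pair.

## Synthetic data: what it emulates, and what it does not

`simulate_bundle()` produces the study conditions the tests run under:
a 64-tip Yule tree (uniform leaf splitting, unit branch lengths), a
140-column amino-acid alignment evolved at 0.05 substitutions per site per
branch under uniform replacement, a planted CPD with a single ~4-species
origin and one with three independent origins, masking partners planted as
`all`/`some`/`none`, a catalogued variant absent from every species, a toy
structure realising the planted contact distances, and a taxonomy table.
These sizes keep the full end-to-end suite in tens of seconds while leaving
all counting logic non-trivial (64 tips, multiple origins, missing-data
paths).

Planted clades are chosen disjoint, each with a reserved wild-type
"witness" tip adjacent to its stem, and the generator verifies with its own
parsimony that the planted number of origins is what an analyst would
count; any residual collision is a hard error, not a silent mislabel.
Structures place residues 15 Å apart by default and reposition designated
partners to exact target distances; partners crowded around one anchor may
contact each other (as in real packing), so ground truth is defined for
anchor sites, and an audit rejects any undesignated contact involving an
unmoved residue.

What the generator does not emulate: empirical amino-acid exchangeabilities
(replacement is uniform; a Miyata-biased mode would be a natural extension),
indels (alignments are gap-free unless corrupted explicitly), rate
heterogeneity across sites, and real protein geometry. Passing the planted
recovery suite therefore demonstrates the correctness of the counting and
classification machinery, not robustness to alignment error or model
misspecification in real data.

## Determinism and degenerate inputs

Every stochastic component is seeded and byte-reproducible; the pipeline
itself draws no random numbers, and reruns on identical inputs produce
byte-identical reports. Degenerate cases have defined behaviour: empty
columns report zero coverage rather than frequencies; a variant absent from
all species yields an empty hit and zero events; an alignment column whose
human state contradicts the catalogue flags the record and warns instead of
silently proceeding; contacts at exactly the threshold are excluded (the
definition is strict inequality); unresolved structure residues are
reported as unassessable, never as absent contacts.

## Known limitations

- Parsimony undercounts events on long branches and cannot resolve
  direction at the root without the tie rule; counts are reported together
  with the resolution-independent parsimony score.
- The masking classification is intra-chain only; compensation through
  nuclear-encoded supernumerary subunits is invisible to it.
- NG86 saturates quickly for deep divergences; for distant pairs the
  `saturated` flag should be taken seriously.
- The rubric's default point values are assumptions (see above), and
  per-variant statuses in a user catalogue always take precedence.
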