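---
title: "Mini-barcode identification of CITES-listed sharks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mini-barcode identification of CITES-listed sharks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharkid)
```

## The problem

Eight shark species are listed on CITES Appendix II (whale, basking,
white, oceanic whitetip, porbeagle and the scalloped, smooth and great
hammerheads); trade in their parts requires export permits. Fins entering
the retail chain are skinned, bleached and often cooked, which removes
morphological characters and fragments the DNA, so the standard ~650 bp
COI barcode frequently cannot be amplified. A mini-barcode assay recovers
a ~150 bp COI amplicon — roughly 110–130 bp of readable sequence — from
such material. The analytical question this package answers is: **what can
a 110–130 bp COI fragment say about species identity, and how should the
uncertainty be reported?**

Two complementary lines of evidence are combined:

1. an *identity search* of the fragment against a labelled reference
   library (operationally what a BLAST or BOLD query does), and
2. a *character-based* check against a compound character attribute (cCA)
   key: a fixed set of COI positions whose joint states separate each
   target species from its close relatives.

The cCA is an independent confirmation, not a tie-breaker: when the two
tracks disagree the result carries a discordance flag rather than a
silently resolved call.

## Sequence model and coordinates

Sequences are strings over the IUPAC nucleotide alphabet plus the
alignment gap `-`. Ambiguity codes denote *sets* of bases (`K` = {G,T});
two states are **compatible** when their sets intersect. Compatibility —
never character equality — defines matching, diagnosis and distance
throughout. The gap expands to the empty set and is therefore
incompatible with everything including `N`: a gap is an alignment
artefact, `N` an unknown base, and conflating them would let missing data
count as evidence.

All public coordinates are 1-based inclusive COI positions counted from
the start codon. A reference library stores one offset (the COI position
of its first alignment column); raw column indices never appear in an
interface. Libraries are assumed pre-registered to COI coordinates —
alignment itself is out of scope, and the synthetic generator produces
registered data directly.

## In-silico PCR

The assay multiplexes two overlapping M13-tailed universal fish forward
primers with a shark-specific reverse primer annealing to a conserved
region ~150 bp into the gene. `find_annealing_sites()` scans a strand for
windows IUPAC-compatible with the primer at all but at most
`max_mismatches` positions (default 2), with zero mismatches tolerated in
the 3'-terminal `three_prime_clamp` bases (default 3), since polymerase
extension is intolerant of 3' mismatches. The published protocol reports
only that all tested species amplified, so these tolerances follow common
primer-scan practice and are configurable rather than constants. The
18-base M13 tail is metadata: it does not bind template on early cycles
and is excluded from the comparison.

`insilico_pcr()` pairs forward and reverse sites whose insert length lies
in 30–1000 bp (rejecting spurious pairings of multiplexed primers on
synthetic templates) and ranks products by total mismatches, ties by
leftmost forward site. `trim_to_readable()` restricts the insert to the
readable window, default COI 57–174 — the span of the bundled key's
positions. The exact amplicon endpoints are not published; the default is
a configuration value, not a constant.

## Union consensus and cCA construction

`build_consensus()` uses a union rule: per column, every observed base
above a frequency threshold (default 0, i.e. all observed bases) enters
the emitted IUPAC code. A majority rule would have been simpler but would
erase within-species polymorphism — the bundled key itself carries
polymorphic cells (porbeagle `K` at position 132, scalloped hammerhead
`Y` at 103, smooth hammerhead `R` at 126), which only a union rule
produces. A single-sequence "consensus" is that sequence unchanged, which
is how a species represented by one record is handled.

`diagnostic_positions()` selects positions separating a target consensus
from each relative. The published work does not state its selection
procedure nor claim minimality of its 21 positions, so the package
defines its own deterministic one: greedy set cover (each step takes the
position separating the most not-yet-separated relatives, ties to the
smaller COI position), with an exhaustive solver used in the test suite
as an optimality oracle on small instances. `build_cca_key()` takes the
union of per-target sets as one shared position list — matching the
published key's use of a single common set for all eight species — and
records every species' consensus state at each position. Construction
fails loudly if a target is inseparable from a relative or if two
finished rows are compatible everywhere.

The bundled key (`load_table3_key()`) is shipped as data of record: 8
species × 21 positions spanning COI 57–174. It is an artifact to be used
and validated, not re-derived — the full reference panels behind it are
not distributed. Its relatives map is package-assembled metadata
(congeners for the hammerheads, lamnids for the lamnoids, the
dusky/Galapagos/Caribbean-reef trio for the whitetip) rather than a
published table. Position 60 is flagged low-confidence as data, not
code: it sits in the poorly resolved early part of the read, and it is
the single position separating the oceanic whitetip from its closest
congeners, so it is excluded from matching unless explicitly enabled.

`key_row_distance()` counts positions with *incompatible* states; `R` vs
`G` contributes nothing. Compatibility is not a metric — triangle
inequality can fail — and nothing in the package assumes it is.

## The identification cascade

`identity_search()` compares a COI-registered query column-by-column with
each reference over their overlapping interval: identity = percentage of
compared columns that are compatible (reported to one decimal, matching
the percent formatting of published result tables), coverage = percentage
of the query compared. Query gap columns are excluded. Hits sort by
identity, then coverage, then record id — a total order, so reports are
byte-stable. A query with unknown registration is first placed against
the library-wide union consensus (best offset, ties to the smallest).
This local search deliberately stands in for remote BLAST/BOLD queries:
the decision logic, not the search engine, is the substance, and a local
deterministic search keeps every result reproducible offline.

`identify()` merges the two tracks:

1. **species** — top identity exactly 100 (every compared column
   compatible), unique to one species, and, when that species has a key
   row, a cCA candidate set of exactly that species;
2. **candidate_set** — the cCA candidates are several species mutually
   closer than `min_separation` key positions (default 2, from the
   observed separation structure: every listed species at least two
   positions from its closest relative except the whitetip at one);
3. **genus** — all maximal-identity hits share a genus;
4. **unidentified**.

The ordering of (2) before (3) is a deliberate design choice: a tight
multi-species cCA set (the whitetip/dusky/Galapagos/Caribbean-reef case)
is strictly more informative than its genus, and reporting the set keeps
the enforcement-relevant possibility visible. A cCA candidate set that
*contains* the search species plus unexcluded neighbours is
under-resolution of a short fragment and simply denies the species-level
call; only a cCA that *excludes* the searched species raises the
discordance flag. Mixed-genus ties yield `unidentified` — a conservative
rule for a case absent from the published data.

## Reference screening

`screen_references()` compares every record against conspecifics and all
other species. A record is `suspect` when its best foreign identity
reaches `foreign_threshold` (default 98%) while its best conspecific
identity is at most `conspecific_threshold` (default 90%) or no
conspecific exists; a species' sole record with no strong foreign hit is
`unresolvable`. The defaults bracket the identity gaps of documented
public-database errors (99-vs-83 and 99-vs-86) with margin on both
sides; the original screening was manual inspection, so the thresholds
are this package's operationalisation and are configurable. The
flagging guarantee (exactly the planted mislabel flagged) holds when
between-species divergence exceeds `100 - conspecific_threshold` and
within-species divergence stays below `100 - foreign_threshold`; the
test and acceptance panels are generated at 12% between-species
divergence, congener scale, satisfying that condition.

## The synthetic generator

`simulate_library()` emulates the study's data classes without any
download: per species, a backbone diverges i.i.d. per site from a common
ancestor (default 5% per site, a typical congeneric COI distance);
records add within-species mutations (default 0.5% per site, the scale of
intraspecific COI variation); bases at key positions are forced
compatible with the species' key state. Where a key state is an ambiguity
code, records cycle deterministically through its expansion, so a
noise-free library of n ≥ 2 reproduces the generating state exactly under
the union consensus for any seed — sampling instead would leave a small
per-seed chance of erasing a polymorphism. A primer scaffold (forward
footprint at COI 31–55, reverse site at 176–195) guarantees in-silico PCR
recovers an insert covering 57–174. `simulate_degraded_queries()` models
processed-fin reads: one random subinterval per record within the
truncation bounds (default 110–130 bp, the assay's read-length regime),
guaranteed to overlap the readable region, with `N` injected at a default
1% rate. `plant_relatives()` extends a key with synthetic relative rows
at prescribed separations, used to validate the separation structure
(two positions everywhere, one for the whitetip) end to end.

What the generator does *not* model, and what passing tests therefore do
not show: transition/transversion bias and codon structure, heterogeneity
of divergence along the gene, PCR or sequencing error beyond uniform `N`
injection, indels (generated libraries are gap-free), and real
phylogenetic correlation between species — backbones are exchangeable
given the key. Results on real data depend on reference-library coverage
in a way no simulation exercises.

## Numerical and degenerate-input choices

- Identity values are reported rounded to one decimal, but the
  species-call condition is exact (all compared columns compatible), so
  rounding can never manufacture a 100.
- All orderings (hits, products, QC flags, tabulations) are total, so
  outputs are byte-identical across runs; every stochastic step consumes
  one integer seed.
- `min_frequency = 0` keeps every observed base in a consensus; an
  all-gap column emits `-`.
- Empty candidate sets, empty hit lists and empty input tables are
  ordinary values, not errors; coordinate violations, inseparable taxa,
  degenerate keys and uncovered queries fail with typed conditions.
- Problem sizes used by the shipped tests and the acceptance script — 8
  species × 10 records (full panel), 200-column × ≤50-record oracle
  comparisons, ≤12-position exhaustive set-cover checks — were chosen as
  the smallest sizes at which every property is non-trivially exercised.

## Known limitations

The identification quality on real data is bounded by the reference
library and the key, both of which this package treats as inputs. The
bundled key's relatives map is package-assembled; a different phylogeny
could nominate different relatives and hence different diagnostic
positions. The identity search is alignment-free given registration and
does not model indels within the fragment. No e-value or abundance
statistics are computed — with libraries of this size, identity and
coverage are the meaningful quantities.
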