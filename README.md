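# sharkid

Identification of shark products from COI mini-barcodes, for wildlife
forensics and CITES trade enforcement.

Shark fins traded into Asian markets are skinned and chemically treated
("processed fins"), and fin soup is cooked; both destroy the morphological
characters and degrade the DNA that standard full-length DNA barcoding
(~650 bp of the mitochondrial cytochrome *c* oxidase I gene, COI) relies
on. A mini-barcode assay amplifies a short fragment instead — a ~150 bp
amplicon yielding ~110–130 bp of readable sequence — that survives this
degradation. `sharkid` implements the computational side of that protocol
as a reusable R toolkit:

- **In-silico PCR** (`insilico_pcr()`): degenerate, IUPAC-aware annealing
  of the multiplexed primer cocktail (two M13-tailed universal fish
  forward primers plus a shark-specific reverse primer), extraction of the
  amplicon and trimming to the readable region (COI 57–174 by default).
- **Consensus and cCA keys** (`build_consensus()`, `build_cca_key()`): a
  per-species IUPAC *union* consensus preserves within-species
  polymorphism as ambiguity codes; a *compound character attribute* (cCA)
  key is a shared set of COI positions whose joint states separate each
  target species from its close relatives. The bundled key covers the
  eight CITES Appendix II listed sharks at 21 positions (COI 57–174).
- **Two-track identification** (`identify()`): a deterministic local
  identity search against a reference library (the stand-in for BLAST/BOLD
  queries) plus an independent cCA check, combined by an explicit cascade
  into a species, genus, candidate-set or unidentified call. Candidate-set
  calls handle the oceanic whitetip, which short fragments cannot separate
  from dusky, Galapagos and Caribbean reef sharks.
- **Reference screening** (`screen_references()`): flags probable
  misidentifications in a labelled library — records far closer to another
  species than to their own conspecifics, as documented for several public
  GenBank shark entries.
- **Synthetic data** (`simulate_library()`, `simulate_degraded_queries()`):
  generates COI-registered libraries and degraded query panels consistent
  with any cCA key, so the entire pipeline is testable with no database
  download.

Diagnosis throughout uses IUPAC *compatibility* (non-empty intersection of
base sets), never raw character equality: the consensus state `R` (= A/G)
must not count as differing from `G`, or polymorphic individuals would be
misdiagnosed. All coordinates are 1-based COI positions counted from the
start codon.

## Worked example

Simulate a reference panel honouring the bundled key, degrade a query to
mini-barcode length, and identify it:

```r
library(sharkid)

key <- load_table3_key()
cfg <- sim_config(key, setNames(rep(10L, 8), rownames(key$rows)), seed = 1L)
lib <- simulate_library(cfg)
lib
#> COI reference library: 80 records, 8 species, columns = COI 1..655
#>   Carcharhinus longimanus      10
#>   ...

dq <- simulate_degraded_queries(lib, cfg)
r <- identify(dq$queries[31, , drop = FALSE], lib, key)
r
#> q_Lamna_nasus_1: Lamna nasus (species)
r$top_hits[1, c("reference_id", "species", "identity", "coverage")]
#>    reference_id     species identity coverage
#> 1 Lamna_nasus_1 Lamna nasus      100      100
r$cca_candidates
#> [1] "Lamna nasus"
```

The species-level call required all three conditions: top identity 100%
unique to one species, and a cCA candidate set containing exactly that
species. A whitetip-like query instead yields a `candidate_set` call
listing the species the fragment cannot separate — never a definitive
species claim.

A thin command-line wrapper exposes the same operations
(`exec/sharkid --help`): subcommands `simulate`, `insilico-pcr`,
`build-key`, `identify`, `qc-refs` and `tabulate`, reading and writing
FASTA/TSV.

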