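#' Configuration for the synthetic sequence generator
#'
#' The generator produces COI-registered reference libraries and degraded
#' query panels that are statistically consistent with a supplied cCA key,
#' so the whole pipeline is testable without downloading any reference
#' sequence. Species backbones diverge i.i.d. per site from a common
#' ancestor; records add within-species mutations; bases at key positions
#' are forced compatible with the species' key state (subject to
#' `key_position_noise`). When a key state is an ambiguity code the records
#' cycle deterministically through its expansion, so a noise-free library of
#' two or more records always reproduces the ambiguity state under the union
#' consensus rule.
#'
#' @param key A `cca_key` the library must honour.
#' @param panel Named integer vector: species -> number of records. Every
#'   panel species must have a key row.
#' @param seq_length,coordinate_offset Alignment geometry; the defaults
#'   (655, 1) give the full barcode region containing COI 57..174.
#' @param within_species_mutation_rate Per-site substitution probability per
#'   record at non-key positions (default 0.005, the scale of intraspecific
#'   COI variation in sharks).
#' @param between_species_background_divergence Per-site substitution
#'   probability from the common ancestor per species backbone (default
#'   0.05, a typical congeneric COI distance).
#' @param key_position_noise Probability a record deviates from its key
#'   state (default 0).
#' @param primer_scaffold Embed the primer annealing sites so in-silico PCR
#'   recovers an insert covering COI 57..174 (default `TRUE`).
#' @param truncation_model Length-2 range for degraded query lengths
#'   (default `c(110, 130)`, the read-length regime of the assay).
#' @param ambiguity_injection_rate Probability a query base is replaced by
#'   `N` (default 0.01).
#' @param seed Integer RNG seed; all generation is deterministic given it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(key, panel, seq_length = 655L, coordinate_offset = 1L,
                       within_species_mutation_rate = 0.005,
                       between_species_background_divergence = 0.05,
                       key_position_noise = 0,
                       primer_scaffold = TRUE,
                       truncation_model = c(110L, 130L),
                       ambiguity_injection_rate = 0.01,
                       seed = 1L) {
  probs <- c(within_species_mutation_rate,
             between_species_background_divergence,
             key_position_noise, ambiguity_injection_rate)
  if (any(probs < 0 | probs > 1))
    abort_config("all rate parameters must lie in [0, 1]")
  if (any(panel < 1L)) abort_config("per-species record counts must be >= 1")
  if (is.null(names(panel)) || any(!nzchar(names(panel))))
    abort_config("panel must be a named vector species -> count")
  missing <- setdiff(names(panel), rownames(key$rows))
  if (length(missing))
    abort_config(sprintf(
      "panel species absent from the key (no backbone rule): %s",
      paste(missing, collapse = ", ")))
  if (truncation_model[1] > truncation_model[2] || truncation_model[1] < 30L)
    abort_config("truncation_model must satisfy 30 <= min <= max")
  if (truncation_model[2] > seq_length)
    abort_config("truncation bounds exceed the sequence length")
  rng <- max(key$positions)
  if (coordinate_offset > min(key$positions) ||
      coordinate_offset + seq_length - 1L < rng)
    abort_config("key positions fall outside the simulated COI range")
  structure(list(
    key = key, panel = panel, seq_length = as.integer(seq_length),
    coordinate_offset = as.integer(coordinate_offset),
    within_species_mutation_rate = within_species_mutation_rate,
    between_species_background_divergence =
      between_species_background_divergence,
    key_position_noise = key_position_noise,
    primer_scaffold = isTRUE(primer_scaffold),
    truncation_model = as.integer(truncation_model),
    ambiguity_injection_rate = ambiguity_injection_rate,
    seed = as.integer(seed)), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# Scaffold layout (COI coordinates): forward-primer footprint just upstream
# of the readable region, reverse-primer binding site just downstream, so
# the insert covers COI 57..174.
scaffold_layout <- function() {
  ps <- primer_set()
  fwd <- substr(ps$forward_primers$bases[1],
                ps$forward_primers$tail_length[1] + 1L,
                nchar(ps$forward_primers$bases[1]))
  rev_site <- reverse_complement(ps$reverse_primer$bases)
  list(fwd = str_chars(fwd), fwd_start = 56L - nchar(fwd),  # ends at COI 55
       rev = str_chars(rev_site), rev_start = 176L)
}

#' Simulate a COI reference library consistent with a cCA key
#'
#' @param config A [sim_config()].
#' @return A `ref_library`; record ids are `<abbrev>_<i>` and labels are the
#'   generating (true) species.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$seq_length
  off <- config$coordinate_offset
  key <- config$key
  key_cols <- key$positions - off + 1L
  anc <- sample(BASES, L, replace = TRUE)
  scaffold_cols <- integer(0)
  if (config$primer_scaffold) {
    lay <- scaffold_layout()
    fcols <- (lay$fwd_start:(lay$fwd_start + length(lay$fwd) - 1L)) - off + 1L
    rcols <- (lay$rev_start:(lay$rev_start + length(lay$rev) - 1L)) - off + 1L
    if (any(c(fcols, rcols) < 1L) || any(c(fcols, rcols) > L))
      abort_config("sequence too short to carry the primer scaffold")
    anc[fcols] <- lay$fwd
    anc[rcols] <- lay$rev
    scaffold_cols <- c(fcols, rcols)
  }
  free_cols <- setdiff(seq_len(L), c(key_cols, scaffold_cols))
  seqs <- list()
  for (sp in names(config$panel)) {
    backbone <- anc
    mut <- free_cols[stats::runif(length(free_cols)) <
                       config$between_species_background_divergence]
    backbone[mut] <- vapply(backbone[mut], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
    states <- key$rows[sp, ]
    expansions <- lapply(states, iupac_set)
    for (r in seq_len(config$panel[[sp]])) {
      rec <- backbone
      mut <- free_cols[stats::runif(length(free_cols)) <
                         config$within_species_mutation_rate]
      rec[mut] <- vapply(rec[mut], function(b)
        sample(setdiff(BASES, b), 1L), character(1))
      # cycle through ambiguity expansions so the union consensus recovers
      # the generating state for any n >= 2
      rec[key_cols] <- vapply(seq_along(expansions), function(k) {
        exp <- expansions[[k]]
        exp[((r - 1L) %% length(exp)) + 1L]
      }, character(1))
      if (config$key_position_noise > 0) {
        noisy <- stats::runif(length(key_cols)) < config$key_position_noise
        rec[key_cols[noisy]] <- sample(BASES, sum(noisy), replace = TRUE)
      }
      seqs[[length(seqs) + 1L]] <- nuc_seq_row(
        sprintf("%s_%d", gsub("[^A-Za-z0-9]+", "_", sp), r), chars_str(rec),
        genus = strsplit(sp, " ")[[1]][1], species = sp, coi_offset = off)
    }
  }
  seqs <- do.call(rbind, seqs)
  class(seqs) <- c("nuc_seqs", "data.frame")
  reference_library(seqs, coordinate_offset = off)
}

#' Simulate degraded mini-barcode queries from a library
#'
#' Emulates reads from processed fins and fin soup: each library record
#' yields one query restricted to a random subinterval within the
#' truncation bounds (guaranteed to overlap the readable region COI 57..174
#' when the scaffold is enabled), with bases replaced by `N` at the
#' ambiguity injection rate. Query registration (`coi_offset`) is retained,
#' as in practice it is recovered by aligning the read to the reference
#' frame.
#'
#' @param library A `ref_library` (typically from [simulate_library()]).
#' @param config The same [sim_config()].
#' @return List with `queries` (a `nuc_seqs` data frame, ids `q_<record>`)
#'   and `truth` (data frame query_id -> species).
#' @export
simulate_degraded_queries <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  tm <- config$truncation_model
  lr <- coi_range(library)
  if (tm[2] > library$width)
    abort_config("truncation bounds exceed the library's aligned length")
  set.seed(config$seed + 1000003L)
  rows <- lapply(seq_along(library$ids), function(i) {
    len <- if (tm[1] == tm[2]) tm[1] else sample(tm[1]:tm[2], 1L)
    lo <- lr[1]; hi <- lr[2] - len + 1L
    if (config$primer_scaffold) {
      lo <- max(lo, 57L - len + 1L)  # end >= 57
      hi <- min(hi, 174L)            # start <= 174
    }
    start <- if (lo >= hi) lo else sample(lo:hi, 1L)
    ch <- library$mat[i, (start - lr[1] + 1L):(start - lr[1] + len)]
    if (config$ambiguity_injection_rate > 0) {
      nn <- stats::runif(len) < config$ambiguity_injection_rate
      ch[nn] <- "N"
    }
    nuc_seq_row(paste0("q_", library$ids[i]), chars_str(ch),
                coi_offset = start)
  })
  queries <- do.call(rbind, rows)
  class(queries) <- c("nuc_seqs", "data.frame")
  list(queries = queries,
       truth = data.frame(query_id = queries$id,
                          species = library$taxa$species,
                          stringsAsFactors = FALSE))
}

#' Extend a cCA key with planted relatives at known separations
#'
#' For each named target species, appends a synthetic relative row equal to
#' the target's states except at a prescribed number of positions, where the
#' state is replaced by an incompatible base. This builds study panels with
#' a known separation structure (e.g. most targets two diagnostic positions
#' from their closest relative, the oceanic whitetip only one), against
#' which consensus and key construction can be validated end to end. The
#' flipped positions rotate with the target index so distinct relatives
#' stay mutually distinguishable; construction is fully deterministic.
#'
#' @param key A `cca_key`.
#' @param separations Named integer vector target species -> number of
#'   separating positions to plant (>= 1).
#' @return List with `key` (the extended, validated `cca_key`; relative
#'   rows are named `<Genus> relsp<i>`) and `relative_of` (named list
#'   target -> its planted relative's row name).
#' @export
plant_relatives <- function(key, separations) {
  if (is.null(names(separations)) ||
      !all(names(separations) %in% rownames(key$rows)))
    abort_input("separations must be named by key species")
  if (any(separations < 1L)) abort_input("separations must be >= 1")
  rows <- key$rows
  npos <- length(key$positions)
  relative_of <- list()
  for (i in seq_along(separations)) {
    sp <- names(separations)[i]
    k <- separations[[i]]
    pick <- ((seq_len(k) - 1L + 2L * (i - 1L)) %% npos) + 1L
    row <- rows[sp, ]
    row[pick] <- vapply(row[pick], function(s)
      setdiff(c("A", "C", "G", "T"), iupac_set(s))[1], character(1))
    relname <- paste(strsplit(sp, " ")[[1]][1], sprintf("relsp%d", i))
    rows <- rbind(rows, row)
    rownames(rows)[nrow(rows)] <- relname
    relative_of[[sp]] <- relname
  }
  list(key = cca_key(key$positions, rows,
                     low_confidence_positions = key$low_confidence_positions),
       relative_of = relative_of)
}

#' Load the bundled cCA key for the eight CITES-listed sharks
#'
#' The machine-readable key ships with the package: 8 species x 21 COI
#' positions spanning 57..174, with position 60 flagged low-confidence and a
#' relatives map assembled from the published identification narrative.
#'
#' @return A `cca_key`.
#' @export
load_table3_key <- function() {
  read_cca_key(
    system.file("extdata", "table3_cca_key.tsv", package = "sharkid",
                mustWork = TRUE),
    system.file("extdata", "table3_cca_meta.json", package = "sharkid",
                mustWork = TRUE))
}

#' Load the bundled published identification results table
#'
#' 72 market samples (41 processed fins from Hong Kong, 31 sequenced fin
#' soup samples from the USA) with their database search results and final
#' identifications, encoded verbatim as data of record. Columns: `sample`,
#' `type` (P = processed fin, S = soup), `loc`, `bold`, `blast_top_hit`,
#' `coverage`, `identity` (printed integer percentages), `unq`, `id`.
#'
#' @return A data frame with 72 rows.
#' @export
load_table2_fixture <- function() {
  utils::read.delim(
    system.file("extdata", "table2_results.tsv", package = "sharkid",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' Common names of the CITES-listed target species
#'
#' Mapping used when tallying published-style result tables, whose final
#' identification column uses common names.
#'
#' @return Named character vector common name -> Latin binomial.
#' @export
cites_common_names <- function() {
  c("Whale" = "Rhincodon typus", "Basking" = "Cetorhinus maximus",
    "White" = "Carcharodon carcharias",
    "Oceanic whitetip" = "Carcharhinus longimanus",
    "Scalloped hammerhead" = "Sphyrna lewini",
    "Smooth hammerhead" = "Sphyrna zygaena",
    "Great hammerhead" = "Sphyrna mokarran", "Porbeagle" = "Lamna nasus")
}
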