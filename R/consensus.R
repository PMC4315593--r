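#' Build an IUPAC union consensus for one species
#'
#' Per alignment column, every input state is expanded to its IUPAC base set
#' and the bases observed in more than `min_frequency` of the records are
#' collected; the minimal IUPAC code covering that union is emitted. With the
#' default `min_frequency = 0` every observed base is kept, so within-species
#' polymorphism is preserved as an ambiguity code (a majority rule would
#' erase it, and the resulting key would misdiagnose polymorphic
#' individuals). An all-gap column emits `-`.
#'
#' A single-sequence "consensus" equals that sequence unchanged.
#'
#' @param records Character vector of equal-length aligned base strings, a
#'   `nuc_seqs` data frame, or a `ref_library` (all of its records).
#' @param min_frequency Bases at per-column frequency `<= min_frequency`
#'   (fraction of records) are dropped before the union is coded.
#' @param species,coi_offset Label and registration carried on the result;
#'   filled automatically from `nuc_seqs`/`ref_library` input.
#' @return Object of class `species_consensus`: list with `species`, `bases`,
#'   `n_sequences`, `coi_offset`.
#' @export
build_consensus <- function(records, min_frequency = 0,
                            species = NA_character_, coi_offset = 1L) {
  if (inherits(records, "ref_library")) {
    coi_offset <- records$coordinate_offset
    if (is.na(species)) {
      sp <- unique(records$taxa$species)
      if (length(sp) == 1L) species <- sp
    }
    records <- apply(records$mat, 1L, paste, collapse = "")
  } else if (is.data.frame(records)) {
    if (is.na(species) && length(unique(records$species)) == 1L)
      species <- records$species[1]
    if (!all(is.na(records$coi_offset))) {
      offs <- unique(records$coi_offset[!is.na(records$coi_offset)])
      if (length(offs) == 1L) coi_offset <- offs
    }
    records <- records$bases
  }
  if (length(records) == 0L) abort_input("no records to consensus")
  if (length(unique(nchar(records))) != 1L)
    abort_input("consensus input records differ in aligned length")
  n <- length(records)
  M <- matrix(iupac_mask(do.call(rbind, strsplit(records, "", fixed = TRUE))),
              nrow = n)
  union_mask <- integer(ncol(M))
  for (bit in c(1L, 2L, 4L, 8L)) {
    has <- matrix(bitwAnd(M, bit) > 0L, nrow = n)  # bitwAnd drops dim
    union_mask <- union_mask + bit * (colSums(has) / n > min_frequency)
  }
  structure(list(species = species,
                 bases = chars_str(mask_to_code(union_mask)),
                 n_sequences = n,
                 coi_offset = as.integer(coi_offset)),
            class = "species_consensus")
}

#' @export
print.species_consensus <- function(x, ...) {
  cat(sprintf("Consensus of %d sequence(s)%s, COI %d..%d\n", x$n_sequences,
              if (is.na(x$species)) "" else paste0(" for ", x$species),
              x$coi_offset, x$coi_offset + nchar(x$bases) - 1L))
  invisible(x)
}

#' Per-species consensuses for a whole reference library
#'
#' @param library A `ref_library`.
#' @param min_frequency Passed to [build_consensus()].
#' @return Named list of `species_consensus`, one per species, in
#'   alphabetical order.
#' @export
consensus_by_species <- function(library, min_frequency = 0) {
  species <- sort(unique(library$taxa$species))
  out <- lapply(species, function(sp) {
    rows <- library$taxa$species == sp
    build_consensus(apply(library$mat[rows, , drop = FALSE], 1L, paste,
                          collapse = ""),
                    min_frequency = min_frequency, species = sp,
                    coi_offset = library$coordinate_offset)
  })
  names(out) <- species
  out
}

# State of a consensus at given COI positions (character vector).
consensus_states <- function(cons, positions) {
  idx <- positions - cons$coi_offset + 1L
  if (any(idx < 1L | idx > nchar(cons$bases)))
    abort_coord("requested COI positions outside the consensus range")
  str_chars(cons$bases)[idx]
}
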