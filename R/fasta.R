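#' Read nucleotide sequences from a FASTA file
#'
#' Records are returned as a data frame with one row per record and columns
#' `id`, `bases`, `genus`, `species`, `cites_listed` and `coi_offset`
#' (`NA` until a sequence is registered to COI coordinates). Bases are
#' upper-cased and `U` is mapped to `T` on ingest; any character outside the
#' IUPAC alphabet (`ACGTRYSWKMBDHVN-`) is rejected rather than silently
#' converted.
#'
#' Taxon labels are parsed from description lines of the form
#' `>id Genus species`; a sidecar taxon table (TSV with header
#' `id<TAB>genus<TAB>species<TAB>cites_listed`) overrides parsed labels,
#' because database headers vary too much to trust unconditionally.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param taxa_tsv Optional path to the sidecar taxon TSV.
#' @return A `nuc_seqs` data frame as described above.
#' @export
read_fasta <- function(path, taxa_tsv = NULL) {
  if (!file.exists(path))
    abort_parse(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_parse(
                    sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  desc <- names(set)
  bases <- toupper(as.character(set))
  bases <- chartr("U", "T", bases)
  tokens <- strsplit(trimws(desc), "[ \t]+")
  id <- vapply(tokens, `[`, character(1), 1L)
  if (any(is.na(id) | id == ""))
    abort_parse(sprintf("FASTA record %d in '%s' has an empty id",
                        which(is.na(id) | id == "")[1], path))
  if (anyDuplicated(id))
    abort_parse(sprintf("duplicate FASTA id '%s' in %s",
                        id[duplicated(id)][1], path))
  empty <- !nzchar(bases)
  if (any(empty))
    abort_parse(sprintf("FASTA record '%s' has an empty sequence", id[empty][1]))
  bad <- !grepl("^[ACGTRYSWKMBDHVN-]*$", bases)
  if (any(bad)) {
    ch <- setdiff(str_chars(bases[bad][1]), IUPAC_ALPHABET)
    abort_parse(sprintf("record '%s' contains non-IUPAC character(s): %s",
                        id[bad][1], paste(ch, collapse = ", ")))
  }
  genus <- vapply(tokens, function(t) if (length(t) >= 2) t[2] else NA_character_,
                  character(1))
  species <- vapply(tokens, function(t)
    if (length(t) >= 3) paste(t[2], t[3]) else NA_character_, character(1))
  out <- data.frame(id = id, bases = bases, genus = genus, species = species,
                    cites_listed = !is.na(species) & species %in% cites_species(),
                    coi_offset = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(taxa_tsv)) out <- apply_taxa_table(out, taxa_tsv)
  class(out) <- c("nuc_seqs", "data.frame")
  rownames(out) <- NULL
  out
}

apply_taxa_table <- function(seqs, taxa_tsv) {
  if (!file.exists(taxa_tsv))
    abort_parse(sprintf("taxon table not found: %s", taxa_tsv))
  tab <- utils::read.delim(taxa_tsv, stringsAsFactors = FALSE)
  need <- c("id", "genus", "species")
  if (!all(need %in% names(tab)))
    abort_parse("taxon table must have columns id, genus, species")
  m <- match(seqs$id, tab$id)
  hit <- !is.na(m)
  seqs$genus[hit] <- tab$genus[m[hit]]
  seqs$species[hit] <- tab$species[m[hit]]
  if ("cites_listed" %in% names(tab)) {
    seqs$cites_listed[hit] <- as.logical(tab$cites_listed[m[hit]])
  } else {
    seqs$cites_listed[hit] <- seqs$species[hit] %in% cites_species()
  }
  seqs
}

#' Write sequences to FASTA (and optionally a taxon sidecar TSV)
#'
#' Round-trips with [read_fasta()]: record order, ids, labels and base
#' strings are preserved exactly.
#'
#' @param seqs A `nuc_seqs` data frame (or anything with `id` and `bases`).
#' @param path Output FASTA path.
#' @param taxa_tsv Optional path for the sidecar taxon table.
#' @export
write_fasta <- function(seqs, path, taxa_tsv = NULL) {
  desc <- ifelse(is.na(seqs$species), seqs$id, paste(seqs$id, seqs$species))
  set <- Biostrings::BStringSet(seqs$bases)
  names(set) <- desc
  Biostrings::writeXStringSet(set, path, width = 70L)
  if (!is.null(taxa_tsv)) {
    tab <- data.frame(id = seqs$id, genus = seqs$genus, species = seqs$species,
                      cites_listed = seqs$cites_listed)
    utils::write.table(tab, taxa_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' The eight CITES Appendix II listed shark species
#'
#' Whale, basking and white shark (listed 2001-2004) plus oceanic whitetip,
#' porbeagle and the three large hammerheads (2013). These are the target
#' species of the bundled cCA key.
#'
#' @return Character vector of eight Latin binomials.
#' @export
cites_species <- function() {
  c("Rhincodon typus", "Cetorhinus maximus", "Carcharodon carcharias",
    "Carcharhinus longimanus", "Sphyrna lewini", "Sphyrna zygaena",
    "Sphyrna mokarran", "Lamna nasus")
}
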