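#' Build a COI-registered reference library
#'
#' A reference library is a labelled collection of aligned sequences whose
#' columns are registered to COI coordinates: column 1 of the alignment sits
#' at COI position `coordinate_offset` (1-based, counted from the COI start
#' codon). All public interfaces in the package speak COI coordinates; raw
#' column indices never leak out.
#'
#' @param seqs A `nuc_seqs` data frame (see [read_fasta()]). All sequences
#'   must have equal length and species labels.
#' @param coordinate_offset 1-based COI position of the first alignment
#'   column (>= 1).
#' @return An object of class `ref_library` with fields `ids`, `taxa`,
#'   `mat` (character matrix, records x columns), `masks` (IUPAC bitmask
#'   matrix), `coordinate_offset` and `width`.
#' @export
reference_library <- function(seqs, coordinate_offset = 1L) {
  coordinate_offset <- as.integer(coordinate_offset)
  if (is.na(coordinate_offset) || coordinate_offset < 1L)
    abort_input("coordinate_offset must be an integer >= 1")
  if (nrow(seqs) == 0L) abort_input("reference library needs at least one record")
  w <- unique(nchar(seqs$bases))
  if (length(w) != 1L)
    abort_input(sprintf(
      "all records must have equal aligned length; found lengths %s",
      paste(sort(w), collapse = ", ")))
  if (anyDuplicated(seqs$id))
    abort_input(sprintf("duplicate record id '%s'", seqs$id[duplicated(seqs$id)][1]))
  if (anyNA(seqs$species))
    abort_input(sprintf("record '%s' has no species label",
                        seqs$id[is.na(seqs$species)][1]))
  mat <- do.call(rbind, strsplit(seqs$bases, "", fixed = TRUE))
  rownames(mat) <- seqs$id
  masks <- matrix(iupac_mask(mat), nrow = nrow(mat),
                  dimnames = dimnames(mat))
  structure(list(
    ids = seqs$id,
    taxa = data.frame(id = seqs$id, genus = seqs$genus, species = seqs$species,
                      cites_listed = seqs$cites_listed,
                      stringsAsFactors = FALSE),
    mat = mat, masks = masks,
    coordinate_offset = coordinate_offset, width = w
  ), class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf(
    "COI reference library: %d records, %d species, columns = COI %d..%d\n",
    length(x$ids), length(unique(x$taxa$species)),
    x$coordinate_offset, x$coordinate_offset + x$width - 1L))
  tab <- sort(table(x$taxa$species), decreasing = TRUE)
  cat(paste(sprintf("  %-28s %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

# COI position -> alignment column index (with range checking).
coi_to_col <- function(library, pos) {
  col <- pos - library$coordinate_offset + 1L
  if (any(col < 1L | col > library$width))
    abort_coord(sprintf(
      "COI position(s) %s outside the registered range %d..%d",
      paste(pos[col < 1L | col > library$width], collapse = ", "),
      library$coordinate_offset, library$coordinate_offset + library$width - 1L))
  col
}

# COI coordinate range covered by the library.
coi_range <- function(library) {
  c(library$coordinate_offset, library$coordinate_offset + library$width - 1L)
}

#' Slice a sequence or library by COI positions
#'
#' Coordinates are 1-based and inclusive, numbered from the beginning of the
#' COI gene; the library's `coordinate_offset` maps them onto alignment
#' columns.
#'
#' @param x A `ref_library`, or a single-record `nuc_seqs` row whose
#'   `coi_offset` is set.
#' @param start,end COI positions (start <= end), both inclusive.
#' @param library For a `nuc_seqs` input without its own `coi_offset`, a
#'   `ref_library` supplying the offset.
#' @return Object of the same class as `x`, restricted to the requested
#'   positions; the returned `coi_offset`/`coordinate_offset` is `start`.
#' @export
slice_by_coi_positions <- function(x, start, end, library = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    abort_coord("need integer COI positions with start <= end")
  UseMethod("slice_by_coi_positions")
}

#' @export
slice_by_coi_positions.ref_library <- function(x, start, end, library = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  cols <- coi_to_col(x, start:end)
  out <- x
  out$mat <- x$mat[, cols, drop = FALSE]
  out$masks <- x$masks[, cols, drop = FALSE]
  out$coordinate_offset <- start
  out$width <- length(cols)
  out
}

#' @export
slice_by_coi_positions.data.frame <- function(x, start, end, library = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (nrow(x) != 1L)
    abort_input("slice_by_coi_positions() on sequences expects a single record")
  off <- x$coi_offset
  if (is.na(off) && !is.null(library)) off <- library$coordinate_offset
  if (is.na(off))
    abort_coord("sequence has no COI registration (coi_offset is NA)")
  len <- nchar(x$bases)
  if (start < off || end > off + len - 1L)
    abort_coord(sprintf("COI positions %d..%d outside the registered range %d..%d",
                        start, end, off, off + len - 1L))
  x$bases <- substr(x$bases, start - off + 1L, end - off + 1L)
  x$coi_offset <- start
  x
}

# One-row nuc_seqs constructor used by generators and the amplicon module.
nuc_seq_row <- function(id, bases, genus = NA_character_,
                        species = NA_character_, coi_offset = NA_integer_) {
  out <- data.frame(id = id, bases = bases, genus = genus, species = species,
                    cites_listed = !is.na(species) & species %in% cites_species(),
                    coi_offset = as.integer(coi_offset),
                    stringsAsFactors = FALSE)
  class(out) <- c("nuc_seqs", "data.frame")
  out
}

# Library -> nuc_seqs data frame (used by write paths and QC reports).
library_to_seqs <- function(library) {
  out <- data.frame(
    id = library$ids,
    bases = apply(library$mat, 1L, paste, collapse = ""),
    genus = library$taxa$genus, species = library$taxa$species,
    cites_listed = library$taxa$cites_listed,
    coi_offset = library$coordinate_offset, stringsAsFactors = FALSE)
  class(out) <- c("nuc_seqs", "data.frame")
  rownames(out) <- NULL
  out
}
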