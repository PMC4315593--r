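#' Compound character attribute (cCA) keys
#'
#' A cCA key is a shared, ordered set of COI positions together with one
#' IUPAC state per position per species, such that every pair of species is
#' separated (IUPAC-incompatible) at at least one position. It is a
#' character-based diagnosis: a query is a candidate for a species when its
#' bases are compatible with that species' states at every covered position.
#'
#' @param positions Integer vector of COI positions (strictly increasing).
#' @param rows Character matrix, species x positions, single IUPAC character
#'   per cell (species names as rownames), or a named character vector of
#'   state strings.
#' @param relatives Named list: target species -> character vector of the
#'   relative species used when the key was constructed.
#' @param low_confidence_positions Subset of `positions` flagged unreliable
#'   (excluded from matching unless explicitly enabled).
#' @return Object of class `cca_key`.
#' @export
cca_key <- function(positions, rows, relatives = list(),
                    low_confidence_positions = integer(0)) {
  positions <- as.integer(positions)
  if (is.character(rows) && !is.matrix(rows))
    rows <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (is.null(rownames(rows)) || anyDuplicated(rownames(rows)))
    abort_input("key rows need unique species rownames")
  if (ncol(rows) != length(positions))
    abort_input(sprintf("rows have %d states but %d positions declared",
                        ncol(rows), length(positions)))
  if (is.unsorted(positions, strictly = TRUE))
    abort_input("key positions must be strictly increasing COI coordinates")
  iupac_mask(as.vector(rows))
  if (!all(low_confidence_positions %in% positions))
    abort_input("low_confidence_positions must be a subset of positions")
  colnames(rows) <- positions
  key <- structure(list(positions = positions, rows = rows,
                        relatives = relatives,
                        low_confidence_positions =
                          as.integer(low_confidence_positions)),
                   class = "cca_key")
  validate_cca_key(key)
  key
}

# Pairwise-uniqueness invariant: every pair of rows must be incompatible at
# >= 1 position, otherwise the key cannot distinguish the pair.
validate_cca_key <- function(key) {
  sp <- rownames(key$rows)
  if (length(sp) >= 2L) for (i in 1:(length(sp) - 1L)) for (j in (i + 1L):length(sp)) {
    if (all(compatible(key$rows[i, ], key$rows[j, ])))
      abort_degenerate(sprintf(
        "key rows for '%s' and '%s' are compatible at every position",
        sp[i], sp[j]))
  }
  invisible(key)
}

#' @export
print.cca_key <- function(x, ...) {
  cat(sprintf("cCA key: %d species x %d COI positions (%d..%d)\n",
              nrow(x$rows), length(x$positions),
              min(x$positions), max(x$positions)))
  if (length(x$low_confidence_positions))
    cat("  low-confidence positions:",
        paste(x$low_confidence_positions, collapse = ", "), "\n")
  print(x$rows, quote = FALSE)
  invisible(x)
}

#' Greedily choose diagnostic COI positions for one target species
#'
#' Returns a position set such that for every relative there is at least one
#' chosen position where the target and relative consensus states are
#' IUPAC-incompatible. Selection is greedy set cover: each step takes the
#' position separating the most not-yet-separated relatives, ties broken by
#' the smaller COI position, which makes the output deterministic.
#'
#' @param target A `species_consensus`.
#' @param relatives List of `species_consensus` for the close relatives.
#' @param candidate_region Length-2 COI interval to draw positions from.
#' @return Increasing integer vector of COI positions.
#' @export
diagnostic_positions <- function(target, relatives,
                                 candidate_region = c(57L, 174L)) {
  if (length(relatives) == 0L) abort_input("no relatives supplied")
  lens <- vapply(relatives, function(r) nchar(r$bases), integer(1))
  if (any(lens != nchar(target$bases)))
    abort_input("target and relative consensuses differ in length")
  pos <- max(candidate_region[1], target$coi_offset):
    min(candidate_region[2], target$coi_offset + nchar(target$bases) - 1L)
  tstates <- consensus_states(target, pos)
  sep <- vapply(relatives, function(r)
    !compatible(tstates, consensus_states(r, pos)), logical(length(pos)))
  sep <- matrix(sep, nrow = length(pos))  # positions x relatives
  chosen <- integer(0)
  uncovered <- rep(TRUE, length(relatives))
  while (any(uncovered)) {
    gain <- rowSums(sep[, uncovered, drop = FALSE])
    if (max(gain) == 0L) {
      bad <- which(uncovered)[1]
      nm <- relatives[[bad]]$species
      abort_inseparable(sprintf(
        "species '%s' cannot be separated from relative '%s' at any candidate position",
        target$species, if (is.na(nm)) as.character(bad) else nm))
    }
    pick <- which.max(gain)  # first maximum = smallest COI position
    chosen <- c(chosen, pos[pick])
    uncovered <- uncovered & !sep[pick, ]
  }
  sort(chosen)
}

#' Build a cCA key from per-species consensuses
#'
#' Takes the union of the per-target greedy diagnostic position sets as one
#' shared position list (the bundled key likewise uses a single common set
#' of 21 positions for all eight species) and records every supplied
#' species' consensus state at each shared position. Passing `positions`
#' explicitly skips position selection and evaluates the given positions
#' (used e.g. to express a key on a prescribed position set).
#'
#' @param consensuses Named list of `species_consensus` (targets and
#'   relatives alike).
#' @param targets Character vector of target species (default: all).
#' @param relatives_map Named list target -> character vector of relatives;
#'   default: all other supplied species.
#' @param candidate_region COI interval positions may be drawn from.
#' @param positions Optional explicit COI position vector.
#' @param low_confidence_positions Passed through to the key.
#' @return A validated [cca_key()].
#' @export
build_cca_key <- function(consensuses, targets = names(consensuses),
                          relatives_map = NULL,
                          candidate_region = c(57L, 174L), positions = NULL,
                          low_confidence_positions = integer(0)) {
  if (is.null(names(consensuses)))
    names(consensuses) <- vapply(consensuses, `[[`, character(1), "species")
  if (is.null(relatives_map))
    relatives_map <- stats::setNames(
      lapply(targets, function(t) setdiff(names(consensuses), t)), targets)
  missing <- setdiff(unique(c(targets, unlist(relatives_map))),
                     names(consensuses))
  if (length(missing))
    abort_input(sprintf("no consensus supplied for: %s",
                        paste(missing, collapse = ", ")))
  if (is.null(positions)) {
    per_target <- lapply(targets, function(t)
      diagnostic_positions(consensuses[[t]], consensuses[relatives_map[[t]]],
                           candidate_region))
    positions <- sort(unique(unlist(per_target)))
  }
  rows <- matrix(
    unlist(lapply(consensuses, consensus_states,
                  positions = as.integer(positions))),
    nrow = length(consensuses), byrow = TRUE,
    dimnames = list(names(consensuses), NULL))
  cca_key(positions, rows, relatives = relatives_map,
          low_confidence_positions = low_confidence_positions)
}

#' Number of diagnostic differences between two key rows
#'
#' Counts positions whose states are IUPAC-*incompatible* (empty base-set
#' intersection); mere character inequality (e.g. `R` vs `G`) does not
#' count, because a polymorphic individual could carry either base.
#'
#' @param key A `cca_key`.
#' @param species_a,species_b Row names present in the key.
#' @return Non-negative integer count.
#' @export
key_row_distance <- function(key, species_a, species_b) {
  for (sp in c(species_a, species_b))
    if (!sp %in% rownames(key$rows))
      abort_lookup(sprintf("species '%s' is not in the key", sp))
  sum(!compatible(key$rows[species_a, ], key$rows[species_b, ]))
}

#' Read / write cCA keys as TSV (+ JSON metadata sidecar)
#'
#' TSV dialect: header `species<TAB>p<pos1><TAB>p<pos2>...`, one row per
#' species, one IUPAC character per cell. The optional JSON sidecar stores
#' the relatives map and low-confidence position flags.
#'
#' @param path Key TSV path.
#' @param meta_path Optional JSON sidecar path.
#' @return `read_cca_key()` returns a `cca_key`.
#' @export
read_cca_key <- function(path, meta_path = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("key file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1] != "species" || ncol(tab) < 2L)
    abort_parse("key TSV must have a 'species' column followed by p<pos> columns")
  posnames <- names(tab)[-1]
  if (!all(grepl("^p[0-9]+$", posnames)))
    abort_parse("key TSV position columns must be named p<COI position>")
  positions <- as.integer(sub("^p", "", posnames))
  rows <- as.matrix(tab[, -1, drop = FALSE])
  rownames(rows) <- tab$species
  relatives <- list(); low_conf <- integer(0)
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$relatives)) relatives <- as.list(meta$relatives)
    if (!is.null(meta$low_confidence_positions))
      low_conf <- as.integer(meta$low_confidence_positions)
  }
  cca_key(positions, rows, relatives = relatives,
          low_confidence_positions = low_conf)
}

#' @rdname read_cca_key
#' @param key A `cca_key` to serialise.
#' @export
write_cca_key <- function(key, path, meta_path = NULL) {
  tab <- data.frame(species = rownames(key$rows),
                    key$rows, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("species", paste0("p", key$positions))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(
      list(relatives = key$relatives,
           low_confidence_positions = key$low_confidence_positions),
      meta_path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
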