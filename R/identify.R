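#' Identity search against a COI-registered reference library
#'
#' Deterministic, alignment-free stand-in for a BLAST/BOLD query: when the
#' query is COI-registered its bases are compared column-by-column with each
#' reference over the overlapping COI interval; a query with unknown
#' registration is first placed by [register_query_offset()]. Identity is
#' the percentage of compared columns whose states are IUPAC-compatible,
#' reported to one decimal; coverage is the percentage of the query included
#' in the comparison. Columns where the query carries an alignment gap are
#' excluded from the comparison.
#'
#' @param query Single-record `nuc_seqs` row (or list with `id`, `bases`,
#'   `coi_offset`).
#' @param library A `ref_library`.
#' @param min_overlap Minimum number of compared columns for a hit to be
#'   reported (default 80).
#' @return Data frame of class `search_hits`, sorted by identity descending,
#'   ties by coverage descending then `reference_id`: columns
#'   `reference_id`, `genus`, `species`, `identity`, `coverage`,
#'   `compared`, `compatible_columns`, `perfect` (all compared columns
#'   compatible), `rank`.
#' @export
identity_search <- function(query, library, min_overlap = 80L) {
  if (length(library$ids) == 0L) abort_input("empty reference library")
  if (is.na(query$coi_offset))
    query$coi_offset <- register_query_offset(query, library, min_overlap)
  qlen <- nchar(query$bases)
  if (qlen < min_overlap)
    abort_input(sprintf("query '%s' is shorter than min_overlap = %d",
                        query$id, min_overlap))
  qr <- c(query$coi_offset, query$coi_offset + qlen - 1L)
  lr <- coi_range(library)
  s <- max(qr[1], lr[1]); e <- min(qr[2], lr[2])
  if (s > e) abort_input("query does not overlap the library's COI range")
  qm <- str_masks(query$bases)[(s - qr[1] + 1L):(e - qr[1] + 1L)]
  sub <- library$masks[, (s - lr[1] + 1L):(e - lr[1] + 1L), drop = FALSE]
  use <- qm > 0L  # drop query gap columns
  qm <- qm[use]; sub <- sub[, use, drop = FALSE]
  compared <- length(qm)
  if (compared < min_overlap)
    return(empty_hits())
  ok <- matrix(bitwAnd(sub, matrix(qm, nrow(sub), compared, byrow = TRUE)) > 0L,
               nrow = nrow(sub))  # bitwAnd drops dim attributes
  comp <- rowSums(ok)
  raw <- 100 * comp / compared
  out <- data.frame(
    reference_id = library$ids, genus = library$taxa$genus,
    species = library$taxa$species,
    identity = round(raw, 1), coverage = round(100 * compared / qlen, 1),
    compared = compared, compatible_columns = comp,
    perfect = comp == compared, stringsAsFactors = FALSE)
  out <- out[order(-raw, -out$coverage, out$reference_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("search_hits", "data.frame")
  out
}

empty_hits <- function() {
  out <- data.frame(reference_id = character(0), genus = character(0),
                    species = character(0), identity = numeric(0),
                    coverage = numeric(0), compared = integer(0),
                    compatible_columns = integer(0), perfect = logical(0),
                    rank = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("search_hits", "data.frame")
  out
}

#' Register an unplaced query to COI coordinates
#'
#' Slides the query along the library-wide union consensus and returns the
#' COI offset maximising the number of compatible columns (requiring at
#' least `min_overlap` columns of overlap); ties resolve to the smallest
#' offset, keeping registration deterministic.
#'
#' @inheritParams identity_search
#' @return Integer COI offset for the query's first base.
#' @export
register_query_offset <- function(query, library, min_overlap = 80L) {
  qm <- str_masks(query$bases)
  qlen <- length(qm)
  cons <- build_consensus(library)
  cm <- str_masks(cons$bases)
  lr <- coi_range(library)
  offs <- (lr[1] - qlen + min_overlap):(lr[2] - min_overlap + 1L)
  if (length(offs) == 0L || offs[1] > offs[length(offs)])
    abort_input("query too short to register against the library")
  best_off <- NA_integer_; best <- -1L
  for (o in offs) {
    s <- max(o, lr[1]); e <- min(o + qlen - 1L, lr[2])
    if (e - s + 1L < min_overlap) next
    qi <- (s - o + 1L):(e - o + 1L)
    ci <- (s - lr[1] + 1L):(e - lr[1] + 1L)
    score <- sum(bitwAnd(qm[qi], cm[ci]) > 0L)
    if (score > best) { best <- score; best_off <- o }
  }
  if (is.na(best_off)) abort_input("query could not be registered")
  best_off
}

#' Match a query against a cCA key
#'
#' For each key row, counts the covered key positions where the query base
#' and the row state are IUPAC-incompatible. Candidates are the rows with
#' zero incompatibilities. Low-confidence positions (for the bundled key,
#' COI 60, which sits in the poorly resolved early part of the read) are
#' excluded unless `use_low_confidence = TRUE`.
#'
#' @param query COI-registered single-record `nuc_seqs` row.
#' @param key A `cca_key`.
#' @param use_low_confidence Include low-confidence positions (default
#'   `FALSE`).
#' @return List with `candidates` (character vector of species with zero
#'   incompatibilities), `incompatibilities` (named integer vector) and
#'   `positions_used`.
#' @export
cca_match <- function(query, key, use_low_confidence = FALSE) {
  if (is.na(query$coi_offset))
    abort_input(sprintf("query '%s' must be COI-registered for cCA matching",
                        query$id))
  pos <- key$positions
  if (!use_low_confidence) pos <- setdiff(pos, key$low_confidence_positions)
  qr <- c(query$coi_offset, query$coi_offset + nchar(query$bases) - 1L)
  pos <- pos[pos >= qr[1] & pos <= qr[2]]
  if (length(pos)) {
    qstates <- str_chars(query$bases)[pos - qr[1] + 1L]
    keep <- qstates != "-"  # a gap carries no information about the base
    pos <- pos[keep]; qstates <- qstates[keep]
  }
  if (length(pos) == 0L)
    abort_noinfo(sprintf("query '%s' covers no usable cCA position", query$id))
  cols <- match(pos, key$positions)
  counts <- apply(key$rows[, cols, drop = FALSE], 1L, function(states)
    sum(!compatible(qstates, states)))
  list(candidates = names(counts)[counts == 0L],
       incompatibilities = counts, positions_used = pos)
}

#' Two-track identification of a mini-barcode query
#'
#' Implements the combined identification strategy: a reference-library
#' identity search (the BLAST/BOLD stand-in) plus an independent cCA check,
#' merged into a final call by an explicit cascade:
#'
#' 1. **species** -- the top identity is 100, unique to a single species,
#'    and (when that species has a key row) the cCA candidate set is exactly
#'    that species;
#' 2. **candidate_set** -- the cCA candidates are a multi-species set whose
#'    members sit mutually closer than `min_separation` diagnostic positions
#'    in the key, so the short fragment cannot tell them apart (the oceanic
#'    whitetip case: whitetip / dusky / Galapagos / Caribbean reef);
#' 3. **genus** -- all maximal-identity hits share one genus;
#' 4. **unidentified** otherwise.
#'
#' Disagreement between the two tracks (e.g. the search names a species the
#' cCA excludes) sets `discordance_flag`; it is reported, never silently
#' resolved, because the cCA is an *independent* check.
#'
#' @inheritParams identity_search
#' @param key A `cca_key` (the bundled key via [load_table3_key()]).
#' @param min_separation Minimum number of diagnostic positions below which
#'   two key species are considered indistinguishable by the cCA alone
#'   (default 2).
#' @param use_low_confidence Passed to [cca_match()].
#' @return Object of class `shark_id`: list with `query_id`, `top_hits`,
#'   `unique_top`, `search_call`, `cca_candidates`, `cca_incompatibilities`,
#'   `final_level` (`"species"`, `"candidate_set"`, `"genus"`,
#'   `"unidentified"`), `final_taxa`, `discordance_flag`.
#' @export
identify <- function(query, library, key, min_overlap = 80L,
                     min_separation = 2L, use_low_confidence = FALSE) {
  if (is.na(query$coi_offset))
    query$coi_offset <- register_query_offset(query, library, min_overlap)
  hits <- identity_search(query, library, min_overlap)
  cca <- tryCatch(cca_match(query, key, use_low_confidence),
                  sharkid_no_information_error = function(e) NULL)
  candidates <- if (is.null(cca)) character(0) else cca$candidates

  if (nrow(hits) == 0L) {
    top <- hits; unique_top <- FALSE; search_call <- NULL
  } else {
    ratio <- hits$compatible_columns / hits$compared  # unrounded identity
    top <- hits[ratio == max(ratio), , drop = FALSE]
    sp <- unique(top$species)
    gn <- unique(top$genus)
    unique_top <- length(sp) == 1L
    search_call <- if (unique_top) list(level = "species", taxon = sp)
      else if (length(gn) == 1L) list(level = "genus", taxon = gn)
      else NULL
  }

  in_key <- function(s) s %in% rownames(key$rows)
  perfect <- nrow(top) > 0L && all(top$perfect)
  discord <- FALSE
  final_level <- "unidentified"; final_taxa <- character(0)

  if (perfect && unique_top) {
    sp <- top$species[1]
    if (!in_key(sp)) {
      final_level <- "species"; final_taxa <- sp
      if (length(candidates) > 0L) discord <- TRUE  # cCA claims a key species
    } else if (identical(candidates, sp)) {
      final_level <- "species"; final_taxa <- sp
    } else if (!(sp %in% candidates)) {
      discord <- TRUE  # the cCA excludes the species the search named
    }
    # candidates containing sp plus unexcluded neighbours is under-resolution
    # of a short fragment, not track conflict: fall through without a flag
  }
  if (final_level == "unidentified" && length(candidates) >= 2L) {
    d <- utils::combn(candidates, 2L, function(p)
      key_row_distance(key, p[1], p[2]))
    if (all(d < min_separation)) {
      final_level <- "candidate_set"
      final_taxa <- sort(candidates)
    }
  }
  if (final_level == "unidentified" && !is.null(search_call)) {
    gn <- unique(top$genus)
    if (length(gn) == 1L && !is.na(gn)) {
      final_level <- "genus"; final_taxa <- gn
    }
  }
  if (!discord && !is.null(search_call) && search_call$level == "species" &&
      in_key(search_call$taxon) && !is.null(cca) &&
      !(search_call$taxon %in% candidates))
    discord <- TRUE

  structure(list(query_id = query$id, top_hits = top, unique_top = unique_top,
                 search_call = search_call, cca_candidates = candidates,
                 cca_incompatibilities =
                   if (is.null(cca)) NULL else cca$incompatibilities,
                 final_level = final_level, final_taxa = final_taxa,
                 discordance_flag = discord),
            class = "shark_id")
}

#' @export
print.shark_id <- function(x, ...) {
  taxa <- if (length(x$final_taxa)) paste(x$final_taxa, collapse = " / ")
    else "-"
  cat(sprintf("%s: %s (%s)%s\n", x$query_id, taxa, x$final_level,
              if (x$discordance_flag) " [tracks discordant]" else ""))
  invisible(x)
}

#' Identify a panel of queries
#'
#' @param queries A `nuc_seqs` data frame.
#' @inheritParams identify
#' @return A list of `shark_id` results; `as.data.frame()` turns it into a
#'   report table (columns mirroring the published result tables: query_id,
#'   top_hit, coverage, identity, unique, cca_candidates, final_call,
#'   discordant).
#' @export
identify_all <- function(queries, library, key, min_overlap = 80L,
                         min_separation = 2L, use_low_confidence = FALSE) {
  out <- lapply(seq_len(nrow(queries)), function(i)
    identify(queries[i, , drop = FALSE], library, key, min_overlap,
             min_separation, use_low_confidence))
  class(out) <- "shark_id_list"
  out
}

#' @export
as.data.frame.shark_id_list <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    query_id = r$query_id,
    top_hit = if (nrow(r$top_hits)) r$top_hits$species[1] else NA_character_,
    coverage = if (nrow(r$top_hits)) r$top_hits$coverage[1] else NA_real_,
    identity = if (nrow(r$top_hits)) r$top_hits$identity[1] else NA_real_,
    unique = ifelse(r$unique_top, "Yes", "No"),
    cca_candidates = paste(r$cca_candidates, collapse = ";"),
    final_call = paste0(r$final_level,
                        if (length(r$final_taxa))
                          paste0(":", paste(r$final_taxa, collapse = ";"))
                        else ""),
    discordant = r$discordance_flag, stringsAsFactors = FALSE)))
}

#' Tabulate identification calls by sample type
#'
#' Accepts either a list of identification results (with an optional
#' `sample_types` vector, matched by query id) or an already-loaded results
#' table such as the bundled published results fixture (columns `type` and
#' `id`). Rows are ordered by taxon name then sample type, so output is
#' deterministic.
#'
#' @param x `shark_id_list`, report data frame, or fixture data frame.
#' @param sample_types Optional named character vector query_id -> type.
#' @return Data frame with columns `taxon`, `sample_type`, `count`.
#' @export
tabulate_identifications <- function(x, sample_types = NULL) {
  if (inherits(x, "shark_id_list")) x <- as.data.frame(x)
  if (nrow(x) == 0L)
    return(data.frame(taxon = character(0), sample_type = character(0),
                      count = integer(0)))
  if (all(c("type", "id") %in% names(x))) {
    taxon <- x$id; type <- x$type
  } else {
    taxon <- sub("^[a-z_]+:", "", x$final_call)
    taxon[x$final_call == "unidentified"] <- "unidentified"
    type <- if (is.null(sample_types)) rep("all", nrow(x))
      else unname(sample_types[x$query_id])
  }
  tab <- as.data.frame(table(taxon = taxon, sample_type = type),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3] <- "count"
  tab <- tab[order(tab$taxon, tab$sample_type), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
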