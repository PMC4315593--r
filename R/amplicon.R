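#' The mini-barcode primer cocktail
#'
#' The assay multiplexes two overlapping M13-tailed universal fish barcoding
#' forward primers (FishF2_t1, VF2_t1; the leading 18 bases
#' `TGTAAAACGACGGCCAGT` are the M13 tail) with a shark-specific reverse
#' primer (Shark COI-MINIR `AAGATTACAAAAGCGTGGGC`) that anneals to a
#' conserved region ~150 bp into the COI gene. The tail is metadata: it does
#' not bind template on the first cycles, so it is excluded from annealing
#' comparison.
#'
#' @param forward_primers Data frame with columns `name`, `bases`,
#'   `tail_length`. Whitespace in `bases` is stripped.
#' @param reverse_primer List or data frame row with `name` and `bases`.
#' @param max_mismatches Mismatch tolerance outside the 3' clamp (default 2).
#' @param three_prime_clamp Number of 3'-terminal primer bases where any
#'   mismatch disqualifies a site (default 3).
#' @return An object of class `primer_set`.
#' @export
primer_set <- function(
    forward_primers = data.frame(
      name = c("FishF2_t1", "VF2_t1"),
      bases = c("TGTAAAACGACGGCCAGTCGACTAATCATAAAGATATCGGCAC",
                "TGTAAAACGACGGCCAGTCAACCAACCACAAAGACATTGGCAC"),
      tail_length = c(18L, 18L), stringsAsFactors = FALSE),
    reverse_primer = list(name = "Shark_COI-MINIR",
                          bases = "AAGATTACAAAAGCGTGGGC"),
    max_mismatches = 2L, three_prime_clamp = 3L) {
  forward_primers$bases <- gsub("[[:space:]]+", "", forward_primers$bases)
  reverse_primer$bases <- gsub("[[:space:]]+", "", reverse_primer$bases)
  iupac_mask(unlist(strsplit(c(forward_primers$bases, reverse_primer$bases), "")))
  if (any(forward_primers$tail_length >= nchar(forward_primers$bases)))
    abort_input("tail_length must be shorter than the primer carrying it")
  structure(list(forward_primers = forward_primers,
                 reverse_primer = reverse_primer,
                 max_mismatches = as.integer(max_mismatches),
                 three_prime_clamp = as.integer(three_prime_clamp)),
            class = "primer_set")
}

#' Locate degenerate-primer annealing sites on a template
#'
#' Scans the requested strand for windows where the primer and template are
#' IUPAC-compatible at all but at most `max_mismatches` positions, with zero
#' mismatches allowed within the 3'-terminal clamp (polymerase extension is
#' intolerant of 3' mismatches). Reverse orientation scans the reverse
#' complement; intervals are always reported in template coordinates.
#'
#' @param template A single-record `nuc_seqs` row, or a plain base string.
#' @param primer Primer base string (IUPAC characters allowed).
#' @param orientation `"forward"` or `"reverse"`.
#' @param max_mismatches,three_prime_clamp See [primer_set()].
#' @return Data frame with columns `start`, `end` (template coordinates,
#'   1-based inclusive), `mismatches` and `orientation`, sorted by
#'   (mismatches, start).
#' @export
find_annealing_sites <- function(template, primer,
                                 orientation = c("forward", "reverse"),
                                 max_mismatches = 2L, three_prime_clamp = 3L) {
  orientation <- match.arg(orientation)
  bases <- if (is.data.frame(template)) template$bases else template
  if (!nzchar(bases)) abort_input("template is empty")
  n <- nchar(bases)
  L <- nchar(primer)
  if (L > n) abort_input("primer is longer than the template")
  scan <- if (orientation == "reverse") reverse_complement(bases) else bases
  tm <- str_masks(scan)
  pm <- str_masks(primer)
  clamp_idx <- if (three_prime_clamp > 0L) (L - three_prime_clamp + 1L):L else integer(0)
  starts <- integer(0); mism <- integer(0)
  for (s in 1:(n - L + 1L)) {
    ok <- bitwAnd(tm[s:(s + L - 1L)], pm) > 0L
    if (length(clamp_idx) && !all(ok[clamp_idx])) next
    mm <- sum(!ok)
    if (mm <= max_mismatches) {
      starts <- c(starts, s); mism <- c(mism, mm)
    }
  }
  if (orientation == "reverse" && length(starts)) {
    # map intervals on the reverse-complement back to plus-strand coordinates
    ends <- n - starts + 1L
    starts <- n - (starts + L - 1L) + 1L
  } else {
    ends <- starts + L - 1L
  }
  out <- data.frame(start = starts, end = ends, mismatches = mism,
                    orientation = rep(orientation, length(starts)))
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' In-silico PCR with the mini-barcode primer cocktail
#'
#' Pairs every forward annealing site (either forward primer, tail excluded
#' from the comparison) with every downstream reverse-primer site whose
#' insert length falls within `insert_bounds`, mimicking the multiplex
#' reaction. The *insert* is the sequencable portion between the primer
#' footprints; the *amplicon* includes them.
#'
#' @param template Single-record `nuc_seqs` row (its `coi_offset`, default 1,
#'   registers the reported COI coordinates) or a plain base string.
#' @param primers A [primer_set()].
#' @param insert_bounds Allowed insert length range; the defaults reject
#'   spurious pairings of multiplexed primers on synthetic templates.
#' @return Data frame of class `amplicon_hits`, one row per product, sorted
#'   by total mismatches then leftmost forward site: columns `template_id`,
#'   `forward_primer`, `fwd_start`, `fwd_end`, `rev_start`, `rev_end`
#'   (template coordinates), `mismatches`, `amplicon_length`,
#'   `insert_length`, `insert`, `insert_coi_start`, `insert_coi_end`.
#' @export
insilico_pcr <- function(template, primers = primer_set(),
                         insert_bounds = c(30L, 1000L)) {
  if (!is.data.frame(template))
    template <- nuc_seq_row("template", template, coi_offset = 1L)
  if (is.na(template$coi_offset)) template$coi_offset <- 1L
  bases <- template$bases
  off <- template$coi_offset
  rev_sites <- find_annealing_sites(bases, primers$reverse_primer$bases,
                                    "reverse", primers$max_mismatches,
                                    primers$three_prime_clamp)
  hits <- list()
  for (i in seq_len(nrow(primers$forward_primers))) {
    p <- primers$forward_primers[i, ]
    anneal <- substr(p$bases, p$tail_length + 1L, nchar(p$bases))
    fwd_sites <- find_annealing_sites(bases, anneal, "forward",
                                      primers$max_mismatches,
                                      primers$three_prime_clamp)
    for (f in seq_len(nrow(fwd_sites))) for (r in seq_len(nrow(rev_sites))) {
      fs <- fwd_sites[f, ]; rs <- rev_sites[r, ]
      if (fs$end >= rs$start) next
      ins_len <- rs$start - fs$end - 1L
      if (ins_len < insert_bounds[1] || ins_len > insert_bounds[2]) next
      hits[[length(hits) + 1L]] <- data.frame(
        template_id = template$id, forward_primer = p$name,
        fwd_start = fs$start, fwd_end = fs$end,
        rev_start = rs$start, rev_end = rs$end,
        mismatches = fs$mismatches + rs$mismatches,
        amplicon_length = rs$end - fs$start + 1L,
        insert_length = ins_len,
        insert = substr(bases, fs$end + 1L, rs$start - 1L),
        insert_coi_start = fs$end + 1L + off - 1L,
        insert_coi_end = rs$start - 1L + off - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    template_id = character(0), forward_primer = character(0),
    fwd_start = integer(0), fwd_end = integer(0), rev_start = integer(0),
    rev_end = integer(0), mismatches = integer(0),
    amplicon_length = integer(0), insert_length = integer(0),
    insert = character(0), insert_coi_start = integer(0),
    insert_coi_end = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$mismatches, out$fwd_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("amplicon_hits", "data.frame")
  out
}

#' Trim an amplicon insert to the readable region
#'
#' Sanger reads off the M13 primer reliably resolve only part of the insert;
#' the readable region default `[57, 174]` in COI coordinates is the span of
#' the bundled cCA key positions. It is configuration, not a constant.
#'
#' @param hit One row of an `amplicon_hits` data frame.
#' @param readable_region Length-2 COI interval, inclusive.
#' @return A single-record `nuc_seqs` row with `coi_offset` set to the
#'   trimmed start.
#' @export
trim_to_readable <- function(hit, readable_region = c(57L, 174L)) {
  if (nrow(hit) != 1L) abort_input("trim_to_readable() expects a single hit")
  s <- max(hit$insert_coi_start, readable_region[1])
  e <- min(hit$insert_coi_end, readable_region[2])
  if (s > e)
    abort_trim(sprintf(
      "insert (COI %d..%d) does not overlap the readable region %d..%d",
      hit$insert_coi_start, hit$insert_coi_end,
      readable_region[1], readable_region[2]))
  bases <- substr(hit$insert, s - hit$insert_coi_start + 1L,
                  e - hit$insert_coi_start + 1L)
  nuc_seq_row(hit$template_id, bases, coi_offset = s)
}
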