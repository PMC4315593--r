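#' IUPAC nucleotide ambiguity algebra
#'
#' The cCA key and per-species consensus sequences use the standard IUPAC
#' single-letter ambiguity codes to encode within-species polymorphism (e.g.
#' `K` = G or T). Two states are *compatible* when their base sets intersect;
#' compatibility -- not plain character equality -- is the relation used
#' throughout for diagnosis, identity and distance, so that a polymorphic
#' consensus state such as `R` is never scored as differing from `G`.
#'
#' The alignment gap `-` expands to the empty set and is therefore
#' incompatible with everything, including itself and `N`: a gap is an
#' alignment artefact, `N` is an unknown base, and the two are deliberately
#' not interchangeable.
#'
#' @param code A single IUPAC character (one of `ACGTRYSWKMBDHVN-`).
#' @return `iupac_set()` returns a character vector of the unambiguous bases
#'   the code stands for (empty for `-`).
#' @examples
#' iupac_set("K")            # G, T
#' compatible("T", "K")      # TRUE
#' compatible("A", "K")      # FALSE
#' @export
iupac_set <- function(code) {
  m <- iupac_mask(code)
  if (length(m) != 1L)
    abort_domain("iupac_set() expects a single character")
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

# Bitmask encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions; gap is 0.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 0L
)

# Minimal IUPAC code covering each of the 16 possible base-set masks.
MASK_TO_CODE <- c("-", "A", "C", "M", "G", "R", "S", "V",
                  "T", "W", "Y", "H", "K", "D", "B", "N")

IUPAC_ALPHABET <- names(IUPAC_MASK)

# Vectorised character -> mask with domain checking.
iupac_mask <- function(x) {
  m <- IUPAC_MASK[x]
  if (anyNA(m)) {
    bad <- unique(x[is.na(m)])
    abort_domain(sprintf("character(s) outside the IUPAC alphabet: %s",
                         paste(bad, collapse = ", ")))
  }
  unname(m)
}

mask_to_code <- function(mask) MASK_TO_CODE[mask + 1L]

#' @rdname iupac_set
#' @param a,b IUPAC characters (vectorised, recycled to common length).
#' @return `compatible()` returns a logical vector: `TRUE` where the two
#'   codes' base sets intersect.
#' @export
compatible <- function(a, b) {
  bitwAnd(iupac_mask(a), iupac_mask(b)) > 0L
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes complement set-wise (`R` <-> `Y`, `K` <-> `M`,
#' `B` <-> `V`, `D` <-> `H`); `S`, `W`, `N` and `-` are self-complementary.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# String <-> character helpers used across modules.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_str <- function(ch) paste(ch, collapse = "")
str_masks <- function(x) iupac_mask(str_chars(x))
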