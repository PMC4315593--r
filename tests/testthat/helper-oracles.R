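# Independent oracles: deliberately naive re-implementations used only to
# check package output. They share no code with the package internals.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), `-` = character(0))

oracle_compatible <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N", `-` = "-")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force degenerate primer scan over every offset of the given strand.
oracle_scan <- function(template, primer, orientation, max_mm, clamp) {
  scan <- if (orientation == "reverse") oracle_revcomp(template) else template
  tch <- strsplit(scan, "")[[1]]
  pch <- strsplit(primer, "")[[1]]
  L <- length(pch); n <- length(tch)
  res <- data.frame(start = integer(0), end = integer(0),
                    mismatches = integer(0))
  for (s in seq_len(n - L + 1)) {
    ok <- mapply(oracle_compatible, tch[s:(s + L - 1)], pch)
    if (clamp > 0 && any(!ok[(L - clamp + 1):L])) next
    if (sum(!ok) > max_mm) next
    if (orientation == "reverse") {
      res <- rbind(res, data.frame(start = n - (s + L - 1) + 1,
                                   end = n - s + 1, mismatches = sum(!ok)))
    } else {
      res <- rbind(res, data.frame(start = s, end = s + L - 1,
                                   mismatches = sum(!ok)))
    }
  }
  res[order(res$mismatches, res$start), , drop = FALSE]
}

# Naive per-column identity between a registered query and one reference.
oracle_identity <- function(qbases, qoff, rbases, roff) {
  qch <- strsplit(qbases, "")[[1]]; rch <- strsplit(rbases, "")[[1]]
  s <- max(qoff, roff); e <- min(qoff + length(qch) - 1, roff + length(rch) - 1)
  if (s > e) return(NULL)
  qi <- (s - qoff + 1):(e - qoff + 1); ri <- (s - roff + 1):(e - roff + 1)
  use <- qch[qi] != "-"
  qs <- qch[qi][use]; rs <- rch[ri][use]
  comp <- sum(mapply(oracle_compatible, qs, rs))
  list(identity = round(100 * comp / length(qs), 1),
       coverage = round(100 * length(qs) / length(qch), 1),
       compared = length(qs))
}

# Exhaustive minimum set cover for diagnostic-position selection:
# sep = logical matrix positions x relatives.
oracle_min_cover_size <- function(sep) {
  np <- nrow(sep)
  for (k in 1:np) {
    for (subset in utils::combn(np, k, simplify = FALSE)) {
      if (all(colSums(sep[subset, , drop = FALSE]) > 0)) return(k)
    }
  }
  Inf
}

# Small handmade aligned library: 2 species x 2 records, 120 columns,
# registered at COI 57.
tiny_library <- function() {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  swap <- function(x, pos) {
    substr(x, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(x, pos, pos))[1]
    x
  }
  a1 <- base
  a2 <- swap(base, 10)
  b <- base
  for (p in c(5, 30, 60, 90, 115)) b <- swap(b, p)
  seqs <- rbind(
    sharkid:::nuc_seq_row("a1", a1, "Genea", "Genea alpha", 57L),
    sharkid:::nuc_seq_row("a2", a2, "Genea", "Genea alpha", 57L),
    sharkid:::nuc_seq_row("b1", b, "Geneb", "Geneb beta", 57L))
  class(seqs) <- c("nuc_seqs", "data.frame")
  reference_library(seqs, coordinate_offset = 57L)
}

# Shared simulated study panel: 8 CITES species x 10 records from the
# bundled key.
sim_panel_library <- function(seed = 42L, n = 10L, ...) {
  key <- load_table3_key()
  cfg <- sim_config(key, stats::setNames(rep(n, nrow(key$rows)),
                                         rownames(key$rows)),
                    seed = seed, ...)
  list(key = key, cfg = cfg, lib = simulate_library(cfg))
}
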