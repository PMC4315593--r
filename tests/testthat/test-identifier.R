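test_that("identity search scores self-matches and single mismatches", {
  lib <- tiny_library()
  rec <- sharkid:::library_to_seqs(lib)[1, , drop = FALSE]
  hits <- identity_search(rec, lib, min_overlap = 50)
  expect_identical(hits$reference_id[1], "a1")
  expect_identical(hits$identity[1], 100)
  expect_identical(hits$coverage[1], 100)
  expect_true(hits$perfect[1])

  # one incompatible column out of 118 compared -> 99.2
  q <- slice_by_coi_positions(rec, 57, 174)  # 118 columns
  b <- strsplit(q$bases, "")[[1]]
  b[40] <- setdiff(c("A", "C", "G", "T"), b[40])[1]
  q$bases <- paste(b, collapse = "")
  q$id <- "q"
  h <- identity_search(q, lib, min_overlap = 50)
  expect_identical(h$identity[h$reference_id == "a1"], 99.2)
  expect_identical(h$coverage[1], 100)

  expect_error(identity_search(rec, lib, min_overlap = 500),
               class = "sharkid_input_error")
})

test_that("identity search matches the brute-force oracle exactly", {
  panel <- sim_panel_library(seed = 77, n = 6, seq_length = 200L,
                             truncation_model = c(60L, 120L),
                             ambiguity_injection_rate = 0.05)
  lib <- panel$lib
  expect_lte(length(lib$ids), 50)
  expect_lte(lib$width, 200)
  dq <- simulate_degraded_queries(lib, panel$cfg)
  refs <- sharkid:::library_to_seqs(lib)
  for (i in seq(1, nrow(dq$queries), by = 7)) {
    q <- dq$queries[i, , drop = FALSE]
    hits <- identity_search(q, lib, min_overlap = 40)
    for (j in seq(1, nrow(hits), by = 11)) {
      ref <- refs[refs$id == hits$reference_id[j], ]
      want <- oracle_identity(q$bases, q$coi_offset, ref$bases,
                              lib$coordinate_offset)
      expect_identical(hits$identity[j], want$identity)
      expect_identical(hits$coverage[j], want$coverage)
      expect_identical(hits$compared[j], want$compared)
    }
  }
})

test_that("unplaced queries register to the correct COI offset", {
  panel <- sim_panel_library(seed = 5, n = 4)
  lib <- panel$lib
  rec <- sharkid:::library_to_seqs(lib)[1, , drop = FALSE]
  q <- slice_by_coi_positions(rec, 80, 200)
  q$coi_offset <- NA_integer_
  expect_identical(register_query_offset(q, lib), 80L)
})

test_that("cCA matching counts incompatibilities per species row", {
  key <- load_table3_key()
  mkq <- function(states, offset = 57L) {
    bases <- rep("N", 174 - 57 + 1)
    bases[key$positions - 57 + 1] <- states
    sharkid:::nuc_seq_row("q", paste(bases, collapse = ""),
                          coi_offset = offset)
  }
  # query equal to the white shark row -> that species alone
  m <- cca_match(mkq(unname(key$rows["Carcharodon carcharias", ])), key)
  expect_identical(m$candidates, "Carcharodon carcharias")
  expect_identical(unname(m$incompatibilities["Carcharodon carcharias"]), 0L)

  # T at position 57 conflicts with the scalloped hammerhead's C there
  q2 <- mkq(unname(key$rows["Lamna nasus", ]))
  m2 <- cca_match(q2, key)
  expect_gte(unname(m2$incompatibilities["Sphyrna lewini"]), 1L)

  # all-N query is compatible with every row
  qn <- sharkid:::nuc_seq_row("qn", paste(rep("N", 118), collapse = ""),
                              coi_offset = 57L)
  expect_setequal(cca_match(qn, key)$candidates, rownames(key$rows))

  # no covered key position -> no information
  qfar <- sharkid:::nuc_seq_row("qf", "ACGTACGT", coi_offset = 300L)
  expect_error(cca_match(qfar, key), class = "sharkid_no_information_error")
})

test_that("masking low-confidence positions shields candidates from noise", {
  key <- load_table3_key()
  panel <- sim_panel_library(seed = 13, n = 4)
  rec <- sharkid:::library_to_seqs(panel$lib)[1, , drop = FALSE]
  q <- slice_by_coi_positions(rec, 57, 174)
  before <- cca_match(q, key, use_low_confidence = FALSE)
  # perturb position 60 to every other base: candidates must not move
  for (b in c("A", "C", "G", "T")) {
    qq <- q
    substr(qq$bases, 60 - 57 + 1, 60 - 57 + 1) <- b
    after <- cca_match(qq, key, use_low_confidence = FALSE)
    expect_identical(after$candidates, before$candidates)
  }
  # with the flag enabled a non-A base at 60 breaks every row (all are A)
  qq <- q
  substr(qq$bases, 4, 4) <- "G"
  expect_length(cca_match(qq, key, use_low_confidence = TRUE)$candidates, 0)
})

test_that("the identification cascade issues species, genus and set calls", {
  panel <- sim_panel_library(seed = 42, n = 10)
  lib <- panel$lib; key <- panel$key
  seqs <- sharkid:::library_to_seqs(lib)

  # full-length library record -> unambiguous species call, cCA concordant
  r <- identify(seqs[1, , drop = FALSE], lib, key)
  expect_identical(r$final_level, "species")
  expect_identical(r$final_taxa, seqs$species[1])
  expect_false(r$discordance_flag)
})

test_that("species call requires uniqueness; shared genus falls back to genus", {
  # two species sharing a genus with an identical sequence over the library
  base <- paste(rep(c("ACGT"), 30), collapse = "")
  seqs <- rbind(
    sharkid:::nuc_seq_row("x1", base, "Carcharhinus",
                          "Carcharhinus falciformis", 57L),
    sharkid:::nuc_seq_row("x2", base, "Carcharhinus",
                          "Carcharhinus obscurus", 57L))
  class(seqs) <- c("nuc_seqs", "data.frame")
  lib <- reference_library(seqs, coordinate_offset = 57L)
  key <- load_table3_key()
  q <- sharkid:::nuc_seq_row("q", base, coi_offset = 57L)
  r <- identify(q, lib, key, min_overlap = 50)
  expect_false(r$unique_top)
  expect_identical(r$final_level, "genus")
  expect_identical(r$final_taxa, "Carcharhinus")
})

test_that("mutually close cCA candidates yield a candidate-set call", {
  # a whitetip-like key: four congeners separated only at the unreliable
  # position 60, so pairwise key distance is 1 everywhere
  pos <- c(60L, 100L, 110L, 120L)
  rows <- rbind(
    `Carcharhinus longimanus` = c("A", "A", "A", "A"),
    `Carcharhinus obscurus` = c("G", "A", "A", "A"),
    `Carcharhinus galapagensis` = c("C", "A", "A", "A"),
    `Carcharhinus perezi` = c("T", "A", "A", "A"))
  key <- cca_key(pos, rows, low_confidence_positions = 60L)
  set.seed(55)
  base <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  for (p in c(100, 110, 120)) substr(base, p - 57 + 1, p - 57 + 1) <- "A"
  mk <- function(id, sp, b) {
    x <- base
    substr(x, 60 - 57 + 1, 60 - 57 + 1) <- b
    sharkid:::nuc_seq_row(id, x, "Carcharhinus", sp, 57L)
  }
  seqs <- rbind(mk("lon", "Carcharhinus longimanus", "A"),
                mk("obs", "Carcharhinus obscurus", "G"))
  class(seqs) <- c("nuc_seqs", "data.frame")
  lib <- reference_library(seqs, coordinate_offset = 57L)
  # whitetip-like query: unique perfect search hit, but with position 60
  # masked the cCA cannot exclude the three relatives
  q <- mk("q", NA, "A")
  r <- identify(q, lib, key, min_overlap = 50, min_separation = 2L)
  expect_true(r$unique_top)
  expect_identical(r$final_level, "candidate_set")
  expect_setequal(r$final_taxa, rownames(rows))
  expect_false(r$discordance_flag)
})

test_that("leave-one-in: every reference receives a call containing its species", {
  panel <- sim_panel_library(seed = 99, n = 5)
  lib <- panel$lib; key <- panel$key
  seqs <- sharkid:::library_to_seqs(lib)
  for (i in seq_len(nrow(seqs))) {
    r <- identify(seqs[i, , drop = FALSE], lib, key)
    truth <- seqs$species[i]
    ok <- switch(r$final_level,
                 species = identical(r$final_taxa, truth),
                 candidate_set = truth %in% r$final_taxa,
                 genus = identical(r$final_taxa, strsplit(truth, " ")[[1]][1]),
                 FALSE)
    expect_true(ok, info = paste(seqs$id[i], r$final_level))
  }
})

test_that("identification reports are deterministic across runs", {
  panel <- sim_panel_library(seed = 7, n = 3)
  dq <- simulate_degraded_queries(panel$lib, panel$cfg)
  r1 <- as.data.frame(identify_all(dq$queries, panel$lib, panel$key))
  r2 <- as.data.frame(identify_all(dq$queries, panel$lib, panel$key))
  expect_identical(r1, r2)
})

test_that("tabulation reproduces the published per-type counts", {
  tab <- load_table2_fixture()
  counts <- tabulate_identifications(tab)
  get <- function(taxon, type) {
    r <- counts[counts$taxon == taxon & counts$sample_type == type, ]
    if (nrow(r)) r$count else 0L
  }
  expect_identical(get("School", "P"), 5L)
  expect_identical(get("Blue", "P"), 2L)
  expect_identical(get("Scalloped hammerhead", "S"), 1L)
  expect_identical(get("Smooth hammerhead", "S"), 2L)
  expect_identical(sum(counts$count[counts$sample_type == "S"]), 31L)
  expect_identical(sum(counts$count[counts$sample_type == "P"]), 41L)
  # empty input -> empty table
  empty <- tabulate_identifications(tab[0, ])
  expect_identical(nrow(empty), 0L)
})
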