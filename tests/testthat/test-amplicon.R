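REV <- "AAGATTACAAAAGCGTGGGC"

test_that("annealing-site detection honours orientation, clamp and degeneracy", {
  set.seed(3)
  pad <- function(n) paste(sample(c("A", "C", "G"), n, replace = TRUE),
                           collapse = "")
  # exact reverse-complement site
  tpl <- paste0(pad(40), reverse_complement(REV), pad(40))
  sites <- find_annealing_sites(tpl, REV, "reverse")
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 41L)
  expect_identical(sites$end, 60L)
  expect_identical(sites$mismatches, 0L)

  # substitution at the primer's 3'-terminal base kills the site (clamp)
  primer <- "ACGTACGTACGTACGTACGT"
  site <- primer
  substr(site, 20, 20) <- "C"  # 3' base A->C on the template copy
  tpl2 <- paste0(pad(30), site, pad(30))
  expect_identical(nrow(find_annealing_sites(tpl2, primer, "forward",
                                             max_mismatches = 2,
                                             three_prime_clamp = 3)), 0L)
  # same mismatch outside the clamp is tolerated
  site2 <- primer
  substr(site2, 5, 5) <- "C"
  tpl3 <- paste0(pad(30), site2, pad(30))
  expect_identical(
    find_annealing_sites(tpl3, primer, "forward")$mismatches, 1L)

  # degenerate template base R opposite primer A counts as a match
  site3 <- primer
  substr(site3, 1, 1) <- "R"
  tpl4 <- paste0(pad(30), site3, pad(30))
  expect_identical(
    find_annealing_sites(tpl4, primer, "forward")$mismatches, 0L)

  expect_error(find_annealing_sites("ACG", primer, "forward"),
               class = "sharkid_input_error")
})

test_that("site scan matches a brute-force oracle on random templates", {
  set.seed(17)
  for (i in 1:8) {
    tpl <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N"), 300,
                        replace = TRUE, prob = c(rep(0.23, 4), .04, .04, .02)),
                 collapse = "")
    primer <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE),
                    collapse = "")
    for (orient in c("forward", "reverse")) {
      got <- find_annealing_sites(tpl, primer, orient,
                                  max_mismatches = 6, three_prime_clamp = 2)
      want <- oracle_scan(tpl, primer, orient, 6, 2)
      expect_equal(got$start, want$start, ignore_attr = TRUE)
      expect_equal(got$end, want$end, ignore_attr = TRUE)
      expect_equal(got$mismatches, want$mismatches, ignore_attr = TRUE)
    }
  }
})

test_that("strand symmetry and mismatch monotonicity hold", {
  set.seed(23)
  tpl <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
               collapse = "")
  primer <- substr(tpl, 100, 119)
  n <- nchar(tpl)
  fwd <- find_annealing_sites(tpl, primer, "forward", 3, 0)
  mirrored <- find_annealing_sites(reverse_complement(tpl), primer,
                                   "reverse", 3, 0)
  expect_identical(sort(n - fwd$end + 1L), sort(mirrored$start))
  expect_identical(sort(n - fwd$start + 1L), sort(mirrored$end))

  loose <- find_annealing_sites(tpl, primer, "forward", 5, 0)
  strict <- find_annealing_sites(tpl, primer, "forward", 2, 0)
  expect_true(all(strict$start %in% loose$start))
})

test_that("in-silico PCR recovers a nominal 150 bp amplicon and trims it", {
  ps <- primer_set()
  fwd_anneal <- substr(ps$forward_primers$bases[1], 19, 43)  # 25 nt
  set.seed(5)
  insert <- paste(sample(c("A", "C", "G", "T"), 150 - 25 - 20,
                         replace = TRUE), collapse = "")
  tpl <- paste0("GGGGGGGGGG", fwd_anneal, insert,
                reverse_complement(REV), "GGGGGGGGGG")
  hits <- insilico_pcr(sharkid:::nuc_seq_row("t", tpl, coi_offset = 21L))
  expect_gte(nrow(hits), 1L)
  expect_identical(hits$amplicon_length[1], 150L)
  expect_identical(hits$insert_length[1],
                   hits$rev_start[1] - hits$fwd_end[1] - 1L)

  # insert here spans COI 56..160: trimming to [57,174] clips only the left
  tr <- trim_to_readable(hits[1, , drop = FALSE], c(57L, 174L))
  expect_identical(tr$coi_offset, 57L)
  expect_identical(nchar(tr$bases), hits$insert_coi_end[1] - 57L + 1L)
  # idempotence on an insert already inside the readable window
  tr2 <- trim_to_readable(hits[1, , drop = FALSE],
                          c(hits$insert_coi_start[1], hits$insert_coi_end[1]))
  expect_identical(tr2$bases, hits$insert[1])
  expect_error(trim_to_readable(hits[1, , drop = FALSE], c(500L, 600L)),
               class = "sharkid_trim_error")

  # no reverse site -> no product
  tpl2 <- paste0("GGGGGGGGGG", fwd_anneal, insert, "GGGGGGGGGG")
  expect_identical(nrow(insilico_pcr(sharkid:::nuc_seq_row("t", tpl2))), 0L)
})

test_that("multiplexed forward primers rank by mismatches, ties leftmost", {
  ps <- primer_set()
  f1 <- substr(ps$forward_primers$bases[1], 19, 43)
  f2 <- substr(ps$forward_primers$bases[2], 19, 43)
  set.seed(9)
  mid <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  tpl <- paste0("CCCCC", f1, "CCCCC", f2, mid, reverse_complement(REV),
                "CCCCC")
  hits <- insilico_pcr(sharkid:::nuc_seq_row("t", tpl))
  expect_identical(nrow(hits), 2L)
  expect_true(!is.unsorted(hits$mismatches))
  same <- hits$mismatches[1] == hits$mismatches[2]
  if (same) expect_lt(hits$fwd_start[1], hits$fwd_start[2])
  # brute-force enumeration of all primer-pair products agrees
  f1s <- oracle_scan(tpl, f1, "forward", 2, 3)
  f2s <- oracle_scan(tpl, f2, "forward", 2, 3)
  rs <- oracle_scan(tpl, REV, "reverse", 2, 3)
  n_pairs <- sum(outer(c(f1s$end, f2s$end), rs$start,
                       function(fe, rs_) rs_ - fe - 1 >= 30 &
                         rs_ - fe - 1 <= 1000 & fe < rs_))
  expect_identical(nrow(hits), as.integer(n_pairs))
})
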