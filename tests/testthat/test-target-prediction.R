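# a 21-nt miRNA whose every base can form a G-U wobble where needed
mir <- "TTGGATTGAAGGGAGCTCTAC"

test_that("a perfect duplex has all matches and energy ratio 1", {
  a <- align_duplex(mir, revcomp(mir))
  expect_true(all(a$states == "match"))
  expect_equal(a$total_mismatches, 0L)
  expect_equal(a$five_prime_score, 0)
  expect_equal(a$duplex_energy, a$perfect_energy)
  pc <- passes_criteria(a)
  expect_true(pc$pass)
  expect_length(pc$violated, 0)
})

test_that("duplex states agree with a brute-force pairing table", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(5)
  for (k in 1:20) {
    m <- paste(sample(names(comp), 21, TRUE), collapse = "")
    s <- paste(sample(names(comp), 21, TRUE), collapse = "")
    a <- align_duplex(m, s)
    mv <- strsplit(m, "")[[1]]
    sv <- strsplit(s, "")[[1]]
    for (i in 1:21) {
      b1 <- mv[i]; b2 <- sv[21 - i + 1]   # antiparallel partner
      exp_state <- if (comp[[b1]] == b2) "match"
        else if ((b1 == "G" && b2 == "T") || (b1 == "T" && b2 == "G")) "GU"
        else "mismatch"
      expect_equal(a$states[i], exp_state)
    }
  }
})

test_that("a G-U wobble scores half a mismatch in the 5' region only", {
  st <- rep("match", 21); st[3] <- "GU"
  a <- align_duplex(mir, make_site(mir, st))
  expect_equal(a$gu_positions, 3L)
  expect_equal(a$total_mismatches, 0L)
  expect_equal(a$five_prime_score, 0.5)
  expect_true(passes_criteria(a)$pass)
  # six GU wobbles in 1-12 breach the 2.5 cap (rule 5) without any
  # mismatch counting toward rules 1-4
  st <- rep("match", 21); st[c(1, 2, 3, 4, 6, 7)] <- "GU"
  a <- align_duplex(mir, make_site(mir, st))
  expect_equal(a$five_prime_score, 3)
  expect_equal(a$total_mismatches, 0L)
  expect_equal(passes_criteria(a)$violated, 5L)
})

test_that("stand-in energies sum per pair and scale the MFE ratio", {
  gc <- strrep("G", 21)
  a <- align_duplex(gc, revcomp(gc))
  expect_equal(a$duplex_energy, -63)
  expect_equal(a$perfect_energy, -63)
  # hand-computed: 4 mismatches at 13,15,17,19 on an all-GC miRNA
  st <- rep("match", 21); st[c(13, 15, 17, 19)] <- "mismatch"
  a <- align_duplex(gc, make_site(gc, st))
  expect_equal(a$duplex_energy, -51)         # 17 x -3
  expect_equal(a$duplex_energy / a$perfect_energy, 51 / 63)
})

test_that("each of the six rules is detected on targeted fixtures", {
  mk <- function(st) align_duplex(mir, make_site(mir, st))
  base <- rep("match", 21)
  # rule 4: single mismatch at position 10
  st <- base; st[10] <- "mismatch"
  expect_equal(passes_criteria(mk(st))$violated, 4L)
  # rule 1: five scattered mismatches outside the 2-12 adjacency zone
  st <- base; st[c(13, 15, 17, 19, 21)] <- "mismatch"
  pc <- passes_criteria(mk(st))
  expect_false(pc$pass)
  expect_true(1L %in% pc$violated)
  expect_false(4L %in% pc$violated)
  # rule 2: adjacent mismatches inside positions 2-12
  st <- base; st[c(5, 6)] <- "mismatch"
  expect_true(2L %in% passes_criteria(mk(st))$violated)
  # adjacent pair outside 2-12 does not trip rule 2
  st <- base; st[c(13, 14)] <- "mismatch"
  expect_false(2L %in% passes_criteria(mk(st))$violated)
  # rule 3: run of three consecutive mismatches
  st <- base; st[13:15] <- "mismatch"
  expect_true(3L %in% passes_criteria(mk(st))$violated)
  # two consecutive mismatches alone do not trip rule 3
  st <- base; st[13:14] <- "mismatch"
  expect_false(3L %in% passes_criteria(mk(st))$violated)
  # rule 6: enough GC-pair mismatches to push the ratio below 75%
  atmir <- paste0(strrep("A", 13), strrep("G", 8))  # perfect energy -50
  st <- base; st[c(14, 15, 17, 19, 21)] <- "mismatch"
  a <- align_duplex(atmir, make_site(atmir, st))
  expect_lt(a$duplex_energy / a$perfect_energy, 0.75)
  expect_true(6L %in% passes_criteria(a)$violated)
})

test_that("rule evaluation is order-independent and side-effect free", {
  st <- rep("match", 21); st[c(10, 5, 6)] <- "mismatch"
  a <- align_duplex(mir, make_site(mir, st))
  v1 <- passes_criteria(a)$violated
  v2 <- passes_criteria(a)$violated
  expect_identical(v1, v2)
  expect_identical(sort(v1), v1)
})

test_that("target scanning recovers planted sites and matches enumeration", {
  set.seed(9)
  bg <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  tx <- paste0(substr(bg, 1, 200), revcomp(mir), substr(bg, 201, 600))
  hits <- scan_targets(mir, data.frame(transcript_id = "t1", sequence = tx),
                       mirna_id = "mir")
  expect_true(any(hits$start == 201 & hits$mismatches == 0))
  # exhaustive window oracle on a random transcriptome
  rnd <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  got <- scan_targets(mir, data.frame(transcript_id = "r", sequence = rnd))
  brute <- integer(0)
  for (s in 1:(3000 - 20)) {
    if (passes_criteria(align_duplex(mir, substr(rnd, s, s + 20)))$pass)
      brute <- c(brute, s)
  }
  expect_equal(got$start, brute)
})

test_that("planted tasiRNA sites in PPR/TPR transcripts are recovered", {
  phased <- function(tid, k) {
    row <- sp_ref$tas_loci[sp_ref$tas_loci$locus_id == tid, ]
    s <- row$cleavage_pos + 21L * k
    substr(row$cdna, s, s + 20L)
  }
  planted <- list(PPR1 = phased("TAS1A", 1L), PPR2 = phased("TAS1A", 2L),
                  PPR3 = phased("TAS2", 1L), TPR1 = phased("TAS1B", 1L),
                  TPR2 = phased("TAS1C", 2L))
  for (tx in names(planted)) {
    hits <- scan_targets(planted[[tx]], sp_ref$transcripts,
                         mirna_id = "tasi")
    expect_true(tx %in% hits$transcript_id)
    expect_true(any(hits$transcript_id == tx & hits$mismatches == 0))
  }
})
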