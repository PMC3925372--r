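# Stand-in base-pair energies for duplex scoring. A full
# nearest-neighbour thermodynamic model is deliberately not used: the
# energy criterion is a ratio against the perfect duplex of the same
# miRNA, which is far less sensitive to the absolute energy scale. The
# function is pluggable via the `pair_energy` argument of align_duplex().
.PAIR_ENERGY <- c(match_GC = -3, match_AU = -2, GU = -1, mismatch = 0)

.pair_state <- function(b1, b2) {
  # b1: miRNA base, b2: target base (both DNA alphabet)
  wc <- unname(.COMP[b1]) == b2
  gu <- (b1 == "G" & b2 == "T") | (b1 == "T" & b2 == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}

.pair_energies <- function(b1, state) {
  e <- numeric(length(state))
  gc <- state == "match" & b1 %in% c("G", "C")
  au <- state == "match" & b1 %in% c("A", "T")
  e[gc] <- .PAIR_ENERGY[["match_GC"]]
  e[au] <- .PAIR_ENERGY[["match_AU"]]
  e[state == "GU"] <- .PAIR_ENERGY[["GU"]]
  e
}

#' Align a miRNA against a candidate target site as an ungapped duplex
#'
#' Both sequences are given 5'->3'; the duplex is antiparallel, so
#' position `i` of the miRNA (counted from its 5' end) pairs with
#' position `L - i + 1` of the site. Each position is classified as
#' Watson-Crick `match`, `GU` wobble, or `mismatch`. Positions are
#' numbered 1..L from the miRNA 5' end, the convention of plant
#' target-prediction rules.
#'
#' @param mirna miRNA sequence, 5'->3' (U or T accepted).
#' @param site target site sequence, 5'->3', same length as the miRNA.
#' @param pair_energy named numeric vector of stand-in pair energies
#'   (`match_GC`, `match_AU`, `GU`, `mismatch`).
#' @return an object of class `duplex_alignment`: a list with `mirna`,
#'   `site`, `states` (character vector over positions 1..L),
#'   `total_mismatches` (GU not counted), `gu_positions`,
#'   `five_prime_score` (positions 1-12; mismatch = 1, GU = 0.5),
#'   `duplex_energy`, and `perfect_energy` (the same miRNA against its
#'   exact complement).
#' @export
align_duplex <- function(mirna, site, pair_energy = .PAIR_ENERGY) {
  mirna <- .as_dna(mirna); site <- .as_dna(site)
  L <- nchar(mirna)
  if (nchar(site) != L) .stopf("site length must equal miRNA length")
  m <- .chars(mirna)
  s <- rev(.chars(site))           # antiparallel register
  states <- .pair_state(m, s)
  five <- seq_len(min(12L, L))
  e <- .pair_energies(m, states)
  pe <- ifelse(m %in% c("G", "C"), pair_energy[["match_GC"]],
               pair_energy[["match_AU"]])
  structure(list(
    mirna = mirna, site = site, states = states,
    total_mismatches = sum(states == "mismatch"),
    gu_positions = which(states == "GU"),
    five_prime_score = sum(states[five] == "mismatch") +
      0.5 * sum(states[five] == "GU"),
    duplex_energy = sum(e),
    perfect_energy = sum(pe)
  ), class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("miRNA 5'-", x$mirna, "-3'\n", sep = "")
  sym <- c(match = "|", GU = "o", mismatch = " ")
  cat("         ", paste(sym[x$states], collapse = ""), "\n", sep = "")
  cat("site  3'-", paste(rev(.chars(x$site)), collapse = ""), "-5'\n",
      sep = "")
  cat(sprintf("mismatches=%d GU=%d 5'score=%.1f energy=%g/%g\n",
              x$total_mismatches, length(x$gu_positions),
              x$five_prime_score, x$duplex_energy, x$perfect_energy))
  invisible(x)
}

#' Evaluate the six target-prediction rules on a duplex
#'
#' The rules, positions counted from the miRNA 5' end:
#' 1. no more than four mismatches (GU wobbles not counted);
#' 2. no adjacent mismatches within positions 2-12;
#' 3. no run of three or more consecutive mismatches anywhere;
#' 4. no mismatch at positions 10 or 11;
#' 5. mismatch score over positions 1-12 at most 2.5, a GU wobble
#'    counting 0.5;
#' 6. duplex energy at least 75% of the perfect-duplex energy of the
#'    same miRNA (ratio of stand-in energies, both negative).
#'
#' @param alignment a `duplex_alignment` from [align_duplex()].
#' @param mfe_ratio_min minimum energy ratio, default 0.75.
#' @return list with `pass` (logical) and `violated` (integer ids of
#'   failed rules, empty when passing).
#' @export
passes_criteria <- function(alignment, mfe_ratio_min = 0.75) {
  st <- alignment$states
  L <- length(st)
  mm <- st == "mismatch"
  violated <- integer(0)
  if (alignment$total_mismatches > 4) violated <- c(violated, 1L)
  # adjacent mismatch pair fully within positions 2-12
  upper <- min(11L, L - 1L)
  if (upper >= 2L) {
    i <- 2:upper
    if (any(mm[i] & mm[i + 1L])) violated <- c(violated, 2L)
  }
  runs <- rle(mm)
  if (any(runs$values & runs$lengths >= 3L)) violated <- c(violated, 3L)
  if (any(mm[intersect(c(10L, 11L), seq_len(L))])) violated <- c(violated, 4L)
  if (alignment$five_prime_score > 2.5) violated <- c(violated, 5L)
  ratio <- alignment$duplex_energy / alignment$perfect_energy
  if (ratio < mfe_ratio_min) violated <- c(violated, 6L)
  list(pass = length(violated) == 0L, violated = violated)
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window of miRNA length on every transcript (sense strand of
#' the mRNA) is aligned as an ungapped duplex and evaluated against the
#' six rules; passing sites are reported.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcripts data.frame with `transcript_id` and `sequence`
#'   columns (optionally `family`), or a named character vector.
#' @param mirna_id identifier recorded in the output.
#' @return data.frame of passing sites: `mirna_id, transcript_id, start,
#'   end` (1-based inclusive on the transcript), `mismatches, gu,
#'   five_prime_score, energy_ratio`.
#' @export
scan_targets <- function(mirna, transcripts, mirna_id = "mirna") {
  if (!is.data.frame(transcripts)) {
    transcripts <- data.frame(transcript_id = names(transcripts),
                              sequence = unname(transcripts),
                              stringsAsFactors = FALSE)
  }
  mirna <- .as_dna(mirna)
  L <- nchar(mirna)
  res <- list()
  for (t in seq_len(nrow(transcripts))) {
    seqc <- .as_dna(transcripts$sequence[t])
    n <- nchar(seqc)
    if (n < L) next
    for (s in seq_len(n - L + 1L)) {
      aln <- align_duplex(mirna, substr(seqc, s, s + L - 1L))
      # cheap pre-filter: rule 1 bound before full rule evaluation
      if (aln$total_mismatches > 4) next
      pc <- passes_criteria(aln)
      if (!pc$pass) next
      res[[length(res) + 1L]] <- data.frame(
        mirna_id = mirna_id,
        transcript_id = transcripts$transcript_id[t],
        start = s, end = s + L - 1L,
        mismatches = aln$total_mismatches,
        gu = length(aln$gu_positions),
        five_prime_score = aln$five_prime_score,
        energy_ratio = aln$duplex_energy / aln$perfect_energy,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), gu = integer(0),
                      five_prime_score = numeric(0), energy_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
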