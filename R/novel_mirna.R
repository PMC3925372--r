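#' Extract the genomic flank around a mapped tag
#'
#' Returns a window (default 250 nt) centred on the tag, on the strand
#' of the hit (reverse-complemented for minus-strand hits), truncated at
#' contig ends.
#'
#' @param genome genome sequence (character or [Biostrings::DNAString]).
#' @param start,end 1-based inclusive genomic coordinates of the hit.
#' @param strand `"+"` or `"-"`.
#' @param window total window width, default 250.
#' @return list with `seq` (the window on the hit strand),
#'   `mature_offset` (1-based position of the tag within the window),
#'   and the genomic `win_start`, `win_end`.
#' @export
extract_flank <- function(genome, start, end, strand = "+", window = 250L) {
  genome <- .as_dna(as.character(genome))
  n <- nchar(genome)
  if (start < 1 || end > n || start > end) .stopf("hit lies off the contig")
  tag_len <- end - start + 1L
  pad <- (window - tag_len) %/% 2L
  ws <- max(1L, start - pad)
  we <- min(n, ws + window - 1L)
  ws <- max(1L, min(ws, we - window + 1L))   # re-anchor if right-truncated
  seqc <- substr(genome, ws, we)
  off <- start - ws + 1L
  if (strand == "-") {
    seqc <- revcomp(seqc)
    off <- (nchar(seqc) - (end - ws + 1L)) + 1L
  }
  list(seq = seqc, mature_offset = off, win_start = ws, win_end = we)
}

# Destabilization charged per unpaired stem position when scoring a
# fold; keeps random low-density pairing from outscoring a true stem.
.HAIRPIN_MM_PENALTY <- 2

# Score one candidate fold: a loop [s, s+l-1] with arms extending
# outward, pairing window[s-1-k] with window[s+l+k], ungapped. The stem
# is truncated at the extension prefix with the lowest penalized score
# (pair energies plus a per-mismatch penalty), so arms stop where
# pairing stops paying. Returns NULL when no stabilizing stem forms.
.fold_candidate <- function(ch, s, l) {
  n <- length(ch)
  m <- min(s - 1L, n - (s + l) + 1L)
  if (m < 1L) return(NULL)
  i <- (s - 1L):(s - m)            # 5' arm, outward
  j <- (s + l):(s + l + m - 1L)    # 3' arm, outward
  st <- .pair_state(ch[i], ch[j])
  e <- .pair_energies(ch[i], st)
  score <- cumsum(e + .HAIRPIN_MM_PENALTY * (st == "mismatch"))
  cut <- which.min(score)
  if (score[cut] >= 0) return(NULL)
  i <- i[seq_len(cut)]; j <- j[seq_len(cut)]; st <- st[seq_len(cut)]
  list(
    i = i, j = j, states = st,
    n_paired = sum(st != "mismatch"),
    energy = sum(.pair_energies(ch[i], st)),
    score = score[cut],
    loop_start = s, loop_len = l
  )
}

#' Screen a genomic window for a miRNA-like hairpin fold
#'
#' A simplified, fully deterministic stand-in for a thermodynamic
#' folder: all candidate folds (loop start x loop length over a small
#' grid) are scored by ungapped antiparallel arm pairing with the
#' stand-in pair energies plus a per-mismatch destabilization penalty,
#' and the fold with the lowest penalized score (ties: more paired
#' positions) is evaluated. The candidate is accepted when the
#' mature tag lies wholly on one arm, at least `min_mature_paired` of
#' its positions are paired (GU allowed), the loop is at least
#' `min_loop` nt, and the fold energy is at most `max_energy`.
#'
#' @param window window sequence on the candidate strand.
#' @param mature_offset 1-based start of the mature tag in the window.
#' @param mature_len length of the mature tag.
#' @param min_mature_paired minimum paired positions within the mature
#'   (default 17, of a 21-nt mature).
#' @param min_loop minimum loop length, default 15.
#' @param max_energy acceptance threshold on the fold energy (stand-in
#'   scale), default -25.
#' @param loop_grid loop lengths tried, default `seq(15, 33, by = 3)`.
#' @return a `hairpin_candidate` list: `status` (`accepted` or
#'   `rejected`), `reason` (for rejections), `arm` (`5p`/`3p`), `star`
#'   sequence, `n_paired`, `mature_paired`, `energy`, `loop_start`,
#'   `loop_len`, and the pairing index vectors `i`, `j`.
#' @export
hairpin_screen <- function(window, mature_offset, mature_len,
                           min_mature_paired = 17L, min_loop = 15L,
                           max_energy = -25, loop_grid = seq(15L, 33L, 3L)) {
  window <- .as_dna(window)
  ch <- .chars(window)
  n <- length(ch)
  reject <- function(reason) {
    structure(list(status = "rejected", reason = reason, window = window),
              class = "hairpin_candidate")
  }
  if (mature_offset < 1 || mature_offset + mature_len - 1L > n)
    return(reject("mature outside window"))
  best <- NULL
  for (l in loop_grid[loop_grid >= min_loop]) {
    for (s in 2:(n - l)) {
      f <- .fold_candidate(ch, s, l)
      if (is.null(f)) next
      if (is.null(best) || f$score < best$score ||
          (f$score == best$score && f$n_paired > best$n_paired)) {
        best <- f
      }
    }
  }
  if (is.null(best)) return(reject("no fold"))
  mat <- mature_offset:(mature_offset + mature_len - 1L)
  arm5 <- rev(best$i)  # ascending positions on 5' arm
  arm3 <- best$j       # ascending positions on 3' arm
  on5 <- all(mat %in% arm5)
  on3 <- all(mat %in% arm3)
  if (!on5 && !on3) return(reject("mature not on a single arm"))
  # partner positions of the mature via the fold pairing
  pos2idx <- integer(n)
  pos2idx[best$i] <- seq_along(best$i)
  pos2idx[best$j] <- seq_along(best$j)
  idx <- pos2idx[mat]
  paired_states <- best$states[idx]
  mature_paired <- sum(paired_states != "mismatch")
  partner <- if (on5) best$j[idx] else best$i[idx]
  star <- paste(ch[sort(partner)], collapse = "")
  out <- structure(list(
    status = "accepted", reason = NA_character_,
    window = window, arm = if (on5) "5p" else "3p",
    mature = paste(ch[mat], collapse = ""), star = star,
    n_paired = best$n_paired, mature_paired = mature_paired,
    energy = best$energy,
    loop_start = best$loop_start, loop_len = best$loop_len,
    i = best$i, j = best$j
  ), class = "hairpin_candidate")
  if (mature_paired < min_mature_paired) {
    out$status <- "rejected"; out$reason <- "insufficient mature pairing"
  } else if (best$energy > max_energy) {
    out$status <- "rejected"; out$reason <- "stem energy above threshold"
  }
  out
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin candidate:", x$status,
      if (!is.na(x$reason)) paste0("(", x$reason, ")") else "", "\n")
  if (x$status == "accepted") {
    cat(sprintf("  arm %s, %d stem pairs (%d/%d mature), energy %g\n",
                x$arm, x$n_paired, x$mature_paired, nchar(x$mature),
                x$energy))
  }
  invisible(x)
}

#' Screen unannotated tags for novel miRNA candidates
#'
#' For each unannotated tag, every genomic mapping position is flanked
#' and screened for a hairpin; accepted loci that do not overlap an
#' annotated known-miRNA feature become candidates.
#'
#' @param tags data.frame with `sequence` and `count` (unannotated tags).
#' @param genome genome sequence.
#' @param hits data.frame from [map_tags()] restricted to these tags.
#' @param known_mirna_features data.frame of features with class
#'   `miRNA` (`start`, `end`), used to exclude known loci; may be empty.
#' @param ... passed to [hairpin_screen()].
#' @return data.frame of accepted candidates: `sequence, count, strand,
#'   start, end, arm, star, energy, mature_paired`.
#' @export
screen_novel_mirnas <- function(tags, genome, hits,
                                known_mirna_features = NULL, ...) {
  res <- list()
  hits <- hits[hits$sequence %in% tags$sequence, , drop = FALSE]
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    if (!is.null(known_mirna_features) && nrow(known_mirna_features) > 0 &&
        any(h$start <= known_mirna_features$end &
            h$end >= known_mirna_features$start)) next
    fl <- extract_flank(genome, h$start, h$end, h$strand)
    hp <- hairpin_screen(fl$seq, fl$mature_offset, h$end - h$start + 1L, ...)
    if (hp$status != "accepted") next
    res[[length(res) + 1L]] <- data.frame(
      sequence = h$sequence,
      count = tags$count[match(h$sequence, tags$sequence)],
      strand = h$strand, start = h$start, end = h$end,
      arm = hp$arm, star = hp$star, energy = hp$energy,
      mature_paired = hp$mature_paired,
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), arm = character(0),
                      star = character(0), energy = numeric(0),
                      mature_paired = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Name accepted novel-miRNA candidates
#'
#' Candidates are numbered by descending summed count, ties broken by
#' lexicographic sequence, and named `<tissue>_miRNA%04d_<arm>`.
#' Candidates whose summed count does not exceed `min_count` are
#' excluded from the reported set.
#'
#' @param candidates data.frame from [screen_novel_mirnas()]; one row
#'   per locus, possibly several per sequence.
#' @param tissue tissue label used as the name prefix.
#' @param min_count report threshold; a candidate is reported only when
#'   its summed count is strictly greater (default 100).
#' @return data.frame with one row per distinct sequence: `name,
#'   sequence, count, arm, reported`.
#' @export
name_candidates <- function(candidates, tissue, min_count = 100L) {
  if (nrow(candidates) == 0) {
    return(data.frame(name = character(0), sequence = character(0),
                      count = integer(0), arm = character(0),
                      reported = logical(0), stringsAsFactors = FALSE))
  }
  per <- candidates[!duplicated(candidates$sequence), , drop = FALSE]
  per <- per[order(-per$count, per$sequence, method = "radix"), ,
             drop = FALSE]
  data.frame(
    name = sprintf("%s_miRNA%04d_%s", tissue, seq_len(nrow(per)), per$arm),
    sequence = per$sequence, count = per$count, arm = per$arm,
    reported = per$count > min_count,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
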