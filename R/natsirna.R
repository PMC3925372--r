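#' Count tags over a region of a NAT gene pair
#'
#' A tag counts toward a region when one of its genomic matches is
#' fully contained in the region interval. Orientation follows the
#' mapping strand: a read whose sequence matches the plus strand is
#' denoted `+`, a read matching the minus strand `-`. All mapping
#' positions are kept; a palindromic tag matching both strands at the
#' same locus counts once per orientation.
#'
#' @param hits data.frame from [map_tags()] (`sequence, strand, start,
#'   end`).
#' @param tags data.frame with `sequence` and `count` for the library.
#' @param start,end 1-based inclusive interval of the region. For
#'   trans pairs pass each paired segment separately and sum.
#' @return list with `plus` and `minus` read counts.
#' @export
count_region <- function(hits, tags, start, end) {
  if (is.na(start) || is.na(end) || start > end)
    .stopf("malformed region interval")
  inside <- hits$start >= start & hits$end <= end
  counts <- list(plus = 0, minus = 0)
  for (str in c("+", "-")) {
    h <- hits[inside & hits$strand == str, , drop = FALSE]
    # each tag counts once per orientation within the region
    seqs <- unique(h$sequence)
    n <- sum(tags$count[match(seqs, tags$sequence)], na.rm = TRUE)
    counts[[if (str == "+") "plus" else "minus"]] <- n
  }
  counts
}

#' Region counts for every NAT pair in a library
#'
#' Counts reads in the overlap region (OL) and both whole-gene regions
#' (WL) of each pair, split by mapping orientation. For cis pairs the
#' OL is a single genomic interval contained in both genes; for trans
#' pairs the two paired segments (one per gene) are counted and summed.
#'
#' @param hits data.frame from [map_tags()].
#' @param tags data.frame with `sequence` and `count`.
#' @param nat_pairs data.frame with columns `pair_id, type` (cis/trans),
#'   `gene_a, a_start, a_end, a_strand, gene_b, b_start, b_end,
#'   b_strand, ol_start, ol_end` and, for trans pairs, `ol_b_start,
#'   ol_b_end` (the second paired segment).
#' @param library_id label recorded in the output.
#' @return data.frame with one row per pair x region (`OL`, `WL_a`,
#'   `WL_b`): `pair_id, region, plus, minus, library_id`.
#' @export
nat_region_counts <- function(hits, tags, nat_pairs, library_id = NA) {
  rows <- list()
  for (k in seq_len(nrow(nat_pairs))) {
    p <- nat_pairs[k, ]
    ol <- count_region(hits, tags, p$ol_start, p$ol_end)
    if (identical(p$type, "trans") &&
        !is.null(p$ol_b_start) && !is.na(p$ol_b_start)) {
      ol2 <- count_region(hits, tags, p$ol_b_start, p$ol_b_end)
      ol$plus <- ol$plus + ol2$plus
      ol$minus <- ol$minus + ol2$minus
    }
    wa <- count_region(hits, tags, p$a_start, p$a_end)
    wb <- count_region(hits, tags, p$b_start, p$b_end)
    rows[[k]] <- data.frame(
      pair_id = p$pair_id,
      region = c("OL", "WL_a", "WL_b"),
      plus = c(ol$plus, wa$plus, wb$plus),
      minus = c(ol$minus, wa$minus, wb$minus),
      library_id = library_id,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential abundance of NAT-pair siRNAs between two libraries
#'
#' Per-pair OL totals (both orientations pooled) are tested with the
#' tag-count statistic and classified; per-orientation columns are
#' retained for inspection.
#'
#' @param counts_control,counts_treatment data.frames from
#'   [nat_region_counts()] for the two libraries.
#' @param N1,N2 clean-read totals.
#' @return [classify_de()] data.frame over pairs (OL region), with
#'   orientation columns `x_plus, x_minus, y_plus, y_minus` appended.
#' @export
natsirna_de <- function(counts_control, counts_treatment, N1, N2) {
  olc <- counts_control[counts_control$region == "OL", , drop = FALSE]
  olt <- counts_treatment[counts_treatment$region == "OL", , drop = FALSE]
  ids <- union(olc$pair_id, olt$pair_id)
  gx <- function(df, col) {
    v <- df[[col]][match(ids, df$pair_id)]
    ifelse(is.na(v), 0, v)
  }
  xp <- gx(olc, "plus"); xm <- gx(olc, "minus")
  yp <- gx(olt, "plus"); ym <- gx(olt, "minus")
  de <- classify_de(ids, as.integer(xp + xm), as.integer(yp + ym), N1, N2)
  de$x_plus <- xp; de$x_minus <- xm; de$y_plus <- yp; de$y_minus <- ym
  de
}

#' Pairs significantly altered in both treatment lines
#'
#' Combines two per-pair DE tables (one per treatment line vs the same
#' control) and reports pairs called non-equal in the same direction in
#' both.
#'
#' @param de1,de2 data.frames from [natsirna_de()] (or any
#'   [classify_de()] output) for the two treatment comparisons.
#' @return data.frame with `id`, `call` (shared direction), and the two
#'   log2 fold changes.
#' @export
altered_in_both <- function(de1, de2) {
  m <- merge(de1[, c("id", "call", "log2fc")],
             de2[, c("id", "call", "log2fc")],
             by = "id", suffixes = c("_1", "_2"))
  keep <- m$call_1 != "equal" & m$call_1 == m$call_2
  data.frame(id = m$id[keep], call = m$call_1[keep],
             log2fc_1 = m$log2fc_1[keep], log2fc_2 = m$log2fc_2[keep],
             stringsAsFactors = FALSE)
}
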