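#' @importFrom GenomicRanges GRanges findOverlaps strand start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols "mcols<-"
NULL

# Category priority, highest first. GenBank structural RNA classes share
# the top level; Rfam ncRNA next; then known miRNA, repeat, exon,
# intron, siRNA. Tags with no hit are unannotated.
.GENBANK_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")
.CATEGORY_LEVELS <- c("GenBank", "Rfam", "known_miRNA", "repeat",
                      "exon_sense", "exon_antisense",
                      "intron_sense", "intron_antisense",
                      "siRNA", "unannotated")

# class label of a feature -> priority tier (1 = highest)
.class_priority <- function(class_label) {
  ifelse(class_label %in% .GENBANK_CLASSES, 1L,
  ifelse(class_label == "rfam_ncRNA", 2L,
  ifelse(class_label == "miRNA", 3L,
  ifelse(class_label == "repeat", 4L,
  ifelse(class_label == "exon", 5L,
  ifelse(class_label == "intron", 6L,
  ifelse(class_label == "siRNA", 7L, 8L)))))))
}

#' Map tags to a genome by exact matching on both strands
#'
#' Every exact occurrence of each tag (forward) or of its reverse
#' complement (minus strand) on the genome is reported; no mismatches.
#' All mapping positions are kept.
#'
#' @param tags character vector of tag sequences (or a data.frame with a
#'   `sequence` column).
#' @param genome a single genome sequence (character or
#'   [Biostrings::DNAString]).
#' @return data.frame with columns `sequence`, `strand` (+/-), `start`,
#'   `end` (1-based inclusive genomic coordinates).
#' @export
map_tags <- function(tags, genome) {
  if (is.data.frame(tags)) tags <- tags$sequence
  genome <- Biostrings::DNAString(.as_dna(as.character(genome)))
  if (length(genome) == 0) .stopf("empty reference genome")
  tags <- unique(.as_dna(tags))
  hits <- list()
  if (length(tags) > 0) {
    w <- nchar(tags)
    tb <- min(w)   # trusted-band width: one PDict for all tag lengths
    for (str in c("+", "-")) {
      pat <- if (str == "+") tags else revcomp(tags)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat),
                              tb.start = 1L, tb.end = tb)
      m <- Biostrings::matchPDict(pd, genome)
      n <- S4Vectors::elementNROWS(m)
      if (sum(n) == 0) next
      starts <- BiocGenerics::start(BiocGenerics::unlist(m))
      hits[[length(hits) + 1L]] <- data.frame(
        sequence = rep(tags, n), strand = str,
        start = starts, end = starts + rep(w, n) - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sequence = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$sequence, out$start, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign genomic hits to annotated features
#'
#' A hit supports a feature when its interval is fully contained in the
#' feature interval. Sense/antisense is the agreement between the hit
#' strand and the feature strand.
#'
#' @param hits data.frame from [map_tags()].
#' @param features data.frame with `feature_id`, `class`, `strand`,
#'   `start`, `end` (1-based inclusive).
#' @return `hits` replicated per supporting feature, with `feature_id`,
#'   `class`, and `orientation` (`sense`/`antisense`) columns appended.
#' @export
feature_hits <- function(hits, features) {
  empty <- cbind(hits[0, , drop = FALSE],
                 data.frame(feature_id = character(0), class = character(0),
                            orientation = character(0)))
  if (nrow(hits) == 0 || nrow(features) == 0) return(empty)
  q <- GRanges("chr", IRanges(hits$start, hits$end))
  s <- GRanges("chr", IRanges(features$start, features$end))
  ov <- findOverlaps(q, s, type = "within")
  if (length(ov) == 0) return(empty)
  hi <- queryHits(ov); fi <- subjectHits(ov)
  out <- hits[hi, , drop = FALSE]
  out$feature_id <- features$feature_id[fi]
  out$class <- features$class[fi]
  out$orientation <- ifelse(hits$strand[hi] == features$strand[fi],
                            "sense", "antisense")
  rownames(out) <- NULL
  out
}

#' Classify tags into a single annotation category
#'
#' Applies the category priority GenBank > Rfam > known miRNA > repeat >
#' exon > intron > siRNA to the feature hits of each tag; exon and
#' intron hits are split into sense and antisense relative to the
#' annotated transcript strand. Tags with no feature hits are
#' `unannotated`. Ties within a priority level are broken by the
#' lexicographically smallest feature id, for determinism.
#'
#' @param tags character vector of all tag sequences to classify
#'   (including those with no hits).
#' @param fhits data.frame from [feature_hits()].
#' @return data.frame with `sequence`, `category` (factor over the
#'   category levels), `feature_id` of the chosen supporting feature
#'   (`NA` if unannotated), and `n_hits` (number of feature hits).
#' @export
classify_tags <- function(tags, fhits) {
  tags <- unique(.as_dna(tags))
  cat <- rep("unannotated", length(tags))
  feat <- rep(NA_character_, length(tags))
  nh <- integer(length(tags))
  if (nrow(fhits) > 0) {
    prio <- .class_priority(fhits$class)
    # exon/intron split into sense/antisense categories
    lab <- fhits$class
    ei <- lab %in% c("exon", "intron")
    lab[ei] <- paste0(lab[ei], "_", fhits$orientation[ei])
    lab[fhits$class %in% .GENBANK_CLASSES] <- "GenBank"
    lab[fhits$class == "rfam_ncRNA"] <- "Rfam"
    lab[fhits$class == "miRNA"] <- "known_miRNA"
    # within exon or intron tier, sense outranks antisense for a stable
    # single assignment; encode as fractional sub-priority
    sub <- ifelse(ei & fhits$orientation == "antisense", 0.5, 0)
    key <- prio + sub
    sp <- split(seq_len(nrow(fhits)), fhits$sequence)
    idx <- match(names(sp), tags)
    for (k in seq_along(sp)) {
      rows <- sp[[k]]
      best <- rows[order(key[rows], fhits$feature_id[rows],
                         method = "radix")][1]
      i <- idx[k]
      cat[i] <- lab[best]
      feat[i] <- fhits$feature_id[best]
      nh[i] <- length(rows)
    }
  }
  data.frame(
    sequence = tags,
    category = factor(cat, levels = .CATEGORY_LEVELS),
    feature_id = feat, n_hits = nh,
    stringsAsFactors = FALSE
  )
}

#' Per-category unique-tag and total-read summaries
#'
#' @param assignments data.frame from [classify_tags()].
#' @param tags data.frame with `sequence` and `count` for one library.
#' @return data.frame with `category`, `unique`, `total`; `unique` sums
#'   to the number of tags and `total` to the clean-read count, so the
#'   categories partition the library.
#' @export
summarize_classes <- function(assignments, tags) {
  cat <- assignments$category[match(tags$sequence, assignments$sequence)]
  stopifnot(!anyNA(cat))
  data.frame(
    category = .CATEGORY_LEVELS,
    unique = as.integer(table(cat)[.CATEGORY_LEVELS]),
    total = vapply(.CATEGORY_LEVELS,
                   function(cl) sum(tags$count[cat == cl]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
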