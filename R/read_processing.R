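#' Trim the 3' adapter from raw reads
#'
#' Locates the left-most exact occurrence of the first 8 nt of the 3'
#' adapter in each read and returns the insert upstream of it. Reads
#' with no adapter seed have no defined insert end and are returned as
#' `NA` (discarded downstream).
#'
#' @param reads character vector of raw read sequences.
#' @param adapter3 the 3' adapter sequence; at least 8 nt.
#' @return character vector of inserts, `NA` where no adapter was found.
#'   A zero-length insert (adapter at position 1, an adapter dimer) is
#'   returned as the empty string.
#' @export
trim_adapter <- function(reads, adapter3) {
  if (nchar(adapter3) < 8) .stopf("adapter must be at least 8 nt")
  seed <- substr(.as_dna(adapter3), 1, 8)
  reads <- .as_dna(reads)
  pos <- regexpr(seed, reads, fixed = TRUE)
  ifelse(pos == -1L, NA_character_, substr(reads, 1, pos - 1L))
}

#' Length-filter inserts and collapse identical sequences into tags
#'
#' Discards inserts shorter than 18 nt, longer than 30 nt, or containing
#' non-ACGT characters, then collapses identical sequences, summing
#' their read counts. The clean-read count of the library is the total
#' number of retained reads.
#'
#' @param inserts character vector of trimmed inserts (`NA` = no
#'   adapter, dropped).
#' @param min_len,max_len retained length range, defaults 18 and 30.
#' @return a list with `tags` (data.frame `sequence`, `count`, sorted by
#'   decreasing count then sequence) and `clean_read_count`.
#' @export
clean_and_collapse <- function(inserts, min_len = 18L, max_len = 30L) {
  inserts <- inserts[!is.na(inserts)]
  len <- nchar(inserts)
  keep <- len >= min_len & len <= max_len & !grepl("[^ACGT]", inserts)
  inserts <- inserts[keep]
  if (length(inserts) == 0) {
    return(list(
      tags = data.frame(sequence = character(0), count = integer(0),
                        stringsAsFactors = FALSE),
      clean_read_count = 0L
    ))
  }
  tab <- table(inserts)
  tags <- data.frame(sequence = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence, method = "radix"), ,
               drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags, clean_read_count = length(inserts))
}

#' Read-length histogram of collapsed tags
#'
#' Distribution over the retained length range by unique tags and by
#' total reads; unique bins sum to the number of tags, total bins to the
#' clean-read count.
#'
#' @param tags data.frame with `sequence` and `count` columns.
#' @param range lengths to tabulate, default `18:30`.
#' @return data.frame with columns `length`, `unique`, `total`.
#' @export
length_distribution <- function(tags, range = 18:30) {
  len <- nchar(tags$sequence)
  data.frame(
    length = range,
    unique = vapply(range, function(l) sum(len == l), integer(1)),
    total = vapply(range, function(l) sum(tags$count[len == l]), integer(1))
  )
}

#' Process one raw FASTQ library into collapsed tags
#'
#' Convenience wrapper: read FASTQ, trim the 3' adapter, length-filter
#' and collapse, and assemble the per-library summary used as the
#' normalization denominator downstream.
#'
#' @param fastq path to a FASTQ file.
#' @param adapter3 3' adapter sequence.
#' @param library_id,tissue,genotype library metadata labels.
#' @return a list with `tags`, `library` (a one-row data.frame:
#'   `library_id, tissue, genotype, raw_read_count, clean_read_count`),
#'   and `length_distribution`.
#' @export
process_library <- function(fastq, adapter3, library_id,
                            tissue = NA_character_,
                            genotype = NA_character_) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  inserts <- trim_adapter(reads, adapter3)
  cc <- clean_and_collapse(inserts)
  list(
    tags = cc$tags,
    library = data.frame(
      library_id = library_id, tissue = tissue, genotype = genotype,
      raw_read_count = length(reads),
      clean_read_count = cc$clean_read_count,
      stringsAsFactors = FALSE
    ),
    length_distribution = length_distribution(cc$tags)
  )
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the `tag_<i>_x<count>` convention.
#'
#' @param tags data.frame with `sequence` and `count`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  seqs <- Biostrings::DNAStringSet(tags$sequence)
  names(seqs) <- sprintf("tag_%d_x%d", seq_len(nrow(tags)), tags$count)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
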