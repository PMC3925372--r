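#' Map 21-nt tags to TAS cDNAs with perfect match
#'
#' Only tags of exactly 21 nt are considered; they are matched exactly
#' against the sense strand (5'->3') of each TAS cDNA, and all match
#' positions are kept.
#'
#' @param tags data.frame with `sequence` and `count` for one library.
#' @param tas_loci data.frame with `locus_id`, `cdna`, `cleavage_pos`
#'   (1-based position of the initiator-miRNA-guided cleavage).
#' @return data.frame with `locus_id, sequence, start, count` (start is
#'   1-based on the cDNA).
#' @export
map_21nt <- function(tags, tas_loci) {
  tags <- tags[nchar(tags$sequence) == 21L, , drop = FALSE]
  out <- list()
  if (nrow(tags) > 0) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$sequence))
    for (k in seq_len(nrow(tas_loci))) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(tas_loci$cdna[k]))
      n <- S4Vectors::elementNROWS(m)
      if (sum(n) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        locus_id = tas_loci$locus_id[k],
        sequence = rep(tags$sequence, n),
        start = BiocGenerics::start(BiocGenerics::unlist(m)),
        count = rep(tags$count, n),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus_id = character(0), sequence = character(0),
                      start = integer(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' 21-bin phase-register profile of a TAS locus
#'
#' Each mapped read falls in register `(start - cleavage_pos) mod 21`;
#' a read starting exactly at the cleavage site (or any multiple of 21
#' downstream) is in register 0, the canonical phasing convention.
#' Counts are accumulated per register.
#'
#' @param positions data.frame from [map_21nt()] for one locus
#'   (`start`, `count`).
#' @param cleavage_pos 1-based cleavage position on the cDNA.
#' @return a `phase_profile` list: `bins` (named numeric, registers
#'   0..20), `total` (sum of counts).
#' @export
phase_registers <- function(positions, cleavage_pos) {
  reg <- (positions$start - cleavage_pos) %% 21L
  bins <- setNames(numeric(21), 0:20)
  if (nrow(positions) > 0) {
    agg <- tapply(positions$count, factor(reg, levels = 0:20), sum,
                  default = 0)
    bins[] <- as.numeric(agg)
  }
  structure(list(bins = bins, total = sum(positions$count)),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat("21-nt phase profile,", x$total, "reads\n")
  print(x$bins)
  invisible(x)
}

#' Differential abundance of TAS-derived 21-nt sRNAs
#'
#' Sequences mapped to TAS loci with more than `min_reads` reads in at
#' least one of the two compared libraries (strictly greater) are
#' tested with the tag-count statistic and classified.
#'
#' @param mapped_control,mapped_treatment data.frames from [map_21nt()]
#'   for the two libraries.
#' @param N1,N2 clean-read totals of control and treatment.
#' @param min_reads read filter, default 10 (strictly greater than).
#' @return the [classify_de()] data.frame over the tested sequences,
#'   with a `loci` column listing the loci each sequence maps to.
#' @export
tasirna_de <- function(mapped_control, mapped_treatment, N1, N2,
                       min_reads = 10L) {
  # per-sequence library counts (a sequence may map to several loci;
  # its library count is counted once)
  cnt <- function(m) {
    u <- m[!duplicated(m$sequence), c("sequence", "count")]
    setNames(u$count, u$sequence)
  }
  cx <- cnt(mapped_control); cy <- cnt(mapped_treatment)
  seqs <- union(names(cx), names(cy))
  x <- ifelse(seqs %in% names(cx), cx[seqs], 0L)
  y <- ifelse(seqs %in% names(cy), cy[seqs], 0L)
  keep <- pmax(x, y) > min_reads
  seqs <- seqs[keep]; x <- as.integer(x[keep]); y <- as.integer(y[keep])
  de <- classify_de(seqs, x, y, N1, N2)
  all_map <- rbind(mapped_control, mapped_treatment)
  loci <- vapply(seqs, function(s) {
    paste(sort(unique(all_map$locus_id[all_map$sequence == s]),
               method = "radix"),
          collapse = ",")
  }, character(1))
  de$loci <- unname(loci)
  de
}

#' Build the initiator-miRNA / tasiRNA / target network
#'
#' Nodes: tasiRNA sequences (typed `sRNA`, annotated with their DE
#' call), TAS loci (`TAS_gene`), the initiator miRNA's gene
#' (`MIR_gene`), and predicted target transcripts (`PPR_target` /
#' `TPR_target`). Edges: `generated_from` (sRNA -> TAS locus it maps
#' to, and initiator miRNA -> its MIR gene), `targets` (sRNA ->
#' transcript with a passing duplex), and `initiates` (initiator miRNA
#' -> each TAS locus it cleaves).
#'
#' @param de data.frame from [tasirna_de()] (columns `id`, `call`).
#' @param mapped data.frame from [map_21nt()] pooled over libraries
#'   (`sequence`, `locus_id`).
#' @param initiator list with `id` (e.g. "miR173"), `sequence`,
#'   `mir_gene` (e.g. "MIR173"), and `tas_loci` (character vector of
#'   locus ids it initiates).
#' @param transcripts data.frame with `transcript_id`, `sequence`, and
#'   `family` (`PPR`/`TPR`/other) for the target scan.
#' @return an [igraph::graph] with vertex attributes `type` and
#'   `de_call` and edge attribute `type`.
#' @export
build_network <- function(de, mapped, initiator, transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0)
    .stopf("a transcriptome is required to build the network")
  srnas <- unique(c(de$id, initiator$sequence))
  edges <- list()
  add_edge <- function(from, to, type) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, stringsAsFactors = FALSE)
  }
  gen <- unique(mapped[mapped$sequence %in% srnas,
                       c("sequence", "locus_id")])
  for (r in seq_len(nrow(gen)))
    add_edge(gen$sequence[r], gen$locus_id[r], "generated_from")
  # target edges, each backed by a passing duplex
  for (s in unique(de$id)) {
    sc <- scan_targets(s, transcripts, mirna_id = s)
    for (t in unique(sc$transcript_id)) add_edge(s, t, "targets")
  }
  add_edge(initiator$id, initiator$mir_gene, "generated_from")
  for (l in initiator$tas_loci) add_edge(initiator$id, l, "initiates")
  ed <- do.call(rbind, edges)
  verts <- unique(c(ed$from, ed$to))
  vtype <- rep("sRNA", length(verts))
  vtype[verts %in% mapped$locus_id | verts %in% initiator$tas_loci] <-
    "TAS_gene"
  vtype[verts == initiator$mir_gene] <- "MIR_gene"
  fam <- transcripts$family[match(verts, transcripts$transcript_id)]
  vtype[!is.na(fam) & fam == "PPR"] <- "PPR_target"
  vtype[!is.na(fam) & fam == "TPR"] <- "TPR_target"
  de_call <- de$call[match(verts, de$id)]
  de_call[is.na(de_call) & vtype == "sRNA"] <- "unchanged"
  g <- igraph::graph_from_data_frame(
    ed, directed = TRUE,
    vertices = data.frame(name = verts, type = vtype, de_call = de_call,
                          stringsAsFactors = FALSE))
  g
}

#' Export a network in SIF format
#'
#' One line per edge: `source <tab> interaction <tab> target`, the
#' Cytoscape simple-interaction format.
#'
#' @param g igraph graph with an edge attribute `type`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  ed <- igraph::as_data_frame(g, what = "edges")
  writeLines(paste(ed$from, ed$type, ed$to, sep = "\t"), path)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' @param g igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
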