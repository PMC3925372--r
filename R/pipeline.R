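#' Per-miRNA tag counts from feature hits
#'
#' Sums the counts of all tags with a genomic hit inside an annotated
#' miRNA precursor feature, per precursor gene.
#'
#' @param fhits data.frame from [feature_hits()].
#' @param tags data.frame with `sequence` and `count` for one library.
#' @return data.frame with `gene_id` and `count` for every `miRNA`
#'   class feature (zero rows when there are none).
#' @export
mirna_counts <- function(fhits, tags) {
  mh <- fhits[fhits$class == "miRNA", , drop = FALSE]
  genes <- sort(unique(mh$feature_id), method = "radix")
  cnt <- vapply(genes, function(g) {
    seqs <- unique(mh$sequence[mh$feature_id == g])
    sum(tags$count[match(seqs, tags$sequence)], na.rm = TRUE)
  }, numeric(1))
  data.frame(gene_id = genes, count = as.integer(cnt),
             row.names = NULL, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Builds the reference, simulates all configured libraries, processes
#' them to collapsed tags, annotates against the genome, computes
#' known-miRNA differential abundance (each OE genotype vs WT, per
#' tissue), screens unannotated tags for novel miRNA candidates, runs
#' the tasiRNA phase-register and DE analysis with network export, and
#' quantifies NAT-pair siRNAs — writing every stage's outputs plus a
#' run manifest under `outdir`. All randomness flows from `seed`;
#' a fixed seed reproduces every output byte-identically.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param config a [sim_config()]; its conditions define the libraries.
#' @param control_genotype,treatment_genotypes genotype labels compared
#'   per tissue; defaults WT vs OE7 and OE21.
#' @param log2_cutoff,p_cutoff DE call thresholds.
#' @param tasirna_min_reads strict read filter for tasiRNA DE.
#' @param novel_min_count report threshold for novel candidates
#'   (summed tag count strictly greater).
#' @param novel_screen_min_count minimum per-tissue summed count for a
#'   tag to enter the hairpin screen.
#' @return (invisibly) a list with the main in-memory results:
#'   `reference`, `libraries`, `assignments`, `mirna_de`, `novel`,
#'   `tasirna`, `natsirna`, `manifest`.
#' @export
run_pipeline <- function(outdir, seed = 1L, config = sim_config(),
                         control_genotype = "WT",
                         treatment_genotypes = c("OE7", "OE21"),
                         log2_cutoff = 1, p_cutoff = 0.05,
                         tasirna_min_reads = 10L, novel_min_count = 100L,
                         novel_screen_min_count = 10L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- .stage("reference", {
    r <- build_reference(config, seed)
    write_reference(r, file.path(outdir, "reference"))
    r
  })

  libs <- .stage("process", {
    res <- list()
    for (cn in names(config$conditions)) {
      fq <- file.path(outdir, paste0(cn, ".fastq"))
      sim <- simulate_library(ref, config, cn, seed, fastq = fq,
                              truth_tsv = file.path(outdir,
                                                    paste0(cn, ".truth.tsv")))
      pl <- process_library(fq, config$adapter3, cn,
                            tissue = config$conditions[[cn]]$tissue,
                            genotype = config$conditions[[cn]]$genotype)
      res[[cn]] <- pl
    }
    stats <- do.call(rbind, lapply(res, `[[`, "library"))
    stats$pct_clean <- round(100 * stats$clean_read_count /
                               stats$raw_read_count, 2)
    .write_tsv(stats, file.path(outdir, "library_stats.tsv"))
    res
  })
  lib_meta <- do.call(rbind, lapply(libs, `[[`, "library"))

  ann <- .stage("annotate", {
    all_tags <- sort(unique(unlist(lapply(libs,
                                          function(l) l$tags$sequence))),
                     method = "radix")
    hits <- map_tags(all_tags, ref$genome)
    fhits <- feature_hits(hits, ref$features)
    assignments <- classify_tags(all_tags, fhits)
    .write_tsv(assignments, file.path(outdir, "annotation.tsv"))
    for (cn in names(libs)) {
      .write_tsv(summarize_classes(assignments, libs[[cn]]$tags),
                 file.path(outdir, paste0(cn, ".class_summary.tsv")))
      .write_tsv(libs[[cn]]$length_distribution,
                 file.path(outdir, paste0(cn, ".length_dist.tsv")))
    }
    list(hits = hits, fhits = fhits, assignments = assignments)
  })

  comparisons <- list()
  for (tis in unique(lib_meta$tissue)) {
    ctrl <- lib_meta$library_id[lib_meta$tissue == tis &
                                lib_meta$genotype == control_genotype]
    if (length(ctrl) != 1) next
    for (gt in treatment_genotypes) {
      trt <- lib_meta$library_id[lib_meta$tissue == tis &
                                 lib_meta$genotype == gt]
      if (length(trt) == 1)
        comparisons[[paste0(tis, "_", gt, "_vs_", control_genotype)]] <-
          c(control = ctrl, treatment = trt)
    }
  }
  Nof <- function(lib) lib_meta$clean_read_count[lib_meta$library_id == lib]

  mirna_de <- .stage("mirna-de", {
    out <- list()
    for (nm in names(comparisons)) {
      cp <- comparisons[[nm]]
      mc <- mirna_counts(ann$fhits, libs[[cp["control"]]]$tags)
      mt <- mirna_counts(ann$fhits, libs[[cp["treatment"]]]$tags)
      ids <- union(mc$gene_id, mt$gene_id)
      x <- ifelse(ids %in% mc$gene_id, mc$count[match(ids, mc$gene_id)], 0L)
      y <- ifelse(ids %in% mt$gene_id, mt$count[match(ids, mt$gene_id)], 0L)
      de <- classify_de(ids, as.integer(x), as.integer(y),
                        Nof(cp["control"]), Nof(cp["treatment"]),
                        log2_cutoff, p_cutoff)
      .write_tsv(de, file.path(outdir, paste0("mirna_de.", nm, ".tsv")))
      out[[nm]] <- de
    }
    out
  })

  novel <- .stage("novel", {
    unann <- ann$assignments$sequence[
      ann$assignments$category == "unannotated"]
    out <- list()
    for (tis in unique(lib_meta$tissue)) {
      tl <- lib_meta$library_id[lib_meta$tissue == tis]
      pooled <- do.call(rbind, lapply(tl, function(cn) libs[[cn]]$tags))
      agg <- tapply(pooled$count, pooled$sequence, sum)
      tags <- data.frame(sequence = names(agg), count = as.integer(agg),
                         stringsAsFactors = FALSE)
      tags <- tags[tags$sequence %in% unann &
                   tags$count >= novel_screen_min_count, , drop = FALSE]
      cand <- screen_novel_mirnas(
        tags, ref$genome, ann$hits,
        known_mirna_features = ref$features[ref$features$class == "miRNA", ])
      named <- name_candidates(cand, tis, min_count = novel_min_count)
      .write_tsv(named, file.path(outdir,
                                  paste0("novel_mirna.", tis, ".tsv")))
      out[[tis]] <- named
    }
    out
  })

  tasi <- .stage("tasirna", {
    mapped <- lapply(libs, function(l) map_21nt(l$tags, ref$tas_loci))
    prof <- list()
    for (cn in names(mapped)) {
      for (k in seq_len(nrow(ref$tas_loci))) {
        tid <- ref$tas_loci$locus_id[k]
        pp <- phase_registers(
          mapped[[cn]][mapped[[cn]]$locus_id == tid, , drop = FALSE],
          ref$tas_loci$cleavage_pos[k])
        prof[[paste(cn, tid, sep = ".")]] <- data.frame(
          library_id = cn, locus_id = tid, register = 0:20,
          count = as.numeric(pp$bins), stringsAsFactors = FALSE)
      }
    }
    .write_tsv(do.call(rbind, prof), file.path(outdir, "phase_profiles.tsv"))
    de <- list()
    for (nm in names(comparisons)) {
      cp <- comparisons[[nm]]
      de[[nm]] <- tasirna_de(mapped[[cp["control"]]],
                             mapped[[cp["treatment"]]],
                             Nof(cp["control"]), Nof(cp["treatment"]),
                             min_reads = tasirna_min_reads)
      .write_tsv(de[[nm]], file.path(outdir,
                                     paste0("tasirna_de.", nm, ".tsv")))
    }
    # network from the first leaf comparison
    leaf_cmp <- grep("^leaf_", names(de), value = TRUE)
    g <- NULL
    if (length(leaf_cmp) > 0) {
      nm <- leaf_cmp[1]
      cp <- comparisons[[nm]]
      pooled <- rbind(mapped[[cp["control"]]], mapped[[cp["treatment"]]])
      initiator <- list(
        id = "miR173",
        sequence = ref$mirnas$mature[ref$mirnas$mirna_id == "miR173"],
        mir_gene = "MIR173",
        tas_loci = c("TAS1A", "TAS1B", "TAS1C", "TAS2"))
      g <- build_network(de[[nm]], pooled, initiator, ref$transcripts)
      write_sif(g, file.path(outdir, "network.sif"))
      write_graphml(g, file.path(outdir, "network.graphml"))
    }
    list(mapped = mapped, de = de, network = g)
  })

  nats <- .stage("natsirna", {
    counts <- list()
    for (cn in names(libs)) {
      counts[[cn]] <- nat_region_counts(ann$hits, libs[[cn]]$tags,
                                        ref$nat_pairs, cn)
    }
    .write_tsv(do.call(rbind, counts), file.path(outdir, "nat_counts.tsv"))
    de <- list()
    for (nm in names(comparisons)) {
      cp <- comparisons[[nm]]
      de[[nm]] <- natsirna_de(counts[[cp["control"]]],
                              counts[[cp["treatment"]]],
                              Nof(cp["control"]), Nof(cp["treatment"]))
      .write_tsv(de[[nm]], file.path(outdir,
                                     paste0("natsirna_de.", nm, ".tsv")))
    }
    both <- list()
    for (tis in unique(lib_meta$tissue)) {
      nms <- grep(paste0("^", tis, "_"), names(de), value = TRUE)
      if (length(nms) >= 2)
        both[[tis]] <- altered_in_both(de[[nms[1]]], de[[nms[2]]])
    }
    list(counts = counts, de = de, altered_in_both = both)
  })

  manifest <- .stage("report", {
    outs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    outs <- outs[!grepl("manifest[.]json$|report[.]md$", outs)]
    mf <- list(
      package = "srnapipe",
      version = as.character(utils::packageVersion("srnapipe")),
      seed = as.integer(seed),
      libraries = lib_meta,
      checksums = as.list(tools::md5sum(sort(outs, method = "radix")))
    )
    names(mf$checksums) <- basename(names(mf$checksums))
    jsonlite::write_json(mf, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    rep <- c(
      "# sRNA pipeline run report", "",
      sprintf("- seed: %d", seed),
      sprintf("- libraries: %d (%s)", nrow(lib_meta),
              paste(lib_meta$library_id, collapse = ", ")),
      sprintf("- clean reads: %s",
              paste(lib_meta$clean_read_count, collapse = ", ")),
      sprintf("- unique tags annotated: %d", nrow(ann$assignments)),
      sprintf("- comparisons: %s", paste(names(comparisons),
                                         collapse = ", ")),
      sprintf("- tasiRNA sequences tested (first comparison): %d",
              if (length(tasi$de) > 0) nrow(tasi$de[[1]]) else 0L),
      sprintf("- NAT pairs tested: %d", nrow(ref$nat_pairs))
    )
    writeLines(rep, file.path(outdir, "report.md"))
    mf
  })

  invisible(list(reference = ref, libraries = libs, assignments = ann,
                 mirna_de = mirna_de, novel = novel, tasirna = tasi,
                 natsirna = nats, manifest = manifest,
                 comparisons = comparisons))
}
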