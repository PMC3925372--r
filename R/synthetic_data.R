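#' Simulation configuration for synthetic sRNA libraries
#'
#' Assembles and validates the configuration driving
#' [build_reference()] and [simulate_library()]. Defaults emulate the
#' structure of plant leaf/root sRNA libraries: read-length weights
#' peaked at 21 and 24 nt, a tRNA-derived 19-nt class that dominates in
#' root tissue, four miR173-initiated TAS loci with phased 21-nt
#' production, cis/trans NAT pairs, and condition-specific abundance
#' multipliers for designated miRNAs, TAS loci, and one NAT pair in the
#' overexpression (OE) genotypes.
#'
#' @param reads_per_library target read count per simulated library.
#' @param length_weights named nonnegative weights over insert lengths
#'   18..30 for the classes without a biologically fixed length; must
#'   sum to 1.
#' @param adapter3,adapter5 adapter sequences (the 3' adapter is ligated
#'   onto every non-decoy read; the 5' adapter is recorded but not
#'   embedded, mirroring a clean ligation).
#' @param phasing_fidelity fraction of TAS-derived reads placed exactly
#'   in the 21-nt register anchored at the cleavage site.
#' @param noise_rate per-read probability of one random substitution.
#' @param decoy_frac fraction of reads emitted without a 3' adapter
#'   (library artefacts, discarded at trimming).
#' @param conditions named list of condition definitions; each has
#'   `tissue` (`leaf`/`root`), `genotype`, and multiplier vectors
#'   `mirna`, `tas`, `nat` (named; absent names default to 1).
#' @param genome_length target mini-genome length.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(reads_per_library = 20000L,
                       length_weights = NULL,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       phasing_fidelity = 0.9,
                       noise_rate = 0,
                       decoy_frac = 0.02,
                       conditions = NULL,
                       genome_length = 50000L) {
  if (is.null(length_weights)) {
    length_weights <- c(
      `18` = 0.03, `19` = 0.04, `20` = 0.07, `21` = 0.22, `22` = 0.08,
      `23` = 0.09, `24` = 0.20, `25` = 0.07, `26` = 0.05, `27` = 0.04,
      `28` = 0.04, `29` = 0.03, `30` = 0.04)
  }
  if (any(length_weights < 0) || abs(sum(length_weights) - 1) > 1e-9)
    .stopf("length weights must be nonnegative and sum to 1")
  if (phasing_fidelity < 0 || phasing_fidelity > 1)
    .stopf("phasing fidelity must be in [0, 1]")
  if (nchar(adapter3) < 8) .stopf("3' adapter must be at least 8 nt")
  if (is.null(conditions)) {
    oe_leaf <- list(
      mirna = c(miR172 = 4, miR319 = 4, miR173 = 4, miR391 = 0.25),
      tas = c(TAS1A = 4, TAS1B = 4, TAS1C = 4, TAS2 = 4),
      nat = c(nat_cis1 = 10))
    oe_root <- list(mirna = c(miR172 = 4, miR391 = 0.25),
                    tas = NULL, nat = NULL)
    none <- list(mirna = NULL, tas = NULL, nat = NULL)
    conditions <- list()
    for (tis in c("leaf", "root")) {
      for (gt in c("WT", "pap2", "OE7", "OE21")) {
        mult <- if (gt %in% c("OE7", "OE21")) {
          if (tis == "leaf") oe_leaf else oe_root
        } else none
        conditions[[paste(tis, gt, sep = "_")]] <-
          c(list(tissue = tis, genotype = gt), mult)
      }
    }
  }
  for (cn in names(conditions)) {
    for (mv in c("mirna", "tas", "nat")) {
      m <- conditions[[cn]][[mv]]
      if (!is.null(m) && any(m <= 0))
        .stopf("multipliers must be > 0 (condition %s)", cn)
    }
  }
  structure(list(
    reads_per_library = as.integer(reads_per_library),
    length_weights = length_weights,
    adapter3 = .as_dna(adapter3), adapter5 = .as_dna(adapter5),
    phasing_fidelity = phasing_fidelity, noise_rate = noise_rate,
    decoy_frac = decoy_frac, conditions = conditions,
    genome_length = as.integer(genome_length)
  ), class = "sim_config")
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mature + loop + reverse complement of mature: a perfect ungapped
# hairpin with the mature on the 5' arm
.make_hairpin <- function(mature_len = 21L, loop_len = 18L) {
  mature <- .rand_seq(mature_len)
  list(mature = mature, loop = .rand_seq(loop_len),
       precursor = paste0(mature, .rand_seq(loop_len), revcomp(mature)))
}

#' Build a deterministic synthetic reference
#'
#' Constructs a mini-genome (default ~50 kb) with embedded known miRNA
#' hairpins, two unannotated (novel) hairpins, structural RNA genes
#' (rRNA/tRNA/snRNA/snoRNA/scRNA), Rfam-style ncRNAs, repeats, siRNA
#' loci, protein-coding genes with exons and introns, four
#' miR173-initiated TAS loci, and cis/trans NAT gene pairs; plus a
#' small off-genome transcriptome of PPR/TPR transcripts carrying
#' planted tasiRNA target sites.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed always yields a
#'   byte-identical reference.
#' @return a `syn_reference` list: `genome`, `features` (data.frame),
#'   `mirnas`, `novel`, `tas_loci`, `nat_pairs`, `transcripts`,
#'   `trna19` (the fixed 19-nt tRNA fragment).
#' @export
build_reference <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(seed, "reference"))
  chunks <- list()
  feats <- list()
  cursor <- 0L
  emit <- function(seqc, feature_rows = NULL) {
    # feature_rows: data.frame with relative start/end within seqc
    chunks[[length(chunks) + 1L]] <<- seqc
    if (!is.null(feature_rows)) {
      feature_rows$start <- feature_rows$start + cursor
      feature_rows$end <- feature_rows$end + cursor
      feats[[length(feats) + 1L]] <<- feature_rows
    }
    start <- cursor + 1L
    cursor <<- cursor + nchar(seqc)
    start
  }
  spacer <- function() emit(.rand_seq(200L))
  feat_row <- function(id, class, strand, start, end) {
    data.frame(feature_id = id, class = class, strand = strand,
               start = start, end = end, stringsAsFactors = FALSE)
  }

  # known miRNA precursors
  mir_names <- c("miR156", "miR172", "miR319", "miR173", "miR390",
                 "miR391", "miR398", "miR408")
  mirnas <- list()
  for (mn in mir_names) {
    spacer()
    hp <- .make_hairpin()
    gid <- sub("^miR", "MIR", mn)
    gstart <- emit(hp$precursor,
                   feat_row(gid, "miRNA", "+", 1L, nchar(hp$precursor)))
    mirnas[[mn]] <- data.frame(
      mirna_id = mn, gene_id = gid, precursor = hp$precursor,
      mature = hp$mature, arm = "5p", star = revcomp(hp$mature),
      genome_start = gstart, stringsAsFactors = FALSE)
  }
  mirnas <- do.call(rbind, mirnas); rownames(mirnas) <- NULL

  # unannotated hairpins -> novel miRNA candidates downstream
  novel <- list()
  for (nid in c("novelA", "novelB")) {
    spacer()
    hp <- .make_hairpin()
    gstart <- emit(hp$precursor)   # deliberately no feature record
    novel[[nid]] <- data.frame(
      novel_id = nid, precursor = hp$precursor, mature = hp$mature,
      arm = "5p", genome_start = gstart, stringsAsFactors = FALSE)
  }
  novel <- do.call(rbind, novel); rownames(novel) <- NULL

  # structural RNAs, ncRNAs, repeats, siRNA loci
  simple <- rbind(
    data.frame(id = c("rRNA_1", "rRNA_2"), class = "rRNA", len = 300L),
    data.frame(id = c("tRNA_Gly", "tRNA_Ala", "tRNA_Met"),
               class = "tRNA", len = 75L),
    data.frame(id = "snRNA_1", class = "snRNA", len = 150L),
    data.frame(id = "snoRNA_1", class = "snoRNA", len = 120L),
    data.frame(id = "scRNA_1", class = "scRNA", len = 110L),
    data.frame(id = c("rfam_1", "rfam_2"), class = "rfam_ncRNA",
               len = 120L),
    data.frame(id = c("repeat_1", "repeat_2"), class = "repeat",
               len = 400L),
    data.frame(id = c("sirna_1", "sirna_2"), class = "siRNA", len = 200L)
  )
  simple_seqs <- character(nrow(simple))
  for (k in seq_len(nrow(simple))) {
    spacer()
    s <- .rand_seq(simple$len[k])
    emit(s, feat_row(simple$id[k], simple$class[k], "+", 1L, simple$len[k]))
    simple_seqs[k] <- s
  }
  trna19 <- substr(simple_seqs[simple$id == "tRNA_Gly"], 1, 19)

  # protein-coding genes: exon - intron - exon
  for (g in 1:3) {
    spacer()
    e1 <- 300L; intr <- 150L; e2 <- 300L
    s <- .rand_seq(e1 + intr + e2)
    emit(s, rbind(
      feat_row(sprintf("gene%d_exon1", g), "exon", "+", 1L, e1),
      feat_row(sprintf("gene%d_intron1", g), "intron", "+", e1 + 1L,
               e1 + intr),
      feat_row(sprintf("gene%d_exon2", g), "exon", "+", e1 + intr + 1L,
               e1 + intr + e2)))
  }

  # TAS loci: cDNA with an embedded perfect miR173 site spanning the
  # cleavage position (cleavage after position 10 of the site)
  mir173 <- mirnas$mature[mirnas$mirna_id == "miR173"]
  tas <- list()
  for (tid in c("TAS1A", "TAS1B", "TAS1C", "TAS2")) {
    spacer()
    cdna <- .rand_seq(400L)
    cleave <- 100L
    site <- revcomp(mir173)
    substr(cdna, cleave - 10L, cleave + 10L) <- site
    gstart <- emit(cdna, feat_row(tid, "siRNA", "+", 1L, 400L))
    tas[[tid]] <- data.frame(locus_id = tid, cdna = cdna,
                             cleavage_pos = cleave, genome_start = gstart,
                             stringsAsFactors = FALSE)
  }
  tas <- do.call(rbind, tas); rownames(tas) <- NULL

  # cis NAT pairs: gene_a (+) 1..600, gene_b (-) 401..1000, OL 401..600
  nat <- list()
  for (k in 1:3) {
    spacer()
    block <- .rand_seq(1000L)
    pid <- sprintf("nat_cis%d", k)
    ga <- sprintf("%s_geneA", pid); gb <- sprintf("%s_geneB", pid)
    gstart <- emit(block, rbind(
      feat_row(ga, "exon", "+", 1L, 600L),
      feat_row(gb, "exon", "-", 401L, 1000L)))
    nat[[pid]] <- data.frame(
      pair_id = pid, type = "cis",
      gene_a = ga, a_start = gstart, a_end = gstart + 599L, a_strand = "+",
      gene_b = gb, b_start = gstart + 400L, b_end = gstart + 999L,
      b_strand = "-",
      ol_start = gstart + 400L, ol_end = gstart + 599L,
      ol_b_start = NA_integer_, ol_b_end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  # one trans pair: gene_b carries the reverse complement of a 150-nt
  # segment of gene_a at a different locus
  spacer()
  a_seq <- .rand_seq(400L)
  ga_start <- emit(a_seq, feat_row("nat_trans1_geneA", "exon", "+", 1L, 400L))
  seg <- substr(a_seq, 101L, 250L)
  spacer()
  b_seq <- paste0(.rand_seq(100L), revcomp(seg), .rand_seq(150L))
  gb_start <- emit(b_seq, feat_row("nat_trans1_geneB", "exon", "-", 1L, 400L))
  nat[["nat_trans1"]] <- data.frame(
    pair_id = "nat_trans1", type = "trans",
    gene_a = "nat_trans1_geneA", a_start = ga_start,
    a_end = ga_start + 399L, a_strand = "+",
    gene_b = "nat_trans1_geneB", b_start = gb_start,
    b_end = gb_start + 399L, b_strand = "-",
    ol_start = ga_start + 100L, ol_end = ga_start + 249L,
    ol_b_start = gb_start + 100L, ol_b_end = gb_start + 249L,
    stringsAsFactors = FALSE)
  nat <- do.call(rbind, nat); rownames(nat) <- NULL

  # pad to the target genome length
  if (cursor < config$genome_length) {
    emit(.rand_seq(config$genome_length - cursor))
  }
  genome <- paste(unlist(chunks), collapse = "")
  features <- do.call(rbind, feats); rownames(features) <- NULL

  # off-genome transcriptome with planted tasiRNA target sites
  phased <- function(tid, k) {
    row <- tas[tas$locus_id == tid, ]
    s <- row$cleavage_pos + 21L * k
    substr(row$cdna, s, s + 20L)
  }
  plant <- list(PPR1 = phased("TAS1A", 1L), PPR2 = phased("TAS1A", 2L),
                PPR3 = phased("TAS2", 1L), TPR1 = phased("TAS1B", 1L),
                TPR2 = phased("TAS1C", 2L))
  transcripts <- list()
  for (tn in names(plant)) {
    tseq <- .rand_seq(600L)
    substr(tseq, 300L, 320L) <- revcomp(plant[[tn]])
    transcripts[[tn]] <- data.frame(
      transcript_id = tn, sequence = tseq,
      family = sub("[0-9]+$", "", tn), stringsAsFactors = FALSE)
  }
  transcripts[["OTHER1"]] <- data.frame(
    transcript_id = "OTHER1", sequence = .rand_seq(600L), family = "other",
    stringsAsFactors = FALSE)
  transcripts <- do.call(rbind, transcripts); rownames(transcripts) <- NULL

  ref <- structure(list(
    genome = genome, features = features, mirnas = mirnas, novel = novel,
    tas_loci = tas, nat_pairs = nat, transcripts = transcripts,
    trna19 = trna19
  ), class = "syn_reference")
  .validate_reference(ref)
  ref
}

.validate_reference <- function(ref) {
  for (k in seq_len(nrow(ref$mirnas))) {
    if (!grepl(ref$mirnas$mature[k], ref$mirnas$precursor[k], fixed = TRUE))
      .stopf("mature %s not in its precursor", ref$mirnas$mirna_id[k])
    if (!grepl(ref$mirnas$precursor[k], ref$genome, fixed = TRUE))
      .stopf("precursor %s not locatable in genome", ref$mirnas$mirna_id[k])
  }
  for (k in seq_len(nrow(ref$tas_loci))) {
    t <- ref$tas_loci[k, ]
    if (!grepl(t$cdna, ref$genome, fixed = TRUE))
      .stopf("TAS cDNA %s not locatable in genome", t$locus_id)
    if (t$cleavage_pos < 1 || t$cleavage_pos > nchar(t$cdna))
      .stopf("cleavage position outside cDNA for %s", t$locus_id)
  }
  for (k in seq_len(nrow(ref$nat_pairs))) {
    p <- ref$nat_pairs[k, ]
    if (p$type == "cis" &&
        !(p$ol_start >= p$a_start && p$ol_end <= p$a_end &&
          p$ol_start >= p$b_start && p$ol_end <= p$b_end))
      .stopf("OL not contained in both WL intervals for %s", p$pair_id)
  }
  invisible(ref)
}

#' @export
print.syn_reference <- function(x, ...) {
  cat(sprintf(
    "synthetic reference: %d bp genome, %d features, %d miRNAs, %d TAS loci, %d NAT pairs\n",
    nchar(x$genome), nrow(x$features), nrow(x$mirnas), nrow(x$tas_loci),
    nrow(x$nat_pairs)))
  invisible(x)
}

# per-condition class weights; tRNA fraction is tissue dependent and
# the remaining classes are rescaled to keep the total at 1
.class_weights <- function(tissue, decoy_frac) {
  w <- c(mirna = 0.10, novel = 0.01, rRNA = 0.12, ncRNA = 0.05,
         repeat_ = 0.12, sirna_locus = 0.10, exon = 0.15, intron = 0.04,
         tas = 0.08, nat = 0.08, genomic = 0.10, trna19 = 0.05)
  trna <- if (tissue == "root") 0.30 else 0.05
  other <- setdiff(names(w), "trna19")
  w[other] <- w[other] * (1 - trna) / (1 - w[["trna19"]])
  w[["trna19"]] <- trna
  w <- w * (1 - decoy_frac)
  c(w, decoy = decoy_frac)
}

#' Simulate one sRNA library
#'
#' Draws reads from the reference according to the per-condition class
#' weights and abundance multipliers, ligates the 3' adapter onto every
#' non-decoy read, and records a truth table. Fixed-length classes:
#' miRNA and TAS reads are 21 nt, the tRNA-derived fragment 19 nt,
#' repeat- and siRNA-locus reads 24 nt; the remaining classes draw
#' their insert length from the configured length weights. TAS reads
#' start in the 21-nt register anchored at the cleavage site with
#' probability `phasing_fidelity`, else uniformly on the cDNA.
#'
#' @param ref a `syn_reference` from [build_reference()].
#' @param config a [sim_config()].
#' @param condition a condition label defined in `config$conditions`.
#' @param seed integer seed; the same seed yields a bit-identical
#'   library.
#' @param fastq,truth_tsv optional output paths; when given, the FASTQ
#'   (constant Q40 qualities) and the truth TSV are written.
#' @return list with `reads` (character vector of raw read sequences),
#'   `truth` (data.frame: `read_id, class, feature_id, insert_length,
#'   start, strand, has_adapter`), and `condition`.
#' @export
simulate_library <- function(ref, config, condition, seed = 1L,
                             fastq = NULL, truth_tsv = NULL) {
  stopifnot(inherits(ref, "syn_reference"), inherits(config, "sim_config"))
  cond <- config$conditions[[condition]]
  if (is.null(cond)) .stopf("unknown condition label '%s'", condition)
  set.seed(.child_seed(seed, paste0("library_", condition)))
  n <- config$reads_per_library
  cw <- .class_weights(cond$tissue, config$decoy_frac)

  mult <- function(ids, m) {
    v <- rep(1, length(ids)); names(v) <- ids
    if (!is.null(m)) v[intersect(ids, names(m))] <- m[intersect(ids, names(m))]
    v
  }
  # within-class source weights, multipliers applied
  mir_base <- c(miR156 = 0.20, miR172 = 0.10, miR319 = 0.10, miR173 = 0.08,
                miR390 = 0.12, miR391 = 0.10, miR398 = 0.15, miR408 = 0.15)
  mir_w <- mir_base * mult(names(mir_base), cond$mirna)
  tas_base <- setNames(rep(0.25, 4), ref$tas_loci$locus_id)
  tas_w <- tas_base * mult(names(tas_base), cond$tas)
  nat_base <- setNames(rep(0.25, 4), ref$nat_pairs$pair_id)
  nat_w <- nat_base * mult(names(nat_base), cond$nat)
  novel_w <- c(novelA = 0.7, novelB = 0.3)

  # one global source-weight vector so a multiplier scales the expected
  # count of its source (up to the overall renormalization)
  src <- c(
    setNames(cw[["mirna"]] * mir_w, paste0("mirna:", names(mir_w))),
    setNames(cw[["novel"]] * novel_w, paste0("novel:", names(novel_w))),
    setNames(cw[["tas"]] * tas_w, paste0("tas:", names(tas_w))),
    setNames(cw[["nat"]] * nat_w, paste0("nat:", names(nat_w))),
    trna19 = cw[["trna19"]], rRNA = cw[["rRNA"]], ncRNA = cw[["ncRNA"]],
    repeat_ = cw[["repeat_"]], sirna_locus = cw[["sirna_locus"]],
    exon = cw[["exon"]], intron = cw[["intron"]],
    genomic = cw[["genomic"]], decoy = cw[["decoy"]]
  )
  draws <- sample(names(src), n, replace = TRUE, prob = src)

  glen <- nchar(ref$genome)
  feat_by_class <- split(ref$features, ref$features$class)
  # cumulative mask of annotated positions (features + unannotated
  # hairpins), so background reads come from intergenic space only
  blocked <- logical(glen)
  for (k in seq_len(nrow(ref$features)))
    blocked[ref$features$start[k]:ref$features$end[k]] <- TRUE
  for (k in seq_len(nrow(ref$novel))) {
    e <- ref$novel$genome_start[k] + nchar(ref$novel$precursor[k]) - 1L
    blocked[ref$novel$genome_start[k]:e] <- TRUE
  }
  blocked_cum <- c(0L, cumsum(blocked))
  draw_intergenic <- function(len) {
    st <- integer(length(len))
    todo <- seq_along(len)
    while (length(todo) > 0) {
      cand <- as.integer(floor(runif(length(todo)) *
                                 (glen - len[todo] + 1)) + 1L)
      ok <- (blocked_cum[cand + len[todo]] - blocked_cum[cand]) == 0L
      st[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
    st
  }
  pick_lengths <- function(k) {
    as.integer(sample(names(config$length_weights), k, replace = TRUE,
                      prob = config$length_weights))
  }
  inserts <- character(n)
  cls <- character(n); fid <- character(n)
  start <- rep(NA_integer_, n); strand <- rep("+", n)
  has_adapter <- rep(TRUE, n)

  # generic genomic classes: sample a feature, a length, a position
  generic <- function(idx, class_key, feature_class, antisense_frac = 0,
                      fixed_len = NULL) {
    if (length(idx) == 0) return()
    fs <- feat_by_class[[feature_class]]
    fi <- sample(nrow(fs), length(idx), replace = TRUE)
    len <- if (is.null(fixed_len)) pick_lengths(length(idx)) else
      rep(fixed_len, length(idx))
    span <- fs$end[fi] - fs$start[fi] + 1L
    len <- pmin(len, span)
    off <- floor(runif(length(idx)) * (span - len + 1))
    st <- as.integer(fs$start[fi] + off)
    anti <- runif(length(idx)) < antisense_frac
    ins <- substring(ref$genome, st, st + len - 1L)
    ins[anti] <- revcomp(ins[anti])
    inserts[idx] <<- ins
    cls[idx] <<- class_key
    fid[idx] <<- fs$feature_id[fi]
    start[idx] <<- st
    strand[idx] <<- ifelse(anti, "-", "+")
  }

  for (key in unique(draws)) {
    idx <- which(draws == key)
    if (startsWith(key, "mirna:")) {
      mn <- sub("^mirna:", "", key)
      row <- ref$mirnas[ref$mirnas$mirna_id == mn, ]
      inserts[idx] <- row$mature
      cls[idx] <- "mirna"; fid[idx] <- mn
      start[idx] <- row$genome_start
    } else if (startsWith(key, "novel:")) {
      nn <- sub("^novel:", "", key)
      row <- ref$novel[ref$novel$novel_id == nn, ]
      inserts[idx] <- row$mature
      cls[idx] <- "novel"; fid[idx] <- nn
      start[idx] <- row$genome_start
    } else if (startsWith(key, "tas:")) {
      tid <- sub("^tas:", "", key)
      row <- ref$tas_loci[ref$tas_loci$locus_id == tid, ]
      L <- nchar(row$cdna)
      max_k <- (L - 20L - row$cleavage_pos) %/% 21L
      inreg <- runif(length(idx)) < config$phasing_fidelity
      st <- integer(length(idx))
      st[inreg] <- row$cleavage_pos +
        21L * sample.int(max_k + 1L, sum(inreg), replace = TRUE) - 21L
      st[!inreg] <- sample.int(L - 20L, sum(!inreg), replace = TRUE)
      inserts[idx] <- substring(row$cdna, st, st + 20L)
      cls[idx] <- "tas"; fid[idx] <- tid
      start[idx] <- st   # cDNA coordinate
    } else if (startsWith(key, "nat:")) {
      pid <- sub("^nat:", "", key)
      p <- ref$nat_pairs[ref$nat_pairs$pair_id == pid, ]
      reg <- sample(c("OL", "WL_a", "WL_b"), length(idx), replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
      rs <- ifelse(reg == "OL", p$ol_start,
                   ifelse(reg == "WL_a", p$a_start, p$b_start))
      re <- ifelse(reg == "OL", p$ol_end,
                   ifelse(reg == "WL_a", p$a_end, p$b_end))
      len <- pick_lengths(length(idx))
      len <- pmin(len, re - rs + 1L)
      st <- as.integer(rs + floor(runif(length(idx)) * (re - rs - len + 2)))
      anti <- runif(length(idx)) < 0.5
      ins <- substring(ref$genome, st, st + len - 1L)
      ins[anti] <- revcomp(ins[anti])
      inserts[idx] <- ins
      cls[idx] <- "nat"; fid[idx] <- pid
      start[idx] <- st
      strand[idx] <- ifelse(anti, "-", "+")
    } else if (key == "trna19") {
      inserts[idx] <- ref$trna19
      cls[idx] <- "trna19"; fid[idx] <- "tRNA_Gly"
      start[idx] <- ref$features$start[ref$features$feature_id == "tRNA_Gly"]
    } else if (key == "decoy") {
      inserts[idx] <- vapply(idx, function(i) .rand_seq(30L), character(1))
      cls[idx] <- "decoy"; fid[idx] <- NA_character_
      has_adapter[idx] <- FALSE
    } else if (key == "rRNA") {
      generic(idx, "rRNA", "rRNA")
    } else if (key == "ncRNA") {
      # split evenly over the structural/Rfam ncRNA classes; iterate in
      # a fixed order so the draw sequence is locale-independent
      nc_classes <- c("snRNA", "snoRNA", "scRNA", "rfam_ncRNA")
      pick <- sample(nc_classes, length(idx), replace = TRUE)
      for (g in nc_classes) generic(idx[pick == g], "ncRNA", g)
    } else if (key == "repeat_") {
      generic(idx, "repeat", "repeat", fixed_len = 24L)
    } else if (key == "sirna_locus") {
      generic(idx, "sirna_locus", "siRNA", fixed_len = 24L)
    } else if (key == "exon") {
      generic(idx, "exon", "exon", antisense_frac = 0.25)
    } else if (key == "intron") {
      generic(idx, "intron", "intron")
    } else if (key == "genomic") {
      len <- pick_lengths(length(idx))
      st <- draw_intergenic(len)
      inserts[idx] <- substring(ref$genome, st, st + len - 1L)
      cls[idx] <- "genomic"; fid[idx] <- NA_character_
      start[idx] <- st
    }
  }

  # optional single-substitution noise
  if (config$noise_rate > 0) {
    noisy <- which(runif(n) < config$noise_rate & cls != "decoy")
    for (i in noisy) {
      p <- sample(nchar(inserts[i]), 1)
      substr(inserts[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
  }

  reads <- ifelse(has_adapter, paste0(inserts, config$adapter3), inserts)
  truth <- data.frame(
    read_id = sprintf("%s_read%06d", condition, seq_len(n)),
    class = cls, feature_id = fid, insert_length = nchar(inserts),
    start = start, strand = strand, has_adapter = has_adapter,
    stringsAsFactors = FALSE
  )
  if (!is.null(fastq)) {
    qual <- vapply(nchar(reads), function(w)
      paste(rep("I", w), collapse = ""), character(1))
    con <- file(fastq, "w")
    writeLines(paste0("@", truth$read_id, "\n", reads, "\n+\n", qual), con)
    close(con)
  }
  if (!is.null(truth_tsv)) {
    write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(reads = reads, truth = truth, condition = condition)
}

#' Write reference files to a directory
#'
#' Emits the genome and transcript FASTA files, a GFF3 of the feature
#' annotation (1-based inclusive, via rtracklayer), the miRNA table,
#' the TAS cleavage-site table, and the NAT pair table as TSV.
#'
#' @param ref a `syn_reference`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(ref$genome); names(g) <- "chr1"
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  tx <- Biostrings::DNAStringSet(ref$transcripts$sequence)
  names(tx) <- ref$transcripts$transcript_id
  Biostrings::writeXStringSet(tx, file.path(dir, "transcripts.fa"))
  gr <- GRanges("chr1",
                IRanges(ref$features$start, ref$features$end),
                strand = ref$features$strand)
  mcols(gr)$type <- ref$features$class
  mcols(gr)$ID <- ref$features$feature_id
  mcols(gr)$class <- ref$features$class
  rtracklayer::export(gr, file.path(dir, "features.gff3"), format = "gff3")
  write.table(ref$mirnas, file.path(dir, "mirnas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ref$tas_loci, file.path(dir, "tas_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ref$nat_pairs, file.path(dir, "nat_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
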