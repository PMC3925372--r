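test_that("configuration is validated", {
  expect_error(sim_config(length_weights = c(`21` = 0.5, `24` = 0.4)),
               "sum to 1")
  expect_error(sim_config(phasing_fidelity = 1.5), "fidelity")
  expect_error(sim_config(adapter3 = "ACGT"), "adapter")
  bad <- list(leaf_X = list(tissue = "leaf", genotype = "X",
                            mirna = c(miR172 = 0), tas = NULL, nat = NULL))
  expect_error(sim_config(conditions = bad), "multipliers")
})

test_that("the reference is byte-identical for a fixed seed", {
  cfg <- sim_config(reads_per_library = 500L)
  r1 <- build_reference(cfg, seed = 5L)
  r2 <- build_reference(cfg, seed = 5L)
  expect_identical(r1, r2)
  r3 <- build_reference(cfg, seed = 6L)
  expect_false(identical(r1$genome, r3$genome))
})

test_that("reference invariants hold by construction", {
  expect_equal(nchar(sp_ref$genome), sp_cfg$genome_length)
  # every mature is inside its precursor, every precursor in the genome
  for (k in seq_len(nrow(sp_ref$mirnas))) {
    expect_true(grepl(sp_ref$mirnas$mature[k], sp_ref$mirnas$precursor[k],
                      fixed = TRUE))
    expect_true(grepl(sp_ref$mirnas$precursor[k], sp_ref$genome,
                      fixed = TRUE))
  }
  # TAS cDNAs locatable, cleavage inside
  for (k in seq_len(nrow(sp_ref$tas_loci))) {
    expect_true(grepl(sp_ref$tas_loci$cdna[k], sp_ref$genome, fixed = TRUE))
    expect_true(sp_ref$tas_loci$cleavage_pos[k] >= 1 &&
                sp_ref$tas_loci$cleavage_pos[k] <=
                  nchar(sp_ref$tas_loci$cdna[k]))
  }
  # cis OL contained in both WL intervals
  cis <- sp_ref$nat_pairs[sp_ref$nat_pairs$type == "cis", ]
  expect_true(all(cis$ol_start >= cis$a_start & cis$ol_end <= cis$a_end))
  expect_true(all(cis$ol_start >= cis$b_start & cis$ol_end <= cis$b_end))
  # each TAS cDNA carries a perfect initiator site over the cleavage
  mir173 <- sp_ref$mirnas$mature[sp_ref$mirnas$mirna_id == "miR173"]
  for (k in seq_len(nrow(sp_ref$tas_loci))) {
    site <- substr(sp_ref$tas_loci$cdna[k],
                   sp_ref$tas_loci$cleavage_pos[k] - 10,
                   sp_ref$tas_loci$cleavage_pos[k] + 10)
    expect_equal(site, revcomp(mir173))
  }
})

test_that("libraries are deterministic and respect the config contract", {
  cfg <- sim_config(reads_per_library = 800L)
  ref <- build_reference(cfg, seed = 3L)
  s1 <- simulate_library(ref, cfg, "leaf_WT", seed = 3L)
  s2 <- simulate_library(ref, cfg, "leaf_WT", seed = 3L)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_error(simulate_library(ref, cfg, "no_such_condition", seed = 3L),
               "unknown condition")
  expect_equal(length(s1$reads), 800L)
  # every non-decoy read carries the full 3' adapter
  nd <- !s1$truth$has_adapter
  expect_true(all(grepl(cfg$adapter3, s1$reads[!nd], fixed = TRUE)))
})

test_that("with zero noise every insert is an exact reference substring", {
  truth <- sp_leaf_wt$sim$truth
  ins <- trim_adapter(sp_leaf_wt$sim$reads, sp_cfg$adapter3)
  genomic <- !truth$class %in% c("decoy")
  check <- which(genomic & !is.na(ins))
  # spot-check a deterministic subset for speed
  check <- check[seq(1, length(check), by = 7)]
  both <- paste0(sp_ref$genome, "NNN", revcomp(sp_ref$genome))
  ok <- vapply(ins[check], function(s) grepl(s, both, fixed = TRUE),
               logical(1))
  expect_true(all(ok))
})

test_that("truth-table counts are conserved per feature", {
  truth <- sp_leaf_wt$sim$truth
  emitted <- table(truth$feature_id[truth$class == "mirna"])
  # summed per feature equals reads emitted per feature, by definition
  # of the truth table; cross-check against the collapsed tags
  for (mn in names(emitted)) {
    mat <- sp_ref$mirnas$mature[sp_ref$mirnas$mirna_id == mn]
    cnt <- sp_leaf_wt$tags$count[sp_leaf_wt$tags$sequence == mat]
    expect_gte(cnt, unname(emitted[mn]))
  }
})

test_that("abundance multipliers shift designated miRNAs by the set factor", {
  # self-normalizing ratio-of-ratios from the truth tables: the spiked
  # miRNA against an unspiked one cancels library composition
  t_wt <- sp_leaf_wt$sim$truth
  t_oe <- sp_leaf_oe$sim$truth
  n_wt <- table(t_wt$feature_id[t_wt$class == "mirna"])
  n_oe <- table(t_oe$feature_id[t_oe$class == "mirna"])
  ratio <- (n_oe[["miR172"]] / n_wt[["miR172"]]) /
           (n_oe[["miR156"]] / n_wt[["miR156"]])
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.4)
  # the 0.25x spike leaves only ~15 expected reads, so the sampling
  # band on the ratio is wide; the bounds still exclude ratio 1 (no
  # multiplier) by a large margin
  down <- (n_oe[["miR391"]] / n_wt[["miR391"]]) /
          (n_oe[["miR156"]] / n_wt[["miR156"]])
  expect_gt(down, 0.25 / 2.6)
  expect_lt(down, 0.25 * 2.6)
})

test_that("written FASTQ and reference files are well-formed", {
  dir <- tempfile()
  cfg <- sim_config(reads_per_library = 300L)
  ref <- build_reference(cfg, seed = 2L)
  write_reference(ref, dir)
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(g[[1]]), ref$genome)
  gff <- rtracklayer::import(file.path(dir, "features.gff3"))
  expect_equal(length(gff), nrow(ref$features))
  fq <- file.path(dir, "lib.fastq")
  sim <- simulate_library(ref, cfg, "leaf_WT", seed = 2L, fastq = fq,
                          truth_tsv = file.path(dir, "truth.tsv"))
  reads <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(as.character(unname(reads)), sim$reads)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 300L)
  unlink(dir, recursive = TRUE)
})
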