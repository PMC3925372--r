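tas1a <- sp_ref$tas_loci[sp_ref$tas_loci$locus_id == "TAS1A", ]

test_that("21-nt perfect-match mapping keeps all sense positions", {
  # planted phased read
  phased <- substr(tas1a$cdna, tas1a$cleavage_pos + 21,
                   tas1a$cleavage_pos + 41)
  tags <- data.frame(sequence = phased, count = 7L)
  m <- map_21nt(tags, sp_ref$tas_loci)
  expect_true(any(m$locus_id == "TAS1A" &
                  m$start == tas1a$cleavage_pos + 21 & m$count == 7))
  # a 22-nt tag identical to a cDNA substring is excluded by the filter
  tags22 <- data.frame(sequence = substr(tas1a$cdna, 50, 71), count = 3L)
  expect_equal(nrow(map_21nt(tags22, sp_ref$tas_loci)), 0L)
  # antisense sequence does not map (sense-strand only)
  anti <- data.frame(sequence = revcomp(phased), count = 1L)
  expect_equal(nrow(map_21nt(anti, sp_ref$tas_loci)), 0L)
})

test_that("mapping agrees with a naive scan over every cDNA position", {
  tags <- sp_leaf_wt$tags[nchar(sp_leaf_wt$tags$sequence) == 21, ]
  got <- map_21nt(tags, sp_ref$tas_loci)
  for (k in seq_len(nrow(sp_ref$tas_loci))) {
    cdna <- sp_ref$tas_loci$cdna[k]
    lid <- sp_ref$tas_loci$locus_id[k]
    sub <- got[got$locus_id == lid, ]
    expected <- list()
    for (s in seq_len(nchar(cdna) - 20)) {
      w <- substr(cdna, s, s + 20)
      i <- match(w, tags$sequence)
      if (!is.na(i)) {
        expected[[length(expected) + 1L]] <-
          data.frame(sequence = w, start = s, count = tags$count[i])
      }
    }
    expected <- if (length(expected)) do.call(rbind, expected) else
      data.frame(sequence = character(0), start = integer(0),
                 count = integer(0))
    o1 <- sub[order(sub$start, sub$sequence), c("sequence", "start", "count")]
    o2 <- expected[order(expected$start, expected$sequence), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
  }
})

test_that("phase registers anchor at the cleavage site", {
  pos <- data.frame(start = tas1a$cleavage_pos + c(0, 21, 42),
                    count = c(1L, 2L, 3L))
  pp <- phase_registers(pos, tas1a$cleavage_pos)
  expect_equal(unname(pp$bins[["0"]]), 6)
  expect_equal(sum(pp$bins), pp$total)
  expect_length(pp$bins, 21L)
  # register is invariant to adding 21 to all positions
  pp2 <- phase_registers(transform(pos, start = start + 21L),
                         tas1a$cleavage_pos)
  expect_equal(pp$bins, pp2$bins)
  # a read one base off the register lands in bin 1
  pp3 <- phase_registers(data.frame(start = tas1a$cleavage_pos + 1L,
                                    count = 1L), tas1a$cleavage_pos)
  expect_equal(unname(pp3$bins[["1"]]), 1)
})

test_that("full-fidelity simulation puts every TAS read in register 0", {
  cfg <- sim_config(reads_per_library = 3000L, phasing_fidelity = 1.0)
  ref <- build_reference(cfg, seed = 8L)
  sim <- simulate_library(ref, cfg, "leaf_WT", seed = 8L)
  cc <- clean_and_collapse(trim_adapter(sim$reads, cfg$adapter3))
  m <- map_21nt(cc$tags, ref$tas_loci)
  for (k in seq_len(nrow(ref$tas_loci))) {
    lid <- ref$tas_loci$locus_id[k]
    pp <- phase_registers(m[m$locus_id == lid, ],
                          ref$tas_loci$cleavage_pos[k])
    if (pp$total > 0) {
      expect_equal(unname(pp$bins[["0"]]) / pp$total, 1.0)
    }
  }
})

test_that("uniform positions give a flat 21-bin profile", {
  set.seed(31)
  # 378 = 18 * 21 positions, so registers are exactly equiprobable
  pos <- data.frame(start = sample.int(378L, 1000L, replace = TRUE),
                    count = 1L)
  pp <- phase_registers(pos, 100L)
  expect_equal(sum(pp$bins), 1000)
  chi <- chisq.test(as.numeric(pp$bins))
  expect_gt(chi$p.value, 0.01)
})

test_that("tasiRNA DE applies the strict >10 read filter and delegates", {
  ctrl <- data.frame(locus_id = "TAS1A",
                     sequence = c("A1", "A2", "A3"),
                     start = 1L, count = c(10L, 11L, 100L),
                     stringsAsFactors = FALSE)
  trt <- data.frame(locus_id = "TAS1A",
                    sequence = c("A1", "A2", "A3"),
                    start = 1L, count = c(10L, 11L, 400L),
                    stringsAsFactors = FALSE)
  de <- tasirna_de(ctrl, trt, 1e6, 1e6)
  # 10 reads everywhere: excluded; 11: kept
  expect_false("A1" %in% de$id)
  expect_true("A2" %in% de$id)
  # delegation: identical numbers to the core classifier
  ref_de <- classify_de("A3", 100L, 400L, 1e6, 1e6)
  expect_equal(de$p[de$id == "A3"], ref_de$p)
  expect_equal(de$log2fc[de$id == "A3"], ref_de$log2fc)
  expect_equal(de$call[de$id == "A3"], ref_de$call)
})

test_that("spiked TAS loci are called up in the OE comparison", {
  mc <- map_21nt(sp_leaf_wt$tags, sp_ref$tas_loci)
  mt <- map_21nt(sp_leaf_oe$tags, sp_ref$tas_loci)
  de <- tasirna_de(mc, mt, sp_leaf_wt$clean, sp_leaf_oe$clean)
  expect_gt(nrow(de), 0)
  # every tested sequence comes from a locus spiked 4x: most individual
  # sequences are recovered as up and none as down
  expect_gt(mean(de$call == "up"), 0.6)
  expect_equal(sum(de$call == "down"), 0L)
  # at the locus level the increase is unambiguous for all four loci
  for (tid in sp_ref$tas_loci$locus_id) {
    sc <- mc[mc$locus_id == tid, ]; st <- mt[mt$locus_id == tid, ]
    x <- sum(sc$count[!duplicated(sc$sequence)])
    y <- sum(st$count[!duplicated(st$sequence)])
    locus_de <- classify_de(tid, x, y, sp_leaf_wt$clean, sp_leaf_oe$clean)
    expect_equal(locus_de$call, "up")
  }
})

test_that("the network links sRNAs, loci, initiator and targets", {
  mc <- map_21nt(sp_leaf_wt$tags, sp_ref$tas_loci)
  mt <- map_21nt(sp_leaf_oe$tags, sp_ref$tas_loci)
  de <- tasirna_de(mc, mt, sp_leaf_wt$clean, sp_leaf_oe$clean)
  pooled <- rbind(mc, mt)
  initiator <- list(
    id = "miR173",
    sequence = sp_ref$mirnas$mature[sp_ref$mirnas$mirna_id == "miR173"],
    mir_gene = "MIR173", tas_loci = c("TAS1A", "TAS1B", "TAS1C", "TAS2"))
  g <- build_network(de, pooled, initiator, sp_ref$transcripts)
  ed <- igraph::as_data_frame(g, what = "edges")
  vs <- igraph::as_data_frame(g, what = "vertices")
  # initiator edges: one to the MIR gene, one per cleaved TAS locus
  expect_equal(sum(ed$from == "miR173" & ed$type == "initiates"), 4L)
  expect_true(any(ed$from == "miR173" & ed$to == "MIR173"))
  # every generated_from edge is backed by a perfect-match mapping
  gen <- ed[ed$type == "generated_from" & ed$from != "miR173", ]
  for (k in seq_len(nrow(gen))) {
    expect_true(any(pooled$sequence == gen$from[k] &
                    pooled$locus_id == gen$to[k]))
  }
  # every targets edge is backed by a passing duplex
  tg <- ed[ed$type == "targets", ]
  for (k in seq_len(nrow(tg))) {
    sc <- scan_targets(tg$from[k], sp_ref$transcripts)
    expect_true(tg$to[k] %in% sc$transcript_id)
  }
  # edge count decomposes into its evidence classes
  expect_equal(nrow(ed),
               nrow(unique(pooled[pooled$sequence %in% de$id,
                                  c("sequence", "locus_id")])) +
               nrow(tg) + 4L + 1L)
  # node typing
  expect_equal(sort(unique(vs$type[vs$name %in% c("TAS1A", "TAS2")])),
               "TAS_gene")
  expect_true(all(c("PPR_target", "TPR_target") %in% vs$type) ||
              nrow(tg) == 0)
  expect_error(build_network(de, pooled, initiator,
                             sp_ref$transcripts[0, ]), "transcriptome")
})

test_that("SIF and GraphML exports round-trip the edge list", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c"),
               type = c("targets", "generated_from")))
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  write_sif(g, sif)
  expect_equal(readLines(sif),
               c("a\ttargets\tb", "b\tgenerated_from\tc"))
  write_graphml(g, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), 2)
  ed2 <- igraph::as_data_frame(g2, what = "edges")
  expect_equal(ed2$type, c("targets", "generated_from"))
  unlink(c(sif, gml))
})
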