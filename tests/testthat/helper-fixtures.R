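# Shared desk-scale fixtures, built once per test run. Library sizes
# are chosen so designated spiked miRNAs exceed 50 counts in every
# library while the whole suite stays fast.
sp_cfg <- sim_config(reads_per_library = 8000L)
sp_ref <- build_reference(sp_cfg, seed = 42L)

.sim_and_collapse <- function(condition) {
  sim <- simulate_library(sp_ref, sp_cfg, condition, seed = 42L)
  cc <- clean_and_collapse(trim_adapter(sim$reads, sp_cfg$adapter3))
  list(sim = sim, tags = cc$tags, clean = cc$clean_read_count)
}

sp_leaf_wt <- .sim_and_collapse("leaf_WT")
sp_leaf_oe <- .sim_and_collapse("leaf_OE7")
sp_root_wt <- .sim_and_collapse("root_WT")

sp_hits_wt <- map_tags(sp_leaf_wt$tags, sp_ref$genome)
sp_fhits_wt <- feature_hits(sp_hits_wt, sp_ref$features)
sp_assign_wt <- classify_tags(sp_leaf_wt$tags$sequence, sp_fhits_wt)

# direct (non-log) evaluation of the tag-count sampling probability,
# used as the independent high-precision oracle for small counts
oracle_ac <- function(x, y, N1, N2) {
  r <- N2 / N1
  choose(x + y, y) * r^y / (1 + r)^(x + y + 1)
}
oracle_two_tailed <- function(x, y, N1, N2) {
  q <- sum(oracle_ac(x, 0:y, N1, N2))
  p <- if (q > 0.5) 2 * (1 - q) else 2 * q
  min(max(p, 0), 1)
}

# random 21-nt duplex partner with controlled per-position states
make_site <- function(mirna, states) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wobble <- c(G = "T", T = "G")
  other <- function(b) setdiff(c("A", "C", "G", "T"), c(comp[[b]],
                               if (b %in% names(wobble)) wobble[[b]]))[1]
  m <- strsplit(mirna, "")[[1]]
  s <- character(length(m))
  for (i in seq_along(m)) {
    s[i] <- switch(states[i],
      match = comp[[m[i]]],
      GU = wobble[[m[i]]],
      mismatch = other(m[i]))
  }
  paste(rev(s), collapse = "")
}
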