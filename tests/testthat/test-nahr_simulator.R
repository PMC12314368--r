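tiny_cfg <- function(...) {
  args <- modifyList(
    list(seed = 5L, n_scaffolds = 1L, genes_per_scaffold = 120L,
         n_te_insertions = 60L, n_hotspots = 1L, hotspot_fraction = 0.3,
         n_nahr_events = 8L),
    list(...))
  do.call(sim_config, args)
}

test_that("ancestor genomes are well-formed and seed-deterministic", {
  set.seed(5)
  anc <- simulate_ancestor(tiny_cfg())
  u <- anc$scaffolds$s01
  expect_equal(nrow(u), 120L)
  expect_true(all(nchar(u$cds) %% 3 == 0))
  # no internal stops in any CDS
  for (cds in u$cds[1:30]) {
    aa <- translate_cds(cds)
    expect_false(grepl("\\*", aa))
  }
  set.seed(5)
  anc2 <- simulate_ancestor(tiny_cfg())
  expect_identical(anc$scaffolds$s01$cds, anc2$scaffolds$s01$cds)
  expect_identical(anc$hotspots, anc2$hotspots)
  # hotspot span covers the configured fraction, away from scaffold ends
  hs <- anc$hotspots
  expect_gte(hs$rank_start, 0.1 * 120)
  expect_lte(hs$rank_end, 0.9 * 120)
})

test_that("transposon insertion respects rate 0, hotspot bias, and CDS", {
  cfg <- tiny_cfg()
  set.seed(5)
  anc <- simulate_ancestor(cfg)
  none <- insert_transposons(anc, modifyList(cfg, list(n_te_insertions = 0L)))
  expect_equal(sum(lengths(none$scaffolds$s01$tes)), 0L)

  set.seed(5)
  anc <- insert_transposons(simulate_ancestor(cfg), cfg)
  u <- anc$scaffolds$s01
  n_te <- vapply(u$tes, length, 0L)
  expect_equal(sum(n_te), 60L)
  in_hs <- u$anc_rank >= anc$hotspots$rank_start &
    u$anc_rank <= anc$hotspots$rank_end
  expect_gt(sum(n_te[in_hs]) / sum(n_te), 0.5)   # biased into hotspots

  # physical layout never places a TE inside a CDS
  lay <- nsrscan:::layout_scaffold(u, cfg)
  if (nrow(lay$tes)) {
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(lay$tes$start + 1L, lay$tes$end),
      IRanges::IRanges(lay$genes$start + 1L, lay$genes$end))
    expect_false(any(ov))
  }
})

test_that("one unequal crossover duplicates a tract and deletes its homolog", {
  cfg <- tiny_cfg()
  set.seed(5)
  anc <- insert_transposons(simulate_ancestor(cfg), cfg)
  genomes <- list(A = lapply(anc$scaffolds, data.table::copy),
                  B = lapply(anc$scaffolds, data.table::copy))
  u <- genomes$A$s01
  te_idx <- which(vapply(u$tes, length, 0L) > 0L)
  # force a single-gene tract between two copies of one family
  fam <- u$tes[[te_idx[1]]][1]
  u$tes[[te_idx[1] + 1L]] <- c(u$tes[[te_idx[1] + 1L]], fam)
  genomes$A$s01 <- u
  sp <- list(left = te_idx[1], right = te_idx[1] + 1L, family = fam)
  before_a <- nrow(genomes$A$s01); before_b <- nrow(genomes$B$s01)
  res <- apply_unequal_crossover(genomes, "s01", sp, "A", event_id = 99L)
  expect_equal(nrow(res$genomes$A$s01), before_a + 1L)   # gain +1
  expect_equal(nrow(res$genomes$B$s01), before_b - 1L)   # loss -1
  ga <- res$genomes$A$s01
  copy_row <- which(grepl("\\.d99$", ga$gene_id))
  expect_length(copy_row, 1L)
  # tandem by construction: copy adjacent to its template, same lineage
  expect_equal(ga$anc_id[copy_row], ga$anc_id[copy_row - 1L])
  expect_true(all(ga$is_dup[c(copy_row - 1L, copy_row)]))
  # deleted lineage gone from B
  expect_false(ga$anc_id[copy_row] %in% res$genomes$B$s01$anc_id)
  # zero-length tract is a no-op
  noop <- apply_unequal_crossover(res$genomes, "s01",
                                  list(left = 5L, right = 5L, family = fam),
                                  "A")
  expect_null(noop$event)
  expect_identical(noop$genomes, res$genomes)
})

test_that("recurrent NAHR grows copy number in the gaining haplotype", {
  sim <- small_sim()
  ev <- sim$events[type == "nahr"]
  expect_gte(nrow(ev), 15L)
  # replay oracle: cumulative gene counts per haplotype follow the log
  counts <- c(A = sim$config$genes_per_scaffold,
              B = sim$config$genes_per_scaffold)
  for (i in seq_len(nrow(ev))) {
    g <- ev$gain_hap[i]
    counts[g] <- counts[g] + ev$n_gained[i]
    counts[setdiff(c("A", "B"), g)] <-
      counts[setdiff(c("A", "B"), g)] - ev$n_lost[i]
    expect_gte(ev$n_gained[i], 1L)
  }
  expect_equal(unname(counts["A"]), nrow(sim$genomes$A$s01))
  expect_equal(unname(counts["B"]), nrow(sim$genomes$B$s01))
  # every post-simulation gene maps to exactly one ancestral lineage
  set.seed(sim$config$seed)
  anc <- simulate_ancestor(sim$config)
  for (hap in c("A", "B")) {
    expect_true(all(sim$genomes[[hap]]$s01$anc_id %in%
                      anc$scaffolds$s01$anc_id))
  }
})

test_that("zero NAHR events leave no truth tracts", {
  cfg <- tiny_cfg(n_nahr_events = 0L)
  sim <- simulate_nahr_dataset(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(!sim$genomes$A$s01$is_dup))
})

test_that("zero substitution rates leave sequences identical (Ks = 0)", {
  cfg <- tiny_cfg(syn_rate = 0, nonsyn_rate = 0, dup_syn_rate = 0,
                  dup_nonsyn_rate = 0)
  sim <- simulate_nahr_dataset(cfg)
  ua <- sim$genomes$A$s01; ub <- sim$genomes$B$s01
  shared <- intersect(ua$anc_id[!ua$is_dup], ub$anc_id[!ub$is_dup])[1:5]
  for (aid in shared) {
    ca <- ua$cds[match(aid, ua$anc_id)]
    cb <- ub$cds[match(aid, ub$anc_id)]
    expect_identical(ca, cb)
    expect_equal(kaks_pair(ca, cb)$Ks, 0)
  }
})

test_that("mutation never introduces an internal stop", {
  sim <- small_sim()
  set.seed(77)
  for (hap in c("A", "B")) {
    u <- sim$genomes[[hap]]$s01
    probe <- sample(nrow(u), 40)
    for (cds in u$cds[probe]) {
      expect_false(grepl("\\*", translate_cds(cds)))
    }
  }
})

test_that("expression: zero noise gives r = 1 for conserved ortholog pairs", {
  cfg <- tiny_cfg(expression_noise_sd = 0)
  sim <- simulate_nahr_dataset(cfg)
  ua <- sim_gene_table(sim, "A"); ub <- sim_gene_table(sim, "B")
  shared <- intersect(ua[is_dup == FALSE]$anc_id, ub[is_dup == FALSE]$anc_id)
  ma <- sim$expression$A; mb <- sim$expression$B
  for (aid in shared[1:10]) {
    ga <- ua$gene_id[match(aid, ua$anc_id)]
    gb <- ub$gene_id[match(aid, ub$anc_id)]
    expect_equal(pearson_r(ma[ga, ], mb[gb, ]), 1)
  }
  expect_true(all(ma >= 0) && all(mb >= 0))
})

test_that("one seed gives a byte-identical emitted dataset", {
  cfg <- tiny_cfg()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  emit_dataset(simulate_nahr_dataset(cfg), d1)
  emit_dataset(simulate_nahr_dataset(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("emitted files parse through the package readers", {
  sim <- small_sim()
  d <- file.path(tempdir(), "parse_ds")
  emit_dataset(sim, d)
  expect_no_warning({
    ga <- read_gff3(file.path(d, "hapA.gff3"))
    hits <- read_tabular_hits(file.path(d, "hits.tsv"))
    reps <- read_repeatmasker_out(file.path(d, "repeats.out"))
    ogs <- read_orthogroups(file.path(d, "orthogroups.txt"))
    bed <- read_bed(file.path(d, "truth_nsr.bed"))
    expr <- read_expression_tsv(file.path(d, "expression_hapA.tsv"))
  })
  expect_equal(nrow(ga), nrow(sim_gene_table(sim, "A")))
  expect_true(all(reps$class %in% c("LTR", "LINE", "SINE", "DNA", "other")))
  expect_gt(nrow(hits), 0)
  # truth intervals are inside scaffold bounds
  lens <- sim_scaffold_lengths(sim)
  expect_true(all(bed$end <= lens[bed$scaffold_id]))
  expect_true(all(bed$start >= 0))
  # genome FASTA carries telomeres at both ends and the declared lengths
  gseq <- Biostrings::readDNAStringSet(file.path(d, "hapA_genome.fa"))
  expect_equal(unname(Biostrings::width(gseq)), unname(lens["A_s01"]))
  s <- as.character(gseq[[1]])
  expect_equal(substr(s, 1, 6), "TTAGGG")
  expect_equal(substr(s, nchar(s) - 5, nchar(s)), "TTAGGG")
})
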