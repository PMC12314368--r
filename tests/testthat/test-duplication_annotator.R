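mk_tags <- function(ids, sp = "sp1", hap = "A") {
  data.table::data.table(gene_id = ids, species = sp, haplotype = hap)
}

sym_hits <- function(pairs, ev = 1e-30, bits = 200) {
  data.table::data.table(query_id = c(pairs$a, pairs$b),
                         subject_id = c(pairs$b, pairs$a),
                         e_value = ev, bit_score = bits)
}

test_that("orthogroup fallback clusters an RBH square and keeps singletons", {
  tags <- rbind(mk_tags(c("a1", "a2"), "sp1", "A"),
                mk_tags(c("b1", "b2"), "sp2", "A"),
                mk_tags("lonely", "sp1", "A"))
  # 4 genes forming a reciprocal-best square (a1-b1, a2-b2 across genomes,
  # a1-a2 and b1-b2 within genomes)
  h <- sym_hits(data.frame(a = c("a1", "a2", "a1", "b1"),
                           b = c("b1", "b2", "a2", "b2")))
  og <- cluster_orthogroups_fallback(h, tags)
  grp <- split(og$gene_id, og$group_id)
  sizes <- sort(lengths(grp))
  expect_equal(unname(sizes), c(1L, 4L))
  expect_true("lonely" %in% grp[[which(lengths(grp) == 1L)]])
})

test_that("fallback clustering equals independent graph components", {
  skip_if_not_installed("igraph")
  set.seed(17)
  ids <- paste0("g", 1:20)
  tags <- mk_tags(ids, "sp1", "A")   # one genome: all hits are within-genome
  pairs <- data.frame(a = sample(ids, 15, replace = TRUE),
                      b = sample(ids, 15, replace = TRUE))
  pairs <- pairs[pairs$a != pairs$b, ]
  h <- sym_hits(pairs)
  og <- cluster_orthogroups_fallback(h, tags)
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = ids)
  want <- igraph::components(g)$membership
  got <- setNames(og$group_id, og$gene_id)[ids]
  # same partition: equal groups iff equal components
  expect_equal(length(unique(got)), length(unique(want)))
  expect_true(all(tapply(want, got, function(x) length(unique(x)) == 1L)))
})

test_that("TDG pairs: adjacency, one intervening unrelated gene, distance 3", {
  genes <- data.table::data.table(
    gene_id = c("A1", "A2", "X", "A3", "Y", "Z", "A4"),
    scaffold_id = "s1", start = (1:7) * 1000L)
  groups <- data.table::data.table(
    gene_id = c("A1", "A2", "A3", "A4", "X", "Y", "Z"),
    group_id = c("OG1", "OG1", "OG1", "OG1", "OG2", "OG3", "OG4"))
  td <- find_tdg_pairs(genes, groups)
  key <- paste(td$gene_a, td$gene_b)
  expect_true("A1 A2" %in% key)                  # adjacent
  expect_true("A2 A3" %in% key)                  # one unrelated in between
  expect_false("A3 A4" %in% key)                 # two intervening genes
  expect_equal(td[td$gene_a == "A2"]$intervening, 1L)
  # same-group intervening gene does not create a distance-2 pair
  genes2 <- data.table::data.table(gene_id = c("B1", "B2", "B3"),
                                   scaffold_id = "s1", start = (1:3) * 100L)
  groups2 <- data.table::data.table(gene_id = c("B1", "B2", "B3"),
                                    group_id = "OG9")
  td2 <- find_tdg_pairs(genes2, groups2)
  expect_false("B1 B3" %in% paste(td2$gene_a, td2$gene_b))
})

test_that("find_tdg_pairs equals the O(n^2) brute-force scan", {
  set.seed(23)
  n <- 400L
  genes <- data.table::data.table(gene_id = paste0("g", 1:n),
                                  scaffold_id = "s1",
                                  start = sort(sample.int(1e6, n)))
  groups <- data.table::data.table(gene_id = genes$gene_id,
                                   group_id = paste0("OG", sample(1:60, n,
                                                                  replace = TRUE)))
  got <- find_tdg_pairs(genes, groups)
  gmap <- setNames(groups$group_id, groups$gene_id)
  ids <- genes$gene_id
  want <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- j - i
    if (d > 2L) next
    if (gmap[ids[i]] != gmap[ids[j]]) next
    if (d == 2L && gmap[ids[i + 1L]] == gmap[ids[i]]) next
    want[[length(want) + 1L]] <- paste(ids[i], ids[j])
  }
  expect_setequal(paste(got$gene_a, got$gene_b), unlist(want))
})

mk_mem <- function(gid, sp, hap, genes) {
  data.table::data.table(group_id = gid, species = sp, haplotype = hap,
                         gene_id = genes)
}

test_that("SSTDG calls require the 1:1 vs 2:2 pattern plus tandem arrangement", {
  mem <- rbind(
    # OG1: sp1 one copy/hap, sp2 two copies/hap, sp2 copies adjacent in hap A
    mk_mem("OG1", "sp1", "A", "s1a"), mk_mem("OG1", "sp1", "B", "s1b"),
    mk_mem("OG1", "sp2", "A", c("t1", "t2")),
    mk_mem("OG1", "sp2", "B", c("t3", "t4")),
    # OG2: copy numbers differ between haplotypes -> rejected
    mk_mem("OG2", "sp1", "A", "u1"), mk_mem("OG2", "sp1", "B", "u2"),
    mk_mem("OG2", "sp2", "A", c("v1", "v2")), mk_mem("OG2", "sp2", "B", "v3"),
    # OG3: both species expanded -> rejected
    mk_mem("OG3", "sp1", "A", c("w1", "w2")), mk_mem("OG3", "sp1", "B", c("w3", "w4")),
    mk_mem("OG3", "sp2", "A", c("x1", "x2")), mk_mem("OG3", "sp2", "B", c("x3", "x4")))
  tdg <- data.table::data.table(gene_a = "t1", gene_b = "t2",
                                scaffold_id = "s", group_id = "OG1",
                                intervening = 0L)
  calls <- call_sstdg(mem, tdg, c("sp1", "sp2"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$expanded_species, "sp2")
  expect_true(calls$tandem)
  expect_equal(sort(c(calls$gene_a, calls$gene_b)), c("t1", "t2"))
  # candidate without tandem arrangement is reported but not an SSTDG
  calls2 <- call_sstdg(mem, tdg[0], c("sp1", "sp2"))
  expect_false(any(calls2$tandem))
  # species labelling symmetry: swapping species only swaps expanded label
  calls3 <- call_sstdg(mem, tdg, c("sp2", "sp1"))
  expect_equal(calls3$expanded_species, "sp2")
})

test_that("SSTDG nSR overlap fractions reproduce printed arithmetic", {
  # geometry: pair span midpoints either inside or outside one interval
  genes <- data.table::data.table(
    gene_id = c("p1", "p2", "q1", "q2"),
    scaffold_id = "s1",
    start = c(1000L, 2000L, 50000L, 52000L),
    end = c(1500L, 2500L, 51000L, 53000L))
  calls <- data.table::data.table(group_id = c("OG1", "OG2"),
                                  expanded_species = "sp2",
                                  gene_a = c("p1", "q1"),
                                  gene_b = c("p2", "q2"),
                                  tandem = TRUE)
  nsr <- data.table::data.table(scaffold_id = "s1", start = 0L, end = 10000L)
  ov <- sstdg_nsr_overlap(calls, genes, nsr)
  expect_equal(ov$n_in_nsr, 1L)
  expect_equal(ov$pct, 50)
  expect_equal(sstdg_nsr_overlap(calls[0], genes, nsr)$pct, 0)
  # the paper-scale fractions via the same rounding rule
  expect_equal(pct_of(7, 56), 12.5)
  expect_equal(pct_of(20, 119), 16.8)
})
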