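mk_genes <- function(n, sc = "s", prefix = "g") {
  data.table::data.table(gene_id = paste0(prefix, seq_len(n)),
                         scaffold_id = sc,
                         start = seq_len(n) * 1000L,
                         end = seq_len(n) * 1000L + 500L,
                         strand = "+")
}

mk_hits <- function(qa, sb, ev = 1e-30) {
  data.table::data.table(query_id = qa, subject_id = sb,
                         pct_identity = 95, aln_length = 100L,
                         e_value = ev, bit_score = 200)
}

test_that("build_anchors applies the e-value cut and collapses duplicates", {
  ga <- mk_genes(10, "sa", "a")
  gb <- mk_genes(10, "sb", "b")
  h <- rbind(mk_hits("a1", "b1", 1e-3),          # above cut, excluded
             mk_hits("a2", "b2", 1e-30),
             mk_hits("a2", "b2", 1e-40))          # duplicate pair
  anc <- build_anchors(h, ga, gb)
  expect_equal(nrow(anc), 1L)
  expect_equal(anc$e_value, 1e-40)                # best e-value kept
  expect_equal(c(anc$index_a, anc$index_b), c(2L, 2L))

  # 1:1 identical gene sets -> n anchors on the diagonal
  diag_h <- mk_hits(paste0("a", 1:10), paste0("b", 1:10))
  anc2 <- build_anchors(diag_h, ga, gb)
  expect_equal(anc2$index_a, anc2$index_b)
  expect_equal(nrow(anc2), 10L)
  expect_error(build_anchors(mk_hits("aX", "b1"), ga, gb), NA)  # unknown ids dropped
})

test_that("tandem arrays collapse to one representative anchor", {
  ga <- mk_genes(6, "sa", "a")
  gb <- mk_genes(6, "sb", "b")
  # a1,a2,a3 consecutive, all hitting b1; a2 best
  h <- rbind(mk_hits("a1", "b1", 1e-20), mk_hits("a2", "b1", 1e-40),
             mk_hits("a3", "b1", 1e-10))
  anc <- build_anchors(h, ga, gb)
  expect_equal(nrow(anc), 1L)
  expect_equal(anc$gene_a, "a2")
})

test_that("chain_anchors recovers a perfect diagonal with the stated score", {
  anc <- data.table::data.table(index_a = 1:20, index_b = 1:20,
                                gene_a = paste0("a", 1:20),
                                gene_b = paste0("b", 1:20),
                                e_value = 1e-30)
  b <- chain_anchors(anc, collinear_params(), 20, 20)
  expect_length(b, 1L)
  expect_equal(b[[1]]$score, 20 * 50)              # no gaps: 20 x match_score
  expect_equal(b[[1]]$orientation, "parallel")
  expect_equal(nrow(b[[1]]$anchors), 20L)
  expect_lt(b[[1]]$e_value, 1e-5)
  expect_silent(validate_block(b[[1]]))

  # 9 perfect anchors: below match_size, no block
  b9 <- chain_anchors(anc[1:9], collinear_params(), 20, 20)
  expect_length(b9, 0L)

  # antiparallel diagonal
  anc_r <- data.table::copy(anc)
  anc_r[, index_b := 21L - index_b]
  br <- chain_anchors(anc_r, collinear_params(), 20, 20)
  expect_equal(br[[1]]$orientation, "antiparallel")
  expect_silent(validate_block(br[[1]]))
})

test_that("a hidden collinear run is recovered from random noise", {
  set.seed(42)
  # 12 collinear anchors spaced 2 ranks apart among 30 random anchors
  run <- data.table::data.table(index_a = seq(5, 27, 2),
                                index_b = seq(5, 27, 2))
  run[, `:=`(gene_a = paste0("ra", .I), gene_b = paste0("rb", .I),
             e_value = 1e-30)]
  # noise index_b values sit on a grid spaced wider than max_gaps, so no
  # two noise anchors (and no noise/run combination) can ever chain
  noise <- data.table::data.table(
    index_a = sample(1:60, 30, replace = TRUE),
    index_b = sample(seq(200L, 2000L, by = 30L), 30))
  noise <- unique(noise)
  noise[, `:=`(gene_a = paste0("na", .I), gene_b = paste0("nb", .I),
               e_value = 1e-30)]
  anc <- rbind(run, noise)
  blocks <- chain_anchors(anc, collinear_params(), 90, 2100)
  expect_length(blocks, 1L)
  expect_setequal(blocks[[1]]$anchors$gene_a, run$gene_a)
})

test_that("k disjoint diagonals give k blocks covering all anchors", {
  mk_diag <- function(off, k = 12L, tag) {
    data.table::data.table(index_a = off + seq_len(k),
                           index_b = off + seq_len(k),
                           gene_a = paste0(tag, "a", seq_len(k)),
                           gene_b = paste0(tag, "b", seq_len(k)),
                           e_value = 1e-30)
  }
  anc <- rbind(mk_diag(0, tag = "x"), mk_diag(60, tag = "y"),
               mk_diag(120, tag = "z"))
  blocks <- chain_anchors(anc, collinear_params(), 140, 140)
  expect_length(blocks, 3L)
  expect_setequal(unlist(lapply(blocks, function(b) b$anchors$gene_a)),
                  anc$gene_a)
  for (b in blocks) expect_silent(validate_block(b))

  # input-order invariance
  set.seed(5)
  blocks2 <- chain_anchors(anc[sample(.N)], collinear_params(), 140, 140)
  s1 <- sort(vapply(blocks, function(b) b$score, 0))
  s2 <- sort(vapply(blocks2, function(b) b$score, 0))
  expect_equal(s1, s2)
})

test_that("DP top-chain score equals exhaustive search on small instances", {
  p <- collinear_params(match_size = 2L, e_value_cut = Inf)
  set.seed(314)
  for (rep in 1:12) {
    n <- sample(8:16, 1)
    anc <- unique(data.table::data.table(
      index_a = sample(1:20, n, replace = TRUE),
      index_b = sample(1:20, n, replace = TRUE)))
    anc[, `:=`(gene_a = paste0("a", .I), gene_b = paste0("b", .I),
               e_value = 1e-30)]
    data.table::setorder(anc, index_a, index_b)
    blocks <- chain_anchors(anc, p, 25, 25)
    got <- if (length(blocks)) max(vapply(blocks, function(b) b$score, 0)) else -Inf
    want <- oracle_best_chain(anc, p)
    if (want < 2 * p$match_score) next  # no chain of >= match_size exists
    expect_equal(got, want)
  }
})

test_that("block e-value behaves like the Monte-Carlo permutation oracle", {
  blk <- list(anchors = data.table::data.table(index_a = 1:20, index_b = 1:20))
  ev <- block_evalue(blk, 20, 20, 20)
  expect_lt(ev, 1e-5)
  # MC oracle: 20 anchors scattered uniformly on a 20x20 grid; count how
  # often a jointly monotone run of >= 20 appears (never, in 1e4 trials)
  set.seed(8)
  hits <- 0L
  for (i in 1:10000) {
    ib <- sample(20)
    # longest increasing subsequence of a permutation
    lis <- integer(0)
    for (v in ib) {
      pos <- findInterval(v, lis) + 1L
      if (pos > length(lis)) lis <- c(lis, v) else lis[pos] <- v
    }
    if (length(lis) >= 20L) hits <- hits + 1L
  }
  expect_equal(hits, 0L)

  # a 2-anchor "block" in a dense field is not significant
  blk2 <- list(anchors = data.table::data.table(index_a = c(3L, 10L),
                                                index_b = c(4L, 12L)))
  expect_gte(block_evalue(blk2, 200, 20, 20), 1e-5)

  # monotone decreasing in anchor count at fixed rectangle
  evs <- vapply(5:15, function(m) {
    nsrscan:::block_evalue_counts(m, 20L, 20L, 50L, 100L, 100L)
  }, 0)
  expect_true(all(diff(evs) < 0))
  expect_error(nsrscan:::block_evalue_counts(2, 0L, 5L, 10L, 10L, 10L),
               "rectangle")
})

test_that("homologous_gene_flags joins blocks with Ka/Ks classifications", {
  blocks <- list(list(anchors = data.table::data.table(
    gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))))
  kaks <- data.table::data.table(
    gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
    Ks = c(0.01, 0.45), Ka = c(0.001, 0.2), ratio = c(0.1, 0.44))
  fl <- homologous_gene_flags(blocks, kaks)
  expect_true(fl[["a1"]] && fl[["b1"]])
  expect_false(fl[["a2"]] || fl[["b2"]])
  # saturated pair -> not homologous
  kaks2 <- data.table::copy(kaks)[gene_a == "a1", Ks := NA_real_]
  fl2 <- homologous_gene_flags(blocks, kaks2)
  expect_false(fl2[["a1"]])
  # missing Ka/Ks for an anchor is an error listing the pair
  expect_error(homologous_gene_flags(blocks, kaks[1]), "a2/b2")
})
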