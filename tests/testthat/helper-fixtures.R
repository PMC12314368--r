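# Shared fixtures, built in code.

gff3_lines <- function(...) {
  c("##gff-version 3", ...)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a minimal 2-gene GFF3 with isoforms of different CDS lengths
fixture_gff3 <- function() {
  write_tmp(gff3_lines(
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=gA.t1.c;Parent=gA.t1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\tCDS\t1\t450\t.\t+\t0\tID=gA.t2.c;Parent=gA.t2",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=gB;species=sp;haplotype=A",
    "chr1\tsrc\tmRNA\t500\t900\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\tCDS\t500\t900\t.\t-\t0\tID=gB.t1.c;Parent=gB.t1"
  ), ".gff3")
}

random_sense_cds <- function(n_internal, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG", paste(sample(nsrscan:::SENSE_CODONS, n_internal,
                             replace = TRUE), collapse = ""), "TAA")
}

# a small but fully featured simulation reused across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_nahr_dataset(sim_config(
        seed = 421L, n_scaffolds = 1L, genes_per_scaffold = 250L,
        n_te_insertions = 150L, n_hotspots = 1L, hotspot_fraction = 0.3,
        n_nahr_events = 30L))
    }
    cache
  }
})

# exhaustive best-chain search: DFS over all anchors obeying the chain
# constraints, in both orientations; independent of the implementation's DP
oracle_best_chain <- function(anc, params) {
  one_orient <- function(ib) {
    n <- nrow(anc)
    best <- -Inf
    extend <- function(last, score) {
      best <<- max(best, score)
      for (j in seq_len(n)) {
        da <- anc$index_a[j] - anc$index_a[last]
        db <- ib[j] - ib[last]
        if (da > 0 && da <= params$max_gaps &&
            db > 0 && db <= params$max_gaps) {
          extend(j, score + params$match_score +
                   params$gap_penalty * (da - 1 + db - 1))
        }
      }
    }
    for (s in seq_len(n)) extend(s, params$match_score)
    best
  }
  max(one_orient(anc$index_b), one_orient(-anc$index_b))
}

# independent NG86 oracle: recomputes fractional sites and
# pathway-averaged differences from first principles (no shared helpers)
oracle_ng86 <- function(codons_a, codons_b) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) for (b in bases) {
      if (b == substr(cod, p, p)) next
      mut <- cod; substr(mut, p, p) <- b
      if (gc[[mut]] == gc[[cod]]) s <- s + 1 / 3
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  }
  diffs <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    walk <- function(ord, skip_stop) {
      cur <- a; s <- 0; n <- 0
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
        if (skip_stop && gc[[nxt]] == "*") return(NULL)
        if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    res <- Filter(Negate(is.null), lapply(perms(pos), walk, skip_stop = TRUE))
    if (!length(res)) res <- lapply(perms(pos), walk, skip_stop = FALSE)
    colMeans(do.call(rbind, res))
  }
  S <- (sum(vapply(codons_a, syn_sites, 0)) +
        sum(vapply(codons_b, syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  d <- rowSums(vapply(seq_along(codons_a),
                      function(i) diffs(codons_a[i], codons_b[i]),
                      numeric(2)))
  ps <- if (S > 0) d[1] / S else 0
  pn <- if (N > 0) d[2] / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = d[1], nd = d[2], Ks = jc(ps), Ka = jc(pn))
}
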