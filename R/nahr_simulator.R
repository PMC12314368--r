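# Forward simulator of a haplotype pair diverging by transposon-mediated
# unequal crossing over (NAHR).
#
# The genome is a list of scaffolds; a scaffold is an ordered table of gene
# units (CDS + upstream intergenic spacer, with transposon copies recorded
# inside spacers). Recurrent unequal crossover events duplicate a
# TE-bounded tract of units in one haplotype and delete the homologous
# loci in the other, so nSR-like tracts of tandem-expanded, order-scrambled
# gene copies accumulate inside designated hotspot regions. Sequences then
# diverge under codon-aware substitution at background rates (orthologs)
# or elevated rates (event-affected copies), and expression profiles are
# shared between conserved orthologs but drawn independently for copies.

TE_FAMILY_CLASSES <- c(Copia = "LTR", Gypsy = "LTR", BEL = "LTR",
                       L1 = "LINE", `Sola-3` = "DNA", Maverick = "DNA",
                       hAT = "DNA")

#' Simulator configuration
#'
#' Defaults describe the validation world used throughout the test suite:
#' two ~4 Mb scaffolds of 1,000 genes each, three NAHR hotspots together
#' covering 30% of the gene space (about 800 kb each, placed away from
#' scaffold ends), 150 unequal-crossover events (50 per hotspot), and
#' substitution rates chosen so ortholog pairs realize Ks about 0.02 /
#' Ka about 0.008 while event-affected copies realize Ks about 0.3 /
#' Ka about 0.1 (rates are per branch; pair divergence doubles them).
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_scaffolds,genes_per_scaffold Genome shape.
#' @param gene_len Range of CDS length in bp (multiples of 3, includes
#'   start and stop codon).
#' @param intergenic_len Range of intergenic spacer length in bp.
#' @param n_te_insertions Transposon copies inserted genome-wide.
#' @param hotspot_bias Probability a TE lands inside a hotspot.
#' @param n_hotspots,hotspot_fraction Number of NAHR-eligible tracts and
#'   the fraction of the gene space they cover.
#' @param n_nahr_events Total unequal-crossover events (spread round-robin
#'   over hotspots).
#' @param tract_gene_count Range of genes per crossover tract.
#' @param syn_rate,nonsyn_rate Background synonymous / nonsynonymous
#'   substitutions per site per branch.
#' @param dup_syn_rate,dup_nonsyn_rate Elevated per-branch rates for
#'   event-affected genes; must be >= the background rates.
#' @param expression_noise_sd SD of the log-normal noise around the shared
#'   latent profile of conserved ortholog pairs.
#' @param stages Developmental stage labels of the expression matrix.
#' @param telomere_copies TTAGGG copies placed at each scaffold end.
#' @param gap_len,max_gaps_per_scaffold Assembly-gap emulation (N runs).
#' @param species Species label written into emitted files.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L,
                       genes_per_scaffold = 1000L,
                       gene_len = c(240L, 720L),
                       intergenic_len = c(2000L, 5000L),
                       n_te_insertions = 500L,
                       hotspot_bias = 0.85,
                       n_hotspots = 3L,
                       hotspot_fraction = 0.30,
                       n_nahr_events = 150L,
                       tract_gene_count = c(3L, 15L),
                       syn_rate = 0.01,
                       nonsyn_rate = 0.004,
                       dup_syn_rate = 0.15,
                       dup_nonsyn_rate = 0.05,
                       expression_noise_sd = 0.25,
                       stages = c("egg", "donut", "prawnchip", "preplanula",
                                  "planula", "polyp", "adult"),
                       telomere_copies = 50L,
                       gap_len = 100L,
                       max_gaps_per_scaffold = 12L,
                       species = "simsp") {
  stopifnot(syn_rate >= 0, nonsyn_rate >= 0,
            dup_syn_rate >= syn_rate, dup_nonsyn_rate >= nonsyn_rate,
            hotspot_fraction >= 0, hotspot_fraction < 0.8,
            length(stages) >= 3L)
  structure(as.list(environment()), class = "sim_config")
}

#' Target pair-level divergence implied by a simulator configuration
#'
#' Rates are per branch; an ortholog/paralog pair accumulates both
#' branches, so the expected NG86 estimate is twice the configured rate.
#'
#' @param config A [sim_config()].
#' @return List with `ks_background`, `ka_background`, `ks_dup`, `ka_dup`.
#' @export
kaks_targets <- function(config) {
  list(ks_background = 2 * config$syn_rate,
       ka_background = 2 * config$nonsyn_rate,
       ks_dup = 2 * config$dup_syn_rate,
       ka_dup = 2 * config$dup_nonsyn_rate)
}

# --- codon lookup tables (built once at load) -------------------------------

SENSE_CODONS <- names(GENCODE)[GENCODE != "*"]

build_codon_tables <- function() {
  syn <- list(); nonsyn <- list(); ssites <- numeric(length(SENSE_CODONS))
  names(ssites) <- SENSE_CODONS
  for (cod in SENSE_CODONS) {
    aa <- GENCODE[[cod]]
    s <- character(0); n <- character(0); cnt <- 0
    for (pos in 1:3) for (b in BASES) {
      if (b == substr(cod, pos, pos)) next
      mut <- cod
      substr(mut, pos, pos) <- b
      if (GENCODE[[mut]] == aa) { s <- c(s, mut); cnt <- cnt + 1 }
      else if (GENCODE[[mut]] != "*") n <- c(n, mut)
    }
    syn[[cod]] <- s
    nonsyn[[cod]] <- n
    ssites[cod] <- cnt / 3
  }
  list(syn = syn, nonsyn = nonsyn, ssites = ssites)
}
CODON_TABLES <- build_codon_tables()

random_cds <- function(n_internal) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_internal, replace = TRUE), collapse = ""),
         "TAA")
}

#' Simulate the ancestral genome
#'
#' Non-overlapping gene units (random sense-codon CDS framed by start and
#' stop) separated by intergenic spacers, with hotspot tracts reserved in
#' the inner region of each scaffold.
#'
#' @param config A [sim_config()]. Uses the current RNG state; seed it (or
#'   call via [simulate_nahr_dataset()]) for reproducibility.
#' @return List with `scaffolds` (named list of unit tables), `hotspots`
#'   (`scaffold`, `rank_start`, `rank_end`) and the `config`.
#' @export
simulate_ancestor <- function(config = sim_config()) {
  scaffolds <- list()
  for (si in seq_len(config$n_scaffolds)) {
    sc <- sprintf("s%02d", si)
    n <- config$genes_per_scaffold
    n_int <- pmax(1L, (sample(config$gene_len[1L]:config$gene_len[2L], n,
                              replace = TRUE) %/% 3L) - 2L)
    units <- data.table::data.table(
      gene_id = sprintf("%s_g%04d", sc, seq_len(n)),
      anc_id = sprintf("%s_g%04d", sc, seq_len(n)),
      anc_rank = seq_len(n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      cds = vapply(n_int, random_cds, ""),
      spacer_len = sample(config$intergenic_len[1L]:config$intergenic_len[2L],
                          n, replace = TRUE),
      is_dup = FALSE
    )
    units[, tes := vector("list", .N)]
    scaffolds[[sc]] <- units
  }
  # hotspots: equal gene spans, round-robin over scaffolds, inner placement
  n_total <- config$n_scaffolds * config$genes_per_scaffold
  hs_genes <- max(2L, as.integer(floor(config$hotspot_fraction * n_total /
                                       max(1L, config$n_hotspots))))
  hs <- list()
  per_scaffold <- split(seq_len(config$n_hotspots),
                        rep(seq_len(config$n_scaffolds),
                            length.out = config$n_hotspots))
  for (si in seq_along(per_scaffold)) {
    k <- length(per_scaffold[[si]])
    if (k == 0L) next
    n <- config$genes_per_scaffold
    inner_lo <- as.integer(0.12 * n)
    inner_hi <- as.integer(0.88 * n)
    # evenly spaced starts inside the inner region
    slots <- as.integer(seq(inner_lo, inner_hi - hs_genes, length.out = k))
    for (st in slots) {
      hs[[length(hs) + 1L]] <- data.table::data.table(
        scaffold = sprintf("s%02d", si),
        rank_start = st, rank_end = min(st + hs_genes - 1L, n))
    }
  }
  list(scaffolds = scaffolds,
       hotspots = data.table::rbindlist(hs),
       config = config)
}

#' Insert transposon copies into intergenic spacers
#'
#' Copies of named synthetic families are dropped into the spacer upstream
#' of randomly chosen gene units, biased into hotspot tracts with
#' probability `hotspot_bias`. Coding sequence is never touched.
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param config The [sim_config()].
#' @return The ancestor with TE annotations attached.
#' @export
insert_transposons <- function(ancestor, config = ancestor$config) {
  if (config$n_te_insertions == 0L) return(ancestor)
  hs <- ancestor$hotspots
  all_slots <- data.table::rbindlist(lapply(names(ancestor$scaffolds), function(sc) {
    u <- ancestor$scaffolds[[sc]]
    hsub <- hs[scaffold == sc]
    in_hs <- rep(FALSE, nrow(u))
    for (r in seq_len(nrow(hsub))) {
      in_hs <- in_hs | (u$anc_rank >= hsub$rank_start[r] &
                        u$anc_rank <= hsub$rank_end[r])
    }
    data.table::data.table(scaffold = sc, idx = seq_len(nrow(u)), in_hs = in_hs)
  }))
  fams <- names(TE_FAMILY_CLASSES)
  for (k in seq_len(config$n_te_insertions)) {
    pool <- if (stats::runif(1) < config$hotspot_bias) all_slots[in_hs == TRUE]
            else all_slots
    if (nrow(pool) == 0L) pool <- all_slots
    row <- pool[sample(.N, 1L)]
    fam <- sample(fams, 1L)
    u <- ancestor$scaffolds[[row$scaffold]]
    u$tes[[row$idx]] <- c(u$tes[[row$idx]], fam)
    ancestor$scaffolds[[row$scaffold]] <- u
  }
  ancestor
}

#' Apply one unequal crossing-over event to a haplotype pair
#'
#' `site_pair` names two spacer-borne copies of one TE family on the
#' gaining haplotype's scaffold (unit indices `left` < `right`); the tract
#' of units `[left, right)` between them is tandemly duplicated in the
#' gaining haplotype (new copies get a `.d<event>` suffix) and the
#' homologous loci (one unit per distinct ancestral gene of the tract) are
#' deleted from the other haplotype. Both the originals and the copies are
#' marked event-affected (`is_dup`). A zero-length tract is a no-op.
#'
#' @param genomes List of two genomes (named `A`, `B`), each a list of
#'   scaffold unit tables.
#' @param scaffold Scaffold name.
#' @param site_pair List with `left`, `right` (unit indices on the gaining
#'   haplotype) and `family` (must be present in both spacers).
#' @param gain_hap `"A"` or `"B"`.
#' @param event_id Integer used to suffix new gene copies.
#' @return List with modified `genomes` and a one-row `event` table
#'   (`NULL` for a no-op).
#' @export
apply_unequal_crossover <- function(genomes, scaffold, site_pair, gain_hap,
                                    event_id = 1L) {
  lose_hap <- setdiff(c("A", "B"), gain_hap)
  g <- genomes[[gain_hap]][[scaffold]]
  i <- site_pair$left; j <- site_pair$right
  stopifnot(i >= 1L, j <= nrow(g) + 1L)
  if (j <= i) return(list(genomes = genomes, event = NULL))
  fam <- site_pair$family
  for (slot in c(i, j)) {
    if (slot <= nrow(g) && !fam %in% g$tes[[slot]]) {
      stop(sprintf("TE family %s absent from spacer of unit %d", fam, slot),
           call. = FALSE)
    }
  }
  tract <- g[i:(j - 1L)]
  copies <- data.table::copy(tract)
  copies[, gene_id := paste0(gene_id, ".d", event_id)]
  copies[, is_dup := TRUE]
  g[i:(j - 1L), is_dup := TRUE]
  new_g <- rbind(g[seq_len(j - 1L)], copies,
                 if (j <= nrow(g)) g[j:nrow(g)] else NULL)
  genomes[[gain_hap]][[scaffold]] <- new_g
  # delete one homologous locus per distinct ancestral gene in the loser
  o <- genomes[[lose_hap]][[scaffold]]
  lost <- integer(0)
  for (aid in unique(tract$anc_id)) {
    hit <- which(o$anc_id == aid)
    if (length(hit)) lost <- c(lost, hit[1L])
  }
  if (length(lost)) {
    o <- o[-lost]
    genomes[[lose_hap]][[scaffold]] <- o
  }
  ev <- data.table::data.table(
    event = event_id, type = "nahr", scaffold = scaffold,
    gain_hap = gain_hap, family = fam,
    tract_left = i, tract_genes = nrow(tract),
    n_gained = nrow(copies), n_lost = length(lost),
    anc_ids = paste(unique(tract$anc_id), collapse = ","),
    copy_ids = paste(copies$gene_id, collapse = ",")
  )
  list(genomes = genomes, event = ev)
}

# sample an eligible TE site pair on one haplotype scaffold within a
# hotspot; NULL when none exists. The left breakpoint is aimed at a
# uniformly drawn hotspot position (nearest TE-bearing unit), so events
# spread over the whole tract instead of piling onto TE-dense subregions
# (duplicated tracts still attract recurrences through their extra TE
# copies when drawn).
sample_site_pair <- function(units, hotspot, tract_range, max_tries = 30L) {
  in_hs <- which(units$anc_rank >= hotspot$rank_start &
                 units$anc_rank <= hotspot$rank_end)
  te_idx <- in_hs[vapply(units$tes[in_hs], length, 0L) > 0L]
  if (length(te_idx) < 2L) return(NULL)
  for (t in seq_len(max_tries)) {
    target <- sample(hotspot$rank_start:hotspot$rank_end, 1L)
    i <- te_idx[which.min(abs(units$anc_rank[te_idx] - target))]
    fams <- units$tes[[i]]
    partners <- te_idx[te_idx > i &
                       te_idx - i >= tract_range[1L] &
                       te_idx - i <= tract_range[2L]]
    partners <- partners[vapply(units$tes[partners],
                                function(f) any(f %in% fams), NA)]
    if (length(partners)) {
      j <- if (length(partners) == 1L) partners else sample(partners, 1L)
      fam <- intersect(units$tes[[i]], units$tes[[j]])[1L]
      return(list(left = i, right = j, family = fam))
    }
  }
  NULL
}

#' Apply recurrent NAHR events to a haplotype pair
#'
#' Events are distributed round-robin over the hotspots (so each receives
#' its share), the gaining haplotype alternates at random, and because
#' duplicated tracts carry their TE copies along, previously hit tracts
#' offer ever more crossover substrates — the recurrence that concentrates
#' duplications in hotspots. Events with no eligible TE site pair are
#' skipped and logged.
#'
#' @param genomes List of genomes `A` and `B` (initially identical copies
#'   of the TE-carrying ancestor).
#' @param hotspots Hotspot table from [simulate_ancestor()].
#' @param config The [sim_config()].
#' @return List with `genomes` and `events` (one row per applied or
#'   skipped event).
#' @export
apply_recurrent_nahr <- function(genomes, hotspots, config) {
  events <- list()
  empty_log <- data.table::data.table(
    event = integer(), type = character(), scaffold = character(),
    gain_hap = character(), family = character(), tract_left = integer(),
    tract_genes = integer(), n_gained = integer(), n_lost = integer(),
    anc_ids = character(), copy_ids = character())
  n_hs <- nrow(hotspots)
  if (config$n_nahr_events == 0L || n_hs == 0L) {
    return(list(genomes = genomes, events = empty_log))
  }
  for (e in seq_len(config$n_nahr_events)) {
    h <- hotspots[((e - 1L) %% n_hs) + 1L]
    gain <- sample(c("A", "B"), 1L)
    units <- genomes[[gain]][[h$scaffold]]
    sp <- sample_site_pair(units, h, config$tract_gene_count)
    if (is.null(sp)) {
      events[[length(events) + 1L]] <- data.table::data.table(
        event = e, type = "skipped", scaffold = h$scaffold, gain_hap = gain,
        family = NA_character_, tract_left = NA_integer_,
        tract_genes = 0L, n_gained = 0L, n_lost = 0L,
        anc_ids = "", copy_ids = "")
      next
    }
    res <- apply_unequal_crossover(genomes, h$scaffold, sp, gain, e)
    genomes <- res$genomes
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
  }
  list(genomes = genomes,
       events = if (length(events)) data.table::rbindlist(events)
                else empty_log)
}

# mutate one CDS in place: Poisson numbers of synonymous and nonsynonymous
# single-base codon changes at the given per-site rates (internal codons
# only; start/stop untouched; stops never created)
mutate_cds <- function(cds, syn_rate, nonsyn_rate) {
  n_cod <- nchar(cds) %/% 3L
  if (n_cod <= 2L) return(cds)
  # internal codons 2..(n_cod-1); start and stop stay intact
  idx <- seq(2L, n_cod - 1L)
  codons <- substring(cds, (idx - 1L) * 3L + 1L, idx * 3L)
  s_sites <- CODON_TABLES$ssites[codons]
  n_sites <- 3 - s_sites
  n_syn <- stats::rpois(1L, syn_rate * sum(s_sites))
  n_non <- stats::rpois(1L, nonsyn_rate * sum(n_sites))
  apply_events <- function(codons, k, weights_of, choices_of) {
    w <- weights_of(codons)
    for (t in seq_len(k)) {
      if (all(w <= 0)) break
      i <- sample.int(length(codons), 1L, prob = w)
      opts <- choices_of(codons[i])
      if (length(opts) == 0L) next
      codons[i] <- if (length(opts) == 1L) opts else sample(opts, 1L)
      w[i] <- weights_of(codons[i])
    }
    codons
  }
  codons <- apply_events(codons, n_syn,
                         function(cc) CODON_TABLES$ssites[cc],
                         function(c1) CODON_TABLES$syn[[c1]])
  codons <- apply_events(codons, n_non,
                         function(cc) 3 - CODON_TABLES$ssites[cc],
                         function(c1) CODON_TABLES$nonsyn[[c1]])
  paste0(substr(cds, 1L, 3L), paste(codons, collapse = ""),
         substr(cds, 3L * n_cod - 2L, 3L * n_cod))
}

#' Diverge the two haplotypes' coding sequences
#'
#' Codon-aware substitution: each gene accumulates Poisson numbers of
#' synonymous and nonsynonymous single-base changes proportional to its
#' NG86 site counts, at background rates for untouched orthologs and
#' elevated rates for event-affected (`is_dup`) genes. Stops are never
#' created and start/stop codons are left intact, so realized NG86
#' estimates of ortholog pairs recover about twice the per-branch rate
#' (see [kaks_targets()]).
#'
#' @param genomes List of genomes after [apply_recurrent_nahr()].
#' @param config The [sim_config()].
#' @return The genomes with mutated CDS.
#' @export
mutate_sequences <- function(genomes, config) {
  for (hap in names(genomes)) {
    for (sc in names(genomes[[hap]])) {
      u <- genomes[[hap]][[sc]]
      for (r in seq_len(nrow(u))) {
        if (u$is_dup[r]) {
          u$cds[r] <- mutate_cds(u$cds[r], config$dup_syn_rate,
                                 config$dup_nonsyn_rate)
        } else {
          u$cds[r] <- mutate_cds(u$cds[r], config$syn_rate,
                                 config$nonsyn_rate)
        }
      }
      genomes[[hap]][[sc]] <- u
    }
  }
  genomes
}
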