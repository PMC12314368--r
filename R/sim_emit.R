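# Layout, ground truth, expression and dataset emission for the NAHR
# simulator. Coordinates materialize only here: unit tables are ordered
# gene/spacer runs; the layout adds telomere arrays, assembly gaps and TE
# positions, then everything is written in standard formats.

TE_LEN <- 200L

# per-scaffold physical layout from a unit table; gap_slots = unit indices
# whose spacer carries an N run
layout_scaffold <- function(units, config, gap_slots = integer(0)) {
  tel <- config$telomere_copies * 6L
  n <- nrow(units)
  genes <- vector("list", n)
  tes <- list()
  gaps <- list()
  pos <- tel
  for (r in seq_len(n)) {
    has_gap <- r %in% gap_slots
    spacer_total <- units$spacer_len[r] + if (has_gap) config$gap_len else 0L
    if (has_gap) {
      gaps[[length(gaps) + 1L]] <- data.table::data.table(
        start = pos + 200L, end = pos + 200L + config$gap_len)
    }
    fams <- units$tes[[r]]
    m <- length(fams)
    if (m > 0L) {
      lo <- pos + (if (has_gap) 200L + config$gap_len else 100L) + 50L
      hi <- pos + spacer_total - TE_LEN - 50L
      offs <- if (m == 1L) as.integer((lo + hi) / 2L)
              else as.integer(seq(lo, hi, length.out = m))
      tes[[length(tes) + 1L]] <- data.table::data.table(
        family = fams, start = offs, end = offs + TE_LEN)
    }
    gstart <- pos + spacer_total
    gend <- gstart + nchar(units$cds[r])
    genes[[r]] <- data.table::data.table(
      gene_id = units$gene_id[r], start = gstart, end = gend,
      strand = units$strand[r], anc_id = units$anc_id[r],
      anc_rank = units$anc_rank[r], is_dup = units$is_dup[r])
    pos <- gend
  }
  list(genes = data.table::rbindlist(genes),
       tes = if (length(tes)) data.table::rbindlist(tes)
             else data.table::data.table(family = character(),
                                         start = integer(), end = integer()),
       gaps = if (length(gaps)) data.table::rbindlist(gaps)
              else data.table::data.table(start = integer(), end = integer()),
       length = pos + tel)
}

sim_layouts <- function(genomes, config) {
  out <- list()
  for (hap in names(genomes)) {
    for (sc in names(genomes[[hap]])) {
      u <- genomes[[hap]][[sc]]
      n_gaps <- sample(seq_len(config$max_gaps_per_scaffold), 1L)
      gap_slots <- sort(sample(seq_len(nrow(u)), min(n_gaps, nrow(u))))
      out[[paste(hap, sc, sep = "_")]] <- c(
        layout_scaffold(u, config, gap_slots),
        list(hap = hap, base_scaffold = sc))
    }
  }
  out
}

#' Gene table of one simulated haplotype, in pipeline coordinates
#'
#' @param sim A `nahr_sim` object from [simulate_nahr_dataset()].
#' @param hap `"A"` or `"B"`.
#' @return `data.table` with `gene_id`, `scaffold_id` (hap-prefixed),
#'   `start`, `end`, `strand`, `anc_id`, `is_dup`.
#' @export
sim_gene_table <- function(sim, hap) {
  out <- list()
  for (nm in names(sim$layouts)) {
    L <- sim$layouts[[nm]]
    if (L$hap != hap) next
    g <- data.table::copy(L$genes)
    g[, scaffold_id := nm]
    out[[nm]] <- g
  }
  data.table::rbindlist(out)[, .(gene_id, scaffold_id, start, end, strand,
                                 anc_id, is_dup)]
}

#' Scaffold lengths of a simulated dataset
#' @param sim A `nahr_sim` object.
#' @return Named numeric vector over hap-prefixed scaffold names.
#' @export
sim_scaffold_lengths <- function(sim) {
  setNames(vapply(sim$layouts, function(L) as.numeric(L$length), 0),
           names(sim$layouts))
}

# ground-truth nSR tracts: one tract per (haplotype, hotspot) = the full
# extent of event-affected genes whose lineage belongs to that hotspot
# (the "event extent"); hotspots without affected genes yield no tract
sim_truth_tracts <- function(layouts, hotspots, config) {
  out <- list()
  for (nm in names(layouts)) {
    L <- layouts[[nm]]
    g <- L$genes
    hsub <- hotspots[scaffold == L$base_scaffold]
    for (r in seq_len(nrow(hsub))) {
      d <- g[is_dup == TRUE & anc_rank >= hsub$rank_start[r] &
               anc_rank <= hsub$rank_end[r]]
      if (nrow(d) < 2L) next
      out[[length(out) + 1L]] <- data.table::data.table(
        scaffold_id = nm, start = min(d$start), end = max(d$end))
    }
  }
  if (!length(out)) {
    return(data.table::data.table(scaffold_id = character(),
                                  start = numeric(), end = numeric()))
  }
  tr <- data.table::rbindlist(out)
  data.table::setorder(tr, scaffold_id, start)
  tr
}

#' Simulate developmental expression matrices for both haplotypes
#'
#' Conserved ortholog pairs (same ancestral gene, untouched by NAHR) share
#' a latent log-normal stage profile plus independent multiplicative noise
#' of SD `expression_noise_sd`; event-affected copies draw independent
#' profiles, so their expected pair correlation is ~0.
#'
#' @param genomes Simulator genomes (after events).
#' @param config The [sim_config()].
#' @return List of two matrices (`A`, `B`), genes x stages.
#' @export
simulate_expression <- function(genomes, config) {
  anc_ids <- sort(unique(unlist(lapply(genomes, function(h)
    lapply(h, function(u) u$anc_id)))))
  ns <- length(config$stages)
  latent <- matrix(exp(stats::rnorm(length(anc_ids) * ns, log(30), 1)),
                   nrow = length(anc_ids), ncol = ns,
                   dimnames = list(anc_ids, config$stages))
  out <- list()
  for (hap in names(genomes)) {
    ids <- character(0); rows <- list()
    for (sc in names(genomes[[hap]])) {
      u <- genomes[[hap]][[sc]]
      for (r in seq_len(nrow(u))) {
        prof <- if (u$is_dup[r]) {
          exp(stats::rnorm(ns, log(30), 1))
        } else {
          latent[u$anc_id[r], ] * exp(stats::rnorm(ns, 0,
                                                   config$expression_noise_sd))
        }
        rows[[length(rows) + 1L]] <- prof
        ids <- c(ids, u$gene_id[r])
      }
    }
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    colnames(m) <- config$stages
    out[[hap]] <- m
  }
  out
}

# all-vs-all hit table derived from true homology: every pair of genes
# sharing an ancestral lineage gets a reciprocal hit whose identity is the
# realized CDS identity
sim_hits <- function(genomes) {
  all_genes <- data.table::rbindlist(lapply(names(genomes), function(hap) {
    data.table::rbindlist(lapply(genomes[[hap]], function(u)
      u[, .(gene_id, anc_id, cds)]))
  }))
  rows <- list()
  for (aid in unique(all_genes$anc_id)) {
    grp <- all_genes[anc_id == aid]
    n <- nrow(grp)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        a <- grp$cds[i]; b <- grp$cds[j]
        len <- min(nchar(a), nchar(b))
        ident <- 100 * sum(utf8ToInt(substr(a, 1L, len)) ==
                           utf8ToInt(substr(b, 1L, len))) / len
        ev <- 10^(-pmin(180, ident * 1.6))
        bs <- round(2 * len * ident / 100, 1)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          query_id = c(grp$gene_id[i], grp$gene_id[j]),
          subject_id = c(grp$gene_id[j], grp$gene_id[i]),
          pct_identity = round(ident, 2), aln_length = len,
          mismatches = round(len * (1 - ident / 100)), gap_opens = 0L,
          q_start = 1L, q_end = len, s_start = 1L, s_end = len,
          e_value = ev, bit_score = bs)
      }
    }
  }
  data.table::rbindlist(rows)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# assemble one scaffold's DNA from its units and layout
assemble_scaffold <- function(units, layout, config, te_seqs) {
  tel <- paste(rep("TTAGGG", config$telomere_copies), collapse = "")
  pieces <- list(tel)
  pos <- nchar(tel)
  te_cursor <- 1L
  tes <- layout$tes
  gaps <- layout$gaps
  for (r in seq_len(nrow(units))) {
    gstart <- layout$genes$start[r]
    spacer_total <- gstart - pos
    sp <- random_dna(spacer_total)
    # overwrite gap run
    if (nrow(gaps)) {
      hit <- which(gaps$start >= pos & gaps$end <= gstart)
      for (k in hit) {
        substr(sp, gaps$start[k] - pos + 1L, gaps$end[k] - pos) <-
          paste(rep("N", gaps$end[k] - gaps$start[k]), collapse = "")
      }
    }
    # overwrite TE copies
    if (nrow(tes)) {
      hit <- which(tes$start >= pos & tes$end <= gstart)
      for (k in hit) {
        substr(sp, tes$start[k] - pos + 1L, tes$end[k] - pos) <-
          te_seqs[[tes$family[k]]]
      }
    }
    cds <- units$cds[r]
    if (units$strand[r] == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    pieces[[length(pieces) + 1L]] <- sp
    pieces[[length(pieces) + 1L]] <- cds
    pos <- layout$genes$end[r]
  }
  pieces[[length(pieces) + 1L]] <- tel
  paste(unlist(pieces), collapse = "")
}

write_sim_gff3 <- function(genes, species, hap, path) {
  lines <- c("##gff-version 3")
  for (r in seq_len(nrow(genes))) {
    g <- genes[r]
    lines <- c(lines,
      sprintf("%s\tnsrscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;species=%s;haplotype=%s",
              g$scaffold_id, g$start + 1L, g$end, g$strand, g$gene_id,
              species, hap),
      sprintf("%s\tnsrscan_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$scaffold_id, g$start + 1L, g$end, g$strand, g$gene_id,
              g$gene_id),
      sprintf("%s\tnsrscan_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.t1.cds;Parent=%s.t1",
              g$scaffold_id, g$start + 1L, g$end, g$strand, g$gene_id,
              g$gene_id))
  }
  writeLines(lines, path)
}

write_sim_repeats <- function(te_table, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query    matching repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat  class/family   begin end (left) ID",
    "")
  lines <- header
  for (r in seq_len(nrow(te_table))) {
    t <- te_table[r]
    cls <- TE_FAMILY_CLASSES[[t$family]]
    lines <- c(lines, sprintf(
      "%5d %6.1f %4.1f %4.1f  %s %d %d (0) + %s %s/%s 1 %d (0) %d",
      1000L, 1.0, 0.0, 0.0, t$scaffold_id, t$start + 1L, t$end, t$family,
      cls, t$family, t$end - t$start, r))
  }
  writeLines(lines, path)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits, per haplotype: GFF3 gene models, genome / CDS / protein FASTA
#' and an expression TSV; plus a single all-vs-all hit table (BLAST
#' outfmt 6), a RepeatMasker-style `.out` TE table, an orthoMCL-style
#' orthogroup file, the ground-truth nSR tracts as BED, the event log as
#' TSV and the scaffold lengths. Every file parses back through the
#' package's readers.
#'
#' Random intergenic DNA is drawn from a seed derived from the simulation
#' seed, so the emitted bytes depend only on the configuration.
#'
#' @param sim A `nahr_sim` object from [simulate_nahr_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
emit_dataset <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  set.seed(sim$config$seed + 1L)
  te_seqs <- lapply(setNames(nm = names(TE_FAMILY_CLASSES)),
                    function(f) random_dna(TE_LEN))
  all_tes <- list()
  for (hap in c("A", "B")) {
    genes <- sim_gene_table(sim, hap)
    write_sim_gff3(genes, sim$config$species, hap,
                   file.path(outdir, sprintf("hap%s.gff3", hap)))
    cds <- character(0); prots <- character(0); gseq <- character(0)
    for (nm in names(sim$layouts)) {
      L <- sim$layouts[[nm]]
      if (L$hap != hap) next
      u <- sim$genomes[[hap]][[L$base_scaffold]]
      gseq[nm] <- assemble_scaffold(u, L, sim$config, te_seqs)
      cds[u$gene_id] <- u$cds
      if (nrow(L$tes)) {
        all_tes[[nm]] <- data.table::data.table(scaffold_id = nm,
                                                family = L$tes$family,
                                                start = L$tes$start,
                                                end = L$tes$end)
      }
    }
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(gseq),
                                file.path(outdir, sprintf("hap%s_genome.fa", hap)))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds),
                                file.path(outdir, sprintf("hap%s_cds.fa", hap)))
    prot <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAStringSet(cds))))
    names(prot) <- names(cds)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                                file.path(outdir, sprintf("hap%s_protein.fa", hap)))
    write_expression_tsv(sim$expression[[hap]],
                         file.path(outdir, sprintf("expression_hap%s.tsv", hap)))
  }
  hits <- sim_hits(sim$genomes)
  data.table::fwrite(hits, file.path(outdir, "hits.tsv"), sep = "\t",
                     col.names = FALSE)
  write_sim_repeats(data.table::rbindlist(all_tes),
                    file.path(outdir, "repeats.out"))
  # orthogroups: one group per ancestral lineage
  mem <- data.table::rbindlist(lapply(c("A", "B"), function(hap) {
    g <- sim_gene_table(sim, hap)
    data.table::data.table(species = sim$config$species, haplotype = hap,
                           gene_id = g$gene_id, anc = g$anc_id)
  }))
  mem[, group_id := sprintf("OG%05d", as.integer(factor(anc)))]
  write_orthogroups(mem[, .(group_id, species, haplotype, gene_id)],
                    file.path(outdir, "orthogroups.txt"))
  write_bed(sim$truth, file.path(outdir, "truth_nsr.bed"))
  data.table::fwrite(sim$events, file.path(outdir, "events.tsv"), sep = "\t")
  lens <- sim_scaffold_lengths(sim)
  data.table::fwrite(data.table::data.table(scaffold_id = names(lens),
                                            length = as.integer(lens)),
                     file.path(outdir, "scaffold_lengths.tsv"), sep = "\t")
  invisible(outdir)
}

#' Run the full NAHR forward simulation
#'
#' Seeds the RNG from `config$seed`, builds the ancestor, inserts
#' transposons, copies the genome into haplotypes A and B, applies
#' recurrent unequal crossover, diverges the sequences, lays out physical
#' coordinates (telomere arrays at both ends, a few assembly gaps), and
#' derives ground-truth nSR tracts and expression matrices. One seed gives
#' a byte-identical dataset.
#'
#' @param config A [sim_config()].
#' @return Object of class `nahr_sim`: `config`, `hotspots`, `genomes`,
#'   `events`, `layouts`, `truth` (tract BED table), `expression`.
#' @export
simulate_nahr_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  anc <- simulate_ancestor(config)
  anc <- insert_transposons(anc, config)
  genomes <- list(A = lapply(anc$scaffolds, data.table::copy),
                  B = lapply(anc$scaffolds, data.table::copy))
  # gene IDs must be unique across the whole dataset: prefix by haplotype
  # (ancestral lineage IDs stay shared)
  for (hap in names(genomes)) {
    for (sc in names(genomes[[hap]])) {
      genomes[[hap]][[sc]][, gene_id := paste0(hap, "_", gene_id)]
    }
  }
  nahr <- apply_recurrent_nahr(genomes, anc$hotspots, config)
  genomes <- mutate_sequences(nahr$genomes, config)
  layouts <- sim_layouts(genomes, config)
  truth <- sim_truth_tracts(layouts, anc$hotspots, config)
  expression <- simulate_expression(genomes, config)
  structure(list(config = config, hotspots = anc$hotspots,
                 genomes = genomes, events = nahr$events,
                 layouts = layouts, truth = truth,
                 expression = expression),
            class = "nahr_sim")
}
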