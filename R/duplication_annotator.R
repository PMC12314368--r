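# Tandem duplicate (TDG) and species-specific tandem duplicate (SSTDG)
# classification from gene order and orthogroup membership.

#' Lightweight orthogroup clustering fallback
#'
#' Stand-in for a full orthoMCL run: connected components of the
#' reciprocal-best-hit (RBH) graph between genomes, augmented by
#' within-genome hits passing the e-value cutoff. A genome is one
#' (species, haplotype) combination. Genes without any edge become
#' singleton groups.
#'
#' @param hits Hit table (`query_id`, `subject_id`, `e_value`,
#'   `bit_score`).
#' @param gene_tags Table with `gene_id`, `species`, `haplotype` covering
#'   every gene to cluster.
#' @param e_value_cut Edge threshold (default 1e-5).
#' @return `data.table` with `group_id`, `species`, `haplotype`,
#'   `gene_id` (orthoMCL-style membership).
#' @export
cluster_orthogroups_fallback <- function(hits, gene_tags,
                                         e_value_cut = 1e-5) {
  tags <- data.table::as.data.table(gene_tags)
  assert_cols(tags, c("gene_id", "species", "haplotype"), "gene_tags")
  h <- data.table::as.data.table(hits)
  h <- h[e_value <= e_value_cut & query_id != subject_id]
  h <- h[query_id %in% tags$gene_id & subject_id %in% tags$gene_id]
  genome <- setNames(paste(tags$species, tags$haplotype, sep = "|"),
                     tags$gene_id)
  edges <- NULL
  if (nrow(h) > 0L) {
    h[, `:=`(gq = genome[query_id], gs = genome[subject_id])]
    within <- h[gq == gs, .(a = query_id, b = subject_id)]
    cross <- h[gq != gs]
    if (nrow(cross) > 0L) {
      data.table::setorder(cross, query_id, gs, -bit_score, subject_id)
      best <- cross[!duplicated(paste(query_id, gs))]
      key <- paste(best$query_id, best$subject_id)
      rkey <- paste(best$subject_id, best$query_id)
      rbh <- best[key %in% rkey, .(a = query_id, b = subject_id)]
    } else rbh <- data.table::data.table(a = character(), b = character())
    edges <- rbind(within, rbh)
  }
  # union-find over all tagged genes
  parent <- seq_len(nrow(tags))
  names(parent) <- tags$gene_id
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(edges) && nrow(edges) > 0L) {
    ia <- match(edges$a, tags$gene_id)
    ib <- match(edges$b, tags$gene_id)
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(nrow(tags)), find, 0L)
  gid <- sprintf("OG%05d", as.integer(factor(roots, levels = unique(roots))))
  data.table::data.table(group_id = gid, species = tags$species,
                         haplotype = tags$haplotype, gene_id = tags$gene_id)
}

#' Find tandemly duplicated gene pairs on each scaffold
#'
#' Two genes form a TDG pair when they belong to the same orthogroup and
#' are adjacent in gene order, or separated by exactly one intervening
#' gene of a different orthogroup.
#'
#' @param genes Gene table with `gene_id`, `scaffold_id`, `start`.
#' @param groups Membership table with `gene_id`, `group_id`.
#' @return `data.table` with `gene_a`, `gene_b`, `scaffold_id`,
#'   `group_id`, `intervening` (0 or 1).
#' @export
find_tdg_pairs <- function(genes, groups) {
  g <- data.table::as.data.table(genes)
  assert_cols(g, c("gene_id", "scaffold_id", "start"), "genes")
  gr <- data.table::as.data.table(groups)
  assert_cols(gr, c("gene_id", "group_id"), "groups")
  gmap <- setNames(gr$group_id, gr$gene_id)
  data.table::setorder(g, scaffold_id, start)
  out <- list()
  for (sc in unique(g$scaffold_id)) {
    ids <- g[scaffold_id == sc]$gene_id
    grp <- unname(gmap[ids])
    n <- length(ids)
    if (n < 2L) next
    adj <- which(grp[-n] == grp[-1L] & !is.na(grp[-n]))
    if (length(adj)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        gene_a = ids[adj], gene_b = ids[adj + 1L], scaffold_id = sc,
        group_id = grp[adj], intervening = 0L)
    }
    if (n >= 3L) {
      skip <- which(grp[seq_len(n - 2L)] == grp[-(1:2)] &
                    !is.na(grp[seq_len(n - 2L)]) &
                    (is.na(grp[seq(2L, n - 1L)]) |
                     grp[seq(2L, n - 1L)] != grp[seq_len(n - 2L)]))
      if (length(skip)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          gene_a = ids[skip], gene_b = ids[skip + 2L], scaffold_id = sc,
          group_id = grp[skip], intervening = 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(gene_a = character(), gene_b = character(),
                                  scaffold_id = character(),
                                  group_id = character(),
                                  intervening = integer()))
  }
  data.table::rbindlist(out)
}

#' Call species-specific tandem duplications (SSTDGs)
#'
#' An orthogroup is a species-specific duplication candidate when one
#' species of the pair has exactly one copy in each of its haplotypes and
#' the other exactly two in each haplotype (fixed copy-number difference).
#' It is an SSTDG when, additionally, the two copies of the expanded
#' species form a TDG pair in at least one haplotype.
#'
#' @param membership Orthogroup membership (`group_id`, `species`,
#'   `haplotype`, `gene_id`), e.g. from [read_orthogroups()].
#' @param tdg_pairs TDG pairs from [find_tdg_pairs()].
#' @param species_pair Character vector of the two species labels.
#' @return `data.table` with one row per copy-number candidate group:
#'   `group_id`, `expanded_species`, `gene_a`, `gene_b` (the duplicated
#'   pair of the haplotype where tandem arrangement was found, `NA` when
#'   none), `tandem` (logical). SSTDGs are the `tandem == TRUE` rows.
#' @export
call_sstdg <- function(membership, tdg_pairs, species_pair) {
  stopifnot(length(species_pair) == 2L)
  mem <- data.table::as.data.table(membership)
  assert_cols(mem, c("group_id", "species", "haplotype", "gene_id"),
              "membership")
  mem <- mem[species %in% species_pair]
  tdg_key <- character(0)
  tp <- data.table::as.data.table(tdg_pairs)
  if (nrow(tp)) {
    tdg_key <- c(paste(tp$gene_a, tp$gene_b, sep = "\r"),
                 paste(tp$gene_b, tp$gene_a, sep = "\r"))
  }
  counts <- mem[, .N, by = .(group_id, species, haplotype)]
  out <- list()
  for (gid in unique(mem$group_id)) {
    cg <- counts[group_id == gid]
    per_species <- lapply(species_pair, function(sp) cg[species == sp])
    names(per_species) <- species_pair
    # both haplotypes of each species must be represented with equal counts
    ok_pattern <- function(tbl, k) {
      nrow(tbl) == 2L && all(tbl$N == k) && length(unique(tbl$haplotype)) == 2L
    }
    expanded <- NULL
    if (ok_pattern(per_species[[1L]], 1L) && ok_pattern(per_species[[2L]], 2L)) {
      expanded <- species_pair[2L]
    } else if (ok_pattern(per_species[[1L]], 2L) && ok_pattern(per_species[[2L]], 1L)) {
      expanded <- species_pair[1L]
    }
    if (is.null(expanded)) next
    copies <- mem[group_id == gid & species == expanded]
    tandem <- FALSE; pa <- NA_character_; pb <- NA_character_
    for (hp in unique(copies$haplotype)) {
      two <- copies[haplotype == hp]$gene_id
      if (length(two) == 2L &&
          paste(two[1L], two[2L], sep = "\r") %in% tdg_key) {
        tandem <- TRUE; pa <- two[1L]; pb <- two[2L]
        break
      }
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      group_id = gid, expanded_species = expanded,
      gene_a = pa, gene_b = pb, tandem = tandem)
  }
  if (!length(out)) {
    return(data.table::data.table(group_id = character(),
                                  expanded_species = character(),
                                  gene_a = character(), gene_b = character(),
                                  tandem = logical()))
  }
  data.table::rbindlist(out)
}

#' Fraction of SSTDGs located inside nSRs
#'
#' An SSTDG is "in nSR" when the midpoint of its duplicated pair's span
#' (from the start of the first copy to the end of the second) lies inside
#' an nSR interval.
#'
#' @param sstdg_calls `tandem == TRUE` rows from [call_sstdg()].
#' @param genes Gene table with coordinates for the duplicated copies.
#' @param nsr_intervals Disjoint nSR intervals.
#' @return List with `n_in_nsr`, `n_total`, `pct` (1 decimal).
#' @export
sstdg_nsr_overlap <- function(sstdg_calls, genes, nsr_intervals) {
  calls <- data.table::as.data.table(sstdg_calls)
  g <- data.table::as.data.table(genes)
  if (nrow(calls) == 0L) return(list(n_in_nsr = 0L, n_total = 0L, pct = 0))
  gi <- setNames(seq_len(nrow(g)), g$gene_id)
  spans <- data.table::data.table(
    scaffold_id = g$scaffold_id[gi[calls$gene_a]],
    start = pmin(g$start[gi[calls$gene_a]], g$start[gi[calls$gene_b]]),
    end = pmax(g$end[gi[calls$gene_a]], g$end[gi[calls$gene_b]])
  )
  inn <- classify_gene_region(spans, nsr_intervals) == "nSR"
  list(n_in_nsr = sum(inn), n_total = nrow(calls),
       pct = round(100 * sum(inn) / nrow(calls), 1L))
}

#' Report a fraction the way printed summaries do (one decimal)
#'
#' Utility for in/out-of-region bookkeeping: `100 * k / n` rounded to one
#' decimal place.
#'
#' @param k,n Counts.
#' @return Percentage (numeric scalar).
#' @export
pct_of <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, 1L)
}
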