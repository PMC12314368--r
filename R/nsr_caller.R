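# Sliding-window non-syntenic region (nSR) calling and genome summaries.
#
# A window is non-syntenic when it holds more than 14 genes (>= 15) and
# strictly less than 15% of them are flagged homologous. Windows are
# 500 kb wide with a 100 kb step by default; one extra right-aligned tail
# window keeps chromosome ends evaluable.

#' Classify sliding windows of one scaffold as syntenic / non-syntenic
#'
#' Genes are assigned to windows by midpoint. Windows with at least
#' `min_genes` genes of which strictly less than `max_homolog_frac` are
#' homologous are labelled `non_syntenic`; windows with fewer genes are
#' `syntenic`, except empty windows which are `undetermined`. When the
#' scaffold is shorter than one window, a single whole-scaffold window is
#' emitted (flagged as tail).
#'
#' @param genes Gene table for one scaffold with columns `start`, `end`
#'   and logical `homologous`.
#' @param scaffold_len Scaffold length (bp).
#' @param window,step Window size and step (bp); defaults 500 kb / 100 kb.
#' @param min_genes Minimum gene count for the non-syntenic rule
#'   (default 15, i.e. "more than 14 genes").
#' @param max_homolog_frac Strict upper bound on the homolog fraction
#'   (default 0.15).
#' @param scaffold_id Label for the output.
#' @return `data.table` of window calls: `scaffold_id`, `start`, `end`,
#'   `n_genes`, `n_homologous`, `homolog_fraction`, `label`, `is_tail`.
#' @export
call_windows <- function(genes, scaffold_len, window = 500000L,
                         step = 100000L, min_genes = 15L,
                         max_homolog_frac = 0.15,
                         scaffold_id = "seq") {
  g <- data.table::as.data.table(genes)
  assert_cols(g, c("start", "end", "homologous"), "genes")
  scaffold_len <- as.numeric(scaffold_len)
  if (nrow(g) > 0L && any(g$end > scaffold_len)) {
    stop("gene beyond scaffold end", call. = FALSE)
  }
  if (scaffold_len < window) {
    starts <- 0; ends <- scaffold_len; tails <- TRUE
  } else {
    starts <- seq(0, scaffold_len - window, by = step)
    ends <- starts + window
    tails <- rep(FALSE, length(starts))
    tail_start <- scaffold_len - window
    if (!tail_start %in% starts) {
      starts <- c(starts, tail_start)
      ends <- c(ends, scaffold_len)
      tails <- c(tails, TRUE)
    }
  }
  mids <- if (nrow(g)) interval_mid(g$start, g$end) else integer(0)
  hom <- if (nrow(g)) as.logical(g$homologous) else logical(0)
  n_genes <- integer(length(starts))
  n_hom <- integer(length(starts))
  for (i in seq_along(starts)) {
    inw <- mids >= starts[i] & mids < ends[i]
    n_genes[i] <- sum(inw)
    n_hom[i] <- sum(hom[inw])
  }
  frac <- ifelse(n_genes > 0L, n_hom / n_genes, NA_real_)
  label <- data.table::fcase(
    n_genes == 0L, "undetermined",
    n_genes >= min_genes & frac < max_homolog_frac, "non_syntenic",
    default = "syntenic"
  )
  data.table::data.table(
    scaffold_id = scaffold_id, start = as.numeric(starts),
    end = as.numeric(ends), n_genes = n_genes, n_homologous = n_hom,
    homolog_fraction = frac, label = label, is_tail = tails
  )
}

#' Merge non-syntenic windows of one scaffold into disjoint nSR intervals
#'
#' @param window_calls Output of [call_windows()] for a single scaffold.
#' @return `data.table` with `scaffold_id`, `start`, `end`; disjoint and
#'   sorted.
#' @export
merge_nsr <- function(window_calls) {
  wc <- data.table::as.data.table(window_calls)
  assert_cols(wc, c("scaffold_id", "start", "end", "label"), "window calls")
  if (length(unique(wc$scaffold_id)) > 1L) {
    stop("merge_nsr expects windows from a single scaffold", call. = FALSE)
  }
  ns <- wc[label == "non_syntenic"]
  if (nrow(ns) == 0L) {
    return(data.table::data.table(scaffold_id = character(),
                                  start = numeric(), end = numeric()))
  }
  m <- merge_intervals(as.integer(ns$start), as.integer(ns$end), gap = 0L)
  data.table::data.table(scaffold_id = wc$scaffold_id[1L],
                         start = as.numeric(m$start), end = as.numeric(m$end))
}

#' Call nSR intervals for many scaffolds at once
#'
#' Convenience wrapper running [call_windows()] and [merge_nsr()] per
#' scaffold.
#'
#' @param genes Gene table (multi-scaffold) with `scaffold_id`, `start`,
#'   `end`, `homologous`.
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param ... Passed to [call_windows()].
#' @return List with `windows` (all window calls) and `nsr` (merged
#'   intervals, all scaffolds).
#' @export
call_nsr <- function(genes, scaffold_lengths, ...) {
  g <- data.table::as.data.table(genes)
  wins <- list(); nsrs <- list()
  for (sc in names(scaffold_lengths)) {
    wc <- call_windows(g[scaffold_id == sc], scaffold_lengths[[sc]],
                       scaffold_id = sc, ...)
    wins[[sc]] <- wc
    nsrs[[sc]] <- merge_nsr(wc)
  }
  list(windows = data.table::rbindlist(wins),
       nsr = data.table::rbindlist(nsrs))
}

#' Summarize nSR spans and gene content
#'
#' @param nsr_intervals Disjoint intervals (`scaffold_id`, `start`, `end`).
#' @param scaffold_lengths Named numeric vector (bp).
#' @param gene_sets Named list of gene tables (`scaffold_id`, `start`,
#'   `end`); each set is counted by gene-midpoint containment.
#' @return List of class `nsr_summary`: `per_scaffold` (span and fraction
#'   per scaffold), `genome_span_bp`, `genome_total_bp`,
#'   `genome_fraction_pct` (rounded to 1 decimal), and `gene_sets`
#'   (`set`, `n_in_nsr`, `n_total`, `pct` to 1 decimal).
#' @export
summarize_nsr <- function(nsr_intervals, scaffold_lengths,
                          gene_sets = list()) {
  iv <- data.table::as.data.table(nsr_intervals)
  if (nrow(iv)) assert_cols(iv, c("scaffold_id", "start", "end"), "intervals")
  per <- data.table::data.table(scaffold_id = names(scaffold_lengths),
                                length = as.numeric(scaffold_lengths))
  span <- if (nrow(iv)) iv[, .(span = sum(end - start)), by = scaffold_id]
          else data.table::data.table(scaffold_id = character(), span = numeric())
  per <- merge(per, span, by = "scaffold_id", all.x = TRUE)
  per[is.na(span), span := 0]
  if (any(per$span > per$length)) {
    stop("nSR span exceeds scaffold length", call. = FALSE)
  }
  per[, fraction_pct := round(100 * span / length, 1L)]
  genome_span <- sum(per$span)
  genome_total <- sum(per$length)
  sets <- data.table::rbindlist(lapply(names(gene_sets), function(nm) {
    gs <- data.table::as.data.table(gene_sets[[nm]])
    n_in <- if (nrow(gs) == 0L) 0L else {
      sum(classify_gene_region(gs, iv) == "nSR")
    }
    data.table::data.table(set = nm, n_in_nsr = n_in, n_total = nrow(gs),
                           pct = round(100 * n_in / max(1L, nrow(gs)), 1L))
  }))
  structure(list(per_scaffold = per[],
                 genome_span_bp = genome_span,
                 genome_total_bp = genome_total,
                 genome_fraction_pct = round(100 * genome_span / genome_total, 1L),
                 gene_sets = sets),
            class = "nsr_summary")
}

#' Classify genes as inside an nSR or in a syntenic region
#'
#' Midpoint containment against half-open intervals: a midpoint exactly at
#' an interval end is outside.
#'
#' @param genes Gene table with `scaffold_id`, `start`, `end`.
#' @param nsr_intervals Disjoint nSR intervals.
#' @return Character vector, `"nSR"` or `"syntenic_region"` per gene.
#' @export
classify_gene_region <- function(genes, nsr_intervals) {
  g <- data.table::as.data.table(genes)
  assert_cols(g, c("scaffold_id", "start", "end"), "genes")
  iv <- data.table::as.data.table(nsr_intervals)
  out <- rep("syntenic_region", nrow(g))
  if (nrow(iv) == 0L || nrow(g) == 0L) return(out)
  mids <- interval_mid(g$start, g$end)
  for (sc in unique(g$scaffold_id)) {
    gi <- which(g$scaffold_id == sc)
    sub <- iv[scaffold_id == sc]
    if (nrow(sub) == 0L) next
    hit <- points_in_intervals(mids[gi], as.integer(sub$start),
                               as.integer(sub$end))
    out[gi[hit]] <- "nSR"
  }
  out
}
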