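# MCScanX-style collinear block detection from protein hits and gene order.
#
# The chaining recurrence, greedy best-first block extraction and the
# Poisson block e-value are documented re-implementations of the MCScanX
# idea (the native tool publishes parameters, not algorithm text); native
# .collinearity output can be imported instead via
# read_mcscanx_collinearity().

#' Collinearity parameter set
#'
#' Defaults follow the standard MCScanX parameterization: match_score 50,
#' gap_penalty -1, match_size 10 (minimum anchors per block), max_gaps 25
#' (maximum rank gap between consecutive anchors, both axes),
#' overlap_window 5, e_value cutoff 1e-5.
#'
#' @param match_score,gap_penalty,match_size,max_gaps,overlap_window,e_value_cut
#'   See description.
#' @return List of class `collinear_params`.
#' @export
collinear_params <- function(match_score = 50, gap_penalty = -1,
                             match_size = 10L, max_gaps = 25L,
                             overlap_window = 5L, e_value_cut = 1e-5) {
  stopifnot(match_size >= 2L, max_gaps >= 0L, gap_penalty <= 0)
  structure(list(match_score = match_score, gap_penalty = gap_penalty,
                 match_size = as.integer(match_size),
                 max_gaps = as.integer(max_gaps),
                 overlap_window = as.integer(overlap_window),
                 e_value_cut = e_value_cut),
            class = "collinear_params")
}

#' Map protein hits to rank-index anchor pairs between two scaffolds
#'
#' Gene ranks are strand-agnostic positions in start order on each
#' scaffold. Hits above the e-value cutoff are dropped; duplicate
#' (gene_a, gene_b) hits collapse to the best e-value. Tandem arrays
#' (consecutive genes on one scaffold hitting the same partner gene) are
#' collapsed to the best-scoring representative so that tandem clusters
#' do not simulate synteny.
#'
#' @param hits Hit table (`query_id`, `subject_id`, `e_value`,
#'   `bit_score`), e.g. from [read_tabular_hits()].
#' @param genes_a,genes_b Gene model tables for the two scaffolds (single
#'   scaffold each), as from [read_gff3()].
#' @param e_value_cut Maximum e-value (default 1e-5).
#' @param collapse_tandem Collapse tandem-array anchors (default TRUE).
#' @return `data.table` of anchors: `index_a`, `index_b` (1-based ranks),
#'   `gene_a`, `gene_b`, `e_value`.
#' @export
build_anchors <- function(hits, genes_a, genes_b, e_value_cut = 1e-5,
                          collapse_tandem = TRUE) {
  assert_cols(hits, c("query_id", "subject_id", "e_value"), "hits")
  ga <- data.table::as.data.table(genes_a)
  gb <- data.table::as.data.table(genes_b)
  data.table::setorder(ga, start)
  data.table::setorder(gb, start)
  rank_a <- setNames(seq_len(nrow(ga)), ga$gene_id)
  rank_b <- setNames(seq_len(nrow(gb)), gb$gene_id)
  h <- data.table::as.data.table(hits)[e_value <= e_value_cut]
  h <- h[query_id %in% names(rank_a) & subject_id %in% names(rank_b)]
  if (nrow(h) == 0L) {
    return(data.table::data.table(index_a = integer(), index_b = integer(),
                                  gene_a = character(), gene_b = character(),
                                  e_value = numeric()))
  }
  anc <- h[, .(e_value = min(e_value)), by = .(gene_a = query_id,
                                               gene_b = subject_id)]
  anc[, `:=`(index_a = unname(rank_a[gene_a]),
             index_b = unname(rank_b[gene_b]))]
  if (collapse_tandem) {
    anc <- collapse_tandem_anchors(anc, "index_a", "gene_b")
    anc <- collapse_tandem_anchors(anc, "index_b", "gene_a")
  }
  data.table::setorder(anc, index_a, index_b)
  anc[, .(index_a, index_b, gene_a, gene_b, e_value)]
}

# collapse runs of consecutive ranks on `axis` that all hit one `partner`
# gene to the single lowest-e-value anchor of the run
collapse_tandem_anchors <- function(anc, axis, partner) {
  data.table::setorderv(anc, c(partner, axis))
  idx <- anc[[axis]]
  new_run <- c(TRUE, diff(idx) > 1L | anc[[partner]][-1L] != anc[[partner]][-nrow(anc)])
  run <- cumsum(new_run)
  anc[, run__ := run]
  out <- anc[anc[, .I[which.min(e_value)], by = run__]$V1]
  out[, run__ := NULL]
  out
}

#' Chain anchors into collinear blocks (MCScanX-like dynamic program)
#'
#' Anchors are chained by a dynamic program: a chain extends from anchor i
#' to anchor j when `0 < index_a(j) - index_a(i) <= max_gaps` and the
#' index_b difference is positive (parallel) or negative (antiparallel)
#' with absolute value `<= max_gaps`; each anchor adds `match_score` and
#' each skipped rank on either axis adds `gap_penalty`. Blocks are
#' extracted greedily best-score-first, removing used anchors plus anchors
#' within `overlap_window` ranks of an accepted block (shadow-block
#' suppression), until no remaining chain has at least `match_size`
#' anchors. Blocks failing the e-value cutoff (see [block_evalue()]) are
#' discarded.
#'
#' @param anchors Anchor table from [build_anchors()].
#' @param params A [collinear_params()] object.
#' @param n_genes_a,n_genes_b Total gene counts of the two scaffolds (for
#'   the e-value rectangle); default: max observed rank.
#' @param scaffold_a,scaffold_b Labels stored on the blocks.
#' @return List of blocks; each block is a list with `scaffold_a`,
#'   `scaffold_b`, `orientation` (`parallel`/`antiparallel`), `score`,
#'   `e_value` and an `anchors` data.table.
#' @export
chain_anchors <- function(anchors, params = collinear_params(),
                          n_genes_a = NULL, n_genes_b = NULL,
                          scaffold_a = "a", scaffold_b = "b") {
  anc <- data.table::as.data.table(anchors)
  blocks <- list()
  if (nrow(anc) == 0L) return(blocks)
  n_genes_a <- n_genes_a %||% max(anc$index_a)
  n_genes_b <- n_genes_b %||% max(anc$index_b)
  n_total <- nrow(anc)
  repeat {
    if (nrow(anc) < params$match_size) break
    best <- NULL
    for (orient in c("parallel", "antiparallel")) {
      ch <- best_chain_dp(anc, params, orient)
      if (!is.null(ch) && (is.null(best) || ch$score > best$score)) best <- ch
    }
    if (is.null(best) || length(best$rows) < params$match_size) break
    ba <- anc[best$rows]
    data.table::setorder(ba, index_a)
    ev <- block_evalue_counts(nrow(ba),
                              diff(range(ba$index_a)) + 1L,
                              diff(range(ba$index_b)) + 1L,
                              n_total, n_genes_a, n_genes_b)
    if (ev <= params$e_value_cut) {
      blocks[[length(blocks) + 1L]] <- list(
        scaffold_a = scaffold_a, scaffold_b = scaffold_b,
        orientation = best$orientation, score = best$score, e_value = ev,
        anchors = ba[, .(index_a, index_b, gene_a, gene_b, e_value)]
      )
    }
    # drop used anchors and shadow anchors near the accepted chain
    w <- params$overlap_window
    shadow <- rep(FALSE, nrow(anc))
    for (r in seq_len(nrow(ba))) {
      shadow <- shadow |
        (abs(anc$index_a - ba$index_a[r]) <= w &
         abs(anc$index_b - ba$index_b[r]) <= w)
    }
    drop <- shadow
    drop[best$rows] <- TRUE
    anc <- anc[!drop]
  }
  blocks
}

# best chain under the DP recurrence for one orientation; returns row
# indices into `anc` (in chain order) and the chain score
best_chain_dp <- function(anc, params, orientation) {
  n <- nrow(anc)
  ib <- if (orientation == "antiparallel") -anc$index_b else anc$index_b
  ord <- order(anc$index_a, ib)
  ia <- anc$index_a[ord]
  ibo <- ib[ord]
  score <- rep(params$match_score, n)
  ptr <- rep(0L, n)
  lo <- 1L
  for (j in seq_len(n)) {
    if (j == 1L) next
    while (ia[lo] < ia[j] - params$max_gaps) lo <- lo + 1L
    if (lo > j - 1L) next
    cand <- lo:(j - 1L)
    da <- ia[j] - ia[cand]
    db <- ibo[j] - ibo[cand]
    ok <- da > 0L & db > 0L & db <= params$max_gaps
    if (!any(ok)) next
    cand <- cand[ok]
    cand_score <- score[cand] + params$match_score +
      params$gap_penalty * ((ia[j] - ia[cand] - 1L) + (ibo[j] - ibo[cand] - 1L))
    bestv <- max(cand_score)
    if (bestv > score[j]) {
      # tie-break: lowest index_a, then lowest index_b
      tied <- cand[cand_score == bestv]
      pick <- tied[order(ia[tied], ibo[tied])][1L]
      score[j] <- bestv
      ptr[j] <- pick
    }
  }
  jbest <- which.max(score)
  rows <- integer(0)
  k <- jbest
  while (k != 0L) { rows <- c(k, rows); k <- ptr[k] }
  list(rows = ord[rows], score = score[jbest], orientation = orientation)
}

block_evalue_counts <- function(m, la, lb, n_anchors_total, n_genes_a,
                                n_genes_b) {
  if (la <= 0L || lb <= 0L || n_genes_a <= 0L || n_genes_b <= 0L) {
    stop("zero-size rank rectangle", call. = FALSE)
  }
  lambda <- n_anchors_total * (la / n_genes_a) * (lb / n_genes_b)
  # P(>= m anchors in the rectangle) x P(m uniform anchors are jointly
  # monotone) = Poisson tail / m!
  logp <- stats::ppois(m - 1L, lambda, lower.tail = FALSE, log.p = TRUE) -
    lfactorial(m)
  exp(logp)
}

#' Poisson e-value of a collinear block
#'
#' Approximates the probability of observing a chain as anchor-rich as the
#' block inside its rank rectangle if all anchors were scattered uniformly
#' over the gene-rank grid: the Poisson upper tail of the rectangle's
#' expected anchor count at the observed count, divided by m! (the chance
#' that m uniformly placed anchors are jointly monotone). Monotone
#' decreasing in anchor count at fixed rectangle.
#'
#' @param block A block from [chain_anchors()].
#' @param n_anchors_total Total anchors between the two scaffolds.
#' @param n_genes_a,n_genes_b Gene counts of the two scaffolds.
#' @return E-value in `[0, Inf)`.
#' @export
block_evalue <- function(block, n_anchors_total, n_genes_a, n_genes_b) {
  a <- block$anchors
  if (is.null(a) || nrow(a) == 0L) stop("empty block", call. = FALSE)
  block_evalue_counts(nrow(a),
                      diff(range(a$index_a)) + 1L,
                      diff(range(a$index_b)) + 1L,
                      n_anchors_total, n_genes_a, n_genes_b)
}

#' Validate the structural invariants of a collinear block
#'
#' Checks minimum anchor count, strict monotonicity of both rank indices
#' (increasing, or decreasing in index_b for antiparallel blocks) and the
#' max_gaps bound between consecutive anchors.
#'
#' @param block Block from [chain_anchors()].
#' @param params [collinear_params()] used to produce it.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_block <- function(block, params = collinear_params()) {
  a <- block$anchors
  if (nrow(a) < params$match_size) stop("block below match_size", call. = FALSE)
  da <- diff(a$index_a)
  db <- diff(a$index_b)
  if (any(da <= 0L)) stop("index_a not strictly increasing", call. = FALSE)
  if (block$orientation == "parallel" && any(db <= 0L)) {
    stop("index_b not strictly increasing in parallel block", call. = FALSE)
  }
  if (block$orientation == "antiparallel" && any(db >= 0L)) {
    stop("index_b not strictly decreasing in antiparallel block", call. = FALSE)
  }
  if (any(da > params$max_gaps) || any(abs(db) > params$max_gaps)) {
    stop("consecutive-anchor rank gap exceeds max_gaps", call. = FALSE)
  }
  invisible(TRUE)
}

#' Flag genes that keep order conservation with a low-divergence partner
#'
#' A gene is flagged homologous when it participates in at least one
#' retained block anchor whose Ka/Ks estimate passes
#' [classify_homologous()].
#'
#' @param blocks List of blocks from [chain_anchors()] (or imported native
#'   output).
#' @param kaks Ka/Ks table from [kaks_table()] covering every block anchor
#'   (pair orientation-insensitive).
#' @param threshold,metric Passed to the classification rule.
#' @return Named logical vector over every gene occurring in a block
#'   anchor; genes outside all blocks are simply absent (treat as FALSE).
#' @export
homologous_gene_flags <- function(blocks, kaks, threshold = 0.3,
                                  metric = c("ks", "ka", "ka_over_ks")) {
  metric <- match.arg(metric)
  k <- data.table::as.data.table(kaks)
  assert_cols(k, c("gene_a", "gene_b"), "kaks")
  val <- switch(metric, ks = k$Ks, ka = k$Ka, ka_over_ks = k$ratio)
  pass_vec <- rep(!is.na(val) & val < threshold, 2L)
  names(pass_vec) <- c(paste(k$gene_a, k$gene_b, sep = "\r"),
                       paste(k$gene_b, k$gene_a, sep = "\r"))
  anchors <- data.table::rbindlist(
    lapply(blocks, function(b) b$anchors[, c("gene_a", "gene_b")])
  )
  if (is.null(anchors) || nrow(anchors) == 0L) {
    return(setNames(logical(0), character(0)))
  }
  idx <- match(paste(anchors$gene_a, anchors$gene_b, sep = "\r"),
               names(pass_vec))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("missing Ka/Ks for block anchor pair(s): ",
         paste(head(paste(anchors$gene_a[bad], anchors$gene_b[bad], sep = "/"),
                    5L), collapse = ", "), call. = FALSE)
  }
  ok <- unname(pass_vec[idx])
  long <- data.table::data.table(
    gene = c(anchors$gene_a, anchors$gene_b), ok = rep(ok, 2L)
  )
  agg <- long[, .(flag = any(ok)), by = gene]
  setNames(agg$flag, agg$gene)
}
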