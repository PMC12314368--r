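# Protein-guided codon alignment and NG86 (Nei & Gojobori 1986) Ka/Ks
# estimation with Jukes-Cantor correction, plus the homolog classification
# used to flag order-conserved gene pairs.

GENCODE <- Biostrings::GENETIC_CODE

#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()] under a BLOSUM62 table (gap opening
#' 10, extension 1 by default).
#'
#' @param prot_a,prot_b Amino-acid sequences (character strings, no gaps).
#' @param substitution_matrix Name of a substitution table available to
#'   Biostrings (default "BLOSUM62").
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return List with gapped strings `a`, `b` and the alignment `score`.
#' @export
global_protein_align <- function(prot_a, prot_b,
                                 substitution_matrix = "BLOSUM62",
                                 gap_open = 10, gap_extend = 1) {
  for (p in c(prot_a, prot_b)) {
    if (!nzchar(p)) stop("empty protein sequence", call. = FALSE)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(p))) {
      stop("invalid amino-acid residue in protein sequence", call. = FALSE)
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(prot_a)), Biostrings::AAString(toupper(prot_b)),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Protein gap columns expand to codon gaps; only gap-free columns whose
#' codons are unambiguous sense codons are retained for substitution
#' counting. Each CDS must translate exactly to its protein (a trailing
#' stop codon on the CDS is tolerated and dropped).
#'
#' @param aln Protein alignment as returned by [global_protein_align()].
#' @param cds_a,cds_b Nucleotide coding sequences.
#' @return List of class `codon_alignment` with character vectors
#'   `codons_a`, `codons_b` (same length) and `n_codons`.
#' @export
codon_align_from_protein <- function(aln, cds_a, cds_b) {
  pa <- strsplit(aln$a, "")[[1L]]
  pb <- strsplit(aln$b, "")[[1L]]
  stopifnot(length(pa) == length(pb))
  ca <- split_codons(cds_a, sum(pa != "-"), "cds_a")
  cb <- split_codons(cds_b, sum(pb != "-"), "cds_b")
  check_translation(ca, gsub("-", "", aln$a), "cds_a")
  check_translation(cb, gsub("-", "", aln$b), "cds_b")
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] == "-" || pb[k] == "-") next
    coda <- ca[ia]; codb <- cb[ib]
    if (grepl("N", coda) || grepl("N", codb)) next
    if (GENCODE[[coda]] == "*" || GENCODE[[codb]] == "*") next
    keep_a <- c(keep_a, coda); keep_b <- c(keep_b, codb)
  }
  structure(list(codons_a = keep_a, codons_b = keep_b,
                 n_codons = length(keep_a)),
            class = "codon_alignment")
}

split_codons <- function(cds, n_aa, label) {
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds)) stop(label, ": non-nucleotide base", call. = FALSE)
  nc <- nchar(cds)
  if (nc == 3L * (n_aa + 1L)) {
    last <- substr(cds, nc - 2L, nc)
    if (!grepl("N", last) && GENCODE[[last]] == "*") {
      cds <- substr(cds, 1L, nc - 3L)
      nc <- nc - 3L
    }
  }
  if (nc != 3L * n_aa) {
    stop(sprintf("%s: length %d does not match 3 x %d protein residues",
                 label, nc, n_aa), call. = FALSE)
  }
  substring(cds, seq(1L, nc, 3L), seq(3L, nc, 3L))
}

check_translation <- function(codons, prot, label) {
  aa <- strsplit(prot, "")[[1L]]
  for (i in seq_along(codons)) {
    if (grepl("N", codons[i])) next
    tr <- GENCODE[[codons[i]]]
    if (tr == "*" && i < length(codons)) {
      stop(sprintf("%s: internal stop codon at codon %d", label, i),
           call. = FALSE)
    }
    if (tr != aa[i] && aa[i] != "X") {
      stop(sprintf("%s: codon %d (%s -> %s) does not translate to protein residue %s",
                   label, i, codons[i], tr, aa[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# --- NG86 internals ---------------------------------------------------------

BASES <- c("A", "C", "G", "T")

# fractional synonymous sites of one sense codon; changes to stop codons
# count as nonsynonymous so S + N = 3 exactly
ng86_syn_sites <- function(codon) {
  aa <- GENCODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENCODE[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two sense codons
# over all minimal mutational pathways; pathways through stop codons are
# excluded unless every pathway is blocked. Results are memoized (at most
# 61 x 61 codon pairs).
.ng86_cache <- new.env(parent = emptyenv())

ng86_codon_diffs_uncached <- function(cod_a, cod_b) {
  pos <- which(strsplit(cod_a, "")[[1L]] != strsplit(cod_b, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  tally <- function(skip_stops) {
    sds <- numeric(0); nds <- numeric(0)
    for (ord in perms) {
      cur <- cod_a; s <- 0; n <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cod_b, p, p)
        if (skip_stops && GENCODE[[nxt]] == "*") { ok <- FALSE; break }
        if (GENCODE[[cur]] == GENCODE[[nxt]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { sds <- c(sds, s); nds <- c(nds, n) }
    }
    if (length(sds) == 0L) NULL else c(sd = mean(sds), nd = mean(nds))
  }
  tally(TRUE) %||% tally(FALSE)
}

ng86_codon_diffs <- function(cod_a, cod_b) {
  key <- paste0(cod_a, cod_b)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- ng86_codon_diffs_uncached(cod_a, cod_b)
  assign(key, v, envir = .ng86_cache)
  v
}

.syn_sites_cache <- new.env(parent = emptyenv())

ng86_syn_sites_cached <- function(codon) {
  hit <- .syn_sites_cache[[codon]]
  if (!is.null(hit)) return(hit)
  v <- ng86_syn_sites(codon)
  assign(codon, v, envir = .syn_sites_cache)
  v
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)     # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks estimation on a codon alignment
#'
#' Nei & Gojobori (1986) counting: fractional synonymous (S) and
#' nonsynonymous (N) sites are averaged over the two sequences (S + N =
#' 3 x codons exactly); observed differences at multiply substituted
#' codons are averaged over all minimal mutational pathways (pathways
#' through stop codons excluded when avoidable); proportions are
#' Jukes-Cantor corrected into rates. A proportion >= 3/4 is flagged
#' `saturated` and yields `NA` for the corresponding rate rather than an
#' error.
#'
#' @param alignment A `codon_alignment` from [codon_align_from_protein()],
#'   or a list with `codons_a`, `codons_b`.
#' @return List of class `kaks_result`: `S`, `N`, `sd`, `nd`, `ps`, `pn`,
#'   `Ka`, `Ks`, `ratio`, `n_codons`, `saturated`.
#' @export
ng86 <- function(alignment) {
  ca <- alignment$codons_a; cb <- alignment$codons_b
  stopifnot(length(ca) == length(cb), length(ca) >= 1L)
  Sa <- sum(vapply(ca, ng86_syn_sites_cached, 0))
  Sb <- sum(vapply(cb, ng86_syn_sites_cached, 0))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  sd_ <- 0; nd_ <- 0
  for (i in seq_along(ca)) {
    d <- ng86_codon_diffs(ca[i], cb[i])
    sd_ <- sd_ + d[["sd"]]; nd_ <- nd_ + d[["nd"]]
  }
  ps <- if (S > 0) sd_ / S else 0
  pn <- if (N > 0) nd_ / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, sd = sd_, nd = nd_, ps = ps, pn = pn,
                 Ka = Ka, Ks = Ks, ratio = ratio,
                 n_codons = length(ca),
                 saturated = is.na(Ka) || is.na(Ks)),
            class = "kaks_result")
}

#' Ka/Ks for one CDS pair (translate, align, back-translate, NG86)
#'
#' @param cds_a,cds_b Coding sequences.
#' @param ... Passed to [global_protein_align()].
#' @return A `kaks_result` (see [ng86()]).
#' @export
kaks_pair <- function(cds_a, cds_b, ...) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- global_protein_align(pa, pb, ...)
  ng86(codon_align_from_protein(aln, cds_a, cds_b))
}

#' Translate a CDS, dropping a trailing stop
#' @param cds Nucleotide coding sequence (length a multiple of 3).
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3 == 0)
  p <- if (grepl("N", cds, fixed = TRUE)) {
    # fuzzy path is slow (rebuilds the fuzzy code); only used for Ns
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       if.fuzzy.codon = "X"))
  } else {
    as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  }
  sub("\\*$", "", p)
}

#' Classify a gene pair as homologous from its Ka/Ks estimate
#'
#' A pair is homologous when the chosen metric is strictly below the
#' threshold (default Ks < 0.3). Saturated or undefined metrics are never
#' homologous.
#'
#' @param kaks A `kaks_result`.
#' @param threshold Classification cutoff (default 0.3).
#' @param metric One of `"ks"`, `"ka"`, `"ka_over_ks"`.
#' @return Logical scalar.
#' @export
classify_homologous <- function(kaks, threshold = 0.3,
                                metric = c("ks", "ka", "ka_over_ks")) {
  metric <- match.arg(metric)
  v <- switch(metric, ks = kaks$Ks, ka = kaks$Ka, ka_over_ks = kaks$ratio)
  if (is.null(v) || is.na(v)) return(FALSE)
  v < threshold
}

#' Ka/Ks table for a set of gene pairs
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param cds Named character vector of CDS keyed by gene ID.
#' @param threshold,metric Passed to [classify_homologous()].
#' @return `data.table` with one row per pair: site/difference counts,
#'   `Ka`, `Ks`, `ratio`, `is_homologous`.
#' @export
kaks_table <- function(pairs, cds, threshold = 0.3, metric = "ks") {
  assert_cols(pairs, c("gene_a", "gene_b"), "pairs")
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(miss)) stop("missing CDS for gene(s): ",
                         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- kaks_pair(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    rows[[i]] <- data.table::data.table(
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
      S = k$S, N = k$N, sd = k$sd, nd = k$nd, Ka = k$Ka, Ks = k$Ks,
      ratio = k$ratio,
      is_homologous = classify_homologous(k, threshold, metric)
    )
  }
  data.table::rbindlist(rows)
}
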