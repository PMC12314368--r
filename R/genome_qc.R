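# Assembly QC: telomere array detection, gap runs, and Ref/Alt haplotype
# assignment for homologous scaffold pairs.

#' Find tandem telomere-motif arrays in a scaffold sequence
#'
#' Scans for maximal tandem runs of the telomere motif (default `TTAGGG`,
#' conserved across metazoans) on the forward strand and of its reverse
#' complement (`CCCTAA`, the 5' end presentation). Exact motif matches
#' separated by at most two motif lengths are merged into one array, which
#' tolerates occasional degenerate copies; arrays are then filtered by
#' copy number and by the fraction of array bases not covered by exact
#' copies.
#'
#' @param seq Nucleotide sequence (character string or
#'   [Biostrings::DNAString]). Alphabet must be A/C/G/T/N.
#' @param scaffold_id Label carried into the output.
#' @param motif Telomere repeat unit (length >= 4).
#' @param min_copies Minimum motif copies per reported array (default 25,
#'   about a 150 bp array for a 6-mer motif).
#' @param max_mismatch_frac Maximum fraction of array bases outside exact
#'   motif copies (default 0.1).
#' @param end_window Distance (bp) from a scaffold end within which an
#'   array is labelled terminal (default 10 kb).
#' @return `data.table` with `scaffold_id`, `start`, `end` (0-based
#'   half-open), `motif_copies`, `mismatch_frac`, `strand`, `scaffold_end`
#'   (`5prime`, `3prime` or `internal`).
#' @export
find_telomere_arrays <- function(seq, scaffold_id = "seq", motif = "TTAGGG",
                                 min_copies = 25L, max_mismatch_frac = 0.1,
                                 end_window = 10000L) {
  s <- as_dna_string(seq)
  stopifnot(nchar(motif) >= 4L)
  slen <- length(s)
  empty <- data.table::data.table(
    scaffold_id = character(), start = integer(), end = integer(),
    motif_copies = integer(), mismatch_frac = numeric(),
    strand = character(), scaffold_end = character()
  )
  mlen <- nchar(motif)
  one_strand <- function(pat, strand) {
    hits <- Biostrings::matchPattern(pat, s)
    if (length(hits) == 0L) return(empty)
    runs <- merge_intervals(Biostrings::start(hits) - 1L,
                            Biostrings::end(hits), gap = 2L * mlen)
    n_exact <- IRanges::countOverlaps(
      IRanges::IRanges(runs$start + 1L, runs$end),
      IRanges::IRanges(Biostrings::start(hits), Biostrings::end(hits)),
      type = "any", minoverlap = mlen
    )
    span <- runs$end - runs$start
    copies <- as.integer(round(span / mlen))
    mm <- (span - mlen * n_exact) / span
    keep <- copies >= min_copies & mm <= max_mismatch_frac
    if (!any(keep)) return(empty)
    data.table::data.table(
      scaffold_id = scaffold_id,
      start = runs$start[keep], end = runs$end[keep],
      motif_copies = copies[keep], mismatch_frac = mm[keep],
      strand = strand,
      scaffold_end = data.table::fcase(
        runs$start[keep] < end_window, "5prime",
        runs$end[keep] > slen - end_window, "3prime",
        default = "internal"
      )
    )
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  out <- rbind(one_strand(motif, "+"), one_strand(rc, "-"))
  data.table::setorder(out, start)
  out[]
}

#' Find assembly gap runs (stretches of N)
#'
#' @param seq Nucleotide sequence (character or DNAString).
#' @param scaffold_id Label for the output.
#' @param min_gap_len Minimum run length reported (default 10).
#' @return `data.table` with `scaffold_id`, `start`, `end` (0-based
#'   half-open), `length`.
#' @export
count_gap_runs <- function(seq, scaffold_id = "seq", min_gap_len = 10L) {
  s <- as_dna_string(seq)
  chars <- as.character(s)
  m <- gregexpr("N+", chars)[[1L]]
  empty <- data.table::data.table(scaffold_id = character(), start = integer(),
                                  end = integer(), length = integer())
  if (m[1L] == -1L) return(empty)
  len <- attr(m, "match.length")
  keep <- len >= min_gap_len
  if (!any(keep)) return(empty)
  data.table::data.table(
    scaffold_id = scaffold_id,
    start = as.integer(m[keep]) - 1L,
    end = as.integer(m[keep]) - 1L + len[keep],
    length = len[keep]
  )
}

as_dna_string <- function(seq) {
  if (inherits(seq, "DNAString")) return(seq)
  if (is.character(seq) && length(seq) == 1L) {
    up <- toupper(seq)
    if (grepl("[^ACGTN]", up)) {
      stop("sequence contains non-nucleotide characters", call. = FALSE)
    }
    return(Biostrings::DNAString(up))
  }
  stop("seq must be a single character string or a DNAString", call. = FALSE)
}

#' Summarize telomere/gap status of one scaffold for haplotype assignment
#'
#' @param seq Scaffold sequence.
#' @param scaffold_id Scaffold name.
#' @param ... Passed to [find_telomere_arrays()] and [count_gap_runs()].
#' @return List with `scaffold_id`, `length`, `telomere_5p`, `telomere_3p`,
#'   `n_gaps` — the input expected by [assign_ref_alt()].
#' @export
scaffold_qc_info <- function(seq, scaffold_id = "seq", ...) {
  s <- as_dna_string(seq)
  args <- list(...)
  tel <- do.call(find_telomere_arrays,
                 c(list(seq = s, scaffold_id = scaffold_id),
                   args[names(args) %in% names(formals(find_telomere_arrays))]))
  gaps <- do.call(count_gap_runs,
                  c(list(seq = s, scaffold_id = scaffold_id),
                    args[names(args) %in% names(formals(count_gap_runs))]))
  list(scaffold_id = scaffold_id, length = length(s),
       telomere_5p = any(tel$scaffold_end == "5prime"),
       telomere_3p = any(tel$scaffold_end == "3prime"),
       n_gaps = nrow(gaps))
}

#' Assign Ref/Alt haplotype labels to a homologous scaffold pair
#'
#' Applies three ordered rules: (i) if only one scaffold of the pair has
#' telomere arrays at both ends it becomes the reference; (ii) if both do,
#' the one with fewer assembly gaps becomes the reference; (iii) otherwise
#' (telomeres at one end or none) the scaffold with fewer gaps becomes the
#' reference. An exact tie on gap count is broken towards the longer
#' scaffold (recorded as rule `tiebreak`).
#'
#' @param info_a,info_b Lists as returned by [scaffold_qc_info()]:
#'   `scaffold_id`, `length`, `telomere_5p`, `telomere_3p`, `n_gaps`.
#' @return List with `ref_id`, `alt_id`, `rule_used` (`"i"`, `"ii"`,
#'   `"iii"` or `"tiebreak"`).
#' @export
assign_ref_alt <- function(info_a, info_b) {
  need <- c("scaffold_id", "length", "telomere_5p", "telomere_3p", "n_gaps")
  for (info in list(info_a, info_b)) {
    miss <- setdiff(need, names(info))
    if (length(miss)) stop("scaffold info missing field(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  both_a <- isTRUE(info_a$telomere_5p) && isTRUE(info_a$telomere_3p)
  both_b <- isTRUE(info_b$telomere_5p) && isTRUE(info_b$telomere_3p)
  pick <- function(ref, alt, rule) list(ref_id = ref$scaffold_id,
                                        alt_id = alt$scaffold_id,
                                        rule_used = rule)
  by_gaps <- function(rule) {
    if (info_a$n_gaps < info_b$n_gaps) return(pick(info_a, info_b, rule))
    if (info_b$n_gaps < info_a$n_gaps) return(pick(info_b, info_a, rule))
    if (info_a$length >= info_b$length) pick(info_a, info_b, "tiebreak")
    else pick(info_b, info_a, "tiebreak")
  }
  if (both_a && !both_b) return(pick(info_a, info_b, "i"))
  if (both_b && !both_a) return(pick(info_b, info_a, "i"))
  if (both_a && both_b) return(by_gaps("ii"))
  by_gaps("iii")
}
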