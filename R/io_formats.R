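# Readers/writers for the standard formats the pipeline touches.
#
# Everything is normalized to the internal convention on the way in:
# 0-based half-open coordinates, genes sorted by (scaffold_id, start),
# one representative transcript per gene (longest summed CDS).

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA` and `CDS` features. GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' When a gene has several mRNAs, the isoform with the longest summed CDS
#' is kept as the representative (ties broken by lexicographically smallest
#' transcript ID).
#'
#' Optional `species` and `haplotype` attributes on gene features are
#' propagated; they default to `"unknown"` and `"unassigned"`.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.table` of gene models with columns `gene_id`,
#'   `scaffold_id`, `start`, `end`, `strand`, `species`, `haplotype`,
#'   `cds_id`, `protein_id`, sorted by `(scaffold_id, start)`.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) == 0L) return(empty_gene_table())

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                 lineno[bad], nf[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  gff <- data.table::data.table(
    scaffold_id = m[, 1L], type = m[, 3L],
    start = suppressWarnings(as.integer(m[, 4L])),
    end   = suppressWarnings(as.integer(m[, 5L])),
    strand = m[, 7L], attrs = m[, 9L], line = lineno
  )
  bad <- which(is.na(gff$start) | is.na(gff$end) | gff$end < gff$start)
  if (length(bad)) {
    stop(sprintf("malformed GFF3 line %d: bad coordinates", gff$line[bad[1L]]),
         call. = FALSE)
  }

  gff[, `:=`(id = gff_attr(attrs, "ID"), parent = gff_attr(attrs, "Parent"))]

  genes <- gff[type == "gene"]
  if (nrow(genes) == 0L) return(empty_gene_table())
  if (anyNA(genes$id)) {
    stop(sprintf("gene feature without ID attribute at line %d",
                 genes$line[which(is.na(genes$id))[1L]]), call. = FALSE)
  }
  if (anyDuplicated(genes$id)) {
    dup <- genes$id[duplicated(genes$id)][1L]
    stop(sprintf("duplicate gene ID '%s'", dup), call. = FALSE)
  }

  # representative transcript: longest total CDS, ties by transcript id
  mrna <- gff[type == "mRNA" & !is.na(id)]
  cds <- gff[type == "CDS" & !is.na(parent)]
  rep_tx <- rep(NA_character_, nrow(genes))
  names(rep_tx) <- genes$id
  if (nrow(mrna) > 0L) {
    cds_len <- if (nrow(cds) > 0L) {
      cds[, .(cds_len = sum(end - start + 1L)), by = .(id2 = parent)]
    } else data.table::data.table(id2 = character(), cds_len = integer())
    tx <- merge(mrna[, .(tx_id = id, gene = parent)],
                cds_len, by.x = "tx_id", by.y = "id2", all.x = TRUE)
    tx[is.na(cds_len), cds_len := 0L]
    data.table::setorder(tx, gene, -cds_len, tx_id)
    best <- tx[!duplicated(gene)]
    rep_tx[best$gene] <- best$tx_id
  }

  out <- data.table::data.table(
    gene_id = genes$id,
    scaffold_id = genes$scaffold_id,
    start = genes$start - 1L,             # to 0-based half-open
    end = genes$end,
    strand = genes$strand,
    species = data.table::fifelse(is.na(gff_attr(genes$attrs, "species")),
                                  "unknown", gff_attr(genes$attrs, "species")),
    haplotype = data.table::fifelse(is.na(gff_attr(genes$attrs, "haplotype")),
                                    "unassigned", gff_attr(genes$attrs, "haplotype")),
    cds_id = unname(rep_tx),
    protein_id = unname(rep_tx)
  )
  if (!all(out$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  data.table::setorder(out, scaffold_id, start)
  out[]
}

gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- regexpr(pat, attrs, perl = TRUE) > 0L
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

empty_gene_table <- function() {
  data.table::data.table(
    gene_id = character(), scaffold_id = character(),
    start = integer(), end = integer(), strand = character(),
    species = character(), haplotype = character(),
    cds_id = character(), protein_id = character()
  )
}

#' Read BLAST tabular (outfmt 6) protein hits
#'
#' Self-hits are dropped; per query only the `max_hits_per_query` best
#' subjects by bit score are retained (ties at the cutoff rank broken by
#' lexicographic subject ID, so output is deterministic).
#'
#' @param path Path to a 12-column tab-separated BLAST report.
#' @param max_hits_per_query Best subjects kept per query (default 5).
#' @return `data.table` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `e_value`, `bit_score`.
#' @export
read_tabular_hits <- function(path, max_hits_per_query = 5L) {
  stopifnot(file.exists(path), max_hits_per_query >= 1L)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.table::data.table(query_id = character(), subject_id = character(),
                                  pct_identity = numeric(), aln_length = integer(),
                                  e_value = numeric(), bit_score = numeric()))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = FALSE)
  if (ncol(dt) != 12L) {
    stop(sprintf("expected 12 tab-separated columns (BLAST outfmt 6), got %d",
                 ncol(dt)), call. = FALSE)
  }
  data.table::setnames(dt, c("query_id", "subject_id", "pct_identity",
                             "aln_length", "mismatches", "gap_opens",
                             "q_start", "q_end", "s_start", "s_end",
                             "e_value", "bit_score"))
  dt <- dt[query_id != subject_id]
  if (any(dt$e_value < 0)) stop("negative e-value in hit table", call. = FALSE)
  data.table::setorder(dt, query_id, -bit_score, subject_id)
  dt <- dt[, head(.SD, max_hits_per_query), by = query_id]
  dt[, .(query_id, subject_id, pct_identity, aln_length, e_value, bit_score)]
}

#' Read Pfam domain annotations from an InterProScan TSV report
#'
#' Keeps rows whose signature accession matches the Pfam pattern
#' `PF\\d{5}`; other analyses in the report are ignored.
#'
#' @param path InterProScan TSV (protein accession in column 1, signature
#'   accession in column 5).
#' @return `data.table` with `gene_id`, `domain_acc`, `description`,
#'   `start`, `end` (protein coordinates, 1-based as reported).
#' @export
read_interproscan_tsv <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          quote = "")
  if (ncol(dt) < 8L) {
    stop("unrecognized InterProScan TSV: fewer than 8 columns; first line: ",
         readLines(path, n = 1L), call. = FALSE)
  }
  out <- dt[, .(gene_id = as.character(V1), domain_acc = as.character(V5),
                description = as.character(V6),
                start = as.integer(V7), end = as.integer(V8))]
  out <- out[grepl("^PF\\d{5}$", domain_acc)]
  out[]
}

#' Read a RepeatMasker .out annotation table
#'
#' The three header lines are skipped. Coordinates are converted to
#' 0-based half-open. The `class/family` column is split into a normalized
#' repeat class (`LTR`, `LINE`, `SINE`, `DNA` or `other`) and a family name.
#'
#' @param path RepeatMasker `.out` file.
#' @return `data.table` with `scaffold_id`, `start`, `end`, `family`,
#'   `class`.
#' @export
read_repeatmasker_out <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  # RepeatMasker emits 2 header lines + 1 blank; be tolerant and drop any
  # leading lines that do not start with a numeric score
  body <- lines[grepl("^\\s*\\d", lines)]
  if (length(body) == 0L) {
    return(data.table::data.table(scaffold_id = character(), start = integer(),
                                  end = integer(), family = character(),
                                  class = character()))
  }
  dt <- data.table::as.data.table(
    read.table(text = body, header = FALSE, fill = TRUE,
               stringsAsFactors = FALSE)
  )
  if (ncol(dt) < 11L) {
    stop("unrecognized RepeatMasker .out dialect; first line: ", body[1L],
         call. = FALSE)
  }
  cf <- as.character(dt[[11L]])
  cls <- toupper(sub("/.*$", "", cf))
  fam <- as.character(dt[[10L]])
  norm <- data.table::fcase(
    grepl("^LTR", cls), "LTR",
    grepl("^LINE", cls), "LINE",
    grepl("^SINE", cls), "SINE",
    grepl("^DNA|^RC", cls), "DNA",
    default = "other"
  )
  out <- data.table::data.table(
    scaffold_id = as.character(dt[[5L]]),
    start = as.integer(dt[[6L]]) - 1L,    # 1-based inclusive -> 0-based half-open
    end = as.integer(dt[[7L]]),
    family = fam, class = norm
  )
  if (any(out$end <= out$start)) stop("RepeatMasker row with end <= start",
                                      call. = FALSE)
  out[]
}

#' Read a genes x stages expression matrix from TSV
#'
#' First column holds gene IDs, remaining columns one developmental stage
#' each. Values must be non-negative and gene IDs unique.
#'
#' @param path TSV file with a header row.
#' @return Numeric matrix, rownames = gene IDs, colnames = stage labels.
#' @export
read_expression_tsv <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 2L) stop("expression TSV needs gene ID + >=1 stage column",
                          call. = FALSE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene ID '%s' in expression matrix",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  m <- as.matrix(dt[, -1L])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric value in expression matrix", call. = FALSE)
  if (any(m < 0)) stop("negative expression value", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a genes x stages expression matrix as TSV
#' @param mat Numeric matrix with rownames (gene IDs) and colnames (stages).
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  dt <- data.table::data.table(gene_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write intervals to a BED file (0-based half-open, sorted)
#'
#' @param intervals data.frame with `scaffold_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand` (BED6).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("scaffold_id", "start", "end"), "BED input")
  dt <- data.table::as.data.table(intervals)
  if (nrow(dt) > 0L && any(dt$end <= dt$start)) {
    stop("BED interval with end <= start", call. = FALSE)
  }
  data.table::setorder(dt, scaffold_id, start, end)
  cols <- c("scaffold_id", "start", "end")
  for (opt in c("name", "score", "strand")) {
    if (opt %in% names(dt)) cols <- c(cols, opt) else break
  }
  data.table::fwrite(dt[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into the internal interval convention
#' @param path BED file path.
#' @return `data.table` with `scaffold_id`, `start`, `end` (+`name`,
#'   `score`, `strand` when present).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    return(data.table::data.table(scaffold_id = character(),
                                  start = integer(), end = integer()))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  nm <- c("scaffold_id", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, nm[seq_len(ncol(dt))])
  dt[]
}

#' Read an MCScanX .collinearity file
#'
#' Imports native MCScanX output so externally computed blocks can be
#' substituted for [chain_anchors()] results.
#'
#' @param path `.collinearity` text file.
#' @return List of collinear blocks (see [chain_anchors()] for the
#'   structure).
#' @export
read_mcscanx_collinearity <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && nrow(cur$anchors) > 0L) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^## Alignment", ln)) {
      blocks <- flush(cur, blocks)
      score <- as.numeric(sub(".*score=([0-9.eE+-]+).*", "\\1", ln))
      ev <- as.numeric(sub(".*e_value=([0-9.eE+-]+).*", "\\1", ln))
      scaf <- sub(".*N=\\d+\\s+(\\S+)&(\\S+).*", "\\1 \\2", ln)
      sc <- strsplit(scaf, " ")[[1L]]
      orient <- if (grepl("minus\\s*$", ln)) "antiparallel" else "parallel"
      cur <- list(scaffold_a = sc[1L], scaffold_b = sc[2L], score = score,
                  e_value = ev, orientation = orient,
                  anchors = data.table::data.table(gene_a = character(),
                                                   gene_b = character()))
    } else if (grepl("^#", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      if (is.null(cur)) stop("anchor line before any '## Alignment' header: ",
                             ln, call. = FALSE)
      f <- strsplit(trimws(ln), "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) stop("unrecognized .collinearity anchor line: ", ln,
                               call. = FALSE)
      cur$anchors <- rbind(cur$anchors,
                           data.table::data.table(gene_a = f[2L], gene_b = f[3L]))
    }
  }
  flush(cur, blocks)
}

#' Write collinear blocks in MCScanX-compatible .collinearity text
#' @param blocks List of blocks as produced by [chain_anchors()].
#' @param path Output path.
#' @export
write_mcscanx_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### collinear blocks ###############", con)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    writeLines(sprintf("## Alignment %d: score=%.1f e_value=%.3g N=%d %s&%s %s",
                       i - 1L, b$score, b$e_value, nrow(b$anchors),
                       b$scaffold_a, b$scaffold_b,
                       if (identical(b$orientation, "antiparallel")) "minus" else "plus"),
               con)
    for (j in seq_len(nrow(b$anchors))) {
      writeLines(sprintf("%3d-%3d:\t%s\t%s\t0", i - 1L, j - 1L,
                         b$anchors$gene_a[j], b$anchors$gene_b[j]), con)
    }
  }
  invisible(path)
}

#' Read an orthoMCL-style orthogroup file
#'
#' One group per line: `GROUP_ID: sp1|gene1 sp1|gene2 sp2|gene3 ...`.
#' The species tag before `|` is split out; an optional second tag
#' (`sp|hap|gene`) is read as the haplotype.
#'
#' @param path Group file path.
#' @return `data.table` with `group_id`, `species`, `haplotype`, `gene_id`.
#' @export
read_orthogroups <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("unrecognized orthogroup line: ", lines[i],
                                 call. = FALSE)
    gid <- trimws(parts[1L])
    members <- strsplit(trimws(paste(parts[-1L], collapse = ":")), "\\s+")[[1L]]
    tags <- strsplit(members, "|", fixed = TRUE)
    out[[i]] <- data.table::data.table(
      group_id = gid,
      species = vapply(tags, function(t) if (length(t) >= 2L) t[1L] else "unknown", ""),
      haplotype = vapply(tags, function(t) if (length(t) >= 3L) t[2L] else "unassigned", ""),
      gene_id = vapply(tags, function(t) t[length(t)], "")
    )
  }
  dt <- data.table::rbindlist(out)
  if (anyDuplicated(dt$gene_id)) {
    stop("gene assigned to more than one orthogroup: ",
         dt$gene_id[duplicated(dt$gene_id)][1L], call. = FALSE)
  }
  dt[]
}

#' Write an orthoMCL-style orthogroup file
#' @param groups `data.table` as returned by [read_orthogroups()].
#' @param path Output path.
#' @export
write_orthogroups <- function(groups, path) {
  assert_cols(groups, c("group_id", "species", "haplotype", "gene_id"),
              "orthogroup table")
  g <- data.table::as.data.table(groups)
  lines <- g[, .(line = paste0(group_id[1L], ": ",
                               paste(species, haplotype, gene_id,
                                     sep = "|", collapse = " "))),
             by = group_id]$line
  writeLines(lines, path)
  invisible(path)
}
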