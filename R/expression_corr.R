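# Pearson correlation of developmental expression profiles between
# homologous gene pairs, contrasted by genomic region (nSR vs syntenic).

#' Pearson correlation of two expression profiles
#'
#' @param x,y Numeric vectors of equal length >= 3 (one value per
#'   developmental stage). A zero-variance profile yields `NA` (flagged
#'   undefined) rather than an error.
#' @return Product-moment correlation coefficient, or `NA_real_`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("profile length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 stages", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite expression value", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Expression correlation for homolog pairs, tagged by region
#'
#' @param pairs Table with `gene_a`, `gene_b` and a `region` column
#'   (`"nSR"` or `"SR"`).
#' @param mat_a,mat_b Expression matrices (genes x stages, identical stage
#'   columns) holding `gene_a` and `gene_b` profiles respectively.
#' @param log1p Apply `log1p` to both profiles first (default FALSE).
#' @return `data.table` with `gene_a`, `gene_b`, `region`, `r`,
#'   `n_stages`. Pairs with a gene missing from its matrix are skipped
#'   with a warning.
#' @export
pair_correlations <- function(pairs, mat_a, mat_b = mat_a, log1p = FALSE) {
  p <- data.table::as.data.table(pairs)
  assert_cols(p, c("gene_a", "gene_b", "region"), "pairs")
  if (!identical(colnames(mat_a), colnames(mat_b))) {
    stop("stage columns differ between matrices", call. = FALSE)
  }
  ok_a <- p$gene_a %in% rownames(mat_a)
  ok_b <- p$gene_b %in% rownames(mat_b)
  if (any(!ok_a | !ok_b)) {
    miss <- unique(c(p$gene_a[!ok_a], p$gene_b[!ok_b]))
    warning("skipping ", sum(!ok_a | !ok_b), " pair(s) with missing gene(s): ",
            paste(head(miss, 5L), collapse = ", "))
    p <- p[ok_a & ok_b]
  }
  r <- vapply(seq_len(nrow(p)), function(i) {
    x <- mat_a[p$gene_a[i], ]
    y <- mat_b[p$gene_b[i], ]
    if (log1p) { x <- log1p(x); y <- log1p(y) }
    pearson_r(x, y)
  }, 0)
  data.table::data.table(gene_a = p$gene_a, gene_b = p$gene_b,
                         region = p$region, r = r,
                         n_stages = ncol(mat_a))
}

#' Mean expression correlation per region
#'
#' Arithmetic mean of defined `r` values per region; undefined
#' (zero-variance) pairs are excluded and counted.
#'
#' @param correlations Output of [pair_correlations()].
#' @return `data.table` with `region`, `mean_r`, `n_pairs` (defined),
#'   `n_undefined`.
#' @export
summarize_mean_r <- function(correlations) {
  ct <- data.table::as.data.table(correlations)
  assert_cols(ct, c("region", "r"), "correlations")
  ct[, .(mean_r = if (any(!is.na(r))) mean(r, na.rm = TRUE) else NA_real_,
         n_pairs = sum(!is.na(r)),
         n_undefined = sum(is.na(r))),
     by = region]
}
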