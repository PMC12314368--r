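# Exact hypergeometric enrichment/depletion with Benjamini-Hochberg
# adjustment. Tails are summed in log space from binomial coefficients so
# extreme probabilities stay accurate.

#' Exact hypergeometric tail probability
#'
#' With `n` items of a feature among `N` items total, of which `K` lie in
#' the region of interest, the number of feature items in the region is
#' hypergeometric. `tail = "lower"` returns `P(X <= k)` (depletion),
#' `tail = "upper"` returns `P(X >= k)` (enrichment). The tail is an exact
#' log-space sum, not a normal approximation.
#'
#' @param k Feature items observed in the region.
#' @param n Feature items total.
#' @param K All items in the region.
#' @param N All items.
#' @param tail `"lower"` or `"upper"`.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, n, K, N, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N && k <= K)) {
    stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  if (tail == "lower" && k < lo) return(0)   # below the support
  if (tail == "upper" && k > hi) return(0)
  i <- if (tail == "lower") lo:k else k:hi
  logt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logt)
  p <- exp(m + log(sum(exp(logt - m))))
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Feature enrichment/depletion inside nSRs
#'
#' One exact hypergeometric test per feature (features carried by fewer
#' than `min_count` items are not tested), BH-adjusted within the tested
#' family. Items carrying several features count once per feature;
#' repeated occurrences of the same feature on one item count once.
#'
#' @param feature_map Table with columns `item` and `feature` (an item may
#'   appear with several features).
#' @param nsr_flag Named logical vector over all items: `TRUE` = in nSR.
#'   Every mapped item must be flagged.
#' @param tail `"upper"` for enrichment, `"lower"` for depletion.
#' @param min_count Minimum items per feature to test (default 5).
#' @return `data.table` sorted by `q`: `feature`, `k`, `n`, `K`, `N`, `p`,
#'   `q`, `tail`.
#' @export
enrich_features <- function(feature_map, nsr_flag,
                            tail = c("upper", "lower"), min_count = 5L) {
  tail <- match.arg(tail)
  fm <- data.table::as.data.table(feature_map)
  assert_cols(fm, c("item", "feature"), "feature_map")
  empty <- data.table::data.table(feature = character(), k = integer(),
                                  n = integer(), K = integer(), N = integer(),
                                  p = numeric(), q = numeric(),
                                  tail = character())
  if (nrow(fm) == 0L) return(empty)
  fm <- unique(fm[, .(item, feature)])
  miss <- setdiff(fm$item, names(nsr_flag))
  if (length(miss)) stop("unflagged item(s): ",
                         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  N <- length(nsr_flag)
  K <- sum(nsr_flag)
  tab <- fm[, .(n = .N, k = sum(nsr_flag[item])), by = feature]
  tab <- tab[n >= min_count]
  if (nrow(tab) == 0L) return(empty)
  tab[, p := vapply(seq_len(.N),
                    function(i) hypergeom_tail(k[i], n[i], K, N, tail), 0)]
  tab[, q := bh_adjust(p)]
  tab[, `:=`(K = K, N = N, tail = tail)]
  data.table::setorder(tab, q, p, feature)
  tab[, .(feature, k, n, K, N, p, q, tail)]
}
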