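# Internal helpers. Coordinates are 0-based half-open throughout.

# merge possibly overlapping/adjacent [start,end) intervals on one scaffold;
# intervals closer than `gap` are fused. Returns sorted disjoint data.table.
merge_intervals <- function(start, end, gap = 0L) {
  stopifnot(length(start) == length(end), all(end > start))
  if (length(start) == 0L) {
    return(data.table::data.table(start = integer(), end = integer()))
  }
  ir <- IRanges::IRanges(start = start + 1L, end = end)   # to 1-based closed
  red <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
  data.table::data.table(start = IRanges::start(red) - 1L,
                         end = IRanges::end(red))
}

# midpoint of a 0-based half-open interval (floor convention)
interval_mid <- function(start, end) (start + end) %/% 2L

# TRUE for each midpoint that falls inside any [start,end) interval
points_in_intervals <- function(points, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(points)))
  q <- IRanges::IRanges(start = points + 1L, width = 1L)
  s <- IRanges::IRanges(start = start + 1L, end = end)
  IRanges::overlapsAny(q, s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
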