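#' Detect CNV boundaries from a depth profile
#'
#' Operationalizes depth-based boundary calling: the profile is cut into
#' fixed windows; a flank baseline is estimated as the median of window
#' medians outside candidate elevated windows (iterated to a fixed point);
#' maximal runs of windows whose median depth is at least
#' `fold_threshold * baseline` become candidate calls; runs spanning less
#' than `min_span` bp are discarded; and each boundary is refined to the base
#' with the largest depth step within one window of the run edge.
#'
#' @param profile A `DepthProfile` (per-base depth).
#' @param window Window size in bp (>= 1).
#' @param fold_threshold Minimum elevation over baseline (> 1).
#' @param min_span Minimum call span in bp.
#' @return data.frame of calls: `start`, `end`, `fold_median`, `fold_max`,
#'   `baseline`. Zero rows when nothing is elevated (an all-zero profile is
#'   not an error).
#' @export
detect_cnv_boundaries <- function(profile, window = 500L, fold_threshold = 2,
                                  min_span = 5000L) {
  stopifnot(window >= 1, fold_threshold > 1)
  d <- profile$depth
  L <- length(d)
  if (L == 0 || all(d == 0)) {
    return(data.frame(start = integer(), end = integer(),
                      fold_median = numeric(), fold_max = numeric(),
                      baseline = numeric()))
  }
  nw <- ceiling(L / window)
  widx <- rep(seq_len(nw), each = window, length.out = L)
  wmed <- as.numeric(tapply(d, widx, median))
  wstart <- (seq_len(nw) - 1L) * window + 1L
  wend <- pmin(seq_len(nw) * window, L)

  cand <- rep(FALSE, nw)
  for (iter in 1:25) {
    baseline <- median(wmed[!cand])
    if (!is.finite(baseline)) baseline <- median(wmed)
    if (baseline <= 0) {
      newcand <- wmed > 0
    } else {
      newcand <- wmed >= fold_threshold * baseline
    }
    if (identical(newcand, cand)) break
    cand <- newcand
  }
  if (!any(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      fold_median = numeric(), fold_max = numeric(),
                      baseline = numeric()))
  }

  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  calls <- list()
  base_depth <- median(d[!widx %in% which(cand)])
  if (!is.finite(base_depth) || base_depth <= 0) base_depth <- baseline
  for (i in which(runs$values)) {
    s <- wstart[starts[i]]
    e <- wend[ends[i]]
    if (e - s + 1L < min_span) next
    left <- refine_step(d, max(1L, s - window), min(L - 1L, s + window), "up")
    right <- refine_step(d, max(1L, e - window), min(L - 1L, e + window), "down")
    if (right <= left) { left <- s; right <- e }
    inside <- d[left:right]
    calls[[length(calls) + 1L]] <- data.frame(
      start = left, end = right,
      fold_median = median(inside) / base_depth,
      fold_max = max(inside) / base_depth,
      baseline = base_depth)
  }
  if (length(calls) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      fold_median = numeric(), fold_max = numeric(),
                      baseline = numeric()))
  }
  do.call(rbind, calls)
}

# Base of maximal depth step within [lo, hi]: for "up" the first elevated
# base (max of d[i+1] - d[i], boundary i+1); for "down" the last elevated
# base (max of d[i] - d[i+1], boundary i).
refine_step <- function(d, lo, hi, direction) {
  idx <- lo:hi
  step <- d[idx + 1L] - d[idx]
  if (direction == "up") {
    i <- idx[which.max(step)]
    i + 1L
  } else {
    i <- idx[which.max(-step)]
    i
  }
}
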