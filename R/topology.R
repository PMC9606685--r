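## Kyte-Doolittle hydropathy smoothing and transmembrane-segment counting,
## used to segregate 11-TMS from 12-TMS architectures.

.kd <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
         X =  0.0)

#' Smoothed Kyte-Doolittle hydropathy
#'
#' Centered moving average of per-residue Kyte-Doolittle values; windows
#' shrink symmetrically at the sequence ends ('X' scores 0).
#'
#' @param seq Sequence string (or single-row `seq_set`).
#' @param window Window length (odd).
#' @return Numeric vector, one value per residue.
#' @export
hydropathy <- function(seq, window = 19) {
  s <- .as_seqstring(seq)
  v <- unname(.kd[strsplit(s, "")[[1]]])
  n <- length(v)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Count transmembrane segments by hydropathy
#'
#' Maximal runs of smoothed hydropathy at or above `threshold` are the
#' candidate segments; runs separated by at most `merge_gap` positions are
#' merged, then runs shorter than `min_len` are dropped.
#'
#' @param seq Sequence string (or single-row `seq_set`).
#' @param window Kyte-Doolittle window.
#' @param threshold Hydropathy threshold for membrane-spanning character.
#' @param min_len Minimum retained run length.
#' @param merge_gap Maximum below-threshold gap merged into one segment.
#' @return List of class `tms_annotation`: `segments` (data.frame start,
#'   end) and `count`.
#' @export
count_tms <- function(seq, window = 19, threshold = 1.6,
                      min_len = 15, merge_gap = 3) {
  s <- .as_seqstring(seq)
  if (nchar(s) < window)
    warning("sequence shorter than window; using shrunken windows throughout")
  hv <- hydropathy(s, window)
  r <- rle(hv >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg[i, 1] - merged[nrow(merged), 2] - 1 <= merge_gap)
        merged[nrow(merged), 2] <- seg[i, 2]
      else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  if (nrow(seg))
    seg <- seg[seg[, 2] - seg[, 1] + 1 >= min_len, , drop = FALSE]
  structure(list(segments = data.frame(start = seg[, 1], end = seg[, 2]),
                 count = nrow(seg)),
            class = "tms_annotation")
}

#' @export
print.tms_annotation <- function(x, ...) {
  cat("TMS count:", x$count, "\n")
  if (nrow(x$segments)) print(x$segments, row.names = FALSE)
  invisible(x)
}
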