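#' Segment a flow trace into breaths
#'
#' Delimits breaths by signed zero crossings with hysteresis. Inspiration is
#' armed when the flow rises above `+h` and anchored back at the preceding
#' zero crossing (the last non-positive sample); it ends when the flow falls
#' through `-h`, anchored at the preceding zero crossing from positive to
#' negative; expiration runs until the flow next returns to non-negative
#' values. The hysteresis level `h` is `hysteresis_frac` times a running
#' median of `|flow|` (60 s window, computed on a decimated copy of the
#' rectified signal), so thresholds track slow amplitude drift, scale with
#' the signal (segmentation is invariant under rescaling the flow), and do
#' not collapse to zero inside apneic gaps.
#'
#' Candidate breaths shorter than `min_breath_s` or with non-positive tidal
#' volume are merged into their neighbor (the preceding breath's expiration
#' absorbs them; a leading runt is dropped). Samples during which no breath
#' is in progress (apneic gaps) belong to no breath and remain available to
#' the raw-signal apnea scan.
#'
#' Tidal volume is the trapezoidal integral of flow over the inspiratory
#' interval; for a half-sine lobe of amplitude `A` and duration `d` this
#' recovers the closed form `TV = 2 A d / pi`. PIF is the maximum flow in
#' the inspiratory interval, and `ratio_s_per_ml = ti_s / tv_ml` is the
#' quantity the flow-limitation detector thresholds.
#'
#' @param trace A [flow_trace()].
#' @param min_breath_s Minimum breath duration (s); shorter candidates are
#'   merged. Default 0.05 s.
#' @param hysteresis_frac Hysteresis as a fraction of the running median
#'   rectified flow. Default 0.05.
#' @return Data frame with one row per breath: `index` (0-based), `onset_s`,
#'   `ti_s`, `te_s`, `tv_ml`, `pif_ml_s`, `ratio_s_per_ml`. A trace with no
#'   crossings (e.g. all zero) yields zero rows.
#' @export
segment_breaths <- function(trace, min_breath_s = 0.05,
                            hysteresis_frac = 0.05) {
  stopifnot(inherits(trace, "flow_trace"))
  f <- trace$flow
  fs <- trace$sample_rate_hz
  n <- length(f)
  if (fs < 10 * 2)  # fewer than ~10 samples per nominal murine breath
    warning("sample rate may be too low to resolve individual breaths")

  h <- hysteresis_frac * running_median_abs(f, fs, window_s = 60)

  above <- f > h
  below <- f < -h
  s <- integer(n)
  s[above] <- 1L
  s[below] <- -1L
  nz <- which(s != 0L)
  if (length(nz) == 0L) return(empty_breaths())
  sv <- s[nz]
  newblk <- c(TRUE, sv[-1L] != sv[-length(sv)])
  blk_sign <- sv[newblk]
  blk_first <- nz[newblk]

  pos_blk <- which(blk_sign == 1L)
  ## pair each +block with the immediately following -block
  has_down <- pos_blk < length(blk_sign)
  pos_blk <- pos_blk[has_down]
  if (length(pos_blk) == 0L) return(empty_breaths())
  up_trig <- blk_first[pos_blk]
  down_trig <- blk_first[pos_blk + 1L]

  nonpos <- which(f <= 0)
  nonneg <- which(f >= 0)
  ## onset anchor: last non-positive sample at/before the up trigger
  oi <- nonpos[pmax(findInterval(up_trig, nonpos), 1L)]
  oi[findInterval(up_trig, nonpos) < 1L] <- 1L
  ## inspiration end anchor: last non-negative sample before the down trigger
  ei <- nonneg[pmax(findInterval(down_trig - 1L, nonneg), 1L)]
  ## expiration end: first non-negative sample after the down trigger
  pos_after <- findInterval(down_trig, nonneg) + 1L
  xi <- ifelse(pos_after <= length(nonneg), nonneg[pmin(pos_after, length(nonneg))], n)

  ## drop duplicate candidates sharing an onset (re-arming inside one lobe)
  keep <- !duplicated(oi)
  oi <- oi[keep]; ei <- ei[keep]; xi <- xi[keep]

  cs <- cumsum(f)
  tv_of <- function(o, e)  # trapezoid over samples o..e
    ((cs[e] - cs[o]) - (f[e] - f[o]) / 2) / fs

  ## merge runts into the preceding breath's expiration
  m <- length(oi)
  o_k <- integer(0); e_k <- integer(0); x_k <- integer(0)
  for (k in seq_len(m)) {
    dur_k <- (xi[k] - oi[k]) / fs
    tv_k <- tv_of(oi[k], ei[k])
    if (dur_k < min_breath_s || tv_k <= 0) {
      if (length(x_k) > 0L) x_k[length(x_k)] <- xi[k]
      next
    }
    o_k <- c(o_k, oi[k]); e_k <- c(e_k, ei[k]); x_k <- c(x_k, xi[k])
  }
  if (length(o_k) == 0L) return(empty_breaths())

  ## breaths are half-open in time: an expiration may not run past the next
  ## breath's onset sample (boundary samples would otherwise be counted twice)
  if (length(x_k) > 1L)
    x_k[-length(x_k)] <- pmin(x_k[-length(x_k)], o_k[-1L])

  tv <- mapply(tv_of, o_k, e_k)
  pif <- vapply(seq_along(o_k),
                function(k) max(f[o_k[k]:e_k[k]]), 0)
  ti <- (e_k - o_k) / fs
  te <- (x_k - e_k) / fs
  bad <- tv <= 0 | ti <= 0
  o_k <- o_k[!bad]; ti <- ti[!bad]; te <- te[!bad]
  tv <- tv[!bad]; pif <- pif[!bad]

  data.frame(index = seq_along(o_k) - 1L,
             onset_s = trace$start_time_s + (o_k - 1L) / fs,
             ti_s = ti, te_s = te, tv_ml = tv, pif_ml_s = pif,
             ratio_s_per_ml = ti / tv)
}

empty_breaths <- function() {
  data.frame(index = integer(0), onset_s = numeric(0), ti_s = numeric(0),
             te_s = numeric(0), tv_ml = numeric(0), pif_ml_s = numeric(0),
             ratio_s_per_ml = numeric(0))
}

## running median of |flow|, computed on a decimated copy for speed
running_median_abs <- function(f, fs, window_s = 60) {
  n <- length(f)
  dec <- max(1L, floor(fs / 50))  # ~50 Hz is ample for an amplitude envelope
  fa <- abs(f[seq(1L, n, by = dec)])
  k <- min(length(fa), round(window_s * fs / dec))
  if (k %% 2 == 0) k <- k - 1L
  if (k < 3) return(rep(stats::median(fa), n))
  med <- stats::runmed(fa, k, endrule = "median")
  med[pmin(ceiling(seq_len(n) / dec), length(med))]
}
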