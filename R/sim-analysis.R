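# Trajectory post-processing: bundle-episode detection on the normalised
# circumferential alignment, width-alignment cross-correlation lag, and
# per-run summaries.

#' Detect bundle episodes in an alignment series
#'
#' A bundle episode is a maximal interval during which the normalised
#' central-region circumferential alignment Nx^2 / S exceeds `threshold`
#' for at least `minDuration`. The normalised statistic is scale-free
#' (isotropic networks sit at 0.5, perfect circumferential bundles at 1).
#' Episodes separated by less than `mergeGap` are merged.
#'
#' @param nx2 numeric, Nx^2 series (central region).
#' @param s numeric, segment-count series (same length).
#' @param times numeric, record times (s).
#' @param threshold normalised-alignment threshold; default 0.65.
#' @param minDuration minimum episode duration (s); default 60.
#' @param mergeGap gaps shorter than this are bridged (s); default 0.
#' @return data.frame with columns `tStart`, `tEnd`, `peak` (max Nx^2/S);
#'   zero rows when no episode qualifies. Episodes are disjoint and ordered.
#' @export
detectBundleEpisodes <- function(nx2, s, times, threshold = 0.65,
                                 minDuration = 60, mergeGap = 0) {
  stopifnot(length(nx2) == length(s), length(nx2) == length(times))
  frac <- ifelse(s > 0, nx2 / s, 0)
  above <- frac > threshold
  if (!any(above))
    return(data.frame(tStart = numeric(0), tEnd = numeric(0),
                      peak = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  # merge across short gaps
  if (mergeGap > 0 && nrow(iv) > 1) {
    keep <- list(iv[1, ])
    for (k in 2:nrow(iv)) {
      last <- keep[[length(keep)]]
      if (times[iv[k, 1]] - times[last[2]] <= mergeGap)
        keep[[length(keep)]] <- c(last[1], iv[k, 2])
      else keep[[length(keep) + 1]] <- iv[k, ]
    }
    iv <- do.call(rbind, keep)
  }
  out <- data.frame(tStart = times[iv[, 1]], tEnd = times[iv[, 2]],
                    peak = apply(iv, 1, function(j)
                      max(frac[j[1]:j[2]])))
  out[out$tEnd - out$tStart >= minDuration, , drop = FALSE]
}

#' Lag between vessel width and circumferential alignment
#'
#' Both series are linearly detrended (slow drift from filament turnover
#' would otherwise bias the estimate) and their normalised cross-correlation
#' is scanned up to `maxLag`; the lag of the most negative correlation is
#' reported, with positive lag meaning alignment leads width. The expected
#' signature of bundle-driven constriction is a negative correlation at
#' positive lag.
#'
#' @param traj a [CortexTrajectory-class] from a deformable-membrane run.
#' @param maxLag maximum |lag| scanned (s); default 600.
#' @return A list: `lag` (s; positive = alignment leads), `correlation`,
#'   plus the full `lags` / `r` scan from [crosscorrLag()].
#' @export
widthAlignmentLag <- function(traj, maxLag = 600) {
  stopifnot(is(traj, "CortexTrajectory"))
  if (traj@params@boundaryMode != "deformable_membrane")
    stop("width-alignment lag needs a deformable-membrane run")
  tt <- traj@times
  if (length(tt) < 12) stop("insufficient samples")
  al <- traj@alignment
  frac <- ifelse(al$SCentral > 0, al$Nx2Central / al$SCentral, 0.5)
  dt <- stats::median(diff(tt))
  # band-pass to the episode scale: 30 s smoothing against frame noise and
  # subtraction of a 600 s rolling mean against slow drift (drift from
  # turnover and network coarsening otherwise dominates the lag scan),
  # then linear detrending
  k <- max(1L, round(30 / dt))
  kHp <- max(k + 1L, round(1200 / dt))
  bandpass <- function(v) {
    v <- rollMean(v, k)
    v - rollMean(v, kHp)
  }
  a <- detrendLinear(tt, bandpass(frac))          # alignment first:
  b <- detrendLinear(tt, bandpass(traj@width))    # positive lag = leads
  res <- crosscorrLag(a, b, maxLag = min(maxLag, (length(tt) / 2 - 1) * dt),
                      which = "min", dt = dt)
  res
}

#' Summarise a simulation run
#'
#' Episode count, episode-averaged vs outside-episode stress anisotropy
#' (sxx - syy, central region), minimum width, and the width-alignment lag
#' for deformable runs. Deterministic given the trajectory.
#'
#' @param traj a [CortexTrajectory-class].
#' @param threshold,minDuration passed to [detectBundleEpisodes()].
#' @param maxLag passed to [widthAlignmentLag()] (deformable runs only).
#' @param burnIn seconds discarded from the start for the stress averages;
#'   default 60.
#' @return A one-row data.frame: `nEpisodes`, `anisotropyInEpisodes`,
#'   `anisotropyOutside`, `anisotropyOverall`, `minWidth`, `initialWidth`,
#'   `lag`, `correlation` (lag fields `NA` for fixed walls; episode fields
#'   `NA` when there are no episodes).
#' @export
summarizeRun <- function(traj, threshold = 0.65, minDuration = 60,
                         maxLag = 600, burnIn = 60) {
  stopifnot(is(traj, "CortexTrajectory"))
  tt <- traj@times
  al <- traj@alignment
  ep <- detectBundleEpisodes(al$Nx2Central, al$SCentral, tt,
                             threshold = threshold,
                             minDuration = minDuration)
  aniso <- traj@stress$sxx - traj@stress$syy
  inEp <- rep(FALSE, length(tt))
  for (k in seq_len(nrow(ep)))
    inEp <- inEp | (tt >= ep$tStart[k] & tt <= ep$tEnd[k])
  keep <- tt >= burnIn
  lag <- corr <- NA_real_
  if (traj@params@boundaryMode == "deformable_membrane" &&
      length(tt) >= 12) {
    wl <- widthAlignmentLag(traj, maxLag = maxLag)
    lag <- wl$lag; corr <- wl$correlation
  }
  data.frame(
    nEpisodes = nrow(ep),
    anisotropyInEpisodes = if (any(inEp & keep)) mean(aniso[inEp & keep])
                           else NA_real_,
    anisotropyOutside = if (any(!inEp & keep)) mean(aniso[!inEp & keep])
                        else NA_real_,
    anisotropyOverall = mean(aniso[keep]),
    minWidth = min(traj@width),
    initialWidth = traj@width[1],
    lag = lag, correlation = corr)
}
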