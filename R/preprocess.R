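#' Time-window specification
#'
#' Windows are half-open `[t_start, t_end)` in seconds, with 0-based
#' sample indexing. The default motor-imagery analysis window covers
#' 2.5-6 s of the trial timing scheme.
#'
#' @param t_start,t_end window bounds in seconds (`t_end > t_start`).
#' @param name optional label (e.g. `"T3"`).
#' @return a list of class `"WindowSpec"`.
#' @export
windowSpec <- function(t_start, t_end, name = "") {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  structure(list(t_start = t_start, t_end = t_end, name = name),
            class = "WindowSpec")
}

#' Multi-scale filter-bank specification
#'
#' The analysis range `[f_lo, f_hi]` is tiled, for each requested
#' bandwidth `w`, into contiguous bands `[f_lo + k w, f_lo + (k+1) w]`
#' truncated at `f_hi`; a truncated final tile is kept iff its width is
#' at least `w/2`. The default widths 2/4/8/16/32 Hz over 4-40 Hz give 35
#' bands (18 + 9 + 5 + 2 + 1). Filters are second-order Butterworth
#' band-pass designs applied forward-backward (zero phase).
#'
#' @param bandwidths band widths in Hz.
#' @param f_lo,f_hi edges of the analysis range (Hz), `f_lo < f_hi`.
#' @param order Butterworth design order (`>= 1`).
#' @return a list of class `"FilterBankSpec"`.
#' @export
filterBankSpec <- function(bandwidths = c(2, 4, 8, 16, 32),
                           f_lo = 4, f_hi = 40, order = 2L) {
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (order < 1L) stop("order must be >= 1")
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  structure(list(bandwidths = sort(bandwidths), f_lo = f_lo, f_hi = f_hi,
                 order = as.integer(order)),
            class = "FilterBankSpec")
}

#' Derive the band edges of a filter bank
#'
#' @param spec a [filterBankSpec()].
#' @return a data.frame with columns `width`, `low`, `high`, sorted by
#'   `(width, low)`; every band lies within `[f_lo, f_hi]`.
#' @examples
#' nrow(buildBands(filterBankSpec()))  # 35
#' @export
buildBands <- function(spec) {
  stopifnot(inherits(spec, "FilterBankSpec"))
  out <- lapply(spec$bandwidths, function(w) {
    lows <- seq(spec$f_lo, spec$f_hi - 1e-9, by = w)
    highs <- pmin(lows + w, spec$f_hi)
    keep <- (highs - lows) >= w / 2
    data.frame(width = w, low = lows[keep], high = highs[keep])
  })
  out <- do.call(rbind, out)
  out[order(out$width, out$low), , drop = FALSE]
}

# Zero-phase Butterworth band-pass: forward-backward filtering with odd
# reflective padding of 3x the filter length to suppress edge transients.
butterBandpass <- function(x, low, high, fs, order = 2L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- length(x)
  nfact <- 3L * (max(length(bf$a), length(bf$b)) - 1L)
  if (n <= nfact + 1L)
    stop("signal too short for edge padding")
  xpad <- c(2 * x[1L] - x[(nfact + 1L):2L],
            x,
            2 * x[n] - x[(n - 1L):(n - nfact)])
  yf <- signal::filter(bf, xpad)
  yb <- rev(signal::filter(bf, rev(yf)))
  as.numeric(yb[(nfact + 1L):(nfact + n)])
}

#' Extract a time window from every trial
#'
#' Windows are half-open `[t_start, t_end)`: the output keeps the
#' `floor((t_end - t_start) * fs)` samples starting at time `t_start`.
#' Labels and sampling rate are preserved; the output `t0` equals
#' `t_start`.
#'
#' @param trials a [TrialSet-class].
#' @param window a [windowSpec()].
#' @return a [TrialSet-class] restricted to the window.
#' @examples
#' ts <- TrialSet(array(rnorm(2 * 2 * 250), c(2, 2, 250)), fs = 100,
#'                labels = c(1L, 2L))
#' nSamples(extractWindow(ts, windowSpec(0.5, 1.5)))  # 100
#' @export
extractWindow <- function(trials, window) {
  stopifnot(is(trials, "TrialSet"), inherits(window, "WindowSpec"))
  fs <- trials@fs
  i0 <- as.integer(round((window$t_start - trials@t0) * fs))
  nOut <- as.integer(floor((window$t_end - window$t_start) * fs + 1e-9))
  nS <- nSamples(trials)
  if (i0 < 0L || i0 + nOut > nS) {
    stop(sprintf(
      "window [%g, %g) s outside recorded span [%g, %g) s",
      window$t_start, window$t_end, trials@t0, trials@t0 + nS / fs))
  }
  TrialSet(trials@data[, , (i0 + 1L):(i0 + nOut), drop = FALSE],
           fs = fs, labels = trials@labels, t0 = window$t_start,
           channelNames = trials@channelNames)
}

#' Apply a multi-scale band-pass filter bank
#'
#' Filters every channel of every trial with a zero-phase (forward-
#' backward) Butterworth band-pass per band of the bank. Each output
#' TrialSet has the same shape, labels and sampling metadata as the
#' input.
#'
#' @param trials a [TrialSet-class].
#' @param spec a [filterBankSpec()]; requires `f_hi < fs/2`.
#' @return a named list of [TrialSet-class] objects, one per band, in
#'   [buildBands()] order; names are `"low-high"` in Hz. The band table
#'   is attached as attribute `"bands"`.
#' @export
filterBank <- function(trials, spec) {
  stopifnot(is(trials, "TrialSet"), inherits(spec, "FilterBankSpec"))
  fs <- trials@fs
  if (spec$f_hi >= fs / 2)
    stop("f_hi must be below the Nyquist frequency fs/2")
  bands <- buildBands(spec)
  d <- trials@data
  nT <- dim(d)[1L]; nC <- dim(d)[2L]
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    fd <- d
    for (tr in seq_len(nT)) {
      for (ch in seq_len(nC)) {
        fd[tr, ch, ] <- butterBandpass(d[tr, ch, ], bands$low[b],
                                       bands$high[b], fs, spec$order)
      }
    }
    out[[b]] <- TrialSet(fd, fs = fs, labels = trials@labels,
                         t0 = trials@t0,
                         channelNames = trials@channelNames)
  }
  names(out) <- sprintf("%g-%g", bands$low, bands$high)
  attr(out, "bands") <- bands
  out
}
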