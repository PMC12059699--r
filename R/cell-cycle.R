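# EdU/DAPI cell-cycle gating: DNA-stain intensity separates 2n (G0/G1) from
# 4n (G2/M); EdU incorporation marks replicating (S-phase) cells and takes
# precedence over the DNA gates.

#' Locate the 2n and 4n DNA-content modes and derive gate boundaries
#'
#' A kernel density estimate of the DNA intensities is scanned for local
#' maxima; the two dominant modes must sit at a 4n/2n ratio inside
#' `ratio_range` (around the ideal 2). Per mode, the half-width at
#' half-maximum is converted to a Gaussian sigma
#' (`sigma = HWHM / sqrt(2 log 2)`) and the gate spans `mode +/- 3 sigma`;
#' the G1/G2 divide is the geometric mean of the two modes, which caps the
#' inner gate edges.
#'
#' @param dna_intensity positive numeric vector (>= 200 events).
#' @param ratio_range admissible 4n/2n mode ratio.
#' @return list: `mode_2n`, `mode_4n`, `sigma_2n`, `sigma_4n`, `divide`,
#'   `gate_2n` (`c(lo, hi)`), `gate_4n`.
#' @export
fit_dna_modes <- function(dna_intensity, ratio_range = c(1.7, 2.3)) {
  x <- dna_intensity[is.finite(dna_intensity) & dna_intensity > 0]
  if (length(x) < 200L) stop("need at least 200 events to fit DNA modes")
  d <- stats::density(x, n = 2048L)
  y <- d$y
  peaks <- which(y > c(y[-1L], -Inf) & y > c(-Inf, y[-length(y)]))
  if (length(peaks) < 2L)
    stop("DNA modes not found (single-mode data); supply manual boundaries")
  # candidate pair: the highest peak plus the best partner near double/half
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  main <- peaks[1L]
  partner <- NA_integer_
  for (p in peaks[-1L]) {
    r <- max(d$x[p], d$x[main]) / min(d$x[p], d$x[main])
    if (r >= ratio_range[1L] && r <= ratio_range[2L]) { partner <- p; break }
  }
  if (is.na(partner))
    stop(sprintf("no pair of DNA modes with ratio in [%.2f, %.2f]; supply manual boundaries",
                 ratio_range[1L], ratio_range[2L]))
  lo_peak <- min(d$x[main], d$x[partner])
  hi_peak <- max(d$x[main], d$x[partner])
  hwhm <- function(peak_idx) {
    half <- y[peak_idx] / 2
    l <- peak_idx; while (l > 1L && y[l] > half) l <- l - 1L
    r <- peak_idx; while (r < length(y) && y[r] > half) r <- r + 1L
    min(d$x[peak_idx] - d$x[l], d$x[r] - d$x[peak_idx])
  }
  i2 <- if (d$x[main] <= d$x[partner]) main else partner
  i4 <- if (d$x[main] <= d$x[partner]) partner else main
  s2 <- hwhm(i2) / sqrt(2 * log(2))
  s4 <- hwhm(i4) / sqrt(2 * log(2))
  divide <- sqrt(lo_peak * hi_peak)
  list(mode_2n = lo_peak, mode_4n = hi_peak, sigma_2n = s2, sigma_4n = s4,
       divide = divide,
       gate_2n = c(lo_peak - 3 * s2, min(lo_peak + 3 * s2, divide)),
       gate_4n = c(max(hi_peak - 3 * s4, divide), hi_peak + 3 * s4))
}

#' EdU positivity threshold
#'
#' The 99.5th percentile of an EdU-negative control sample when one is
#' provided; otherwise the deepest density valley between the two modes of
#' the (log-scale) EdU intensity distribution.
#'
#' @param edu_intensity EdU intensities of the sample to gate.
#' @param negative_control optional EdU intensities of a no-EdU control.
#' @param q control quantile (default 0.995).
#' @return the threshold (single number).
#' @export
edu_threshold <- function(edu_intensity, negative_control = NULL, q = 0.995) {
  if (!is.null(negative_control))
    return(unname(stats::quantile(negative_control, q)))
  lx <- log(edu_intensity[edu_intensity > 0])
  d <- stats::density(lx, n = 1024L)
  y <- d$y
  peaks <- which(y > c(y[-1L], -Inf) & y > c(-Inf, y[-length(y)]))
  if (length(peaks) < 2L)
    stop("EdU distribution is not bimodal; supply a negative control")
  peaks <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  valley <- lo + which.min(y[lo:hi]) - 1L
  exp(d$x[valley])
}

#' Classify events into cell-cycle phases and report phase percentages
#'
#' EdU above the threshold assigns S phase regardless of DNA content;
#' otherwise events inside the 2n gate are G0/G1 and events inside the 4n
#' gate are G2/M. Everything else is counted as unclassified; percentages
#' are over classified events and sum to 100.
#'
#' @param dna_intensity,edu_intensity per-event intensities.
#' @param boundaries output of [fit_dna_modes()] (or a list with `gate_2n`,
#'   `gate_4n`).
#' @param edu_thr EdU positivity threshold.
#' @return a `PhaseFractions` list: `pct_g0g1`, `pct_s`, `pct_g2m`,
#'   `n_events`, `n_classified`, `n_unclassified`.
#' @export
classify_events <- function(dna_intensity, edu_intensity, boundaries, edu_thr) {
  stopifnot(length(dna_intensity) == length(edu_intensity))
  s_phase <- edu_intensity > edu_thr
  g1 <- !s_phase & dna_intensity >= boundaries$gate_2n[1L] &
    dna_intensity <= boundaries$gate_2n[2L]
  g2 <- !s_phase & dna_intensity >= boundaries$gate_4n[1L] &
    dna_intensity <= boundaries$gate_4n[2L]
  n_class <- sum(s_phase) + sum(g1) + sum(g2)
  if (n_class == 0L) stop("no classifiable events")
  structure(list(pct_g0g1 = 100 * sum(g1) / n_class,
                 pct_s = 100 * sum(s_phase) / n_class,
                 pct_g2m = 100 * sum(g2) / n_class,
                 n_events = length(dna_intensity),
                 n_classified = n_class,
                 n_unclassified = length(dna_intensity) - n_class),
            class = "PhaseFractions")
}

#' @export
print.PhaseFractions <- function(x, ...) {
  cat(sprintf("Phases: G0/G1 %.1f%%, S %.1f%%, G2/M %.1f%% (%d events, %d unclassified)\n",
              x$pct_g0g1, x$pct_s, x$pct_g2m, x$n_events, x$n_unclassified))
  invisible(x)
}

#' Gate one event table end to end
#'
#' Fits the DNA modes, derives the EdU threshold (from a negative control if
#' given, otherwise from the EdU mixture) and classifies all events.
#'
#' @param events data.frame with `dna_intensity`, `edu_intensity`.
#' @param negative_control optional EdU-negative control intensities.
#' @return `PhaseFractions`.
#' @export
run_cell_cycle <- function(events, negative_control = NULL) {
  b <- fit_dna_modes(events$dna_intensity)
  thr <- edu_threshold(events$edu_intensity, negative_control)
  classify_events(events$dna_intensity, events$edu_intensity, b, thr)
}
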