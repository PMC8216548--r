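# Expectation templates: background rate plus Gaussian peaks over phase.

#' Construct a Gaussian expectation peak
#'
#' A peak encodes the expectation that an event occurs near phase `phi`,
#' with temporal variance `v` (so `1/v` is the temporal precision of the
#' expectation) and strength `lam` (the scale of its contribution to the
#' event rate).
#'
#' @param phi Expected event phase (phase units; here seconds at nominal
#'   tempo).
#' @param v Temporal variance of the expectation (phase units squared).
#'   Must be positive.
#' @param lam Expectation strength (dimensionless scale). Must be
#'   non-negative.
#' @return A `gaussian_peak` object (named list with `phi`, `v`, `lam`).
#' @export
#' @examples
#' gaussian_peak(phi = 0.5, v = 0.01, lam = 1)
gaussian_peak <- function(phi, v, lam) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("peak variance 'v' must be a positive finite number")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("peak strength 'lam' must be a non-negative finite number")
  structure(list(phi = phi, v = v, lam = lam), class = "gaussian_peak")
}

#' Construct an expectation template
#'
#' An expectation template is the phase-dependent event rate
#' \deqn{\lambda(\phi) = \lambda_0 + \sum_i \lambda_i \,
#'   \varphi(\phi \mid \phi_i, v_i)}
#' where \eqn{\varphi} is the Gaussian density: a uniform background rate
#' `lambda_0` plus Gaussian peaks at the phases where events are expected.
#' If `period` is given, the peak set is understood to repeat with that
#' period over the whole real line (periodic rhythmic expectations);
#' otherwise the template is aperiodic and the listed peaks are all there
#' is.
#'
#' @param lambda_0 Background event rate (events per unit phase, >= 0).
#' @param peaks A list of [gaussian_peak()] objects, or a data.frame with
#'   columns `phi`, `v`, `lam`. Peak means must be strictly increasing;
#'   for periodic templates they must lie in `[0, period)`.
#' @param period Optional repetition period (phase units, > 0).
#' @return An `expectation_template` object.
#' @seealso [evaluate_rate()], [make_isochronous_template()],
#'   [make_swing_template()], [tile_periodic()]
#' @export
expectation_template <- function(lambda_0, peaks = list(), period = NULL) {
  if (!is.numeric(lambda_0) || length(lambda_0) != 1L || !is.finite(lambda_0) ||
      lambda_0 < 0)
    stop("'lambda_0' must be a non-negative finite number")
  if (is.data.frame(peaks)) {
    stopifnot(all(c("phi", "v", "lam") %in% names(peaks)))
    pk <- peaks[, c("phi", "v", "lam"), drop = FALSE]
  } else {
    stopifnot(is.list(peaks))
    pk <- data.frame(
      phi = vapply(peaks, function(p) p$phi, numeric(1)),
      v   = vapply(peaks, function(p) p$v, numeric(1)),
      lam = vapply(peaks, function(p) p$lam, numeric(1))
    )
  }
  if (nrow(pk) > 0) {
    if (any(pk$v <= 0)) stop("all peak variances must be positive")
    if (any(pk$lam < 0)) stop("all peak strengths must be non-negative")
    if (is.unsorted(pk$phi, strictly = TRUE))
      stop("peak means must be strictly increasing")
  }
  if (!is.null(period)) {
    if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
        period <= 0)
      stop("'period' must be a positive finite number")
    if (nrow(pk) > 0 && (any(pk$phi < 0) || any(pk$phi >= period)))
      stop("for a periodic template all peak means must lie in [0, period)")
  }
  rownames(pk) <- NULL
  structure(list(lambda_0 = lambda_0, peaks = pk, period = period),
            class = "expectation_template")
}

#' @export
print.expectation_template <- function(x, ...) {
  cat("<expectation_template>\n")
  cat("  lambda_0:", x$lambda_0, "\n")
  cat("  period:  ", if (is.null(x$period)) "none (aperiodic)" else x$period, "\n")
  cat("  peaks:   ", nrow(x$peaks), "\n")
  if (nrow(x$peaks) > 0) print(utils::head(x$peaks, 10))
  invisible(x)
}

is_periodic <- function(template) !is.null(template$period)

# All peak copies (tiled for periodic templates) whose mean lies within
# [lo - 8*sqrt(v + spread), hi + 8*sqrt(v + spread)] of the query window.
# `spread` widens the relevance window by the belief variance so that
# subjective-hazard computations keep every peak that matters. Returns a
# data.frame(phi, v, lam). Truncation at 8 sd keeps relative error below
# float precision (~1e-15 of the peak's own scale).
relevant_peaks <- function(template, lo, hi, spread = 0) {
  pk <- template$peaks
  if (nrow(pk) == 0)
    return(pk)
  half <- 8 * sqrt(pk$v + spread)
  if (!is_periodic(template)) {
    keep <- pk$phi >= lo - half & pk$phi <= hi + half
    return(pk[keep, , drop = FALSE])
  }
  P <- template$period
  out <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    k_lo <- ceiling((lo - half[i] - pk$phi[i]) / P)
    k_hi <- floor((hi + half[i] - pk$phi[i]) / P)
    if (k_hi < k_lo) next
    ks <- seq.int(k_lo, k_hi)
    out[[i]] <- data.frame(phi = pk$phi[i] + ks * P, v = pk$v[i],
                           lam = pk$lam[i])
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(pk[0, , drop = FALSE])
  out <- out[order(out$phi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate the expectation template rate
#'
#' Computes \eqn{\lambda(\phi)} at the given phases. For periodic
#' templates the Gaussian mixture is summed over all periodic copies of
#' each peak within 8 standard deviations of the query phase (copies
#' beyond that contribute below float precision).
#'
#' @param template An [expectation_template()].
#' @param phase Numeric vector of phases.
#' @return Numeric vector of non-negative rates, same length as `phase`.
#' @export
#' @examples
#' tpl <- expectation_template(0.5, list(gaussian_peak(0.5, 0.01, 1)))
#' evaluate_rate(tpl, c(0.5, 0.4))
evaluate_rate <- function(template, phase) {
  stopifnot(inherits(template, "expectation_template"), is.numeric(phase))
  if (length(phase) == 0) return(numeric(0))
  pk <- relevant_peaks(template, min(phase), max(phase))
  out <- rep(template$lambda_0, length(phase))
  for (i in seq_len(nrow(pk))) {
    out <- out + pk$lam[i] * stats::dnorm(phase, pk$phi[i], sqrt(pk$v[i]))
  }
  out
}

#' Unroll a periodic template over a phase window
#'
#' Converts a periodic template into an equivalent aperiodic one whose
#' peaks are all the periodic copies needed to evaluate the rate on
#' `[phase_lo, phase_hi]` to within truncation tolerance (copies within an
#' 8-standard-deviation margin of the window are kept).
#'
#' @param template A periodic [expectation_template()].
#' @param phase_lo,phase_hi Window bounds, `phase_lo < phase_hi`.
#' @return An aperiodic `expectation_template`.
#' @export
tile_periodic <- function(template, phase_lo, phase_hi) {
  stopifnot(inherits(template, "expectation_template"))
  if (!is_periodic(template))
    stop("'template' has no period; tile_periodic() needs a periodic template")
  if (!(phase_lo < phase_hi)) stop("'phase_lo' must be < 'phase_hi'")
  pk <- relevant_peaks(template, phase_lo, phase_hi)
  expectation_template(template$lambda_0, pk, period = NULL)
}

#' Isochronous (metronomic) expectation template
#'
#' Peaks of equal strength and variance at `0, period, 2*period, ...`.
#'
#' @param period Inter-peak interval (seconds at nominal tempo, > 0).
#' @param n Number of peaks (aperiodic template with peaks
#'   `0, ..., (n-1)*period`), or `NULL` for a periodic template with a
#'   single peak at 0 repeating with `period`.
#' @param strength Expectation strength of each peak.
#' @param variance Temporal variance of each peak (> 0).
#' @param lambda_0 Background rate.
#' @return An `expectation_template`.
#' @export
#' @examples
#' make_isochronous_template(0.5, n = 4, strength = 1, variance = 0.001)
make_isochronous_template <- function(period, n = NULL, strength = 1,
                                      variance = 0.001, lambda_0 = 0) {
  if (!is.numeric(period) || period <= 0) stop("'period' must be positive")
  if (variance <= 0) stop("'variance' must be positive")
  if (is.null(n)) {
    expectation_template(
      lambda_0,
      data.frame(phi = 0, v = variance, lam = strength),
      period = period
    )
  } else {
    stopifnot(n >= 1)
    expectation_template(
      lambda_0,
      data.frame(phi = period * (seq_len(n) - 1), v = variance,
                 lam = strength),
      period = NULL
    )
  }
}

#' Swung eighth-note expectation template
#'
#' A grid of alternating strong and weak expectation peaks emulating
#' "swung" eighth notes: each pair of eighth notes spans one `cycle`, the
#' strong peak opens the pair and the weak peak divides the cycle in the
#' given swing ratio. For a ratio `a:b` the weak peak sits `a/(a+b) *
#' cycle` after the strong one (ratio 3:2 puts it at 0.6 of the cycle —
#' long-short). Strong peaks carry stronger, more precise expectations
#' than weak ones.
#'
#' @param cycle Duration of one eighth-note pair (seconds, > 0).
#' @param swing_ratio Length-2 numeric `c(a, b)`, the long:short split of
#'   the cycle. Both entries must be positive.
#' @param strong Named list or vector with `lam` and `v` for strong peaks.
#' @param weak Same for weak peaks.
#' @param lambda_0 Background rate.
#' @param n_cycles Number of cycles (aperiodic), or `NULL` for a periodic
#'   template of period `cycle`.
#' @return An `expectation_template`.
#' @export
#' @examples
#' make_swing_template(1, c(3, 2),
#'   strong = list(lam = 1, v = 0.001),
#'   weak = list(lam = 0.5, v = 0.003))
make_swing_template <- function(cycle, swing_ratio = c(3, 2),
                                strong = list(lam = 1, v = 0.0005),
                                weak = list(lam = 0.4, v = 0.002),
                                lambda_0 = 0, n_cycles = NULL) {
  if (!is.numeric(cycle) || cycle <= 0) stop("'cycle' must be positive")
  swing_ratio <- as.numeric(swing_ratio)
  if (length(swing_ratio) != 2L || any(!is.finite(swing_ratio)) ||
      any(swing_ratio <= 0))
    stop("'swing_ratio' must be two positive numbers (long:short)")
  frac <- swing_ratio[1] / sum(swing_ratio)
  if (frac >= 1 || frac <= 0) stop("degenerate swing ratio")
  strong <- as.list(strong); weak <- as.list(weak)
  one_cycle <- data.frame(
    phi = c(0, frac * cycle),
    v   = c(strong$v, weak$v),
    lam = c(strong$lam, weak$lam)
  )
  if (is.null(n_cycles)) {
    expectation_template(lambda_0, one_cycle, period = cycle)
  } else {
    stopifnot(n_cycles >= 1)
    pk <- do.call(rbind, lapply(seq_len(n_cycles) - 1, function(k) {
      data.frame(phi = one_cycle$phi + k * cycle, v = one_cycle$v,
                 lam = one_cycle$lam)
    }))
    expectation_template(lambda_0, pk, period = NULL)
  }
}

#' Write a template to a key-value text file
#'
#' One JSON document per template with fields `lambda_0`, `period`
#' (omitted when aperiodic) and `peaks` (array of `{phi, v, lam}`).
#' Numbers are written at full precision so decimal inputs round-trip
#' bit-exactly.
#'
#' @param template An [expectation_template()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "expectation_template"))
  doc <- list(lambda_0 = template$lambda_0)
  if (is_periodic(template)) doc$period <- template$period
  doc$peaks <- lapply(seq_len(nrow(template$peaks)), function(i) {
    list(phi = template$peaks$phi[i], v = template$peaks$v[i],
         lam = template$peaks$lam[i])
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a template written by [write_template()]
#'
#' @param path File path.
#' @return An `expectation_template`.
#' @export
read_template <- function(path) {
  doc <- jsonlite::read_json(path)
  peaks <- if (length(doc$peaks) == 0) {
    data.frame(phi = numeric(0), v = numeric(0), lam = numeric(0))
  } else {
    do.call(rbind, lapply(doc$peaks, function(p)
      data.frame(phi = p$phi, v = p$v, lam = p$lam)))
  }
  expectation_template(doc$lambda_0, peaks, period = doc$period)
}
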