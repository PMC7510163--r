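#' @title QC metrics from a cross-correlation profile
#' @name metrics
#' @description
#' Quantities extracted from a merged NCC/MSCC profile: the fragment length
#' (argmax shift outside the read-length phantom window), the enriched
#' region width via the FWHM of the fragment-length peak, the virtual
#' signal-to-noise metric VSN = (2w/M) * max(MSCC), and the legacy NSC/RSC
#' ratios.
NULL

merged_or_stop <- function(profile) {
  stopifnot(inherits(profile, "CCProfile"))
  if (is.null(profile$merged)) profile <- merge_profiles(profile)
  profile
}

#' Estimate the mean fragment length from a profile
#'
#' The profile maximum is typically at the mean fragment length, but NCC
#' profiles carry a second, spurious maximum at the read length R (the
#' "phantom" peak). Shifts within `exclusion_halfwidth` of R are therefore
#' excluded from the argmax for NCC; MSCC removes the phantom by
#' construction, so exclusion is optional there (kept on by default for
#' uniformity).
#'
#' @param profile A merged `CCProfile` defined on at least 10 shifts.
#' @param R Read length (default: profile metadata).
#' @param exclusion_halfwidth Half-width of the phantom exclusion window
#'   around R, in bp (default 10).
#' @param exclude_phantom Apply the exclusion window (default `TRUE`).
#' @return The shift (bp) maximising the merged coefficient; ties break
#'   toward the smallest shift.
#' @export
estimate_fragment_length <- function(profile, R = profile$read_length,
                                     exclusion_halfwidth = 10,
                                     exclude_phantom = TRUE) {
  profile <- merged_or_stop(profile)
  ok <- !is.na(profile$merged)
  if (sum(ok) < 10) stop("merged profile must be defined on at least 10 shifts")
  if (exclude_phantom)
    ok <- ok & (profile$shifts < R - exclusion_halfwidth |
                profile$shifts > R + exclusion_halfwidth)
  if (!any(ok)) stop("phantom exclusion removed every shift")
  cand <- which(ok)
  profile$shifts[cand[which.max(profile$merged[cand])]]
}

#' Estimate the enriched-region width from the peak FWHM
#'
#' Under the model the fragment-length peak is triangular with base width
#' 2w, so its full width at half maximum approximates w. The half-maximum
#' level is `baseline + (peak - baseline)/2`, with the baseline taken as
#' the minimum of the merged profile over the computed shift range; the
#' two crossings are located by linear interpolation between adjacent
#' shifts.
#'
#' @param profile A merged `CCProfile`.
#' @param peak_shift The peak position (default: [estimate_fragment_length()]).
#' @param ... Passed on to [estimate_fragment_length()].
#' @return The FWHM in bp.
#' @export
estimate_w_fwhm <- function(profile, peak_shift = NULL, ...) {
  profile <- merged_or_stop(profile)
  if (is.null(peak_shift)) peak_shift <- estimate_fragment_length(profile, ...)
  s <- profile$shifts
  y <- profile$merged
  k <- match(peak_shift, s)
  if (is.na(k) || is.na(y[k])) stop("'peak_shift' not on the computed profile")
  baseline <- min(y, na.rm = TRUE)
  half <- baseline + (y[k] - baseline) / 2
  cross <- function(idx) {
    # walk outward from the peak; find the first shift with y <= half and
    # interpolate linearly against the previous (peak-side) shift
    below <- which(y[idx] <= half)
    if (!length(below))
      stop("profile does not descend to half maximum within the shift range; ",
           "recompute with a wider range")
    i2 <- idx[below[1L]]
    i1 <- if (below[1L] == 1L) k else idx[below[1L] - 1L]
    s[i1] + (half - y[i1]) * (s[i2] - s[i1]) / (y[i2] - y[i1])
  }
  left <- cross(rev(seq_len(k - 1L)))
  right <- cross(if (k < length(s)) (k + 1L):length(s) else integer(0))
  right - left
}

#' Adjust an FWHM-based width estimate by a regression slope
#'
#' FWHM-based width estimates are proportional to, but not identical with,
#' reference widths estimated from read pileups around peaks; dividing by
#' the slope of a through-origin regression of FWHM on the reference width
#' calibrates them. The default slope of 1 leaves the estimate unchanged
#' (the calibration slope is dataset-specific).
#'
#' @param w_fwhm FWHM estimate (bp).
#' @param slope Positive regression slope.
#' @return `w_fwhm / slope`.
#' @export
adjust_w <- function(w_fwhm, slope = 1) {
  if (!is.numeric(slope) || slope <= 0) stop("'slope' must be > 0")
  w_fwhm / slope
}

#' Fit a through-origin slope of FWHM on reference widths
#'
#' @param w_fwhm Vector of FWHM estimates.
#' @param w_ref Vector of reference widths (same length).
#' @return The least-squares slope of `w_fwhm ~ 0 + w_ref`.
#' @export
fit_w_slope <- function(w_fwhm, w_ref) {
  unname(stats::coef(stats::lm(w_fwhm ~ 0 + w_ref)))
}

#' Virtual signal-to-noise (VSN)
#'
#' `VSN = (2w / M) * max(MSCC)`, with the maximum taken at the estimated
#' fragment length. Under the generative model VSN approximates
#' alpha^2 / n, making it a peak-call-free signal-to-noise readout that is
#' robust to sequencing depth.
#'
#' @param profile A merged `CCProfile` (MSCC recommended).
#' @param M Total mapped reads.
#' @param w Enriched-region width in bp (e.g. an adjusted FWHM estimate).
#' @param fragment_length Shift at which to read the maximum (default:
#'   [estimate_fragment_length()]).
#' @param ... Passed on to [estimate_fragment_length()].
#' @return The VSN value.
#' @export
vsn <- function(profile, M, w, fragment_length = NULL, ...) {
  if (M <= 0 || w <= 0) stop("'M' and 'w' must be positive")
  profile <- merged_or_stop(profile)
  if (is.null(fragment_length))
    fragment_length <- estimate_fragment_length(profile, ...)
  cc_max <- profile$merged[match(fragment_length, profile$shifts)]
  if (is.na(cc_max)) stop("coefficient undefined at the fragment length")
  2 * w / M * cc_max
}

#' NSC and RSC
#'
#' The normalised strand coefficient `NSC = cc(fragment) / cc_min` and the
#' relative strand correlation
#' `RSC = (cc(fragment) - cc_min) / (cc(R) - cc_min)`, computed from a
#' profile with `cc_min` the minimum merged coefficient over the computed
#' shift range. Provided for comparison with phantom-peak-style QC; NSC is
#' undefined (NA, with a flag) when `cc_min <= 0` and RSC when
#' `cc(R) = cc_min`.
#'
#' @param profile A merged `CCProfile`.
#' @param fragment_shift Fragment-length shift.
#' @param R Read length (default: profile metadata).
#' @return List with `nsc`, `rsc` and logical flags `nsc_defined`,
#'   `rsc_defined`.
#' @export
nsc_rsc <- function(profile, fragment_shift, R = profile$read_length) {
  profile <- merged_or_stop(profile)
  cc_frag <- profile$merged[match(fragment_shift, profile$shifts)]
  cc_read <- profile$merged[match(R, profile$shifts)]
  cc_min <- suppressWarnings(min(profile$merged, na.rm = TRUE))
  if (is.na(cc_frag) || is.na(cc_read) || !is.finite(cc_min))
    stop("profile must define coefficients at the fragment shift, at R, ",
         "and a minimum")
  nsc_defined <- cc_min > 0
  rsc_defined <- cc_read != cc_min
  list(nsc = if (nsc_defined) cc_frag / cc_min else NA_real_,
       rsc = if (rsc_defined) (cc_frag - cc_min) / (cc_read - cc_min)
             else NA_real_,
       nsc_defined = nsc_defined, rsc_defined = rsc_defined)
}

#' Bundle the QC metrics of a profile
#'
#' Convenience wrapper running fragment-length estimation, FWHM, VSN and
#' NSC/RSC in one pass.
#'
#' @param profile A merged `CCProfile`.
#' @param M Total mapped reads.
#' @param R Read length (default: profile metadata).
#' @param w Width to use for VSN; defaults to the slope-adjusted FWHM.
#' @param slope Calibration slope for [adjust_w()] (default 1).
#' @param ... Passed on to [estimate_fragment_length()].
#' @return An object of class `QCMetrics` (a named list).
#' @export
qc_metrics <- function(profile, M, R = profile$read_length, w = NULL,
                       slope = 1, ...) {
  profile <- merged_or_stop(profile)
  frag <- estimate_fragment_length(profile, R = R, ...)
  w_fwhm <- tryCatch(estimate_w_fwhm(profile, peak_shift = frag),
                     error = function(e) NA_real_)
  w_adj <- if (is.na(w_fwhm)) NA_real_ else adjust_w(w_fwhm, slope)
  if (is.null(w)) w <- w_adj
  v <- if (is.null(w) || is.na(w)) NA_real_
       else vsn(profile, M, w, fragment_length = frag)
  nr <- tryCatch(nsc_rsc(profile, frag, R),
                 error = function(e) list(nsc = NA_real_, rsc = NA_real_))
  structure(list(
    fragment_length = frag,
    cc_max = profile$merged[match(frag, profile$shifts)],
    cc_min = suppressWarnings(min(profile$merged, na.rm = TRUE)),
    cc_at_read_length = profile$merged[match(R, profile$shifts)],
    w_fwhm = w_fwhm, w_adjusted = w_adj,
    vsn = v, nsc = nr$nsc, rsc = nr$rsc,
    mode = profile$mode, M = M, R = R), class = "QCMetrics")
}

#' @export
print.QCMetrics <- function(x, ...) {
  cat("QC metrics (", x$mode, " profile, M = ", format(x$M, big.mark = ","),
      ")\n", sep = "")
  cat(sprintf("  fragment length : %d bp\n", x$fragment_length))
  cat(sprintf("  cc max / min    : %.4g / %.4g\n", x$cc_max, x$cc_min))
  cat(sprintf("  w (FWHM / adj.) : %.1f / %.1f bp\n", x$w_fwhm, x$w_adjusted))
  cat(sprintf("  VSN             : %.4g\n", x$vsn))
  cat(sprintf("  NSC / RSC       : %.3g / %.3g\n", x$nsc, x$rsc))
  invisible(x)
}
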