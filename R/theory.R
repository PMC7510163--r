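#' Parameters of the generative read-density model
#'
#' The model places n binding events on a genome of length G. Each event
#' carries a forward-read enriched region of width w and a reverse-read
#' enriched region of the same width, separated by a gap d (so forward and
#' reverse 5' ends of the same event are d + w apart, the fragment length).
#' Of M total mapped reads (M/2 per strand), a fraction alpha are signal
#' reads with 5' ends uniform over the enriched regions; the remaining
#' 1 - alpha are noise reads uniform over the genome. M_u is the mapped
#' read count after duplicate collapse (defaults to M).
#'
#' @param G Genome length (bp).
#' @param n Number of binding events (may be 0 only with `alpha = 0`).
#' @param w Enriched-region width (bp).
#' @param d Distance between the paired forward/reverse regions (bp).
#' @param alpha Signal fraction in \[0, 1\].
#' @param M Total mapped reads.
#' @param M_u Deduplicated mapped reads (default `M`).
#' @param R Read length (bp).
#' @return An object of class `ModelParams`.
#' @examples
#' model_params(G = 1e6, n = 100, w = 100, d = 200, alpha = 0.5, M = 1e4)
#' @export
model_params <- function(G, n, w, d, alpha, M, M_u = M, R = 50) {
  p <- list(G = as.numeric(G), n = as.numeric(n), w = as.numeric(w),
            d = as.numeric(d), alpha = as.numeric(alpha),
            M = as.numeric(M), M_u = as.numeric(M_u), R = as.numeric(R))
  with(p, {
    if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
    if (n < 0 || n != floor(n)) stop("'n' must be a non-negative integer")
    if (n == 0 && alpha > 0) stop("'n' may be 0 only when alpha = 0")
    if (any(c(G, w, d, M, R) < 1)) stop("G, w, d, M and R must all be >= 1")
    if (M_u > M) stop("'M_u' cannot exceed 'M'")
    if (n * (2 * w + d) > G) stop("enriched regions do not fit: n(2w+d) > G")
  })
  structure(p, class = "ModelParams")
}

#' @export
print.ModelParams <- function(x, ...) {
  cat(sprintf("ModelParams: G=%g n=%g w=%g d=%g alpha=%g M=%g M_u=%g R=%g\n",
              x$G, x$n, x$w, x$d, x$alpha, x$M, x$M_u, x$R))
  cat(sprintf("  degree of saturation: %.4g (%s)\n",
              degree_of_saturation(x), saturation_regime(x)))
  invisible(x)
}

#' Degree of saturation
#'
#' The ratio M*alpha / (2*n*w) of expected signal reads per strand to
#' available enriched-region positions. Values above 1 mean reads must
#' duplicate inside the enriched regions ("saturated" regime); the
#' unsaturated closed forms assume the ratio is at most 1.
#'
#' @param params A [model_params()].
#' @return The dimensionless ratio (0 when `alpha = 0`).
#' @export
degree_of_saturation <- function(params) {
  stopifnot(inherits(params, "ModelParams"))
  if (params$alpha == 0) return(0)
  if (params$n * params$w == 0)
    stop("signal reads with no enriched regions: n*w = 0 with alpha > 0")
  params$M * params$alpha / (2 * params$n * params$w)
}

#' @rdname degree_of_saturation
#' @return `saturation_regime`: `"saturated"` if the degree exceeds 1,
#'   otherwise `"unsaturated"` (the boundary counts as unsaturated).
#' @export
saturation_regime <- function(params) {
  if (degree_of_saturation(params) > 1) "saturated" else "unsaturated"
}

# Unsaturated per-position set-bit probabilities: pN genome-wide for noise,
# pS inside an enriched region (noise and signal combined).
unsaturated_probs <- function(params) {
  with(params, {
    pN <- M / (2 * G) * (1 - alpha)
    pS <- if (alpha == 0) pN else pN + M * alpha / (2 * n * w) * (1 - pN)
    list(pS = pS, pN = pN, mu = M / (2 * G))
  })
}

check_model_preconditions <- function(params) {
  if (params$M >= 2 * params$G)
    stop("model preconditions violated: M >= 2G")
}

#' Theoretical maximum cross-correlation coefficient
#'
#' The expected coefficient at the fragment-length shift x = d + w, where
#' every forward enriched region aligns with its reverse partner. In the
#' unsaturated regime three forms are available: the exact closed form, a
#' first approximation valid for d + w << G, and the headline approximation
#' M * alpha^2 / (2 n w). In the saturated regime the maximum is
#' n w / (M_u/2 * (1 - alpha) + n w) (a single printed form, returned at
#' every level).
#'
#' @param params A [model_params()].
#' @param level `"exact"`, `"approx1"` or `"approx2"`.
#' @param regime `"auto"` (select by [degree_of_saturation()]),
#'   `"unsaturated"` or `"saturated"`.
#' @return The expected maximum coefficient.
#' @export
theoretical_max <- function(params, level = c("exact", "approx1", "approx2"),
                            regime = c("auto", "unsaturated", "saturated")) {
  level <- match.arg(level)
  regime <- match.arg(regime)
  stopifnot(inherits(params, "ModelParams"))
  check_model_preconditions(params)
  if (regime == "auto") regime <- saturation_regime(params)
  with(params, {
    if (alpha == 0) return(0)
    if (regime == "saturated")
      return(n * w / (M_u / 2 * (1 - alpha) + n * w))
    xm <- d + w
    switch(level,
      exact = M * alpha^2 * (2 * G - (1 - alpha) * M)^2 /
                (4 * n * w * (2 * G - M) * (G - xm)) -
              M * alpha * (M * (1 - alpha)^2 + (G + xm) * alpha - 2 * xm) /
                ((2 * G - M) * (G - xm)),
      approx1 = M * alpha^2 * (2 * G - (1 - alpha) * M)^2 /
                  (4 * n * w * (2 * G - M) * G) -
                M * alpha * (M * (1 - alpha)^2 + G * alpha) /
                  ((2 * G - M) * G),
      approx2 = M * alpha^2 / (2 * n * w))
  })
}

#' Theoretical minimum cross-correlation coefficient
#'
#' The expected coefficient at a shift x0 where no forward enriched region
#' overlaps any shifted reverse region. The exact unsaturated form is
#' non-positive for alpha in (0, 1\]; dropping x0 (requires x0 << G) gives
#' the first approximation, and for M << G the minimum approximates 0.
#' In the saturated regime the printed result is 0.
#'
#' @inheritParams theoretical_max
#' @param x0 The non-overlapping shift (0 <= x0 < G).
#' @return The expected minimum coefficient.
#' @export
theoretical_min <- function(params, x0 = 0,
                            level = c("exact", "approx1", "approx2"),
                            regime = c("auto", "unsaturated", "saturated")) {
  level <- match.arg(level)
  regime <- match.arg(regime)
  stopifnot(inherits(params, "ModelParams"))
  check_model_preconditions(params)
  if (x0 < 0 || x0 >= params$G) stop("'x0' must satisfy 0 <= x0 < G")
  if (regime == "auto") regime <- saturation_regime(params)
  with(params, {
    if (alpha == 0 || regime == "saturated") return(0)
    switch(level,
      exact = -M * alpha * (M * (1 - alpha)^2 + (G + x0) * alpha - 2 * x0) /
                ((2 * G - M) * (G - x0)),
      approx1 = -M * alpha * (M * (1 - alpha)^2 + G * alpha) /
                  ((2 * G - M) * G),
      approx2 = 0)
  })
}

#' Expected shifted-AND count |D_x| and expected NCC from set sizes
#'
#' `expected_dx` evaluates the expected number of positions i with
#' f(i) = g(i + x) = 1 from the sizes of the four index classes (both in an
#' enriched region, forward only, reverse only, neither) and the unsaturated
#' per-position probabilities. `expected_ncc_at` maps an expected |D_x| to
#' an expected coefficient through the global-moment form of the Pearson
#' correlation.
#'
#' @param params A [model_params()].
#' @param sizes Numeric vector or list with elements `SS`, `SN`, `NS`, `NN`;
#'   they must sum to G - x.
#' @param x The shift.
#' @return `expected_dx`: the expected count. `expected_ncc_at`: the
#'   expected coefficient.
#' @export
expected_dx <- function(params, sizes, x) {
  stopifnot(inherits(params, "ModelParams"))
  sizes <- as.list(sizes)
  if (!all(c("SS", "SN", "NS", "NN") %in% names(sizes)))
    stop("'sizes' must provide SS, SN, NS and NN")
  s <- vapply(sizes[c("SS", "SN", "NS", "NN")], as.numeric, 0)
  if (any(s < 0)) stop("set sizes must be non-negative")
  if (abs(sum(s) - (params$G - x)) > 1e-6)
    stop("set sizes must sum to G - x = ", params$G - x)
  pr <- unsaturated_probs(params)
  s[["SS"]] * pr$pS^2 + (s[["SN"]] + s[["NS"]]) * pr$pS * pr$pN +
    s[["NN"]] * pr$pN^2
}

#' @rdname expected_dx
#' @param dx Expected |D_x|.
#' @export
expected_ncc_at <- function(params, dx, x) {
  stopifnot(inherits(params, "ModelParams"))
  mu <- params$M / (2 * params$G)
  sigma <- mu * (1 - mu)
  (dx / (params$G - x) - mu^2) / sigma
}

#' Expected NCC profile over a range of shifts
#'
#' Extends the printed minimum/maximum cases to arbitrary shifts by the
#' geometric overlap of non-interacting site pairs:
#' `|X_SS|(x) = n * max(0, w - |x - (d + w)|)`, with the forward-only and
#' reverse-only classes making up the remaining n*w positions each. This
#' reproduces the triangular fragment-length peak of width 2w.
#'
#' @param params A [model_params()].
#' @param shifts Integer vector of shifts.
#' @return Numeric vector of expected coefficients.
#' @export
expected_ncc_profile <- function(params, shifts = 0:1000) {
  stopifnot(inherits(params, "ModelParams"))
  vapply(shifts, function(x) {
    ss <- params$n * max(0, params$w - abs(x - (params$d + params$w)))
    sn <- params$n * params$w - ss
    nn <- (params$G - x) - ss - 2 * sn
    expected_ncc_at(params, expected_dx(params,
      list(SS = ss, SN = sn, NS = sn, NN = nn), x), x)
  }, 0)
}

#' FRiP from the model parameters, and alpha from FRiP
#'
#' Under the model, the fraction of reads in peaks is
#' `FRiP = alpha + n(2w + d)/G * (1 - alpha)`: all signal reads fall inside
#' called regions, plus the noise reads that land in the n(2w + d) bp of
#' peak territory. `alpha_from_frip` inverts this exactly, given post-peak-
#' calling estimates of n, w and d (note `w + d` is the fragment length).
#' Estimates below 0 (FRiP under the noise floor) are clamped to 0 with a
#' warning.
#'
#' @param params A [model_params()].
#' @return `frip_from_alpha`: the FRiP fraction in \[0, 1\].
#' @export
frip_from_alpha <- function(params) {
  stopifnot(inherits(params, "ModelParams"))
  with(params, alpha + n * (2 * w + d) / G * (1 - alpha))
}

#' @rdname frip_from_alpha
#' @param frip Observed FRiP in \[0, 1\].
#' @param n_hat,w_hat,d_hat Estimated peak count, region width and gap.
#' @param G Genome length.
#' @return `alpha_from_frip`: the estimated signal fraction.
#' @export
alpha_from_frip <- function(frip, n_hat, w_hat, d_hat, G) {
  if (frip < 0 || frip > 1) stop("'frip' must lie in [0, 1]")
  territory <- n_hat * (2 * w_hat + d_hat) / G
  if (territory >= 1) stop("peak territory n(2w+d) must be smaller than G")
  a <- (frip - territory) / (1 - territory)
  if (a < 0) {
    warning("FRiP below the noise floor; alpha estimate clamped to 0")
    a <- 0
  }
  a
}
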