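#' @title Cohort QC workflow: n-alpha regression and VSN-based prediction
#' @name workflow
#' @description
#' Across a cohort of ChIP-seq samples for one target, the number of called
#' peaks n and the signal fraction alpha (derived from FRiP) follow an
#' approximately linear relation in log10-log10 space. Fitting that relation
#' once on samples with peak calls, and combining it with the model identity
#' VSN = alpha^2 / n, lets the expected signal-to-noise and the expected
#' number of callable peaks of a *new* sample be computed from its VSN
#' alone, before any peak calling.
NULL

#' Read a peak-call summary table
#'
#' Expected TSV columns: `sample`, `n_peaks`, `frip`, `fragment_length`,
#' `w`, `genome_length`. The fragment length corresponds to w + d, so the
#' peak territory per sample is `n_peaks * (w + fragment_length)`.
#'
#' @param path TSV file with a header row.
#' @return A validated data.frame of class `peak_call_summary`.
#' @export
read_peak_summaries <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  peak_call_summary(df)
}

#' @rdname read_peak_summaries
#' @param df A data.frame with the columns listed above.
#' @export
peak_call_summary <- function(df) {
  need <- c("sample", "n_peaks", "frip", "fragment_length", "w",
            "genome_length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$frip < 0 | df$frip > 1)) stop("'frip' must lie in [0, 1]")
  if (any(df$n_peaks < 0)) stop("'n_peaks' must be >= 0")
  class(df) <- c("peak_call_summary", "data.frame")
  df
}

#' Estimate alpha for each sample of a summary table
#'
#' Applies [alpha_from_frip()] per row with `d = fragment_length - w`.
#'
#' @param summaries A [peak_call_summary()].
#' @return Numeric vector of alpha estimates.
#' @export
alpha_estimates <- function(summaries) {
  vapply(seq_len(nrow(summaries)), function(i) {
    with(summaries[i, ], alpha_from_frip(frip, n_peaks, w,
                                         fragment_length - w, genome_length))
  }, 0)
}

#' Fit the log-log regression of peak count on alpha
#'
#' Ordinary least squares of `log10(n_peaks)` on `log10(alpha)`. Samples
#' with `alpha <= 0` or `n_peaks <= 0` are excluded with a warning; at
#' least two usable samples are required.
#'
#' @param summaries A [peak_call_summary()] (or data.frame with its columns).
#' @return An object of class `n_alpha_model`: list with `a` (intercept),
#'   `b` (slope), `n_samples` and the underlying `lm` fit.
#' @export
fit_n_alpha_regression <- function(summaries) {
  summaries <- peak_call_summary(as.data.frame(summaries))
  alpha <- suppressWarnings(alpha_estimates(summaries))
  usable <- alpha > 0 & summaries$n_peaks > 0
  if (any(!usable))
    warning(sum(!usable), " sample(s) with alpha <= 0 or n_peaks <= 0 excluded")
  if (sum(usable) < 2)
    stop("need at least 2 samples with alpha > 0 and n_peaks > 0")
  fit <- stats::lm(log10(n_peaks) ~ log10(alpha),
                   data = data.frame(n_peaks = summaries$n_peaks[usable],
                                     alpha = alpha[usable]))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf[1]), b = unname(cf[2]),
                 n_samples = sum(usable), fit = fit),
            class = "n_alpha_model")
}

#' @export
print.n_alpha_model <- function(x, ...) {
  cat(sprintf("n-alpha regression (%d samples): log10(n) = %.4g %+.4g * log10(alpha)\n",
              x$n_samples, x$a, x$b))
  invisible(x)
}

#' Expected signal-to-noise and peak count from a VSN value
#'
#' Solves the system formed by the fitted relation
#' `log10(n) = a + b * log10(alpha)` and the model identity
#' `alpha^2 / n = VSN`, giving `alpha = (VSN * 10^a)^(1/(2 - b))` and
#' `n = 10^(a + b * log10(alpha))`. The back-substitution
#' `alpha^2 / n = VSN` holds exactly for every solution. A validity flag
#' marks solutions with alpha outside (0, 1].
#'
#' @param vsn A positive VSN value (see [vsn()]).
#' @param model An [fit_n_alpha_regression()] result.
#' @return List with `alpha`, `n` and `valid`.
#' @export
expected_from_vsn <- function(vsn, model) {
  stopifnot(inherits(model, "n_alpha_model"))
  if (!is.numeric(vsn) || vsn <= 0) stop("'vsn' must be positive")
  if (abs(model$b - 2) < 1e-12)
    stop("regression slope b = 2 makes the system degenerate")
  alpha <- (vsn * 10^model$a)^(1 / (2 - model$b))
  n <- 10^(model$a + model$b * log10(alpha))
  list(alpha = alpha, n = n, valid = alpha > 0 && alpha <= 1)
}
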