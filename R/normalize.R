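#' Add per-bin M and A values
#'
#' For each bin with counts `x1`, `x2` and pseudocount `c`:
#' `M = ln(x1 + c) - ln(x2 + c)` and `A = ln(x1 + c) + ln(x2 + c)`.
#' The pseudocount guards against the logarithm of zero counts.
#'
#' @param bins Bin tibble from [bin_clip_clusters()].
#' @param pseudocount Positive pseudocount `c` added to every count
#'   (default 1).
#' @return `bins` with columns `M_raw` and `A` added.
#' @export
add_ma <- function(bins, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  dplyr::mutate(
    bins,
    M_raw = log(.data$x1 + pseudocount) - log(.data$x2 + pseudocount),
    A = log(.data$x1 + pseudocount) + log(.data$x2 + pseudocount)
  )
}

#' Fit the MA normalization regression
#'
#' Sequencing depth and signal-to-noise ratio differ between the two
#' libraries, so raw M values are biased. Assuming that bins covered well
#' in both conditions are dominated by common binding of similar strength,
#' an ordinary least-squares line `M = a + b * A` is fitted to the bins
#' whose `x1` and `x2` are both strictly larger than `joint_count_cutoff`;
#' the fitted line captures the scaling relationship between the samples.
#'
#' @param bins Bin tibble with `M_raw` and `A` (see [add_ma()]).
#' @param joint_count_cutoff Both raw counts must exceed this for a bin to
#'   enter the regression (default 5).
#' @return An object of class `clip_normalization` with elements `a`
#'   (intercept), `b` (slope), `n_fit`, and the underlying `lm` fit.
#' @export
fit_normalization <- function(bins, joint_count_cutoff = 5) {
  fit_bins <- dplyr::filter(bins, .data$x1 > joint_count_cutoff,
                            .data$x2 > joint_count_cutoff)
  if (nrow(fit_bins) < 2 || dplyr::n_distinct(fit_bins$A) < 2) {
    stop("fewer than 2 jointly-covered bins with distinct A values at ",
         "joint_count_cutoff = ", joint_count_cutoff,
         "; lower the cutoff or check library depth")
  }
  fit <- stats::lm(M_raw ~ A, data = fit_bins)
  structure(
    list(
      a = unname(stats::coef(fit)[1]),
      b = unname(stats::coef(fit)[2]),
      n_fit = nrow(fit_bins),
      joint_count_cutoff = joint_count_cutoff,
      fit = fit
    ),
    class = "clip_normalization"
  )
}

#' Apply the fitted normalization to every bin
#'
#' Subtracts the fitted `a + b * A` from the raw M value of every bin in
#' all clusters (not only the bins used in the fit), extrapolating the
#' scaling relationship to the whole dataset.
#'
#' @param bins Bin tibble with `M_raw` and `A`.
#' @param model A `clip_normalization` fit.
#' @return `bins` with an `M_adj` column added.
#' @export
adjust_m <- function(bins, model) {
  stopifnot(inherits(model, "clip_normalization"))
  dplyr::mutate(bins, M_adj = .data$M_raw - (model$a + model$b * .data$A))
}

#' @export
print.clip_normalization <- function(x, ...) {
  cat("MA normalization: M =", format(x$a, digits = 4), "+",
      format(x$b, digits = 4), "* A  (fitted on", x$n_fit, "bins with both",
      "counts >", x$joint_count_cutoff, ")\n")
  invisible(x)
}

#' @export
tidy.clip_normalization <- function(x, ...) {
  tidy(x$fit, ...)
}

#' @export
glance.clip_normalization <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n_fit = x$n_fit,
                 joint_count_cutoff = x$joint_count_cutoff)
}

#' MA plot of bin counts before/after normalization
#'
#' @param bins Bin tibble with `M_raw`, `A` and optionally `M_adj`.
#' @param adjusted Plot adjusted M values (if present) instead of raw.
#' @param model Optional `clip_normalization` whose line is drawn over a
#'   raw-M plot.
#' @return A ggplot object.
#' @export
plot_ma <- function(bins, adjusted = FALSE, model = NULL) {
  y <- if (adjusted) "M_adj" else "M_raw"
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$A, y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "A = ln(x1+c) + ln(x2+c)",
                  y = if (adjusted) "adjusted M" else "M = ln(x1+c) - ln(x2+c)")
  if (!adjusted && !is.null(model)) {
    p <- p + ggplot2::geom_abline(intercept = model$a, slope = model$b,
                                  colour = "red")
  }
  p
}
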