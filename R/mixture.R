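#' Robust sigma estimate for the emission mixture
#'
#' Adjusted M values are modelled as a three-component normal mixture in
#' which the zero-mean (non-differential) component dominates; treating the
#' outer components as outliers, the shared standard deviation is estimated
#' robustly as `median(|M - median(M)|) * 1.4826` (the median absolute
#' deviation scaled to be consistent for the normal).
#'
#' @param m Numeric vector of adjusted M values.
#' @return The scalar sigma estimate.
#' @export
estimate_sigma_mad <- function(m) {
  stopifnot(length(m) >= 2)
  sigma <- stats::mad(m, constant = 1.4826)
  if (sigma <= 0) {
    stop("degenerate sigma estimate (all adjusted M values identical)")
  }
  sigma
}

#' Outer-component mean from the second-moment constraint
#'
#' The mixture's second moment equals the sample second moment when
#' `m2_hat = 2 * p * mu^2 + sigma^2`, giving
#' `mu = sqrt((m2_hat - sigma^2) / (2 * p))` for each candidate weight `p`.
#'
#' @param p Weight of each outer component, in (0, 0.5).
#' @param sigma Shared component standard deviation.
#' @param m2_hat Sample second moment `mean(M^2)`.
#' @return `mu`, or `NA_real_` when `m2_hat <= sigma^2` (no real solution).
#' @export
mu_from_moment_constraint <- function(p, sigma, m2_hat) {
  stopifnot(all(p > 0), all(p < 0.5), sigma > 0)
  mu2 <- (m2_hat - sigma^2) / (2 * p)
  ifelse(mu2 > 0, sqrt(mu2), NA_real_)
}

mixture_loglik <- function(m, p, mu, sigma) {
  sum(log(p * stats::dnorm(m, mean = mu, sd = sigma) +
            (1 - 2 * p) * stats::dnorm(m, mean = 0, sd = sigma) +
            p * stats::dnorm(m, mean = -mu, sd = sigma)))
}

#' Fit the three-component emission mixture by constrained grid search
#'
#' Emission distributions for the three hidden states are normal with
#' means `+mu`, `0`, `-mu` and shared standard deviation `sigma`; the
#' outer components carry weight `p` each. `sigma` is fixed by the MAD
#' estimate, then `(p, mu)` is found by maximising the mixture likelihood
#' over a grid of `p` values, with `mu` tied to each `p` through the
#' second-moment constraint, so every candidate matches the sample second
#' moment exactly.
#'
#' When the estimated fraction of non-differential binding `1 - 2p` falls
#' below 50%, a warning is issued: the normalization assumes that common
#' binding of similar strength dominates, and the fit is unreliable when
#' it does not.
#'
#' @param m Numeric vector of adjusted M values.
#' @param sigma Shared standard deviation; defaults to
#'   [estimate_sigma_mad()] of `m`.
#' @param p_grid Candidate outer-component weights (default 0.001 to 0.499
#'   in steps of 0.001).
#' @return An object of class `clip_mixture`: elements `p`, `mu`, `sigma`,
#'   `common_fraction`, `loglik`, `n`, `m2_hat`, `grid` (tibble of all
#'   evaluated candidates).
#' @export
fit_clip_mixture <- function(m, sigma = NULL,
                             p_grid = seq(0.001, 0.499, by = 0.001)) {
  if (is.null(sigma)) {
    sigma <- estimate_sigma_mad(m)
  }
  m2_hat <- mean(m^2)
  mu_grid <- mu_from_moment_constraint(p_grid, sigma, m2_hat)
  feasible <- !is.na(mu_grid)
  if (!any(feasible)) {
    stop("no differential signal detectable: sample second moment (",
         format(m2_hat, digits = 4), ") does not exceed sigma^2 (",
         format(sigma^2, digits = 4), ")")
  }
  ll <- rep(NA_real_, length(p_grid))
  phi0 <- stats::dnorm(m, mean = 0, sd = sigma)
  for (i in which(feasible)) {
    p <- p_grid[i]
    mu <- mu_grid[i]
    dens <- p * stats::dnorm(m, mean = mu, sd = sigma) +
      (1 - 2 * p) * phi0 +
      p * stats::dnorm(m, mean = -mu, sd = sigma)
    ll[i] <- sum(log(dens))
  }
  best <- which.max(ll)
  out <- structure(
    list(
      p = p_grid[best],
      mu = mu_grid[best],
      sigma = sigma,
      common_fraction = 1 - 2 * p_grid[best],
      loglik = ll[best],
      n = length(m),
      m2_hat = m2_hat,
      grid = tibble::tibble(p = p_grid, mu = mu_grid, loglik = ll)
    ),
    class = "clip_mixture"
  )
  check_common_fraction(out)
  out
}

#' Warn when common binding no longer dominates
#'
#' The method assumes that most sites bind similarly in both conditions.
#' A warning is issued if the estimated common fraction `1 - 2p` is
#' strictly below 0.5; the analysis continues.
#'
#' @param params A `clip_mixture` fit.
#' @return `TRUE` (warning issued) or `FALSE`, invisibly.
#' @export
check_common_fraction <- function(params) {
  fired <- params$common_fraction < 0.5
  if (fired) {
    warning("estimated proportion of common binding sites with similar ",
            "binding strength is ",
            format(params$common_fraction, digits = 3),
            " (< 50%); the normalization assumption may not hold",
            call. = FALSE)
  }
  invisible(fired)
}

#' Per-bin emission probabilities under the fitted mixture
#'
#' State 0 (stronger in condition 1) pairs with the `+mu` component since
#' `M = ln(x1+c) - ln(x2+c)` is positive when condition 1 is higher;
#' state 1 with the zero-mean component; state 2 with `-mu`.
#'
#' @param m Numeric vector of adjusted M values.
#' @param params A `clip_mixture` fit (only `mu` and `sigma` are used).
#' @return A `length(m)` x 3 matrix of normal densities, columns =
#'   states 0, 1, 2.
#' @export
emission_probabilities <- function(m, params) {
  cbind(
    stats::dnorm(m, mean = params$mu, sd = params$sigma),
    stats::dnorm(m, mean = 0, sd = params$sigma),
    stats::dnorm(m, mean = -params$mu, sd = params$sigma)
  )
}

#' @export
print.clip_mixture <- function(x, ...) {
  cat("Three-component normal emission mixture (n =", x$n, "bins)\n")
  cat("  sigma =", format(x$sigma, digits = 4), "(MAD)\n")
  cat("  p =", format(x$p, digits = 4), " mu =", format(x$mu, digits = 4),
      "\n")
  cat("  common fraction 1 - 2p =", format(x$common_fraction, digits = 3),
      "\n")
  cat("  log-likelihood =", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' @export
tidy.clip_mixture <- function(x, ...) {
  tibble::tibble(
    state = 0:2,
    label = c("stronger in condition 1", "non-differential",
              "stronger in condition 2"),
    weight = c(x$p, 1 - 2 * x$p, x$p),
    mean = c(x$mu, 0, -x$mu),
    sd = rep(x$sigma, 3)
  )
}

#' @export
glance.clip_mixture <- function(x, ...) {
  tibble::tibble(p = x$p, mu = x$mu, sigma = x$sigma,
                 common_fraction = x$common_fraction,
                 logLik = x$loglik, n = x$n)
}

#' @export
autoplot.clip_mixture <- function(object, m = NULL, bins = 80, ...) {
  comp <- tidy(object)
  xs <- seq(-4 * object$mu - 4 * object$sigma,
            4 * object$mu + 4 * object$sigma, length.out = 512)
  dens <- purrr::pmap(comp, function(state, label, weight, mean, sd) {
    tibble::tibble(x = xs, density = weight * stats::dnorm(xs, mean, sd),
                   component = label)
  }) |> dplyr::bind_rows()
  total <- dens |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  p <- ggplot2::ggplot()
  if (!is.null(m)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(m = m),
      ggplot2::aes(x = .data$m, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = NA
    )
  }
  p +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "black") +
    ggplot2::labs(x = "adjusted M", y = "density", colour = NULL)
}
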