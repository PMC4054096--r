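#' Default transition matrix for the three-state chain
#'
#' Diagonal 0.9 with off-diagonal 0.05 encodes the expected spatial
#' persistence of binding states along a cluster without favouring any
#' state; it is only the starting point for transition re-estimation.
#'
#' @return A 3x3 row-stochastic matrix.
#' @export
default_transitions <- function() {
  m <- matrix(0.05, 3, 3)
  diag(m) <- 0.9
  m
}

#' Scaled forward-backward pass for one observation sequence
#'
#' Computes posterior state probabilities, pooled expected transition
#' counts and the log-likelihood for one cluster's sequence of emission
#' densities, using per-position scaling for numerical stability.
#'
#' @param emit L x 3 matrix of emission densities (columns = states
#'   0, 1, 2).
#' @param transitions 3x3 row-stochastic transition matrix.
#' @param initial Length-3 initial state distribution.
#' @return List with `gamma` (L x 3 posterior state probabilities), `xi`
#'   (3x3 expected transition counts summed over positions) and `loglik`.
#' @export
forward_backward <- function(emit, transitions, initial = rep(1 / 3, 3)) {
  L <- nrow(emit)
  stopifnot(L >= 1, ncol(emit) == 3)
  alpha <- matrix(0, L, 3)
  scl <- numeric(L)
  a <- initial * emit[1, ]
  scl[1] <- sum(a)
  if (scl[1] <= 0) stop("numerical underflow in forward pass (position 1)")
  alpha[1, ] <- a / scl[1]
  if (L > 1) {
    for (t in 2:L) {
      a <- as.vector(alpha[t - 1, ] %*% transitions) * emit[t, ]
      scl[t] <- sum(a)
      if (scl[t] <= 0) {
        stop("numerical underflow in forward pass (position ", t, ")")
      }
      alpha[t, ] <- a / scl[t]
    }
  }
  beta <- matrix(0, L, 3)
  beta[L, ] <- 1
  xi <- matrix(0, 3, 3)
  if (L > 1) {
    for (t in (L - 1):1) {
      eb <- emit[t + 1, ] * beta[t + 1, ]
      beta[t, ] <- as.vector(transitions %*% eb) / scl[t + 1]
      xi <- xi + (alpha[t, ] %o% eb) * transitions / scl[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, loglik = sum(log(scl)))
}

#' Estimate the shared transition matrix across all clusters
#'
#' Baum-Welch restricted to the transition matrix: emissions are fixed
#' per bin before iteration starts and the initial distribution is never
#' re-estimated. Each iteration runs the scaled forward-backward pass over
#' every cluster's sequence, pools the expected transition counts, and
#' renormalises the rows. Iteration stops when the largest absolute change
#' of any entry falls below `tolerance` or after `max_iterations`.
#'
#' @param emissions List of L_j x 3 emission-density matrices, one per
#'   cluster.
#' @param transitions Starting 3x3 matrix (default [default_transitions()]).
#' @param initial Initial state distribution, kept fixed.
#' @param max_iterations Iteration cap (default 100).
#' @param tolerance Convergence threshold on `max |delta pi_rs|`
#'   (default 1e-4).
#' @return List with `transitions`, `iterations`, `converged` and
#'   `loglik_trace` (total log-likelihood at the start of each iteration).
#' @export
train_hmm_transitions <- function(emissions, transitions = default_transitions(),
                                  initial = rep(1 / 3, 3),
                                  max_iterations = 100L, tolerance = 1e-4) {
  stopifnot(length(emissions) >= 1, all(vapply(emissions, nrow, 1L) >= 1))
  loglik_trace <- numeric()
  converged <- FALSE
  iterations <- 0L
  if (all(vapply(emissions, nrow, 1L) == 1)) {
    # no transition events anywhere
    return(list(transitions = transitions, iterations = 0L,
                converged = TRUE, loglik_trace = numeric()))
  }
  for (iter in seq_len(max_iterations)) {
    xi_total <- matrix(0, 3, 3)
    ll <- 0
    for (emit in emissions) {
      fb <- forward_backward(emit, transitions, initial)
      xi_total <- xi_total + fb$xi
      ll <- ll + fb$loglik
    }
    loglik_trace <- c(loglik_trace, ll)
    row_sums <- rowSums(xi_total)
    new_pi <- transitions
    for (r in 1:3) {
      if (row_sums[r] > 0) {
        new_pi[r, ] <- xi_total[r, ] / row_sums[r]
      } else {
        warning("state ", r - 1, " never visited; transition row reset to ",
                "uniform", call. = FALSE)
        new_pi[r, ] <- rep(1 / 3, 3)
      }
    }
    delta <- max(abs(new_pi - transitions))
    transitions <- new_pi
    iterations <- iter
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  list(transitions = transitions, iterations = iterations,
       converged = converged, loglik_trace = loglik_trace)
}

#' Most probable state path for one observation sequence
#'
#' Log-space Viterbi dynamic programme. Ties at any arg-max are broken
#' toward the lowest state index, making the decode deterministic.
#'
#' @param emit L x 3 matrix of emission densities.
#' @param transitions 3x3 transition matrix.
#' @param initial Length-3 initial state distribution.
#' @return Integer vector of states in `{0, 1, 2}`, length L.
#' @export
viterbi_path <- function(emit, transitions, initial = rep(1 / 3, 3)) {
  L <- nrow(emit)
  stopifnot(L >= 1)
  log_pi <- log(transitions)
  log_e <- log(emit)
  delta <- matrix(-Inf, L, 3)
  psi <- matrix(0L, L, 3)
  delta[1, ] <- log(initial) + log_e[1, ]
  if (L > 1) {
    for (t in 2:L) {
      for (s in 1:3) {
        cand <- delta[t - 1, ] + log_pi[, s]
        psi[t, s] <- which.max(cand) # first max = lowest-index tie-break
        delta[t, s] <- cand[psi[t, s]] + log_e[t, s]
      }
    }
  }
  states <- integer(L)
  states[L] <- which.max(delta[L, ])
  if (L > 1) {
    for (t in (L - 1):1) {
      states[t] <- psi[t + 1, states[t + 1]]
    }
  }
  states - 1L
}

# per-cluster emission matrices from a bins tibble with M_adj
emissions_by_cluster <- function(bins, mixture) {
  split_ids <- unique(bins$cluster_id)
  e_all <- emission_probabilities(bins$M_adj, mixture)
  lapply(split(seq_len(nrow(bins)), factor(bins$cluster_id, levels = split_ids)),
         function(idx) e_all[idx, , drop = FALSE])
}

#' Fit the three-state HMM over all clusters
#'
#' Each cluster contributes one observation sequence of adjusted M values;
#' all sequences share one transition matrix and the fixed mixture
#' emissions. Transitions are estimated by [train_hmm_transitions()] and
#' every cluster is then decoded by [viterbi_path()].
#'
#' @param bins Bin tibble with `M_adj` (ordered by cluster and bin).
#' @param mixture A `clip_mixture` fit providing the emission densities.
#' @param max_iterations,tolerance Stop conditions for transition
#'   re-estimation.
#' @param transitions Starting transition matrix.
#' @param initial Fixed initial state distribution (uniform by default).
#' @return An object of class `clip_hmm`: `transitions`, `initial`,
#'   `iterations`, `converged`, `loglik_trace`, `mixture`.
#' @export
fit_clip_hmm <- function(bins, mixture, max_iterations = 100L,
                         tolerance = 1e-4,
                         transitions = default_transitions(),
                         initial = rep(1 / 3, 3)) {
  emissions <- emissions_by_cluster(bins, mixture)
  trained <- train_hmm_transitions(emissions, transitions, initial,
                                   max_iterations, tolerance)
  structure(
    list(
      transitions = trained$transitions,
      initial = initial,
      iterations = trained$iterations,
      converged = trained$converged,
      loglik_trace = trained$loglik_trace,
      mixture = mixture
    ),
    class = "clip_hmm"
  )
}

#' Decode every cluster's bins to binding states
#'
#' Independent Viterbi decode per cluster under the trained model. State 0
#' marks stronger binding in condition 1, state 1 non-differential
#' binding, state 2 stronger binding in condition 2.
#'
#' @param bins Bin tibble with `M_adj`.
#' @param model A `clip_hmm` fit.
#' @return `bins` with an integer `state` column added.
#' @export
infer_states <- function(bins, model) {
  stopifnot(inherits(model, "clip_hmm"))
  emissions <- emissions_by_cluster(bins, model$mixture)
  states <- lapply(emissions, viterbi_path,
                   transitions = model$transitions, initial = model$initial)
  out <- bins
  out$state <- NA_integer_
  split_ids <- unique(bins$cluster_id)
  idx <- split(seq_len(nrow(bins)), factor(bins$cluster_id, levels = split_ids))
  for (k in seq_along(idx)) {
    out$state[idx[[k]]] <- states[[k]]
  }
  out
}

#' @export
print.clip_hmm <- function(x, ...) {
  cat("Three-state CLIP HMM\n")
  cat("  transition matrix (rows = from state 0,1,2):\n")
  print(round(x$transitions, 4))
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  invisible(x)
}

#' @export
tidy.clip_hmm <- function(x, ...) {
  tibble::tibble(
    from = rep(0:2, each = 3),
    to = rep(0:2, 3),
    probability = as.vector(t(x$transitions))
  )
}

#' @export
glance.clip_hmm <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    logLik = if (length(x$loglik_trace)) utils::tail(x$loglik_trace, 1)
             else NA_real_,
    diag0 = x$transitions[1, 1],
    diag1 = x$transitions[2, 2],
    diag2 = x$transitions[3, 3]
  )
}
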