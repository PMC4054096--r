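# Exhaustive-enumeration oracles for the three-state chain (L <= 6).

all_paths <- function(L) {
  as.matrix(expand.grid(rep(list(0:2), L)))
}

path_probability <- function(path, emit, transitions, initial) {
  p <- initial[path[1] + 1] * emit[1, path[1] + 1]
  L <- length(path)
  if (L > 1) {
    for (t in 2:L) {
      p <- p * transitions[path[t - 1] + 1, path[t] + 1] *
        emit[t, path[t] + 1]
    }
  }
  p
}

# max path probability over all 3^L paths
oracle_viterbi_prob <- function(emit, transitions, initial) {
  paths <- all_paths(nrow(emit))
  max(apply(paths, 1, path_probability, emit = emit,
            transitions = transitions, initial = initial))
}

# posterior expected transition counts by path enumeration
oracle_xi <- function(emit, transitions, initial) {
  paths <- all_paths(nrow(emit))
  probs <- apply(paths, 1, path_probability, emit = emit,
                 transitions = transitions, initial = initial)
  total <- sum(probs)
  xi <- matrix(0, 3, 3)
  L <- nrow(emit)
  if (L < 2) return(xi)
  for (k in seq_len(nrow(paths))) {
    path <- paths[k, ]
    for (t in 2:L) {
      r <- path[t - 1] + 1
      s <- path[t] + 1
      xi[r, s] <- xi[r, s] + probs[k]
    }
  }
  xi / total
}

random_hmm_instance <- function(L) {
  emit <- matrix(stats::runif(L * 3, 0.01, 1), L, 3)
  pi_raw <- matrix(stats::runif(9, 0.05, 1), 3, 3)
  transitions <- pi_raw / rowSums(pi_raw)
  init_raw <- stats::runif(3, 0.1, 1)
  list(emit = emit, transitions = transitions,
       initial = init_raw / sum(init_raw))
}

mixture_params <- function(p, mu, sigma) {
  structure(list(p = p, mu = mu, sigma = sigma,
                 common_fraction = 1 - 2 * p),
            class = "clip_mixture")
}
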