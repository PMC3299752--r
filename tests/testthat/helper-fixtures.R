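# Shared fixtures: noise-free models, small simulated planes, and an
# independent brute-force marginal oracle (kept free of the package's
# message-passing code on purpose).

noiseless <- function(seed = 1L) {
  noise_model(jitter_h = 0, jitter_c = 0, jitter_n = 0, missing_prob = 0,
              artifact_rate = 0, intensity_cv = 0, seed = seed)
}

mild_noise <- function(seed = 1L) {
  noise_model(jitter_h = 0.01, jitter_c = 0.05, jitter_n = 0.05,
              missing_prob = 0.05, artifact_rate = 3, intensity_cv = 0.2,
              seed = seed)
}

# a short sequence free of proline and glycine (keeps peak counts exact)
simple_sequence <- function(L, seed = 1L) {
  withr::with_seed(seed, paste(sample(setdiff(rdassign:::AA1, c("P", "G")),
                                      L, replace = TRUE), collapse = ""))
}

# run the full loop quietly on a simulated sample
quiet_run <- function(seqs, seed, sd_scale = 1, noise = mild_noise(seed),
                      ...) {
  cfg <- run_config(seed = seed, ...)
  sample <- sample_shifts(seqs, seed = seed, sd_scale = sd_scale)
  spec <- sim_spectrometer(sample, noise, cfg)
  st <- suppressWarnings(run_assignment(seqs, cfg, spec))
  list(state = st, sample = sample, config = cfg)
}

# Independent oracle: exact marginals of a factor graph by enumerating all
# joint states and multiplying factor tables directly.
brute_force_marginals <- function(graph) {
  domains <- graph$domains
  grid <- expand.grid(lapply(domains, seq_along), KEEP.OUT.ATTRS = FALSE)
  w <- rep(1, nrow(grid))
  for (f in graph$factors) {
    idx <- as.matrix(grid[, f$vars, drop = FALSE])
    w <- w * if (length(f$vars) == 1L) f$table[idx[, 1]] else f$table[idx]
  }
  lapply(stats::setNames(names(domains), names(domains)), function(v) {
    p <- tapply(w, grid[[v]], sum)
    p <- p / sum(p)
    stats::setNames(as.numeric(p), domains[[v]])
  })
}

# random small factor graph (pairwise + unary, optionally acyclic)
random_factor_graph <- function(n_var, n_states, acyclic = TRUE,
                                seed = 1L) {
  withr::with_seed(seed, {
    states <- paste0("s", seq_len(n_states))
    vars <- paste0("v", seq_len(n_var))
    domains <- stats::setNames(replicate(n_var, states, simplify = FALSE),
                               vars)
    factors <- lapply(vars, function(v)
      list(vars = v, table = exp(stats::rnorm(n_states))))
    edges <- if (acyclic) {
      if (n_var < 2L) matrix(integer(0), ncol = 2) else
        cbind(2:n_var, vapply(2:n_var, function(i)
          sample.int(i - 1L, 1L), integer(1)))
    } else {
      t(utils::combn(n_var, 2))[sample(choose(n_var, 2),
                                       min(n_var + 1L, choose(n_var, 2))), ,
                                drop = FALSE]
    }
    for (r in seq_len(nrow(edges)))
      factors[[length(factors) + 1L]] <-
        list(vars = vars[edges[r, ]],
             table = matrix(exp(stats::rnorm(n_states^2)),
                            n_states, n_states))
    factor_graph(domains, factors)
  })
}
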