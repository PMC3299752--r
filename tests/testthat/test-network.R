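# The pseudo-energetic network: energies, Boltzmann form, factor graphs,
# message passing (checked against an independent brute-force oracle),
# assignment extraction, secondary structure, outliers.

small_potentials <- function(seed = 1, n_var = 3, n_states = 3,
                             beta = 1.3) {
  withr::with_seed(seed, {
    states <- paste0("s", seq_len(n_states))
    vars <- paste0("v", seq_len(n_var))
    domains <- stats::setNames(replicate(n_var, states, simplify = FALSE),
                               vars)
    singles <- lapply(domains, function(d)
      stats::setNames(stats::rnorm(length(d)), d))
    pairs <- list()
    if (n_var >= 2) {
      for (i in seq_len(n_var - 1)) {
        U <- matrix(stats::rnorm(n_states^2), n_states, n_states,
                    dimnames = list(states, states))
        pairs[[length(pairs) + 1L]] <- list(vars = vars[c(i, i + 1)], U = U)
      }
    }
    triples <- list()
    if (n_var >= 3) {
      U3 <- array(stats::rnorm(n_states^3), dim = rep(n_states, 3),
                  dimnames = list(states, states, states))
      triples <- list(list(vars = vars[1:3], U = U3))
    }
    potential_set(domains, singles, pairs, triples, beta = beta)
  })
}

test_that("total energy is the term-by-term sum, with hard exclusions", {
  pots <- potential_set(list(a = c("x", "y")),
                        singles = list(a = c(x = 0, y = 0)))
  expect_equal(total_energy(c(a = "x"), pots), 0)
  pots$singles$a["x"] <- 1
  expect_equal(total_energy(c(a = "x"), pots), 1)

  ps <- small_potentials(seed = 4, n_var = 4)
  st <- c(v1 = "s1", v2 = "s3", v3 = "s2", v4 = "s1")
  # independent summation oracle
  manual <- ps$singles$v1[["s1"]] + ps$singles$v2[["s3"]] +
    ps$singles$v3[["s2"]] + ps$singles$v4[["s1"]] +
    ps$pairs[[1]]$U["s1", "s3"] + ps$pairs[[2]]$U["s3", "s2"] +
    ps$pairs[[3]]$U["s2", "s1"] + ps$triples[[1]]$U["s1", "s3", "s2"]
  expect_equal(total_energy(st, ps), manual)
  ps$singles$v1[["s1"]] <- Inf
  expect_equal(total_energy(st, ps), Inf)
  expect_error(total_energy(c(v1 = "s1"), ps), "cover")
})

test_that("Boltzmann probabilities normalize and match enumeration", {
  two <- potential_set(list(a = c("x", "y")),
                       singles = list(a = c(x = 1, y = 1)))
  expect_equal(boltzmann_probability(c(a = "x"), two), 0.5)

  ps <- small_potentials(seed = 5)
  grid <- expand.grid(ps$domains, stringsAsFactors = FALSE)
  p <- vapply(seq_len(nrow(grid)), function(i)
    boltzmann_probability(unlist(grid[i, ]), ps), numeric(1))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # brute-force check of one configuration
  E <- vapply(seq_len(nrow(grid)), function(i)
    total_energy(unlist(grid[i, ]), ps), numeric(1))
  expect_equal(p, exp(-ps$beta * E) / sum(exp(-ps$beta * E)),
               tolerance = 1e-9)

  # beta -> 0 gives the uniform distribution
  ps0 <- ps; ps0$beta <- 1e-9
  p0 <- boltzmann_probability(unlist(grid[1, ]), ps0)
  expect_equal(p0, 1 / nrow(grid), tolerance = 1e-4)

  ps_bad <- potential_set(list(a = c("x", "y")),
                          singles = list(a = c(x = Inf, y = Inf)))
  expect_error(boltzmann_probability(c(a = "x"), ps_bad), "infeasible")
})

test_that("the factor-graph form reproduces the Boltzmann distribution", {
  for (seed in 1:5) {
    ps <- small_potentials(seed = seed, n_var = 3, n_states = 2)
    fg <- as_factor_graph(ps)
    oracle <- brute_force_marginals(fg)
    grid <- expand.grid(ps$domains, stringsAsFactors = FALSE)
    pb <- vapply(seq_len(nrow(grid)), function(i)
      boltzmann_probability(unlist(grid[i, ]), ps), numeric(1))
    # marginal of v1 from the Boltzmann side
    m1 <- tapply(pb, grid$v1, sum)
    expect_equal(as.numeric(m1[names(oracle$v1)]),
                 as.numeric(oracle$v1), tolerance = 1e-9)
  }
})

test_that("sum-product equals brute force on random acyclic graphs", {
  for (seed in 1:25) {
    fg <- random_factor_graph(n_var = sample(2:7, 1), n_states = 3,
                              acyclic = TRUE, seed = seed)
    mt <- run_inference(fg, damping = 0.3, max_iters = 400, tol = 1e-10)
    oracle <- brute_force_marginals(fg)
    for (v in names(oracle))
      expect_equal(unname(mt$marginals[[v]]), unname(oracle[[v]]),
                   tolerance = 1e-6)
  }
})

test_that("a single-variable graph returns its normalized factor", {
  fg <- factor_graph(list(a = c("x", "y", "z")),
                     list(list(vars = "a", table = c(2, 1, 1))))
  mt <- run_inference(fg)
  expect_equal(unname(mt$marginals$a), c(0.5, 0.25, 0.25),
               tolerance = 1e-9)
})

test_that("delta factors are exp(-beta U) with exclusions at zero", {
  ps <- small_potentials(seed = 8, n_var = 2, n_states = 2)
  ps$singles$v1[["s1"]] <- Inf
  fg <- as_factor_graph(ps)
  unary1 <- fg$factors[[1]]
  expect_equal(unary1$table[1], 0)
  expect_equal(unary1$table[2],
               exp(-ps$beta * ps$singles$v1[["s2"]]))
  # energies recoverable up to the hard exclusions
  pairf <- fg$factors[[3]]
  expect_equal(-log(pairf$table) / ps$beta, unname(ps$pairs[[1]]$U),
               tolerance = 1e-12)
})

# --- the assignment graph ---------------------------------------------

planted_systems <- function(seqs, seed) {
  s <- sample_shifts(seqs, ss = "auto", seed = seed)
  sh <- s$shifts
  sys <- lapply(anchored_residues(s), function(r) {
    x <- rdassign:::new_spin_system(paste0("sys", r), paste0("a", r),
                                    h = sh[r, "H"], n = sh[r, "N"],
                                    anchor_src = r)
    put <- function(f, v, src) {
      if (is.na(v)) return()
      x$fields[[f]] <<- field_dist(v, 0.9, 0.1, list(character(0)),
                                   h_support = sh[r, "H"], src = src)
    }
    put("CA", sh[r, "CA"], r); put("CB", sh[r, "CB"], r)
    put("CO", sh[r, "C"], r)
    if (r > 1) {
      put("CA_prev", sh[r - 1, "CA"], r - 1)
      put("CB_prev", sh[r - 1, "CB"], r - 1)
      put("CO_prev", sh[r - 1, "C"], r - 1)
    }
    x$quality <- rdassign:::system_quality(x)
    x
  })
  list(sample = s, systems = sys)
}

test_that("build_graph lays out domains, exclusions and glycine priors", {
  fx <- planted_systems("ADE", 41)
  g <- build_graph(fx$systems[1], "ADE")
  expect_equal(ncol(g$logpsi), 4L)    # 3 positions + null
  expect_equal(g$logpsi[1, 1], 0)     # null state is the reference

  # a system with a solid CB choice is penalized at a glycine position
  fxg <- planted_systems("AAGAA", 42)
  gg <- build_graph(fxg$systems, "AAGAA")
  sys_cb <- which(vapply(fxg$systems, function(s)
    !rdassign:::is_null_field(s$fields[["CB"]]), logical(1)))[1]
  expect_lt(gg$logpsi[sys_cb, 3 + 1], max(gg$logpsi[sys_cb, -1]))

  # sequentially consistent systems beat non-adjacent placements
  expect_gt(gg$C[1, 2], 5)            # residue 1 then residue 2
  expect_lt(gg$C[3, 2], 1)            # mismatching links fall below neutral
  expect_equal(diag(gg$C), rep(0, 5)) # hard self-succession exclusion
})

test_that("the structured graph agrees with its generic expansion", {
  fx <- planted_systems("ADEK", 43)
  g <- build_graph(fx$systems, "ADEK")
  mt_fast <- run_inference(g, damping = 0.4, max_iters = 400, tol = 1e-8)
  fg <- as_factor_graph(g)
  oracle <- brute_force_marginals(fg)
  for (v in names(oracle)) {
    expect_equal(unname(mt_fast$marginals[[v]]), unname(oracle[[v]]),
                 tolerance = 0.05)
  }
  # and the top state agrees exactly
  for (v in names(oracle))
    expect_equal(which.max(mt_fast$marginals[[v]]),
                 which.max(oracle[[v]]))
})

test_that("inference recovers a planted mapping on clean systems", {
  hits <- 0L; total <- 0L
  for (seed in 1:6) {
    seqs <- simple_sequence(8, seed + 50)
    fx <- planted_systems(seqs, seed + 50)
    perm <- withr::with_seed(seed, sample(fx$systems))
    g <- build_graph(perm, seqs)
    mt <- infer_with_decimation(g, max_iters = 150, tol = 1e-6)
    assign <- extract_assignment(mt, perm, seqs)
    truth <- vapply(perm, function(s) s$anchor_src, integer(1))
    ids <- vapply(perm, function(s) s$id, character(1))
    want <- stats::setNames(ids, truth)
    ok <- sum(assign$winner[as.integer(names(want))] == want,
              na.rm = TRUE)
    hits <- hits + ok
    total <- total + length(want)
  }
  expect_gte(hits / total, 0.9)
})

test_that("extract_assignment resolves conflicts deterministically", {
  fx <- planted_systems("ADEK", 44)
  g <- build_graph(fx$systems, "ADEK")
  mt <- run_inference(g, max_iters = 300, tol = 1e-8)
  a1 <- extract_assignment(mt, fx$systems, "ADEK")
  a2 <- extract_assignment(mt, fx$systems, "ADEK")
  expect_identical(a1$winner, a2$winner)
  expect_true(!anyDuplicated(stats::na.omit(a1$winner)))
  expect_gte(a1$score, 0)
  expect_lte(a1$score, 1)
})

test_that("secondary structure follows the secondary shifts", {
  seqs <- paste(rep("A", 12), collapse = "")
  st <- shift_stats()
  mu <- st[st$aa == "A", ]
  shifts <- matrix(NA_real_, 12, 5,
                   dimnames = list(NULL, c("H", "N", "CA", "CB", "C")))
  for (nu in c("CA", "CB", "C"))
    shifts[, nu] <- mu$mean[mu$nucleus == nu]
  assign <- structure(list(sequence = seqs, shifts = shifts,
                           winner = rep("x", 12)),
                      class = "assignment_state")
  flat <- secondary_structure(assign)
  # at the random-coil means no structured state may take over (coil
  # itself is legitimately modal for coil-mean shifts)
  expect_true(all(flat$ss[, "H"] < 0.5))
  expect_true(all(flat$ss[, "E"] < 0.5))
  expect_true(all(colnames(flat$ss)[apply(flat$ss, 1, which.max)] == "C"))

  helix <- assign
  off <- ss_offsets()
  for (nu in c("CA", "CB", "C"))
    helix$shifts[3:10, nu] <- helix$shifts[3:10, nu] + off["H", nu]
  hss <- secondary_structure(helix)
  expect_true(all(colnames(hss$ss)[apply(hss$ss[5:8, ], 1, which.max)] ==
                  "H"))
})

test_that("outlier flags fire beyond 4 SD only", {
  st <- shift_stats()
  mu <- st[st$aa == "A" & st$nucleus == "CA", ]
  shifts <- matrix(NA_real_, 2, 5,
                   dimnames = list(NULL, c("H", "N", "CA", "CB", "C")))
  shifts[1, "CA"] <- mu$mean
  shifts[2, "CA"] <- mu$mean + 5.5 * mu$sd
  assign <- structure(list(sequence = "AA", shifts = shifts, ss = NULL),
                      class = "assignment_state")
  flagged <- detect_outliers(assign)
  expect_false(flagged$outliers[1, "CA"])
  expect_true(flagged$outliers[2, "CA"])
})
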