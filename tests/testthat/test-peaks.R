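# Peak probabilities, registration, candidate reconstruction and updates.

test_that("conclusive probability is a monotone logistic with guards", {
  p <- conclusive_probability(c(0.05, 0.2, 1, 5), 0.05, 50, "HNCO")
  expect_true(all(diff(p) > 0))
  expect_lte(p[1], 0.5)             # at the noise floor
  expect_gt(p[4], 0.99)
  expect_error(conclusive_probability(1, 0, 50, "HNCO"), "positive")
  expect_error(conclusive_probability(1, -1, 50, "HNCO"), "positive")
})

test_that("true peaks rank above artifacts on simulated HNCO planes", {
  hits <- vapply(1:20, function(sd) {
    s <- sample_shifts(simple_sequence(20, sd), ss = "auto", seed = sd)
    pk <- generate_true_peaks(s, "HNCO")
    pl <- simulate_plane(pk, "HNCO", 40L,
                         noise_model(artifact_rate = 5, seed = sd))
    pl <- rdassign:::pick_peaks(pl, 20)
    ob <- pl$peaks
    if (!any(ob$artifact)) return(1)
    top_art <- max(ob$conclusive_prob[ob$artifact])
    mean(ob$conclusive_prob[!ob$artifact] > top_art)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("register_planes recovers injected 1H offsets", {
  s <- sample_shifts(simple_sequence(20, 9), ss = "auto", seed = 9)
  pk <- generate_true_peaks(s, "HNCO")
  a <- simulate_plane(pk, "HNCO", 30L, noiseless(1))
  b <- simulate_plane(pk, "HNCO", 50L, noiseless(2))
  reg0 <- register_planes(list(a, b))
  expect_lt(max(abs(reg0$offsets)), 0.011)   # already aligned

  b_shift <- b
  b_shift$peaks$h_ppm <- b_shift$peaks$h_ppm + 0.02
  reg <- register_planes(list(a, b_shift))
  expect_lt(abs(reg$offsets[2] - 0.02), 0.005)
  expect_equal(reg$planes[[2]]$peaks$h_ppm, b$peaks$h_ppm, tolerance = 1e-6)

  # degenerate case: a single shared peak defines the offset exactly
  a1 <- a; a1$peaks <- a$peaks[1, ]
  b1 <- b; b1$peaks <- a$peaks[1, ]
  b1$peaks$h_ppm <- b1$peaks$h_ppm + 0.01
  reg1 <- register_planes(list(a1, b1))
  expect_equal(reg1$offsets[2], 0.01, tolerance = 1e-9)
})

make_orthogonal <- function(seqs, seed, experiment = "HNCO") {
  cfg <- run_config(seed = seed)
  s <- sample_shifts(seqs, ss = "auto", seed = seed)
  spec <- sim_spectrometer(s, noiseless(seed), cfg)
  hsqc <- rdassign:::pick_peaks(spec("HSQC", 90L), nchar(seqs))
  hc <- rdassign:::pick_peaks(spec(experiment, 0L), nchar(seqs))
  list(sample = s, hsqc = hsqc, hc = hc, spec = spec, cfg = cfg)
}

test_that("reconstruct_candidates pairs orthogonal planes on common 1H", {
  fx <- make_orthogonal(simple_sequence(10, 21), 21)
  cands <- reconstruct_candidates(fx$hsqc, fx$hc, h_tol = 0.03)
  true_pk <- generate_true_peaks(fx$sample, "HNCO")
  # every true 3D peak has a candidate at its coordinates
  found <- vapply(seq_len(nrow(true_pk)), function(i)
    any(abs(cands$h_ppm - true_pk$h_ppm[i]) <= 0.03 &
        abs(cands$n_ppm - true_pk$n_ppm[i]) <= 0.2 &
        abs(cands$c_ppm - true_pk$c_ppm[i]) <= 0.2), logical(1))
  expect_true(all(found))

  # disjoint 1H coordinates produce nothing
  hc2 <- fx$hc
  hc2$peaks$h_ppm <- hc2$peaks$h_ppm + 5
  expect_equal(nrow(reconstruct_candidates(fx$hsqc, hc2, 0.03)), 0L)

  # one HSQC peak and two C peaks within tolerance give two candidates
  h1 <- fx$hsqc; h1$peaks <- h1$peaks[1, ]
  hc3 <- fx$hc
  hc3$peaks <- hc3$peaks[1:2, ]
  hc3$peaks$h_ppm <- h1$peaks$h_ppm + c(0.01, -0.01)
  two <- reconstruct_candidates(h1, hc3, 0.03)
  expect_equal(nrow(two), 2L)
  expect_equal(unique(two$n_ppm), h1$peaks$v_hz / h1$fc$n_mhz)
})

test_that("update_candidates supports, penalizes and prunes", {
  fx <- make_orthogonal(simple_sequence(10, 22), 22)
  cands <- reconstruct_candidates(fx$hsqc, fx$hc, h_tol = 0.03)
  pl <- rdassign:::pick_peaks(fx$spec("HNCO", 33L), 10)
  upd <- update_candidates(cands, pl)
  # a plane containing exact projections never lowers a matching
  # candidate's probability
  shared <- intersect(upd$id, cands$id)
  p0 <- stats::setNames(cands$conclusive_prob, cands$id)[shared]
  p1 <- stats::setNames(upd$conclusive_prob, upd$id)[shared]
  matched_up <- p1 >= p0
  expect_true(any(matched_up))

  # three consecutive misses prune a candidate at the default factors
  lone <- cands[1, ]
  lone$c_ppm <- 170.0   # nothing observed there
  lone$h_ppm <- 6.0
  for (ang in c(31L, 44L, 57L)) {
    pl <- rdassign:::pick_peaks(fx$spec("HNCO", ang), 10)
    lone <- update_candidates(lone, pl)
  }
  expect_equal(nrow(lone), 0L)

  expect_error(update_candidates(cands, fx$hc), "tilted")
})

test_that("probabilities stay in [0, 1] under any update sequence", {
  fx <- make_orthogonal(simple_sequence(12, 23), 23)
  cands <- reconstruct_candidates(fx$hsqc, fx$hc, h_tol = 0.03)
  for (ang in c(15L, -15L, 60L, -60L, 72L)) {
    pl <- rdassign:::pick_peaks(fx$spec("HNCO", ang), 12)
    cands <- update_candidates(cands, pl)
    expect_true(all(cands$conclusive_prob >= 0 &
                    cands$conclusive_prob <= 1))
  }
})
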