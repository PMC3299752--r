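# Spin systems: initialization, field distributions, overlap, splitting.

init_fixture <- function(seqs, seed, noise = noiseless(seed)) {
  cfg <- run_config(seed = seed)
  s <- sample_shifts(seqs, ss = "auto", seed = seed)
  spec <- sim_spectrometer(s, noise, cfg)
  hsqc <- rdassign:::pick_peaks(spec("HSQC", 90L), nchar(seqs))
  cands <- rdassign:::empty_candidates()
  for (e in rdassign:::EXPERIMENTS) {
    hc <- rdassign:::pick_peaks(spec(e, 0L), nchar(seqs))
    cands <- rbind(cands, reconstruct_candidates(hsqc, hc, 0.03))
  }
  list(sample = s, hsqc = hsqc, cands = cands, spec = spec, cfg = cfg)
}

test_that("spin systems initialize one per accepted HSQC peak", {
  fx <- init_fixture("AAPAA", 31)
  systems <- init_spin_systems(fx$hsqc)
  expect_equal(length(systems), 4L)   # proline is unanchored, residue 1 is
  for (sys in systems) {
    expect_named(sys$fields, rdassign:::SPIN_FIELDS)
    carb <- setdiff(rdassign:::SPIN_FIELDS, c("H", "N"))
    for (f in carb) expect_equal(sys$fields[[f]]$null_prob, 1)
    expect_equal(sys$fields[["H"]]$prob, 1)
  }
  # peaks below the pick floor anchor nothing
  weak <- fx$hsqc
  weak$peaks$conclusive_prob <- 0.1
  expect_error(init_spin_systems(weak), "empty HSQC")
})

test_that("field distributions normalize and respect the null state", {
  fd <- field_dist(ppm = c(55, 58), prob = c(0.5, 0.3), null_prob = 0.2)
  expect_equal(sum(fd$prob) + fd$null_prob, 1, tolerance = 1e-9)
  expect_true(all(diff(fd$prob) <= 0))
  # unnormalized inputs are renormalized
  fd2 <- field_dist(ppm = 55, prob = 2, null_prob = 2)
  expect_equal(sum(fd2$prob) + fd2$null_prob, 1, tolerance = 1e-9)
})

test_that("update_fields routes candidates into the right fields", {
  fx <- init_fixture(simple_sequence(10, 33), 33)
  systems <- init_spin_systems(fx$hsqc)
  systems <- update_fields(systems, fx$cands)
  # normalization invariant after the update
  for (sys in systems) for (f in rdassign:::SPIN_FIELDS) {
    fd <- sys$fields[[f]]
    expect_equal(sum(fd$prob) + fd$null_prob, 1, tolerance = 1e-9)
  }
  # no candidates at all: fields stay null
  empty <- update_fields(init_spin_systems(fx$hsqc),
                         rdassign:::empty_candidates())
  for (sys in empty)
    expect_equal(sys$fields[["CO_prev"]]$null_prob, 1)

  # a single certain HNCO candidate lands in CO_prev with probability ~1
  one <- fx$cands[fx$cands$experiment == "HNCO", ][1, ]
  one$conclusive_prob <- 1
  sys1 <- init_spin_systems(fx$hsqc)
  keep <- which(vapply(sys1, function(s)
    abs(s$h_ref - one$h_ppm) <= 0.03 && abs(s$n - one$n_ppm) <= 0.4,
    logical(1)))[1]
  upd <- update_fields(sys1, one)
  fd <- upd[[keep]]$fields[["CO_prev"]]
  expect_gte(fd$prob[1], 0.99)
  expect_lte(fd$null_prob, 0.01)
})

test_that("on clean complete data true shifts become the top choices", {
  fx <- init_fixture(simple_sequence(10, 34), 34)
  systems <- init_spin_systems(fx$hsqc)
  cands <- fx$cands
  # two tilted pairs per experiment settle the candidate set
  for (e in rdassign:::EXPERIMENTS) {
    ce <- cands[cands$experiment == e, ]
    for (ang in c(35L, -35L, 55L, -55L)) {
      pl <- rdassign:::pick_peaks(fx$spec(e, ang), 10)
      ce <- update_candidates(ce, pl)
    }
    cands <- rbind(cands[cands$experiment != e, ], ce)
  }
  systems <- update_fields(systems, cands)
  sh <- fx$sample$shifts
  n_checked <- 0L
  for (sys in systems) {
    r <- sys$anchor_src
    if (is.na(r) || r < 2) next
    tops <- vapply(c(CA = "CA", CB = "CB", CO = "CO"), function(f)
      rdassign:::top_choice(sys$fields[[f]])$ppm, numeric(1))
    truth <- c(sh[r, "CA"], sh[r, "CB"], sh[r, "C"])
    expect_true(all(abs(tops - truth) < 0.2, na.rm = TRUE))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 5L)
})

test_that("orphan candidates spawn systems only with corroboration", {
  fx <- init_fixture(simple_sequence(8, 35), 35)
  systems <- init_spin_systems(fx$hsqc)
  n0 <- length(systems)
  # no orphans: nothing happens
  expect_length(add_spin_systems(systems, fx$cands), n0)
  # a corroborated orphan far from every anchor spawns one system
  orphan <- do.call(rbind, lapply(c("HNCO", "HNCA"), function(e) {
    x <- fx$cands[fx$cands$experiment == e, ][1, ]
    x$h_ppm <- 10.9; x$n_ppm <- 133; x$conclusive_prob <- 0.95
    x$n_support <- 6L; x$anchor_id <- NA_character_
    x
  }))
  grown <- add_spin_systems(systems, rbind(fx$cands, orphan))
  expect_length(grown, n0 + 1L)
  # a half-hearted orphan (single experiment, weak support) does not
  lone <- orphan[1, ]; lone$n_support <- 2L
  expect_length(add_spin_systems(systems, rbind(fx$cands, lone)), n0)
})

test_that("the overlap classifier separates merged from single systems", {
  clf <- train_overlap_classifier(n = 200, seed = 99)
  withr::with_seed(7, {
    pos <- lapply(1:60, function(i)
      rdassign:::.synth_training_system(sprintf("p%d", i), TRUE))
    neg <- lapply(1:60, function(i)
      rdassign:::.synth_training_system(sprintf("n%d", i), FALSE))
  })
  all_sys <- c(pos, neg)
  p_pos <- vapply(pos, overlap_probability, numeric(1), systems = all_sys,
                  classifier = clf)
  p_neg <- vapply(neg, overlap_probability, numeric(1), systems = all_sys,
                  classifier = clf)
  expect_gte(mean(p_pos > 0.5), 0.9)
  expect_lte(mean(p_neg >= 0.5), 0.25)
  # the positive centroid itself must classify positive
  expect_gt(overlap_probability(pos[[1]], all_sys,
                                features = clf$centroid_pos,
                                classifier = clf), 0.5)
})

test_that("splitting bipartitions choices and conserves them", {
  mk <- function(h) list(h = h)
  sys <- rdassign:::new_spin_system("m", "m", h = 8.3, n = 120)
  # two coherent choice sets, distinguishable by their support 1H
  for (f in c("CA", "CB", "CO", "CA_prev", "CB_prev", "CO_prev")) {
    base <- switch(f, CA = 55, CB = 30, CO = 176, CA_prev = 58,
                   CB_prev = 33, CO_prev = 174)
    sys$fields[[f]] <- field_dist(
      ppm = c(base, base + 3), prob = c(0.45, 0.45), null_prob = 0.1,
      sources = list("candA", "candB"),
      h_support = c(8.29, 8.32))
  }
  sys$overlap_prob <- 0.9
  kids <- split_system(sys)
  expect_length(kids, 2L)
  for (f in c("CA", "CB", "CO")) {
    parent_ppm <- sort(sys$fields[[f]]$ppm)
    child_ppm <- sort(c(kids[[1]]$fields[[f]]$ppm,
                        kids[[2]]$fields[[f]]$ppm))
    expect_equal(child_ppm, parent_ppm)     # conservation
    expect_length(kids[[1]]$fields[[f]]$ppm, 1L)  # coherent partition
  }
  expect_equal(kids[[1]]$anchor, kids[[2]]$anchor)

  # below the threshold the operation refuses
  sys$overlap_prob <- 0.3
  expect_error(split_system(sys), "threshold")
  # all-single-choice fields cannot be bipartitioned
  flat <- rdassign:::new_spin_system("f", "f", h = 8.0, n = 118)
  flat$fields[["CA"]] <- field_dist(55, 0.9, 0.1, list("x"), 8.0)
  flat$overlap_prob <- 0.9
  expect_warning(out <- split_system(flat), "bipartition")
  expect_length(out, 1L)
})

test_that("spin-system dumps are written", {
  fx <- init_fixture(simple_sequence(5, 36), 36)
  systems <- update_fields(init_spin_systems(fx$hsqc), fx$cands)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spin_systems(systems, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^spin_system ", txt)), length(systems))
  expect_true(any(grepl("null=", txt)))
})
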