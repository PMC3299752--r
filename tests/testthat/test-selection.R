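# Information-theoretic planning: entropies, weak links, experiment and
# angle choice.

test_that("field entropy has its closed forms", {
  expect_equal(field_entropy(field_dist(55, 1, 0, list(character(0)), 8)),
               0)
  u4 <- field_dist(c(1, 2, 3), rep(0.25, 3), 0.25,
                   replicate(3, character(0), simplify = FALSE), 1:3)
  expect_equal(field_entropy(u4), log(4), tolerance = 1e-9)
  half <- field_dist(c(1, 2), c(0.5, 0.5), 0,
                     replicate(2, character(0), simplify = FALSE), 1:2)
  expect_equal(field_entropy(half), log(2), tolerance = 1e-9)
  bad <- half; bad$null_prob <- 0.5
  expect_error(field_entropy(bad), "normalized")
})

weak_fixture <- function() {
  amb <- rdassign:::new_spin_system("amb", "amb", 8.2, 119)
  amb$fields[["CA"]] <- field_dist(c(55, 58), c(0.5, 0.5), 0,
                                   replicate(2, character(0),
                                             simplify = FALSE), c(8.2, 8.2))
  sure <- rdassign:::new_spin_system("sure", "sure", 8.5, 121)
  for (f in setdiff(rdassign:::SPIN_FIELDS, c("H", "N")))
    sure$fields[[f]] <- field_dist(50, 0.999, 0.001, list(character(0)),
                                   8.5)
  list(amb = amb, sure = sure)
}

test_that("weak links rank by weighted entropy", {
  fx <- weak_fixture()
  weak <- pinpoint_weak_links(list(fx$amb, fx$sure), NULL, k = 10)
  expect_equal(weak$system[1], "amb")
  expect_equal(weak$field[1], "CA")
  expect_equal(weak$entropy[1], log(2), tolerance = 1e-9)

  # an all-certain state yields nothing above the floor
  certain <- pinpoint_weak_links(list(fx$sure), NULL, k = 10)
  expect_false("sure" %in% certain$system[certain$entropy > 0.5])
})

test_that("experiment choice follows the pattern table and the gains", {
  weak_co <- data.frame(system = "s", field = "CO_prev", entropy = 1,
                        weight = 1, weighted = 1)
  expect_equal(select_experiment(weak_co, list()), "HNCO")

  weak_cb <- data.frame(system = "s", field = c("CB", "CB_prev"),
                        entropy = 1, weight = 1, weighted = c(1, 1))
  pick <- select_experiment(weak_cb, list())
  expect_true(pick %in% c("CBCA(CO)NH", "HN(CA)CB"))

  # argmax equals an independent gain summation
  weak_mix <- data.frame(system = "s",
                         field = c("CA", "CA_prev", "CO_prev"),
                         entropy = c(0.9, 0.4, 0.2), weight = 1,
                         weighted = c(0.9, 0.4, 0.2))
  pat <- experiment_patterns()
  gains <- vapply(rdassign:::EXPERIMENTS, function(e) {
    rows <- pat[pat$experiment == e, ]
    sum(vapply(seq_len(nrow(rows)), function(r)
      sum(weak_mix$weighted[weak_mix$field == rows$field[r]]) *
        rows$intensity[r], numeric(1)))
  }, numeric(1))
  expect_equal(select_experiment(weak_mix, list()),
               names(which.max(gains)))

  # exhausted experiments are unavailable
  full <- stats::setNames(rep(12L, 6), rdassign:::EXPERIMENTS)
  expect_true(is.na(select_experiment(weak_co, list(),
                                      planes_collected = full,
                                      max_planes = 12L)))
})

test_that("angle choice avoids predicted collisions and obeys the grid", {
  fc <- field_config()
  # two peaks sharing 1H that collide at 30 degrees but not at 60
  theta <- 30 * pi / 180
  dn <- 3
  dc_hz <- -dn * fc$n_mhz * tan(theta)
  pk <- data.frame(h_ppm = c(8.20, 8.21),
                   c_ppm = c(55, 55 + dc_hz / fc$c_mhz),
                   n_ppm = c(115, 115 + dn))
  ang <- select_angle("HNCA", character(0), pk, collected = integer(0),
                      resolution = 30, fc = fc)
  expect_false(ang == 30L)
  pred <- abs(project_frequency(diff(pk$c_ppm), diff(pk$n_ppm), ang, fc))

  # collision-free situations fall back to the smallest angle
  apart <- data.frame(h_ppm = c(7, 9), c_ppm = c(50, 60),
                      n_ppm = c(110, 125))
  expect_equal(select_angle("HNCA", character(0), apart), 1L)

  # the grid is 1..89 minus collected planes, and exhausts cleanly
  expect_equal(select_angle("HNCA", character(0), apart,
                            collected = 1:3), 4L)
  expect_true(is.na(select_angle("HNCA", character(0), apart,
                                 collected = 1:89)))
})

test_that("plans never revisit a collected plane", {
  fx <- weak_fixture()
  cands <- rdassign:::empty_candidates()
  collected <- data.frame(experiment = rep(rdassign:::EXPERIMENTS, 2),
                          angle = rep(c(0L, 25L), each = 6))
  cfg <- run_config(seed = 1)
  plan <- plan_next(list(fx$amb, fx$sure), NULL, cands, collected, cfg)
  expect_false(is.null(plan))
  hit <- collected$experiment == plan$experiment &
    abs(collected$angle) == plan$angle_deg
  expect_false(any(hit))
})
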