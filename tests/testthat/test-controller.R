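# The adaptive loop: termination rules, checkpointing, reports, and
# end-to-end behaviour on small fixtures.

test_that("should_continue implements the stated decision rules", {
  cfg <- run_config(seed = 1)
  mk_state <- function(scores, iter, quality = 0.9,
                       collected = data.frame(experiment = "HNCO",
                                              angle = 30L)) {
    sys <- rdassign:::new_spin_system("s1", "s1", 8.2, 120)
    sys$quality <- quality
    list(score_history = scores, quality_history = scores,
         nsys_history = rep(1L, length(scores)), iteration = iter,
         systems = list(sys), collected = collected,
         assignment = NULL, last_assign_iter = iter)
  }
  expect_error(should_continue(mk_state(numeric(0), 1), cfg),
               "no assignment")
  # target reached (score and quality)
  dec <- should_continue(mk_state(0.99, 2), cfg)
  expect_false(dec$continue)
  expect_match(dec$reason, "target")
  # below minimum iterations: continue
  expect_true(should_continue(mk_state(c(0.4, 0.5), 2), cfg)$continue)
  # flat history beyond the minimum iteration count: stalled
  dec2 <- should_continue(mk_state(c(0.6, 0.602, 0.603), 13), cfg)
  expect_false(dec2$continue)
  expect_match(dec2$reason, "stall")
  # hard quality floor
  dec3 <- should_continue(mk_state(c(0.2, 0.25, 0.4), 13, quality = 0.05),
                          cfg)
  expect_false(dec3$continue)
})

test_that("a clean small run reaches the target before exhaustion", {
  seqs <- simple_sequence(20, 61)
  run <- quiet_run(seqs, 61, noise = noiseless(61))
  st <- run$state
  expect_lt(st$iteration, 6 * run$config$max_pairs)
  expect_gte(utils::tail(st$score_history, 1), run$config$target_score)
  ev <- evaluate_against_truth(st$assignment, run$sample)
  expect_gte(ev$completeness, 0.9)
  expect_gte(ev$accuracy, 0.95)
})

test_that("a zero target stops after the first assignment phase", {
  seqs <- simple_sequence(10, 62)
  run <- quiet_run(seqs, 62, noise = noiseless(62), target_score = 0,
                   quality_target = 0)
  expect_equal(length(run$state$score_history), 1L)
  expect_match(run$state$stop_reason, "target")
})

test_that("checkpoints restore bit-identically and resume seamlessly", {
  seqs <- simple_sequence(10, 63)
  cfg <- run_config(seed = 63)
  sample <- sample_shifts(seqs, seed = 63)
  spec <- sim_spectrometer(sample, noiseless(63), cfg)
  # uninterrupted reference run
  st <- suppressWarnings(run_assignment(seqs, cfg, spec))
  # interrupted run: stop after two iterations, checkpoint, resume
  ck <- withr::local_tempfile(fileext = ".rds")
  mid <- suppressWarnings(run_assignment(seqs, cfg, spec,
                                         checkpoint_path = ck,
                                         max_iterations = 2))
  expect_equal(mid$stop_reason, "iteration cap")
  # save -> load -> save produces identical bytes
  st2 <- load_checkpoint(ck)
  ck2 <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st2, ck2)
  expect_identical(readBin(ck, "raw", file.size(ck)),
                   readBin(ck2, "raw", file.size(ck2)))
  resumed <- suppressWarnings(run_assignment(seqs, cfg, spec,
                                             resume_from = ck))
  expect_identical(resumed$assignment$shifts, st$assignment$shifts)
  expect_identical(resumed$score_history, st$score_history)
})

test_that("write_report emits the full file set and valid JSON", {
  seqs <- simple_sequence(10, 64)
  run <- quiet_run(seqs, 64, noise = noiseless(64))
  dir <- withr::local_tempdir()
  paths <- write_report(run$state, dir, truth = run$sample)
  expect_true(all(file.exists(file.path(dir,
    c("shifts.tsv", "shifts.str", "secondary_structure.tsv",
      "spin_systems.txt", "candidates.list", "run.json")))))
  js <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(js$sequence, seqs)
  expect_true(is.numeric(js$evaluation$completeness))
  star <- readLines(file.path(dir, "shifts.str"))
  expect_true(any(grepl("loop_", star)))
  expect_true(any(grepl("_Atom_chem_shift.Val", star)))

  # an empty state still writes headers-only files
  empty <- run$state
  empty$assignment <- NULL
  empty$systems <- list()
  dir2 <- withr::local_tempdir()
  write_report(empty, dir2)
  expect_true(file.exists(file.path(dir2, "shifts.tsv")))
})

test_that("evaluate_against_truth computes the three metrics", {
  seqs <- "ACDEF"
  truth <- sample_shifts(seqs, ss = "CCCCC", seed = 70)
  shifts <- truth$shifts
  src <- matrix(rep(1:5, 5), 5, 5,
                dimnames = list(NULL, colnames(shifts)))
  perfect <- structure(list(sequence = seqs, shifts = shifts,
                            shift_src = src,
                            winner = paste0("s", 1:5),
                            ss = {
                              m <- matrix(0, 5, 3,
                                          dimnames = list(NULL,
                                                          c("H", "E", "C")))
                              m[, "C"] <- 1; m
                            }),
                       class = "assignment_state")
  ev <- evaluate_against_truth(perfect, truth)
  expect_equal(ev$completeness, 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$ss_accuracy, 1)

  # one wrong residue mapping out of ten reported shifts
  some <- perfect
  some$shifts[] <- NA
  some$shifts[1:2, ] <- truth$shifts[1:2, ]
  some$shift_src[2, ] <- 4L
  ev2 <- evaluate_against_truth(some, truth)
  expect_equal(ev2$accuracy, 0.5)

  # the empty assignment reports accuracy 1 with the flag set
  none <- perfect
  none$shifts[] <- NA
  ev3 <- evaluate_against_truth(none, truth)
  expect_equal(ev3$completeness, 0)
  expect_equal(ev3$accuracy, 1)
  expect_true(ev3$empty)
})

test_that("the spectrometer serves deterministic, seeded planes", {
  seqs <- simple_sequence(8, 65)
  cfg <- run_config(seed = 65)
  s <- sample_shifts(seqs, seed = 65)
  spec <- sim_spectrometer(s, mild_noise(65), cfg)
  a <- spec("HNCA", 37L, 1L)
  b <- spec("HNCA", 37L, 1L)
  expect_equal(a$peaks$h_ppm, b$peaks$h_ppm)
  d <- spec("HNCA", -37L, 1L)
  expect_false(isTRUE(all.equal(a$peaks$v_hz, d$peaks$v_hz)))
  expect_error(spec("XXX", 10L, 1L), "unknown experiment")
})
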