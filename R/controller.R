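# The adaptive data-collection loop: acquire planes from the (simulated)
# spectrometer, process peaks, update spin systems, run assignment when the
# systems are good enough, plan the next plane, and decide termination.

#' Run configuration
#'
#' Every tunable of the engine with its default.  Units: ppm for shift
#' tolerances, Hz for the combined dimension.
#'
#' @param seed simulation / run seed (mandatory for reproducible runs).
#' @param target_score stop once the assignment score reaches this.
#' @param max_pairs maximum +/- plane pairs per experiment.
#' @param min_improvement minimum score improvement over the last two
#'   iterations before the run is declared stalled.
#' @param min_iterations iterations before the stall / quality rules apply.
#' @param quality_floor hard floor on mean spin-system quality.
#' @param quality_gate mean spin-system quality required to enter the
#'   assignment phase.
#' @param quality_target mean spin-system quality required, together with
#'   the target score, before the run stops as "target reached".
#' @param h_tol 1H matching tolerance (ppm).
#' @param n_tol 15N anchor-matching tolerance (ppm).
#' @param resolution plane resolution in the combined dimension (Hz).
#' @param noise_floor initial per-plane noise floor.
#' @param beta pseudo-energy inverse-temperature scale.
#' @param damping,bp_tol,bp_iters loopy message-passing controls.
#' @param weak_k weak links considered by the planner.
#' @param tol_h,tol_n,tol_c evaluation tolerances against ground truth.
#' @param field_mhz spectrometer 1H frequency (MHz).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, target_score = 0.97, max_pairs = 6L,
                       min_improvement = 0.005, min_iterations = 4L,
                       quality_floor = 0.1, quality_gate = 0.25,
                       quality_target = 0.7,
                       h_tol = 0.03, n_tol = 0.4, resolution = 30,
                       noise_floor = 0.05, beta = 1, damping = 0.5,
                       bp_tol = 3e-4, bp_iters = 100L, weak_k = 10L,
                       tol_h = 0.06, tol_n = 0.4, tol_c = 0.25,
                       field_mhz = 600.13) {
  structure(list(seed = as.integer(seed), target_score = target_score,
                 max_pairs = as.integer(max_pairs),
                 min_improvement = min_improvement,
                 min_iterations = as.integer(min_iterations),
                 quality_floor = quality_floor, quality_gate = quality_gate,
                 quality_target = quality_target,
                 h_tol = h_tol, n_tol = n_tol, resolution = resolution,
                 noise_floor = noise_floor, beta = beta, damping = damping,
                 bp_tol = bp_tol, bp_iters = as.integer(bp_iters),
                 weak_k = as.integer(weak_k), tol_h = tol_h, tol_n = tol_n,
                 tol_c = tol_c, fc = field_config(field_mhz)),
            class = "run_config")
}

# One HSQC peak per anchored residue (the 90-degree projection shared by
# all amide-rooted experiments).
hsqc_true_peaks <- function(sample) {
  anchors <- anchored_residues(sample)
  sh <- sample$shifts
  out <- data.frame(residue = anchors, experiment = "HNCA",
                    h_ppm = sh[anchors, "H"], n_ppm = sh[anchors, "N"],
                    c_ppm = sh[anchors, "CA"], kind = "HSQC",
                    intensity = 1.0, src_residue = anchors,
                    artifact = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("true_peaks", "data.frame")
  out
}

#' Simulated spectrometer
#'
#' Returns a plane provider: a function `(experiment, angle_deg,
#' collected_at)` that generates the requested tilted plane from the
#' ground-truth sample under the noise model.  `experiment = "HSQC"` (with
#' angle 90) serves the shared amide anchor plane.
#'
#' @param sample a `true_sample`.
#' @param noise a [noise_model()].
#' @param config a [run_config()].
#' @return plane-provider function.
#' @export
sim_spectrometer <- function(sample, noise, config = run_config()) {
  true_cache <- list(HSQC = hsqc_true_peaks(sample))
  for (e in EXPERIMENTS) true_cache[[e]] <- generate_true_peaks(sample, e)
  function(experiment, angle_deg, collected_at = 0L) {
    key <- if (identical(experiment, "HSQC")) "HSQC" else {
      check_experiment(experiment)
      experiment
    }
    pk <- true_cache[[key]]
    exp_label <- if (key == "HSQC") "HNCA" else key
    nm <- noise
    if (key == "HSQC") nm$seed <- noise$seed + 777L
    simulate_plane(pk, exp_label, angle_deg, noise = nm,
                   resolution = config$resolution, fc = config$fc,
                   h_tol = config$h_tol, noise_floor = config$noise_floor,
                   collected_at = collected_at)
  }
}

#' Decide whether data collection should continue
#'
#' Stop when the target score is reached; when every experiment has its
#' maximum number of planes; when, after the minimum iteration count, the
#' score improvement over the last two completed assignment phases falls
#' below `min_improvement`; or when the mean spin-system quality sits below
#' the hard quality floor after the minimum iteration count.
#'
#' @param state a `run_state`.
#' @param config a [run_config()].
#' @return list with logical `continue` and a `reason` string.
#' @export
should_continue <- function(state, config) {
  hist <- state$score_history
  if (!length(hist)) stop("no assignment phase completed yet")
  score <- hist[length(hist)]
  mq <- mean_quality(state)
  # reaching the mapping target only counts once the spin-system fields
  # themselves are resolved (the quality factors of the decision)
  if (score >= config$target_score && mq >= config$quality_target)
    return(list(continue = FALSE, reason = "target reached"))
  tilted <- state$collected[!(state$collected$angle %in% c(0L, 90L)), ,
                            drop = FALSE]
  counts <- table(factor(tilted$experiment, levels = EXPERIMENTS))
  if (all(counts >= 2L * config$max_pairs))
    return(list(continue = FALSE, reason = "plane budget exhausted"))
  # improvement-based stopping presumes the run had a fair chance: either
  # the score is already in sight of the target, or the iteration count is
  # commensurate with the protein size (more residues warrant more planes)
  ripe <- score >= 0.6 * config$target_score ||
    state$iteration >= max(2L * length(EXPERIMENTS),
                           ceiling(nchar(state$sequence) / 3))
  if (state$iteration >= config$min_iterations && length(hist) >= 3L &&
      ripe) {
    imp <- score - hist[length(hist) - 2L]
    qh <- state$quality_history
    qimp <- if (length(qh) >= 3L) qh[length(qh)] - qh[length(qh) - 2L] else 1
    nh <- state$nsys_history
    # early on, churn in the system set (splits, recovered anchors) counts
    # as progress; late in the run it no longer defers the stall decision
    grew <- length(nh) >= 3L && nh[length(nh)] != nh[length(nh) - 2L] &&
      state$iteration < 3L * length(EXPERIMENTS)
    # the run is stalled only when neither the mapping score nor the
    # spin-system quality is improving and the system set has settled
    if (imp < config$min_improvement && qimp < config$min_improvement &&
        !grew)
      return(list(continue = FALSE, reason = "stalled"))
  }
  if (state$iteration >= config$min_iterations &&
      !is.null(state$last_assign_iter) &&
      state$iteration - state$last_assign_iter >= 3L)
    return(list(continue = FALSE, reason = "quality stalled"))
  if (state$iteration >= config$min_iterations && mq < config$quality_floor)
    return(list(continue = FALSE, reason = "quality below floor"))
  list(continue = TRUE, reason = "continue")
}

# Mean spin-system quality over the systems that carry the assignment
# (winners when an assignment exists); unassigned leftovers (artifact
# anchors, spare split children) park at the null state and do not gate
# the termination decision.
mean_quality <- function(state, assigned_only = TRUE) {
  q <- vapply(state$systems, function(s) s$quality, numeric(1))
  if (assigned_only && !is.null(state$assignment)) {
    ids <- vapply(state$systems, function(s) s$id, character(1))
    used <- ids %in% state$assignment$winner
    if (any(used)) q <- q[used]
  }
  mean(q)
}

#' Run the goal-directed assignment loop
#'
#' Phase 1 collects the 90-degree HSQC and the six 0-degree 1H-13C
#' orthogonal planes and builds initial candidates and spin systems.  Each
#' iteration then plans the most informative (experiment, angle), acquires
#' the +/- pair, updates candidates and spin systems (including overlap
#' splitting and orphan recovery), runs factor-graph inference once the
#' spin systems pass the quality gate, and applies the termination rule.
#'
#' @param sequence protein sequence (one-letter string).
#' @param config a [run_config()].
#' @param spectrometer plane provider, e.g. from [sim_spectrometer()].
#' @param checkpoint_path optional RDS path written after every iteration.
#' @param resume_from optional checkpoint to restore before continuing.
#' @param verbose log each iteration's plan and score.
#' @param max_iterations optional hard cap on collection iterations for
#'   this call (the run can later be resumed from its checkpoint).
#' @return final `run_state`.
#' @export
run_assignment <- function(sequence, config = run_config(), spectrometer,
                           checkpoint_path = NULL, resume_from = NULL,
                           verbose = FALSE, max_iterations = Inf) {
  get_overlap_classifier(auto_train = TRUE)
  if (!is.null(resume_from)) {
    state <- load_checkpoint(resume_from)
  } else {
    state <- init_run_state(sequence, config, spectrometer, verbose)
  }
  priors <- shift_stats()
  repeat {
    if (state$iteration >= max_iterations) {
      state$stop_reason <- "iteration cap"
      break
    }
    plan <- plan_next(state$systems, state$marginals, state$candidates,
                      state$collected, config)
    if (is.null(plan)) {
      state$stop_reason <- "plane grid exhausted"
      break
    }
    state$iteration <- state$iteration + 1L
    state <- acquire_pair(state, plan, spectrometer, config)
    state <- refresh_systems(state, config)
    # gates on data maturity use the overall system quality; the
    # assigned-only quality is reserved for the termination decision
    mq <- mean_quality(state, assigned_only = FALSE)
    # full inference every iteration is wasted while the fields are still
    # filling up: run the assignment phase every other iteration early on,
    # every iteration once quality approaches the target
    phase_due <- mq >= config$quality_target - 0.1 ||
      state$iteration %% 2L == 0L
    if (mq >= config$quality_gate && phase_due) {
      graph <- build_graph(state$systems, state$sequence, priors,
                           beta = config$beta)
      warm <- state$messages
      # plain message passing suffices to steer the planner early on;
      # the costlier decimation rounds start once the fields approach
      # their target quality and the marginals are worth sharpening
      state$marginals <- if (mq >= config$quality_target - 0.1)
        infer_with_decimation(graph, damping = config$damping,
                              max_iters = config$bp_iters,
                              tol = config$bp_tol, warm_start = warm)
      else run_inference(graph, damping = config$damping,
                         max_iters = config$bp_iters,
                         tol = config$bp_tol, warm_start = warm)
      state$messages <- state$marginals$messages
      assign <- extract_assignment(state$marginals, state$systems,
                                   state$sequence)
      assign <- secondary_structure(assign, priors)
      assign <- detect_outliers(assign, priors)
      state$assignment <- assign
      state$score_history <- c(state$score_history, assign$score)
      state$last_assign_iter <- state$iteration
    }
    state$quality_history <- c(state$quality_history,
                               mean_quality(state, assigned_only = FALSE))
    state$nsys_history <- c(state$nsys_history, length(state$systems))
    state$plans[[length(state$plans) + 1L]] <-
      c(plan[c("experiment", "angle_deg", "expected_gain")],
        list(iteration = state$iteration,
             score = if (length(state$score_history))
               state$score_history[length(state$score_history)] else NA,
             pinpointed = plan$pinpointed))
    if (verbose)
      message(sprintf("iter %d: %s %+d deg, gain %.3f, score %s",
                      state$iteration, plan$experiment, plan$angle_deg,
                      plan$expected_gain,
                      if (length(state$score_history))
                        sprintf("%.4f", state$score_history[
                          length(state$score_history)]) else "-"))
    if (!is.null(checkpoint_path)) save_checkpoint(state, checkpoint_path)
    if (length(state$score_history)) {
      dec <- should_continue(state, config)
      if (!dec$continue) { state$stop_reason <- dec$reason; break }
    }
  }
  if (!is.null(checkpoint_path)) save_checkpoint(state, checkpoint_path)
  state
}

init_run_state <- function(sequence, config, spectrometer, verbose = FALSE) {
  seq_vec <- split_sequence(sequence)
  n_res <- length(seq_vec)
  hsqc <- spectrometer("HSQC", 90L, 0L)
  hsqc <- pick_peaks(hsqc, n_res)
  planes <- list(hsqc = hsqc)
  collected <- data.frame(experiment = "HSQC", angle = 90L)
  candidates <- empty_candidates()
  nf <- stats::setNames(rep(config$noise_floor, length(EXPERIMENTS)),
                        EXPERIMENTS)
  for (e in EXPERIMENTS) {
    hc <- spectrometer(e, 0L, 0L)
    hc <- pick_peaks(hc, n_res, nf[[e]])
    nf[[e]] <- hc$noise_floor
    reg <- register_planes(list(hsqc, hc), reference = 1L)
    hc <- reg$planes[[2L]]
    planes[[paste0(e, "@0")]] <- hc
    collected <- rbind(collected, data.frame(experiment = e, angle = 0L))
    candidates <- rbind(candidates,
                        reconstruct_candidates(hsqc, hc, config$h_tol))
  }
  systems <- init_spin_systems(hsqc)
  systems <- update_fields(systems, candidates, config$h_tol, config$n_tol)
  list(sequence = paste(seq_vec, collapse = ""), iteration = 0L,
       planes = planes, collected = collected, candidates = candidates,
       systems = systems, marginals = NULL, messages = NULL,
       assignment = NULL, score_history = numeric(0),
       quality_history = numeric(0), plans = list(),
       noise_floors = nf, config = config, seed = config$seed,
       stop_reason = NA_character_)
}

acquire_pair <- function(state, plan, spectrometer, config) {
  n_res <- nchar(state$sequence)
  e <- plan$experiment
  cand_e <- state$candidates[state$candidates$experiment == e, ,
                             drop = FALSE]
  matched <- list()
  pair <- list()
  for (sgn in c(1L, -1L)) {
    ang <- sgn * plan$angle_deg
    pl <- spectrometer(e, ang, state$iteration)
    pl <- pick_peaks(pl, n_res, state$noise_floors[[e]])
    state$noise_floors[[e]] <- pl$noise_floor
    reg <- register_planes(list(state$planes$hsqc, pl), reference = 1L)
    pl <- reg$planes[[2L]]
    cand_e <- update_candidates(cand_e, pl,
                                match_tol = 2 * config$resolution,
                                h_tol = config$h_tol)
    pair[[as.character(sgn)]] <- pl
    state$planes[[sprintf("%s@%+d", e, ang)]] <- pl
    state$collected <- rbind(state$collected,
                             data.frame(experiment = e, angle = ang))
  }
  # explained sets are recomputed from the candidates that SURVIVED both
  # pair members, so peaks whose only "explanation" was refuted can spawn
  for (sgn in c("1", "-1"))
    matched[[sgn]] <- explained_ids(cand_e, pair[[sgn]],
                                    match_tol = 2 * config$resolution,
                                    h_tol = config$h_tol)
  cand_e <- spawn_candidates(cand_e, pair[["1"]], pair[["-1"]],
                             matched[["1"]], matched[["-1"]], config$h_tol)
  state$candidates <- rbind(
    state$candidates[state$candidates$experiment != e, , drop = FALSE],
    cand_e)
  rownames(state$candidates) <- NULL
  state
}

refresh_systems <- function(state, config) {
  systems <- add_spin_systems(state$systems, state$candidates,
                              config$h_tol, config$n_tol)
  systems <- update_fields(systems, state$candidates, config$h_tol,
                           config$n_tol)
  n_before <- length(systems)
  systems <- apply_splitting(systems, state$candidates)
  if (length(systems) != n_before)
    systems <- update_fields(systems, state$candidates, config$h_tol,
                             config$n_tol)
  systems <- dedupe_systems(systems)
  # hard population cap: at most a few systems beyond the anchorable
  # residue count; drop the weakest unassigned leftovers beyond it
  cap <- sum(split_sequence(state$sequence) != "P") + 4L
  if (length(systems) > cap) {
    q <- vapply(systems, function(s) s$quality, numeric(1))
    ids <- vapply(systems, function(s) s$id, character(1))
    protected <- if (!is.null(state$assignment))
      ids %in% state$assignment$winner else rep(FALSE, length(systems))
    droppable <- order(ifelse(protected, Inf, q))
    drop <- droppable[seq_len(min(length(systems) - cap,
                                  sum(!protected)))]
    if (length(drop)) systems <- systems[-drop]
  }
  state$systems <- systems
  state
}

# Drop clear duplicates: two systems from different families sitting on
# the same (H, N) spot describe one amide; the far weaker one goes.
dedupe_systems <- function(systems, h_win = 0.02, n_win = 0.25) {
  if (length(systems) < 2L) return(systems)
  hs <- vapply(systems, function(s) s$h_ref, numeric(1))
  ns <- vapply(systems, function(s) s$n, numeric(1))
  fam <- vapply(systems, function(s) s$family, character(1))
  q <- vapply(systems, function(s) s$quality, numeric(1))
  drop <- rep(FALSE, length(systems))
  for (i in seq_along(systems)) {
    if (drop[i]) next
    dup <- which(!drop & seq_along(systems) != i & fam != fam[i] &
                 abs(hs - hs[i]) <= h_win & abs(ns - ns[i]) <= n_win)
    for (j in dup)
      if (q[j] < 0.5 * q[i]) drop[j] <- TRUE
  }
  systems[!drop]
}

#' Save / load a run checkpoint
#'
#' The run state is fully serializable; `save -> load -> save` produces
#' byte-identical files, which is what makes restarts reproducible.
#'
#' @param state a `run_state`.
#' @param path RDS file path.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Compare an assignment against the ground truth
#'
#' * completeness: fraction of assignable backbone resonances (present in
#'   the truth and reachable through some anchored amide) with a reported
#'   shift;
#' * accuracy: fraction of reported shifts that are within tolerance of the
#'   truth at their residue and whose evidence traces back to that residue;
#' * ss_accuracy: fraction of assigned residues whose modal predicted
#'   secondary-structure state matches the truth.
#'
#' @param assignment an `assignment_state`.
#' @param truth the `true_sample` behind the simulation.
#' @param tol named per-nucleus tolerances (ppm); defaults from the config.
#' @return list with `completeness`, `accuracy`, `ss_accuracy`, counts, and
#'   an `empty` flag (empty assignments report accuracy 1 with the flag).
#' @export
evaluate_against_truth <- function(assignment, truth,
                                   tol = c(H = 0.06, N = 0.4, CA = 0.25,
                                           CB = 0.25, C = 0.25)) {
  sh_true <- truth$shifts
  L <- nrow(sh_true)
  anchors <- anchored_residues(truth)
  anchored <- seq_len(L) %in% anchors
  assignable <- matrix(FALSE, L, 5, dimnames = list(NULL, BACKBONE_NUCLEI))
  for (nu in BACKBONE_NUCLEI) {
    present <- !is.na(sh_true[, nu])
    reach <- if (nu %in% c("H", "N")) anchored
             else anchored | c(anchored[-1L], FALSE)
    assignable[, nu] <- present & reach
  }
  reported <- !is.na(assignment$shifts)
  completeness <- if (any(assignable))
    sum(reported & assignable) / sum(assignable) else 0
  n_rep <- sum(reported)
  if (n_rep == 0L) {
    acc <- 1.0
  } else {
    idx <- which(reported, arr.ind = TRUE)
    ok <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      k <- idx[r, 1]; nu <- colnames(reported)[idx[r, 2]]
      tv <- sh_true[k, nu]
      src <- assignment$shift_src[k, idx[r, 2]]
      ok[r] <- !is.na(tv) &&
        abs(assignment$shifts[k, idx[r, 2]] - tv) <= tol[[nu]] &&
        (is.na(src) || src == k)
    }
    acc <- mean(ok)
  }
  assigned <- !is.na(assignment$winner)
  ss_acc <- if (!is.null(assignment$ss) && any(assigned)) {
    modal <- colnames(assignment$ss)[apply(assignment$ss, 1L, which.max)]
    mean(modal[assigned] == truth$ss_true[assigned])
  } else NA_real_
  list(completeness = completeness, accuracy = acc, ss_accuracy = ss_acc,
       n_assignable = sum(assignable), n_reported = n_rep,
       empty = n_rep == 0L)
}

#' Write the run report
#'
#' Shift table (TSV and NMR-STAR loop), secondary-structure table,
#' spin-system dump, candidate peak lists, and a JSON run summary with the
#' per-iteration plans and scores.  When ground truth is supplied the JSON
#' gains completeness / accuracy metrics.
#'
#' @param state a `run_state`.
#' @param dir output directory (created if needed).
#' @param truth optional `true_sample` for evaluation metrics.
#' @return invisible vector of written paths.
#' @export
write_report <- function(state, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  assign <- state$assignment
  if (is.null(assign)) {
    assign <- structure(list(sequence = state$sequence,
                             winner = rep(NA_character_,
                                          nchar(state$sequence)),
                             win_prob = rep(0, nchar(state$sequence)),
                             shifts = matrix(NA_real_,
                                             nchar(state$sequence), 5,
                                             dimnames = list(NULL,
                                                             BACKBONE_NUCLEI)),
                             shift_prob = NULL, shift_src = NULL,
                             ss = NULL, outliers = NULL, score = 0),
                        class = "assignment_state")
    assign$shift_prob <- assign$shifts
    assign$shift_src <- matrix(NA_integer_, nchar(state$sequence), 5)
  }
  p <- file.path(dir, "shifts.tsv"); write_assignment_tsv(assign, p)
  paths <- c(paths, p)
  p <- file.path(dir, "shifts.str"); write_nmrstar(assign, p)
  paths <- c(paths, p)
  p <- file.path(dir, "secondary_structure.tsv")
  ss <- if (!is.null(assign$ss)) assign$ss else
    matrix(1 / 3, nchar(state$sequence), 3,
           dimnames = list(NULL, c("H", "E", "C")))
  utils::write.table(
    data.frame(residue_index = seq_len(nrow(ss)),
               residue_type = split_sequence(state$sequence),
               p_H = round(ss[, "H"], 4), p_E = round(ss[, "E"], 4),
               p_C = round(ss[, "C"], 4),
               modal = colnames(ss)[apply(ss, 1L, which.max)]),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "spin_systems.txt")
  write_spin_systems(state$systems, p); paths <- c(paths, p)
  p <- file.path(dir, "candidates.list")
  write_candidates(state$candidates, p); paths <- c(paths, p)
  summary <- list(sequence = state$sequence, iterations = state$iteration,
                  score = if (length(state$score_history))
                    state$score_history[length(state$score_history)] else 0,
                  score_history = state$score_history,
                  stop_reason = state$stop_reason,
                  planes = state$collected, plans = state$plans)
  if (!is.null(truth)) {
    summary$evaluation <- evaluate_against_truth(
      assign, truth, c(H = state$config$tol_h, N = state$config$tol_n,
                       CA = state$config$tol_c, CB = state$config$tol_c,
                       C = state$config$tol_c))
  }
  p <- file.path(dir, "run.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = 8,
                       dataframe = "rows", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
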