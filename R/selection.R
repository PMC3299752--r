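# The optimization step: quantify per-field uncertainty, pick the next
# experiment to maximize expected information gain, and pick the tilt angle
# that minimizes predicted overlap for the pinpointed peaks.

ENTROPY_FLOOR <- 0.05  # fields below this entropy are considered settled

#' Shannon entropy of a field distribution
#'
#' Entropy in nats over the field's choices plus its null state.
#'
#' @param dist a [field_dist()].
#' @return nonnegative entropy; 0 iff the distribution is a point mass.
#' @export
field_entropy <- function(dist) {
  p <- c(dist$prob, dist$null_prob)
  if (abs(sum(p) - 1) > 1e-6)
    stop("field distribution is not normalized (sum = ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pinpoint the weakest links of the current assignment
#'
#' Ranks (spin system, field) pairs by field entropy weighted by the
#' system's mapping-variable entropy (systems whose residue mapping is
#' already certain contribute less), and returns the top k above the
#' entropy floor.
#'
#' @param systems list of spin systems.
#' @param marginals `marginal_table` from the last inference run, or NULL
#'   before the first assignment phase (weight 1 is used).
#' @param k number of links to return.
#' @return data.frame with columns `system`, `field`, `entropy`, `weight`,
#'   `weighted` (sorted by descending weighted entropy; possibly empty).
#' @export
pinpoint_weak_links <- function(systems, marginals = NULL, k = 10L) {
  stopifnot(k >= 1L)
  carb <- setdiff(SPIN_FIELDS, c("H", "N"))
  rows <- list()
  for (sys in systems) {
    wmap <- 1
    if (!is.null(marginals) && sys$id %in% names(marginals$marginals)) {
      m <- marginals$marginals[[sys$id]]
      m <- m[m > 0]
      wmap <- 0.25 + 0.75 * min(1, -sum(m * log(m)) / log(4))
    }
    for (f in carb) {
      h <- field_entropy(sys$fields[[f]])
      # a still-empty field is maximally uninformed, not settled: treat its
      # uncertainty as the null-mass entropy bonus
      h_eff <- h + 0.5 * sys$fields[[f]]$null_prob
      if (h_eff <= ENTROPY_FLOOR) next
      rows[[length(rows) + 1L]] <-
        data.frame(system = sys$id, field = f, entropy = h,
                   weight = wmap, weighted = h_eff * wmap,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(system = character(0), field = character(0),
                      entropy = numeric(0), weight = numeric(0),
                      weighted = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$weighted, out$system, out$field), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Select the experiment with the largest expected information gain
#'
#' For each experiment the expected gain is the sum, over the weak fields
#' it informs, of the weighted field uncertainty times the probability that
#' the experiment yields a resolvable peak for that field (its pattern
#' sensitivity: 1 for the strong transfer, 0.5 for the weak one).  Ties are
#' broken by the fewest planes already collected, then by the fixed
#' experiment order.
#'
#' @param weak data.frame from [pinpoint_weak_links()]; must be non-empty.
#' @param systems list of spin systems (unused by the gain model but part
#'   of the planning interface).
#' @param planes_collected named integer vector: experiment -> number of
#'   tilted planes already collected.
#' @param max_planes maximum tilted planes per experiment.
#' @return experiment id, or `NA_character_` if every experiment is
#'   exhausted.
#' @export
select_experiment <- function(weak, systems,
                              planes_collected = stats::setNames(
                                rep(0L, length(EXPERIMENTS)), EXPERIMENTS),
                              max_planes = 12L) {
  stopifnot(nrow(weak) >= 1L)
  pat <- experiment_patterns()
  gains <- vapply(EXPERIMENTS, function(e) {
    rows <- pat[pat$experiment == e, ]
    g <- 0
    for (r in seq_len(nrow(rows))) {
      hits <- weak$field == rows$field[r]
      if (any(hits))
        g <- g + sum(weak$weighted[hits]) * rows$intensity[r]
    }
    # diminishing returns: uncertainty that resisted this experiment's
    # earlier planes is less likely to yield to another one
    g * 0.6^(planes_collected[[e]] / 2)
  }, numeric(1))
  avail <- planes_collected[EXPERIMENTS] < max_planes
  if (!any(avail)) return(NA_character_)
  gains[!avail] <- -Inf
  best <- which(gains == max(gains))
  if (length(best) > 1L) {
    nc <- planes_collected[EXPERIMENTS[best]]
    best <- best[nc == min(nc)]
  }
  EXPERIMENTS[best[1L]]
}

#' Select the tilt angle with minimal predicted overlap
#'
#' Searches the 1 to 89 degree integer grid, excluding already collected
#' (experiment, angle) planes.  For each candidate angle the current
#' candidate peaks of the experiment are projected at +theta and -theta; the
#' objective counts predicted pairwise collisions (1H separation below the
#' 1H tolerance and combined-coordinate separation below the plane
#' resolution) that involve a pinpointed peak, tie-broken by total collision
#' count, then by the largest minimum pairwise separation among close-in-1H
#' pairs, then by the smallest angle.
#'
#' @param experiment experiment id.
#' @param pinpointed character vector of spin-system ids from the weak-link
#'   list (candidates anchored near those systems are the pinpointed peaks).
#' @param shift_estimates data.frame of the experiment's current candidate
#'   peaks (columns `h_ppm`, `n_ppm`, `c_ppm`, optionally `pinned`).
#' @param collected set of already collected angles for this experiment
#'   (positive integers; the +/- pair counts as one entry).
#' @param resolution plane resolution in Hz.
#' @param h_tol 1H tolerance in ppm.
#' @param fc a [field_config()].
#' @return the selected angle (positive integer), or `NA_integer_` if the
#'   grid is exhausted.
#' @export
select_angle <- function(experiment, pinpointed, shift_estimates,
                         collected = integer(0), resolution = 30,
                         h_tol = 0.03, fc = field_config()) {
  grid <- setdiff(1:89, abs(collected))
  if (!length(grid)) return(NA_integer_)
  pk <- shift_estimates
  if (is.null(pk$pinned)) pk$pinned <- rep(TRUE, nrow(pk))
  pk <- pk[!is.na(pk$h_ppm) & !is.na(pk$c_ppm) & !is.na(pk$n_ppm), ,
           drop = FALSE]
  n <- nrow(pk)
  if (n < 2L) return(grid[1L])
  close_h <- which(abs(outer(pk$h_ppm, pk$h_ppm, "-")) < h_tol &
                   upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (!nrow(close_h)) return(grid[1L])
  i <- close_h[, 1]; j <- close_h[, 2]
  pin_pair <- pk$pinned[i] | pk$pinned[j]
  dc <- (pk$c_ppm[i] - pk$c_ppm[j]) * fc$c_mhz
  dn <- (pk$n_ppm[i] - pk$n_ppm[j]) * fc$n_mhz
  best <- NA_integer_
  best_key <- c(Inf, Inf, -Inf, Inf)
  for (a in grid) {
    th <- a * pi / 180
    sep_p <- abs(dc * cos(th) + dn * sin(th))
    sep_m <- abs(dc * cos(th) - dn * sin(th))
    coll_p <- sep_p < resolution
    coll_m <- sep_m < resolution
    pin_coll <- sum(coll_p & pin_pair) + sum(coll_m & pin_pair)
    tot_coll <- sum(coll_p) + sum(coll_m)
    min_sep <- min(c(sep_p, sep_m))
    key <- c(pin_coll, tot_coll, -min_sep, a)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] &&
         key[3] < best_key[3] - 1e-12)) {
      best <- a
      best_key <- key
    }
  }
  best
}

#' Build the next experiment plan
#'
#' Combines [pinpoint_weak_links()], [select_experiment()] and
#' [select_angle()] into one plan record.  When no field is uncertain yet
#' (bootstrap), the least-collected experiment is chosen directly.
#'
#' @param systems list of spin systems.
#' @param marginals last `marginal_table` or NULL.
#' @param candidates combined candidate data.frame.
#' @param collected data.frame with columns `experiment`, `angle` of planes
#'   already collected.
#' @param config run configuration (see [run_config()]).
#' @return list with `experiment`, `angle_deg`, `expected_gain`,
#'   `pinpointed`, or NULL when every experiment is exhausted.
#' @export
plan_next <- function(systems, marginals, candidates, collected, config) {
  tilted <- collected[!(collected$angle %in% c(0L, 90L)), , drop = FALSE]
  counts <- stats::setNames(rep(0L, length(EXPERIMENTS)), EXPERIMENTS)
  if (nrow(tilted)) {
    tb <- table(tilted$experiment)
    counts[names(tb)] <- as.integer(tb)
  }
  weak <- pinpoint_weak_links(systems, marginals, k = config$weak_k)
  if (nrow(weak)) {
    exp_id <- select_experiment(weak, systems, counts,
                                max_planes = 2L * config$max_pairs)
  } else {
    avail <- counts < 2L * config$max_pairs
    if (!any(avail)) return(NULL)
    exp_id <- EXPERIMENTS[avail][which.min(counts[avail])]
  }
  if (is.na(exp_id)) return(NULL)
  cand <- candidates[candidates$experiment == exp_id, , drop = FALSE]
  pin_sys <- unique(weak$system)
  if (nrow(cand)) {
    sysh <- vapply(systems, function(s) s$h_ref, numeric(1))
    sysid <- vapply(systems, function(s) s$id, character(1))
    pin_h <- sysh[sysid %in% pin_sys]
    cand$pinned <- if (length(pin_h))
      vapply(cand$h_ppm, function(h) any(abs(pin_h - h) <= config$h_tol),
             logical(1)) else TRUE
  }
  done_angles <- abs(tilted$angle[tilted$experiment == exp_id])
  angle <- select_angle(exp_id, pin_sys, cand, collected = done_angles,
                        resolution = config$resolution,
                        h_tol = config$h_tol, fc = config$fc)
  if (is.na(angle)) return(NULL)
  gain <- if (nrow(weak)) sum(weak$weighted) else 0
  list(experiment = exp_id, angle_deg = as.integer(angle),
       expected_gain = gain, pinpointed = pin_sys)
}
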