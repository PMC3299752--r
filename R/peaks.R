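# The engine's view of the data: probabilistic peak acceptance ("conclusive
# probability"), cross-plane 1H registration, and construction / updating of
# candidate 3D peaks from orthogonal and tilted planes.

PICK_FLOOR <- 0.5         # acceptance floor on conclusive probability
SUPPORT_FACTOR <- 1.6     # candidate probability boost per matched plane
MISS_PENALTY <- 0.5       # candidate probability penalty per missed plane
PRUNE_FLOOR <- 0.2        # candidates below this probability are dropped
ORPHAN_FLOOR <- 0.9       # spawn threshold for unexplained peaks

#' Probability that a picked peak is real
#'
#' Logistic function of `log(intensity / noise_floor)`, offset so that the
#' acceptance count tracks the experiment's theoretical peak count for the
#' protein: when many more peaks than expected are on the table the offset
#' rises (stricter picking) and vice versa.  Monotone nondecreasing in
#' intensity; at the noise floor the probability is far below 1/2.
#'
#' @param intensity peak intensity (vectorized).
#' @param noise_floor positive plane noise floor.
#' @param n_residues number of residues in the protein.
#' @param experiment experiment id (sets the expected peak count).
#' @param n_peaks_so_far number of peaks picked from this plane so far.
#' @return acceptance probabilities in \[0, 1\].
#' @export
conclusive_probability <- function(intensity, noise_floor, n_residues,
                                   experiment, n_peaks_so_far = NA) {
  if (!is.numeric(noise_floor) || noise_floor <= 0)
    stop("noise_floor must be positive")
  check_experiment(experiment)
  mu <- log(3)                       # p = 1/2 at 3x the noise floor
  if (is.finite(n_peaks_so_far) && n_peaks_so_far > 0) {
    expected <- expected_peak_count(experiment, n_residues)
    mu <- mu + max(-0.8, min(0.8, 0.25 * log(n_peaks_so_far / expected)))
  }
  stats::plogis((log(pmax(intensity, 1e-12) / noise_floor) - mu) / 0.6)
}

# Theoretical peak count of an experiment for an n-residue protein,
# discounted for prolines and chain ends (the engine does not see truth).
expected_peak_count <- function(experiment, n_residues) {
  npat <- sum(experiment_patterns()$experiment == experiment)
  max(1, round(npat * n_residues * 0.9))
}

# Assign conclusive probabilities to a plane's peaks, with the dynamic
# noise threshold: start from the previous plane's floor and apply one
# multiplicative correction driving the accepted count toward the expected
# count for this experiment.
pick_peaks <- function(plane, n_residues, prev_floor = NULL) {
  nf <- if (is.null(prev_floor)) plane$noise_floor else prev_floor
  pk <- plane$peaks
  if (!nrow(pk)) { plane$noise_floor <- nf; return(plane) }
  p <- conclusive_probability(pk$intensity, nf, n_residues,
                              plane$experiment, nrow(pk))
  expected <- expected_peak_count(plane$experiment, n_residues)
  accepted <- sum(p >= PICK_FLOOR)
  corr <- sqrt(max(0.5, min(2, (accepted + 1) / (expected + 1))))
  nf <- nf * corr
  pk$conclusive_prob <- conclusive_probability(pk$intensity, nf, n_residues,
                                               plane$experiment, nrow(pk))
  plane$peaks <- pk
  plane$noise_floor <- nf
  plane
}

#' Co-register planes by their 1H coordinates
#'
#' Estimates one constant 1H offset per plane by robust matching of peak 1H
#' coordinates against a reference plane (median discrepancy over peaks with
#' a unique partner inside a 0.06 ppm window), applies the corrections and
#' reports them.
#'
#' @param planes list of `tilt_plane` objects sharing the 1H dimension.
#' @param reference index or plane id of the reference plane.
#' @return list with `planes` (corrected) and `offsets` (numeric vector).
#' @export
register_planes <- function(planes, reference = 1L) {
  stopifnot(length(planes) >= 2L)
  ref <- planes[[reference]]
  href <- ref$peaks$h_ppm
  offsets <- numeric(length(planes))
  for (k in seq_along(planes)) {
    if (k == reference) next
    h <- planes[[k]]$peaks$h_ppm
    if (!length(h) || !length(href)) {
      warning("no overlapping peak support; zero offset applied")
      next
    }
    d <- outer(h, href, "-")
    nearest <- apply(abs(d), 1L, which.min)
    delta <- d[cbind(seq_along(h), nearest)]
    delta <- delta[abs(delta) < 0.06]
    if (!length(delta)) {
      warning("no overlapping peak support; zero offset applied")
      next
    }
    offsets[k] <- stats::median(delta)
    planes[[k]]$peaks$h_ppm <- planes[[k]]$peaks$h_ppm - offsets[k]
  }
  list(planes = planes, offsets = offsets)
}

empty_candidates <- function(experiment = character(0)) {
  data.frame(id = character(0), experiment = character(0),
             h_ppm = numeric(0), n_ppm = numeric(0), c_ppm = numeric(0),
             intensity = numeric(0), conclusive_prob = numeric(0),
             anchor_id = character(0), n_support = integer(0),
             last_angle = integer(0), last_v = numeric(0),
             src_residue = integer(0), artifact = logical(0),
             stringsAsFactors = FALSE)
}

#' Build candidate 3D peaks from the two orthogonal planes
#'
#' Cartesian pairing of accepted 15N-HSQC peaks (90 degrees) and accepted
#' 1H-13C peaks (0 degrees) of one experiment whose 1H coordinates agree
#' within `h_tol`.  The candidate takes H and N from the HSQC peak, C from
#' the 0-degree plane, and a conclusive probability equal to the product of
#' its parents'.
#'
#' @param hsqc the 90-degree `tilt_plane`.
#' @param hc_plane the 0-degree `tilt_plane` of one experiment.
#' @param h_tol 1H matching tolerance in ppm.
#' @return data.frame of candidate 3D peaks (possibly empty).
#' @export
reconstruct_candidates <- function(hsqc, hc_plane, h_tol = 0.03) {
  stopifnot(hsqc$angle_deg == 90L, hc_plane$angle_deg == 0L)
  a <- hsqc$peaks[!is.na(hsqc$peaks$conclusive_prob) &
                  hsqc$peaks$conclusive_prob >= PICK_FLOOR, , drop = FALSE]
  b <- hc_plane$peaks[!is.na(hc_plane$peaks$conclusive_prob) &
                      hc_plane$peaks$conclusive_prob >= PICK_FLOOR, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(empty_candidates())
  hits <- which(abs(outer(a$h_ppm, b$h_ppm, "-")) <= h_tol, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_candidates())
  i <- hits[, 1]; j <- hits[, 2]
  out <- data.frame(
    id = sprintf("%s:%s|%s", hc_plane$experiment, a$id[i], b$id[j]),
    experiment = hc_plane$experiment,
    h_ppm = a$h_ppm[i],
    n_ppm = a$v_hz[i] / hsqc$fc$n_mhz,
    c_ppm = b$v_hz[j] / hc_plane$fc$c_mhz,
    intensity = b$intensity[j],
    conclusive_prob = a$conclusive_prob[i] * b$conclusive_prob[j],
    anchor_id = a$id[i],
    n_support = 2L, last_angle = NA_integer_, last_v = NA_real_,
    src_residue = b$src_residue[j],
    artifact = a$artifact[i] & b$artifact[j],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Update candidate 3D peaks against a newly collected tilted plane
#'
#' Each candidate's predicted projection at the plane's angle is compared to
#' the accepted observed peaks.  A match (within `h_tol` in 1H and
#' `match_tol` in the combined dimension) multiplies the conclusive
#' probability by the support factor (capped at 1), a miss by the penalty
#' factor; candidates falling below the pruning floor are removed.  When the
#' matched plane completes a +/- pair for a candidate, the pair is
#' back-projected and the candidate's (C, N) coordinates are refined toward
#' the back-projection.
#'
#' @param candidates candidate data.frame of the plane's experiment.
#' @param new_plane a tilted `tilt_plane` (0 < |angle| < 90).
#' @param match_tol combined-dimension tolerance in Hz (default twice the
#'   plane resolution).
#' @param h_tol 1H tolerance in ppm.
#' @return updated candidate data.frame; attribute `"matched"` carries the
#'   ids of observed peaks explained by at least one candidate.
#' @export
update_candidates <- function(candidates, new_plane,
                              match_tol = 2 * new_plane$resolution,
                              h_tol = 0.03) {
  if (nrow(candidates) &&
      any(candidates$experiment != new_plane$experiment))
    stop("plane experiment does not match candidate experiment")
  if (abs(new_plane$angle_deg) %in% c(0L, 90L))
    stop("update_candidates expects a tilted plane")
  obs <- new_plane$peaks[!is.na(new_plane$peaks$conclusive_prob) &
                         new_plane$peaks$conclusive_prob >= PICK_FLOOR, ,
                         drop = FALSE]
  if (!nrow(candidates)) {
    attr(candidates, "matched") <- character(0)
    return(candidates)
  }
  pred <- project_frequency(candidates$c_ppm, candidates$n_ppm,
                            new_plane$angle_deg, new_plane$fc)
  matched_obs <- character(0)
  if (nrow(obs)) {
    dh <- abs(outer(candidates$h_ppm, obs$h_ppm, "-"))
    dv <- abs(outer(pred, obs$v_hz, "-"))
    ok <- dh <= h_tol & dv <= match_tol
    best <- apply(ifelse(ok, dv, Inf), 1L, which.min)
    hit <- ok[cbind(seq_len(nrow(candidates)), best)]
  } else {
    hit <- rep(FALSE, nrow(candidates))
    best <- rep(NA_integer_, nrow(candidates))
  }
  p <- candidates$conclusive_prob
  p[hit] <- pmin(1, p[hit] * SUPPORT_FACTOR)
  p[!hit] <- p[!hit] * MISS_PENALTY
  candidates$conclusive_prob <- p
  if (any(hit)) {
    matched_obs <- unique(obs$id[best[hit]])
    candidates$n_support[hit] <- candidates$n_support[hit] + 1L
    # refine 1H toward the matched observation
    candidates$h_ppm[hit] <- 0.7 * candidates$h_ppm[hit] +
      0.3 * obs$h_ppm[best[hit]]
    # +/- pair back-projection: refine (C, N) when the pair agrees with the
    # candidate's coordinates, refute the candidate when it does not (a
    # cross-pairing carries the wrong 15N and the pair exposes it)
    pairable <- hit & !is.na(candidates$last_angle) &
      candidates$last_angle == -new_plane$angle_deg
    if (any(pairable)) {
      if (new_plane$angle_deg > 0) {
        vp <- obs$v_hz[best[pairable]]
        vm <- candidates$last_v[pairable]
      } else {
        vp <- candidates$last_v[pairable]
        vm <- obs$v_hz[best[pairable]]
      }
      theta <- abs(new_plane$angle_deg) * pi / 180
      bp <- back_project(vp, vm, abs(new_plane$angle_deg), new_plane$fc)
      # tolerance grows at angles where the pair poorly conditions C or N
      n_gate <- pmax(0.6, 1.2 * new_plane$resolution /
                       (sin(theta) * new_plane$fc$n_mhz))
      c_gate <- pmax(0.3, 1.2 * new_plane$resolution /
                       (cos(theta) * new_plane$fc$c_mhz))
      agree <- abs(bp$n_ppm - candidates$n_ppm[pairable]) <= n_gate &
        abs(bp$c_ppm - candidates$c_ppm[pairable]) <= c_gate
      w_pair <- which(pairable)
      ok <- w_pair[agree]
      if (length(ok)) {
        candidates$c_ppm[ok] <- 0.5 * (candidates$c_ppm[ok] +
                                         bp$c_ppm[agree])
        candidates$n_ppm[ok] <- 0.5 * (candidates$n_ppm[ok] +
                                         bp$n_ppm[agree])
      }
      bad <- w_pair[!agree]
      if (length(bad))
        candidates$conclusive_prob[bad] <-
          candidates$conclusive_prob[bad] * MISS_PENALTY^2
    }
    candidates$last_angle[hit] <- new_plane$angle_deg
    candidates$last_v[hit] <- obs$v_hz[best[hit]]
  }
  keep <- candidates$conclusive_prob >= PRUNE_FLOOR
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matched") <- matched_obs
  out
}

# Spawn new candidates from unexplained high-probability peaks present in
# both members of a +/- pair: peaks unmatched in either plane that share a
# 1H coordinate are back-projected to a (C, N) estimate.
spawn_candidates <- function(candidates, plane_plus, plane_minus,
                             matched_plus, matched_minus, h_tol = 0.03) {
  stopifnot(plane_plus$angle_deg == -plane_minus$angle_deg,
            plane_plus$angle_deg > 0)
  sel <- function(plane, matched) {
    pk <- plane$peaks
    pk[!is.na(pk$conclusive_prob) & pk$conclusive_prob >= ORPHAN_FLOOR &
       !(pk$id %in% matched), , drop = FALSE]
  }
  a <- sel(plane_plus, matched_plus)
  b <- sel(plane_minus, matched_minus)
  if (!nrow(a) || !nrow(b)) return(candidates)
  hits <- which(abs(outer(a$h_ppm, b$h_ppm, "-")) <= h_tol, arr.ind = TRUE)
  if (!nrow(hits)) return(candidates)
  i <- hits[, 1]; j <- hits[, 2]
  # pair members of one true peak have comparable intensity
  ratio <- pmax(a$intensity[i], b$intensity[j]) /
    pmin(a$intensity[i], b$intensity[j])
  i <- i[ratio <= 2.5]; j <- j[ratio <= 2.5]
  if (!length(i)) return(candidates)
  bp <- back_project(a$v_hz[i], b$v_hz[j], plane_plus$angle_deg,
                     plane_plus$fc)
  fresh <- data.frame(
    id = sprintf("%s:%s|%s", plane_plus$experiment, a$id[i], b$id[j]),
    experiment = plane_plus$experiment,
    h_ppm = (a$h_ppm[i] + b$h_ppm[j]) / 2,
    n_ppm = bp$n_ppm, c_ppm = bp$c_ppm,
    intensity = (a$intensity[i] + b$intensity[j]) / 2,
    # spawns must earn further plane support before they count as settled
    conclusive_prob = pmin(0.88, a$conclusive_prob[i] * b$conclusive_prob[j]),
    anchor_id = NA_character_,
    n_support = 2L,
    last_angle = -plane_plus$angle_deg, last_v = b$v_hz[j],
    src_residue = a$src_residue[i],
    artifact = isTRUE(a$artifact[i]) & isTRUE(b$artifact[j]),
    stringsAsFactors = FALSE)
  # plausible carbon window, and not a duplicate of an existing candidate
  win <- experiment_windows(plane_plus$experiment)$c
  keep <- fresh$c_ppm >= win[1] & fresh$c_ppm <= win[2] &
    !(fresh$id %in% candidates$id)
  if (nrow(candidates)) {
    dup <- vapply(seq_len(nrow(fresh)), function(r)
      any(abs(candidates$h_ppm - fresh$h_ppm[r]) <= h_tol &
          abs(candidates$c_ppm - fresh$c_ppm[r]) <= 0.2 &
          abs(candidates$n_ppm - fresh$n_ppm[r]) <= 0.4), logical(1))
    keep <- keep & !dup
  }
  fresh <- fresh[keep, , drop = FALSE]
  out <- rbind(candidates, fresh)
  rownames(out) <- NULL
  out
}

# Ids of a plane's accepted peaks explained by the surviving candidates
# (projection within tolerance).  Used after a +/- pair has been fully
# processed, so refuted cross-pairings no longer shadow orphan peaks.
explained_ids <- function(candidates, plane, match_tol = 2 * plane$resolution,
                          h_tol = 0.03, min_prob = 0.5) {
  obs <- plane$peaks[!is.na(plane$peaks$conclusive_prob) &
                     plane$peaks$conclusive_prob >= PICK_FLOOR, ,
                     drop = FALSE]
  cand <- candidates[candidates$conclusive_prob >= min_prob, , drop = FALSE]
  if (!nrow(obs) || !nrow(cand)) return(character(0))
  pred <- project_frequency(cand$c_ppm, cand$n_ppm, plane$angle_deg,
                            plane$fc)
  ok <- abs(outer(cand$h_ppm, obs$h_ppm, "-")) <= h_tol &
    abs(outer(pred, obs$v_hz, "-")) <= match_tol
  obs$id[colSums(ok) > 0]
}

#' Write candidate 3D peaks to a Sparky-like list with probabilities
#' @param candidates candidate data.frame.
#' @param path output file.
#' @export
write_candidates <- function(candidates, path) {
  lines <- c(sprintf("%28s %9s %9s %9s %12s %8s",
                     "Assignment", "w1", "w2", "w3", "Intensity", "Prob"),
             sprintf("%28s %9.4f %9.3f %9.3f %12.4g %8.4f",
                     candidates$id, candidates$h_ppm, candidates$n_ppm,
                     candidates$c_ppm, candidates$intensity,
                     candidates$conclusive_prob))
  writeLines(lines, path)
  invisible(path)
}
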