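# Overlap detection and spin-system splitting.  In crowded spectra several
# residues can collapse onto one HSQC anchor; a margin classifier with a
# Platt-calibrated sigmoid output continuously scores that possibility, and
# systems above the split threshold are bipartitioned.

.rdassign_env <- new.env(parent = emptyenv())

#' Features for the overlap classifier
#'
#' Four features per system: local anchor density (other anchors within a
#' 0.1 ppm 1H x 1.5 ppm 15N window), number of carbon fields carrying at
#' least two strong conflicting choices, anchor intensity relative to the
#' anchor-intensity median, and mean strong-choice multiplicity across the
#' carbon fields (an i/i-1 pattern-inconsistency proxy).
#'
#' @param sys a `spin_system`.
#' @param systems all current spin systems.
#' @param candidates optional candidate data.frame; when given, only
#'   choices corroborated by tilted planes (supporting candidates with
#'   `n_support >= 5`) count toward the conflict features, so transient
#'   orthogonal-plane cross-pairings do not look like overlap.
#' @return numeric feature vector of length 4.
#' @export
overlap_features <- function(sys, systems, candidates = NULL) {
  hs <- vapply(systems, function(s) s$h_ref, numeric(1))
  ns <- vapply(systems, function(s) s$n, numeric(1))
  ids <- vapply(systems, function(s) s$id, character(1))
  others <- ids != sys$id
  f1 <- sum(others & abs(hs - sys$h_ref) <= 0.1 & abs(ns - sys$n) <= 1.5)
  carb <- setdiff(SPIN_FIELDS, c("H", "N"))
  corroborated <- function(fd, i) {
    if (is.null(candidates)) return(TRUE)
    src <- fd$sources[[i]]
    if (!length(src)) return(FALSE)
    sup <- candidates$n_support[candidates$id %in% src]
    length(sup) > 0 && max(sup) >= 5L
  }
  strong_idx <- lapply(carb, function(f) {
    fd <- sys$fields[[f]]
    idx <- which(fd$prob >= 0.25)
    idx[vapply(idx, function(i) corroborated(fd, i), logical(1))]
  })
  names(strong_idx) <- carb
  nconf <- vapply(carb, function(f) {
    fd <- sys$fields[[f]]
    strong <- strong_idx[[f]]
    if (length(strong) < 2L) return(0L)
    spread <- max(fd$ppm[strong]) - min(fd$ppm[strong])
    as.integer(spread > 0.25)
  }, integer(1))
  f2 <- sum(nconf)
  med_int <- stats::median(vapply(systems, function(s) s$intensity,
                                  numeric(1)))
  f3 <- sys$intensity / max(med_int, 1e-9)
  f4 <- mean(lengths(strong_idx))
  c(density = f1, conflicts = f2, intensity_excess = f3, multiplicity = f4)
}

# Build one synthetic labelled training system.  Positives merge the
# candidate evidence of two residues onto one anchor; negatives carry a
# single residue's evidence plus occasional spurious choices.
.synth_training_system <- function(id, positive) {
  st_means <- shift_means_matrix()
  st_sds <- shift_sds_matrix()
  draw_res <- function() {
    aa <- sample(setdiff(AA1, "P"), 1)
    vapply(c("CA", "CB", "C"), function(nu) {
      m <- st_means[aa, nu]
      if (is.na(m)) NA_real_ else stats::rnorm(1, m, st_sds[aa, nu])
    }, numeric(1))
  }
  mk_field <- function(vals, probs) {
    keep <- !is.na(vals)
    vals <- vals[keep]; probs <- probs[keep]
    if (!length(vals)) return(field_dist())
    field_dist(ppm = vals, prob = probs,
               null_prob = max(0, 1 - sum(probs)),
               sources = replicate(length(vals), character(0),
                                   simplify = FALSE),
               h_support = stats::rnorm(length(vals), 8.3, 0.01))
  }
  carb_fields <- c(CA_prev = "CA", CB_prev = "CB", CO_prev = "C",
                   CA = "CA", CB = "CB", CO = "C")
  sys <- new_spin_system(id = id, anchor = id,
                         h = stats::rnorm(1, 8.3, 0.5),
                         n = stats::rnorm(1, 120, 3),
                         intensity = if (positive)
                           stats::rlnorm(1, log(2), 0.25)
                         else stats::rlnorm(1, 0, 0.2))
  r1 <- draw_res(); r1p <- draw_res()
  r2 <- draw_res(); r2p <- draw_res()
  for (f in names(carb_fields)) {
    nu <- carb_fields[[f]]
    v1 <- if (grepl("prev", f)) r1p[[nu]] else r1[[nu]]
    v2 <- if (grepl("prev", f)) r2p[[nu]] else r2[[nu]]
    if (positive) {
      sys$fields[[f]] <- mk_field(c(v1, v2),
                                  stats::runif(2, 0.25, 0.48))
    } else {
      vals <- v1; probs <- stats::runif(1, 0.5, 0.95)
      # residual cross-pairing ambiguity survives in crowded 1H regions
      # even for single-residue systems: add 0-2 spurious weaker choices
      n_extra <- stats::rbinom(1, 2, 0.25)
      if (n_extra > 0) {
        vals <- c(vals, v1 + stats::rnorm(n_extra, 0, 4))
        probs <- c(probs * 0.75,
                   stats::runif(n_extra, 0.05, 0.35))
      }
      sys$fields[[f]] <- mk_field(vals, probs)
    }
  }
  sys
}

#' Train the overlap classifier on synthetic fixtures
#'
#' Generates labelled synthetic spin systems (overlap created by merging two
#' residues' evidence onto one anchor), fits a least-squares linear margin on
#' the four [overlap_features()], and calibrates the decision value with a
#' Platt-style sigmoid.  The trained classifier is cached for the session.
#'
#' @param n systems per class.
#' @param seed training seed (fixed default so the classifier is
#'   reproducible).
#' @return classifier object (list with `w`, `b`, `platt`, and the class
#'   centroids); invisibly cached.
#' @export
train_overlap_classifier <- function(n = 250, seed = 20260910) {
  local_rng(seed)
  pos <- lapply(seq_len(n), function(i) .synth_training_system(
    sprintf("pos%d", i), TRUE))
  neg <- lapply(seq_len(n), function(i) .synth_training_system(
    sprintf("neg%d", i), FALSE))
  all_sys <- c(pos, neg)
  X <- t(vapply(all_sys, overlap_features, numeric(4), systems = all_sys))
  y <- c(rep(1, n), rep(-1, n))
  # least-squares linear margin
  fit <- stats::lm.fit(cbind(1, X), y)
  b <- fit$coefficients[1]; w <- fit$coefficients[-1]
  dec <- as.numeric(X %*% w + b)
  platt <- suppressWarnings(
    stats::glm((y + 1) / 2 ~ dec, family = stats::binomial()))
  pc <- stats::coef(platt)
  pc[2] <- max(min(pc[2], 8), 0.1)   # keep the sigmoid finite-sloped
  clf <- list(w = w, b = b,
              platt = pc,
              centroid_pos = colMeans(X[y == 1, , drop = FALSE]),
              centroid_neg = colMeans(X[y == -1, , drop = FALSE]))
  assign("overlap_clf", clf, envir = .rdassign_env)
  invisible(clf)
}

get_overlap_classifier <- function(auto_train = FALSE) {
  if (!exists("overlap_clf", envir = .rdassign_env)) {
    if (!auto_train)
      stop("overlap classifier not trained; run train_overlap_classifier()")
    train_overlap_classifier()
  }
  get("overlap_clf", envir = .rdassign_env)
}

#' Calibrated probability that a spin system is overlapped
#'
#' Applies the trained margin classifier to the system's
#' [overlap_features()] and maps the decision value through the Platt
#' sigmoid.
#'
#' @param sys a `spin_system`.
#' @param systems all current spin systems.
#' @param features optional precomputed feature vector.
#' @param classifier optional classifier object; defaults to the cached one.
#' @return probability in \[0, 1\].
#' @export
overlap_probability <- function(sys, systems, features = NULL,
                                classifier = NULL) {
  clf <- if (is.null(classifier)) get_overlap_classifier() else classifier
  x <- if (is.null(features)) overlap_features(sys, systems) else features
  dec <- sum(clf$w * x) + clf$b
  as.numeric(stats::plogis(clf$platt[1] + clf$platt[2] * dec))
}

#' Split an overlapped spin system in two
#'
#' Bipartitions the carbon-field choices by weighted 2-means on the mean 1H
#' coordinate of their supporting candidate peaks (choices merged from the
#' same candidates stay together by construction).  Both children keep the
#' anchor coordinates; each child's refined 1H moves to its cluster
#' centroid, its fields are renormalized, and each child rejects the
#' sibling's supporting candidates for future field updates.
#'
#' @param sys a `spin_system` with `overlap_prob` above the threshold.
#' @param threshold split threshold (default 0.7).
#' @return list of two `spin_system`s, or list of the unchanged system
#'   (with a warning) if the fields cannot be bipartitioned.
#' @export
split_system <- function(sys, threshold = SPLIT_THRESHOLD) {
  if (sys$overlap_prob <= threshold)
    stop("overlap probability ", format(sys$overlap_prob),
         " does not exceed the split threshold ", threshold)
  carb <- setdiff(SPIN_FIELDS, c("H", "N"))
  hs <- ws <- numeric(0); key <- list()
  for (f in carb) {
    fd <- sys$fields[[f]]
    for (i in seq_along(fd$ppm)) {
      hs <- c(hs, fd$h_support[i]); ws <- c(ws, fd$prob[i])
      key[[length(key) + 1L]] <- c(f, i)
    }
  }
  multi <- any(vapply(carb, function(f)
    length(sys$fields[[f]]$ppm) >= 2L, logical(1)))
  if (!multi || length(hs) < 2L) {
    warning("system ", sys$id, " cannot be bipartitioned; split skipped")
    return(list(sys))
  }
  cl <- kmeans2_weighted(hs, ws)
  make_child <- function(tag, members) {
    child <- sys
    child$id <- paste0(sys$id, tag)
    child$family <- sys$family
    child$overlap_prob <- 0
    child$intensity <- sys$intensity / 2
    rej <- character(0)
    for (f in carb) {
      fd <- sys$fields[[f]]
      sel <- vapply(seq_along(fd$ppm), function(i)
        any(vapply(members, function(m)
          m[1] == f && as.integer(m[2]) == i, logical(1))), logical(1))
      if (length(fd$ppm)) {
        rej <- c(rej, unlist(fd$sources[!sel]))
        child$fields[[f]] <- field_dist(
          ppm = fd$ppm[sel], prob = fd$prob[sel],
          null_prob = max(0, 1 - sum(fd$prob[sel])),
          sources = fd$sources[sel],
          h_support = fd$h_support[sel], src = fd$src[sel])
      }
    }
    child$rejected <- unique(c(sys$rejected, rej))
    hsel <- vapply(members, function(m) {
      fd <- sys$fields[[m[1]]]
      fd$h_support[as.integer(m[2])]
    }, numeric(1))
    wsel <- vapply(members, function(m) {
      fd <- sys$fields[[m[1]]]
      fd$prob[as.integer(m[2])]
    }, numeric(1))
    if (length(hsel) && sum(wsel) > 0)
      child$h_ref <- sum(hsel * wsel) / sum(wsel)
    child$quality <- system_quality(child)
    child
  }
  a <- make_child(".a", key[cl == 1L])
  b <- make_child(".b", key[cl == 2L])
  list(a, b)
}

# Weighted 1D 2-means with deterministic extreme-point initialization.
kmeans2_weighted <- function(x, w, iters = 25L) {
  c1 <- min(x); c2 <- max(x)
  cl <- rep(1L, length(x))
  for (it in seq_len(iters)) {
    cl_new <- ifelse(abs(x - c1) <= abs(x - c2), 1L, 2L)
    if (all(cl_new == cl) && it > 1L) break
    cl <- cl_new
    if (any(cl == 1L)) c1 <- sum(x[cl == 1L] * w[cl == 1L]) /
        max(sum(w[cl == 1L]), 1e-12)
    if (any(cl == 2L)) c2 <- sum(x[cl == 2L] * w[cl == 2L]) /
        max(sum(w[cl == 2L]), 1e-12)
  }
  cl
}

# A system is mature enough to judge for overlap once the choices of its
# conflicting fields are corroborated by tilted planes (candidates with
# enough supporting planes) rather than by raw orthogonal-plane pairings.
system_mature <- function(sys, candidates, min_support = 4L) {
  carb <- setdiff(SPIN_FIELDS, c("H", "N"))
  src_ids <- unlist(lapply(carb, function(f) {
    fd <- sys$fields[[f]]
    unlist(fd$sources[fd$prob >= 0.25])
  }))
  if (!length(src_ids)) return(FALSE)
  sup <- candidates$n_support[candidates$id %in% src_ids]
  length(sup) > 0 && min(sup) >= min_support
}

# Evaluate all systems and split those above threshold (at most one split
# per system per call; children can split again at later iterations).
apply_splitting <- function(systems, candidates,
                            threshold = SPLIT_THRESHOLD) {
  clf <- get_overlap_classifier(auto_train = TRUE)
  out <- list()
  for (sys in systems) {
    if (!system_mature(sys, candidates)) {
      out <- c(out, list(sys))
      next
    }
    sys$overlap_prob <- overlap_probability(
      sys, systems, features = overlap_features(sys, systems, candidates),
      classifier = clf)
    if (sys$overlap_prob > threshold) {
      kids <- withCallingHandlers(split_system(sys, threshold),
                                  warning = function(w)
                                    invokeRestart("muffleWarning"))
      out <- c(out, kids)
    } else out <- c(out, list(sys))
  }
  out
}
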