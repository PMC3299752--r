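# Probabilistic spin systems: eight-field objects anchored to 15N-HSQC
# peaks, with explicit null states, field distributions rebuilt from the
# candidate 3D peaks at every iteration, overlap detection via a calibrated
# margin classifier, and splitting of overlapped systems.

SPLIT_THRESHOLD <- 0.7   # overlap probability above which a system splits
N_MATCH_TOL <- 0.4       # 15N anchor-matching tolerance (ppm)
CHOICE_MERGE_TOL <- 0.1  # carbon ppm separation below which choices merge

#' Construct a field distribution
#'
#' A field holds the chemical-shift choices of one spin-system slot with an
#' explicit null state ("no shift in the data matches this field").
#' Probabilities and the null mass always sum to 1; choices are sorted by
#' descending probability.
#'
#' @param ppm choice values (ppm).
#' @param prob choice probabilities.
#' @param null_prob null-state mass.
#' @param sources list of candidate-id character vectors, one per choice.
#' @param h_support mean 1H coordinate of the supporting candidates.
#' @param src majority ground-truth source residue per choice (evaluation
#'   bookkeeping only; NA when unknown).
#' @return object of class `field_dist`.
#' @export
field_dist <- function(ppm = numeric(0), prob = numeric(0), null_prob = 1,
                       sources = list(), h_support = numeric(0),
                       src = integer(0)) {
  tot <- sum(prob) + null_prob
  if (abs(tot - 1) > 1e-9) {
    prob <- prob / tot
    null_prob <- null_prob / tot
  }
  o <- order(prob, decreasing = TRUE)
  structure(list(ppm = ppm[o], prob = prob[o], null_prob = null_prob,
                 sources = sources[o],
                 h_support = if (length(h_support)) h_support[o] else h_support,
                 src = if (length(src)) src[o] else rep(NA_integer_, length(o))),
            class = "field_dist")
}

is_null_field <- function(f) length(f$ppm) == 0L

top_choice <- function(f) {
  if (is_null_field(f)) return(list(ppm = NA_real_, prob = 0, src = NA_integer_))
  list(ppm = f$ppm[1], prob = f$prob[1], src = f$src[1])
}

#' Initialize spin systems from an HSQC plane
#'
#' One system per HSQC peak with conclusive probability at or above the pick
#' floor.  Carbon fields start as pure null; the H and N fields are point
#' distributions at the anchor coordinates.
#'
#' @param hsqc the 90-degree `tilt_plane` with conclusive probabilities set.
#' @return list of `spin_system` objects.
#' @export
init_spin_systems <- function(hsqc) {
  stopifnot(hsqc$angle_deg == 90L)
  pk <- hsqc$peaks
  pk <- pk[!is.na(pk$conclusive_prob) & pk$conclusive_prob >= PICK_FLOOR, ,
           drop = FALSE]
  if (!nrow(pk)) stop("empty HSQC: nothing to anchor spin systems to")
  lapply(seq_len(nrow(pk)), function(i) {
    sys <- new_spin_system(id = pk$id[i], anchor = pk$id[i],
                           h = pk$h_ppm[i], n = pk$v_hz[i] / hsqc$fc$n_mhz,
                           intensity = pk$intensity[i],
                           anchor_src = pk$src_residue[i])
    sys$anchor_merged <- isTRUE(pk$n_merged[i] > 1L)
    sys
  })
}

new_spin_system <- function(id, anchor, h, n, intensity = 1,
                            anchor_src = NA_integer_, family = anchor,
                            rejected = character(0)) {
  fields <- stats::setNames(vector("list", length(SPIN_FIELDS)), SPIN_FIELDS)
  for (f in SPIN_FIELDS) fields[[f]] <- field_dist()
  fields[["H"]] <- field_dist(ppm = h, prob = 1, null_prob = 0,
                              sources = list(character(0)), h_support = h,
                              src = anchor_src)
  fields[["N"]] <- field_dist(ppm = n, prob = 1, null_prob = 0,
                              sources = list(character(0)), h_support = h,
                              src = anchor_src)
  structure(list(id = id, anchor = anchor, family = family,
                 h = h, n = n, h_ref = h, intensity = intensity,
                 fields = fields, overlap_prob = 0, quality = 0,
                 rejected = rejected, anchor_src = anchor_src),
            class = "spin_system")
}

# Posterior weight that a dual-pattern peak is the strong (own-residue)
# transfer rather than the weak (i-1) one, from its intensity relative to
# the experiment's strong reference.
own_field_weight <- function(intensity, ref, sdlog = 0.3) {
  d_own <- stats::dlnorm(pmax(intensity, 1e-9), log(ref), sdlog)
  d_prev <- stats::dlnorm(pmax(intensity, 1e-9), log(ref / 2), sdlog)
  d_own / (d_own + d_prev)
}

# Weight that a CBCA(CO)NH carbon is CA rather than CB, from the packaged
# pooled CA / CB distributions.
ca_vs_cb_weight <- function(c_ppm) {
  st <- shift_stats()
  ca <- st[st$nucleus == "CA", ]; cb <- st[st$nucleus == "CB", ]
  d_ca <- rowMeans(outer(c_ppm, seq_len(nrow(ca)), function(x, i)
    stats::dnorm(x, ca$mean[i], ca$sd[i] + 1)))
  d_cb <- rowMeans(outer(c_ppm, seq_len(nrow(cb)), function(x, i)
    stats::dnorm(x, cb$mean[i], cb$sd[i] + 1)))
  d_ca / (d_ca + d_cb)
}

#' Rebuild the carbon fields of every spin system from the candidate peaks
#'
#' Every candidate whose (H, N) matches a system's anchor within tolerance
#' contributes its carbon coordinate to the experiment-appropriate
#' field(s); dual-pattern experiments (e.g. HNCA) split the contribution
#' between the own and i-1 fields by the intensity posterior.  Choice
#' probabilities are proportional to the accumulated conclusive-probability
#' mass; the null mass is the product of (1 - p) over contributions.
#' Within a split family a candidate feeds only the child whose refined 1H
#' coordinate is nearest.
#'
#' @param systems list of spin systems.
#' @param candidates combined candidate data.frame (all experiments).
#' @param h_tol,n_tol anchor matching tolerances (ppm).
#' @return updated list of spin systems (with refreshed `quality`).
#' @export
update_fields <- function(systems, candidates, h_tol = 0.03,
                          n_tol = N_MATCH_TOL) {
  if (!length(systems)) return(systems)
  nsys <- length(systems)
  sys_h <- vapply(systems, function(s) s$h_ref, numeric(1))
  sys_n <- vapply(systems, function(s) s$n, numeric(1))
  sys_fam <- vapply(systems, function(s) s$family, character(1))
  cand <- candidates
  eligible <- matrix(FALSE, nrow = nsys, ncol = nrow(cand))
  if (nrow(cand)) {
    dh <- abs(outer(sys_h, cand$h_ppm, "-"))
    dn <- abs(outer(sys_n, cand$n_ppm, "-"))
    eligible <- dh <= h_tol & dn <= n_tol
    for (k in seq_len(nsys))
      if (length(systems[[k]]$rejected))
        eligible[k, cand$id %in% systems[[k]]$rejected] <- FALSE
    # within a split family, give each candidate to the nearest child only
    fam_groups <- split(seq_len(nsys), sys_fam)
    for (g in fam_groups) {
      if (length(g) < 2L) next
      sub <- eligible[g, , drop = FALSE]
      multi <- which(colSums(sub) > 1L)
      for (j in multi) {
        ks <- g[sub[, j]]
        best <- ks[which.min(abs(sys_h[ks] - cand$h_ppm[j]))]
        eligible[setdiff(ks, best), j] <- FALSE
      }
    }
  }
  pat <- experiment_patterns()
  # per-experiment strong-intensity reference
  refs <- vapply(EXPERIMENTS, function(e) {
    x <- cand$intensity[cand$experiment == e]
    if (length(x)) stats::quantile(x, 0.75, names = FALSE) else 1
  }, numeric(1))
  for (k in seq_len(nsys)) {
    sys <- systems[[k]]
    idx <- which(eligible[k, ])
    contrib <- list()   # per carbon field: list of (ppm, p, id, h, src)
    for (f in setdiff(SPIN_FIELDS, c("H", "N")))
      contrib[[f]] <- list(ppm = numeric(0), p = numeric(0),
                           id = character(0), h = numeric(0),
                           src = integer(0), exp = character(0))
    if (length(idx)) {
      cc <- cand[idx, , drop = FALSE]
      for (e in unique(cc$experiment)) {
        ce <- cc[cc$experiment == e, , drop = FALSE]
        rows <- pat[pat$experiment == e, ]
        if (nrow(rows) == 1L) {
          w <- stats::setNames(1, rows$field)
          wmat <- matrix(1, nrow(ce), 1, dimnames = list(NULL, rows$field))
        } else if (e == "CBCA(CO)NH") {
          wa <- ca_vs_cb_weight(ce$c_ppm)
          wmat <- cbind("CA_prev" = wa, "CB_prev" = 1 - wa)
        } else {
          own_field <- rows$field[rows$intensity == 1]
          prev_field <- rows$field[rows$intensity == 0.5]
          wo <- own_field_weight(ce$intensity, refs[[e]])
          wmat <- matrix(c(wo, 1 - wo), ncol = 2,
                         dimnames = list(NULL, c(own_field, prev_field)))
        }
        for (f in colnames(wmat)) {
          p <- ce$conclusive_prob * wmat[, f]
          keep <- p > 0.02
          if (!any(keep)) next
          contrib[[f]]$ppm <- c(contrib[[f]]$ppm, ce$c_ppm[keep])
          contrib[[f]]$p <- c(contrib[[f]]$p, p[keep])
          contrib[[f]]$id <- c(contrib[[f]]$id, ce$id[keep])
          contrib[[f]]$h <- c(contrib[[f]]$h, ce$h_ppm[keep])
          contrib[[f]]$src <- c(contrib[[f]]$src, ce$src_residue[keep])
          contrib[[f]]$exp <- c(contrib[[f]]$exp, rep(e, sum(keep)))
        }
      }
    }
    contrib <- explain_away_fields(contrib)
    for (f in names(contrib))
      sys$fields[[f]] <- build_field(contrib[[f]])
    sys$fields[["H"]] <- field_dist(ppm = sys$h_ref, prob = 1, null_prob = 0,
                                    sources = list(character(0)),
                                    h_support = sys$h_ref,
                                    src = sys$anchor_src)
    sys$fields[["N"]] <- field_dist(ppm = sys$n, prob = 1, null_prob = 0,
                                    sources = list(character(0)),
                                    h_support = sys$h_ref,
                                    src = sys$anchor_src)
    sys$quality <- system_quality(sys)
    systems[[k]] <- sys
  }
  systems
}

# Cross-experiment explaining away.  Two ambiguities are resolved against
# the experiments that carry unambiguous information:
# * CBCA(CO)NH reports CA(i-1) and CB(i-1) in one carbon dimension; values
#   pinned by HN(CO)CA (pure CA(i-1)) or HN(CA)CB (CB) lose their
#   cross-talk copy in the sibling field.
# * The dual own/(i-1) experiments (HNCA, HN(CA)CB, HN(CA)CO) split every
#   peak between the own and i-1 fields by an intensity posterior; a value
#   that a pure i-1 experiment (HN(CO)CA, CBCA(CO)NH, HNCO) already pins as
#   i-1 has its own-field copy damped.
explain_away_fields <- function(contrib, tol = 0.15, damp = 0.15) {
  match_any <- function(x, refs)
    if (!length(refs)) rep(FALSE, length(x)) else
      vapply(x, function(v) any(abs(v - refs) <= tol), logical(1))
  ca <- contrib[["CA_prev"]]; cb <- contrib[["CB_prev"]]
  unamb_ca <- ca$ppm[ca$exp == "HN(CO)CA" & ca$p >= 0.25]
  unamb_cb <- cb$ppm[cb$exp == "HN(CA)CB" & cb$p >= 0.3]
  hit <- cb$exp == "CBCA(CO)NH" & match_any(cb$ppm, unamb_ca)
  cb$p[hit] <- cb$p[hit] * damp
  hit <- ca$exp == "CBCA(CO)NH" & match_any(ca$ppm, unamb_cb)
  ca$p[hit] <- ca$p[hit] * damp
  contrib[["CA_prev"]] <- ca
  contrib[["CB_prev"]] <- cb
  # prev references per nucleus, from the cleaned prev contributions.
  # The own-field cross-talk window must stay at the jitter scale:
  # consecutive residues genuinely share near-identical values far more
  # often than the i-1 experiments can distinguish (carbonyls especially,
  # which cluster within ~1 ppm), so only a confident reference within
  # 0.06 ppm explains an own-field copy away.
  own_tol <- 0.06
  prev_refs <- list(
    CA = ca$ppm[ca$exp %in% c("HN(CO)CA", "CBCA(CO)NH") & ca$p >= 0.4],
    CB = cb$ppm[cb$exp == "CBCA(CO)NH" & cb$p >= 0.4],
    CO = contrib[["CO_prev"]]$ppm[contrib[["CO_prev"]]$exp == "HNCO" &
                                  contrib[["CO_prev"]]$p >= 0.4])
  own_of <- c(CA = "CA", CB = "CB", CO = "CO")
  for (nu in names(own_of)) {
    own <- contrib[[own_of[[nu]]]]
    hit <- vapply(own$ppm, function(v)
      length(prev_refs[[nu]]) > 0 &&
        any(abs(v - prev_refs[[nu]]) <= own_tol), logical(1))
    own$p[hit] <- own$p[hit] * 0.3
    contrib[[own_of[[nu]]]] <- own
  }
  contrib
}

# Cluster contributions within CHOICE_MERGE_TOL into choices; null mass is
# the product of (1 - p) over all contributions to the field.
build_field <- function(ct) {
  if (!length(ct$ppm)) return(field_dist())
  o <- order(ct$ppm)
  ppm <- ct$ppm[o]; p <- ct$p[o]; id <- ct$id[o]; h <- ct$h[o]
  src <- ct$src[o]
  grp <- cumsum(c(1L, diff(ppm) > CHOICE_MERGE_TOL))
  null_prob <- prod(1 - pmin(p, 0.999))
  vals <- weights <- hsup <- numeric(0)
  srcs <- integer(0); sources <- list()
  for (g in unique(grp)) {
    i <- which(grp == g)
    w <- sum(p[i])
    vals <- c(vals, sum(ppm[i] * p[i]) / w)
    weights <- c(weights, w)
    hsup <- c(hsup, sum(h[i] * p[i]) / w)
    sources <- c(sources, list(id[i]))
    tab <- tapply(p[i], factor(src[i], exclude = NULL), sum)
    srcs <- c(srcs, {
      top <- names(tab)[which.max(tab)]
      if (is.na(top) || top == "NA") NA_integer_ else as.integer(top)
    })
  }
  prob <- (1 - null_prob) * weights / sum(weights)
  field_dist(ppm = vals, prob = prob, null_prob = null_prob,
             sources = sources, h_support = hsup, src = srcs)
}

#' Quality of a spin system
#'
#' Mean top-choice probability over the six carbon fields (null fields
#' contribute 0); in \[0, 1\].
#' @param sys a `spin_system`.
#' @return numeric scalar.
#' @export
system_quality <- function(sys) {
  carb <- setdiff(SPIN_FIELDS, c("H", "N"))
  mean(vapply(carb, function(f) top_choice(sys$fields[[f]])$prob, numeric(1)))
}

#' Add spin systems for orphan high-probability candidates
#'
#' Candidates with conclusive probability at or above the orphan threshold
#' whose (H, N) matches no existing anchor spawn a new system anchored at
#' their coordinates (recovering, e.g., HSQC peaks lost to dropout).
#'
#' @param systems list of spin systems.
#' @param candidates combined candidate data.frame.
#' @param h_tol,n_tol anchor matching tolerances (ppm).
#' @return possibly extended list of spin systems.
#' @export
add_spin_systems <- function(systems, candidates, h_tol = 0.03,
                             n_tol = N_MATCH_TOL) {
  # orphans carry slightly sub-threshold probabilities right after their
  # creation pair (spawned candidates are capped until corroborated), so
  # admission combines the probability with plane support and, below,
  # cross-experiment agreement
  # only anchorless candidates (spawned from +/- pairs) can seed systems:
  # anchored candidates belong to their HSQC anchor however far their
  # refined coordinates drift
  orf <- candidates[is.na(candidates$anchor_id) &
                    ((candidates$conclusive_prob >= ORPHAN_FLOOR &
                      candidates$n_support >= 4L) |
                     (candidates$conclusive_prob >= 0.8 &
                      candidates$n_support >= 2L)), , drop = FALSE]
  if (!nrow(orf)) return(systems)
  sys_h <- vapply(systems, function(s) s$h_ref, numeric(1))
  sys_n <- vapply(systems, function(s) s$n, numeric(1))
  # suppression window slightly wider than the matching window: a
  # candidate whose refined coordinates drifted from an existing anchor
  # must not spawn a near-duplicate system (grossly displaced phantoms are
  # already refuted by the +/- pair back-projection check upstream)
  free <- vapply(seq_len(nrow(orf)), function(j)
    !length(sys_h) || !any(abs(sys_h - orf$h_ppm[j]) <= 1.5 * h_tol &
                           abs(sys_n - orf$n_ppm[j]) <= 1.25 * n_tol),
    logical(1))
  orf <- orf[free, , drop = FALSE]
  # a real lost anchor leaves orphan evidence in more than one experiment:
  # cluster the orphans and keep multi-experiment clusters only
  while (nrow(orf)) {
    j <- which.max(orf$conclusive_prob)
    grp <- abs(orf$h_ppm - orf$h_ppm[j]) <= h_tol &
      abs(orf$n_ppm - orf$n_ppm[j]) <= n_tol
    ok <- length(unique(orf$experiment[grp])) >= 2L ||
      (sum(grp) >= 2L && mean(orf$n_support[grp]) >= 5) ||
      any(orf$n_support[grp] >= 6L)
    if (ok) {
      id <- paste0("add#", orf$id[j])
      systems[[length(systems) + 1L]] <-
        new_spin_system(id = id, anchor = id,
                        h = stats::median(orf$h_ppm[grp]),
                        n = stats::median(orf$n_ppm[grp]),
                        intensity = max(orf$intensity[grp]),
                        anchor_src = NA_integer_)
    }
    orf <- orf[!grp, , drop = FALSE]
  }
  systems
}

#' Text dump of spin systems
#'
#' One block per system listing the eight fields with every choice's ppm,
#' probability and source peaks, plus the null mass.
#'
#' @param systems list of spin systems.
#' @param path output file.
#' @export
write_spin_systems <- function(systems, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sys in systems) {
    writeLines(sprintf("spin_system %s anchor=%s H=%.4f N=%.3f overlap=%.3f quality=%.3f",
                       sys$id, sys$anchor, sys$h_ref, sys$n,
                       sys$overlap_prob, sys$quality), con)
    for (f in SPIN_FIELDS) {
      fd <- sys$fields[[f]]
      writeLines(sprintf("  %-8s null=%.4f", f, fd$null_prob), con)
      for (i in seq_along(fd$ppm))
        writeLines(sprintf("    %9.4f p=%.4f [%s]", fd$ppm[i], fd$prob[i],
                           paste(fd$sources[[i]], collapse = ",")), con)
    }
  }
  invisible(path)
}
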