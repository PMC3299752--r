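# From marginals to reported assignments: greedy conflict-resolved residue
# mapping, per-nucleus shift extraction (merging the own fields of the
# residue's system with the i-1 fields of its successor's system),
# chemical-shift based secondary structure, and outlier flags.

ASSIGN_FLOOR <- 0.5   # minimum winning marginal to claim a residue
REPORT_FLOOR <- 0.55  # minimum field top-choice probability to report

#' Extract an assignment state from marginals
#'
#' Greedy conflict resolution: all (system, residue) pairs are visited by
#' descending marginal probability (ties broken by system id); a pair is
#' claimed when both the system and the residue are still free and the
#' marginal is at least the assignment floor.  Per-nucleus shifts come from
#' the winning system's own fields merged with the i-1 fields of the
#' successor position's system; the overall score is the mean winning
#' marginal over anchorable (non-proline) residues.
#'
#' @param marginals a `marginal_table` from [run_inference()].
#' @param systems list of spin systems (order matching the graph).
#' @param sequence protein sequence.
#' @return object of class `assignment_state`.
#' @export
extract_assignment <- function(marginals, systems, sequence) {
  seq_vec <- split_sequence(sequence)
  L <- length(seq_vec)
  ids <- names(marginals$marginals)
  sys_by_id <- stats::setNames(systems, vapply(systems, function(s) s$id,
                                               character(1)))
  N <- length(ids)
  pm <- matrix(0, N, L)
  for (i in seq_len(N)) {
    m <- marginals$marginals[[i]]
    pm[i, ] <- m[-1]                       # drop the null state
  }
  ord <- order(-as.vector(pm), rep(ids, times = L))
  winner <- rep(NA_character_, L)
  win_p <- rep(0, L)
  claimed <- character(0)
  sys_quality <- vapply(systems, function(s) s$quality, numeric(1))
  names(sys_quality) <- vapply(systems, function(s) s$id, character(1))
  for (o in ord) {
    p <- as.vector(pm)[o]
    if (p < ASSIGN_FLOOR) break
    i <- ((o - 1L) %% N) + 1L
    k <- ((o - 1L) %/% N) + 1L
    if (!is.na(winner[k]) || ids[i] %in% claimed) next
    # a system with essentially no carbon evidence cannot claim a residue
    if (sys_quality[[ids[i]]] < 0.2) next
    winner[k] <- ids[i]
    win_p[k] <- p
    claimed <- c(claimed, ids[i])
  }
  shifts <- prob <- matrix(NA_real_, L, 5,
                           dimnames = list(NULL, BACKBONE_NUCLEI))
  src <- matrix(NA_integer_, L, 5, dimnames = list(NULL, BACKBONE_NUCLEI))
  own_map <- c(H = "H", N = "N", CA = "CA", CB = "CB", C = "CO")
  prev_map <- c(CA = "CA_prev", CB = "CB_prev", C = "CO_prev")
  # mapping provenance is judged at the system level: the residue a
  # system's own-field evidence points at (per-choice sources are noisy
  # when near-coincident values merge)
  sys_src <- vapply(systems, system_src, numeric(1))
  names(sys_src) <- vapply(systems, function(s) s$id, character(1))
  for (k in seq_len(L)) {
    sys <- if (!is.na(winner[k])) sys_by_id[[winner[k]]] else NULL
    succ <- if (k < L && !is.na(winner[k + 1L]))
      sys_by_id[[winner[k + 1L]]] else NULL
    for (nu in BACKBONE_NUCLEI) {
      cand <- list()
      if (!is.null(sys)) {
        tc <- top_choice(sys$fields[[own_map[[nu]]]])
        if (tc$prob >= 0.3)
          cand[[length(cand) + 1L]] <-
            list(ppm = tc$ppm, p = tc$prob * win_p[k],
                 src = sys_src[[winner[k]]])
      }
      if (!is.null(succ) && nu %in% names(prev_map)) {
        tc <- top_choice(succ$fields[[prev_map[[nu]]]])
        if (tc$prob >= 0.3)
          cand[[length(cand) + 1L]] <-
            list(ppm = tc$ppm, p = tc$prob * win_p[k + 1L],
                 src = sys_src[[winner[k + 1L]]] - 1L)
      }
      if (!length(cand)) next
      # two independent routes (own field and successor's i-1 field) that
      # agree form a consensus even when each alone is below the floor
      consensus <- length(cand) == 2L &&
        abs(cand[[1]]$ppm - cand[[2]]$ppm) <= 0.15
      best_p <- max(vapply(cand, `[[`, numeric(1), "p"))
      if (best_p < REPORT_FLOOR &&
          !(consensus && cand[[1]]$p + cand[[2]]$p >= REPORT_FLOOR)) next
      if (consensus) {
        w <- c(cand[[1]]$p, cand[[2]]$p)
        shifts[k, nu] <- sum(c(cand[[1]]$ppm, cand[[2]]$ppm) * w) / sum(w)
        prob[k, nu] <- max(w)
        src[k, nu] <- cand[[which.max(w)]]$src
      } else {
        pick <- cand[[which.max(vapply(cand, `[[`, numeric(1), "p"))]]
        shifts[k, nu] <- pick$ppm
        prob[k, nu] <- pick$p
        src[k, nu] <- pick$src
      }
    }
  }
  anchorable <- seq_vec != "P"
  score <- if (any(anchorable)) mean(win_p[anchorable]) else 0
  structure(list(sequence = paste(seq_vec, collapse = ""), winner = winner,
                 win_prob = win_p, shifts = shifts, shift_prob = prob,
                 shift_src = src, ss = NULL, outliers = NULL,
                 score = score),
            class = "assignment_state")
}

# Evaluation-only: the residue a system's own-field evidence points at
# (majority vote over own carbon top choices; split children inherit the
# vote, not the merged anchor's label).
system_src <- function(sys) {
  # an unmerged HSQC anchor identifies its residue directly; only merged
  # anchors (and anchorless added systems) need the field-evidence vote
  if (!is.na(sys$anchor_src) && !isTRUE(sys$anchor_merged) &&
      !grepl("\\.(a|b)$", sys$id))
    return(as.integer(sys$anchor_src))
  votes <- integer(0)
  for (f in c("CA", "CB", "CO")) {
    tc <- top_choice(sys$fields[[f]])
    if (tc$prob >= REPORT_FLOOR && !is.na(tc$src))
      votes <- c(votes, tc$src)
  }
  for (f in c("CA_prev", "CB_prev", "CO_prev")) {
    tc <- top_choice(sys$fields[[f]])
    if (tc$prob >= REPORT_FLOOR && !is.na(tc$src))
      votes <- c(votes, tc$src + 1L)
  }
  if (!length(votes)) return(sys$anchor_src)
  as.integer(names(which.max(table(votes))))
}

#' Secondary structure from assigned secondary shifts
#'
#' Per-residue log-odds of {helix, strand, coil} from the deviations of the
#' reported CA/CB/C' shifts from the residue-type random-coil means,
#' smoothed over a +/-2 residue window (weights 0.25/0.5/1/0.5/0.25) and
#' normalized to a 3-state distribution.  Residues without reported carbon
#' shifts get the uniform distribution.
#'
#' @param assign an `assignment_state`.
#' @param priors shift-statistics data.frame from [shift_stats()].
#' @return the `assignment_state` with an `ss` matrix (L x 3, states HEC).
#' @export
secondary_structure <- function(assign, priors = shift_stats()) {
  seq_vec <- split_sequence(assign$sequence)
  L <- length(seq_vec)
  off <- ss_offsets()
  states <- rownames(off)
  logl <- matrix(0, L, 3, dimnames = list(NULL, states))
  informed <- rep(FALSE, L)
  for (nu in c("CA", "CB", "C")) {
    sub <- priors[priors$nucleus == nu, ]
    mu <- stats::setNames(sub$mean, sub$aa)[seq_vec]
    sd <- stats::setNames(sub$sd, sub$aa)[seq_vec] + 0.08
    obs <- assign$shifts[, nu]
    ok <- !is.na(obs) & !is.na(mu)
    informed <- informed | ok
    for (s in states)
      logl[ok, s] <- logl[ok, s] +
        stats::dnorm(obs[ok], mu[ok] + off[s, nu], sd[ok], log = TRUE)
  }
  w <- c(0.25, 0.5, 1, 0.5, 0.25)
  sm <- matrix(0, L, 3, dimnames = list(NULL, states))
  for (k in seq_len(L)) {
    idx <- (k - 2L):(k + 2L)
    keep <- idx >= 1L & idx <= L
    idx <- idx[keep]; wk <- w[keep]
    use <- informed[idx]
    if (!any(use)) { sm[k, ] <- 0; next }
    sm[k, ] <- colSums(logl[idx[use], , drop = FALSE] * wk[use])
  }
  p <- exp(sm - apply(sm, 1L, max))
  p <- p / rowSums(p)
  p[!informed & rowSums(abs(sm)) == 0, ] <- 1 / 3
  assign$ss <- p
  assign
}

#' Flag outlier chemical shifts
#'
#' Flags any reported shift more than `z` SDs from its residue-type prior
#' conditioned on the modal predicted secondary-structure state.
#'
#' @param assign an `assignment_state` (after [secondary_structure()]).
#' @param priors shift-statistics data.frame.
#' @param z flag threshold in SD units (default 4).
#' @return the `assignment_state` with an `outliers` logical matrix.
#' @export
detect_outliers <- function(assign, priors = shift_stats(), z = 4) {
  seq_vec <- split_sequence(assign$sequence)
  L <- length(seq_vec)
  off <- ss_offsets()
  modal <- if (!is.null(assign$ss))
    rownames(off)[apply(assign$ss, 1L, which.max)] else rep("C", L)
  flags <- matrix(FALSE, L, 5, dimnames = list(NULL, BACKBONE_NUCLEI))
  for (nu in BACKBONE_NUCLEI) {
    sub <- priors[priors$nucleus == nu, ]
    mu <- stats::setNames(sub$mean, sub$aa)[seq_vec] + off[modal, nu]
    sd <- stats::setNames(sub$sd, sub$aa)[seq_vec]
    obs <- assign$shifts[, nu]
    ok <- !is.na(obs) & !is.na(mu)
    flags[ok, nu] <- abs(obs[ok] - mu[ok]) / sd[ok] > z
  }
  assign$outliers <- flags
  assign
}

#' Write the shift table as TSV
#'
#' Columns: residue_index, residue_type, nucleus, ppm, probability.
#' @param assign an `assignment_state`.
#' @param path output file.
#' @export
write_assignment_tsv <- function(assign, path) {
  seq_vec <- split_sequence(assign$sequence)
  rows <- which(!is.na(assign$shifts), arr.ind = TRUE)
  df <- data.frame(residue_index = rows[, 1],
                   residue_type = seq_vec[rows[, 1]],
                   nucleus = colnames(assign$shifts)[rows[, 2]],
                   ppm = assign$shifts[rows],
                   probability = assign$shift_prob[rows])
  df <- df[order(df$residue_index, df$nucleus), ]
  utils::write.table(format(df, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal NMR-STAR 3.1 chemical-shift loop
#' @param assign an `assignment_state`.
#' @param path output file.
#' @export
write_nmrstar <- function(assign, path) {
  seq_vec <- split_sequence(assign$sequence)
  rows <- which(!is.na(assign$shifts), arr.ind = TRUE)
  o <- order(rows[, 1], rows[, 2])
  rows <- rows[o, , drop = FALSE]
  atom <- c(H = "H", N = "N", CA = "CA", CB = "CB", C = "C")
  elem <- c(H = "H", N = "N", CA = "C", CB = "C", C = "C")
  lines <- c("data_assigned_chemical_shifts", "",
             "save_assigned_chem_shift_list_1",
             "   _Assigned_chem_shift_list.Sf_category assigned_chemical_shifts",
             "   loop_",
             "      _Atom_chem_shift.ID",
             "      _Atom_chem_shift.Seq_ID",
             "      _Atom_chem_shift.Comp_ID",
             "      _Atom_chem_shift.Atom_ID",
             "      _Atom_chem_shift.Atom_type",
             "      _Atom_chem_shift.Val",
             "      _Atom_chem_shift.Val_err",
             "")
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  if (nrow(rows)) {
    nus <- colnames(assign$shifts)[rows[, 2]]
    lines <- c(lines, sprintf("      %4d %4d %3s %-2s %s %9.3f 0.05",
                              seq_len(nrow(rows)), rows[, 1],
                              aa3[seq_vec[rows[, 1]]], atom[nus], elem[nus],
                              assign$shifts[rows]))
  }
  lines <- c(lines, "   stop_", "save_")
  writeLines(lines, path)
  invisible(path)
}
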