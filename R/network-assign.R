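# The assignment network: spin-system -> residue mapping variables with
# single potentials from the shift-statistics prior, pairwise sequential
# compatibility plus hard one-system-per-position exclusion, and sparse
# triple-wise factors penalizing double use of one observed peak across the
# two links that share a middle system.
#
# The graph is stored in a structured form (an `assign_graph`, subclass of
# the generic representation): the dense per-pair factor tables would not
# fit in memory for real problem sizes, but the exclusion and sequential
# factors have closed-form messages that vectorize.

PAIR_TOL <- 0.1          # ppm tolerance scale of sequential match terms
PAIR_CAP <- 9            # per-nucleus mismatch energy cap (hard ceiling)
MAX_CHOICES <- 3L        # field choices entering the network

# Background densities (1 / window width, ppm^-1) per nucleus.
.bg_density <- c(H = 1 / 3, N = 1 / 30, CA = 1 / 25, CB = 1 / 55, C = 1 / 12)

#' Build the assignment factor graph
#'
#' One mapping variable per spin system with domain {null, 1..L}.  Single
#' potentials score the system's field choices against the residue-type /
#' secondary-structure prior at each position (field-choice variables are
#' marginalized into the factors choice-by-choice); pairwise potentials
#' score sequential compatibility of the i-1 fields of a successor against
#' the own fields of a predecessor, with a hard exclusion (factor 0) for
#' two systems on one position; sparse triple-wise potentials over three
#' consecutive placements penalize explanations that spend the same
#' observed peak on both links through the middle system.
#'
#' @param systems list of spin systems.
#' @param sequence protein sequence (one-letter string).
#' @param priors shift-statistics data.frame from [shift_stats()].
#' @param beta inverse-temperature scale of the pseudo-energies.
#' @return object of class `c("assign_graph", "factor_graph")`.
#' @export
build_graph <- function(systems, sequence, priors = shift_stats(),
                        beta = 1) {
  stopifnot(length(systems) >= 1L)
  seq_vec <- split_sequence(sequence)
  L <- length(seq_vec)
  N <- length(systems)
  n_anchorable <- sum(seq_vec != "P")
  if (N > n_anchorable + max(3, round(0.2 * n_anchorable)))
    warning("more spin systems (", N, ") than anchorable residues (",
            n_anchorable, "); null-padded domains in effect")
  logpsi <- single_log_potentials(systems, seq_vec, priors, beta)
  Cp <- pair_compatibility(systems, beta)
  triples <- triple_factors(systems, Cp, beta)
  structure(list(systems_id = vapply(systems, function(s) s$id, character(1)),
                 systems = systems, seq_vec = seq_vec, L = L,
                 logpsi = logpsi, C = Cp, triples = triples, beta = beta),
            class = c("assign_graph", "factor_graph"))
}

# Per-nucleus prior parameter matrices over positions: mean under each of
# the three secondary-structure states, and SD.
.position_priors <- function(seq_vec, priors) {
  off <- ss_offsets()
  out <- list()
  for (nu in BACKBONE_NUCLEI) {
    sub <- priors[priors$nucleus == nu, ]
    mu <- stats::setNames(sub$mean, sub$aa)[seq_vec]
    sd <- stats::setNames(sub$sd, sub$aa)[seq_vec]
    out[[nu]] <- list(mu = outer(unname(mu), off[, nu], "+"),
                      sd = unname(sd) + 0.08)
  }
  out
}

# log psi matrix, N x (L + 1); column 1 is the null state (log psi = 0).
single_log_potentials <- function(systems, seq_vec, priors, beta) {
  L <- length(seq_vec)
  N <- length(systems)
  pp <- .position_priors(seq_vec, priors)
  logpsi <- matrix(0, nrow = N, ncol = L + 1L)
  # per-field density-ratio of a choice value across positions
  ratio_at <- function(nu, v) {
    p <- pp[[nu]]
    dens <- rowMeans(stats::dnorm(v, p$mu, p$sd))   # ss mixture
    dens[is.na(dens)] <- 0                          # chemically absent
    r <- dens / .bg_density[[nu]]
    pmin(pmax(r, 0.05), 150)
  }
  for (s in seq_len(N)) {
    sys <- systems[[s]]
    tot <- rep(0, L)
    for (f in SPIN_FIELDS) {
      fd <- sys$fields[[f]]
      if (is_null_field(fd)) next
      nu <- field_nucleus(f)
      offk <- field_offset(f)
      m <- min(length(fd$ppm), MAX_CHOICES)
      acc <- rep(fd$null_prob + max(0, 1 - fd$null_prob - sum(fd$prob[1:m])),
                 L)
      for (i in seq_len(m)) {
        r_shift <- ratio_at(nu, fd$ppm[i])          # indexed by residue
        # field at offset offk: system at position k reads residue k + offk
        r_pos <- if (offk == 0L) r_shift else c(0.05, r_shift[-L])
        acc <- acc + fd$prob[i] * r_pos
      }
      tot <- tot + log(pmax(acc, 1e-12))
    }
    # missing i-1 evidence is evidence of absence at interior positions:
    # where a (non-proline) predecessor exists, its carbons should have
    # produced peaks, so an empty i-1 field costs log(0.5) per unit null
    # mass; chain starts and post-proline positions are exempt, as is
    # CB(i-1) after glycine
    pred <- c("", seq_vec[-L])
    for (f in c("CA_prev", "CB_prev", "CO_prev")) {
      expect <- pred != "" & pred != "P"
      if (f == "CB_prev") expect <- expect & pred != "G"
      null_mass <- systems[[s]]$fields[[f]]$null_prob
      tot[expect] <- tot[expect] + log(0.5) * null_mass
    }
    logpsi[s, 2:(L + 1L)] <- tot
  }
  # temper and keep the null state at 0
  logpsi[, 2:(L + 1L)] <- beta * logpsi[, 2:(L + 1L)]
  logpsi
}

# Sequential pair compatibility C[u, v]: factor value for u at position k
# and v at position k + 1 (any k), marginalized over the field choices of
# u's own carbons against v's i-1 carbons, with the explicit null states
# contributing a neutral factor of 1.
pair_compatibility <- function(systems, beta) {
  N <- length(systems)
  links <- list(c("CA", "CA_prev"), c("CB", "CB_prev"), c("CO", "CO_prev"))
  Cmat <- matrix(1, N, N)
  for (ln in links) {
    Vo <- Po <- matrix(0, N, MAX_CHOICES)
    Vp <- Pp <- matrix(0, N, MAX_CHOICES)
    for (s in seq_len(N)) {
      fo <- systems[[s]]$fields[[ln[1]]]
      fp <- systems[[s]]$fields[[ln[2]]]
      mo <- min(length(fo$ppm), MAX_CHOICES)
      mp <- min(length(fp$ppm), MAX_CHOICES)
      if (mo) { Vo[s, 1:mo] <- fo$ppm[1:mo]; Po[s, 1:mo] <- fo$prob[1:mo] }
      if (mp) { Vp[s, 1:mp] <- fp$ppm[1:mp]; Pp[s, 1:mp] <- fp$prob[1:mp] }
    }
    term <- matrix(0, N, N)
    for (i in seq_len(MAX_CHOICES)) for (j in seq_len(MAX_CHOICES)) {
      pw <- outer(Po[, i], Pp[, j])
      if (!any(pw > 0)) next
      d <- outer(Vo[, i], Vp[, j], "-")
      u <- pmin((d / PAIR_TOL)^2, PAIR_CAP) - 1
      term <- term + pw * exp(-beta * u)
    }
    null_mass <- 1 - outer(rowSums(Po), rowSums(Pp))
    Cmat <- Cmat * (term + pmax(null_mass, 0))
  }
  diag(Cmat) <- 0   # a system cannot follow itself
  Cmat
}

# Sparse triple factors over strong consecutive links (u -> v -> w): if the
# top i-1 choice of v used by link (u, v) and the top own choice of v used
# by link (v, w) are supported by the same observed candidate peak, that
# peak is being spent twice; the triple factor pays energy +1.
triple_factors <- function(systems, Cmat, beta, strong = exp(1.5)) {
  N <- length(systems)
  idx <- which(Cmat > strong, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(u = integer(0), v = integer(0),
                                    w = integer(0), tau = numeric(0)))
  succ <- split(idx[, 2], idx[, 1])   # u -> strong successors v
  out <- list()
  for (u in as.integer(names(succ))) {
    for (v in succ[[as.character(u)]]) {
      vs <- succ[[as.character(v)]]
      if (is.null(vs)) next
      for (w in vs) {
        if (w == u) next
        tau <- 1
        for (ln in list(c("CA", "CA_prev"), c("CB", "CB_prev"),
                        c("CO", "CO_prev"))) {
          prev_fd <- systems[[v]]$fields[[ln[2]]]
          own_fd <- systems[[v]]$fields[[ln[1]]]
          if (is_null_field(prev_fd) || is_null_field(own_fd)) next
          shared <- length(intersect(prev_fd$sources[[1]],
                                     own_fd$sources[[1]])) > 0
          if (shared) tau <- tau * exp(-beta * 1)
        }
        if (tau < 1)
          out[[length(out) + 1L]] <- data.frame(u = u, v = v, w = w,
                                                tau = tau)
      }
    }
  }
  if (!length(out)) return(data.frame(u = integer(0), v = integer(0),
                                      w = integer(0), tau = numeric(0)))
  do.call(rbind, out)
}

#' @export
run_inference.assign_graph <- function(graph, damping = 0.5,
                                       max_iters = 500, tol = 1e-6,
                                       warm_start = NULL, ...) {
  N <- length(graph$systems_id)
  d <- graph$L + 1L
  logpsi <- graph$logpsi
  Cmat <- graph$C
  # messages live in a (N*N) x d matrix, row (u, v) with u fastest:
  # Mm[(u,v), k] is the log message into v computed from u
  Mm <- if (!is.null(warm_start) && is.matrix(warm_start) &&
            nrow(warm_start) == N * N && ncol(warm_start) == d)
    warm_start else matrix(0, N * N, d)
  residual <- Inf
  converged <- FALSE
  tri <- graph$triples
  npos <- d - 1L
  # flattened (u, v) pair index, u fastest: cf[uv] = C[u, v], cr = C[v, u]
  cf <- as.vector(Cmat) - 1
  cr <- as.vector(t(Cmat)) - 1
  diag_rows <- which(as.vector(diag(N) == 1))
  u_of_row <- rep(seq_len(N), times = N)          # broadcast index for B
  v_groups <- rep(seq_len(N), each = N)           # group index for sums
  perm_vu <- as.vector(t(matrix(seq_len(N * N), N, N)))  # (u,v) -> (v,u)
  for (it in seq_len(max_iters)) {
    S <- rowsum(Mm, v_groups, reorder = TRUE)     # S[v, k] = sum_u msg
    B <- logpsi + S                               # beliefs (log)
    B <- B + triple_field(tri, B, N, d)
    # q_{u -> (u,v)}(k) = b_u(k) - Mm[(v,u), k]; row-max of B is enough
    # for overflow safety because message magnitudes are bounded
    B <- B - apply(B, 1L, max)
    Qm <- exp(B[u_of_row, , drop = FALSE] - Mm[perm_vu, , drop = FALSE])
    Qm <- Qm / rowSums(Qm)
    P <- Qm[, 2:d, drop = FALSE]
    m_pos <- 1 - P
    if (npos >= 2L) {
      m_pos[, 2:npos] <- m_pos[, 2:npos] +
        P[, seq_len(npos - 1L), drop = FALSE] * cf
      m_pos[, seq_len(npos - 1L)] <- m_pos[, seq_len(npos - 1L)] +
        P[, 2:npos, drop = FALSE] * cr
    }
    m_pos[m_pos < 1e-12] <- 1e-12
    lm <- matrix(0, N * N, d)
    lm[, 2:d] <- log(m_pos)
    lm[diag_rows, ] <- 0
    Mnew <- damping * Mm + (1 - damping) * lm
    residual <- max(abs(Mnew - Mm))
    Mm <- Mnew
    if (residual < tol) { converged <- TRUE; break }
  }
  M <- Mm
  S <- rowsum(Mm, v_groups, reorder = TRUE)
  B <- logpsi + S + triple_field(tri, logpsi + S, N, d)
  B <- exp(B - apply(B, 1L, max))
  B <- B / rowSums(B)
  marg <- lapply(seq_len(N), function(v)
    stats::setNames(B[v, ], c("null", as.character(seq_len(graph$L)))))
  names(marg) <- graph$systems_id
  structure(list(marginals = marg, converged = converged,
                 residual = residual, messages = M),
            class = "marginal_table")
}

# Belief-level contribution of the sparse triple factors: for a stored
# triple (u, v, w) with value tau on consecutive placements, each member
# receives log(1 + q(.)q(.)(tau - 1)) at the compatible positions.
triple_field <- function(tri, B, N, d) {
  out <- matrix(0, N, d)
  if (!nrow(tri)) return(out)
  Q <- exp(B - apply(B, 1L, max))
  Q <- Q / rowSums(Q)
  at <- function(s, k) {
    v <- numeric(length(k))
    ok <- k >= 1L & k <= d - 1L
    v[ok] <- Q[s, k[ok] + 1L]
    v
  }
  pos <- seq_len(d - 1L)
  for (r in seq_len(nrow(tri))) {
    u <- tri$u[r]; v <- tri$v[r]; w <- tri$w[r]; tau <- tri$tau[r]
    out[u, pos + 1L] <- out[u, pos + 1L] +
      log1p(at(v, pos + 1L) * at(w, pos + 2L) * (tau - 1))
    out[v, pos + 1L] <- out[v, pos + 1L] +
      log1p(at(u, pos - 1L) * at(w, pos + 1L) * (tau - 1))
    out[w, pos + 1L] <- out[w, pos + 1L] +
      log1p(at(u, pos - 2L) * at(v, pos - 1L) * (tau - 1))
  }
  out
}

#' Marginal inference with guided decimation
#'
#' Plain loopy sum-product on the assignment graph can leave symmetric
#' placements (e.g. equivalent residues following prolines) in near-ties
#' that never resolve.  This wrapper interleaves message passing with
#' decimation: after each converged sweep, systems whose top position
#' carries at least `clamp_prob` of their marginal are clamped there
#' (conflict-free, by descending confidence), and inference resumes from
#' the warm messages.  The threshold relaxes stepwise to `min_clamp`;
#' systems that never reach it stay free, so genuinely ambiguous mappings
#' keep their soft marginals.
#'
#' @param graph an `assign_graph` from [build_graph()].
#' @param damping,max_iters,tol as in [run_inference()].
#' @param warm_start optional message array from a previous call.
#' @param clamp_prob initial clamping threshold.
#' @param min_clamp lowest threshold tried.
#' @param max_rounds maximum decimation rounds.
#' @return a `marginal_table` (marginals of the final conditioned graph).
#' @export
infer_with_decimation <- function(graph, damping = 0.5, max_iters = 150,
                                  tol = 1e-4, warm_start = NULL,
                                  clamp_prob = 0.9, min_clamp = 0.8,
                                  max_rounds = 4L) {
  N <- length(graph$systems_id)
  d <- graph$L + 1L
  clamped_sys <- rep(FALSE, N)
  clamped_pos <- logical(d)
  thr <- clamp_prob
  warm <- warm_start
  mt <- NULL
  for (round in seq_len(max_rounds)) {
    iters <- if (round == 1L) max_iters else max(30L, max_iters %/% 3L)
    mt <- run_inference(graph, damping = damping, max_iters = iters,
                        tol = tol, warm_start = warm)
    warm <- mt$messages
    B <- do.call(rbind, mt$marginals)
    top_k <- apply(B[, -1, drop = FALSE], 1L, which.max)
    top_p <- B[cbind(seq_len(N), top_k + 1L)]
    ord <- order(-top_p)
    newly <- 0L
    for (s in ord) {
      if (clamped_sys[s] || top_p[s] < thr) next
      k <- top_k[s]
      if (clamped_pos[k]) next
      graph$logpsi[s, ] <- -50
      graph$logpsi[s, k + 1L] <- 0
      clamped_sys[s] <- TRUE
      clamped_pos[k] <- TRUE
      newly <- newly + 1L
    }
    if (newly == 0L) {
      if (thr <= min_clamp) break
      thr <- max(min_clamp, thr - 0.15)
    }
    if (all(clamped_sys)) break
  }
  mt
}

#' @export
as_factor_graph.assign_graph <- function(potentials) {
  g <- potentials
  N <- length(g$systems_id)
  d <- g$L + 1L
  states <- c("null", as.character(seq_len(g$L)))
  domains <- stats::setNames(replicate(N, states, simplify = FALSE),
                             g$systems_id)
  factors <- list()
  for (s in seq_len(N))
    factors[[length(factors) + 1L]] <-
      list(vars = g$systems_id[s], table = exp(g$logpsi[s, ]))
  for (u in seq_len(N - 1L)) for (v in (u + 1L):N) {
    tab <- matrix(1, d, d)
    for (k in 2:d) {
      tab[k, k] <- 0
      if (k < d) { tab[k, k + 1L] <- g$C[u, v]; tab[k + 1L, k] <- g$C[v, u] }
    }
    factors[[length(factors) + 1L]] <-
      list(vars = g$systems_id[c(u, v)], table = tab)
  }
  if (nrow(g$triples)) for (r in seq_len(nrow(g$triples))) {
    arr <- array(1, dim = c(d, d, d))
    for (k in 2:(d - 2L))
      arr[k, k + 1L, k + 2L] <- g$triples$tau[r]
    factors[[length(factors) + 1L]] <-
      list(vars = g$systems_id[c(g$triples$u[r], g$triples$v[r],
                                 g$triples$w[r])], table = arr)
  }
  factor_graph(domains, factors)
}
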