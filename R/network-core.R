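# Pseudo-energetic probabilistic network, generic layer: microstate
# energies, the Boltzmann/canonical-ensemble form, the factor-graph
# representation (factors delta = exp(-beta * U)), and generic sum-product
# message passing (exact on acyclic graphs, damped loopy otherwise).

#' Construct a potential set
#'
#' Holds the pseudo-energy terms of the network: individual potentials
#' `U_i`, pairwise `U_ij` and triple-wise `U_ijk` interaction potentials,
#' together with the inverse-temperature-like parameter `beta`.  Energies
#' may be `+Inf` (hard exclusion).
#'
#' @param domains named list: variable id -> character vector of states.
#' @param singles named list: variable id -> named numeric (state -> U).
#' @param pairs list of `list(vars = c(v1, v2), U = matrix)` with dimnames
#'   matching the two domains.
#' @param triples list of `list(vars = c(v1, v2, v3), U = 3d array)`.
#' @param beta positive real.
#' @return object of class `potential_set`.
#' @export
potential_set <- function(domains, singles = list(), pairs = list(),
                          triples = list(), beta = 1) {
  stopifnot(beta > 0)
  structure(list(domains = domains, singles = singles, pairs = pairs,
                 triples = triples, beta = beta),
            class = "potential_set")
}

#' Total energy of a microstate
#'
#' `E_s = sum U_i(lambda) + sum U_ij(lambda, lambda) + sum U_ijk(...)`;
#' infinite energies (hard exclusions) propagate.
#'
#' @param state named character vector / list: variable id -> state label.
#' @param potentials a [potential_set()].
#' @return numeric energy (possibly `Inf`).
#' @export
total_energy <- function(state, potentials) {
  state <- unlist(state)
  need <- unique(c(names(potentials$singles),
                   unlist(lapply(potentials$pairs, `[[`, "vars")),
                   unlist(lapply(potentials$triples, `[[`, "vars"))))
  missing <- setdiff(need, names(state))
  if (length(missing))
    stop("microstate does not cover variable(s): ",
         paste(missing, collapse = ", "))
  e <- 0
  for (v in names(potentials$singles))
    e <- e + potentials$singles[[v]][[state[[v]]]]
  for (p in potentials$pairs)
    e <- e + p$U[state[[p$vars[1]]], state[[p$vars[2]]]]
  for (t in potentials$triples)
    e <- e + t$U[state[[t$vars[1]]], state[[t$vars[2]]], state[[t$vars[3]]]]
  e
}

# Enumerate all microstates of a potential set (small instances only).
enumerate_states <- function(domains) {
  grid <- expand.grid(domains, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  names(grid) <- names(domains)
  grid
}

#' Boltzmann probability of a microstate
#'
#' `exp(-beta * E_s) / Z` with the partition function `Z` computed by full
#' enumeration of the (small) state space.
#'
#' @param state named character vector: variable id -> state label.
#' @param potentials a [potential_set()].
#' @return probability.
#' @export
boltzmann_probability <- function(state, potentials) {
  grid <- enumerate_states(potentials$domains)
  E <- vapply(seq_len(nrow(grid)), function(i)
    total_energy(as.list(grid[i, , drop = FALSE]), potentials), numeric(1))
  if (!any(is.finite(E)))
    stop("infeasible model: every configuration is excluded")
  w <- exp(-potentials$beta * (E - min(E[is.finite(E)])))
  Z <- sum(w)
  if (Z == 0) stop("infeasible model: every configuration is excluded")
  e_s <- total_energy(state, potentials)
  exp(-potentials$beta * (e_s - min(E[is.finite(E)]))) / Z
}

#' Construct a factor graph
#'
#' Variables with finite domains and nonnegative factor tables over scopes
#' of one to three variables.
#'
#' @param domains named list: variable id -> character vector of states.
#' @param factors list of `list(vars = <ids>, table = <array>)`; tables must
#'   be nonnegative with dims matching the variable domains.
#' @return object of class `factor_graph`.
#' @export
factor_graph <- function(domains, factors) {
  for (f in factors) {
    if (any(f$table < 0)) stop("factor tables must be nonnegative")
    if (length(dim(f$table) %||% length(f$table)) != length(f$vars) &&
        !(length(f$vars) == 1L && is.null(dim(f$table))))
      stop("factor table rank does not match scope size")
  }
  structure(list(domains = domains, factors = factors),
            class = "factor_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a potential set to its factor-graph form
#'
#' Factors `delta_i`, `delta_ij`, `delta_ijk` are computed entrywise as
#' `exp(-beta * U)`; hard exclusions (`U = Inf`) map to factor value 0.
#'
#' @param potentials a [potential_set()].
#' @return a [factor_graph()].
#' @export
as_factor_graph <- function(potentials) {
  UseMethod("as_factor_graph")
}

#' @export
as_factor_graph.potential_set <- function(potentials) {
  b <- potentials$beta
  factors <- list()
  for (v in names(potentials$singles)) {
    u <- potentials$singles[[v]][potentials$domains[[v]]]
    factors[[length(factors) + 1L]] <-
      list(vars = v, table = exp(-b * unname(u)))
  }
  for (p in potentials$pairs)
    factors[[length(factors) + 1L]] <-
      list(vars = p$vars, table = exp(-b * unname(p$U)))
  for (t in potentials$triples)
    factors[[length(factors) + 1L]] <-
      list(vars = t$vars, table = exp(-b * unname(t$U)))
  factor_graph(potentials$domains, factors)
}

#' Run marginal inference
#'
#' Generic: dispatches on the graph representation.  The generic
#' factor-graph method runs damped sum-product message passing with
#' log-space messages (exact on acyclic graphs); the structured assignment
#' graph uses an equivalent vectorized schedule.
#'
#' @param graph a `factor_graph` or `assign_graph`.
#' @param damping message damping in \[0, 1).
#' @param max_iters maximum sweeps.
#' @param tol stop when the largest message change falls below this.
#' @param ... passed to methods.
#' @return object of class `marginal_table`: list with `marginals` (named
#'   list of per-variable distributions), `converged`, `residual`.
#' @export
run_inference <- function(graph, damping = 0.5, max_iters = 500,
                          tol = 1e-6, ...) {
  UseMethod("run_inference")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
run_inference.factor_graph <- function(graph, damping = 0.5, max_iters = 500,
                                       tol = 1e-6, ...) {
  vars <- names(graph$domains)
  dsize <- vapply(graph$domains, length, integer(1))
  nf <- length(graph$factors)
  # messages in log space, normalized to logsumexp 0
  f2v <- v2f <- vector("list", nf)
  for (fi in seq_len(nf)) {
    sc <- graph$factors[[fi]]$vars
    f2v[[fi]] <- lapply(sc, function(v) rep(-log(dsize[[v]]), dsize[[v]]))
    v2f[[fi]] <- lapply(sc, function(v) rep(-log(dsize[[v]]), dsize[[v]]))
  }
  # factor lists per variable
  fac_of <- lapply(vars, function(v) {
    hits <- list()
    for (fi in seq_len(nf)) {
      pos <- which(graph$factors[[fi]]$vars == v)
      for (p in pos) hits[[length(hits) + 1L]] <- c(fi, p)
    }
    hits
  })
  names(fac_of) <- vars
  norm_log <- function(x) x - logsumexp(x)
  residual <- Inf
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    residual <- 0
    # variable -> factor
    for (v in vars) {
      hits <- fac_of[[v]]
      if (!length(hits)) next
      msgs <- lapply(hits, function(h) f2v[[h[1]]][[h[2]]])
      total <- Reduce(`+`, msgs)
      for (i in seq_along(hits)) {
        h <- hits[[i]]
        v2f[[h[1]]][[h[2]]] <- norm_log(total - msgs[[i]])
      }
    }
    # factor -> variable
    for (fi in seq_len(nf)) {
      fac <- graph$factors[[fi]]
      sc <- fac$vars
      k <- length(sc)
      lt <- log(fac$table)
      if (k == 1L) {
        # unary messages are constants of the graph: no damping needed
        new <- norm_log(as.numeric(lt))
        d <- max(abs(exp(new) - exp(f2v[[fi]][[1]])))
        residual <- max(residual, d)
        f2v[[fi]][[1]] <- new
        next
      }
      arr <- lt
      for (p in seq_len(k)) {
        inc <- v2f[[fi]][[p]]
        perm_dim <- rep(1L, k); perm_dim[p] <- length(inc)
        arr <- arr + array(rep(inc, each = prod(dsize[sc][seq_len(p - 1L)])),
                           dim = dsize[sc])
      }
      for (p in seq_len(k)) {
        inc <- v2f[[fi]][[p]]
        sub <- arr - array(rep(inc, each = prod(dsize[sc][seq_len(p - 1L)])),
                           dim = dsize[sc])
        other <- setdiff(seq_len(k), p)
        new <- apply(sub, p, logsumexp)
        new <- norm_log(new)
        d <- max(abs(exp(new) - exp(f2v[[fi]][[p]])))
        residual <- max(residual, d)
        f2v[[fi]][[p]] <- damping * f2v[[fi]][[p]] + (1 - damping) * new
      }
    }
    if (residual < tol) { converged <- TRUE; break }
  }
  marg <- lapply(vars, function(v) {
    hits <- fac_of[[v]]
    total <- rep(0, dsize[[v]])
    for (h in hits) total <- total + f2v[[h[1]]][[h[2]]]
    p <- exp(norm_log(total))
    stats::setNames(p / sum(p), graph$domains[[v]])
  })
  names(marg) <- vars
  structure(list(marginals = marg, converged = converged,
                 residual = residual),
            class = "marginal_table")
}
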