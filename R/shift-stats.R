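# Packaged chemical-shift statistics and triple-resonance peak patterns.
#
# The per-residue-type table below is loosely modelled on public random-coil
# shift compilations (means in ppm).  SDs are chosen so that every generated
# shift, including secondary-structure offsets and the +/-5 SD truncation,
# stays inside the plausibility windows CA [40,70], N [100,135], H [6,11].
# The same table serves both the synthetic-sample generator and the
# assignment engine's priors.

BACKBONE_NUCLEI <- c("H", "N", "CA", "CB", "C")

SPIN_FIELDS <- c("CA_prev", "CB_prev", "CO_prev", "H", "N", "CA", "CB", "CO")

EXPERIMENTS <- c("HNCO", "HN(CO)CA", "HN(CA)CO", "HNCA", "CBCA(CO)NH", "HN(CA)CB")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Approximate natural abundance of each amino acid, used by random_sequence().
AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.8,
             G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)

.shift_mean_table <- function() {
  m <- rbind(
    #      H      N     CA    CB      C
    A = c(8.24, 123.8, 52.5, 19.1, 177.8),
    R = c(8.23, 120.5, 56.0, 30.9, 176.3),
    N = c(8.40, 118.7, 53.1, 38.9, 175.2),
    D = c(8.34, 120.4, 54.2, 41.1, 176.3),
    C = c(8.32, 118.8, 58.2, 28.0, 174.6),
    Q = c(8.32, 119.8, 55.7, 29.4, 176.0),
    E = c(8.42, 120.2, 56.6, 29.9, 176.6),
    G = c(8.33, 108.8, 45.1,   NA, 174.9),
    H = c(8.42, 118.2, 55.0, 29.0, 174.1),
    I = c(8.00, 119.9, 61.1, 38.8, 176.4),
    L = c(8.16, 121.8, 55.1, 42.4, 177.6),
    K = c(8.29, 120.4, 56.2, 33.1, 176.6),
    M = c(8.28, 119.6, 55.4, 32.9, 176.3),
    F = c(8.30, 120.3, 57.7, 39.6, 175.8),
    P = c(  NA,    NA, 63.3, 32.1, 177.3),
    S = c(8.31, 115.7, 58.3, 63.8, 174.6),
    T = c(8.15, 113.6, 61.8, 69.8, 174.7),
    W = c(8.25, 121.3, 57.5, 29.6, 176.1),
    Y = c(8.12, 120.3, 57.9, 38.8, 175.9),
    V = c(8.03, 119.2, 62.2, 32.9, 176.3))
  colnames(m) <- BACKBONE_NUCLEI
  m
}

.shift_sd_table <- function() {
  m <- matrix(NA_real_, nrow = 20, ncol = 5,
              dimnames = list(AA1, BACKBONE_NUCLEI))
  m[, "H"]  <- 0.38
  m[, "N"]  <- 2.2
  m["G", "N"] <- 1.7
  m[, "CA"] <- 1.2
  m[c("G"), "CA"] <- 0.6
  m[c("P", "T", "V"), "CA"] <- 0.8
  m[, "CB"] <- 1.2
  m[, "C"]  <- 1.0
  means <- .shift_mean_table()
  m[is.na(means)] <- NA_real_
  m
}

# Secondary-structure offsets added to the random-coil means.  CA moves up in
# helix and down in strand; CB mirrors at half amplitude; the carbonyl gets a
# smaller same-signed offset as CA so that all three carbons carry signal.
.ss_offset_table <- function() {
  off <- array(0, dim = c(3L, 5L),
               dimnames = list(c("H", "E", "C"), BACKBONE_NUCLEI))
  off["H", "CA"] <- 2.5
  off["E", "CA"] <- -2.0
  off["H", "CB"] <- -1.25
  off["E", "CB"] <- 1.0
  off["H", "C"]  <- 1.0
  off["E", "C"]  <- -0.8
  off
}

#' Packaged residue-type chemical-shift statistics
#'
#' Returns the static per-residue-type shift distribution table used both by
#' the synthetic-sample generator and (as the assignment prior) by the
#' probabilistic network.  One row per (residue type, nucleus) with the
#' distribution mean and standard deviation in ppm; entries for chemically
#' absent nuclei (glycine CB, proline amide H/N) are omitted.
#'
#' @param sd_scale multiplier applied to all standard deviations; values
#'   below 1 compress the dispersion, emulating disordered proteins.
#' @return data.frame with columns `aa`, `nucleus`, `mean`, `sd`.
#' @export
shift_stats <- function(sd_scale = 1) {
  stopifnot(is.numeric(sd_scale), sd_scale > 0)
  means <- .shift_mean_table()
  sds <- .shift_sd_table() * sd_scale
  df <- expand.grid(aa = AA1, nucleus = BACKBONE_NUCLEI,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$mean <- means[cbind(df$aa, df$nucleus)]
  df$sd <- sds[cbind(df$aa, df$nucleus)]
  df <- df[!is.na(df$mean), ]
  rownames(df) <- NULL
  df
}

#' Secondary-structure offset table
#'
#' Offsets (ppm) added to the random-coil mean of each nucleus for residues
#' in helix (`H`), strand (`E`) or coil (`C`).
#'
#' @return 3 x 5 numeric matrix (states x nuclei).
#' @export
ss_offsets <- function() .ss_offset_table()

# Internal matrix accessors (fast paths; rows = residue letters).
shift_means_matrix <- function() .shift_mean_table()
shift_sds_matrix <- function(sd_scale = 1) .shift_sd_table() * sd_scale

#' Triple-resonance peak pattern table
#'
#' For each of the six supported experiments, the spin-system fields its
#' carbon dimension reports, together with the relative peak intensity
#' (1.0 for the strong transfer, 0.5 for the weak one).  Field names follow
#' the eight-field spin-system convention: `CA_prev`/`CB_prev`/`CO_prev` are
#' the i-1 carbons, `CA`/`CB`/`CO` the residue's own.
#'
#' @return data.frame with columns `experiment`, `field`, `intensity`.
#' @export
experiment_patterns <- function() {
  df <- rbind(
    data.frame(experiment = "HNCO",        field = "CO_prev", intensity = 1.0),
    data.frame(experiment = "HN(CO)CA",    field = "CA_prev", intensity = 1.0),
    data.frame(experiment = "HN(CA)CO",    field = "CO",      intensity = 1.0),
    data.frame(experiment = "HN(CA)CO",    field = "CO_prev", intensity = 0.5),
    data.frame(experiment = "HNCA",        field = "CA",      intensity = 1.0),
    data.frame(experiment = "HNCA",        field = "CA_prev", intensity = 0.5),
    data.frame(experiment = "CBCA(CO)NH",  field = "CA_prev", intensity = 1.0),
    data.frame(experiment = "CBCA(CO)NH",  field = "CB_prev", intensity = 1.0),
    data.frame(experiment = "HN(CA)CB",    field = "CB",      intensity = 1.0),
    data.frame(experiment = "HN(CA)CB",    field = "CB_prev", intensity = 0.5))
  df$experiment <- as.character(df$experiment)
  df$field <- as.character(df$field)
  df
}

# Map a spin-system field to (nucleus, residue offset relative to anchor).
field_nucleus <- function(field) {
  switch(field,
         CA_prev = "CA", CB_prev = "CB", CO_prev = "C",
         CA = "CA", CB = "CB", CO = "C",
         H = "H", N = "N",
         stop("unknown field: ", field))
}
field_offset <- function(field) {
  if (field %in% c("CA_prev", "CB_prev", "CO_prev")) -1L else 0L
}

check_experiment <- function(experiment) {
  if (!(is.character(experiment) && length(experiment) == 1L &&
        experiment %in% EXPERIMENTS))
    stop("unknown experiment id: ", paste(experiment, collapse = ", "))
  invisible(experiment)
}

#' Random amino-acid sequence
#'
#' Draws a sequence from natural amino-acid frequencies; used to build
#' synthetic benchmark proteins.
#'
#' @param length number of residues.
#' @param seed integer seed.
#' @return one-letter amino-acid string.
#' @export
random_sequence <- function(length, seed) {
  stopifnot(length >= 1)
  local_rng(seed)
  paste(sample(AA1, length, replace = TRUE, prob = AA_FREQ), collapse = "")
}

# Seeded RNG helper: runs `sample`/`rnorm` etc. under a private RNG stream
# and restores the caller's state when the calling frame exits.
local_rng <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed %% .Machine$integer.max),
                    .local_envir = env)
  invisible(NULL)
}
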