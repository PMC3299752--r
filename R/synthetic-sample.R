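# Synthetic sample generator: ground-truth backbone shifts and idealized 3D
# peak lists, plus the corruption model that turns them into "observable"
# peaks.  Stands in for the labelled protein inside the spectrometer.

#' Draw ground-truth backbone chemical shifts for a sequence
#'
#' Shifts are drawn per residue from the packaged residue-type normal
#' distributions plus secondary-structure offsets, truncated at +/- 5 SD.
#' Glycines carry no CB shift and prolines no amide H/N (hence no HSQC
#' anchor).  Deterministic for a fixed `(sequence, ss, seed)`.
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @param ss per-residue secondary structure in `{H,E,C}`, or `"auto"` to
#'   invent alternating helix/coil/strand segments of length 6-10 (seeded).
#' @param seed integer seed.
#' @param sd_scale multiplier on the packaged SDs (e.g. 0.5 to emulate a
#'   disordered, shift-compressed protein).
#' @return object of class `true_sample`: list with `sequence`, `ss_true`,
#'   `shifts` (L x 5 matrix, ppm, NA where chemically absent), `seed`.
#' @export
sample_shifts <- function(sequence, ss = "auto", seed = 1L, sd_scale = 1) {
  seq_vec <- split_sequence(sequence)
  L <- length(seq_vec)
  bad <- which(!(seq_vec %in% AA1))
  if (length(bad))
    stop("unknown residue letter '", seq_vec[bad[1]], "' at position ", bad[1])
  if (identical(ss, "auto")) {
    ss <- auto_secondary_structure(L, seed)
  } else {
    ss <- as.character(ss)
    if (length(ss) == 1L && nchar(ss) == L) ss <- strsplit(ss, "")[[1]]
    if (length(ss) != L) stop("ss length must match sequence length")
    if (!all(ss %in% c("H", "E", "C"))) stop("ss labels must be H, E or C")
  }
  means <- shift_means_matrix()
  sds <- shift_sds_matrix(sd_scale)
  off <- ss_offsets()
  local_rng(seed + 104729)
  shifts <- matrix(NA_real_, nrow = L, ncol = length(BACKBONE_NUCLEI),
                   dimnames = list(NULL, BACKBONE_NUCLEI))
  for (nu in BACKBONE_NUCLEI) {
    mu <- means[seq_vec, nu] + off[ss, nu]
    sd <- sds[seq_vec, nu]
    z <- rnorm(L)
    z <- pmin(pmax(z, -5), 5)          # truncate at +/- 5 SD
    shifts[, nu] <- mu + z * sd
  }
  structure(list(sequence = paste(seq_vec, collapse = ""),
                 ss_true = ss, shifts = shifts, seed = seed,
                 sd_scale = sd_scale),
            class = "true_sample")
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1L) strsplit(toupper(sequence), "")[[1]]
  else toupper(as.character(sequence))
}

# Alternating helix/coil/strand segments of seeded length 6-10.
auto_secondary_structure <- function(L, seed) {
  local_rng(seed + 7919)
  states <- c("H", "C", "E", "C")
  ss <- character(0)
  k <- 0L
  while (length(ss) < L) {
    len <- sample(6:10, 1L)
    ss <- c(ss, rep(states[(k %% 4L) + 1L], len))
    k <- k + 1L
  }
  ss[seq_len(L)]
}

#' Residues carrying an amide anchor
#'
#' @param sample a `true_sample`.
#' @return integer vector of residue indices with both amide H and N shifts
#'   (every non-proline residue, including residue 1).
#' @export
anchored_residues <- function(sample) {
  which(!is.na(sample$shifts[, "H"]) & !is.na(sample$shifts[, "N"]))
}

#' Idealized 3D peaks of one triple-resonance experiment
#'
#' Applies the experiment's peak pattern to the ground-truth shifts: each
#' anchored residue i contributes one peak per pattern entry at
#' `(H_i, N_i, C)` where C is the shift of the patterned carbon of residue
#' i or i-1.  Peaks requiring a chemically missing nucleus (residue 1's
#' i-1 partner, proline anchors, glycine CB) are omitted.  Weak (i-1)
#' transfers carry relative intensity 0.5.
#'
#' @param sample a `true_sample`.
#' @param experiment one of the six experiment ids in [EXPERIMENTS].
#' @return data.frame of class `true_peaks`: `residue`, `experiment`,
#'   `h_ppm`, `n_ppm`, `c_ppm`, `kind`, `intensity`, plus evaluation-only
#'   columns `src_residue` (residue whose carbon the peak reports) and
#'   `artifact` (FALSE here).
#' @export
generate_true_peaks <- function(sample, experiment) {
  check_experiment(experiment)
  pat <- experiment_patterns()
  pat <- pat[pat$experiment == experiment, ]
  sh <- sample$shifts
  anchors <- anchored_residues(sample)
  rows <- list()
  for (i in anchors) {
    for (r in seq_len(nrow(pat))) {
      fld <- pat$field[r]
      j <- i + field_offset(fld)
      if (j < 1L) next
      c_ppm <- sh[j, field_nucleus(fld)]
      if (is.na(c_ppm)) next
      rows[[length(rows) + 1L]] <- data.frame(
        residue = i, experiment = experiment,
        h_ppm = sh[i, "H"], n_ppm = sh[i, "N"], c_ppm = c_ppm,
        kind = if (field_offset(fld) < 0L)
          paste0(field_nucleus(fld), "(i-1)") else field_nucleus(fld),
        intensity = pat$intensity[r],
        src_residue = j, artifact = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = integer(0), experiment = character(0),
               h_ppm = numeric(0), n_ppm = numeric(0), c_ppm = numeric(0),
               kind = character(0), intensity = numeric(0),
               src_residue = integer(0), artifact = logical(0))
  rownames(out) <- NULL
  class(out) <- c("true_peaks", "data.frame")
  out
}

#' Noise model for peak corruption
#'
#' @param jitter_h,jitter_c,jitter_n per-nucleus positional jitter SD (ppm).
#' @param missing_prob per-peak dropout probability.
#' @param artifact_rate expected artifact peaks per plane (Poisson).
#' @param intensity_cv coefficient of variation of peak intensities.
#' @param artifact_intensity median artifact intensity (relative to a strong
#'   true peak at 1.0).
#' @param seed integer seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(jitter_h = 0.01, jitter_c = 0.05, jitter_n = 0.05,
                        missing_prob = 0.05, artifact_rate = 3,
                        intensity_cv = 0.2, artifact_intensity = 0.1,
                        seed = 1L) {
  stopifnot(missing_prob >= 0, missing_prob <= 1,
            artifact_rate >= 0, intensity_cv >= 0,
            jitter_h >= 0, jitter_c >= 0, jitter_n >= 0)
  structure(list(jitter_h = jitter_h, jitter_c = jitter_c,
                 jitter_n = jitter_n, missing_prob = missing_prob,
                 artifact_rate = artifact_rate, intensity_cv = intensity_cv,
                 artifact_intensity = artifact_intensity,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Spectral windows (ppm) for the carbon dimension of each experiment, plus
# the shared amide windows.  Artifacts are placed uniformly inside these.
experiment_windows <- function(experiment) {
  check_experiment(experiment)
  cw <- switch(experiment,
               "HNCO" = , "HN(CA)CO" = c(168, 182),
               "HN(CO)CA" = , "HNCA" = c(38, 72),
               "CBCA(CO)NH" = , "HN(CA)CB" = c(12, 75))
  list(h = c(5.5, 11.5), n = c(98, 137), c = cw)
}

#' Corrupt an idealized peak list
#'
#' Seeded Gaussian jitter on every surviving coordinate, independent
#' dropout, multiplicative log-normal intensity noise, and Poisson-count
#' artifact peaks placed uniformly inside the experiment's spectral
#' windows.  The `artifact`/`src_residue` columns are bookkeeping for
#' evaluation code only; the engine never reads them.
#'
#' @param peaks `true_peaks` data.frame (single experiment).
#' @param model a [noise_model()].
#' @return corrupted `true_peaks` data.frame.
#' @export
corrupt_peaks <- function(peaks, model) {
  stopifnot(inherits(model, "noise_model"))
  local_rng(model$seed + 15485863)
  n <- nrow(peaks)
  out <- peaks
  if (n) {
    keep <- runif(n) >= model$missing_prob
    out <- out[keep, , drop = FALSE]
    m <- nrow(out)
    if (m) {
      out$h_ppm <- out$h_ppm + rnorm(m, 0, model$jitter_h)
      out$n_ppm <- out$n_ppm + rnorm(m, 0, model$jitter_n)
      out$c_ppm <- out$c_ppm + rnorm(m, 0, model$jitter_c)
      if (model$intensity_cv > 0) {
        sdl <- sqrt(log(1 + model$intensity_cv^2))
        out$intensity <- out$intensity * rlnorm(m, -sdl^2 / 2, sdl)
      }
    }
  }
  if (model$artifact_rate > 0 && n) {
    experiment <- peaks$experiment[1]
    win <- experiment_windows(experiment)
    k <- rpois(1L, model$artifact_rate)
    if (k > 0) {
      art <- data.frame(
        residue = NA_integer_, experiment = experiment,
        h_ppm = runif(k, win$h[1], win$h[2]),
        n_ppm = runif(k, win$n[1], win$n[2]),
        c_ppm = runif(k, win$c[1], win$c[2]),
        kind = "artifact",
        intensity = rlnorm(k, log(model$artifact_intensity), 0.5),
        src_residue = NA_integer_, artifact = TRUE,
        stringsAsFactors = FALSE)
      out <- rbind(out, art)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("true_peaks", "data.frame")
  out
}

#' Serialize a sample's shifts to a tab-separated table
#'
#' Columns: `residue_index`, `residue_type`, `nucleus`, `ppm`.
#'
#' @param sample a `true_sample`.
#' @param path output file.
#' @export
write_shift_table <- function(sample, path) {
  seq_vec <- split_sequence(sample$sequence)
  df <- expand.grid(residue_index = seq_along(seq_vec),
                    nucleus = BACKBONE_NUCLEI,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$residue_type <- seq_vec[df$residue_index]
  df$ppm <- sample$shifts[cbind(df$residue_index,
                                match(df$nucleus, colnames(sample$shifts)))]
  df <- df[!is.na(df$ppm), c("residue_index", "residue_type", "nucleus", "ppm")]
  df <- df[order(df$residue_index, df$nucleus), ]
  utils::write.table(format(df, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sequence to FASTA
#' @param sample a `true_sample` (or a plain sequence string).
#' @param path output file.
#' @param name FASTA record name.
#' @export
write_fasta <- function(sample, path, name = "synthetic") {
  seqs <- if (inherits(sample, "true_sample")) sample$sequence else sample
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to write FASTA files")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a sequence from FASTA
#' @param path FASTA file; the first record is used.
#' @return one-letter amino-acid string.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA files")
  as.character(Biostrings::readAAStringSet(path)[[1]])
}

#' Write peaks to a Sparky-like .list file
#'
#' Three frequency columns (w1 = H, w2 = N, w3 = C) plus intensity, with an
#' assignment label derived from the peak's residue and kind.
#'
#' @param peaks `true_peaks` data.frame.
#' @param path output file.
#' @export
write_peak_list <- function(peaks, path) {
  lab <- ifelse(is.na(peaks$residue), "?-?",
                paste0("R", peaks$residue, peaks$kind))
  lines <- c(sprintf("%17s %8s %8s %8s %12s",
                     "Assignment", "w1", "w2", "w3", "Intensity"),
             sprintf("%17s %8.3f %8.3f %8.3f %12.4g",
                     lab, peaks$h_ppm, peaks$n_ppm, peaks$c_ppm,
                     peaks$intensity))
  writeLines(lines, path)
  invisible(path)
}
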