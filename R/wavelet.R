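# Wavelet feature extraction.
#
# Each of a protein's eight digital signals is summarised twice:
#   * a 4-level dyadic DWT with the discrete Meyer wavelet ->
#     5 coefficient subsequences (details D1-D4 + approximation A4),
#     10 statistics each (mean, sd, top-4 |coefficients| and their
#     relative positions)                                   -> 50 values
#   * a 25-scale Mexican-hat CWT -> L x 25 coefficient matrix,
#     summarised by its singular values                      -> 25 values
# giving 75 values per property and 8 x 75 = 600 per protein.

# 62-tap FIR approximation of the Meyer scaling filter ("dmey"),
# standard published coefficients (decomposition low-pass).
.dmey_dec_lo <- c(
  0, -1.0099999569414229e-12, 8.519459636796214e-09, -1.111944952595278e-08,
  -1.0798819539621958e-08, 6.0669757413511352e-08, -1.0866516536735883e-07,
  8.2006806503864813e-08, 1.1783004497663934e-07, -5.5063405652522782e-07,
  1.1307947017916706e-06, -1.4895492164971559e-06, 7.367572885903746e-07,
  3.2054419133447798e-06, -1.6312699734552807e-05, 6.5543059305751491e-05,
  -0.00060115023435160925, -0.002704672124643725, 0.0022025341009110021,
  0.006045814097323304, -0.0063877183184971563, -0.011061496392513451,
  0.015270015130934803, 0.017423434103729693, -0.032130793990211758,
  -0.024348745906078023, 0.063739024322801596, 0.030655091960824263,
  -0.13284520043622938, -0.035087555656258346, 0.44459300275757724,
  0.74458559231880628, 0.44459300275757724, -0.035087555656258346,
  -0.13284520043622938, 0.030655091960824263, 0.063739024322801596,
  -0.024348745906078023, -0.032130793990211758, 0.017423434103729693,
  0.015270015130934803, -0.011061496392513451, -0.0063877183184971563,
  0.006045814097323304, 0.0022025341009110021, -0.002704672124643725,
  -0.00060115023435160925, 6.5543059305751491e-05, -1.6312699734552807e-05,
  3.2054419133447798e-06, 7.367572885903746e-07, -1.4895492164971559e-06,
  1.1307947017916706e-06, -5.5063405652522782e-07, 1.1783004497663934e-07,
  8.2006806503864813e-08, -1.0866516536735883e-07, 6.0669757413511352e-08,
  -1.0798819539621958e-08, -1.111944952595278e-08, 8.519459636796214e-09,
  -1.0099999569414229e-12)

#' Discrete Meyer (dmey) decomposition filter bank
#'
#' The 62-tap FIR approximation of the Meyer wavelet used for the fast
#' DWT. The high-pass filter follows from the low-pass by the standard
#' quadrature-mirror relation.
#'
#' @return list with `lo` and `hi` numeric filters (length 62).
#' @export
dmey_filters <- function() {
  lo <- .dmey_dec_lo
  hi <- rev(lo) * rep_len(c(-1, 1), length(lo))
  list(lo = lo, hi = hi)
}

# Half-point symmetric extension (... x2 x1 | x1 x2 ... xL | xL xL-1 ...),
# by n samples on each side; reflections repeat for n > L.
.sym_extend <- function(x, n) {
  L <- length(x)
  pos <- (-n):(L - 1L + n)          # 0-based positions into the extension
  m <- pos %% (2L * L)
  idx <- ifelse(m < L, m + 1L, 2L * L - m)
  x[idx]
}

# One analysis step: symmetric extension, correlation with the filter,
# dyadic downsampling. Output length floor((L + F - 1) / 2).
.dwt_step <- function(x, f) {
  Fl <- length(f)
  ext <- .sym_extend(x, Fl - 1L)
  cv <- stats::convolve(ext, rev(f), type = "filter")
  cv[seq.int(2L, length(cv), by = 2L)]
}

#' Four-level discrete Meyer wavelet decomposition
#'
#' The signal passes through a half-band high-pass / low-pass filter pair;
#' the low-pass output is re-decomposed, iterated to `levels` levels. The
#' result is the detail subsequences D1..D4 plus the final approximation
#' A4 — five subsequences for the default four levels. Boundaries use
#' half-point symmetric extension.
#'
#' @param signal numeric vector.
#' @param levels number of decomposition levels (default 4).
#' @return named list of `levels + 1` coefficient vectors, ordered
#'   `D1, ..., D<levels>, A<levels>`.
#' @export
dwt_decompose <- function(signal, levels = 4L) {
  if (!is.numeric(signal) || !length(signal))
    stop("`signal` must be a non-empty numeric vector")
  if (length(signal) < 2^levels)
    stop(sprintf("sequence too short: %d-level decomposition needs at least %d samples, got %d",
                 levels, 2^levels, length(signal)))
  flt <- dmey_filters()
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  a <- signal
  for (lev in seq_len(levels)) {
    out[[lev]] <- .dwt_step(a, flt$hi)
    a <- .dwt_step(a, flt$lo)
  }
  out[[levels + 1L]] <- a
  out
}

#' Summary statistics of one wavelet coefficient subsequence
#'
#' Extracts the 10 values kept per subsequence: the mean and (population)
#' standard deviation of the coefficients, the four coefficients of
#' largest absolute value (signed, ties broken toward the earlier index),
#' and their relative positions `m / n` where `m` is the 1-based position
#' and `n` the subsequence length. Subsequences shorter than four
#' coefficients are padded with value 0 / location 0.
#'
#' @param subseq numeric vector of wavelet coefficients.
#' @return list with `mean`, `sd`, `top_values` (4), `top_locations` (4).
#' @export
subsequence_stats <- function(subseq) {
  if (!is.numeric(subseq) || !length(subseq))
    stop("`subseq` must be a non-empty numeric vector")
  n <- length(subseq)
  mu <- mean(subseq)
  sdev <- sqrt(sum((subseq - mu)^2) / n)
  ord <- order(-abs(subseq), seq_len(n))
  k <- min(4L, n)
  top <- ord[seq_len(k)]
  vals <- c(subseq[top], rep(0, 4L - k))
  locs <- c(top / n, rep(0, 4L - k))
  list(mean = mu, sd = sdev, top_values = vals, top_locations = locs)
}

# Ricker (Mexican hat) wavelet sampled on an integer grid of `points`
# samples at scale `a`: second derivative of a Gaussian, L2-normalised.
.ricker <- function(points, a) {
  t <- seq_len(points) - 1 - (points - 1) / 2
  amp <- 2 / (sqrt(3 * a) * pi^0.25)
  amp * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

#' Mexican-hat continuous wavelet transform
#'
#' Convolves the signal with a Ricker wavelet at each integer scale,
#' "same"-mode so every row has length L. The wavelet at scale `a` is
#' sampled on a centred integer grid of `min(10 a, L)` points.
#'
#' @param signal numeric vector of length L.
#' @param scales integer scales (default 1..25).
#' @return L x length(scales) coefficient matrix (rows = positions,
#'   columns = scales).
#' @export
cwt_mexh <- function(signal, scales = 1:25) {
  if (!is.numeric(signal) || !length(signal))
    stop("`signal` must be a non-empty numeric vector")
  L <- length(signal)
  out <- matrix(0, nrow = L, ncol = length(scales))
  for (k in seq_along(scales)) {
    a <- scales[k]
    M <- min(10L * a, L)
    psi <- .ricker(M, a)
    if (M == 1L) {
      out[, k] <- signal * psi
    } else {
      full <- stats::convolve(signal, rev(psi), type = "open")
      start <- ((M - 1L) %/% 2L) + 1L
      out[, k] <- full[start:(start + L - 1L)]
    }
  }
  colnames(out) <- paste0("s", scales)
  out
}

#' Singular-value profile of the 25-scale Mexican-hat CWT
#'
#' Builds the L x 25 CWT coefficient matrix of the signal and returns its
#' singular values in descending order, zero-padded to length 25 when the
#' signal is shorter than 25 samples.
#'
#' @inheritParams cwt_mexh
#' @return numeric vector of 25 non-negative, non-increasing values.
#' @export
cwt_features <- function(signal, scales = 1:25) {
  m <- cwt_mexh(signal, scales)
  sv <- svd(m, nu = 0, nv = 0)$d
  ns <- length(scales)
  if (length(sv) < ns) sv <- c(sv, rep(0, ns - length(sv)))
  sv[seq_len(ns)]
}

# 10 slot names of one subsequence-statistics block
.stat_slot_names <- c("mean", "sd", paste0("v", 1:4), paste0("loc", 1:4))

#' Layout of the 600-dimensional protein descriptor
#'
#' For each property (order H1, H2, V, P1, P2, SASA, NCI, P): five
#' 10-slot DWT blocks (subsequences D1, D2, D3, D4, A4; slots mean, sd,
#' v1..v4, loc1..loc4) followed by the 25 CWT singular values — 75 slots
#' per property. Feature `(t, j)` of the recurrent reshaping lives at
#' index `75 (j - 1) + t`.
#'
#' @return character vector of 600 feature names, e.g. `"H1.D1.mean"`,
#'   `"P.sv25"`.
#' @export
feature_layout <- function() {
  per_prop <- c(as.vector(t(outer(c("D1", "D2", "D3", "D4", "A4"),
                                  .stat_slot_names, paste, sep = "."))),
                sprintf("sv%02d", 1:25))
  as.vector(t(outer(PPI_PROPERTY_NAMES, per_prop, paste, sep = ".")))
}

.flatten_stats <- function(s) {
  c(s$mean, s$sd, s$top_values, s$top_locations)
}

#' Convert one protein sequence into its 600-dimensional descriptor
#'
#' Digitizes the sequence into eight physicochemical signals
#' ([encode_sequence()]), then summarises each signal by its four-level
#' discrete Meyer DWT statistics (50 values) and 25-scale Mexican-hat CWT
#' singular values (25 values). See [feature_layout()] for the ordering.
#'
#' @inheritParams encode_sequence
#' @param min_len,max_len accepted sequence length range; sequences
#'   shorter than 64 residues are dominated by boundary padding in the
#'   four-level DWT and are rejected by default, as are sequences longer
#'   than 1200 residues.
#' @return a `protein_feature`: list with `protein_id` and the named
#'   600-vector `values`.
#' @export
featurize_protein <- function(sequence, table = aa_property_table(),
                              protein_id = "", min_len = 64L, max_len = 1200L,
                              policy = "strict") {
  ds <- tryCatch(
    encode_sequence(sequence, table, protein_id = protein_id, policy = policy),
    error = function(e) stop(sprintf("protein '%s': %s", protein_id,
                                     conditionMessage(e)), call. = FALSE))
  if (ds$length < min_len || ds$length > max_len)
    stop(sprintf("protein '%s': length %d outside accepted range [%d, %d]",
                 protein_id, ds$length, min_len, max_len), call. = FALSE)
  vals <- numeric(0)
  for (j in seq_along(PPI_PROPERTY_NAMES)) {
    sig <- ds$signals[, j]
    sub <- dwt_decompose(sig)
    dwt_block <- unlist(lapply(sub, function(s) .flatten_stats(subsequence_stats(s))),
                        use.names = FALSE)
    vals <- c(vals, dwt_block, cwt_features(sig))
  }
  names(vals) <- feature_layout()
  stopifnot(length(vals) == 600L)
  structure(list(protein_id = protein_id, values = vals),
            class = "protein_feature")
}

#' @export
print.protein_feature <- function(x, ...) {
  cat(sprintf("Protein descriptor '%s': %d features\n", x$protein_id,
              length(x$values)))
  invisible(x)
}

#' Featurize a set of protein sequences into a feature matrix
#'
#' @param sequences named character vector (names are protein ids).
#' @inheritParams featurize_protein
#' @return numeric matrix, one row per protein (rownames = ids), 600
#'   columns named per [feature_layout()].
#' @export
featurize_proteins <- function(sequences, table = aa_property_table(),
                               min_len = 64L, max_len = 1200L,
                               policy = "strict") {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("`sequences` must be a named character vector of protein sequences")
  out <- matrix(NA_real_, nrow = length(sequences), ncol = 600L,
                dimnames = list(names(sequences), feature_layout()))
  for (i in seq_along(sequences)) {
    out[i, ] <- featurize_protein(sequences[[i]], table,
                                  protein_id = names(sequences)[i],
                                  min_len = min_len, max_len = max_len,
                                  policy = policy)$values
  }
  out
}
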