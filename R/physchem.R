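# Physicochemical encoding of amino-acid sequences.
#
# Eight per-residue properties drive the whole feature pipeline:
# H1  hydrophobicity            H2  hydrophilicity
# V   side-chain volume         P1  polarity
# P2  polarizability            SASA solvent-accessible surface area
# NCI side-chain net charge     P   composite isoelectric point + pKa

#' Names of the eight physicochemical properties, in canonical order
#' @export
PPI_PROPERTY_NAMES <- c("H1", "H2", "V", "P1", "P2", "SASA", "NCI", "P")

#' One-letter codes of the 20 standard amino acids, in table order
#' @export
PPI_AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 20 x 8 raw property values (rows in PPI_AA_CODES order, columns in
# PPI_PROPERTY_NAMES order).
.ppi_raw_properties <- matrix(c(
  # H1     H2     V      P1    P2     SASA   NCI        P
   0.62,  -0.5,   27.5,  8.1,  0.046, 1.181,  0.007187, 12.772,
   0.29,  -1.0,   44.6,  5.5,  0.128, 1.461, -0.03661,  10.4312,
  -0.90,   3.0,   40.0, 13.0,  0.105, 1.587, -0.02382,   8.4134,
  -0.74,   3.0,   62.0, 12.3,  0.151, 1.862,  0.006802,  9.1455,
   1.19,  -2.5,  115.5,  5.2,  0.290, 2.228,  0.037552, 11.6877,
   0.48,   0.0,    0.0,  9.0,  0.000, 0.881,  0.179052, 12.742,
  -0.40,  -0.5,   79.0, 10.4,  0.230, 2.025, -0.01069,  12.669,
   1.38,  -1.8,   93.5,  5.2,  0.186, 1.810,  0.021631, 12.5099,
  -1.50,   3.0,  100.0, 11.3,  0.219, 2.258,  0.017708, 15.9477,
   1.06,  -1.8,   93.5,  4.9,  0.186, 1.931,  0.051672, 12.4699,
   0.64,  -1.3,   94.1,  5.7,  0.221, 2.034,  0.002683, 11.6655,
  -0.78,   2.0,   58.7, 11.6,  0.134, 1.655,  0.005392, 11.3355,
   0.12,   0.0,   41.9,  8.0,  0.131, 1.468,  0.239531, 11.9434,
  -0.85,   0.2,   80.7, 10.5,  0.180, 1.932,  0.049211, 11.8677,
  -2.53,   3.0,  105.0, 10.5,  0.291, 2.560,  0.043587, 15.839,
  -0.18,   0.3,   29.3,  9.2,  0.062, 1.298,  0.004627, 11.8877,
  -0.05,  -0.4,   51.3,  8.6,  0.108, 1.525,  0.003352, 12.0855,
   1.08,  -1.5,   71.5,  5.9,  0.140, 1.645,  0.057004, 12.1677,
   0.81,  -3.4,  145.5,  5.4,  0.409, 2.663,  0.037977, 12.662,
   0.26,  -2.3,  117.3,  6.2,  0.298, 2.368,  0.023599, 11.8677),
  nrow = 20, byrow = TRUE,
  dimnames = list(PPI_AA_CODES, PPI_PROPERTY_NAMES))

#' Combine isoelectric point and pKa into the composite P property
#'
#' For each amino acid, `P_n = PI_n + u * pKa_n` where
#' `u = sum(PI) / sum(pKa)` over the 20 standard amino acids. The ratio
#' `u` puts the two scales on a common footing so neither dominates.
#'
#' @param pi_values numeric vector of 20 isoelectric points (table order).
#' @param pka_values numeric vector of 20 ionization equilibrium constants.
#' @return numeric vector of 20 composite P values.
#' @export
compute_p_property <- function(pi_values, pka_values) {
  if (length(pi_values) != 20L || length(pka_values) != 20L)
    stop("`pi_values` and `pka_values` must each have exactly 20 entries")
  if (!is.numeric(pi_values) || !is.numeric(pka_values))
    stop("PI and pKa values must be numeric")
  s <- sum(pka_values)
  if (s == 0)
    stop("degenerate input: sum of pKa values is zero")
  u <- sum(pi_values) / s
  pi_values + u * pka_values
}

#' Standardize a property table column-wise
#'
#' Each column is centred and scaled to mean 0 and standard deviation 1
#' across the 20 amino acids. The population form of the standard
#' deviation (denominator n) is used because the table is the complete
#' population of standard residues, not a sample.
#'
#' @param raw numeric matrix (amino acids in rows, properties in columns).
#' @return matrix of the same shape with standardized columns.
#' @export
standardize_table <- function(raw) {
  raw <- as.matrix(raw)
  n <- nrow(raw)
  mu <- colMeans(raw)
  centred <- sweep(raw, 2L, mu)
  sdev <- sqrt(colSums(centred^2) / n)
  if (any(sdev == 0))
    stop("degenerate input: constant property column(s): ",
         paste(colnames(raw)[sdev == 0], collapse = ", "))
  sweep(centred, 2L, sdev, "/")
}

#' The 20 x 8 amino-acid physicochemical property table
#'
#' Returns the canonical property table used throughout the package, as an
#' object of class `aa_property_table` holding both the raw values and the
#' column-standardized values (see [standardize_table()]).
#'
#' @param raw optional replacement 20 x 8 matrix (rows in `PPI_AA_CODES`
#'   order, columns in `PPI_PROPERTY_NAMES` order) for users supplying their
#'   own property set, e.g. a P column rebuilt with [compute_p_property()].
#' @return an `aa_property_table`: list with `codes`, `property_names`,
#'   `raw` and `standardized`.
#' @export
aa_property_table <- function(raw = NULL) {
  if (is.null(raw)) raw <- .ppi_raw_properties
  raw <- as.matrix(raw)
  if (!identical(dim(raw), c(20L, 8L)))
    stop("property table must be 20 amino acids x 8 properties")
  if (is.null(rownames(raw))) rownames(raw) <- PPI_AA_CODES
  if (is.null(colnames(raw))) colnames(raw) <- PPI_PROPERTY_NAMES
  structure(
    list(codes = rownames(raw),
         property_names = colnames(raw),
         raw = raw,
         standardized = standardize_table(raw)),
    class = "aa_property_table")
}

#' @export
print.aa_property_table <- function(x, ...) {
  cat("Amino-acid physicochemical property table (20 x 8)\n")
  cat("Properties:", paste(x$property_names, collapse = ", "), "\n")
  print(round(x$raw, 4))
  invisible(x)
}

#' Digitize an amino-acid sequence into eight numeric signals
#'
#' Each residue is replaced by its row of the standardized property table,
#' turning a length-L sequence into an L x 8 matrix: column j is the
#' digital signal of property j along the chain.
#'
#' @param sequence character scalar over the 20-letter amino-acid alphabet
#'   (case-insensitive).
#' @param table an [aa_property_table()].
#' @param protein_id identifier attached to the result.
#' @param policy `"strict"` rejects non-standard residues (B, J, O, U, X, Z,
#'   `*`, ...) with an error naming position and character; `"lenient"`
#'   drops them with a warning. Silent imputation is never done: it would
#'   corrupt the downstream wavelet statistics.
#' @return a `digital_sequence`: list with `protein_id`, `length` and the
#'   L x 8 `signals` matrix.
#' @export
encode_sequence <- function(sequence, table = aa_property_table(),
                            protein_id = "", policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string")
  if (!nzchar(sequence))
    stop("empty sequence", if (nzchar(protein_id)) paste0(" for protein '", protein_id, "'"))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, table$codes)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    if (policy == "strict") {
      stop(sprintf("invalid residue '%s' at position %d%s",
                   chars[bad[1]], bad[1],
                   if (nzchar(protein_id)) paste0(" in protein '", protein_id, "'") else ""))
    }
    warning(sprintf("dropping %d non-standard residue(s)%s",
                    length(bad),
                    if (nzchar(protein_id)) paste0(" in protein '", protein_id, "'") else ""))
    idx <- idx[-bad]
    if (!length(idx)) stop("no standard residues left after dropping")
  }
  signals <- table$standardized[idx, , drop = FALSE]
  rownames(signals) <- NULL
  structure(list(protein_id = protein_id,
                 length = length(idx),
                 signals = signals),
            class = "digital_sequence")
}

#' @export
print.digital_sequence <- function(x, ...) {
  cat(sprintf("Digital sequence%s: %d residues x %d property signals\n",
              if (nzchar(x$protein_id)) paste0(" '", x$protein_id, "'") else "",
              x$length, ncol(x$signals)))
  invisible(x)
}

#' Write / read a property table as delimited text
#'
#' Plain TSV with amino-acid codes in the first column and a header row of
#' property names, so users can swap in their own property sets.
#'
#' @param table an [aa_property_table()].
#' @param path file path.
#' @return `read_property_table` returns an [aa_property_table()].
#' @export
write_property_table <- function(table, path) {
  df <- data.frame(code = table$codes, table$raw, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "code"))
    stop("property table file must have a leading 'code' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$code
  aa_property_table(m)
}
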