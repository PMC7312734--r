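# Pair feature construction and forward/backward order augmentation.
#
# A pair record concatenates the two 600-dimensional protein descriptors
# in (A, B) order into a 1200-vector with a one-hot label: (1,0) =
# interacting, (0,1) = non-interacting. Because concatenation imposes an
# arbitrary order, the training set is augmented with the (B, A) copy of
# every record so the classifier cannot exploit input order; test sets
# are never augmented.

#' Concatenate two protein descriptors into one pair feature
#'
#' @param fa,fb `protein_feature` objects or plain 600-vectors.
#' @param label 1 (interacting) or 0 (non-interacting), or the one-hot
#'   pair c(1,0) / c(0,1).
#' @return a `pair_feature`: list with `values` (1200), `label` (one-hot),
#'   `id_a`, `id_b`.
#' @export
build_pair_feature <- function(fa, fb, label) {
  ida <- ""; idb <- ""
  if (inherits(fa, "protein_feature")) { ida <- fa$protein_id; fa <- fa$values }
  if (inherits(fb, "protein_feature")) { idb <- fb$protein_id; fb <- fb$values }
  if (length(fa) != 600L || length(fb) != 600L)
    stop("protein descriptors must have length 600 (got ",
         length(fa), " and ", length(fb), ")")
  structure(list(values = c(unname(fa), unname(fb)),
                 label = as_one_hot(label),
                 id_a = ida, id_b = idb),
            class = "pair_feature")
}

# 1/0 scalar or length-2 one-hot -> one-hot c(l1, l2)
as_one_hot <- function(label) {
  if (length(label) == 2L) {
    if (identical(unname(as.numeric(label)), c(1, 0)) ||
        identical(unname(as.numeric(label)), c(0, 1)))
      return(as.numeric(label))
    stop("one-hot label must be (1,0) or (0,1)")
  }
  if (!label %in% c(0, 1)) stop("label must be 1 (interacting) or 0")
  if (label == 1) c(1, 0) else c(0, 1)
}

#' Assemble a pair set from a feature matrix and a pair list
#'
#' @param features numeric matrix from [featurize_proteins()] (rownames
#'   are protein ids).
#' @param pairs data frame with columns `id_a`, `id_b`, `label` (1/0).
#' @param role `"training"` or `"test"`; only training pair sets may be
#'   augmented.
#' @return a `ppi_pairset`: list with `x` (n x 1200 matrix), `y` (n x 2
#'   one-hot matrix), `pairs` (the pair list with an `origin` column),
#'   `role`.
#' @export
build_pair_features <- function(features, pairs, role = c("training", "test")) {
  role <- match.arg(role)
  need <- c("id_a", "id_b", "label")
  if (!all(need %in% names(pairs)))
    stop("`pairs` must have columns id_a, id_b, label")
  missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(features))
  if (length(missing_ids))
    stop("pair list references proteins absent from the feature matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  if (!all(pairs$label %in% c(0, 1)))
    stop("pair labels must be 1 (interacting) or 0 (non-interacting)")
  x <- cbind(features[pairs$id_a, , drop = FALSE],
             features[pairs$id_b, , drop = FALSE])
  dimnames(x) <- NULL
  y <- cbind(pairs$label, 1 - pairs$label)
  meta <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                     label = pairs$label, origin = "fwd",
                     stringsAsFactors = FALSE)
  structure(list(x = x, y = y, pairs = meta, role = role),
            class = "ppi_pairset")
}

#' @export
print.ppi_pairset <- function(x, ...) {
  cat(sprintf("PPI pair set (%s): %d pairs (%d interacting), %d features\n",
              x$role, nrow(x$x), sum(x$y[, 1] == 1), ncol(x$x)))
  invisible(x)
}

#' Forward/backward pair-order augmentation
#'
#' Appends to a training pair set the order-swapped copy (B, A) of every
#' record, carrying the same label, so the set is exactly doubled.
#' Duplicates arising from self-pairs or pre-existing reversed pairs are
#' kept. Test sets must stay untouched: augmenting a pair set whose
#' `role` is `"test"` is an error (it would leak order information into
#' evaluation).
#'
#' @param pairset a `ppi_pairset` with `role == "training"`.
#' @return the doubled `ppi_pairset`; the `origin` column marks swapped
#'   records `"bwd"`.
#' @export
augment_forward_backward <- function(pairset) {
  if (!inherits(pairset, "ppi_pairset"))
    stop("`pairset` must be a ppi_pairset")
  if (!identical(pairset$role, "training"))
    stop("refusing to augment a '", pairset$role,
         "' pair set: forward/backward augmentation applies to training splits only")
  swapped <- pairset$x[, c(601:1200, 1:600), drop = FALSE]
  bwd <- pairset$pairs
  bwd$id_a <- pairset$pairs$id_b
  bwd$id_b <- pairset$pairs$id_a
  bwd$origin <- "bwd"
  structure(list(x = rbind(pairset$x, swapped),
                 y = rbind(pairset$y, pairset$y),
                 pairs = rbind(pairset$pairs, bwd),
                 role = "training"),
            class = "ppi_pairset")
}
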