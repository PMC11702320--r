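# Cell ordering conventions used throughout:
#   single tables:  (tp, fp, fn, tn) = (p11, p10, p01, p00), index (predicted, actual)
#   paired tables:  8 cells p_{ijk}, i = prediction of classifier 1,
#                   j = prediction of classifier 2, k = actual label, ordered
#                   (111, 110, 101, 100, 011, 010, 001, 000)

.PAIRED_CELLS <- c("p111", "p110", "p101", "p100", "p011", "p010", "p001", "p000")
.SINGLE_CELLS <- c("p11", "p10", "p01", "p00")

# 4x8 0/1 maps taking the 8 joint cells to (tp, fp, fn, tn) of each classifier.
# Classifier 1 reads (i, k); classifier 2 reads (j, k).
.J1 <- rbind(
  tp = c(1, 0, 1, 0, 0, 0, 0, 0),
  fp = c(0, 1, 0, 1, 0, 0, 0, 0),
  fn = c(0, 0, 0, 0, 1, 0, 1, 0),
  tn = c(0, 0, 0, 0, 0, 1, 0, 1)
)
.J2 <- rbind(
  tp = c(1, 0, 0, 0, 1, 0, 0, 0),
  fp = c(0, 1, 0, 0, 0, 1, 0, 0),
  fn = c(0, 0, 1, 0, 0, 0, 1, 0),
  tn = c(0, 0, 0, 1, 0, 0, 0, 1)
)
colnames(.J1) <- colnames(.J2) <- .PAIRED_CELLS

#' Construct a 2x2 confusion-count table
#'
#' Counts follow the usual layout: rows are the actual class, columns the
#' predicted class, with the positive class coded 1.
#'
#' @param tp,fp,fn,tn Non-negative integer counts of true positives, false
#'   positives, false negatives and true negatives.
#' @return An object of class `confusion_counts`: a named integer vector
#'   `(tp, fp, fn, tn)` with attribute `n`, the total count.
#' @examples
#' confusion_counts(90, 9, 1, 0)
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  x <- c(tp = unname(tp), fp = unname(fp), fn = unname(fn), tn = unname(tn))
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- sum(x)
  if (n < 1) stop("total count must be at least 1", call. = FALSE)
  structure(x, n = n, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x[["tp"]], x[["fn"]], x[["fp"]], x[["tn"]]), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  cat("2x2 confusion counts (n =", attr(x, "n"), ")\n")
  print(m)
  invisible(x)
}

#' Construct a cell-probability vector for a single classifier
#'
#' @param p11,p10,p01,p00 Joint probabilities P(prediction = i, actual = j);
#'   `p11` is the true-positive cell, `p10` false-positive, `p01`
#'   false-negative, `p00` true-negative. Must be non-negative and sum to 1.
#' @return An object of class `cell_probs`, a named numeric vector of length 4.
#' @examples
#' cell_probs(0.35, 0.15, 0.15, 0.35)
#' @export
cell_probs <- function(p11, p10, p01, p00) {
  p <- c(p11 = unname(p11), p10 = unname(p10), p01 = unname(p01),
         p00 = unname(p00))
  .check_simplex(p)
  structure(p, class = "cell_probs")
}

#' Construct a paired 2x2x2 count table
#'
#' @param x A named numeric vector with the eight cells `p111 ... p000`
#'   (index order: prediction of classifier 1, prediction of classifier 2,
#'   actual label), or an unnamed length-8 vector in that order, or a
#'   2x2x2 array with dimnames levels `c("1","0")`.
#' @return An object of class `paired_counts`: named integer vector of length
#'   8 with attribute `n`.
#' @examples
#' paired_counts(c(p111 = 40, p110 = 5, p101 = 5, p100 = 3,
#'                 p011 = 2, p010 = 4, p001 = 1, p000 = 40))
#' @export
paired_counts <- function(x) {
  x <- .coerce_paired_vector(x)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("paired counts must be non-negative integers", call. = FALSE)
  n <- sum(x)
  if (n < 1) stop("total count must be at least 1", call. = FALSE)
  structure(x, n = n, class = "paired_counts")
}

#' Construct a paired 2x2x2 cell-probability vector
#'
#' @param x Eight cell probabilities, same naming/order rules as
#'   [paired_counts()]. Must be non-negative and sum to 1.
#' @return An object of class `paired_cell_probs`.
#' @export
paired_cell_probs <- function(x) {
  p <- .coerce_paired_vector(x)
  .check_simplex(p)
  structure(p, class = "paired_cell_probs")
}

.coerce_paired_vector <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L && all(dim(x) == 2L)) {
    dn <- dimnames(x)
    if (is.null(dn)) dn <- rep(list(c("1", "0")), 3L)
    v <- vapply(.PAIRED_CELLS, function(nm) {
      idx <- strsplit(substring(nm, 2L), "")[[1]]
      x[match(idx[1], dn[[1]]), match(idx[2], dn[[2]]), match(idx[3], dn[[3]])]
    }, numeric(1))
    return(v)
  }
  x <- unlist(x)
  if (length(x) != 8L) stop("paired table needs exactly 8 cells", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), .PAIRED_CELLS))
      stop("paired cell names must be ", paste(.PAIRED_CELLS, collapse = ", "),
           call. = FALSE)
    x <- x[.PAIRED_CELLS]
  } else {
    names(x) <- .PAIRED_CELLS
  }
  x
}

.check_simplex <- function(p, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol))
    stop("cell probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("cell probabilities must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  invisible(p)
}

#' Tally a confusion table from binary label vectors
#'
#' @param actual,predicted Vectors of 0/1 labels of equal length.
#' @return A [confusion_counts()] object.
#' @examples
#' counts_from_labels(c(1, 1, 0), c(1, 0, 0))
#' @export
counts_from_labels <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have the same length (",
         length(actual), " vs ", length(predicted), ")", call. = FALSE)
  if (length(actual) < 1) stop("need at least one observation", call. = FALSE)
  .check_binary(actual, "actual")
  .check_binary(predicted, "predicted")
  confusion_counts(tp = sum(predicted == 1 & actual == 1),
                   fp = sum(predicted == 1 & actual == 0),
                   fn = sum(predicted == 0 & actual == 1),
                   tn = sum(predicted == 0 & actual == 0))
}

#' Tally a paired 2x2x2 table from binary label vectors
#'
#' @param actual,pred1,pred2 Vectors of 0/1 labels of equal length.
#' @return A [paired_counts()] object.
#' @export
paired_counts_from_labels <- function(actual, pred1, pred2) {
  if (length(actual) != length(pred1) || length(actual) != length(pred2))
    stop("label vectors must have the same length", call. = FALSE)
  .check_binary(actual, "actual")
  .check_binary(pred1, "pred1")
  .check_binary(pred2, "pred2")
  cnt <- vapply(.PAIRED_CELLS, function(nm) {
    idx <- as.integer(strsplit(substring(nm, 2L), "")[[1]])
    sum(pred1 == idx[1] & pred2 == idx[2] & actual == idx[3])
  }, numeric(1))
  paired_counts(cnt)
}

.check_binary <- function(x, what) {
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad))
    stop(what, " must be 0/1; offending value '", x[bad[1]],
         "' at index ", bad[1], call. = FALSE)
  invisible(x)
}

.as_cells <- function(x) {
  # returns (p11, p10, p01, p00) on whatever scale x carries
  if (inherits(x, "confusion_counts"))
    return(c(p11 = x[["tp"]], p10 = x[["fp"]], p01 = x[["fn"]], p00 = x[["tn"]]))
  if (inherits(x, "cell_probs")) return(unclass(x))
  stop("expected a confusion_counts or cell_probs object", call. = FALSE)
}

#' Matthews correlation coefficient
#'
#' Computes the MCC (phi coefficient)
#' \deqn{\mathrm{MCC} = \frac{TP\,TN - FP\,FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' from a confusion table or a cell-probability vector. The value is invariant
#' to the overall scale of the table, so counts and plug-in probabilities give
#' the same result.
#'
#' @param x A [confusion_counts()] or [cell_probs()] object.
#' @return A number in \eqn{[-1, 1]}, or `NA` when any of the four margins
#'   (predicted positive/negative, actual positive/negative) is zero, in which
#'   case the denominator vanishes.
#' @examples
#' mcc(confusion_counts(90, 9, 1, 0))   # -0.032: poor classifier despite 0.9 accuracy
#' @export
mcc <- function(x) {
  p <- .as_cells(x)
  m <- c(p[1] + p[2], p[1] + p[3], p[4] + p[2], p[4] + p[3])
  if (any(m == 0)) return(NA_real_)
  if (p[2] == 0 && p[3] == 0) return(1)   # exact: no off-diagonal mass
  if (p[1] == 0 && p[4] == 0) return(-1)
  v <- (p[1] * p[4] - p[2] * p[3]) / sqrt(prod(m))
  unname(min(1, max(-1, v)))
}

#' Confusion-matrix performance metrics
#'
#' Computes MCC together with the common companion metrics. Each metric is
#' `NA` exactly when its own denominator is zero.
#'
#' @param x A [confusion_counts()] object.
#' @return A named list with elements `mcc`, `accuracy`, `balanced_accuracy`,
#'   `f1`, `tpr`, `tnr`, `precision`.
#' @examples
#' metric_set(confusion_counts(90, 9, 1, 0))
#' @export
metric_set <- function(x) {
  p <- .as_cells(x)
  tp <- p[[1]]; fp <- p[[2]]; fn <- p[[3]]; tn <- p[[4]]
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr  <- rat(tp, tp + fn)
  tnr  <- rat(tn, tn + fp)
  prec <- rat(tp, tp + fp)
  f1   <- if (is.na(prec) || is.na(tpr) || prec + tpr == 0) NA_real_ else
    2 * prec * tpr / (prec + tpr)
  list(
    mcc = mcc(x),
    accuracy = rat(tp + tn, tp + fp + fn + tn),
    balanced_accuracy = if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2,
    f1 = f1,
    tpr = tpr, tnr = tnr, precision = prec
  )
}

#' Fisher's z transformation and its inverse
#'
#' `fisher_z()` is artanh, mapping a correlation in \eqn{(-1,1)} to the real
#' line; `fisher_z_inv()` is tanh.
#'
#' @param x A numeric vector with entries in \eqn{(-1, 1)}.
#' @param y Any numeric vector.
#' @return Transformed numeric vector.
#' @examples
#' fisher_z(0.4)
#' fisher_z_inv(fisher_z(0.4))
#' @export
fisher_z <- function(x) {
  if (any(abs(x) >= 1)) stop("fisher_z requires |x| < 1", call. = FALSE)
  atanh(x)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(y) tanh(y)

#' Modified artanh transformation for an MCC difference
#'
#' `mt_transform()` maps a difference of two correlations, which lives in
#' \eqn{(-2, 2)}, to the real line via
#' \eqn{g(x) = \tfrac12 \log\{(2+x)/(2-x)\}}; identically
#' `mt_transform(x) == fisher_z(x/2)`. `mt_transform_inv()` is
#' \eqn{y \mapsto 2\tanh(y)}.
#'
#' @param x Numeric vector with entries in \eqn{(-2, 2)}.
#' @param y Any numeric vector.
#' @return Transformed numeric vector.
#' @export
mt_transform <- function(x) {
  if (any(abs(x) >= 2)) stop("mt_transform requires |x| < 2", call. = FALSE)
  0.5 * log((2 + x) / (2 - x))
}

#' @rdname mt_transform
#' @export
mt_transform_inv <- function(y) 2 * tanh(y)

#' Marginalize a paired table to one classifier's 2x2 table
#'
#' Collapses the 2x2x2 joint table over the other classifier's prediction:
#' for classifier 1, \eqn{TP = p_{111} + p_{101}}, \eqn{FP = p_{110} + p_{100}},
#' \eqn{FN = p_{011} + p_{001}}, \eqn{TN = p_{010} + p_{000}}; symmetrically
#' for classifier 2.
#'
#' @param x A [paired_counts()] or [paired_cell_probs()] object.
#' @param which Which classifier's margin to extract, 1 or 2.
#' @return A [confusion_counts()] (for counts input) or [cell_probs()]
#'   (for probability input) object.
#' @export
marginalize <- function(x, which = 1) {
  which <- match.arg(as.character(which), c("1", "2"))
  J <- if (which == "1") .J1 else .J2
  v <- drop(J %*% as.numeric(x))
  if (inherits(x, "paired_counts"))
    confusion_counts(tp = v[1], fp = v[2], fn = v[3], tn = v[4])
  else if (inherits(x, "paired_cell_probs"))
    cell_probs(v[1], v[2], v[3], v[4])
  else stop("expected a paired_counts or paired_cell_probs object", call. = FALSE)
}
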