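#' Area-based extraction accuracy
#'
#' P = (1 - |a - b| / b) * 100, comparing an extracted quantity `a` (pixel
#' count or area) against the reference quantity `b` from the validation
#' survey. The ratio is dimensionless, so counts and areas are
#' interchangeable as long as `a` and `b` use the same unit. Values of `a`
#' beyond twice the reference yield a negative percentage, returned as
#' computed rather than clamped.
#'
#' @param a Extracted amount (>= 0).
#' @param b Reference amount (> 0).
#' @return Accuracy in percent.
#' @examples
#' area_accuracy(43.20, 43.90)  # 98.4% for the 2019 heavy class
#' @export
area_accuracy <- function(a, b) {
  if (!is.numeric(b) || any(b <= 0))
    stop("domain error: reference amount b must be > 0", call. = FALSE)
  (1 - abs(a - b) / b) * 100
}

#' Confusion matrix of two categorical rasters
#'
#' Cross-tabulates reference (rows) against predicted (columns) classes over
#' pixels valid in both rasters; nodata on either side is excluded. The
#' label set is the sorted union of codes seen on both sides.
#'
#' @param reference,predicted Aligned categorical [raster_grid]s.
#' @return An object of class `confusion_matrix`: integer `counts` matrix
#'   with class labels as dimnames, and `total`.
#' @export
confusion <- function(reference, predicted) {
  check_aligned(reference, predicted, what = "confusion inputs")
  r <- reference$values; p <- predicted$values
  keep <- !is.na(r) & !is.na(p)
  labels <- sort(unique(c(r[keep], p[keep])))
  counts <- table(factor(r[keep], levels = labels),
                  factor(p[keep], levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(reference = labels, predicted = labels))
  structure(list(counts = counts, total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = reference, cols = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' Cohen's kappa of a confusion matrix
#'
#' kappa = (P_o - P_e) / (1 - P_e), with P_o the diagonal share of the
#' matrix total and P_e the chance agreement sum_k(row_k * col_k) / total^2.
#'
#' @param cm A `confusion_matrix`, or a plain square numeric matrix of
#'   counts.
#' @return Kappa (<= 1; 1 iff all off-diagonal mass is zero).
#' @examples
#' kappa_coefficient(matrix(c(30, 5, 10, 55), 2, 2))
#' @export
kappa_coefficient <- function(cm) {
  m <- if (inherits(cm, "confusion_matrix")) cm$counts else cm
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n <= 0) stop("domain error: empty confusion matrix", call. = FALSE)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stop("undefined kappa: chance agreement P_e = 1 (single class on both sides)",
         call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Write a confusion matrix as labelled CSV
#'
#' @param cm A `confusion_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- as.data.frame(cm$counts)
  df <- cbind(reference = rownames(cm$counts), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
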