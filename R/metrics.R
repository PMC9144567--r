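#' Sleep stage class labels
#'
#' The five AASM stage labels in canonical order: wake, the three NREM
#' depths, and REM. All confusion matrices and probability vectors in the
#' package use this order.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "R")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' Confusion matrix for sleep stage predictions
#'
#' Rows are the actual (reference) stages, columns the predicted stages,
#' both in the canonical order `stage_levels()`.
#'
#' @param y_true character or factor vector of reference stages.
#' @param y_pred character or factor vector of predicted stages, same length.
#' @param levels class labels; defaults to the five AASM stages.
#' @return An integer matrix of class `sleep_confusion` with row and column
#'   names equal to `levels`.
#' @examples
#' confusion(c("W", "N2", "N2"), c("W", "N2", "N1"))
#' @export
confusion <- function(y_true, y_pred, levels = stage_levels()) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  yt <- factor(as.character(y_true), levels = levels)
  yp <- factor(as.character(y_pred), levels = levels)
  if (anyNA(yt) || anyNA(yp))
    stop("labels outside the class set: ",
         paste(setdiff(unique(c(as.character(y_true), as.character(y_pred))),
                       levels), collapse = ", "))
  cm <- table(actual = yt, predicted = yp)
  cm <- matrix(as.integer(cm), nrow = length(levels),
               dimnames = list(actual = levels, predicted = levels))
  class(cm) <- c("sleep_confusion", class(cm))
  cm
}

#' Scoring metrics from a confusion matrix
#'
#' Computes overall accuracy, macro-averaged precision and recall
#' (unweighted means of the per-class rates), macro-F, per-class
#' precision/recall/F1, and Cohen's kappa
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_e = \sum_i r_i c_i / n^2} (chance agreement from the row and
#' column marginals).
#'
#' Two macro-F conventions circulate in the sleep-scoring literature:
#' the unweighted mean of the per-class F1 scores (the default here, and
#' the one consistent with per-class F1 tables), and the harmonic mean of
#' macro-precision and macro-recall. Both are computed; `macro_f` selects
#' which one is reported as `macro_F`.
#'
#' A class absent from the predictions (empty column) gets precision 0, and
#' an empty reference row gets recall 0; such classes are listed in the
#' `degenerate` field.
#'
#' @param cm a 5x5 (or k x k) confusion matrix, rows = actual,
#'   columns = predicted.
#' @param macro_f `"mean_f1"` (default) or `"harmonic"`.
#' @return An object of class `eval_report`: a list with fields `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_F`, `macro_F_harmonic`,
#'   `kappa`, `per_class` (data frame of precision/recall/F1), `n`,
#'   and `degenerate`.
#' @examples
#' cm <- confusion(c("W", "N2", "N2", "R"), c("W", "N2", "N1", "R"))
#' evaluate_confusion(cm)
#' @export
evaluate_confusion <- function(cm, macro_f = c("mean_f1", "harmonic")) {
  macro_f <- match.arg(macro_f)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix entries must be non-negative")
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  col_tot <- colSums(cm)
  row_tot <- rowSums(cm)
  degenerate <- rownames(cm)[col_tot == 0 | row_tot == 0]
  prec <- ifelse(col_tot > 0, tp / col_tot, 0)
  rec <- ifelse(row_tot > 0, tp / row_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  po <- sum(tp) / n
  pe <- sum(row_tot * col_tot) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  mp <- mean(prec)
  mr <- mean(rec)
  rep <- list(
    accuracy = po,
    macro_precision = mp,
    macro_recall = mr,
    macro_F = if (macro_f == "mean_f1") mean(f1) else
      2 * mp * mr / (mp + mr),
    macro_F_mean_f1 = mean(f1),
    macro_F_harmonic = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0,
    kappa = kappa,
    per_class = data.frame(class = rownames(cm), precision = prec,
                           recall = rec, f1 = f1, row.names = NULL),
    n = n,
    macro_f_variant = macro_f,
    degenerate = degenerate
  )
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Sleep staging evaluation (n = %d epochs)\n", x$n))
  cat(sprintf("  accuracy        %5.1f %%\n", 100 * x$accuracy))
  cat(sprintf("  macro-precision %5.1f %%\n", 100 * x$macro_precision))
  cat(sprintf("  macro-recall    %5.1f %%\n", 100 * x$macro_recall))
  cat(sprintf("  macro-F         %5.1f %%  (%s)\n", 100 * x$macro_F,
              x$macro_f_variant))
  cat(sprintf("  Cohen's kappa   %5.2f\n", x$kappa))
  cat("  per-class F1 (%):",
      paste(sprintf("%s %.1f", x$per_class$class, 100 * x$per_class$f1),
            collapse = ", "), "\n")
  if (length(x$degenerate))
    cat("  degenerate classes (empty row/column):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Read a labelled confusion matrix from TSV
#'
#' Expects a header row of predicted-stage labels and a first column of
#' actual-stage labels; any `Total` row/column is dropped.
#'
#' @param path TSV file path.
#' @return A `sleep_confusion` matrix.
#' @export
read_confusion_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  df <- df[rownames(df) != "Total", colnames(df) != "Total", drop = FALSE]
  cm <- as.matrix(df)
  storage.mode(cm) <- "integer"
  names(dimnames(cm)) <- c("actual", "predicted")
  class(cm) <- c("sleep_confusion", class(cm))
  cm
}

#' Write a confusion matrix to TSV with labels
#' @param cm confusion matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confusion_tsv <- function(cm, path) {
  df <- as.data.frame(as.matrix(cm))
  utils::write.table(cbind(stage = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
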