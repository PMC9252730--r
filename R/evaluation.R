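#' Confusion counts for binary residue predictions
#'
#' @param predictions Named 0/1 vector (or `bsite_predictions` data
#'   frame) of predicted labels by residue key.
#' @param labels Named 0/1 vector of true labels over the same keys.
#' @return List of class `bsite_confusion` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predictions, labels) {
  if (is.data.frame(predictions))
    predictions <- setNames(predictions$predicted, predictions$key)
  if (!setequal(names(predictions), names(labels)))
    stop("prediction and label residue keys differ")
  p <- as.integer(predictions[names(labels)])
  y <- as.integer(labels)
  base::structure(list(
    tp = sum(p == 1 & y == 1), tn = sum(p == 0 & y == 0),
    fp = sum(p == 1 & y == 0), fn = sum(p == 0 & y == 1)),
    class = "bsite_confusion")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0
#' when any factor of the denominator is 0.
#'
#' @param counts A `bsite_confusion` list (or any list with tp, tn,
#'   fp, fn).
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

precision_of <- function(counts) {
  if (counts$tp + counts$fp == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fp)
}

recall_of <- function(counts) {
  if (counts$tp + counts$fn == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fn)
}

#' Distance from a pocket center to the nearest ligand atom (DCA)
#'
#' @param center Numeric length-3 vector.
#' @param ligand Data frame of ligand atoms with `x`, `y`, `z` columns
#'   (e.g. from the structure's atom table), or a numeric matrix.
#' @return Minimum Euclidean distance in Angstrom.
#' @export
dca <- function(center, ligand) {
  xyz <- if (is.matrix(ligand)) ligand else
    as.matrix(ligand[, c("x", "y", "z")])
  if (nrow(xyz) == 0) stop("ligand has no atoms")
  min(sqrt(colSums((t(xyz) - center)^2)))
}

#' Evaluate predictions for one structure
#'
#' Residue-level MCC, precision and recall against true labels; when
#' pockets and a ligand are supplied, per-pocket DCA and whether any
#' pocket "hits" (DCA below `dca_threshold`).
#'
#' @param predictions `bsite_predictions` or named 0/1 vector.
#' @param labels Named 0/1 vector of true labels.
#' @param pockets Optional `bsite_pockets`.
#' @param structure Optional `bsite_structure` (required for DCA).
#' @param ligand_key Optional ligand key; default first ligand.
#' @param dca_threshold Pocket hit cutoff in Angstrom (default 4.0).
#' @return List of class `bsite_evaluation`: `mcc`, `precision`,
#'   `recall`, `counts`, and optionally `dca` (per pocket) and `hit`.
#' @export
evaluate_structure <- function(predictions, labels, pockets = NULL,
                               structure = NULL, ligand_key = NULL,
                               dca_threshold = 4.0) {
  if (length(labels) == 0) stop("empty label set")
  cts <- confusion(predictions, labels)
  out <- list(mcc = mcc(cts), precision = precision_of(cts),
              recall = recall_of(cts), counts = cts)
  if (!is.null(pockets) && !is.null(structure) &&
      nrow(structure$ligands) > 0) {
    lk <- if (is.null(ligand_key)) structure$ligands$key[1] else ligand_key
    la <- ligand_atoms(structure, lk)
    out$dca <- vapply(pockets$pockets, function(p) dca(p$center, la), 0)
    out$hit <- length(out$dca) > 0 && any(out$dca <= dca_threshold)
  }
  class(out) <- "bsite_evaluation"
  out
}

#' @export
print.bsite_evaluation <- function(x, ...) {
  cat(sprintf("MCC %.3f  precision %.3f  recall %.3f  (tp %d fp %d fn %d tn %d)\n",
              x$mcc, x$precision, x$recall, x$counts$tp, x$counts$fp,
              x$counts$fn, x$counts$tn))
  if (!is.null(x$dca))
    cat("  DCA per pocket:", paste(sprintf("%.2f", x$dca),
                                   collapse = ", "),
        if (isTRUE(x$hit)) " [hit]" else "", "\n")
  invisible(x)
}

#' Aggregate evaluations over a dataset
#'
#' @param evaluations List of `bsite_evaluation` objects.
#' @param mode `"macro"` (default): unweighted mean of per-structure
#'   metrics; `"micro"`: metrics recomputed on pooled confusion counts.
#' @return List with `mcc`, `precision`, `recall`, `n_structures`.
#' @export
evaluate_dataset <- function(evaluations, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  if (mode == "macro") {
    list(mcc = mean(vapply(evaluations, `[[`, 0, "mcc")),
         precision = mean(vapply(evaluations, `[[`, 0, "precision"),
                          na.rm = TRUE),
         recall = mean(vapply(evaluations, `[[`, 0, "recall"),
                       na.rm = TRUE),
         n_structures = length(evaluations))
  } else {
    pooled <- base::structure(list(
      tp = sum(vapply(evaluations, function(e) e$counts$tp, 0)),
      tn = sum(vapply(evaluations, function(e) e$counts$tn, 0)),
      fp = sum(vapply(evaluations, function(e) e$counts$fp, 0)),
      fn = sum(vapply(evaluations, function(e) e$counts$fn, 0))),
      class = "bsite_confusion")
    list(mcc = mcc(pooled), precision = precision_of(pooled),
         recall = recall_of(pooled), n_structures = length(evaluations))
  }
}
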