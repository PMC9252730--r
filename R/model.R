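#' Label binding residues by ligand proximity
#'
#' A residue is a binding residue iff some heavy atom of the residue
#' and some heavy atom of the ligand are closer than the sum of their
#' van der Waals radii plus `margin` (the contact convention used by curated binding databases).
#'
#' @param structure A `bsite_structure` containing the ligand.
#' @param ligand_key Key of the ligand group (see
#'   `structure$ligands$key`); default: the union over every ligand in
#'   the structure.
#' @param margin Margin in Angstrom added to the vdW sum (default 0.5).
#' @return Named integer vector (0/1) over all polymer residue keys.
#' @export
label_binding_residues <- function(structure, ligand_key = NULL,
                                   margin = 0.5) {
  keys <- structure$residues$key
  labels <- setNames(integer(length(keys)), keys)
  lkeys <- if (is.null(ligand_key)) structure$ligands$key else ligand_key
  if (is.null(ligand_key) && length(lkeys) == 0) return(labels)
  ha <- heavy_atoms(structure)
  rxyz <- as.matrix(ha[, c("x", "y", "z")])
  rr <- vdw_of(ha$element)
  for (lk in lkeys) {
    la <- ligand_atoms(structure, lk)
    lxyz <- as.matrix(la[, c("x", "y", "z")])
    lr <- vdw_of(la$element)
    for (m in seq_len(nrow(la))) {
      d <- sqrt(colSums((t(rxyz) - lxyz[m, ])^2))
      hit <- d <= rr + lr[m] + margin
      labels[unique(ha$key[hit])] <- 1L
    }
  }
  labels
}

#' Select training templates by sequence identity
#'
#' Ranks store templates by global pairwise alignment identity to the
#' query sequence (BLOSUM62 scoring), keeps those inside
#' `[min_identity, max_identity]`, and truncates to `max_templates`.
#' Setting `max_identity < 1` excludes the query itself and
#' near-duplicates, enabling leakage-free benchmarking.
#'
#' @param query_sequence One-letter amino-acid string.
#' @param store A `bsite_store` (see [read_template_store()]).
#' @param min_identity,max_identity Identity window, fractions in
#'   \[0, 1\].
#' @param max_templates Maximum number of templates kept.
#' @return The store restricted to the selected templates, ordered by
#'   decreasing identity; each record gains an `identity` field.
#' @export
select_templates <- function(query_sequence, store, min_identity = 0,
                             max_identity = 0.95, max_templates = 50) {
  if (length(store$templates) == 0) stop("template store is empty")
  ids <- vapply(store$templates, function(t) t$id, "")
  idents <- vapply(store$templates, function(t)
    sequence_identity(query_sequence, t$sequence), 0)
  keep <- which(idents >= min_identity & idents <= max_identity)
  if (!length(keep))
    stop(structure(class = c("bsite_no_templates_error", "error",
                             "condition"),
                   list(message = paste0(
                     "no templates in identity window [", min_identity,
                     ", ", max_identity, "]"), call = NULL)))
  keep <- keep[order(-idents[keep], ids[keep])]
  keep <- keep[seq_len(min(length(keep), max_templates))]
  out <- store
  out$templates <- lapply(keep, function(i) {
    t <- store$templates[[i]]
    t$identity <- idents[i]
    t
  })
  out
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring; identity is
#' the fraction of identical positions over the alignment length.
#'
#' @param a,b One-letter amino-acid strings (non-standard residues as
#'   `X`).
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Fit the balanced extremely-randomized-trees ensemble
#'
#' Binding residues are rare, so a plain forest would drown them in
#' negatives. The fit draws `n_bags` class-balanced subsamples — every
#' bag keeps all minority-class rows and an equal-size majority sample
#' drawn without replacement (bag seed = `seed + bag index`) — and
#' fits one extremely-randomized-trees probability forest per bag.
#' Rows are put in a canonical order (by label, then feature values)
#' before sampling so the fit is invariant to input row order.
#'
#' @param x Feature matrix / data frame (a `bsite_features` object or
#'   any numeric matrix whose columns are the model's features).
#' @param y Binary labels (0/1, logical, or 2-level factor), positives
#'   = binding.
#' @param n_bags Number of balanced bags (default 10).
#' @param trees_per_bag Trees per bag (default 100).
#' @param seed Integer seed; all bag sampling and tree randomness
#'   derives from it.
#' @param threshold Decision threshold on the mean positive-class
#'   probability (default 0.5).
#' @return An object of class `bsite_model`.
#' @export
bsite_fit <- function(x, y, n_bags = 10, trees_per_bag = 100, seed = 1,
                      threshold = 0.5) {
  if (inherits(x, "bsite_features")) x <- feature_block(x)
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("row/label length mismatch")
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  if (is.null(colnames(x))) stop("feature columns must be named")

  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(x)),
                                          function(j) x[, j])))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]

  minority <- if (sum(y == 1) <= sum(y == 0)) 1L else 0L
  idx_min <- which(y == minority)
  idx_maj <- which(y != minority)
  n_min <- length(idx_min)

  bags <- vector("list", n_bags)
  compositions <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    bag_seed <- seed + b
    set.seed(bag_seed)
    samp <- sample(idx_maj, n_min)
    rows <- c(idx_min, sort(samp))
    yf <- factor(ifelse(y[rows] == 1, "pos", "neg"),
                 levels = c("neg", "pos"))
    fit <- ranger::ranger(
      x = as.data.frame(x[rows, , drop = FALSE]), y = yf,
      num.trees = trees_per_bag, splitrule = "extratrees",
      probability = TRUE, importance = "impurity",
      seed = bag_seed, num.threads = 1,
      respect.unordered.factors = "order")
    bags[[b]] <- fit
    compositions[[b]] <- rows
  }

  structure(list(
    bags = bags, n_bags = n_bags, trees_per_bag = trees_per_bag,
    feature_names = colnames(x), threshold = threshold, seed = seed,
    minority_class = minority, n_train = length(y),
    n_pos = sum(y == 1), bag_rows = compositions),
    class = "bsite_model")
}

#' @export
print.bsite_model <- function(x, ...) {
  cat("<bsite_model> balanced extremely-randomized-trees ensemble\n")
  cat("  bags: ", x$n_bags, " x ", x$trees_per_bag, " trees",
      "  (bag size ", length(x$bag_rows[[1]]), " rows)\n", sep = "")
  cat("  training rows: ", x$n_train, " (", x$n_pos, " binding)\n",
      sep = "")
  cat("  features: ", length(x$feature_names),
      "   threshold: ", x$threshold, "   seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.bsite_model <- function(object, ...) {
  imp <- feature_importance(object)
  cat("Balanced extra-trees binding-site classifier\n")
  print(object)
  cat("  top features by importance:\n")
  top <- utils::head(imp, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-28s %.4f\n", top$feature[i], top$importance[i]))
  invisible(imp)
}

#' Predict per-residue binding labels
#'
#' The confidence of a residue is the mean positive-class probability
#' over all trees in all bags; the label is `confidence >= threshold`.
#'
#' @param object A `bsite_model`.
#' @param newdata A `bsite_features` data frame or numeric matrix whose
#'   column names match the training features exactly.
#' @param ... Unused.
#' @return A data frame of class `bsite_predictions` with columns
#'   `key` (when available), `confidence` and `predicted` (0/1).
#' @export
predict.bsite_model <- function(object, newdata, ...) {
  keys <- NULL
  if (inherits(newdata, "bsite_features")) {
    keys <- newdata$key
    newdata <- feature_block(newdata)
  }
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$feature_names))
    stop("feature columns do not match the model's training columns")
  probs <- vapply(object$bags, function(fit) {
    p <- predict(fit, data = as.data.frame(newdata),
                 num.threads = 1)$predictions
    p[, "pos"]
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1) probs <- matrix(probs, nrow = 1)
  conf <- rowMeans(probs)
  out <- data.frame(confidence = conf,
                    predicted = as.integer(conf >= object$threshold))
  if (!is.null(keys)) out <- cbind(key = keys, out,
                                   stringsAsFactors = FALSE)
  class(out) <- c("bsite_predictions", "data.frame")
  out
}

#' Ranked feature importances
#'
#' Per-bag impurity importances are normalized to sum to one, averaged
#' over bags, re-normalized, and sorted descending (ties broken by
#' column order).
#'
#' @param model A `bsite_model`.
#' @return Data frame with columns `feature`, `importance` (summing to
#'   1), sorted descending.
#' @export
feature_importance <- function(model) {
  imps <- vapply(model$bags, function(fit) {
    v <- fit$variable.importance[model$feature_names]
    s <- sum(v)
    if (s > 0) v / s else rep(0, length(v))
  }, numeric(length(model$feature_names)))
  avg <- rowMeans(imps)
  if (sum(avg) > 0) avg <- avg / sum(avg)
  ord <- order(-avg, seq_along(avg))
  data.frame(feature = model$feature_names[ord],
             importance = unname(avg[ord]), stringsAsFactors = FALSE)
}
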