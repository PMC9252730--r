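#' DBSCAN over 3-D points
#'
#' Standard DBSCAN semantics with Euclidean distances: a point is a
#' core point when its eps-neighborhood (itself included) holds at
#' least `min_samples` points; clusters are the connected components of
#' core points under eps-reachability; border points join the first
#' core cluster that reaches them in input order; the rest is noise.
#'
#' @param coords Numeric matrix, one point per row.
#' @param eps Neighborhood radius.
#' @param min_samples Density threshold (neighborhood size including
#'   the point itself).
#' @return Integer vector of cluster ids (1, 2, ...) with 0 for noise.
#' @export
dbscan_points <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_samples
  labels <- integer(n)  # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (labels[q] == 0L) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nb[[q]][labels[nb[[q]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster predicted binding residues into candidate pockets
#'
#' Runs DBSCAN on the representative coordinates (CA, else heavy-atom
#' centroid) of the predicted-positive residues.
#'
#' @param predictions A `bsite_predictions` data frame with `key` and
#'   `predicted` columns.
#' @param structure The `bsite_structure` the predictions refer to.
#' @param eps DBSCAN radius in Angstrom (default 6.0).
#' @param min_samples DBSCAN density threshold (default 3).
#' @return An object of class `bsite_pockets`: list of pockets (each
#'   with `pocket_id`, `keys`, `center`, `n`) plus a `noise` key set.
#' @export
cluster_predictions <- function(predictions, structure, eps = 6.0,
                                min_samples = 3) {
  pos <- predictions$key[predictions$predicted == 1]
  # deterministic residue order
  pos <- structure$residues$key[structure$residues$key %in% pos]
  if (length(pos) == 0)
    return(base::structure(list(pockets = list(), noise = character(0)),
                            class = "bsite_pockets"))
  xyz <- representative_coords(structure, pos)
  labels <- dbscan_points(xyz, eps, min_samples)
  pockets <- lapply(sort(unique(labels[labels > 0])), function(cl) {
    keys <- pos[labels == cl]
    list(pocket_id = cl, keys = keys,
         center = colMeans(xyz[labels == cl, , drop = FALSE]),
         n = length(keys))
  })
  base::structure(list(pockets = pockets, noise = pos[labels == 0]),
                  class = "bsite_pockets")
}

#' @export
print.bsite_pockets <- function(x, ...) {
  cat("<bsite_pockets> ", length(x$pockets), " pocket(s), ",
      length(x$noise), " noise residue(s)\n", sep = "")
  for (p in x$pockets)
    cat(sprintf("  pocket %d: %d residues, center (%.1f, %.1f, %.1f)\n",
                p$pocket_id, p$n, p$center[1], p$center[2], p$center[3]))
  invisible(x)
}

#' Geometric center of a pocket
#'
#' @param pocket A pocket entry (with `keys`) or a character vector of
#'   residue keys.
#' @param structure The `bsite_structure`.
#' @return Numeric length-3 vector: the arithmetic mean of the member
#'   residues' representative coordinates.
#' @export
pocket_center <- function(pocket, structure) {
  keys <- if (is.list(pocket)) pocket$keys else pocket
  if (length(keys) == 0) stop("empty pocket")
  colMeans(representative_coords(structure, keys))
}

# Residue chemical category for site signatures: fixed precedence over
# the residue's atom-class counts.
.category_precedence <- c("positive", "negative", "aromatic", "polar",
                          "hydrophobic", "other")

residue_categories <- function(structure, keys) {
  if (!has_classes(structure)) structure <- assign_atom_classes(structure)
  ha <- heavy_atoms(structure)
  vapply(keys, function(k) {
    sub <- ha[ha$key == k, , drop = FALSE]
    if (any(sub$cls_positive)) return("positive")
    if (any(sub$cls_negative)) return("negative")
    if (any(sub$cls_aromatic)) return("aromatic")
    # polar means donor/acceptor beyond the backbone N/O every residue has
    side <- sub[!(sub$name %in% c("N", "CA", "C", "O", "OXT")), ,
                drop = FALSE]
    if (any(side$cls_donor) || any(side$cls_acceptor)) return("polar")
    if (any(sub$cls_hydrophobic)) return("hydrophobic")
    "other"
  }, "")
}

#' Distance signature of a binding site
#'
#' A rotation/translation-invariant descriptor of a residue set: all
#' pairwise distances between residue representative coordinates,
#' binned by the unordered pair of residue chemical categories
#' (positive, negative, aromatic, polar, hydrophobic, other) and sorted
#' ascending within each bin.
#'
#' @param keys Character vector of at least 2 residue keys.
#' @param structure The `bsite_structure`.
#' @return An object of class `site_signature`: named list of sorted
#'   distance vectors, names `"catA:catB"`.
#' @export
site_signature <- function(keys, structure) {
  if (length(keys) < 2) stop("site signature requires >= 2 residues")
  xyz <- representative_coords(structure, keys)
  cats <- residue_categories(structure, keys)
  n <- length(keys)
  pairs <- utils::combn(n, 2)
  d <- sqrt(colSums((t(xyz[pairs[1, ], , drop = FALSE]) -
                       t(xyz[pairs[2, ], , drop = FALSE]))^2))
  bin <- vapply(seq_len(ncol(pairs)), function(p) {
    cc <- sort(c(cats[pairs[1, p]], cats[pairs[2, p]]))
    paste(cc, collapse = ":")
  }, "")
  sig <- lapply(split(d, bin), sort)
  base::structure(sig, class = "site_signature", n_residues = n)
}

# Greedy two-pointer match count between two sorted vectors: pairs
# within tol, each element used at most once. For sorted lists this
# equals the optimal interval matching.
match_sorted <- function(a, b, tol) {
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[i] - b[j]) <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) i <- i + 1L else j <- j + 1L
  }
  m
}

#' Similarity score between two site signatures
#'
#' For each shared category-pair bin the two sorted distance lists are
#' aligned greedily, counting matches within `tol`; the score is
#' `2 * matches / (pairs_a + pairs_b)`, in \[0, 1\] (1 for identical
#' sites, 0 for category-disjoint ones).
#'
#' @param a,b `site_signature` objects.
#' @param tol Distance tolerance in Angstrom (default 0.5).
#' @return Similarity in \[0, 1\].
#' @export
site_similarity <- function(a, b, tol = 0.5) {
  ta <- sum(lengths(a)); tb <- sum(lengths(b))
  if (ta + tb == 0) return(0)
  m <- sum(vapply(intersect(names(a), names(b)), function(nm)
    match_sorted(a[[nm]], b[[nm]], tol), 0L))
  2 * m / (ta + tb)
}

#' Rank candidate ligands for each pocket
#'
#' Compares every pocket against every template binding site in the
#' store and keeps, per HET code, the best similarity score; returns
#' the `top_k` ligands per pocket, sorted by score descending (ties by
#' HET code).
#'
#' @param pockets A `bsite_pockets` object.
#' @param structure The query `bsite_structure`.
#' @param store A `bsite_store` whose templates carry `sites` records.
#' @param top_k Suggestions per pocket (default 5).
#' @param tol Similarity tolerance passed to [site_similarity()].
#' @return Named list (by pocket id) of data frames `het_code`,
#'   `template_id`, `score`.
#' @export
suggest_ligands <- function(pockets, structure, store, top_k = 5,
                            tol = 0.5) {
  sites <- list()
  for (t in store$templates) {
    for (s in t$sites) {
      if (length(s$keys) < 2) next
      sites[[length(sites) + 1]] <- list(
        template_id = t$id, het_code = s$het_code,
        sig = site_signature(s$keys, t$structure))
    }
  }
  if (length(sites) == 0) {
    warning("template store contains no usable binding sites")
    return(setNames(
      rep(list(data.frame(het_code = character(0),
                          template_id = character(0),
                          score = numeric(0))),
          length(pockets$pockets)),
      vapply(pockets$pockets, function(p) as.character(p$pocket_id), "")))
  }
  out <- lapply(pockets$pockets, function(p) {
    if (length(p$keys) < 2 || top_k == 0)
      return(data.frame(het_code = character(0),
                        template_id = character(0), score = numeric(0)))
    sig <- site_signature(p$keys, structure)
    scores <- data.frame(
      het_code = vapply(sites, function(s) s$het_code, ""),
      template_id = vapply(sites, function(s) s$template_id, ""),
      score = vapply(sites, function(s)
        site_similarity(sig, s$sig, tol), 0),
      stringsAsFactors = FALSE)
    scores <- scores[order(-scores$score, scores$het_code), ]
    best <- scores[!duplicated(scores$het_code), ]
    utils::head(best[order(-best$score, best$het_code), ],
                top_k)
  })
  setNames(out, vapply(pockets$pockets,
                       function(p) as.character(p$pocket_id), ""))
}
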