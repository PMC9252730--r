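.descriptor_names <- c(
  "rsa", "is_cysteine",
  paste0("atoms_", .atom_classes),
  paste0("inter_", .interaction_types))

#' Names of the 42 feature columns
#'
#' The fixed column order of the feature matrix: the 14 descriptors of
#' the central residue, then their first-shell means, then their
#' second-shell means.
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  c(.descriptor_names,
    paste0("shell1_mean_", .descriptor_names),
    paste0("shell2_mean_", .descriptor_names))
}

#' Residue contact graph
#'
#' Two residues are adjacent iff any pair of their heavy atoms lies
#' within `cutoff` Angstrom. Adjacency crosses chain boundaries, so
#' shells (and therefore predictions) see protein-protein interfaces.
#'
#' @param structure A `bsite_structure`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 6.0).
#' @return Symmetric logical adjacency matrix with residue keys as
#'   dimnames (diagonal `FALSE`).
#' @export
residue_contact_graph <- function(structure, cutoff = 6.0) {
  keys <- structure$residues$key
  ha <- heavy_atoms(structure)
  n <- length(keys)
  adj <- matrix(FALSE, n, n, dimnames = list(keys, keys))
  if (nrow(ha) >= 2) {
    xyz <- as.matrix(ha[, c("x", "y", "z")])
    pr <- grid_pairs(xyz, cutoff)
    if (nrow(pr)) {
      d2 <- rowSums((xyz[pr[, 1], , drop = FALSE] -
                       xyz[pr[, 2], , drop = FALSE])^2)
      hit <- d2 <= cutoff^2
      ri <- match(ha$key[pr[hit, 1]], keys)
      rj <- match(ha$key[pr[hit, 2]], keys)
      off <- ri != rj
      adj[cbind(ri[off], rj[off])] <- TRUE
      adj[cbind(rj[off], ri[off])] <- TRUE
    }
  }
  adj
}

#' First and second shell of a residue
#'
#' Shells are breadth-first levels of the contact graph: shell 1 is the
#' direct neighbors of the center; shell 2 the neighbors-of-neighbors
#' not already in shell 1 and not the center.
#'
#' @param adjacency Adjacency matrix from [residue_contact_graph()].
#' @param center Residue key.
#' @return List with `center`, `shell1`, `shell2` (character vectors).
#' @export
build_neighborhood <- function(adjacency, center) {
  keys <- rownames(adjacency)
  if (!center %in% keys) stop("unknown residue key: ", center)
  s1 <- keys[adjacency[center, ]]
  s2 <- character(0)
  if (length(s1)) {
    reach <- keys[colSums(adjacency[s1, , drop = FALSE]) > 0]
    s2 <- setdiff(reach, c(s1, center))
  }
  list(center = center, shell1 = s1, shell2 = s2)
}

# 14-descriptor matrix for every polymer residue (rows keyed).
descriptor_matrix <- function(structure, rsa_records, interactions) {
  keys <- structure$residues$key
  ha <- heavy_atoms(structure)
  fk <- factor(ha$key, levels = keys)
  D <- matrix(0, length(keys), length(.descriptor_names),
              dimnames = list(keys, .descriptor_names))
  D[, "rsa"] <- rsa_records$rsa[match(keys, rsa_records$key)]
  D[, "is_cysteine"] <- as.numeric(structure$residues$restype == "CYS")
  for (cl in .atom_classes)
    D[, paste0("atoms_", cl)] <-
      as.numeric(tapply(ha[[paste0("cls_", cl)]], fk, sum, default = 0))
  if (nrow(interactions)) {
    for (tp in .interaction_types) {
      sub <- interactions[interactions$itype == tp, ]
      cnt <- table(factor(c(sub$key_a, sub$key_b), levels = keys))
      D[, paste0("inter_", tp)] <- as.numeric(cnt)
    }
  }
  D
}

#' The 14 descriptors of a single residue
#'
#' Residue level: relative solvent accessibility and a cysteine
#' indicator. Atom level: how many of the residue's heavy atoms carry
#' each of the six classes (an atom with k classes increments k
#' counters). Interaction level: how many detected interactions of each
#' of the six types have at least one endpoint in the residue.
#'
#' @param structure A `bsite_structure` with classes assigned.
#' @param key Residue key.
#' @param rsa_records Output of [compute_rsa()].
#' @param interactions Output of [detect_interactions()].
#' @return Named numeric vector of length 14.
#' @export
compute_descriptors <- function(structure, key, rsa_records, interactions) {
  if (!key %in% structure$residues$key)
    stop("unknown residue key: ", key)
  if (!key %in% rsa_records$key)
    stop("residue absent from rsa records: ", key)
  descriptor_matrix(structure, rsa_records, interactions)[key, ]
}

#' Encode a structure as a 42-column feature matrix
#'
#' Runs atom typing, solvent accessibility, interaction detection and
#' the residue contact graph, then emits one row per polymer residue:
#' the residue's own 14 descriptors followed by the arithmetic mean of
#' its first-shell members' descriptors and of its second-shell
#' members' descriptors. Empty shells encode as zero blocks.
#'
#' @param structure A `bsite_structure`.
#' @param config A [bsite_config()] list (contact cutoff, SASA and
#'   interaction settings).
#' @return A data frame of class `bsite_features`: metadata columns
#'   (`key`, `structure_id`, `chain`, `resnum`, `icode`, `restype`)
#'   followed by the 42 feature columns of [feature_names()].
#' @export
featurize <- function(structure, config = bsite_config()) {
  if (nrow(structure$residues) == 0) stop("empty structure")
  structure <- assign_atom_classes(structure, config$atom_table)
  rsa <- compute_rsa(structure, config$probe_radius, config$sasa_points)
  ints <- detect_interactions(structure, config$interactions)
  adj <- residue_contact_graph(structure, config$contact_cutoff)
  D <- descriptor_matrix(structure, rsa, ints)

  A1 <- adj * 1
  deg1 <- rowSums(A1)
  S1 <- (A1 %*% D) / ifelse(deg1 > 0, deg1, 1)
  # second shell: reachable in two steps, not adjacent, not self
  A2 <- ((A1 %*% A1) > 0) & !adj
  diag(A2) <- FALSE
  A2 <- A2 * 1
  deg2 <- rowSums(A2)
  S2 <- (A2 %*% D) / ifelse(deg2 > 0, deg2, 1)

  M <- cbind(D, S1, S2)
  colnames(M) <- feature_names()
  res <- structure$residues
  out <- cbind(
    data.frame(key = res$key, structure_id = structure$structure_id,
               chain = res$chain, resnum = res$resno, icode = res$icode,
               restype = res$restype, stringsAsFactors = FALSE),
    as.data.frame(M, optional = TRUE))
  rownames(out) <- NULL
  class(out) <- c("bsite_features", "data.frame")
  out
}

feature_block <- function(features) {
  as.matrix(features[, feature_names(), drop = FALSE])
}

#' Write / read a feature matrix as CSV (training interchange format)
#'
#' Header: `structure_id,chain,resnum,icode,restype` then the 42 named
#' feature columns.
#'
#' @param features A `bsite_features` data frame.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_features()` returns the data frame
#'   with the `key` column reconstructed.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features[, c("structure_id", "chain", "resnum",
                                "icode", "restype", feature_names())],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(icode = "character",
                                       chain = "character"))
  df$icode[is.na(df$icode)] <- ""
  df$chain[is.na(df$chain)] <- ""
  df <- cbind(key = res_key(df$chain, df$resnum, df$icode), df,
              stringsAsFactors = FALSE)
  class(df) <- c("bsite_features", "data.frame")
  df
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its documented default.
#'
#' @param contact_cutoff Heavy-atom neighbor cutoff, Angstrom.
#' @param probe_radius,sasa_points Solvent-accessibility settings.
#' @param atom_table An [atom_class_table()].
#' @param interactions An [interaction_config()] data frame.
#' @param label_margin Margin added to the vdW-sum contact rule when
#'   labeling binding residues, Angstrom.
#' @param n_bags,trees_per_bag Ensemble shape.
#' @param threshold Decision threshold on the mean class probability.
#' @param min_identity,max_identity,max_templates Template selection
#'   window and cap.
#' @param eps,min_samples DBSCAN pocket clustering parameters.
#' @param sim_tol Distance tolerance of the site-similarity score,
#'   Angstrom.
#' @param top_k Ligand suggestions returned per pocket.
#' @param dca_threshold Pocket "hit" cutoff on DCA, Angstrom.
#' @param seed Top-level random seed; all randomness derives from it.
#' @return A named list of class `bsite_config`.
#' @export
bsite_config <- function(contact_cutoff = 6.0, probe_radius = 1.4,
                         sasa_points = 960,
                         atom_table = atom_class_table(),
                         interactions = interaction_config(),
                         label_margin = 0.5, n_bags = 10,
                         trees_per_bag = 100, threshold = 0.5,
                         min_identity = 0, max_identity = 0.95,
                         max_templates = 50, eps = 6.0,
                         min_samples = 3, sim_tol = 0.5, top_k = 5,
                         dca_threshold = 4.0, seed = 1) {
  structure(list(
    contact_cutoff = contact_cutoff, probe_radius = probe_radius,
    sasa_points = sasa_points, atom_table = atom_table,
    interactions = interactions, label_margin = label_margin,
    n_bags = n_bags, trees_per_bag = trees_per_bag,
    threshold = threshold, min_identity = min_identity,
    max_identity = max_identity, max_templates = max_templates,
    eps = eps, min_samples = min_samples, sim_tol = sim_tol,
    top_k = top_k, dca_threshold = dca_threshold, seed = seed),
    class = "bsite_config")
}

config_as_json <- function(config) {
  x <- unclass(config)
  x$atom_table <- x$atom_table$path
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
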