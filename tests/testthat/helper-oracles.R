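# Independent brute-force oracles. Each re-derives a quantity from
# first principles (plain all-pairs scans, BFS, reachability closure,
# exhaustive matching) without touching the production code paths.

# all-pairs interaction scan: full distance matrix, explicit per-pair
# per-type checks
oracle_interactions <- function(structure, config = interaction_config()) {
  if (!has_classes_oracle(structure))
    structure <- assign_atom_classes(structure)
  a <- structure$atoms
  a <- a[!a$het & !(a$element %in% c("H", "D")), ]
  n <- nrow(a)
  res <- structure$residues
  pos <- match(a$key, res$key)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (a$key[i] == a$key[j]) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      bb <- c("N", "CA", "C", "O", "OXT")
      if (a$chain[i] == a$chain[j] && abs(pos[i] - pos[j]) == 1 &&
          a$name[i] %in% bb && a$name[j] %in% bb) next
      for (tp in config$type) {
        w <- config[config$type == tp, ]
        if (d < w$d_min || d > w$d_max) next
        ok <- switch(tp,
          hydrogen_bond = (a$cls_donor[i] && a$cls_acceptor[j]) ||
            (a$cls_acceptor[i] && a$cls_donor[j]),
          salt_bridge = (a$cls_positive[i] && a$cls_negative[j]) ||
            (a$cls_negative[i] && a$cls_positive[j]),
          repulsive = (a$cls_positive[i] && a$cls_positive[j]) ||
            (a$cls_negative[i] && a$cls_negative[j]),
          hydrophobic = a$cls_hydrophobic[i] && a$cls_hydrophobic[j],
          aromatic_stacking = a$cls_aromatic[i] && a$cls_aromatic[j],
          disulfide_bridge = a$restype[i] == "CYS" &&
            a$name[i] == "SG" && a$restype[j] == "CYS" &&
            a$name[j] == "SG")
        if (ok)
          out[[length(out) + 1]] <- data.frame(
            itype = tp, key_a = a$key[i], key_b = a$key[j],
            atom_a = a$name[i], atom_b = a$name[j], distance = d,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(itype = character(0), key_a = character(0),
                      key_b = character(0), atom_a = character(0),
                      atom_b = character(0), distance = numeric(0)))
  do.call(rbind, out)
}

has_classes_oracle <- function(structure) {
  "cls_donor" %in% colnames(structure$atoms)
}

# canonical multiset representation of an interaction table (unordered
# atom pairs within each type)
interaction_multiset <- function(df) {
  if (nrow(df) == 0) return(character(0))
  pa <- paste(df$key_a, df$atom_a)
  pb <- paste(df$key_b, df$atom_b)
  sort(paste(df$itype, pmin(pa, pb), pmax(pa, pb),
             round(df$distance, 6)))
}

# BFS levels 1 and 2 by explicit frontier expansion
oracle_shells <- function(adjacency, center) {
  keys <- rownames(adjacency)
  level <- setNames(rep(NA_integer_, length(keys)), keys)
  level[center] <- 0L
  frontier <- center
  depth <- 0L
  while (length(frontier) && depth < 2L) {
    depth <- depth + 1L
    nxt <- character(0)
    for (f in frontier)
      nxt <- union(nxt, keys[adjacency[f, ]])
    nxt <- nxt[is.na(level[nxt])]
    level[nxt] <- depth
    frontier <- nxt
  }
  list(shell1 = sort(names(level)[!is.na(level) & level == 1L]),
       shell2 = sort(names(level)[!is.na(level) & level == 2L]))
}

# residue adjacency by a plain double loop over residues
oracle_contact_graph <- function(structure, cutoff = 6.0) {
  keys <- structure$residues$key
  a <- structure$atoms
  a <- a[!a$het & !(a$element %in% c("H", "D")), ]
  n <- length(keys)
  adj <- matrix(FALSE, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1)) {
    xi <- as.matrix(a[a$key == keys[i], c("x", "y", "z")])
    for (j in (i + 1):n) {
      xj <- as.matrix(a[a$key == keys[j], c("x", "y", "z")])
      dmin <- sqrt(min(outer(rowSums(xi^2), rowSums(xj^2), `+`) -
                         2 * xi %*% t(xj)))
      if (dmin <= cutoff) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

# brute-force DBSCAN: core points, then transitive closure of
# eps-reachability among cores; border points take the cluster of the
# first core (in index order) within eps
oracle_dbscan <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(coords))
  core <- rowSums(d <= eps) >= min_samples
  reach <- d <= eps & outer(core, core, `&`)
  diag(reach) <- core
  # transitive closure over core points
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    comp <- which(reach[i, ] & core)
    labels[comp] <- cl
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    near_core <- which(core & d[i, ] <= eps)
    if (length(near_core)) labels[i] <- labels[near_core[1]]
  }
  labels
}

# cluster labelings are equal up to renaming of cluster ids
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a != 0L
  length(unique(paste(a[ok], b[ok]))) ==
    length(unique(a[ok])) &&
    length(unique(paste(a[ok], b[ok]))) == length(unique(b[ok]))
}

# exhaustive optimal one-to-one matching within tol between two small
# vectors (recursion over the first list)
oracle_match_count <- function(a, b, tol) {
  if (!length(a) || !length(b)) return(0L)
  best <- oracle_match_count(a[-1], b, tol)  # skip a[1]
  for (j in seq_along(b)) {
    if (abs(a[1] - b[j]) <= tol) {
      cand <- 1L + oracle_match_count(a[-1], b[-j], tol)
      if (cand > best) best <- cand
    }
  }
  best
}

# rigid rotation helper (fixed axis-angle), applied to every atom
rotate_structure <- function(structure, angle = 0.7,
                             axis = c(1, 2, 3), shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, shift, `+`)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
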