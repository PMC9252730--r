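.atom_classes <- c("aromatic", "acceptor", "donor", "hydrophobic",
                   "positive", "negative")
.interaction_types <- c("aromatic_stacking", "disulfide_bridge",
                        "hydrogen_bond", "hydrophobic", "repulsive",
                        "salt_bridge")

#' Load an atom physicochemical typing table
#'
#' The shipped default covers backbone and side-chain heavy atoms of
#' the 20 standard amino acids; `res = "*"` rows apply to every residue
#' type unless overridden by a residue-specific row.
#'
#' @param path Path to a typing table (tab-separated: res, atom,
#'   comma-separated classes); default is the packaged table.
#' @return An object of class `atom_class_table` (lookup environment).
#' @export
atom_class_table <- function(path = pkg_extdata("atom_classes.tsv")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  tab$classes[is.na(tab$classes)] <- ""
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tab))) {
    cls <- strsplit(tab$classes[i], ",", fixed = TRUE)[[1]]
    cls <- trimws(cls[nzchar(trimws(cls))])
    bad <- setdiff(cls, .atom_classes)
    if (length(bad)) stop("unknown atom class in table: ", bad[1])
    assign(paste(toupper(tab$res[i]), toupper(tab$atom[i]), sep = "|"),
           cls, envir = env)
  }
  structure(list(env = env, path = path), class = "atom_class_table")
}

lookup_classes <- function(table, restype, atom_name) {
  k1 <- paste(toupper(restype), toupper(atom_name), sep = "|")
  if (exists(k1, envir = table$env, inherits = FALSE))
    return(get(k1, envir = table$env))
  k2 <- paste("*", toupper(atom_name), sep = "|")
  if (exists(k2, envir = table$env, inherits = FALSE))
    return(get(k2, envir = table$env))
  NULL
}

#' Assign physicochemical classes to every heavy protein atom
#'
#' Adds six logical columns (`cls_aromatic` ... `cls_negative`) to the
#' structure's atom table. Unknown (residue type, atom name) pairs get
#' the empty class set and are tallied in the `unknown_atoms` attribute
#' of the returned structure. Hydrogens and ligand atoms are left
#' untyped.
#'
#' @param structure A `bsite_structure`.
#' @param table An [atom_class_table()].
#' @return The structure with class columns populated.
#' @export
assign_atom_classes <- function(structure, table = atom_class_table()) {
  a <- structure$atoms
  flags <- matrix(FALSE, nrow(a), length(.atom_classes),
                  dimnames = list(NULL, paste0("cls_", .atom_classes)))
  unknown <- character(0)
  typed <- !a$het & !(a$element %in% c("H", "D"))
  for (i in which(typed)) {
    cls <- lookup_classes(table, a$restype[i], a$name[i])
    if (is.null(cls)) {
      unknown <- c(unknown, paste(a$restype[i], a$name[i]))
    } else if (length(cls)) {
      flags[i, paste0("cls_", cls)] <- TRUE
    }
  }
  structure$atoms <- cbind(a, as.data.frame(flags))
  attr(structure, "unknown_atoms") <- table(unknown)
  structure
}

has_classes <- function(structure) {
  all(paste0("cls_", .atom_classes) %in% colnames(structure$atoms))
}

# Deterministic near-uniform points on the unit sphere (golden-spiral
# lattice) used by the Shrake-Rupley sampler.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Maximum accessible surface area table
#'
#' @param path Optional alternative table path.
#' @return Named numeric vector (Angstrom^2) by 3-letter residue code.
#' @export
max_asa_table <- function(path = pkg_extdata("max_asa.tsv")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  setNames(tab$max_asa, toupper(tab$res))
}

#' Per-residue solvent accessibility (Shrake-Rupley)
#'
#' Computes solvent-accessible surface area over heavy atoms by sphere
#' sampling with standard van der Waals radii, sums it per residue, and
#' normalizes by a theoretical maximum-ASA table to give relative
#' solvent accessibility clamped to \[0, 1\].
#'
#' @param structure A `bsite_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Data frame with columns `key`, `sasa`, `max_asa`, `rsa`, one
#'   row per polymer residue in structure order.
#' @export
compute_rsa <- function(structure, probe_radius = 1.4, n_points = 960) {
  ha <- heavy_atoms(structure)
  xyz <- as.matrix(ha[, c("x", "y", "z")])
  r <- vdw_of(ha$element) + probe_radius
  n <- nrow(ha)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  if (n > 0) {
    # neighbor candidates: atoms whose expanded spheres can intersect
    d2 <- as.matrix(stats::dist(xyz))^2
    for (i in seq_len(n)) {
      nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
      p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
      if (length(nb)) {
        acc <- rep(TRUE, n_points)
        for (j in nb) {
          dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
          acc <- acc & dj > r[j]^2
          if (!any(acc)) break
        }
        frac <- sum(acc) / n_points
      } else frac <- 1
      area[i] <- frac * 4 * pi * r[i]^2
    }
  }
  sasa <- tapply(area, factor(ha$key, levels = structure$residues$key),
                 sum, default = 0)
  maxasa <- max_asa_table()
  mx <- maxasa[structure$residues$restype]
  mx[is.na(mx)] <- stats::median(maxasa)  # non-standard residues
  data.frame(key = structure$residues$key, sasa = as.numeric(sasa),
             max_asa = as.numeric(mx),
             rsa = pmin(1, as.numeric(sasa) / as.numeric(mx)),
             stringsAsFactors = FALSE)
}

#' Default interaction distance windows
#'
#' @param path Optional alternative config path (tab-separated: type,
#'   d_min, d_max).
#' @return Data frame with one row per interaction type.
#' @export
interaction_config <- function(path = pkg_extdata("interaction_defaults.tsv")) {
  cfg <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  missing_t <- setdiff(.interaction_types, cfg$type)
  if (length(missing_t))
    stop("interaction config lacks type(s): ",
         paste(missing_t, collapse = ", "))
  if (any(!(cfg$d_min >= 0 & cfg$d_min < cfg$d_max)))
    stop("interaction config requires 0 <= d_min < d_max")
  cfg[match(.interaction_types, cfg$type), , drop = FALSE]
}

# Candidate atom pairs within `cutoff` via a uniform cell grid; returns
# a 2-column index matrix (i < j). Complexity ~linear in atoms for
# globular structures.
grid_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  id <- paste(cell[, 1], cell[, 2], cell[, 3])
  cells <- split(seq_len(n), id)
  coords <- do.call(rbind, strsplit(names(cells), " "))
  storage.mode(coords) <- "integer"
  keymap <- new.env(parent = emptyenv())
  for (k in seq_along(cells)) assign(names(cells)[k], k, envir = keymap)
  out <- vector("list", length(cells) * 14)
  np <- 0L
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  # half-space of offsets so each cell pair is visited once
  offsets <- offsets[offsets[, 1] > 0 |
                       (offsets[, 1] == 0 & offsets[, 2] > 0) |
                       (offsets[, 1] == 0 & offsets[, 2] == 0 &
                          offsets[, 3] >= 0), , drop = FALSE]
  for (k in seq_along(cells)) {
    ik <- cells[[k]]
    for (o in seq_len(nrow(offsets))) {
      tgt <- coords[k, ] + offsets[o, ]
      tk <- paste(tgt[1], tgt[2], tgt[3])
      if (!exists(tk, envir = keymap, inherits = FALSE)) next
      m <- get(tk, envir = keymap)
      im <- cells[[m]]
      if (m == k) {
        if (length(ik) > 1) {
          pr <- t(utils::combn(ik, 2))
          np <- np + 1L; out[[np]] <- pr
        }
      } else {
        pr <- cbind(rep(ik, each = length(im)), rep(im, length(ik)))
        np <- np + 1L; out[[np]] <- pr
      }
    }
  }
  if (np == 0) return(matrix(integer(0), ncol = 2))
  pr <- do.call(rbind, out[seq_len(np)])
  cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
}

#' Detect non-covalent interactions
#'
#' Emits one interaction per atom pair and type whose atom-class
#' requirement and distance window are both satisfied: hydrogen bonds
#' (donor x acceptor), salt bridges (positive x negative), repulsive
#' contacts (like charges), hydrophobic contacts, aromatic stacking
#' (atom-atom between aromatic atoms) and disulfide bridges (CYS SG
#' pairs). Atoms must belong to different residues; pairs where both
#' atoms are backbone atoms (N, CA, C, O, OXT) of sequence-adjacent
#' residues on the same chain are excluded as covalent neighborhood. A
#' single atom pair may yield several interaction types.
#'
#' @param structure A `bsite_structure` with classes assigned (see
#'   [assign_atom_classes()]; called automatically if absent).
#' @param config An [interaction_config()] data frame.
#' @return Data frame: `itype`, `key_a`, `key_b`, `atom_a`, `atom_b`,
#'   `distance`.
#' @export
detect_interactions <- function(structure, config = interaction_config()) {
  if (!has_classes(structure)) structure <- assign_atom_classes(structure)
  ha <- heavy_atoms(structure)
  empty <- data.frame(itype = character(0), key_a = character(0),
                      key_b = character(0), atom_a = character(0),
                      atom_b = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(ha) < 2) return(empty)
  xyz <- as.matrix(ha[, c("x", "y", "z")])
  pr <- grid_pairs(xyz, max(config$d_max))
  if (nrow(pr) == 0) return(empty)
  i <- pr[, 1]; j <- pr[, 2]
  keep <- ha$key[i] != ha$key[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty)
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))

  # covalent neighborhood: both backbone, sequence-adjacent, same chain
  bb <- c("N", "CA", "C", "O", "OXT")
  pos <- match(ha$key, structure$residues$key)  # file-order index
  res <- structure$residues
  adjacent <- ha$chain[i] == ha$chain[j] &
    abs(pos[i] - pos[j]) == 1 &
    res$chain[pos[i]] == res$chain[pos[j]]
  both_bb <- ha$name[i] %in% bb & ha$name[j] %in% bb
  keep <- !(adjacent & both_bb)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  if (!length(i)) return(empty)

  cls <- function(nm) ha[[paste0("cls_", nm)]]
  pair_ok <- list(
    aromatic_stacking = cls("aromatic")[i] & cls("aromatic")[j],
    disulfide_bridge = ha$restype[i] == "CYS" & ha$name[i] == "SG" &
      ha$restype[j] == "CYS" & ha$name[j] == "SG",
    hydrogen_bond = (cls("donor")[i] & cls("acceptor")[j]) |
      (cls("acceptor")[i] & cls("donor")[j]),
    hydrophobic = cls("hydrophobic")[i] & cls("hydrophobic")[j],
    repulsive = (cls("positive")[i] & cls("positive")[j]) |
      (cls("negative")[i] & cls("negative")[j]),
    salt_bridge = (cls("positive")[i] & cls("negative")[j]) |
      (cls("negative")[i] & cls("positive")[j]))

  out <- lapply(.interaction_types, function(tp) {
    w <- config[config$type == tp, ]
    hit <- which(pair_ok[[tp]] & d >= w$d_min & d <= w$d_max)
    if (!length(hit)) return(NULL)
    data.frame(itype = tp, key_a = ha$key[i[hit]], key_b = ha$key[j[hit]],
               atom_a = ha$name[i[hit]], atom_b = ha$name[j[hit]],
               distance = d[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out[order(out$itype, out$key_a, out$key_b, out$atom_a, out$atom_b), ,
      drop = FALSE]
}
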