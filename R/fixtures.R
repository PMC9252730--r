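# Pseudo side-chain heavy-atom templates: every name appears in the
# shipped typing table, so atom-class coverage on fixtures is complete.
.side_templates <- list(
  ALA = "CB", GLY = character(0), SER = c("CB", "OG"),
  THR = c("CB", "OG1"), VAL = c("CB", "CG1"),
  LEU = c("CB", "CG", "CD1"), ILE = c("CB", "CG1", "CD1"),
  MET = c("CB", "CG", "SD"), PRO = c("CB", "CG"),
  PHE = c("CB", "CG", "CZ"), TYR = c("CB", "CG", "OH"),
  TRP = c("CB", "CG", "NE1"), CYS = c("CB", "SG"),
  ASN = c("CB", "OD1", "ND2"), GLN = c("CB", "OE1", "NE2"),
  ASP = c("CB", "OD1", "OD2"), GLU = c("CB", "OE1", "OE2"),
  LYS = c("CB", "CD", "NZ"), ARG = c("CB", "NH1", "NH2"),
  HIS = c("CB", "ND1", "NE2"))

# Background composition: hydrophobic/small-polar residues only, so a
# charged/polar planted site is the distinguishing signal.
.background_weights <- c(
  ALA = 0.18, LEU = 0.14, VAL = 0.12, GLY = 0.10, ILE = 0.08,
  SER = 0.10, THR = 0.08, PHE = 0.06, MET = 0.05, PRO = 0.05,
  ASN = 0.02, GLN = 0.02)

.site_alphabet <- c("ASP", "GLU", "LYS", "ARG", "HIS")

#' Specification of a synthetic fixture structure
#'
#' @param n_residues Residues per chain.
#' @param fold `"helix"` (ideal alpha-helix spiral), `"lattice"`
#'   (cubic grid) or `"coil"` (random walk).
#' @param n_chains 1 or 2 chains (chain B is a translated copy
#'   geometry, independently sampled sequence).
#' @param composition Named residue-type weights for background
#'   positions.
#' @param ligand `NULL` for an apo structure, or a list with `targets`
#'   (global residue indices that must be exactly the binding
#'   residues), `contact_distance` (Angstrom, informative), and
#'   `het_code` (default `"LG1"`).
#' @param site_types Residue types planted at target positions (drawn
#'   from the charged/polar site alphabet by default).
#' @param chain_sep Translation between the two chains in Angstrom.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 30, fold = c("helix", "lattice",
                                                   "coil"),
                         n_chains = 1,
                         composition = .background_weights,
                         ligand = NULL, site_types = .site_alphabet,
                         chain_sep = 10, seed = 1) {
  fold <- match.arg(fold)
  if (!is.null(ligand)) {
    if (is.null(ligand$het_code)) ligand$het_code <- "LG1"
    if (is.null(ligand$contact_distance)) ligand$contact_distance <- 3.0
    if (is.null(ligand$targets)) stop("ligand spec requires targets")
  }
  base::structure(list(
    n_residues = n_residues, fold = fold, n_chains = n_chains,
    composition = composition, ligand = ligand,
    site_types = site_types, chain_sep = chain_sep, seed = seed),
    class = "fixture_spec")
}

pdb_atom_line <- function(record, serial, name, restype, chain, resno,
                          x, y, z, occ = 1, b = 0, element = "") {
  nm <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else
    name
  # wwPDB v3.3 fixed columns: name 13-16, altLoc 17, resName 18-20,
  # chain 22, resSeq 23-26, iCode 27, x from 31, element 77-78
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, restype, chain, resno, x, y, z, occ, b,
          element)
}

# backbone + side-chain coordinates for one residue, local frame given
# by outward unit u, tangent t_hat, axis z_hat
place_residue <- function(ca, u, t_hat, z_hat, restype, jitter) {
  atoms <- list(
    N = ca - 1.2 * t_hat + 0.3 * z_hat,
    CA = ca,
    C = ca + 1.2 * t_hat,
    O = ca + 1.2 * t_hat + 1.2 * z_hat)
  side <- .side_templates[[restype]]
  for (k in seq_along(side)) {
    off <- (1.5 + 0.9 * (k - 1)) * u +
      ((-1)^k * 0.5 * (k > 1)) * t_hat + jitter[k, ]
    atoms[[side[k]]] <- ca + off
  }
  atoms
}

#' Generate a synthetic PDB structure with known ground truth
#'
#' Places residues on an ideal geometry (helix, lattice or coil) with
#' realistic backbone atom names plus 1-3 pseudo side-chain heavy
#' atoms whose names trigger the shipped typing table. When a ligand
#' is requested, a small HET group is positioned so that the residues
#' in contact (vdW-sum + margin rule) are exactly the requested
#' targets; target positions receive charged/polar residue types from
#' the site alphabet. Generation is deterministic given the seed;
#' infeasible target sets raise an error.
#'
#' @param spec A [fixture_spec()].
#' @param structure_id Identifier written into the manifest.
#' @return List with `pdb` (a single PDB-format string), `structure`
#'   (the parsed `bsite_structure`) and `manifest` (ground-truth
#'   labels, adjacency at 6 Angstrom computed by direct scan, ligand
#'   record, per-residue table, spec echo).
#' @export
generate_structure <- function(spec, structure_id = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  chains <- LETTERS[seq_len(spec$n_chains)]

  restypes <- character(0)
  for (ch in chains)
    restypes <- c(restypes, sample(names(spec$composition), n,
                                   replace = TRUE,
                                   prob = spec$composition))
  targets <- spec$ligand$targets
  if (!is.null(targets)) {
    if (any(targets < 1 | targets > n * spec$n_chains))
      stop("ligand targets out of range")
    restypes[targets] <- sample(spec$site_types, length(targets),
                                replace = TRUE)
  }

  # geometry
  ntot <- n * spec$n_chains
  ca <- matrix(0, ntot, 3)
  uu <- matrix(0, ntot, 3)
  tt <- matrix(0, ntot, 3)
  zz <- matrix(rep(c(0, 0, 1), each = ntot), ntot, 3)
  for (c_i in seq_len(spec$n_chains)) {
    off <- c((c_i - 1) * spec$chain_sep, 0, 0)
    idx <- (c_i - 1) * n + seq_len(n)
    if (spec$fold == "helix") {
      th <- (seq_len(n) - 1) * 100 * pi / 180
      r <- 2.3
      # chain B winds opposite so its side chains can face chain A
      sgn <- if (c_i == 1) 1 else -1
      ca[idx, ] <- cbind(sgn * r * cos(th), r * sin(th),
                         1.5 * seq_len(n)) + rep(off, each = n)
      uu[idx, ] <- cbind(sgn * cos(th), sin(th), 0)
      tt[idx, ] <- cbind(-sgn * sin(th), cos(th), 0)
    } else if (spec$fold == "lattice") {
      side <- ceiling(n^(1 / 3))
      g <- as.matrix(expand.grid(seq_len(side), seq_len(side),
                                 seq_len(side)))[seq_len(n), ]
      ca[idx, ] <- g * 5.0 + rep(off, each = n)
      dirs <- matrix(stats::rnorm(3 * n), n, 3)
      uu[idx, ] <- dirs / sqrt(rowSums(dirs^2))
      tt[idx, ] <- cbind(-uu[idx, 2], uu[idx, 1], 0)
      nt <- sqrt(rowSums(tt[idx, , drop = FALSE]^2))
      tt[idx, ] <- tt[idx, , drop = FALSE] / ifelse(nt > 0, nt, 1)
    } else { # coil: self-avoiding-ish random walk, 3.8 A steps
      pos <- matrix(0, n, 3)
      for (i in 2:n) {
        repeat {
          step <- stats::rnorm(3)
          step <- 3.8 * step / sqrt(sum(step^2))
          cand <- pos[i - 1, ] + step
          if (i < 3 || min(sqrt(rowSums(sweep(pos[seq_len(i - 2), ,
                                                  drop = FALSE], 2,
                                              cand)^2))) > 4.0) break
        }
        pos[i, ] <- cand
      }
      ca[idx, ] <- pos + rep(off, each = n)
      dirs <- matrix(stats::rnorm(3 * n), n, 3)
      uu[idx, ] <- dirs / sqrt(rowSums(dirs^2))
      tt[idx, ] <- cbind(-uu[idx, 2], uu[idx, 1], 0)
      nt <- sqrt(rowSums(tt[idx, , drop = FALSE]^2))
      tt[idx, ] <- tt[idx, , drop = FALSE] / ifelse(nt > 0, nt, 1)
    }
  }
  # per-residue atom lists
  res_atoms <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    side_n <- length(.side_templates[[restypes[i]]])
    jitter <- matrix(stats::rnorm(3 * max(side_n, 1), sd = 0.05),
                     ncol = 3)
    res_atoms[[i]] <- place_residue(ca[i, ], uu[i, ], tt[i, ], zz[i, ],
                                    restypes[i], jitter)
  }

  chain_of <- rep(chains, each = n)
  resno_of <- rep(seq_len(n), spec$n_chains)

  # ligand placement: scan along the outward direction from the target
  # side-chain tips until the vdW-contact rule labels exactly the
  # requested targets
  lig <- NULL
  if (!is.null(targets)) {
    tips <- t(vapply(targets, function(i) {
      a <- res_atoms[[i]]
      a[[length(a)]]
    }, numeric(3)))
    center0 <- colMeans(tips)
    centroid <- colMeans(ca)
    out_dir <- center0 - centroid
    nrm <- sqrt(sum(out_dir^2))
    out_dir <- if (nrm > 1e-6) out_dir / nrm else c(0, 0, 1)
    lig_offsets <- rbind(c(0, 0, 0), c(1.1, 0.4, 0), c(-0.8, 0.8, 0.4),
                         c(0, -0.9, 0.8))
    lig_elements <- c("C", "O", "N", "C")
    lig_names <- c("C1", "O1", "N1", "C2")
    found <- FALSE
    for (d in as.vector(rbind(seq(0, 8, by = 0.25),
                              -seq(0, 8, by = 0.25)))) {
      cen <- center0 + d * out_dir
      lxyz <- sweep(lig_offsets, 2, cen, `+`)
      labs <- contact_targets(res_atoms, restypes, lxyz, lig_elements)
      if (setequal(labs, targets)) {
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("fixture generation error: infeasible ligand placement ",
           "for targets ", paste(targets, collapse = ","))
    lig <- list(het_code = spec$ligand$het_code, chain = chains[1],
                resno = 900, xyz = lxyz, names = lig_names,
                elements = lig_elements)
  }

  # emit PDB text
  lines <- character(0)
  serial <- 0L
  truth <- integer(ntot)
  if (!is.null(targets)) truth[targets] <- 1L
  for (i in seq_len(ntot)) {
    for (nm in names(res_atoms[[i]])) {
      serial <- serial + 1L
      p <- res_atoms[[i]][[nm]]
      el <- infer_element(nm)
      lines <- c(lines, pdb_atom_line("ATOM", serial, nm, restypes[i],
                                      chain_of[i], resno_of[i],
                                      p[1], p[2], p[3], element = el))
    }
  }
  if (!is.null(lig)) {
    for (m in seq_len(nrow(lig$xyz))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("HETATM", serial, lig$names[m],
                                      lig$het_code, lig$chain,
                                      lig$resno, lig$xyz[m, 1],
                                      lig$xyz[m, 2], lig$xyz[m, 3],
                                      element = lig$elements[m]))
    }
  }
  lines <- c(lines, "END")
  pdb_text <- paste(lines, collapse = "\n")

  keys <- res_key(chain_of, resno_of, "")
  # adjacency ground truth by direct double loop at 6 A
  edges <- list()
  for (i in seq_len(ntot - 1)) {
    xi <- do.call(rbind, res_atoms[[i]])
    for (j in (i + 1):ntot) {
      xj <- do.call(rbind, res_atoms[[j]])
      dmin <- sqrt(min(outer(rowSums(xi^2), rowSums(xj^2), `+`) -
                         2 * xi %*% t(xj)))
      if (dmin <= 6.0)
        edges[[length(edges) + 1]] <- c(keys[i], keys[j])
    }
  }
  adjacency <- if (length(edges))
    do.call(rbind, edges) else matrix(character(0), ncol = 2)

  st <- parse_pdb(pdb_text, structure_id = structure_id)
  manifest <- list(
    structure_id = structure_id,
    residues = data.frame(key = keys, restype = restypes,
                          chain = chain_of, resno = resno_of,
                          stringsAsFactors = FALSE),
    labels = setNames(truth, keys),
    adjacency = adjacency,
    ligand = lig,
    spec = spec)
  list(pdb = pdb_text, structure = st, manifest = manifest)
}

# generator-side contact rule (independent double loop): which residue
# indices have a heavy atom within vdW sum + 0.5 A of a ligand atom
contact_targets <- function(res_atoms, restypes, lxyz, lig_elements,
                            margin = 0.5) {
  radii <- vdw_radii()
  lr <- vdw_of(lig_elements, radii)
  hit <- integer(0)
  for (i in seq_along(res_atoms)) {
    a <- res_atoms[[i]]
    for (nm in names(a)) {
      ra <- vdw_of(infer_element(nm), radii)
      d <- sqrt(colSums((t(lxyz) - a[[nm]])^2))
      if (any(d <= ra + lr + margin)) {
        hit <- c(hit, i)
        break
      }
    }
  }
  hit
}

#' Generate an on-disk template store of bound synthetic structures
#'
#' Each template is a helix fixture with a planted ligand-binding
#' patch (targets on one helix face), written in the store layout read
#' by [read_template_store()]: `structure.pdb`, `ligands.tsv`,
#' `labels.csv`, `sequence.fasta` per template plus a store
#' `manifest.json`.
#'
#' @param n_templates Number of templates (>= 1).
#' @param dir Output directory (created).
#' @param n_residues Residues per template.
#' @param seed Top-level seed; template t uses `seed * 1000 + t`.
#' @param het_codes HET codes cycled over templates (fake alphabet
#'   LG1..LG9, never colliding with the exclusion list).
#' @return The store directory path, invisibly.
#' @export
generate_template_store <- function(n_templates, dir, n_residues = 30,
                                    seed = 1,
                                    het_codes = paste0("LG", 1:9)) {
  stopifnot(n_templates >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("T%03d", seq_len(n_templates))
  for (t in seq_len(n_templates)) {
    fix <- generate_bound_fixture(n_residues = n_residues,
                                  seed = seed * 1000 + t,
                                  het_code =
                                    het_codes[(t - 1) %% length(het_codes) + 1],
                                  structure_id = ids[t])
    tdir <- file.path(dir, ids[t])
    dir.create(tdir, showWarnings = FALSE)
    writeLines(fix$pdb, file.path(tdir, "structure.pdb"))
    st <- fix$structure
    utils::write.table(
      data.frame(het_code = st$ligands$het_code, chain = st$ligands$chain,
                 resno = st$ligands$resno),
      file.path(tdir, "ligands.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    mres <- fix$manifest$residues
    utils::write.csv(
      data.frame(chain = mres$chain, resnum = mres$resno, icode = "",
                 restype = mres$restype,
                 label = unname(fix$manifest$labels)),
      file.path(tdir, "labels.csv"), row.names = FALSE, quote = FALSE)
    writeLines(c(paste0(">", ids[t]),
                 extract_sequence(st)),
               file.path(tdir, "sequence.fasta"))
  }
  jsonlite::write_json(list(templates = ids, seed = seed,
                            n_residues = n_residues),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' One bound helix fixture with a feasible planted site
#'
#' Convenience wrapper around [generate_structure()]: picks a helix
#' anchor deterministically (scanning until ligand placement is
#' feasible) and plants targets on one helix face (anchor + 0, 3, 4).
#'
#' @param n_residues Residues in the helix.
#' @param seed Seed for the underlying spec.
#' @param het_code Ligand HET code.
#' @param structure_id Structure identifier.
#' @return As [generate_structure()].
#' @export
generate_bound_fixture <- function(n_residues = 30, seed = 1,
                                   het_code = "LG1",
                                   structure_id = "fixture") {
  set.seed(seed)
  anchors <- sample(seq(5, n_residues - 5))
  for (a in anchors) {
    spec <- fixture_spec(n_residues = n_residues,
                         ligand = list(targets = a + c(0, 3, 4),
                                       het_code = het_code),
                         seed = seed)
    fix <- tryCatch(generate_structure(spec, structure_id),
                    error = function(e) NULL)
    if (!is.null(fix)) return(fix)
  }
  stop("could not place a feasible ligand site for seed ", seed)
}

#' Synthetic separable feature matrix
#'
#' Standard-normal noise on all 42 feature columns; positive rows are
#' shifted by `shift` standard deviations on 5 known signal columns.
#' Used to verify that training recovers a separable signal and that
#' the importance ranking finds the planted columns.
#'
#' @param n_pos,n_neg Class sizes.
#' @param signal_cols The planted columns (default: a fixed set of 5).
#' @param shift Shift in SD units (default 3).
#' @param seed Seed.
#' @return List with `x` (matrix), `y` (0/1), `signal_cols`.
#' @export
generate_separable_features <- function(n_pos = 30, n_neg = 300,
                                        signal_cols = c(
                                          "rsa", "atoms_positive",
                                          "atoms_negative",
                                          "inter_salt_bridge",
                                          "shell1_mean_rsa"),
                                        shift = 3, seed = 1) {
  set.seed(seed)
  cols <- feature_names()
  stopifnot(all(signal_cols %in% cols))
  n <- n_pos + n_neg
  x <- matrix(stats::rnorm(n * length(cols)), n, length(cols),
              dimnames = list(NULL, cols))
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  x[y == 1, signal_cols] <- x[y == 1, signal_cols] + shift
  list(x = x, y = y, signal_cols = signal_cols)
}
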