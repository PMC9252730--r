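#' @importFrom stats setNames
NULL

# Residue key: "chain|resno|icode" — the opaque identifier used for all
# internal indexing (residue numbering, insertion codes included, is
# preserved verbatim from the input file).
res_key <- function(chain, resno, icode) {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = "|")
}

# Non-standard polymer residues recorded as HETATM in real files.
.polymer_het <- c("MSE", "SEC", "PYL", "SEP", "TPO", "PTR")

.three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

pkg_extdata <- function(name) {
  path <- system.file("extdata", name, package = "resibind")
  if (!nzchar(path)) stop("missing packaged data file: ", name)
  path
}

#' Default ligand exclusion list
#'
#' HET codes (water, cryo-protectants, buffers, counter-ions) that are
#' never treated as ligands when parsing a structure. Read from the
#' editable file shipped in `inst/extdata/ligand_exclude.txt`.
#'
#' @param path Optional path to an alternative exclusion file (one HET
#'   code per line, `#` comments allowed).
#' @return Character vector of excluded HET codes.
#' @export
ligand_exclusion_list <- function(path = pkg_extdata("ligand_exclude.txt")) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  toupper(x[nzchar(x)])
}

#' Van der Waals radii table
#'
#' @param path Optional path to an alternative radii file.
#' @return Named numeric vector of radii in Angstrom by element symbol,
#'   with a `default` entry for unlisted elements.
#' @export
vdw_radii <- function(path = pkg_extdata("vdw_radii.tsv")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$radius, toupper(tab$element))
}

vdw_of <- function(elements, radii = vdw_radii()) {
  r <- radii[toupper(elements)]
  r[is.na(r)] <- radii[["DEFAULT"]]
  unname(r)
}

infer_element <- function(name) {
  # PDB atom names lead with the element; strip digits/primes and take
  # letters. Two-letter elements in protein/ligand context are rare and
  # left to the explicit element column when present.
  el <- gsub("[^A-Za-z]", "", name)
  toupper(substr(el, 1, 1))
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into a residue/atom/ligand data model.
#' Only the first MODEL of a multi-model file is used. Alternate
#' locations are resolved to the highest-occupancy conformer (ties
#' broken by altloc letter order). HETATM groups become ligands after
#' filtering against the exclusion list; water never survives the
#' filter. Hydrogens are retained in the atom table but ignored by all
#' descriptor computations.
#'
#' @param source Path to a PDB file, or a character scalar/vector of
#'   PDB-format text.
#' @param structure_id Identifier for the structure; defaults to the
#'   file base name (or `"structure"` for text input).
#' @param exclude Character vector of HET codes to drop from the ligand
#'   list (default [ligand_exclusion_list()]).
#' @return An object of class `bsite_structure`: a list with
#'   `structure_id`, an `atoms` data frame (serial, name, element,
#'   chain, resno, icode, restype, x, y, z, occ, het, key), a
#'   `residues` data frame (polymer residues in file order), a
#'   `ligands` data frame and `chain_ids`.
#' @export
parse_pdb <- function(source, structure_id = NULL,
                      exclude = ligand_exclusion_list()) {
  is_text <- length(source) > 1 ||
    (is.character(source) && grepl("\n", source)) ||
    (is.character(source) && !file.exists(source) &&
       grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|TER|END)", source))
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(source) > 1) source else
      strsplit(source, "\n", fixed = TRUE)[[1]], path)
    if (is.null(structure_id)) structure_id <- "structure"
  } else {
    if (!file.exists(source)) stop("cannot read PDB source: ", source)
    path <- source
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(source))
  }

  pdb <- tryCatch(
    suppressWarnings(suppressMessages(
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))),
    error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  at <- pdb$atom

  # multi=FALSE can still leave later-model rows in $atom for some NMR
  # layouts; keep rows up to the first repeat of an (ATOM) serial.
  if (anyDuplicated(paste(at$type, at$eleno))) {
    first_dup <- which(duplicated(paste(at$type, at$eleno)))[1]
    at <- at[seq_len(first_dup - 1L), , drop = FALSE]
  }

  chain <- ifelse(is.na(at$chain), "", at$chain)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  elesy <- ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                  infer_element(at$elety), toupper(trimws(at$elesy)))

  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elesy,
    chain = chain, resno = at$resno, icode = icode,
    restype = toupper(trimws(at$resid)),
    x = at$x, y = at$y, z = at$z, occ = occ, alt = alt,
    record = at$type, stringsAsFactors = FALSE)

  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("PDB parse error: non-finite coordinates")

  # altloc resolution: within (chain, resno, icode, name), keep the
  # highest-occupancy row; ties broken by altloc letter order.
  gid <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$restype,
               atoms$name, sep = "\r")
  ord <- order(gid, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(gid[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$serial, at$eleno)), , drop = FALSE]

  is_poly <- atoms$record == "ATOM" | atoms$restype %in% .polymer_het
  atoms$het <- !is_poly
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)

  poly <- atoms[is_poly, , drop = FALSE]
  if (nrow(poly) == 0)
    stop("empty structure: no polymer ATOM records in ", structure_id)

  ridx <- !duplicated(poly$key)
  residues <- data.frame(
    key = poly$key[ridx], chain = poly$chain[ridx],
    resno = poly$resno[ridx], icode = poly$icode[ridx],
    restype = poly$restype[ridx], stringsAsFactors = FALSE)

  hets <- atoms[!is_poly, , drop = FALSE]
  hets <- hets[!(hets$restype %in% toupper(exclude)), , drop = FALSE]
  atoms <- atoms[is_poly | (paste(atoms$key, atoms$restype) %in%
                              paste(hets$key, hets$restype)), , drop = FALSE]
  lidx <- !duplicated(hets$key)
  ligands <- data.frame(
    key = hets$key[lidx], het_code = hets$restype[lidx],
    chain = hets$chain[lidx], resno = hets$resno[lidx],
    n_atoms = as.integer(table(hets$key)[hets$key[lidx]]),
    stringsAsFactors = FALSE)

  structure(list(
    structure_id = structure_id, atoms = atoms, residues = residues,
    ligands = ligands, chain_ids = unique(residues$chain)),
    class = "bsite_structure")
}

#' @export
print.bsite_structure <- function(x, ...) {
  cat("<bsite_structure> ", x$structure_id, "\n", sep = "")
  cat("  residues: ", nrow(x$residues), " in ", length(x$chain_ids),
      " chain(s) [", paste(x$chain_ids, collapse = ","), "]\n", sep = "")
  cat("  atoms:    ", nrow(x$atoms), "\n", sep = "")
  if (nrow(x$ligands))
    cat("  ligands:  ", paste(x$ligands$het_code, collapse = ", "), "\n",
        sep = "")
  else cat("  ligands:  none\n")
  invisible(x)
}

# Heavy (non-hydrogen) polymer atoms.
heavy_atoms <- function(structure) {
  a <- structure$atoms
  a[!a$het & !(a$element %in% c("H", "D")), , drop = FALSE]
}

ligand_atoms <- function(structure, ligand_key) {
  a <- structure$atoms
  out <- a[a$het & a$key == ligand_key &
             !(a$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(out) == 0) stop("ligand has no atoms: ", ligand_key)
  out
}

# Representative coordinate per polymer residue: CA if present, else
# the heavy-atom centroid. Returns a matrix with residue keys as rows.
representative_coords <- function(structure, keys = structure$residues$key) {
  ha <- heavy_atoms(structure)
  out <- matrix(NA_real_, nrow = length(keys), ncol = 3,
                dimnames = list(keys, c("x", "y", "z")))
  for (i in seq_along(keys)) {
    sub <- ha[ha$key == keys[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    ca <- sub[sub$name == "CA", , drop = FALSE]
    out[i, ] <- if (nrow(ca)) unlist(ca[1, c("x", "y", "z")]) else
      colMeans(sub[, c("x", "y", "z")])
  }
  out
}

#' Extract the amino-acid sequence of a structure
#'
#' @param structure A `bsite_structure`.
#' @param chain_id A chain identifier, or `"all"` (default) for the
#'   concatenation of every chain in file order.
#' @param mse_as_met Map selenomethionine (MSE) to `M` instead of the
#'   default `X` used for all non-standard residues.
#' @return A one-letter character scalar; for `chain_id = "all"` the
#'   attribute `chains` holds the per-chain lengths so chain boundaries
#'   are recoverable.
#' @export
extract_sequence <- function(structure, chain_id = "all",
                             mse_as_met = FALSE) {
  res <- structure$residues
  map <- .three_to_one
  if (mse_as_met) map <- c(map, MSE = "M")
  if (identical(chain_id, "all")) {
    letters1 <- map[res$restype]
    letters1[is.na(letters1)] <- "X"
    seqs <- vapply(split(letters1, factor(res$chain,
                                          levels = structure$chain_ids)),
                   paste, collapse = "", FUN.VALUE = "")
    out <- paste(seqs, collapse = "")
    attr(out, "chains") <- setNames(nchar(seqs), names(seqs))
    return(out)
  }
  if (!chain_id %in% structure$chain_ids)
    stop("unknown chain: ", chain_id)
  letters1 <- map[res$restype[res$chain == chain_id]]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Write a structure (optionally with per-residue confidences) as PDB
#'
#' @param structure A `bsite_structure`.
#' @param out Output file path.
#' @param bfactor Optional named numeric vector (by residue key) written
#'   into the temperature-factor column of every atom of that residue;
#'   unnamed residues get 0.
#' @return `out`, invisibly.
#' @export
write_pdb <- function(structure, out, bfactor = NULL) {
  a <- structure$atoms
  b <- rep(0, nrow(a))
  if (!is.null(bfactor)) {
    b <- ifelse(!a$het & a$key %in% names(bfactor),
                round(unname(bfactor[a$key]), 2), 0)
  }
  bio3d::write.pdb(
    pdb = NULL, file = out,
    type = ifelse(a$het, "HETATM", "ATOM"),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$restype, eleno = a$serial,
    elety = a$name, chain = ifelse(nzchar(a$chain), a$chain, " "),
    insert = ifelse(nzchar(a$icode), a$icode, ""),
    o = a$occ, b = b, elesy = a$element)
  invisible(out)
}

#' Write per-residue binding predictions
#'
#' CSV output has one row per predicted residue with columns
#' `structure_id,chain,resnum,icode,restype,predicted,confidence`; PDB
#' output is the input structure with each residue's confidence times
#' 100 (rounded to 2 decimals) in the temperature-factor column.
#'
#' @param structure A `bsite_structure`.
#' @param predictions A data frame with columns `key`, `predicted`
#'   (0/1) and `confidence` (as returned by [predict.bsite_model()]).
#' @param out Output path.
#' @param format `"csv"` or `"pdb"`.
#' @return `out`, invisibly.
#' @export
write_predictions <- function(structure, predictions, out,
                              format = c("csv", "pdb")) {
  format <- match.arg(format)
  bad <- setdiff(predictions$key, structure$residues$key)
  if (length(bad))
    stop("prediction refers to residue(s) absent from structure: ",
         paste(bad, collapse = ", "))
  if (format == "csv") {
    res <- structure$residues
    m <- match(predictions$key, res$key)
    df <- data.frame(
      structure_id = rep(structure$structure_id, nrow(predictions)),
      chain = res$chain[m], resnum = res$resno[m], icode = res$icode[m],
      restype = res$restype[m],
      predicted = as.integer(predictions$predicted),
      confidence = predictions$confidence, stringsAsFactors = FALSE)
    utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
  } else {
    conf <- setNames(predictions$confidence * 100, predictions$key)
    write_pdb(structure, out, bfactor = conf)
  }
  invisible(out)
}

#' Read a predictions CSV written by [write_predictions()]
#'
#' @param path CSV path.
#' @return Data frame with a reconstructed `key` column plus
#'   `predicted` and `confidence`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(icode = "character",
                                       chain = "character"))
  df$icode[is.na(df$icode)] <- ""
  df$chain[is.na(df$chain)] <- ""
  df$key <- res_key(df$chain, df$resnum, df$icode)
  df
}
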