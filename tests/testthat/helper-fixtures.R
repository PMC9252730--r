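# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from disk except what the tests
# themselves write.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 30-residue bound helix fixture (query of the recovery experiments)
query_fixture <- function() {
  cached("query_fixture", function()
    generate_bound_fixture(n_residues = 30, seed = 42,
                           structure_id = "query"))
}

# small template store (10 templates) for fast pipeline tests
small_store <- function() {
  cached("small_store", function() {
    dir <- file.path(tempdir(), "resibind_store10")
    if (!dir.exists(dir)) generate_template_store(10, dir, seed = 3)
    read_template_store(dir)
  })
}

# 20-template store for the parameter-recovery experiment
recovery_store <- function() {
  cached("recovery_store", function() {
    dir <- file.path(tempdir(), "resibind_store20")
    if (!dir.exists(dir)) generate_template_store(20, dir, seed = 11)
    read_template_store(dir)
  })
}

# apo 25-residue helix used by structural round-trip tests
apo_fixture <- function() {
  cached("apo_fixture", function()
    generate_structure(fixture_spec(n_residues = 25, seed = 7),
                       structure_id = "apo25"))
}

# hand-written minimal PDB texts
pdb_single_gly <- function() {
  paste(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "END", sep = "\n")
}

pdb_three_res <- function() {
  # ALA-GLY-CYS backbone stubs, one atom each is enough for sequence
  paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  CYS A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
}

# tiny two-residue structure with atoms at controlled distances; used
# for targeted interaction checks. atom_spec: data.frame with name,
# restype, resno, x, y, z
pdb_from_spec <- function(atom_spec, het = NULL) {
  lines <- character(0)
  for (i in seq_len(nrow(atom_spec))) {
    r <- atom_spec[i, ]
    nm <- r$name
    nm <- if (nchar(nm) < 4) paste0(" ", formatC(nm, width = -3)) else nm
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (!is.null(r$record)) r$record else "ATOM",
      i, nm, r$restype, "A", r$resno, r$x, r$y, r$z, 1, 0,
      gsub("[^A-Za-z]", "", substr(r$name, 1, 1))))
  }
  paste(c(lines, "END"), collapse = "\n")
}

res_key_test <- function(chain, resno, icode) {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  chain <- ifelse(is.na(chain), "", chain)
  paste(chain, resno, icode, sep = "|")
}

.atom_classes_test <- function() {
  c("aromatic", "acceptor", "donor", "hydrophobic", "positive",
    "negative")
}

lookup_classes_test <- function(tbl, restype, name) {
  env <- tbl$env
  k1 <- paste(restype, name, sep = "|")
  if (exists(k1, envir = env, inherits = FALSE)) return(get(k1, env))
  k2 <- paste("*", name, sep = "|")
  if (exists(k2, envir = env, inherits = FALSE)) return(get(k2, env))
  NULL
}

# restrict a structure to one chain (atoms, residues, ligands)
subset_structure_test <- function(st, chain) {
  st$atoms <- st$atoms[st$atoms$chain == chain, ]
  st$residues <- st$residues[st$residues$chain == chain, ]
  st$ligands <- st$ligands[st$ligands$chain == chain, ]
  st$chain_ids <- chain
  st
}
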