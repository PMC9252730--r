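#' Read a template store from disk
#'
#' A store directory holds `manifest.json` (field `templates`: ids) and
#' one subdirectory per template containing `structure.pdb`,
#' `ligands.tsv` (het_code, chain, resno), `labels.csv`
#' (chain,resnum,icode,restype,label) and `sequence.fasta`. Per-ligand
#' binding-site records (residue key sets) are derived at load time
#' with the vdW-contact rule so they stay consistent with the labels.
#'
#' @param path Store directory.
#' @param margin Contact margin for deriving per-ligand sites.
#' @return An object of class `bsite_store`: list with `path` and
#'   `templates` (each: `id`, `structure`, `labels`, `sequence`,
#'   `ligands`, `sites`).
#' @export
read_template_store <- function(path, margin = 0.5) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("not a template store (no manifest): ",
                                  path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  templates <- lapply(manifest$templates, function(id) {
    dir <- file.path(path, id)
    st <- parse_pdb(file.path(dir, "structure.pdb"), structure_id = id)
    lab <- utils::read.csv(file.path(dir, "labels.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(icode = "character",
                                          chain = "character"))
    lab$icode[is.na(lab$icode)] <- ""
    lab$chain[is.na(lab$chain)] <- ""
    labels <- setNames(as.integer(lab$label),
                       res_key(lab$chain, lab$resnum, lab$icode))
    seq <- read_fasta_seq(file.path(dir, "sequence.fasta"))
    ligs <- utils::read.delim(file.path(dir, "ligands.tsv"),
                              stringsAsFactors = FALSE)
    sites <- lapply(seq_len(nrow(st$ligands)), function(i) {
      lk <- st$ligands$key[i]
      site_labels <- label_binding_residues(st, lk, margin)
      list(het_code = st$ligands$het_code[i], ligand_key = lk,
           keys = names(site_labels)[site_labels == 1])
    })
    list(id = id, structure = st, labels = labels, sequence = seq,
         ligands = ligs, sites = sites)
  })
  base::structure(list(path = path, templates = templates),
                  class = "bsite_store")
}

#' @export
print.bsite_store <- function(x, ...) {
  cat("<bsite_store> ", length(x$templates), " template(s) at ",
      x$path, "\n", sep = "")
  invisible(x)
}

read_fasta_seq <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  paste(as.character(x), collapse = "")
}

#' End-to-end binding-site prediction for a query structure
#'
#' Runs the full pipeline: extract the query sequence, select templates
#' from the store by sequence identity, featurize the selected
#' templates and train a balanced extra-trees ensemble on their labeled
#' residues, featurize the query and predict per-residue binding labels
#' with confidences, cluster the predicted residues into pockets, and
#' rank candidate ligands per pocket by site similarity.
#'
#' @param query A `bsite_structure` or a PDB path.
#' @param store A `bsite_store` or a store directory path.
#' @param config A [bsite_config()].
#' @param cluster Set `FALSE` to skip pocket clustering and ligand
#'   suggestion.
#' @return List of class `bsite_result`: `predictions`, `pockets`,
#'   `suggestions`, `importance`, `model`, `templates_used`, `config`.
#' @export
predict_binding_sites <- function(query, store,
                                  config = bsite_config(),
                                  cluster = TRUE) {
  if (is.character(query)) query <- parse_pdb(query)
  if (is.character(store))
    store <- read_template_store(store, margin = config$label_margin)
  qseq <- extract_sequence(query)
  sel <- select_templates(qseq, store, config$min_identity,
                          config$max_identity, config$max_templates)

  feats <- lapply(sel$templates, function(t) featurize(t$structure,
                                                       config))
  labels <- lapply(sel$templates, function(t) {
    f <- feats[[match(t$id, vapply(sel$templates, `[[`, "", "id"))]]
    lab <- t$labels[f$key]
    if (anyNA(lab)) stop("template labels do not cover residues: ", t$id)
    lab
  })
  X <- do.call(rbind, lapply(feats, feature_block))
  y <- unlist(labels, use.names = FALSE)
  model <- bsite_fit(X, y, n_bags = config$n_bags,
                     trees_per_bag = config$trees_per_bag,
                     seed = config$seed, threshold = config$threshold)

  qf <- featurize(query, config)
  preds <- predict(model, qf)

  pockets <- NULL
  suggestions <- NULL
  if (cluster) {
    pockets <- cluster_predictions(preds, query, config$eps,
                                   config$min_samples)
    suggestions <- suggest_ligands(pockets, query, sel,
                                   top_k = config$top_k,
                                   tol = config$sim_tol)
  }
  base::structure(list(
    predictions = preds, pockets = pockets, suggestions = suggestions,
    importance = feature_importance(model), model = model,
    templates_used = vapply(sel$templates, `[[`, "", "id"),
    identities = vapply(sel$templates, `[[`, 0, "identity"),
    structure_id = query$structure_id, config = config),
    class = "bsite_result")
}

#' @export
print.bsite_result <- function(x, ...) {
  np <- sum(x$predictions$predicted)
  cat("<bsite_result> ", x$structure_id, "\n", sep = "")
  cat("  templates used: ", length(x$templates_used),
      "  (identity ", sprintf("%.2f", min(x$identities)), "-",
      sprintf("%.2f", max(x$identities)), ")\n", sep = "")
  cat("  predicted binding residues: ", np, " / ",
      nrow(x$predictions), "\n", sep = "")
  if (!is.null(x$pockets)) print(x$pockets)
  if (!is.null(x$suggestions) && length(x$suggestions)) {
    for (pid in names(x$suggestions)) {
      s <- x$suggestions[[pid]]
      if (nrow(s))
        cat("  pocket ", pid, " ligands: ",
            paste(sprintf("%s (%.2f)", s$het_code, s$score),
                  collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}
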