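make_preds <- function(st, pos_keys) {
  data.frame(key = st$residues$key,
             confidence = as.numeric(st$residues$key %in% pos_keys),
             predicted = as.integer(st$residues$key %in% pos_keys))
}

test_that("DBSCAN clustering handles canonical cases", {
  # two groups of 5 residues, 3 A spacing within, 40 A apart
  spec <- data.frame(
    name = rep("CA", 10), restype = rep("ALA", 10), resno = 1:10,
    x = c(seq(0, 12, by = 3), seq(40, 52, by = 3)), y = 0, z = 0)
  st <- parse_pdb(pdb_from_spec(spec))
  pk <- cluster_predictions(make_preds(st, st$residues$key), st,
                            eps = 6, min_samples = 3)
  expect_length(pk$pockets, 2)
  expect_setequal(vapply(pk$pockets, function(p) p$n, 0L), c(5L, 5L))
  expect_length(pk$noise, 0)

  # no positives -> no pockets
  pk0 <- cluster_predictions(make_preds(st, character(0)), st)
  expect_length(pk0$pockets, 0)

  # 2 isolated positives below min_samples -> all noise
  pk2 <- cluster_predictions(make_preds(st, st$residues$key[c(1, 10)]),
                             st, eps = 6, min_samples = 3)
  expect_length(pk2$pockets, 0)
  expect_length(pk2$noise, 2)
})

test_that("DBSCAN equals brute-force density reachability", {
  for (s in 1:4) {
    set.seed(s)
    pts <- matrix(stats::runif(3 * 60, 0, 30), ncol = 3)
    got <- dbscan_points(pts, eps = 5, min_samples = 3)
    want <- oracle_dbscan(pts, eps = 5, min_samples = 3)
    # core-point clusters must agree as partitions
    d <- as.matrix(stats::dist(pts))
    core <- rowSums(d <= 5) >= 3
    expect_true(same_partition(got[core], want[core]))
    # noise sets identical; border points may differ only in id
    expect_identical(got == 0L, want == 0L)
  }
})

test_that("clusters merge (never split) as eps grows", {
  set.seed(7)
  pts <- matrix(stats::runif(3 * 50, 0, 25), ncol = 3)
  l1 <- dbscan_points(pts, eps = 4, min_samples = 3)
  l2 <- dbscan_points(pts, eps = 6, min_samples = 3)
  for (cl in unique(l1[l1 > 0])) {
    members <- which(l1 == cl)
    expect_length(unique(l2[members]), 1)  # contained in one cluster
    expect_true(all(l2[members] > 0))
  }
})

test_that("pocket centers are means with rigid equivariance", {
  spec <- data.frame(name = rep("CA", 2), restype = rep("ALA", 2),
                     resno = 1:2, x = c(0, 2), y = 0, z = 0)
  st <- parse_pdb(pdb_from_spec(spec))
  expect_equal(unname(pocket_center(st$residues$key, st)), c(1, 0, 0))
  expect_equal(unname(pocket_center(st$residues$key[1], st)),
               c(0, 0, 0))
  expect_error(pocket_center(character(0), st), "empty")

  st_shift <- st
  st_shift$atoms$x <- st$atoms$x + 5
  st_shift$atoms$y <- st$atoms$y - 2
  expect_equal(unname(pocket_center(st$residues$key, st_shift)),
               c(6, -2, 0))
})

test_that("site signatures count pairs and ignore rigid motion", {
  st <- query_fixture()$structure
  keys <- st$residues$key[1:6]
  sig <- site_signature(keys, st)
  expect_equal(sum(lengths(sig)), choose(6, 2))
  expect_error(site_signature(keys[1], st), ">= 2 residues")

  sig_rot <- site_signature(keys, rotate_structure(st))
  expect_equal(sig_rot, sig, tolerance = 1e-9)

  # all-same-category set: one list with C(3,2) distances
  spec <- data.frame(name = rep("CA", 3), restype = rep("ALA", 3),
                     resno = 1:3, x = c(0, 4, 9), y = 0, z = 0)
  st3 <- parse_pdb(pdb_from_spec(spec))
  sig3 <- site_signature(st3$residues$key, st3)
  expect_length(sig3, 1)
  expect_length(sig3[[1]], 3)
})

test_that("site similarity is a symmetric score with known extremes", {
  st <- query_fixture()$structure
  keys <- st$residues$key[5:10]
  sig <- site_signature(keys, st)
  expect_equal(site_similarity(sig, sig), 1.0)

  other <- site_signature(st$residues$key[15:20], st)
  expect_equal(site_similarity(sig, other),
               site_similarity(other, sig))

  # category-disjoint signatures share no lists
  a <- base::structure(list("hydrophobic:hydrophobic" = c(1, 2, 3)),
                       class = "site_signature")
  b <- base::structure(list("negative:positive" = c(1, 2, 3)),
                       class = "site_signature")
  expect_equal(site_similarity(a, b), 0.0)
})

test_that("greedy sorted matching equals exhaustive optimal matching", {
  set.seed(11)
  for (rep in 1:25) {
    a <- sort(stats::runif(sample(1:8, 1), 0, 10))
    b <- sort(stats::runif(sample(1:8, 1), 0, 10))
    tol <- stats::runif(1, 0.1, 2)
    got <- resibind:::match_sorted(a, b, tol)
    expect_identical(got, oracle_match_count(a, b, tol),
                     info = paste("rep", rep))
  }
})

test_that("ligand suggestion ranks a self-matching template first", {
  store <- small_store()
  st <- query_fixture()$structure
  labels <- label_binding_residues(st)
  pos <- names(labels)[labels == 1]
  preds <- make_preds(st, pos)
  pockets <- cluster_predictions(preds, st, min_samples = 2)
  expect_gte(length(pockets$pockets), 1)

  # a store whose only template is the query itself: its ligand must
  # rank first with score 1
  self_store <- list(path = "", templates = list(list(
    id = "self", structure = st, sequence = extract_sequence(st),
    labels = labels,
    sites = list(list(het_code = "LG1",
                      ligand_key = st$ligands$key[1],
                      keys = pos)))))
  class(self_store) <- "bsite_store"
  sug <- suggest_ligands(pockets, st, self_store)
  expect_equal(sug[["1"]]$het_code[1], "LG1")
  expect_equal(sug[["1"]]$score[1], 1.0)

  # top_k = 0 -> empty
  sug0 <- suggest_ligands(pockets, st, store, top_k = 0)
  expect_equal(nrow(sug0[["1"]]), 0)

  # planted-similarity: jittering site coordinates by <= 0.2 A keeps a
  # near-1 score and outranks unrelated random-geometry templates
  # (coil folds, so site distance sets are not congruent with the
  # helix pocket)
  jit <- st
  set.seed(5)
  jit$atoms$x <- jit$atoms$x + stats::runif(nrow(jit$atoms), -0.1, 0.1)
  jit$atoms$y <- jit$atoms$y + stats::runif(nrow(jit$atoms), -0.1, 0.1)
  jit$atoms$z <- jit$atoms$z + stats::runif(nrow(jit$atoms), -0.1, 0.1)
  jit_store <- self_store
  jit_store$templates[[1]]$structure <- jit
  jit_store$templates[[1]]$sites[[1]]$het_code <- "LG9"
  random_templates <- lapply(1:5, function(s) {
    coil <- generate_structure(fixture_spec(n_residues = 12,
                                            fold = "coil",
                                            seed = 100 + s))$structure
    set.seed(200 + s)
    list(id = paste0("R", s), structure = coil,
         sequence = extract_sequence(coil),
         labels = setNames(integer(12), coil$residues$key),
         sites = list(list(het_code = paste0("LG", s + 1),
                           ligand_key = NA,
                           keys = sample(coil$residues$key, 4))))
  })
  both <- self_store
  both$templates <- c(random_templates, jit_store$templates)
  sug2 <- suggest_ligands(pockets, st, both)
  expect_equal(sug2[["1"]]$het_code[1], "LG9")
  expect_gt(sug2[["1"]]$score[1], 0.9)
  expect_gt(sug2[["1"]]$score[1], max(sug2[["1"]]$score[-1]))
})
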