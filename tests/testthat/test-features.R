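test_that("contact graph matches its definition at the cutoff boundary", {
  spec <- data.frame(name = c("CA", "CA"), restype = c("ALA", "ALA"),
                     resno = c(1, 2), x = c(0, 5.9), y = 0, z = 0)
  st <- parse_pdb(pdb_from_spec(spec))
  expect_true(residue_contact_graph(st, cutoff = 6.0)[1, 2])
  expect_false(residue_contact_graph(st, cutoff = 5.5)[1, 2])
})

test_that("contact graph equals the brute-force residue-pair scan", {
  fix <- cached("coil50", function()
    generate_structure(fixture_spec(n_residues = 50, fold = "coil",
                                    seed = 21)))
  st <- fix$structure
  expect_identical(residue_contact_graph(st), oracle_contact_graph(st))
})

test_that("shells are BFS levels 1 and 2 of the contact graph", {
  # linear chain A-B-C-D of contacts
  spec <- data.frame(name = rep("CA", 4), restype = rep("ALA", 4),
                     resno = 1:4, x = c(0, 5, 10, 15), y = 0, z = 0)
  st <- parse_pdb(pdb_from_spec(spec))
  adj <- residue_contact_graph(st)
  nb <- build_neighborhood(adj, "A|1|")
  expect_setequal(nb$shell1, "A|2|")
  expect_setequal(nb$shell2, "A|3|")
  expect_error(build_neighborhood(adj, "A|99|"), "unknown residue")

  # isolated residue
  iso <- parse_pdb(pdb_single_gly())
  nb0 <- build_neighborhood(residue_contact_graph(iso), "A|1|")
  expect_length(nb0$shell1, 0)
  expect_length(nb0$shell2, 0)

  # random geometric graphs: shells equal an independent BFS
  for (s in c(3, 8)) {
    fix <- generate_structure(fixture_spec(n_residues = 25,
                                           fold = "coil", seed = s))
    adj <- residue_contact_graph(fix$structure)
    for (k in rownames(adj)[c(1, 10, 25)]) {
      got <- build_neighborhood(adj, k)
      want <- oracle_shells(adj, k)
      expect_setequal(got$shell1, want$shell1)
      expect_setequal(got$shell2, want$shell2)
      expect_false(k %in% c(got$shell1, got$shell2))
      expect_length(intersect(got$shell1, got$shell2), 0)
    }
  }
})

test_that("descriptors tally atoms and interactions as defined", {
  iso <- parse_pdb(pdb_single_gly())
  iso <- assign_atom_classes(iso)
  rsa <- compute_rsa(iso)
  ints <- detect_interactions(iso)
  d <- compute_descriptors(iso, "A|1|", rsa, ints)
  expect_length(d, 14)
  expect_true(all(d[paste0("inter_", c("aromatic_stacking",
                                       "disulfide_bridge",
                                       "hydrogen_bond", "hydrophobic",
                                       "repulsive", "salt_bridge"))] == 0))
  expect_error(compute_descriptors(iso, "A|1|", rsa[0, ], ints),
               "absent from rsa")

  # ASP side chain contributes >= 2 acceptor and >= 2 negative counts
  spec <- data.frame(
    name = c("CA", "OD1", "OD2"), restype = rep("ASP", 3), resno = 1,
    x = c(0, 1.5, 2.2), y = c(0, 0.5, -0.5), z = 0)
  st <- assign_atom_classes(parse_pdb(pdb_from_spec(spec)))
  d2 <- compute_descriptors(st, "A|1|", compute_rsa(st),
                            detect_interactions(st))
  expect_gte(d2[["atoms_acceptor"]], 2)
  expect_gte(d2[["atoms_negative"]], 2)
  expect_equal(d2[["is_cysteine"]], 0)

  # one salt bridge is counted at both endpoint residues
  spec3 <- data.frame(
    name = c("NZ", "OD1"), restype = c("LYS", "ASP"), resno = c(1, 2),
    x = c(0, 4.5), y = 0, z = 0)
  st3 <- assign_atom_classes(parse_pdb(pdb_from_spec(spec3)))
  ints3 <- detect_interactions(st3)
  expect_equal(sum(ints3$itype == "salt_bridge"), 1)
  rsa3 <- compute_rsa(st3)
  expect_equal(compute_descriptors(st3, "A|1|", rsa3,
                                   ints3)[["inter_salt_bridge"]], 1)
  expect_equal(compute_descriptors(st3, "A|2|", rsa3,
                                   ints3)[["inter_salt_bridge"]], 1)
})

test_that("featurize emits 42 columns in three 14-descriptor blocks", {
  f <- cached("query_features", function()
    featurize(query_fixture()$structure))
  fn <- feature_names()
  expect_length(fn, 42)
  expect_true(all(fn %in% colnames(f)))
  expect_identical(fn[15:28], paste0("shell1_mean_", fn[1:14]))
  expect_identical(fn[29:42], paste0("shell2_mean_", fn[1:14]))
  expect_equal(nrow(f), 30)
  expect_true(all(is.finite(as.matrix(f[, fn]))))
})

test_that("single-residue structures have all-zero shell blocks", {
  f <- featurize(parse_pdb(pdb_single_gly()))
  expect_true(all(f[, feature_names()[15:42]] == 0))
  expect_error(featurize(structure(list(residues = data.frame()),
                                   class = "bsite_structure")),
               "empty")
})

test_that("a single-member shell mean equals that member's descriptors", {
  # path A-B-C: B is A's only shell-1 member, C its only shell-2 member
  spec <- data.frame(name = rep("CA", 3), restype = rep("ALA", 3),
                     resno = 1:3, x = c(0, 5, 10), y = 0, z = 0)
  st <- parse_pdb(pdb_from_spec(spec))
  f <- featurize(st)
  fn <- feature_names()
  central <- as.numeric(f[2, fn[1:14]])     # B's own block
  shell1_of_A <- as.numeric(f[1, fn[15:28]])
  expect_equal(shell1_of_A, central)
  central_C <- as.numeric(f[3, fn[1:14]])
  expect_equal(as.numeric(f[1, fn[29:42]]), central_C)
})

test_that("shell means stay inside the members' elementwise envelope", {
  st <- query_fixture()$structure
  f <- cached("query_features", function() featurize(st))
  st_cls <- assign_atom_classes(st)
  rsa <- compute_rsa(st_cls)
  ints <- detect_interactions(st_cls)
  D <- resibind:::descriptor_matrix(st_cls, rsa, ints)
  adj <- residue_contact_graph(st)
  fn <- feature_names()
  for (i in c(1, 15, 30)) {
    k <- st$residues$key[i]
    s1 <- rownames(adj)[adj[k, ]]
    if (!length(s1)) next
    mn <- apply(D[s1, , drop = FALSE], 2, min)
    mx <- apply(D[s1, , drop = FALSE], 2, max)
    got <- as.numeric(f[i, fn[15:28]])
    expect_true(all(got >= mn - 1e-9 & got <= mx + 1e-9))
  }
})

test_that("feature vectors are invariant under rigid motion", {
  st <- query_fixture()$structure
  f1 <- cached("query_features", function() featurize(st))
  f2 <- featurize(rotate_structure(st))
  fn <- feature_names()
  # counts are exactly invariant; rsa only up to sphere-sampling noise
  count_cols <- setdiff(fn, grep("rsa", fn, value = TRUE))
  expect_equal(as.matrix(f2[, count_cols]), as.matrix(f1[, count_cols]))
  expect_lt(max(abs(as.matrix(f2[, grep("rsa", fn, value = TRUE)]) -
                      as.matrix(f1[, grep("rsa", fn, value = TRUE)]))),
            0.02)
})

test_that("chain order permutation permutes rows but not values", {
  fix <- cached("twochain", function()
    generate_structure(fixture_spec(n_residues = 10, n_chains = 2,
                                    seed = 17)))
  st <- fix$structure
  a <- st$atoms
  swapped <- st
  swapped$atoms <- a[order(match(a$chain, c("B", "A")),
                           match(seq_len(nrow(a)), seq_len(nrow(a)))), ]
  swapped$residues <- st$residues[order(match(st$residues$chain,
                                              c("B", "A"))), ]
  swapped$chain_ids <- c("B", "A")
  f1 <- featurize(st)
  f2 <- featurize(swapped)
  fn <- feature_names()
  m <- match(f1$key, f2$key)
  expect_false(identical(f1$key, f2$key))
  expect_equal(as.matrix(f2[m, fn]), as.matrix(f1[, fn]),
               ignore_attr = TRUE)
})

test_that("per-chain featurization matches whole-structure only without interface", {
  # two chains far apart: identical features chainwise
  fix_far <- generate_structure(fixture_spec(n_residues = 8,
                                             n_chains = 2,
                                             chain_sep = 60, seed = 19))
  st <- fix_far$structure
  f_all <- featurize(st)
  sub <- subset_structure_test(st, "A")
  f_a <- featurize(sub)
  fn <- feature_names()
  expect_equal(as.matrix(f_all[f_all$chain == "A", fn]),
               as.matrix(f_a[, fn]), ignore_attr = TRUE)

  # two chains in contact: the interface must change some feature
  fix_near <- cached("twochain", function()
    generate_structure(fixture_spec(n_residues = 10, n_chains = 2,
                                    seed = 17)))
  stn <- fix_near$structure
  adj <- residue_contact_graph(stn)
  keys_a <- stn$residues$key[stn$residues$chain == "A"]
  keys_b <- stn$residues$key[stn$residues$chain == "B"]
  expect_true(any(adj[keys_a, keys_b]))  # interface exists
  f_alln <- featurize(stn)
  f_an <- featurize(subset_structure_test(stn, "A"))
  expect_false(isTRUE(all.equal(
    as.matrix(f_alln[f_alln$chain == "A", fn]),
    as.matrix(f_an[, fn]), check.attributes = FALSE)))
})

test_that("feature CSV export/import round-trips", {
  f <- cached("query_features", function()
    featurize(query_fixture()$structure))
  path <- tempfile(fileext = ".csv")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(back$key, f$key)
  expect_equal(as.matrix(back[, feature_names()]),
               as.matrix(f[, feature_names()]), tolerance = 1e-12)
})
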