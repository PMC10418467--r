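test_that("subgraph enumeration matches exhaustive counts", {
  butane <- parse_smiles("CCCC")
  expect_length(enumerate_subgraphs(butane, 2, "path"), 2)
  isobutane <- parse_smiles("CC(C)C")
  expect_length(enumerate_subgraphs(isobutane, 3, "cluster"), 1)
  benzene <- parse_smiles("C1=CC=CC=C1")
  expect_length(enumerate_subgraphs(benzene, 2, "path"), 6)
  # order 0 = atoms
  expect_length(enumerate_subgraphs(butane, 0, "path"), 4)
  # invalid combinations error
  expect_error(enumerate_subgraphs(butane, 2, "cluster"), "undefined")
  expect_error(enumerate_subgraphs(butane, 3, "path-cluster"), "undefined")
})

test_that("chi indices reproduce hand-computed values", {
  expect_equal(chi_index(parse_smiles("CCCC"), 1, "path"),
               1 / sqrt(2) + 1 / 2 + 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(chi_index(parse_smiles("CC"), 0), 2)
  # X0v of ethanol: deltas 1, 2 and O's Zv - h = 5
  expect_equal(chi_index(parse_smiles("CCO"), 0, valence = TRUE),
               1 + 1 / sqrt(2) + 1 / sqrt(5), tolerance = 1e-12)
})

test_that("chi indices equal the exhaustive-enumeration oracle", {
  fixtures <- list(parse_smiles("CC(C)CC"), parse_smiles("C1=CC=CC=C1C"),
                   parse_smiles("CC(C)(C)CO"))
  graphs <- c(fixtures, lapply(1:15, function(s) {
    random_molecular_graph(sample(4:10, 1), seed = s)
  }))
  grid <- expand.grid(k = 0:4,
                      type = c("path", "cluster", "path-cluster"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$k >= c(path = 0, cluster = 3,
                           `path-cluster` = 4)[grid$type], ]
  for (g in graphs) {
    for (r in seq_len(nrow(grid))) {
      for (v in c(FALSE, TRUE)) {
        expect_equal(chi_index(g, grid$k[r], grid$type[r], valence = v),
                     oracle_chi(g, grid$k[r], grid$type[r], valence = v),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("adding a pendant vertex strictly increases 0-chi", {
  for (seed in 1:10) {
    g <- random_molecular_graph(sample(3:10, 1), seed = seed)
    n <- nrow(g$atoms)
    open <- which(rowSums(g$adjacency) < 4)[1]
    atoms <- dplyr::bind_rows(g$atoms, g$atoms[1, ])
    atoms$element[n + 1] <- "C"
    atoms$implicit_h[n + 1] <- 3L
    atoms$formal_charge[n + 1] <- 0L
    atoms$aromatic[n + 1] <- FALSE
    atoms$Z[n + 1] <- 6L
    atoms$Zv[n + 1] <- 4L
    bonds <- dplyr::bind_rows(
      g$bonds,
      tibble::tibble(from = open, to = n + 1L, order = 1L,
                     aromatic = FALSE)
    )
    bigger <- mol_graph(atoms, bonds)
    expect_gt(chi_index(bigger, 0), chi_index(g, 0))
  }
})

test_that("difference and quotient identities hold on every fixture", {
  t1 <- load_table1()
  grid <- list(c(0, "path"), c(1, "path"), c(2, "path"))
  for (s in t1$smiles) {
    g <- parse_smiles(s)
    for (kt in grid) {
      k <- as.integer(kt[1])
      dq <- chi_difference_quotient(g, k, kt[2])
      x <- chi_index(g, k, kt[2])
      xv <- chi_index(g, k, kt[2], valence = TRUE)
      expect_equal(dq$difference, x - xv, tolerance = 1e-15)
      expect_equal(dq$quotient * xv, x, tolerance = 1e-12)
    }
  }
  # saturated hydrocarbon: delta == delta_v, so D = 0, C = 1
  dq <- chi_difference_quotient(parse_smiles("CC"), 0, "path")
  expect_equal(dq$difference, 0)
  expect_equal(dq$quotient, 1)
  dq <- chi_difference_quotient(parse_smiles("CCC(C)CC"), 1, "path")
  expect_equal(dq$difference, 0, tolerance = 1e-12)
  expect_error(chi_difference_quotient(parse_smiles("CC"), 3, "cluster"),
               "undefined")
})

test_that("constitutional counts follow their definitions", {
  expect_equal(count_double_bonds(parse_smiles("C=C")), 1)
  expect_equal(count_double_bonds(parse_smiles("C1=CC=CC=C1")), 0)
  expect_equal(count_nitrogens(parse_smiles("C1=CC=CC=C1")), 0)
  t1 <- load_table1()
  expect_equal(count_nitrogens(parse_smiles(t1$smiles[t1$id == "5"])), 7)
  expect_equal(count_nitrogens(parse_smiles(t1$smiles[t1$id == "12"])), 2)
  # charged nitrogen still counts
  expect_equal(count_nitrogens(parse_smiles(t1$smiles[t1$id == "17a"])), 1)
})

test_that("mean van der Waals volume averages over all atoms incl. H", {
  vt <- vdw_volume_table()
  vH <- vt$volume[vt$element == "H"]
  expect_equal(mean_vdw_volume(parse_smiles("C")), (1 + 4 * vH) / 5)
  expect_equal(mean_vdw_volume(parse_smiles("CC")), (2 + 6 * vH) / 8)
  for (s in c("CCO", "CS(=O)(=O)N", "FC(Cl)Br")) {
    g <- parse_smiles(s)
    mv <- mean_vdw_volume(g)
    present <- vt$volume[vt$element %in% c(g$atoms$element,
                                           if (sum(g$atoms$implicit_h)) "H")]
    expect_gte(mv, min(present))
    expect_lte(mv, max(present))
  }
  bad <- parse_smiles("CCO")
  expect_error(mean_vdw_volume(bad, volume_table = vt[vt$element != "O", ]),
               "no van der Waals volume")
})

test_that("descriptor vectors are complete, finite and invariant", {
  v <- descriptor_vector(parse_smiles("CC"))
  expect_true(all(c("nDB", "nN", "Mv", "X0v", "GGI7", "GGI9", "JGI4",
                    "X4pc", "D0", "C0") %in% names(v)))
  expect_true(all(vapply(v[paste0("GGI", 1:10)], identical, logical(1), 0)))
  core <- setdiff(names(v), grep("^C", names(v), value = TRUE))
  expect_true(all(is.finite(unlist(v[core]))))

  for (seed in 1:12) {
    g <- random_molecular_graph(sample(4:10, 1), seed = seed)
    expect_equal(descriptor_vector(permute_atoms(g, seed = seed + 500)),
                 descriptor_vector(g), tolerance = 1e-12)
  }
})

test_that("compute_descriptors appends tidy columns", {
  out <- compute_descriptors(tibble::tibble(id = c("a", "b"),
                                            smiles = c("CCO", "C=C")))
  expect_s3_class(out, "tbl_df")
  expect_equal(out$nDB, c(0, 1))
  expect_equal(out$id, c("a", "b"))
  expect_true("JGI4" %in% names(out))
})
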