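test_that("engineered salt bridges are found at and only at the built distances", {
  tc <- make_toy_complex(12, 12, salt_bridges = 3.2)
  a <- select_atoms(tc$model, chain = "A")
  b <- select_atoms(tc$model, chain = "B")
  sb <- salt_bridges(a, b)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.2, tolerance = 1e-6)
  expect_equal(sb$basic_res, tc$manifest$salt_bridges$res_b)
  expect_equal(sb$acidic_res, tc$manifest$salt_bridges$res_a)
  expect_equal(sb$partner_kind, "carboxylate")

  # beyond the cutoff: nothing (5.5 A pair with 4.0 A cutoff)
  tc2 <- make_toy_complex(12, 12, salt_bridges = 5.5)
  sb2 <- salt_bridges(select_atoms(tc2$model, chain = "A"),
                      select_atoms(tc2$model, chain = "B"))
  expect_equal(nrow(sb2), 0)
  # poly-Ala chains carry no charged groups at all
  tc3 <- make_toy_complex(8, 8)
  expect_equal(nrow(salt_bridges(select_atoms(tc3$model, chain = "A"),
                                 select_atoms(tc3$model, chain = "B"))), 0)
})

test_that("hydrogen bonds follow the heavy-atom donor/acceptor criterion", {
  tc <- make_toy_complex(12, 12, hbonds = 2.9)
  a <- select_atoms(tc$model, chain = "A")
  b <- select_atoms(tc$model, chain = "B")
  hb <- hydrogen_bonds(a, b)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  # distant chains: no contacts of either kind
  far <- make_toy_complex(8, 8, gap = 100)
  fa <- select_atoms(far$model, chain = "A")
  fb <- select_atoms(far$model, chain = "B")
  expect_equal(nrow(hydrogen_bonds(fa, fb)), 0)
  expect_equal(nrow(salt_bridges(fa, fb)), 0)
})

test_that("salt-bridge pairs are excluded from the hydrogen-bond inventory", {
  tc <- make_toy_complex(12, 12, salt_bridges = 3.2)
  a <- select_atoms(tc$model, chain = "A")
  b <- select_atoms(tc$model, chain = "B")
  hb <- hydrogen_bonds(a, b)
  sb <- salt_bridges(a, b)
  expect_equal(nrow(sb), 1)
  # the Asp-Arg N-O pair qualifies geometrically as an H-bond but must not
  # be double-counted
  expect_false(any(hb$atom_a == "OD1" & hb$atom_b %in% c("NH1", "NE")))
})

test_that("contact inventories are monotone in the cutoff", {
  tc <- make_toy_complex(15, 15, salt_bridges = c(3.0, 3.9), hbonds = c(2.7, 3.4))
  a <- select_atoms(tc$model, chain = "A")
  b <- select_atoms(tc$model, chain = "B")
  n_sb <- sapply(c(3.2, 4.0, 6.0), function(d) nrow(salt_bridges(a, b, d)))
  n_hb <- sapply(c(2.8, 3.5, 5.0), function(d) nrow(hydrogen_bonds(a, b, d)))
  expect_true(all(diff(n_sb) >= 0))
  expect_true(all(diff(n_hb) >= 0))
  expect_equal(n_sb[2], 2)   # both engineered bridges inside 4.0 A
  expect_equal(n_hb[2], 2)   # both engineered H-bonds inside 3.5 A
})

test_that("contacts match brute-force classification on the toy complex", {
  tc <- make_toy_complex(15, 15, salt_bridges = c(3.0, 3.9), hbonds = 2.7)
  aa <- select_atoms(tc$model, chain = "A")$atoms
  ab <- select_atoms(tc$model, chain = "B")$atoms
  # brute force: every Asp OD1/OD2 against every Arg NE/NH1/NH2
  acid <- aa[aa$resid == "ASP" & aa$elety %in% c("OD1", "OD2"), ]
  base <- ab[ab$resid == "ARG" & ab$elety %in% c("NE", "NH1", "NH2"), ]
  want <- 0
  for (i in seq_len(nrow(acid))) for (j in seq_len(nrow(base)))
    if (sqrt(sum((acid[i, c("x", "y", "z")] - base[j, c("x", "y", "z")])^2)) <= 4)
      want <- want + 1
  got <- salt_bridges(select_atoms(tc$model, chain = "A"),
                      select_atoms(tc$model, chain = "B"))
  # table is per residue pair; brute force counted atom pairs in the same
  # two residue pairs
  expect_equal(nrow(got), 2)
  expect_gte(want, nrow(got))
})

test_that("contact residues appear in the delta-SASA interface sets", {
  tc <- make_toy_complex(12, 12, salt_bridges = 3.2, hbonds = 2.9)
  m <- tc$model
  a <- select_atoms(m, chain = "A"); b <- select_atoms(m, chain = "B")
  ir <- interface_residues(m, a, b)
  sb <- salt_bridges(a, b); hb <- hydrogen_bonds(a, b)
  contact_res_a <- c(sb$acidic_resno[sb$acidic_chain == "A"],
                     hb$resno_a)
  contact_res_b <- c(sb$basic_resno[sb$basic_chain == "B"],
                     hb$resno_b)
  expect_true(all(contact_res_a %in% ir$residues_a$resno))
  expect_true(all(contact_res_b %in% ir$residues_b$resno))
})

test_that("intramolecular bridges are found when a selection is paired with itself", {
  # Asp and Arg side chains engineered toward each other across the gap
  # belong to the same model half when we treat the whole complex as one
  # selection; same-residue pairs must be excluded
  tc <- make_toy_complex(12, 12, salt_bridges = 3.4)
  whole <- tc$model
  sb <- salt_bridges(structure_model(whole$atoms, "w"),
                     structure_model(whole$atoms, "w"))
  expect_equal(nrow(sb), 1)
  expect_false(any(paste(sb$basic_chain, sb$basic_res) ==
                     paste(sb$acidic_chain, sb$acidic_res)))
})
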