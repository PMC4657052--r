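test_that("ring centroids are unweighted means of the member atoms", {
  s <- structure_model(phe_ring(1, c(0, 0, 0), radius = 1))
  rc <- ring_centroids(s)
  expect_equal(nrow(rc), 1)
  expect_equal(c(rc$cx, rc$cy, rc$cz), c(0, 0, 0), tolerance = 1e-12)

  s2 <- structure_model(trp_rings(2, c(3, 4, 5)))
  rc2 <- ring_centroids(s2)
  expect_equal(nrow(rc2), 2)
  expect_setequal(rc2$ring, c("pyrrole", "benzene"))

  s3 <- structure_model(phe_ring(3, c(0, 0, 0), drop_atom = "CZ"))
  expect_warning(rc3 <- ring_centroids(s3), "missing atom")
  expect_equal(nrow(rc3), 0)
})

test_that("motif calls apply the 7 Angstrom nearest-centroid rule", {
  s <- structure_model(rbind(sd_atom(1, c(0, 0, 6.9)),
                             phe_ring(2, c(0, 0, 0))))
  mc <- s_aromatic_calls(s)
  expect_equal(mc$calls$nearest_dist, 6.9, tolerance = 1e-9)
  expect_true(mc$calls$forms_motif)

  s2 <- structure_model(rbind(sd_atom(1, c(0, 0, 7.1)),
                              phe_ring(2, c(0, 0, 0))))
  mc2 <- s_aromatic_calls(s2)
  expect_false(mc2$calls$forms_motif)
  expect_equal(nrow(mc2$contacts), 0)

  # raising the cutoff never revokes a motif
  mc3 <- s_aromatic_calls(s2, cutoff = 8)
  expect_true(mc3$calls$forms_motif)

  # no aromatic residues at all
  s4 <- structure_model(sd_atom(1, c(0, 0, 0)))
  mc4 <- s_aromatic_calls(s4)
  expect_false(mc4$calls$forms_motif)
  expect_true(is.na(mc4$calls$nearest_dist))

  # MET without a resolved SD is skipped with a warning
  s5 <- structure_model(rbind(
    atom_df("A", 1, "MET", "CA", "C", 0, 0, 0),
    phe_ring(2, c(0, 0, 5))))
  expect_warning(mc5 <- s_aromatic_calls(s5), "no SD")
  expect_equal(nrow(mc5$calls), 0)
})

test_that("motif calls match a brute-force all-pairs oracle", {
  set.seed(55)
  for (rep in seq_len(100)) {
    s <- random_motif_structure(n_met = sample(2:5, 1),
                                n_ring = sample(1:5, 1))
    mc <- s_aromatic_calls(s)
    brute <- brute_nearest(s)
    expect_equal(mc$calls$nearest_dist, brute, tolerance = 1e-9)
    expect_identical(mc$calls$forms_motif, brute <= 7.0)
  }
})

test_that("motif calls are invariant under rigid transforms", {
  ts <- gen_toy_structure(synthetic_config(), seed = 77, n_met = 30)
  base <- s_aromatic_calls(ts$structure)
  moved <- rigid_transform(ts$structure)
  mc <- s_aromatic_calls(moved)
  expect_identical(base$calls$forms_motif, mc$calls$forms_motif)
  expect_equal(base$calls$nearest_dist, mc$calls$nearest_dist,
               tolerance = 1e-9)
})

test_that("nearest-distance histogram finds the inter-mode minimum", {
  ts <- gen_toy_structure(synthetic_config(), seed = 5, n_met = 6)
  mc <- s_aromatic_calls(ts$structure)
  mc$calls$nearest_dist <- rep(5.0, nrow(mc$calls))
  h <- distance_histogram(mc, binwidth = 0.5)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$counts[h$mids == 5.25], nrow(mc$calls))

  # two Gaussian distance populations at 5 and 8 Angstrom
  set.seed(8)
  d <- c(rnorm(400, 5, 0.5), rnorm(400, 8, 0.5))
  mc2 <- mc
  mc2$calls <- data.frame(chain = "A", resno = seq_along(d),
                          nearest_dist = d, nearest_chain = "A",
                          nearest_resno = 1, nearest_resname = "PHE",
                          nearest_ring = "ring",
                          forms_motif = d <= 7)
  h2 <- distance_histogram(mc2, binwidth = 0.5)
  expect_true(h2$first_min > 5 && h2$first_min < 8)

  mc3 <- mc
  mc3$calls <- mc2$calls[0, ]
  h3 <- distance_histogram(mc3, binwidth = 0.5)
  expect_true(all(h3$counts == 0))
})

test_that("chain deduplication keeps one chain per identical sequence", {
  seqA <- "MKTAYIAKQR"
  dimer <- structure_model(rbind(ca_chain(seqA, "A"),
                                 ca_chain(seqA, "B")))
  expect_equal(dedup_chains(dimer), "A")

  hetero <- structure_model(rbind(ca_chain(seqA, "A"),
                                  ca_chain("MWGYPLDE", "B")))
  expect_equal(dedup_chains(hetero), c("A", "B"))

  tri <- structure_model(rbind(ca_chain(seqA, "B"),
                               ca_chain(seqA, "A"),
                               ca_chain("MWGYPLDE", "C")))
  expect_equal(dedup_chains(tri), c("A", "C"))
})

test_that("linear separations use sequence distance and drop cross-chain", {
  s <- structure_model(rbind(
    sd_atom(10, c(0, 0, 0)),
    phe_ring(25, c(0, 0, 5)),
    sd_atom(7, c(100, 0, 0), chain = "B"),
    phe_ring(3, c(100, 0, 5))))  # chain A ring near chain B met
  mc <- s_aromatic_calls(s)
  expect_message(ls1 <- linear_separations(mc), "cross-chain")
  expect_equal(ls1$pairs$separation, 15)
  expect_equal(ls1$summary$n[ls1$summary$resname == "PHE"], 1)

  # Trp's two rings collapse to a single pair
  s2 <- structure_model(rbind(sd_atom(10, c(0, 0, 0)),
                              trp_rings(30, c(0, 0, 4))))
  mc2 <- s_aromatic_calls(s2)
  expect_gt(nrow(mc2$contacts), 1)
  ls2 <- linear_separations(mc2)
  expect_equal(nrow(ls2$pairs), 1)
  expect_equal(ls2$pairs$separation, 20)

  # a residue map translates author numbering to sequence positions
  map <- data.frame(seq_pos = c(110, 125), chain = "A",
                    resno = c(10, 25))
  class(map) <- c("residue_map", "data.frame")
  s3 <- structure_model(rbind(sd_atom(10, c(0, 0, 0)),
                              phe_ring(25, c(0, 0, 5))))
  ls3 <- linear_separations(s_aromatic_calls(s3), map)
  expect_equal(ls3$pairs$separation, 15)
})
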