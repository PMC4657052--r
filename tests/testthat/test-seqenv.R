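freq_of <- function(f_mat, n) {
  structure(list(f = f_mat, n = n), class = "freq_matrix")
}

zero_f <- function() {
  matrix(0, 20, length(metox:::ENV_OFFSETS),
         dimnames = list(metox:::AA20, as.character(metox:::ENV_OFFSETS)))
}

test_that("env_frequencies counts flanking residues with the window rule", {
  prot <- data.frame(id = "P1",
                     seq = paste0(strrep("A", 10), "M", strrep("A", 10)))
  sites <- data.frame(protein_id = "P1", pos = 11)
  fm <- env_frequencies(sites, prot)
  expect_equal(fm$n, 1)
  expect_true(all(fm$f["A", ] == 1))
  expect_true(all(fm$f[setdiff(rownames(fm$f), "A"), ] == 0))
  # columns sum to one when every site has a residue at each offset
  expect_true(all(abs(colSums(fm$f) - 1) < 1e-12))

  # a site with only 4 N-terminal neighbours is excluded
  prot2 <- data.frame(id = "P2", seq = strrep("A", 30))
  prot2$seq <- paste0("AAAA", "M", strrep("A", 25))
  sites2 <- rbind(sites, data.frame(protein_id = "P2", pos = 5))
  fm2 <- env_frequencies(sites2, rbind(prot, prot2))
  expect_equal(fm2$n, 1)
  expect_error(env_frequencies(data.frame(protein_id = "P2", pos = 5),
                               prot2), "neighbours")

  # two sites with A-only and C-only windows split the mass
  protC <- data.frame(id = "P3",
                      seq = paste0(strrep("C", 10), "M", strrep("C", 10)))
  fm3 <- env_frequencies(
    data.frame(protein_id = c("P1", "P3"), pos = c(11, 11)),
    rbind(prot, protC))
  expect_true(all(fm3$f["A", ] == 0.5))
  expect_true(all(fm3$f["C", ] == 0.5))
})

test_that("z-scores follow the two-proportion standardization", {
  f0 <- zero_f()
  fa <- f0; fa["E", "-1"] <- 0.5
  fb <- f0; fb["E", "-1"] <- 0.3
  zm <- zscore_matrix(freq_of(fa, 100), freq_of(fb, 100))
  expect_equal(zm$z["E", "-1"],
               0.2 / sqrt((0.25 + 0.21) / 100), tolerance = 1e-12)
  # hand value of the stated formula
  expect_equal(zm$z["E", "-1"], 2.948839, tolerance = 1e-6)
  # absent in both -> 0, not NaN
  expect_true(all(zm$z[-match("E", rownames(zm$z)), ] == 0))

  same <- zscore_matrix(freq_of(fa, 50), freq_of(fa, 50))
  expect_true(all(same$z == 0))

  expect_error(zscore_matrix(freq_of(fa, 100), freq_of(fb, 99)),
               "different site counts")
})

test_that("swapping the frequency matrices negates every z exactly", {
  set.seed(404)
  ra <- matrix(runif(400), 20, 20, dimnames = dimnames(zero_f()))
  rb <- matrix(runif(400), 20, 20, dimnames = dimnames(zero_f()))
  ra <- sweep(ra, 2, colSums(ra), "/")
  rb <- sweep(rb, 2, colSums(rb), "/")
  z1 <- zscore_matrix(freq_of(ra, 250), freq_of(rb, 250))
  z2 <- zscore_matrix(freq_of(rb, 250), freq_of(ra, 250))
  expect_identical(z1$z, -z2$z)
})

test_that("interval counts and per-residue aggregates summarise |z|", {
  zm <- structure(list(z = zero_f(), n = 100), class = "zscore_matrix")
  ic <- interval_counts(zm, bounds = c(2, 3))
  expect_equal(ic$n_outside, c(0, 0))
  expect_equal(ic$expected_null[2], 400 * 2 * (1 - pnorm(3)))

  z1 <- zero_f(); z1["Y", "-1"] <- -4; z1["K", "5"] <- 7.5
  zm1 <- structure(list(z = z1, n = 100), class = "zscore_matrix")
  ic1 <- interval_counts(zm1, bounds = c(2, 7))
  expect_equal(ic1$n_outside, c(2, 1))
  expect_equal(ic1$frac_negative, c(0.5, 0))

  s <- aa_aggregate_scores(zm1)
  expect_equal(unname(s["Y"]), 4)
  expect_equal(unname(s["K"]), 7.5)
  expect_equal(sum(s), 11.5)

  # brute-force oracle on a random matrix
  set.seed(17)
  zr <- matrix(rnorm(400), 20, 20, dimnames = dimnames(zero_f()))
  zmr <- structure(list(z = zr, n = 100), class = "zscore_matrix")
  brute <- vapply(seq_len(20), function(i) {
    acc <- 0
    for (j in seq_len(20)) acc <- acc + abs(zr[i, j])
    acc
  }, numeric(1))
  expect_equal(unname(aa_aggregate_scores(zmr)), brute)
})

test_that("resistant-site pairing honours eligibility and determinism", {
  # exactly one eligible non-oxidized Met: always chosen
  seq1 <- paste0(strrep("A", 10), "M", strrep("A", 10), "M",
                 strrep("A", 10))
  prot <- data.frame(id = "P1", seq = seq1)
  ox <- data.frame(protein_id = "P1", pos = 11, oxidized = TRUE)
  for (sd in 1:5) {
    pr <- pair_resistant_sites(ox, prot, seed = sd)
    expect_equal(pr$resistant$pos, 22)
  }

  # no non-oxidized partner: pair dropped
  prot2 <- data.frame(id = "P2",
                      seq = paste0(strrep("A", 10), "M", strrep("A", 10)))
  ox2 <- data.frame(protein_id = "P2", pos = 11, oxidized = TRUE)
  pr2 <- pair_resistant_sites(ox2, prot2, seed = 1)
  expect_equal(nrow(pr2$oxidized), 0)
  expect_equal(pr2$n_dropped, 1)

  # fixed seed gives identical pairing on a larger synthetic proteome
  cfg <- synthetic_config(n_proteins = 40, mean_length = 300)
  pl <- plant_env_bias(gen_proteome(cfg, 3), cfg, 4)
  oxs <- pl$sites[pl$sites$oxidized, ]
  a <- pair_resistant_sites(oxs, pl$proteome, seed = 9)
  b <- pair_resistant_sites(oxs, pl$proteome, seed = 9)
  expect_identical(a, b)
  # partners are never oxidized sites of the same protein
  key_ox <- paste(oxs$protein_id, oxs$pos)
  expect_false(any(paste(a$resistant$protein_id, a$resistant$pos)
                   %in% key_ox))
})
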