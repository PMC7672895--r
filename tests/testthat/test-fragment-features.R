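test_that("functional-group frequencies match a brute-force tally", {
  fb <- functional_group_frequencies("AAAA")
  expect_equal(sum(fb$values), 1)
  expect_equal(fb$values[[2]], 1)  # aliphatic group {A,V,L,I}

  fb <- functional_group_frequencies("GPGP")
  expect_equal(fb$values[[1]], 0.5)  # {G}
  expect_equal(fb$values[[6]], 0.5)  # {P}
  expect_equal(sum(fb$values != 0), 2L)

  part <- functional_groups()
  res <- strsplit("ACDEFGHIKL", "")[[1]]
  hand <- sapply(seq_len(10), function(g)
    sum(res %in% part$groups[[g]]) / length(res))
  expect_equal(functional_group_frequencies("ACDEFGHIKL")$values, hand)

  set.seed(2)
  for (i in 1:20)
    expect_equal(sum(functional_group_frequencies(random_fragment())$values), 1,
                 tolerance = 1e-12)
  expect_error(functional_group_frequencies(""), "empty")
})

test_that("sequence entropies follow the Shannon definition in bits", {
  expect_equal(sequence_entropy("AAAA")$values, c(0, 0))
  expect_equal(sequence_entropy("ACDE")$values[[1]], 2)
  # dipeptides of ACAC: AC (2/3), CA (1/3)
  expect_equal(sequence_entropy("ACAC")$values[[2]],
               -(2/3 * log2(2/3) + 1/3 * log2(1/3)), tolerance = 1e-10)
  expect_error(sequence_entropy("A"), "length >= 2")
})

test_that("residue distribution is the mean relative position per type", {
  fb <- residue_distribution("A")
  expect_equal(fb$values[[1]], 1)
  expect_equal(sum(fb$values != 0), 1L)

  fb <- residue_distribution("ACA")
  expect_equal(fb$values[[match("A", AA_ALPHABET)]], (1/3 + 3/3) / 2)
  expect_equal(fb$values[[match("C", AA_ALPHABET)]], 2/3)
  absent <- setdiff(AA_ALPHABET, c("A", "C"))
  expect_true(all(fb$values[match(absent, AA_ALPHABET)] == 0))
})

test_that("group transitions count unordered cross-group adjacencies", {
  pair_index <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    (lo - 1) * 10 - lo * (lo - 1) / 2 + (hi - lo)
  }
  fb <- group_transitions("GP")
  expect_equal(fb$values[[pair_index(1, 6)]], 1)
  expect_equal(sum(fb$values), 1)

  expect_equal(group_transitions("GGGG")$values, numeric(45))

  # GPGA adjacencies: G-P, P-G, G-A over 3 pairs
  fb <- group_transitions("GPGA")
  expect_equal(fb$values[[pair_index(1, 6)]], 2/3)
  expect_equal(fb$values[[pair_index(1, 2)]], 1/3)

  set.seed(3)
  part <- functional_groups()
  for (i in 1:20) {
    res <- random_fragment()
    total <- sum(group_transitions(res, part)$values)
    g <- part$index[strsplit(res, "")[[1]]]
    same <- sum(g[-length(g)] == g[-1])
    expect_equal(total, (length(g) - 1 - same) / (length(g) - 1), tolerance = 1e-12)
  }
})

test_that("PseAAC matches the straight-line oracle and its invariants", {
  fb <- pseaac("AAAAA")
  expect_equal(fb$values[[1]], 1)
  expect_equal(fb$values[21:40], numeric(20))

  # L = 4 supports only theta_1..theta_3; entries 24..40 are padding
  fb <- pseaac("ACDE", lam = 19)
  expect_equal(fb$values[24:40], numeric(17))

  expect_equal(pseaac("ACDEF", lam = 2, w = 0.05)$values,
               unname(oracle_pseaac("ACDEF", 2, 0.05)), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:20) {
    res <- random_fragment()
    v <- pseaac(res)$values
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
  expect_warning(pseaac("ACDEFGH", lam = 20), "clipped")
})

test_that("property profiles are direct scale lookups", {
  hyd <- property_scales()$hydrophobicity
  expect_equal(property_profile("AR", hyd), c(1.8, -4.5))
  expect_equal(property_profile("GGGG", hyd), rep(-0.4, 4))
  expect_length(property_profile(random_fragment(13), hyd), 13L)
})

test_that("Haar wavelet features satisfy Parseval and match the matrix oracle", {
  # constant profile: zero detail statistics, energy 32 c^2
  v <- dwt_features("AAAAAAAA")$values
  hyd_a <- 1.8
  d_stats <- v[4:12]   # D3, D2, D1 stats of the first (hydrophobicity) profile
  expect_equal(d_stats, numeric(9), tolerance = 1e-12)
  expect_equal(v[13][[1]], 32 * hyd_a^2, tolerance = 1e-10)

  # impulse decomposition equals the explicit 32x32 orthonormal Haar matrix
  H <- oracle_haar_matrix()
  x <- c(1, numeric(31))
  dec <- haar_dwt(x, 3)
  expect_equal(c(dec$approx, dec$details[[1]], dec$details[[2]], dec$details[[3]]),
               as.numeric(H %*% x), tolerance = 1e-12)

  set.seed(6)
  for (i in 1:100) {
    res <- random_fragment()
    prof <- property_profile(res, property_scales()$flexibility)
    x32 <- approx(seq(0, 1, length.out = length(prof)), prof,
                  xout = seq(0, 1, length.out = 32))$y
    dec <- haar_dwt(x32, 3)
    energy <- sum(unlist(dec)^2)
    expect_equal(energy, sum(x32^2), tolerance = 1e-10)
  }
})

test_that("feature groups concatenate with the declared dimensions and order", {
  res <- "GPGPACDEKL"
  seqf <- sequence_group_features(res)
  expect_equal(sum(vapply(seqf, `[[`, integer(1), "dim")), 77L)
  expect_equal(vapply(seqf, `[[`, character(1), "name"),
               c("group_freq", "entropy", "distribution", "transition"))
  expect_equal(seqf[[1]]$values, functional_group_frequencies(res)$values)

  phys <- physchem_group_features(res)
  expect_equal(sum(vapply(phys, `[[`, integer(1), "dim")), 82L)
  expect_equal(phys[[1]]$values, pseaac(res)$values)
  expect_equal(phys[[2]]$values, dwt_features(res)$values)
})
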