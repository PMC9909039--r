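test_that("per-encoder dimensions at defaults match the fixed schema", {
  v <- encode_all("GFLK")
  expect_identical(names(v), c("AAC", "TPAAC", "APAAC", "ASDC", "DPC",
                               "DDE", "GAAC", "GDPC", "SOCNumber", "QSOrder"))
  expect_equal(unname(vapply(v, length, integer(1))),
               c(20L, 21L, 22L, 400L, 400L, 400L, 5L, 25L, 2L, 42L))
  expect_equal(sum(vapply(v, length, integer(1))), 1337L)
})

test_that("a dipeptide is encodable by all ten encoders at defaults", {
  v <- encode_all("GF")
  expect_true(all(vapply(v, function(x) all(is.finite(x)), logical(1))))
})

test_that("hand-checked small cases come out exactly", {
  aac <- encode_aac("AAY")
  expect_equal(aac[["A"]], 2 / 3)
  expect_equal(aac[["Y"]], 1 / 3)
  expect_equal(sum(aac[setdiff(AA_ALPHABET, c("A", "Y"))]), 0)

  # homopolymer: zero correlations collapse TPAAC/QSOrder onto composition
  tp <- encode_tpaac("AAAA")
  expect_equal(tp[["A"]], 1)
  expect_equal(tp[["lambda1"]], 0)
  soc <- encode_socnumber("AAAA")
  expect_equal(as.vector(soc), c(0, 0))
  qso <- encode_qsorder("AAAA")
  expect_equal(qso[["SchneiderWrede.A"]], 1)
  expect_equal(qso[["Grantham.A"]], 1)
  expect_equal(qso[["SchneiderWrede.lag1"]], 0)

  asdc <- encode_asdc("AAA")
  expect_equal(asdc[["AA"]], 1)
  expect_equal(sum(asdc), 1)
  expect_equal(encode_asdc("AY")[["AY"]], 1)

  dpc <- encode_dpc("ARA")
  expect_equal(dpc[["AR"]], 0.5)
  expect_equal(dpc[["RA"]], 0.5)
  expect_equal(encode_dpc("AAA")[["AA"]], 1)

  gaac <- encode_gaac("GFKDS")
  expect_equal(as.vector(gaac), rep(0.2, 5))
  expect_equal(encode_gaac("GGGG")[["g1"]], 1)

  gdpc <- encode_gdpc("GF")
  expect_equal(gdpc[["g1g2"]], 1)
})

test_that("DDE standardization matches the literal codon-background formula", {
  # "AA": N = 2, A has 4 of the 61 sense codons
  dde <- encode_dde("AA")
  tm <- (4 / 61)^2
  expect_equal(dde[["AA"]], (1 - tm) / sqrt(tm * (1 - tm)), tolerance = 1e-12)
  # absent dipeptides are strictly negative
  expect_true(all(dde[names(dde) != "AA"] < 0))
  for (seq in c("GFLK", "MWMW", random_peptide(9))) {
    d <- encode_dde(seq)
    expect_true(all(d[o_dpc(seq) == 0] < 0))
  }
})

test_that("literal-equation oracle agrees on GFLK for the weighted encoders", {
  expect_equal(encode_tpaac("GFLK"), o_tpaac("GFLK"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(encode_apaac("GFLK"), o_apaac("GFLK"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(encode_qsorder("GFLK"), o_qso("GFLK"),
               tolerance = 1e-12, ignore_attr = TRUE)
  dm <- aa_distance_matrices()
  soc <- encode_socnumber("ARN")
  expect_equal(soc[["SchneiderWrede.lag1"]],
               dm$SchneiderWrede["A", "R"]^2 + dm$SchneiderWrede["R", "N"]^2)
  expect_equal(soc[["Grantham.lag1"]],
               dm$Grantham["A", "R"]^2 + dm$Grantham["R", "N"]^2)
})

test_that("every encoder equals its brute-force oracle on random peptides", {
  set.seed(101)
  for (rep in 1:60) {
    seq <- random_peptide(sample(2:30, 1))
    got <- encode_all(seq)
    want <- o_all(seq)
    for (e in names(got))
      expect_equal(got[[e]], want[[e]], tolerance = 1e-10,
                   ignore_attr = TRUE, label = paste(e, seq))
  }
})

test_that("composition encoders are permutation invariant, order encoders are not", {
  set.seed(7)
  seq <- random_peptide(12)
  perm <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
  expect_equal(encode_aac(seq), encode_aac(perm))
  expect_equal(encode_gaac(seq), encode_gaac(perm))
  # reversal is a witness for order sensitivity on a non-palindromic pair
  expect_false(isTRUE(all.equal(encode_dpc("ARND"), encode_dpc("DNRA"))))
  expect_false(isTRUE(all.equal(encode_socnumber("ARND"),
                                encode_socnumber("NARD"))))
})

test_that("duplicating a homopolymer leaves composition encoders unchanged", {
  expect_equal(encode_aac("CCC"), encode_aac("CCCCCC"))
  expect_equal(encode_gaac("CCC"), encode_gaac("CCCCCC"))
})

test_that("normalization invariants hold across random lengths 2-30", {
  set.seed(33)
  for (rep in 1:50) {
    seq <- random_peptide(sample(2:30, 1))
    expect_equal(sum(encode_aac(seq)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_tpaac(seq)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_apaac(seq)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_asdc(seq)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_dpc(seq)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_gaac(seq)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_gdpc(seq)), 1, tolerance = 1e-12)
    q <- encode_qsorder(seq)
    expect_equal(sum(q[1:21]), 1, tolerance = 1e-12)
    expect_equal(sum(q[22:42]), 1, tolerance = 1e-12)
  }
})

test_that("lambda and nlag must stay below the peptide length", {
  cfg <- encoder_config(lambda = 3, nlag = 3)
  expect_error(encode_tpaac("GF", cfg), "lambda")
  expect_error(encode_apaac("GFL", cfg), "lambda")
  expect_error(encode_socnumber("GF", cfg), "nlag")
  expect_error(encode_qsorder("GFL", cfg), "nlag")
  # and succeed just above the bound, with the advertised dimensions
  expect_length(encode_tpaac("GFLK", cfg), 23)
  expect_length(encode_apaac("GFLK", cfg), 26)
  expect_length(encode_socnumber("GFLK", cfg), 6)
  expect_length(encode_qsorder("GFLK", cfg), 46)
})

test_that("encoder_config rejects invalid parameters", {
  expect_error(encoder_config(lambda = 0), ">= 1")
  expect_error(encoder_config(w_apaac = 0), "> 0")
})
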