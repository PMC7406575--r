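make_peak <- function(mz, polarity = "positive", rt = 10, intensity = 100,
                      charge = NA_integer_) {
  data.frame(mz = mz, rt = rt, intensity = intensity, polarity = polarity,
             charge = charge, stringsAsFactors = FALSE)
}

test_that("peaks match the correct library entry with polarity filtering", {
  lib <- enumerate_library()
  mzt <- library_mz_table(lib)
  hit <- match_peaks(make_peak(384.0), mzt, tol_da = 0.5)
  expect_equal(nrow(hit$matched), 1)
  expect_equal(hit$matched$name, "gA_2_m_1")
  expect_equal(hit$matched$adduct, "ammonium")
  expect_equal(hit$matched$z, 1L)
  # same m/z in negative mode: no deprotonated/formate expectation at 384
  miss <- match_peaks(make_peak(384.0, polarity = "negative"), mzt)
  expect_equal(nrow(miss$matched), 0)
  expect_equal(nrow(miss$unmatched), 1)
  expect_error(match_peaks(make_peak(384), mzt[0, ]), "empty")
  expect_error(match_peaks(make_peak(384), mzt, tol_da = 0), "tolerance")
})

test_that("jittered library peaks are all recovered, exactly where the
          composition is mass-unique", {
  set.seed(101)
  lib <- enumerate_library()
  # positive-mode expectations only, one peak per compound
  mzt <- library_mz_table(lib, adducts = list(adduct_spec("ammonium", 1L)))
  peaks <- data.frame(mz = mzt$mz + stats::runif(nrow(mzt), -0.3, 0.3),
                      rt = seq_len(nrow(mzt)), intensity = 1,
                      polarity = "positive")
  res <- match_peaks(peaks, mzt, tol_da = 0.5)
  expect_equal(nrow(res$unmatched), 0)
  # the true compound is always within tolerance of its own peak
  hit <- mapply(function(truth, cands)
    truth %in% strsplit(cands, ";", fixed = TRUE)[[1]],
    mzt$name, res$matched$candidates)
  expect_true(all(hit))
  # 3 x CH2 = C2H2O: compositions (dp, m, a+1) and (dp, m+3, a) are
  # exactly isobaric, so unique assignment is only possible off the
  # degeneracy; there it must be exact
  unique_mass <- !(mzt$mz %in% mzt$mz[duplicated(mzt$mz)])
  expect_identical(res$matched$name[unique_mass], mzt$name[unique_mass])
  expect_false(any(res$matched$ambiguous[unique_mass]))
  expect_true(all(res$matched$ambiguous[!unique_mass]))
  # the lyase-product prior resolves ties toward the methylated reading
  iso <- which(!unique_mass)[1]
  tied_names <- strsplit(res$matched$candidates[iso], ";")[[1]]
  tied <- mzt[mzt$name %in% tied_names & mzt$mz == mzt$mz[iso], ]
  expect_equal(res$matched$name[iso],
               tied$name[which.max(tied$n_methyl)])
})

test_that("matching is invariant under library row permutation", {
  set.seed(7)
  lib <- enumerate_library()
  mzt <- library_mz_table(lib)
  peaks <- rbind(make_peak(588.2), make_peak(486.1), make_peak(954.4))
  a <- match_peaks(peaks, mzt)
  b <- match_peaks(peaks, mzt[sample(nrow(mzt)), ])
  expect_identical(a$matched$name, b$matched$name)
  expect_identical(a$matched$z, b$matched$z)
})

test_that("ties prefer the smaller mass error, then the lower charge", {
  lib <- enumerate_library()
  mzt <- library_mz_table(lib)
  # gA_5_m_4 is observed at 954 (z=1) and 486 (z=2): each hits its own
  hi <- match_peaks(make_peak(954.0), mzt)
  expect_equal(hi$matched$z, 1L)
  lo <- match_peaks(make_peak(486.0), mzt)
  expect_equal(lo$matched$name, "gA_5_m_4")
  expect_equal(lo$matched$z, 2L)
  # charge hint filters candidates
  hinted <- match_peaks(make_peak(486.0, charge = 1L), mzt)
  expect_true(nrow(hinted$matched) == 0 || all(hinted$matched$z == 1L))
})

test_that("retention-time isomers are split by gap and numbered by elution", {
  lib <- enumerate_library()
  mzt <- library_mz_table(lib)
  two <- rbind(make_peak(820.1, rt = 12.1, intensity = 40),
               make_peak(820.2, rt = 14.8, intensity = 60))
  gi <- group_isomers(match_peaks(two, mzt)$matched, rt_gap = 1.0)
  expect_identical(sort(gi$compound),
                   c("gA_4_m_4_a_1", "gA_4_m_4_a_1 #2"))
  expect_equal(gi$isomer[order(gi$rt)], c(1L, 2L))
  # a single peak stays isomer 1 with no suffix
  one <- group_isomers(match_peaks(make_peak(820.1), mzt)$matched)
  expect_identical(one$compound, "gA_4_m_4_a_1")
  # three co-eluting peaks merge into one identification, intensity summed
  three <- do.call(rbind, lapply(c(12.0, 12.2, 12.4), function(rt)
    make_peak(820.1, rt = rt, intensity = 10)))
  merged <- group_isomers(match_peaks(three, mzt)$matched, rt_gap = 0.5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$intensity, 30)
})

test_that("profiles cover the whole library and conserve intensity", {
  lib <- enumerate_library()
  mzt <- library_mz_table(lib)
  # empty identifications -> all-zero profile over the library keys
  p0 <- build_profile(match_peaks(make_peak(9999), mzt)$matched, lib)
  expect_identical(names(p0$intensities), lib$name)
  expect_true(all(p0$intensities == 0))
  # one compound seen via both charge states is summed into one entry
  both <- rbind(make_peak(954.0, intensity = 70),
                make_peak(486.0, intensity = 30))
  m <- match_peaks(both, mzt)$matched
  pr <- build_profile(m, lib, enzyme = "E", substrate = "apple", time = 5)
  expect_equal(pr$intensities[["gA_5_m_4"]], 100)
  expect_equal(sum(pr$intensities), sum(m$intensity))
})

test_that("profile intensity equals matched peak intensity on random data", {
  set.seed(202)
  lib <- enumerate_library()
  mzt <- library_mz_table(lib, adducts = list(adduct_spec("ammonium", 1L),
                                              adduct_spec("ammonium", 2L)))
  pick <- mzt[sample(nrow(mzt), 30), ]
  peaks <- data.frame(mz = pick$mz + stats::runif(30, -0.2, 0.2),
                      rt = stats::runif(30, 2, 30),
                      intensity = stats::rexp(30, 1 / 100),
                      polarity = "positive")
  m <- match_peaks(peaks, mzt)
  gi <- group_isomers(m$matched)
  pr <- build_profile(gi, lib)
  expect_equal(sum(pr$intensities), sum(m$matched$intensity))
})
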