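test_that("chain generation hits the extreme and asymptotic DM targets", {
  all_m <- generate_chains(substrate_spec(5, 20, dm = 100), seed = 1)
  expect_true(all(vapply(all_m, function(ch) all(ch$methyl), logical(1))))
  none <- generate_chains(substrate_spec(5, 20, dm = 0), seed = 1)
  expect_false(any(vapply(none, function(ch) any(ch$methyl), logical(1))))
  # 1e5 residues at DM 69, random pattern: realized DM within 69 +/- 0.5
  big <- generate_chains(substrate_spec(1000, 100, dm = 69, dac = 2),
                         seed = 42)
  meth <- sum(vapply(big, function(ch) sum(ch$methyl), numeric(1)))
  expect_lt(abs(100 * meth / 1e5 - 69), 0.5)
  # acetyl placement respects DAc and uses one site per residue
  ac2 <- sum(vapply(big, function(ch)
    sum(ch$acetyl_o2) + sum(ch$acetyl_o3), numeric(1)))
  expect_lt(abs(100 * ac2 / 1e5 - 2), 0.5)
  expect_false(any(vapply(big, function(ch)
    any(ch$acetyl_o2 & ch$acetyl_o3), logical(1))))
  expect_error(substrate_spec(5, 20, dm = 120), "DM")
  expect_error(substrate_spec(5, 20, dm = 50, dac = 300), "DAc")
})

test_that("blockwise placement yields the target methyl count in runs", {
  spec <- substrate_spec(20, 60, dm = 50, methyl_pattern = "blockwise",
                         block_length = 5L)
  chains <- generate_chains(spec, seed = 3)
  for (ch in chains) expect_equal(sum(ch$methyl), 30)
  # blockwise runs are longer on average than random ones at equal DM
  run_len <- function(ch) {
    r <- rle(ch$methyl); mean(r$lengths[r$values])
  }
  rnd <- generate_chains(substrate_spec(20, 60, dm = 50), seed = 3)
  expect_gt(mean(vapply(chains, run_len, numeric(1))),
            mean(vapply(rnd, run_len, numeric(1))))
})

test_that("subsite rule: strict {+1,+3} requirement on small chains", {
  dp10 <- cleavable_bonds(residue_chain(rep(TRUE, 10)), strict_rule())
  expect_identical(dp10$bond, 1:7)
  expect_equal(dp10$rate, rep(1, 7))
  # fully methylated DP3 is inert: +3 never exists
  expect_equal(nrow(cleavable_bonds(residue_chain(rep(TRUE, 3)),
                                    strict_rule())), 0)
  # unmethylated chains are inert under any rule
  expect_equal(nrow(cleavable_bonds(residue_chain(rep(FALSE, 10)),
                                    cleavage_rule(rho = 1))), 0)
  # partial rate rho applies when only +1 is methylated
  part <- cleavable_bonds(residue_chain(c(FALSE, TRUE, FALSE, FALSE)),
                          cleavage_rule(rho = 0.25))
  expect_equal(part$bond, 1L)
  expect_equal(part$rate, 0.25)
  # acetyl in the subsite window multiplies the penalty
  ch <- residue_chain(rep(TRUE, 6), acetyl_o2 = c(0, 0, 1, 0, 0, 0) == 1)
  pen <- cleavable_bonds(ch, cleavage_rule(rho = 0, acetyl_penalty = 0.5))
  full <- cleavable_bonds(residue_chain(rep(TRUE, 6)), strict_rule())
  expect_equal(pen$rate, full$rate * 0.5)
  # hard block flag kills bonds with acetylated +1
  blocked <- cleavable_bonds(ch, cleavage_rule(
    rho = 0, block_acetyl_plus1 = TRUE))
  expect_false(2 %in% blocked$bond)  # +1 of bond 2 is residue 3
})

test_that("digest trajectories conserve residues and count new ends", {
  chains <- generate_chains(substrate_spec(20, 30, dm = 70, dac = 5),
                            seed = 10)
  tot0 <- sum(vapply(chains, function(ch) length(ch$methyl), numeric(1)))
  m0 <- sum(vapply(chains, function(ch) sum(ch$methyl), numeric(1)))
  a0 <- sum(vapply(chains, function(ch)
    sum(ch$acetyl_o2) + sum(ch$acetyl_o3), numeric(1)))
  dig <- simulate_digest(chains, cleavage_rule(), time_points = c(0, 1, 5, Inf),
                         seed = 11)
  expect_equal(dig$snapshots[[1]]$cleavage_count, 0)
  expect_equal(dig$snapshots[[1]]$n_chains, 20)
  for (s in dig$snapshots) {
    expect_equal(s$total_residues, tot0)
    expect_equal(s$total_methyl, m0)
    expect_equal(s$total_acetyl, a0)
    expect_equal(s$n_chains, 20 + s$cleavage_count)
    expect_equal(s$unsaturated_ends, s$cleavage_count)
  }
  # determinism under a fixed seed
  dig2 <- simulate_digest(chains, cleavage_rule(),
                          time_points = c(0, 1, 5, Inf), seed = 11)
  expect_identical(dig$snapshots[[4]]$compositions,
                   dig2$snapshots[[4]]$compositions)
})

test_that("terminal states of exhaustive digestion are inert", {
  # fully methylated DP6, strict rule, run to completion
  for (seed in 1:5) {
    dig <- simulate_digest(list(residue_chain(rep(TRUE, 6))), strict_rule(),
                           time_points = c(Inf), seed = seed)
    s <- dig$snapshots[[1]]
    expect_equal(s$total_residues, 6)
    for (ch in dig$final_chains)
      expect_equal(nrow(cleavable_bonds(ch, strict_rule())), 0)
  }
})

test_that("absorbance traces follow Beer-Lambert and never decrease", {
  chains <- generate_chains(substrate_spec(10, 25, dm = 80), seed = 20)
  dig <- simulate_digest(chains, cleavage_rule(),
                         time_points = c(0, 0.5, 1, 2, 5, Inf), seed = 21)
  tr <- absorbance_trace(dig, extinction = 5500, path_cm = 1,
                         mol_per_event = 1e-9, volume_l = 1e-3)
  expect_equal(tr$a235[1], 0)  # zero cleavages at t = 0
  expect_true(all(diff(tr$a235) >= 0))
  # 10 uM product, 1 cm path: A = 5500 * 1e-5 = 0.055
  fake <- structure(list(snapshots = list(list(time = 1,
                                               cleavage_count = 10))),
                    class = "pel_digest")
  expect_equal(absorbance_trace(fake, 5500, 1, mol_per_event = 1e-9,
                                volume_l = 1e-3)$a235, 0.055)
})

test_that("synthetic peak tables are proportional to counts at zero noise", {
  chains <- generate_chains(substrate_spec(30, 30, dm = 75), seed = 30)
  dig <- simulate_digest(chains, cleavage_rule(), time_points = c(0, Inf),
                         seed = 31)
  lib <- enumerate_library()
  snap <- dig$snapshots[[2]]
  pk <- synthesize_peak_table(snap, lib, noise_cv = 0, seed = 32,
                              mz_jitter = 0)
  comps <- snap$compositions
  key <- paste(comps$dp, comps$n_methyl, comps$n_acetyl)
  in_lib <- comps$unsaturated & key %in% paste(lib$dp, lib$n_methyl,
                                               lib$n_acetyl)
  expect_equal(nrow(pk$peaks), sum(in_lib))
  expect_equal(pk$peaks$intensity, 1e4 * comps$count[in_lib])
  # out-of-library products are reported, not dropped
  expect_equal(nrow(pk$excluded), sum(!in_lib))
  expect_equal(sum(pk$excluded$dp * pk$excluded$count) +
                 sum(comps$dp[in_lib] * comps$count[in_lib]),
               snap$total_residues)
  # empty digest snapshot -> empty peak table
  empty <- list(compositions = data.frame(dp = integer(),
                                          n_methyl = integer(),
                                          n_acetyl = integer(),
                                          unsaturated = logical(),
                                          count = integer()),
                total_residues = 0)
  expect_equal(nrow(synthesize_peak_table(empty, lib)$peaks), 0)
})

test_that("blockwise methylation raises the initial cleavable rate", {
  # small-scale version of the stochastic acceptance check
  rule <- cleavage_rule()
  rates <- vapply(1:10, function(seed) {
    blk <- generate_chains(substrate_spec(10, 100, dm = 50,
                                          methyl_pattern = "blockwise"),
                           seed = seed)
    rnd <- generate_chains(substrate_spec(10, 100, dm = 50), seed = seed)
    c(total_initial_rate(blk, rule), total_initial_rate(rnd, rule))
  }, numeric(2))
  expect_gte(mean(rates[1, ]), mean(rates[2, ]))
})

test_that("acetylation monotonically suppresses the initial rate", {
  rule <- cleavage_rule(acetyl_penalty = 0.5)
  means <- vapply(c(0, 10, 25, 50), function(dac) {
    mean(vapply(1:5, function(seed) {
      chains <- generate_chains(substrate_spec(10, 100, dm = 70, dac = dac),
                                seed = seed)
      total_initial_rate(chains, rule)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})
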