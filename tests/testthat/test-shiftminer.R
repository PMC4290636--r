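# Phosphate-loss pair mining: knee cut-off, filtering, pair search against a
# brute-force oracle, and replicate merging.

test_that("intensity knee sits before the largest drop", {
  expect_equal(intensity_knee(c(100, 90, 10, 9, 8)), 2)
  expect_equal(intensity_knee(c(100, 10, 9)), 1)
  expect_equal(intensity_knee(c(5, 5, 5, 5)), 4)  # no drop: retain all
  expect_equal(intensity_knee(c(10, 7, 4, 1)), 1) # tie broken to smaller N
  expect_warning(n <- intensity_knee(c(3, 1)), "fewer than 3")
  expect_equal(n, 2)
})

test_that("intensity chart data is a non-increasing rank series", {
  expect_equal(intensity_chart_data(c(3, 1, 2)),
               data.frame(rank = 1:3, intensity = c(3, 2, 1)))
  expect_equal(nrow(intensity_chart_data(numeric(0))), 0)
  set.seed(3)
  d <- intensity_chart_data(rlnorm(3000, 12, 1))
  expect_equal(nrow(d), 3000)
  expect_true(all(diff(d$intensity) <= 0))
})

test_that("filter_peaks applies charge, floor, and deterministic top-N", {
  pl <- peaklist(mz = c(500, 510, 520, 530, 540),
                 rt = rep(10, 5), intensity = c(5, 4, 3, 2, 1),
                 charge = c(1, 2, 2, 3, 2))
  expect_equal(nrow(filter_peaks(pl, miner_params(min_charge = 2))), 4)
  f2 <- filter_peaks(pl, miner_params(min_charge = 2, top_n = 2))
  expect_setequal(f2$intensity, c(4, 3))
  expect_equal(nrow(filter_peaks(
    peaklist(numeric(0), numeric(0), numeric(0)), miner_params())), 0)
  # ties on intensity resolved by ascending mz
  tied <- peaklist(mz = c(700, 600), rt = c(1, 1), intensity = c(9, 9),
                   charge = 2)
  expect_equal(filter_peaks(tied, miner_params(top_n = 1))$mz, 600)
  # peaks lacking charge are dropped only when min_charge > 1
  nach <- peaklist(mz = c(500, 510), rt = c(1, 1), intensity = c(2, 1),
                   charge = c(NA, 2L), mass = c(998, NA))
  expect_equal(nrow(filter_peaks(nach, miner_params(min_charge = 2))), 1)
  expect_equal(nrow(filter_peaks(nach, miner_params(min_charge = 1))), 2)
})

demo_pair <- function() {
  u <- peaklist(mz = 812.858, rt = 24.1, intensity = 1e6, charge = 2,
                condition = "untreated")
  t_ <- peaklist(mz = 772.870, rt = 23.5, intensity = 8e5, charge = 2,
                 condition = "ap_treated")
  list(u = u, t = t_)
}

test_that("the worked demonstration pair is accepted with n_mods = 1", {
  d <- demo_pair()
  cand <- mine_pair(d$u, d$t, miner_params())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_mods, 1L)
  expect_equal(cand$mass_error, 0.010, tolerance = 1e-3)
  expect_equal(cand$rt_diff, 0.6, tolerance = 1e-9)
  # empty treated list yields no candidates
  expect_equal(nrow(mine_pair(d$u, filter_peaks(
    peaklist(numeric(0), numeric(0), numeric(0)), miner_params()))), 0)
})

test_that("mine_pair equals the exhaustive (u, t, n) oracle", {
  set.seed(42)
  for (rep in 1:12) {
    nu <- sample(c(20, 50, 120, 200), 1)
    nt <- sample(c(20, 50, 120, 200), 1)
    params <- miner_params(mass_tol = runif(1, 0.02, 0.2),
                           rt_tol = runif(1, 1, 8),
                           max_mods = sample(1:5, 1),
                           same_charge = rep %% 3 == 0)
    u <- random_peaklist(nu)
    t_ <- random_peaklist(nt, "ap_treated")
    got <- mine_pair(u, t_, params)
    want <- oracle_mine(u, t_, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      key_got <- paste(round(got$untreated_mass, 6),
                       round(got$treated_mass, 6), got$n_mods)
      key_want <- paste(round(u$mass[want$u_idx], 6),
                        round(t_$mass[want$t_idx], 6), want$n_mods)
      expect_setequal(key_got, key_want)
    }
  }
})

test_that("every emitted candidate satisfies its tolerance invariants", {
  set.seed(99)
  for (rep in 1:10) {
    params <- miner_params(mass_tol = runif(1, 0.01, 0.3),
                           rt_tol = runif(1, 0.5, 10),
                           max_mods = sample(1:5, 1))
    cand <- mine_pair(random_peaklist(80), random_peaklist(80, "ap_treated"),
                      params)
    if (nrow(cand) == 0) next
    expect_true(all(abs(cand$mass_error) <= params$mass_tol))
    expect_true(all(abs(cand$rt_diff) <= params$rt_tol))
    expect_true(all(cand$n_mods >= 1))
    expect_true(all(cand$untreated_mass > cand$treated_mass))
  }
})

test_that("candidate count is monotone in the tolerances", {
  set.seed(7)
  u <- random_peaklist(150)
  t_ <- random_peaklist(150, "ap_treated")
  n_at <- function(mt, rt) nrow(mine_pair(u, t_, miner_params(
    mass_tol = mt, rt_tol = rt)))
  counts_m <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), n_at, numeric(1),
                     rt = 5)
  expect_true(all(diff(counts_m) >= 0))
  counts_r <- vapply(c(0.5, 1, 2, 5, 10), function(r) n_at(0.1, r),
                     numeric(1))
  expect_true(all(diff(counts_r) >= 0))
})

test_that("merge_replicates clusters across replicates and counts support", {
  base <- function(mz, rt, rep, inten = 1e5) data.frame(
    untreated_mz = mz, untreated_charge = 2L,
    untreated_mass = compute_neutral_mass(mz, 2), untreated_rt = rt,
    untreated_intensity = inten, treated_mz = mz - 40,
    treated_mass = compute_neutral_mass(mz, 2) - PHOSPHO_MASS,
    treated_rt = rt, treated_intensity = inten, n_mods = 1L,
    mass_error = 0, rt_diff = 0, replicate = rep)
  mk <- function(df, rep) structure(df, replicate = rep,
                                    condition = "untreated",
                                    class = c("shift_candidates",
                                              "data.frame"))
  # same planted candidate jittered across 3 replicates
  reps <- lapply(1:3, function(r)
    mk(base(812.858 + r * 0.002, 24 + r * 0.1, r), r))
  merged <- merge_replicates(reps, cluster_mz_tol = 0.01,
                             cluster_rt_tol = 2, min_support = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$support, 3L)
  # min_support = 1 on a single replicate is the identity on candidates
  one <- merge_replicates(list(mk(base(600.5, 20, 1), 1)), min_support = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$support, 1L)
  # two candidates far apart in m/z form two clusters
  two <- merge_replicates(list(mk(rbind(base(600.5, 20, 1),
                                        base(600.6, 20, 1)), 1)),
                          cluster_mz_tol = 0.01)
  expect_equal(nrow(two), 2)
  # min_support above replicate count empties the set with a warning
  expect_warning(none <- merge_replicates(reps, min_support = 5),
                 "min_support")
  expect_equal(nrow(none), 0)
})

test_that("raising min_support never increases the merged count", {
  set.seed(21)
  params <- miner_params(top_n = 1000)
  sim <- generate_pairs(synth_config(n_phospho = 15, n_decoys = 60,
                                     n_replicates = 3, seed = 21))
  cands <- lapply(1:3, function(r)
    mine_pair(filter_peaks(sim$untreated[[r]], params),
              filter_peaks(sim$treated[[r]], params), params))
  counts <- vapply(1:3, function(s)
    nrow(merge_replicates(cands, min_support = s)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("candidate tables round-trip through the TSV dialect", {
  d <- demo_pair()
  cand <- merge_replicates(mine_pair(d$u, d$t, miner_params()))
  path <- tempfile(fileext = ".tsv")
  write_candidates(cand, path)
  back <- read_candidates(path)
  expect_equal(back$untreated_mz, cand$untreated_mz, tolerance = 1e-9)
  expect_equal(back$n_mods, cand$n_mods)
  expect_equal(back$support, cand$support)
})
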