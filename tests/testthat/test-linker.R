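# Identification-quantification linking: modification parsing, tolerance
# matching against a brute-force oracle, ratios, ANOVA, and delta scores.

test_that("parse_mod_string extracts phosphosites and ignores other mods", {
  s <- parse_mod_string("DEHLSTLDAYRPK", "pY10")
  expect_equal(s$residue, "Y"); expect_equal(s$position, 10L)
  expect_true(all(s$valid))
  expect_equal(nrow(parse_mod_string("PEPTIDE", "")), 0)
  multi <- parse_mod_string("ATKGSAAPK", "pT2; pS5")
  expect_equal(multi$residue, c("T", "S"))
  expect_equal(multi$position, c(2L, 5L))
  alt <- parse_mod_string("ATKGSAAPK", "Phospho (T2); Oxidation (M3)")
  expect_equal(nrow(alt), 1)
  expect_equal(alt$residue, "T")
  # residue letter disagreeing with the sequence is flagged invalid
  bad <- parse_mod_string("DEHLSTLDAYRPK", "pS10")
  expect_false(bad$valid)
  out_of_range <- parse_mod_string("PEPY", "pY99")
  expect_false(out_of_range$valid)
})

mk_ids <- function(...) {
  annotate_peptide_ids(data.frame(..., stringsAsFactors = FALSE))
}

default_feats <- function(mz, rt, charge,
                          ctrl = list(c(10, 11, 12)),
                          trt = list(c(10, 11, 12))) {
  n <- length(mz)
  df <- data.frame(feature_id = sprintf("F%02d", seq_len(n)), mz = mz,
                   charge = charge, rt = rt, stringsAsFactors = FALSE)
  for (k in 1:3) {
    df[[paste0("c", k)]] <- vapply(ctrl, `[`, numeric(1), k)
    df[[paste0("t", k)]] <- vapply(trt, `[`, numeric(1), k)
  }
  quant_features(df, c(c1 = "control", c2 = "control", c3 = "control",
                       t1 = "treatment", t2 = "treatment",
                       t3 = "treatment"))
}

test_that("link matches within tolerances and computes ratio and p-value", {
  ids <- mk_ids(sequence = "DEHLSTLDAYRPK", mod_string = "pY10",
                mz = 812.86, charge = 2L, rt = 24.5, score = 39,
                accession = "ACC1")
  feats <- default_feats(812.858, 23.9, 2L,
                         ctrl = list(c(100, 110, 90)),
                         trt = list(c(10, 11, 9)))
  lk <- link(ids, feats, link_params())
  expect_true(lk$linked)
  expect_equal(abs(lk$mz_diff), 0.002, tolerance = 1e-9)
  expect_equal(abs(lk$rt_diff), 0.6, tolerance = 1e-9)
  expect_equal(lk$ratio, 10, tolerance = 1e-9)
  expect_lt(lk$p_value, 0.05)
})

test_that("zero treatment abundance yields an infinite ratio", {
  ids <- mk_ids(sequence = "DEHLSTLDAYRPK", mod_string = "pY10",
                mz = 812.86, charge = 2L, rt = 24.5, score = 39,
                accession = "ACC1")
  feats <- default_feats(812.858, 24.5, 2L,
                         ctrl = list(c(100, 110, 90)),
                         trt = list(c(0, 0, 0)))
  lk <- link(ids, feats, link_params())
  expect_identical(lk$ratio, Inf)
})

test_that("empty feature tables leave every identification unlinked", {
  ids <- mk_ids(sequence = c("DEHLSTLDAYRPK", "AYKGSAAPK"),
                mod_string = c("pY10", "pY2"), mz = c(812.86, 500.1),
                charge = c(2L, 2L), rt = c(24, 30), score = c(39, 41),
                accession = c("A", "B"))
  feats <- default_feats(numeric(0), numeric(0), integer(0),
                         ctrl = list(), trt = list())
  lk <- link(ids, feats, link_params())
  expect_equal(nrow(lk), 2)
  expect_false(any(lk$linked))
})

test_that("score and phospho-type filters drop identifications", {
  ids <- mk_ids(sequence = c("AYKGSAAPK", "ASKGSAAPK", "AYKGSAAPK"),
                mod_string = c("pY2", "pS2", "pY2"),
                mz = c(500.1, 500.1, 600.1), charge = 2L,
                rt = 30, score = c(40, 40, 10),
                accession = c("A", "B", "C"))
  feats <- default_feats(c(500.1, 600.1), c(30, 30), 2L,
                         ctrl = list(c(1, 1, 1), c(1, 1, 1)),
                         trt = list(c(1, 1, 1), c(1, 1, 1)))
  lk <- link(ids, feats, link_params(phospho_filter = "pTyr",
                                     min_score = 25))
  expect_equal(nrow(lk), 1)  # pSer-only and low-score ids removed
  expect_equal(lk$accession, "A")
})

test_that("pTyr filter excludes ids whose sites are all S/T", {
  set.seed(17)
  ids <- random_ids(120)
  feats <- random_features(5)  # mostly unlinked; filtering is the point
  lk <- link(ids, feats, link_params(min_score = 0,
                                     phospho_filter = "pTyr"))
  res <- sub("^p([STY]).*", "\\1", ids$phospho_sites)
  expect_equal(nrow(lk), sum(res == "Y"))
})

test_that("link assignment equals the all-pairs oracle", {
  set.seed(23)
  for (rep in 1:6) {
    n_ids <- sample(c(50, 200, 500), 1)
    n_feat <- sample(c(50, 200, 500), 1)
    ids <- random_ids(n_ids)
    feats <- random_features(n_feat)
    params <- link_params(mz_tol = runif(1, 0.05, 0.5),
                          rt_tol = runif(1, 0.5, 5),
                          min_score = 0,
                          phospho_filter = c("pSer", "pThr", "pTyr"),
                          require_charge_match = rep %% 2 == 0)
    lk <- link(ids, feats, params)
    want <- oracle_link_assignment(ids, feats, params)
    got <- match(lk$feature_id, feats$feature_id)
    expect_equal(got, unname(want))
  }
})

test_that("linked count is monotone in tolerances and min_score", {
  set.seed(31)
  ids <- random_ids(200)
  feats <- random_features(200)
  n_at <- function(mz_tol, rt_tol, min_score)
    sum(link(ids, feats, link_params(
      mz_tol = mz_tol, rt_tol = rt_tol, min_score = min_score,
      phospho_filter = c("pSer", "pThr", "pTyr")))$linked)
  expect_true(all(diff(vapply(c(0.05, 0.1, 0.3, 0.6),
                              n_at, numeric(1), rt_tol = 2,
                              min_score = 0)) >= 0))
  expect_true(all(diff(vapply(c(0.5, 1, 2, 4),
                              function(r) n_at(0.2, r, 0),
                              numeric(1))) >= 0))
  expect_true(all(diff(vapply(c(0, 20, 40, 60),
                              function(s) n_at(0.2, 2, s),
                              numeric(1))) <= 0))
})

test_that("md_score follows the top-two definition", {
  expect_equal(md_score(c(39, 20)), 19)
  expect_equal(md_score(30), 30)        # single-candidate convention
  expect_equal(md_score(c(10, 10)), 0)
  expect_equal(md_score(c(20, 39, 5)), md_score(c(39, 5, 20))) # order-free
  expect_error(md_score(numeric(0)), "at least one")
  set.seed(2)
  for (i in 1:20) expect_gte(md_score(runif(sample(1:6, 1), 0, 60)), 0)
})

test_that("md_score_table groups alternative placements by sequence", {
  ids <- mk_ids(sequence = c("AYKGSAAPK", "AYKGSAAPK", "ASKGSAAPK"),
                mod_string = c("pY2", "pS5", "pS2"),
                mz = 500, charge = 2L, rt = 30,
                score = c(39, 20, 33), accession = "X")
  tab <- md_score_table(ids)
  expect_equal(tab$md_score[tab$sequence == "AYKGSAAPK"], 19)
  expect_equal(tab$md_score[tab$sequence == "ASKGSAAPK"], 33)
})

test_that("summarize_linked flags planted differences and not null ones", {
  ids <- mk_ids(sequence = c("AYKGSAAPK", "CYKGAAAPK"),
                mod_string = c("pY2", "pY2"),
                mz = c(500.1, 600.1), charge = 2L, rt = 30,
                score = 40, accession = c("FLAT", "TENX"))
  set.seed(12)
  feats <- default_feats(c(500.1, 600.1), c(30, 30), 2L,
                         ctrl = list(c(5, 5, 5),
                                     100 * exp(rnorm(3, 0, 0.05))),
                         trt = list(c(5, 5, 5),
                                    10 * exp(rnorm(3, 0, 0.05))))
  tab <- summarize_linked(link(ids, feats, link_params()), alpha = 0.05)
  expect_false(tab$differential[tab$accession == "FLAT"])
  expect_true(tab$differential[tab$accession == "TENX"])
  expect_equal(tab$accession[1], "TENX")  # sorted by ratio descending
  empty <- summarize_linked(link(mk_ids(
    sequence = character(0), mod_string = character(0), mz = numeric(0),
    charge = integer(0), rt = numeric(0), score = numeric(0),
    accession = character(0)), feats, link_params()))
  expect_equal(nrow(empty), 0)
})

test_that("csv readers reconstruct ids and features with remapped columns", {
  idp <- tempfile(fileext = ".csv")
  write.csv(data.frame(pep_seq = "AYKGSAAPK", mods = "pY2", obs_mz = 500.1,
                       z = 2, ret = 30, ion_score = 40, prot = "P1"),
            idp, row.names = FALSE)
  ids <- read_peptide_ids(idp, columns = c(
    sequence = "pep_seq", mod_string = "mods", mz = "obs_mz", charge = "z",
    rt = "ret", score = "ion_score", accession = "prot"))
  expect_equal(ids$phospho_sites, "pY2")
  qp <- tempfile(fileext = ".csv")
  write.csv(data.frame(feature_id = "F1", mz = 500.1, charge = 2, rt = 30,
                       a = 1, b = 2), qp, row.names = FALSE)
  feats <- read_quant_features(qp, c(a = "control", b = "treatment"))
  expect_s3_class(feats, "quant_features")
  expect_error(read_quant_features(qp, c(a = "control", zz = "treatment")),
               "absent")
  expect_error(quant_features(data.frame(feature_id = "F1", mz = 1,
                                         charge = 2, rt = 1, a = 1),
                              c(a = "control")), "two conditions")
})
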