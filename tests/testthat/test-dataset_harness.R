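# Mutation tables, ddG ground truth, splits and metrics.

write_skempi_fixture <- function(path = tempfile(fileext = ".csv")) {
  lines <- c(
    paste("#Pdb", "Mutation(s)_cleaned", "Affinity_wt_parsed",
          "Affinity_mut_parsed", "Temperature", "Method", "Hold_out_type",
          sep = ";"),
    "1ABC_A_B;KI38A;1e-9;1e-8;298;ITC;Pr/PI",
    "1ABC_A_B;KI38A,TI40A;1e-9;1e-7;298;ITC;Pr/PI",     # multi-point
    "1ABC_A_B;RA12G;1e-9;1e-8;298;IASP;AB/AG",           # disallowed method
    "2XYZ_C_D;LC7W;2e-8;4e-8;310;SPR;TCR/pMHC",
    "2XYZ_C_D;LC7W;2e-8;8e-8;310;SPR;TCR/pMHC",          # replicate
    "3DEF_E_F;GE5F;1e-6;;298;FL;Pr/PI"                   # missing affinity
  )
  writeLines(lines, path)
  path
}

test_that("ddG from affinities matches the closed form", {
  expect_equal(ddg_from_affinities(1e-9, 1e-9), 0)
  rtln10 <- 1.9872e-3 * 298 * log(10)
  expect_equal(ddg_from_affinities(1e-9, 1e-8, 298), rtln10,
               tolerance = 1e-10)
  expect_equal(rtln10, 1.364, tolerance = 1e-3)
  # antisymmetry and linearity in T
  expect_equal(ddg_from_affinities(1e-8, 1e-9), -rtln10)
  expect_equal(ddg_from_affinities(1e-9, 1e-8, 596),
               2 * ddg_from_affinities(1e-9, 1e-8, 298))
  expect_error(ddg_from_affinities(-1e-9, 1e-8), "positive")
})

test_that("SKEMPI-style filtering keeps only reliable single points", {
  recs <- parse_skempi(write_skempi_fixture())
  # 1 single-point ITC + the aggregated SPR replicate pair
  expect_equal(nrow(recs), 2)
  log <- attr(recs, "log")
  expect_equal(sum(!log$kept), 3)  # multi-point, bad method, bad affinity
  expect_true(any(grepl("multi-point", log$reason)))
  expect_true(any(grepl("method", log$reason)))
  expect_true(any(grepl("affinity", log$reason)))

  k <- recs[recs$pdb == "1ABC", ]
  expect_equal(k$wt, "K"); expect_equal(k$chain, "I")
  expect_equal(k$resno, 38); expect_equal(k$mut, "A")
  expect_equal(k$ddg, ddg_from_affinities(1e-9, 1e-8, 298))

  rep2 <- recs[recs$pdb == "2XYZ", ]
  expect_equal(rep2$n_replicates, 2)
  d1 <- ddg_from_affinities(2e-8, 4e-8, 310)
  d2 <- ddg_from_affinities(2e-8, 8e-8, 310)
  expect_equal(rep2$ddg, median(c(d1, d2)))
  expect_equal(rep2$function_class, "TCR/pMHC")
})

test_that("split plans partition records as promised", {
  recs <- data.frame(complex_id = rep(paste0("cx", 1:6), each = 5),
                     ddg = rnorm(30))
  cb <- make_split(recs, "complex", holdout_fraction = 0.34, seed = 3)
  expect_length(intersect(recs$complex_id[cb$in_test],
                          recs$complex_id[!cb$in_test]), 0)
  mb <- make_split(recs, "mutation", k = 10, seed = 3)
  expect_equal(sort(unique(mb$fold)), 1:10)
  expect_equal(length(mb$fold), nrow(recs))  # every record in one fold
  # determinism
  expect_identical(
    make_split(recs, "complex", holdout_fraction = 0.34,
               seed = 3)$test_complexes,
    cb$test_complexes)
  expect_error(make_split(recs[1:5, ], "complex"), "at least 2")
})

test_that("sequence-identity filtering removes near-duplicate complexes", {
  recs <- data.frame(complex_id = rep(c("cx1", "cx2", "cx3", "tst"),
                                      each = 2),
                     ddg = rnorm(8))
  cx <- c("cx1", "cx2", "cx3", "tst")
  idm <- matrix(0.1, 4, 4, dimnames = list(cx, cx))
  diag(idm) <- 1
  idm["cx2", "tst"] <- idm["tst", "cx2"] <- 0.8  # near-duplicate
  out <- filter_by_identity(recs, idm, "tst", cutoff = 0.3)
  expect_setequal(unique(out$complex_id), c("cx1", "cx3"))
  expect_error(filter_by_identity(recs, idm[1:3, 1:3], "tst"), "lacks")
})

test_that("PCC/RMSE match the hand-derived example and an oracle", {
  ev <- evaluate_predictions(c(0, 1, 2), c(0, 1, 2))
  expect_equal(ev$overall$pcc, 1)
  expect_equal(ev$overall$rmse, 0)
  expect_equal(evaluate_predictions(c(0, -1, -2) * 2 + 3,
                                    c(0, 1, 2))$overall$pcc, -1)
  ev2 <- evaluate_predictions(c(0, 1, 4), c(0, 1, 2))
  expect_equal(ev2$overall$rmse, sqrt(4 / 3), tolerance = 1e-12)
  # two-pass formula oracle
  pcc_oracle <- function(p, t) {
    mp <- mean(p); mt <- mean(t)
    sum((p - mp) * (t - mt)) /
      sqrt(sum((p - mp)^2) * sum((t - mt)^2))
  }
  expect_equal(ev2$overall$pcc, pcc_oracle(c(0, 1, 4), c(0, 1, 2)),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    p <- rnorm(50); t <- rnorm(50)
    ev <- evaluate_predictions(p, t)
    expect_equal(ev$overall$pcc, pcc_oracle(p, t), tolerance = 1e-10)
    expect_equal(ev$overall$rmse, sqrt(sum((p - t)^2) / 50),
                 tolerance = 1e-10)
  }
  expect_error(evaluate_predictions(1:3, 1:4), "length")
})

test_that("strata with fewer than 2 points are reported, not dropped", {
  ev <- evaluate_predictions(c(1, 2, 3, 9), c(1, 2, 3, 4),
                             strata = c("COR", "COR", "COR", "RIM"))
  tab <- ev$by_stratum
  expect_setequal(tab$stratum, c("COR", "RIM"))
  expect_true(is.na(tab$pcc[tab$stratum == "RIM"]))
  expect_equal(tab$n[tab$stratum == "RIM"], 1)
  expect_equal(tab$pcc[tab$stratum == "COR"], 1)
})

test_that("predictions export as a readable TSV", {
  recs <- parse_skempi(write_skempi_fixture())
  f <- tempfile(fileext = ".tsv")
  write_predictions(recs, c(0.5, -0.2), f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$predicted_ddg, c(0.5, -0.2))
  expect_equal(tab$truth_ddg, recs$ddg)
})
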