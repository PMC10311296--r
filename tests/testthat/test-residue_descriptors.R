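# Circular variance, amino-acid classes, size change, score files and the
# encoded auxiliary vector.

test_that("circular variance matches its closed forms", {
  expect_equal(circular_variance(c(0, 0, 0), rbind(c(2, 0, 0))), 0)
  expect_equal(circular_variance(c(0, 0, 0),
                                 rbind(c(1, 0, 0), c(-3, 0, 0))), 1)
  expect_error(circular_variance(c(0, 0, 0),
                                 matrix(numeric(0), ncol = 3)), "neighbour")
})

test_that("uniform spherical neighbourhoods give CV near 1", {
  set.seed(5)
  pts <- matrix(rnorm(3000), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * 8
  cv <- circular_variance(c(0, 0, 0), pts)
  expect_equal(cv, 1, tolerance = 0.05)
})

test_that("circular variance is invariant to rigid motion and permutation", {
  set.seed(6)
  nb <- matrix(rnorm(60), ncol = 3)
  ctr <- c(1, 2, 3)
  cv <- circular_variance(ctr, nb)
  R <- random_rotation(7); t <- c(-4, 2, 9)
  nb2 <- t(R %*% t(nb)) + matrix(t, nrow(nb), 3, byrow = TRUE)
  expect_equal(circular_variance(as.numeric(R %*% ctr + t), nb2), cv,
               tolerance = 1e-10)
  expect_equal(circular_variance(ctr, nb[sample(nrow(nb)), ]), cv)
})

test_that("the seven amino-acid classes partition the 20 residues", {
  expect_equal(as.character(amino_class("F")), "ARO")
  expect_equal(as.character(amino_class("G")), "GLY")
  all20 <- sort(unname(aa_three_to_one()))
  cls <- amino_class(all20)
  expect_false(anyNA(cls))
  sizes <- as.numeric(table(cls))
  expect_equal(sizes, c(4, 4, 4, 2, 4, 1, 1))
  expect_equal(sum(sizes), 20)
  expect_error(amino_class("Z"), "unknown")
})

test_that("size-change classes follow the volume difference", {
  expect_equal(as.character(size_change_class("L", "L")), "size-neutral")
  expect_equal(as.character(size_change_class("G", "W")), "small-to-large")
  expect_equal(as.character(size_change_class("W", "G")), "large-to-small")
  # antisymmetry over all ordered pairs
  aa <- names(residue_volume_reference())
  pairs <- expand.grid(wt = aa, mut = aa, stringsAsFactors = FALSE)
  fwd <- size_change_class(pairs$wt, pairs$mut)
  rev <- size_change_class(pairs$mut, pairs$wt)
  swap <- c(`size-neutral` = "size-neutral",
            `small-to-large` = "large-to-small",
            `large-to-small` = "small-to-large")
  expect_identical(as.character(rev), unname(swap[as.character(fwd)]))
})

test_that("conservation and substitution-score files parse strictly", {
  f <- tempfile()
  writeLines(c("chain resno tjet", "A 25 0.8", "B 3 0.1"), f)
  tj <- load_conservation(f)
  expect_equal(unname(tj[residue_key("A", 25)]), 0.8)

  g <- tempfile()
  writeLines(c("chain resno mut score", "A 25 W -3.1"), g)
  gs <- load_gemme(g)
  expect_equal(unname(gs[paste(residue_key("A", 25), "W", sep = "|")]), -3.1)

  bad <- tempfile()
  writeLines(c("chain resno tjet", "A 25 0.8", "A 25 0.3"), bad)
  expect_error(load_conservation(bad), "conflicting")

  hdr <- tempfile()
  writeLines(c("chain resno value", "A 25 0.8"), hdr)
  expect_error(load_conservation(hdr), "lacks column")
})

test_that("score lookup fails loudly listing every missing key", {
  f <- tempfile()
  writeLines(c("chain resno mut score", "A 25 W -3.1", "A 26 G 0.4"), f)
  gs <- load_gemme(f)
  keys <- paste(residue_key(c("A", "A"), c(25, 26)), c("W", "G"),
                sep = "|")
  expect_equal(lookup_scores(gs, keys), c(-3.1, 0.4))
  bad <- paste(residue_key(c("A", "B"), c(25, 99)), c("W", "F"),
               sep = "|")
  expect_error(lookup_scores(gs, bad), "B\\|99\\|\\|F")
})

test_that("the encoded auxiliary vector has the documented layout", {
  v <- assemble_aux(0.8, 0.3, 0.5, "COR", -1.2)
  expect_length(v, 9)
  expect_equal(unname(v[4:8]), c(0, 0, 0, 1, 0))  # (INT,SUR,SUP,COR,RIM)
  expect_equal(unname(v[c(1, 2, 3, 9)]), c(0.8, 0.3, 0.5, -1.2))
  # ablations zero scalars but keep the length
  v_sr <- assemble_aux(0.8, 0.3, 0.5, "COR", -1.2, config = "SR")
  expect_length(v_sr, 9)
  expect_equal(unname(v_sr[c(1, 2, 3, 9)]), c(0, 0, 0, 0))
  expect_equal(unname(v_sr[4:8]), unname(v[4:8]))
  v_tj <- assemble_aux(0.8, 0.3, 0.5, "COR", -1.2, config = "SR-Tjet")
  expect_equal(unname(v_tj[c(1, 9)]), c(0.8, 0))
  v_ge <- assemble_aux(0.8, 0.3, 0.5, "COR", -1.2, config = "SR-GEMME")
  expect_equal(unname(v_ge[c(1, 9)]), c(0, -1.2))
  expect_error(assemble_aux(NA, 0.3, 0.5, "COR", -1.2), "t_jet")
  expect_error(assemble_aux(0.8, 0.3, 0.5, "XXX", -1.2), "region")
})

test_that("auxiliary scalars min-max scale over the training rows", {
  aux <- rbind(assemble_aux(0.2, -1, 0.1, "SUP", -4),
               assemble_aux(0.8, 1, 0.9, "RIM", 2))
  sc <- scale_aux(aux)
  expect_equal(unname(sc$scaled[, 1]), c(0, 1))
  expect_equal(unname(sc$scaled[, 9]), c(0, 1))
  expect_equal(sc$scaled[, 4:8], aux[, 4:8])  # one-hot untouched
  # stored ranges apply to new data
  new <- scale_aux(rbind(assemble_aux(0.5, 0, 0.5, "COR", -1)),
                   ranges = sc$ranges)
  expect_equal(unname(new$scaled[1, 1]), 0.5)
})

test_that("per-residue CV separates exposed from enclosed residues", {
  st <- toy_complex(1)
  cv <- residue_circular_variance(st)
  expect_true(all(cv[!is.na(cv)] >= 0 & cv[!is.na(cv)] <= 1))
  expect_gt(sum(!is.na(cv)), 0)
})
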