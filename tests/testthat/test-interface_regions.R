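# Solvent accessibility and the five-region interface classification.

# Independent brute-force reading of the five-case decision table, written
# directly from its definition (burial: does rASA drop upon binding?).
region_oracle <- function(rc, rf, theta = 0.25) {
  if (rf <= rc) {                 # no burial
    if (rc < theta) "INT" else "SUR"
  } else if (rf < theta) {
    "SUP"
  } else if (rc < theta) {
    "COR"
  } else {
    "RIM"
  }
}

test_that("classify_region matches the spot cases of the decision table", {
  expect_equal(as.character(classify_region(0.50, 0.50)), "SUR")
  expect_equal(as.character(classify_region(0.05, 0.10)), "SUP")
  expect_equal(as.character(classify_region(0.10, 0.40)), "COR")
  expect_equal(as.character(classify_region(0.30, 0.50)), "RIM")
  expect_equal(as.character(classify_region(0.05, 0.05)), "INT")
})

test_that("classify_region agrees with the brute-force table on a dense grid", {
  g <- seq(0, 1, by = 0.01)
  grid <- expand.grid(rc = g, rf = g)
  got <- as.character(classify_region(grid$rc, grid$rf))
  want <- mapply(region_oracle, grid$rc, grid$rf)
  expect_identical(got, unname(want))
})

test_that("separated partners have no occlusion and no interface", {
  st <- make_toy_complex(gap = 100, seed = 2)
  acc <- compute_accessibility(st)
  expect_true(all(acc$asa_free - acc$asa_complex < 0.1))
  expect_warning(ir <- interface_residues(acc), "no interfacial")
  expect_equal(nrow(ir), 0)
})

test_that("free-state accessibility is never below the bound state", {
  st <- toy_complex(4)
  acc <- compute_accessibility(st)
  expect_true(all(acc$asa_free >= acc$asa_complex - 1e-6))
  expect_true(all(acc$asa_complex > 0 | acc$rasa_complex == 0))
})

test_that("a residue enclosed in a synthetic atom shell is buried", {
  # chain A: one ALA; chain B: a tight shell of carbon atoms around it
  tmpl <- voxddg:::.residue_template("ALA", 1)
  shell <- voxddg:::fibonacci_sphere(400) * 5.5
  atoms <- rbind(
    data.frame(chain = "A", resno = 1L, insert = "", resid = "ALA",
               elety = rownames(tmpl), elesy = substr(rownames(tmpl), 1, 1),
               x = tmpl[, 1], y = tmpl[, 2], z = tmpl[, 3], partner = 1L,
               stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = seq_len(nrow(shell)), insert = "",
               resid = "GLY", elety = "CA", elesy = "C",
               x = shell[, 1], y = shell[, 2] + 0.5, z = shell[, 3],
               partner = 2L, stringsAsFactors = FALSE)
  )
  st <- voxddg:::new_ppi_structure(atoms, "A", "B")
  acc <- compute_accessibility(st)
  ala <- acc[acc$chain == "A", ]
  expect_lt(ala$rasa_complex, 0.01)
  expect_gt(ala$rasa_free, 0.5)  # alone it is fully exposed
})

test_that("the constructed contact patch is recovered exactly", {
  st <- toy_complex(1)
  acc <- assign_regions(compute_accessibility(st))
  ir <- acc[acc$region %in% c("SUP", "COR", "RIM"), ]
  expect_setequal(ir$key, attr(st, "patch_keys"))
  # every residue receives exactly one label
  expect_false(anyNA(acc$region))
  expect_equal(nrow(acc), length(unique(acc$key)))
})

test_that("the region table round-trips through its TSV export", {
  st <- toy_complex(1)
  acc <- assign_regions(compute_accessibility(st))
  f <- tempfile(fileext = ".tsv")
  write_region_table(acc, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(acc))
  expect_equal(as.character(tab$region), as.character(acc$region))
})
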