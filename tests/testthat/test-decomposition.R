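# Component algebra, table IO, consistency checking, and the WCA split.

test_that("compose reproduces hand-computed totals from the packaged table", {
  tab <- load_component_table(fixture_table_path())
  sums <- compose(tab)
  # rows whose components sum exactly to the printed total
  exact <- c(Pyrene = -4.67, Anthracene = -3.65, Biphenyl = -2.29,
             Fluorene = -3.01)
  for (nm in names(exact)) {
    expect_equal(sums$dA_hyd[tab$name == nm], exact[[nm]], tolerance = 1e-12)
  }
  # benzene's independently rounded components recompose to -1.13,
  # 0.01 away from the printed -1.14
  expect_equal(sums$dA_hyd[tab$name == "Benzene"], -1.13, tolerance = 1e-12)
  expect_lt(abs(sums$dA_hyd[tab$name == "Benzene"] - (-1.14)), 0.015)

  zero <- solute_table("null", 0, 0, 0, 0)
  expect_equal(unlist(compose(zero)[, c("dA_wat", "dA_non_es", "dA_hyd")]),
               c(dA_wat = 0, dA_non_es = 0, dA_hyd = 0))
})

test_that("compose obeys its arithmetic identities and is linear in scaling", {
  set.seed(7)
  tab <- solute_table(sprintf("s%d", 1:20), rnorm(20), rnorm(20), rnorm(20),
                      rnorm(20))
  sums <- compose(tab)
  expect_equal(sums$dA_wat, tab$dA_es + tab$dA_disp + tab$dA_cav)
  expect_equal(sums$dA_non_es, tab$dA_disp + tab$dA_cav)
  expect_equal(sums$dA_hyd, tab$e_reorg + sums$dA_wat)
  for (c_scale in c(-2, 0.5, 3)) {
    scaled <- tab
    for (f in c("e_reorg", "dA_es", "dA_disp", "dA_cav")) {
      scaled[[f]] <- c_scale * tab[[f]]
    }
    expect_equal(compose(scaled)$dA_hyd, c_scale * sums$dA_hyd)
  }
})

test_that("component table loader enforces the schema", {
  tab <- load_component_table(fixture_table_path())
  expect_equal(nrow(tab), 8)
  expect_equal(tab$name[1], "Benzene")
  expect_equal(tab$name[8], "Anthracene")

  dir <- withr::local_tempdir()
  # empty data section -> empty table with a warning
  empty <- file.path(dir, "empty.csv")
  writeLines("name,dA_hyd,e_reorg,dA_es,dA_disp,dA_cav", empty)
  expect_warning(out <- load_component_table(empty), "no data rows")
  expect_equal(nrow(out), 0)

  dup <- file.path(dir, "dup.csv")
  writeLines(c("name,dA_hyd,e_reorg,dA_es,dA_disp,dA_cav",
               "A,-1,0.3,-1,-9,9", "A,-2,0.4,-2,-10,10"), dup)
  expect_error(load_component_table(dup), "duplicate")

  bad <- file.path(dir, "bad.csv")
  writeLines(c("name,dA_hyd,e_reorg,dA_es,dA_disp,dA_cav",
               "A,-1,0.3,-1,-9,9", "B,-2,0.4,oops,-10,10"), bad)
  expect_error(load_component_table(bad), "row 2")

  miss <- file.path(dir, "miss.csv")
  writeLines(c("name,dA_hyd,e_reorg,dA_es,dA_disp,dA_cav",
               "A,-1,0.3,-1,-9,", "B,-2,0.4,-2,-10,10"), miss)
  expect_error(load_component_table(miss), "dA_cav.*row 1")

  nohdr <- file.path(dir, "nohdr.csv")
  writeLines(c("solute,total", "A,-1"), nohdr)
  expect_error(load_component_table(nohdr), "header lacks")
})

test_that("Unicode minus signs are normalized on read", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "uminus.csv")
  writeLines(c("name,dA_hyd,e_reorg,dA_es,dA_disp,dA_cav",
               "Pyrene,−4.67,0.82,−3.02,−19.70,17.23"), f,
             useBytes = FALSE)
  tab <- load_component_table(f)
  expect_equal(tab$dA_es, -3.02)
  expect_equal(compose(tab)$dA_hyd, -4.67, tolerance = 1e-12)
})

test_that("component tables round-trip through write and load", {
  tab <- load_component_table(fixture_table_path())
  f <- withr::local_tempfile(fileext = ".csv")
  write_component_table(tab, f)
  back <- load_component_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("consistency check flags only deviations above tolerance", {
  tab <- load_component_table(fixture_table_path())
  rep <- check_consistency(tab, tol = 0.015)
  expect_equal(sum(rep$flagged), 0)
  expect_lt(max(rep$deviation), 0.0101)

  strict <- check_consistency(tab, tol = 0.005)
  expect_setequal(strict$name[strict$flagged],
                  c("Benzene", "Toluene", "Naphthalene", "Phenanthrene"))

  exact <- solute_table("x", 0.5, -1, -9, 9, dA_hyd = -0.5)
  expect_equal(check_consistency(exact)$deviation, 0)

  mixed <- solute_table(c("a", "b"), c(0.5, 0.5), c(-1, -1), c(-9, -9),
                        c(9, 9), dA_hyd = c(-0.5, NA))
  expect_warning(out <- check_consistency(mixed), "skipping 1")
  expect_equal(nrow(out), 1)
})

test_that("WCA split satisfies its defining identities", {
  eps <- 0.25; sig <- 3.4
  r_min <- 2^(1 / 6) * sig

  at_min <- wca_split(r_min, eps, sig)
  expect_equal(at_min$u_repulsive, 0, tolerance = 1e-12)
  expect_equal(at_min$u_attractive, -eps, tolerance = 1e-12)

  at_sigma <- wca_split(sig, eps, sig)
  expect_equal(at_sigma$u_lj, 0, tolerance = 1e-12)
  expect_equal(at_sigma$u_repulsive, eps, tolerance = 1e-12)
  expect_equal(at_sigma$u_attractive, -eps, tolerance = 1e-12)

  r <- seq(0.8 * sig, 3 * sig, length.out = 2000)
  sweep <- wca_split(r, eps, sig)
  expect_equal(sweep$u_repulsive + sweep$u_attractive, sweep$u_lj,
               tolerance = 1e-12)
  expect_true(all(sweep$u_repulsive >= 0))
  expect_true(all(diff(sweep$u_repulsive) <= 1e-12))
  expect_true(all(sweep$u_attractive >= -eps - 1e-12))

  expect_error(wca_split(0, eps, sig), "positive")
  expect_error(wca_split(-1, eps, sig), "positive")
})
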