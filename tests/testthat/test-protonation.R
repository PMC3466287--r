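# independent route to the same physics: logistic function evaluation
logistic_charge <- function(class, pKa, pH) {
  acid <- class %in% c("ASP", "GLU", "CTERM", "TYR", "CYS")
  ifelse(acid,
         -stats::plogis(log(10) * (pH - pKa)),
         +stats::plogis(log(10) * (pKa - pH)))
}

test_that("titration charges match an independent logistic evaluation", {
  set.seed(11)
  classes <- c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG",
               "NTERM", "CTERM")
  cls <- sample(classes, 200, replace = TRUE)
  pKa <- runif(200, 0, 14)
  pH <- runif(200, 0, 14)
  expect_equal(titration_charge(cls, pKa, pH),
               logistic_charge(cls, pKa, pH), tolerance = 1e-12)

  # midpoint of titration
  expect_equal(titration_charge("GLU", 4.5, 4.5), -0.5)
  expect_equal(titration_charge("ARG", 12.5, 12.5), +0.5)
  # direct evaluations
  expect_equal(titration_charge("LYS", 10.5, 7.4), 0.999206, tolerance = 1e-5)
  expect_equal(titration_charge("ASP", 3.8, 7.4), -0.99975, tolerance = 1e-5)

  expect_error(titration_charge("UNK", 7, 7), "unknown site class",
               class = "nanofet_input_error")
  expect_error(titration_charge("ASP", NaN, 7), class = "nanofet_input_error")
})

test_that("site charges are bounded, monotone in pH, and symmetric", {
  set.seed(12)
  for (cls in c("ASP", "LYS", "HIS", "CTERM", "NTERM")) {
    pKa <- runif(1, 2, 12)
    grid <- sort(runif(50, 0, 14))
    q <- titration_charge(rep(cls, 50), pKa, grid)
    expect_true(all(abs(q) < 1))
    expect_true(all(diff(q) <= 0))  # charge never increases with pH
  }
  # limits
  expect_equal(titration_charge("ASP", 3.8, 0), 0, tolerance = 1e-3)
  expect_equal(titration_charge("LYS", 10.5, 0), 1, tolerance = 1e-3)
  expect_equal(titration_charge("ASP", 3.8, 14), -1, tolerance = 1e-3)
  # acid(pKa, pH) = -base(pKa', pH') when pKa - pH = pH' - pKa'
  set.seed(13)
  for (i in 1:20) {
    pKa <- runif(1, 0, 14); pH <- runif(1, 0, 14)
    delta <- pKa - pH
    pKa2 <- runif(1, 0, 14); pH2 <- pKa2 + delta
    expect_equal(titration_charge("GLU", pKa, pH),
                 -titration_charge("LYS", pKa2, pH2), tolerance = 1e-12)
  }
})

test_that("charge assignment covers residues and termini", {
  pep <- build_peptide("KKAAAAAAAADD")
  dist <- assign_charges(pep, pH = 7.4)
  expect_equal(nrow(dist), 6L)

  # net charge equals the independent per-site logistic sum
  tbl <- default_pka_table()
  pk <- setNames(tbl$pKa, tbl$class)
  expected <- sum(logistic_charge(c("LYS", "LYS", "ASP", "ASP",
                                    "NTERM", "CTERM"),
                                  pk[c("LYS", "LYS", "ASP", "ASP",
                                       "NTERM", "CTERM")], 7.4))
  expect_equal(net_charge(dist), expected, tolerance = 1e-12)
  expect_equal(net_charge(dist), -0.20178, tolerance = 1e-4)

  # acid/base limits at extreme pH
  low <- assign_charges(pep, pH = 0)
  expect_true(all(abs(low$charge[low$class %in% c("ASP", "CTERM")]) < 0.01))
  expect_true(all(low$charge[low$class %in% c("LYS", "NTERM")] > 0.99))

  # Lys site sits on the terminal side-chain nitrogen
  nz <- pep[pep$atom == "NZ" & pep$resno == 1L, ]
  lys1 <- dist[dist$class == "LYS" & dist$resno == 1L, ]
  expect_equal(c(lys1$x_nm, lys1$y_nm, lys1$z_nm),
               c(nz$x, nz$y, nz$z) / 10)
  # Asp site is the carboxylate midpoint
  od <- pep[pep$atom %in% c("OD1", "OD2") & pep$resno == 11L, ]
  asp11 <- dist[dist$class == "ASP" & dist$resno == 11L, ]
  expect_equal(asp11$x_nm, mean(od$x) / 10)

  # only termini on a non-titratable chain
  expect_equal(nrow(assign_charges(build_peptide("AAAA"))), 2L)

  # a missing class in the pKa table is an error
  expect_error(assign_charges(pep, pka_table = default_pka_table()[1:2, ]),
               "lacks class", class = "nanofet_input_error")
  expect_error(assign_charges(pep, pH = 15), class = "nanofet_input_error")
})

test_that("per-site pKa files override the null model", {
  pep <- build_peptide("KKAAAAAAAADD")
  f <- withr::local_tempfile(fileext = ".pka")
  writeLines(c("# structure-based predictions",
               "ASP 11 A 3.65",
               "LYS 1 A 10.20",
               "N+ 1 A 7.70"), f)
  site_pka <- read_pka_file(f)
  expect_equal(nrow(site_pka), 3L)
  expect_equal(site_pka$class[3], "NTERM")

  dist <- assign_charges(pep, pH = 7.4, site_pka = site_pka)
  expect_equal(dist$pKa[dist$class == "ASP" & dist$resno == 11], 3.65)
  expect_equal(dist$pKa[dist$class == "LYS" & dist$resno == 1], 10.20)
  expect_equal(dist$pKa[dist$class == "NTERM"], 7.70)
  # untouched sites keep the null model
  expect_equal(dist$pKa[dist$class == "ASP" & dist$resno == 12], 3.80)

  # malformed line reported with its number
  bad <- withr::local_tempfile()
  writeLines(c("ASP 11 A 3.65", "GLU eleven A"), bad)
  expect_error(read_pka_file(bad), "line 2", class = "nanofet_parse_error")

  # duplicate entries: last one wins, with a warning
  dup <- withr::local_tempfile()
  writeLines(c("ASP 11 A 3.65", "ASP 11 A 4.00"), dup)
  expect_warning(tbl <- read_pka_file(dup), "duplicate")
  expect_equal(tbl$pKa, 4.00)

  # empty file: empty map, assignment falls back to the null model
  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_equal(nrow(read_pka_file(empty)), 0L)
  d2 <- assign_charges(pep, site_pka = read_pka_file(empty))
  expect_equal(net_charge(d2), net_charge(assign_charges(pep)))
})
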