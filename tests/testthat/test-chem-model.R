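test_that("element property lookups return the tabulated constants", {
  expect_equal(element_property("F", "electronegativity"), 3.98)
  expect_equal(element_property("H", "vdw_radius"), 1.20)
  expect_equal(element_property("C", "mass"), 12.011)
  expect_equal(element_property(c("H", "S"), "vdw_radius"), c(1.20, 1.80))
  expect_error(element_property("Xx", "mass"), "unsupported.*Xx")
  tab <- element_table()
  expect_true(all(tab$electronegativity >= 0.7 &
                    tab$electronegativity <= 4.0))
  expect_true(all(tab$vdw_radius > 0) && all(tab$atomic_mass > 0))
  expect_setequal(tab$symbol, c("H", "C", "N", "O", "F", "S", "Cl", "Br"))
})

test_that("formula weights match hand sums", {
  expect_equal(formula_weight("H2O"), 2 * 1.008 + 15.999)
  # sulfentrazone, C11H10Cl2F2N4O3S
  hand <- 11 * 12.011 + 10 * 1.008 + 2 * 35.45 + 2 * 18.998 +
    4 * 14.007 + 3 * 15.999 + 32.06
  expect_equal(formula_weight("C11H10Cl2F2N4O3S"), hand)
  expect_equal(round(hand, 2), 387.18)
  expect_error(formula_weight("C2!x"), "cannot parse")
})

test_that("assembled molecules share the scaffold exactly", {
  tpl <- default_template()
  m1 <- assemble_molecule(compound_spec("1", "S", "CH", "H", "H"), tpl)
  sc <- m1$atoms[m1$atoms$scaffold, c("element", "x", "y")]
  expect_identical(sc$x, tpl$scaffold$x)
  expect_identical(sc$y, tpl$scaffold$y)
  # bit-identical core across every dataset compound and proposal
  for (sp in c(ppo_compounds(), ppo_proposals())) {
    m <- assemble_molecule(sp, tpl)
    msc <- m$atoms[m$atoms$scaffold, c("element", "x", "y")]
    expect_identical(msc, sc)
  }
})

test_that("substituent swaps only touch the slot region", {
  tpl <- default_template()
  m1 <- assemble_molecule(compound_spec("1", "S", "CH", "H", "H"), tpl)
  m22 <- assemble_molecule(compound_spec("22", "S", "CH", "Br", "H"), tpl)
  key <- function(m) paste(m$atoms$element, round(m$atoms$x, 9),
                           round(m$atoms$y, 9))
  only1 <- setdiff(key(m1), key(m22))
  only22 <- setdiff(key(m22), key(m1))
  # they differ exactly by the para H vs Br
  expect_equal(length(only1), 1)
  expect_equal(length(only22), 1)
  expect_match(only1, "^H ")
  expect_match(only22, "^Br ")
  # R2 = 3,5-CH3 replaces the 3-H and 5-H with methyls: +2 C, net +4 H
  m_dim <- assemble_molecule(compound_spec("p", "S", "CH", "H", "3,5-CH3"),
                             tpl)
  tab0 <- table(m1$atoms$element)
  tab1 <- table(m_dim$atoms$element)
  expect_equal(tab1[["C"]] - tab0[["C"]], 2)
  expect_equal(tab1[["H"]] - tab0[["H"]], 4)
})

test_that("molecular weight is additive and matches the series", {
  tpl <- default_template()
  m1 <- assemble_molecule(compound_spec("1", "S", "CH", "H", "H"), tpl)
  expect_equal(molecular_weight(m1),
               sum(element_property(m1$atoms$element, "mass")))
  # back-calculated MW of compound 20 from its printed activity pair
  m20 <- assemble_molecule(compound_spec("20", "S", "C", "CF3", "5-CH3"),
                           tpl)
  implied <- 0.033 / 1000 * 10^7.03
  expect_lt(abs(molecular_weight(m20) - implied) / implied, 0.012)
})

test_that("ic50 to pic50 conversion is correct and monotone", {
  expect_equal(round(ic50_to_pic50(0.078, 387.18), 2), 6.70)
  expect_equal(ic50_to_pic50(1000 * 250, 250), 0)
  expect_gt(ic50_to_pic50(0.01, 300), ic50_to_pic50(0.02, 300))
  expect_error(ic50_to_pic50(-1, 300), "ic50")
  expect_error(ic50_to_pic50(1, 0), "mw")
})

test_that("every dataset row round-trips IC50 to the printed pIC50", {
  tpl <- default_template()
  for (sp in ppo_compounds()) {
    mw <- molecular_weight(assemble_molecule(sp, tpl))
    expect_lt(abs(ic50_to_pic50(sp$ic50_mg_per_L, mw) - sp$pic50),
              0.01 + 1e-12)
  }
  # activity_vector enforces the same consistency check
  expect_silent(y <- activity_vector(ppo_compounds(), tpl))
  expect_length(y, 33)
  bad <- make_series(data.frame(id = "z", X = "S", Y = "CH", R1 = "H",
                                R2 = "H", ic50 = 1.404, pic50 = 6.5))
  expect_error(activity_vector(bad, tpl), "disagree")
})

test_that("invalid slot codes are rejected with the available codes", {
  expect_error(compound_spec("q", "N", "CH", "H", "H"), "available.*S")
  expect_error(compound_spec("q", "S", "CH", "OH", "H"), "available")
  expect_error(compound_spec("q", "S", "CH", "H", "4-CH3"), "available")
  expect_error(compound_spec("q", "S", "CH", "H", "H",
                             ic50_mg_per_L = -2), "> 0")
  # a 5-substituent cannot sit on Y = S
  expect_error(assemble_molecule(compound_spec("q", "CH", "S", "H",
                                               "5-CH3")), "Y = S")
})

test_that("the shipped template fixture matches the built-in geometry", {
  shipped <- read_template(system.file("extdata",
                                       "phenyltriazolinone_template.json",
                                       package = "miaqsar",
                                       mustWork = TRUE))
  tpl <- default_template()
  expect_equal(shipped$scaffold$element, tpl$scaffold$element)
  expect_equal(shipped$scaffold$x, tpl$scaffold$x, tolerance = 1e-12)
  expect_equal(shipped$scaffold$y, tpl$scaffold$y, tolerance = 1e-12)
  expect_setequal(names(shipped$slots), names(tpl$slots))
  for (nm in names(tpl$slots))
    expect_equal(shipped$slots[[nm]]$codes, tpl$slots[[nm]]$codes)
})

test_that("template JSON round-trips and rebuilds identical molecules", {
  tpl <- default_template()
  path <- withr::local_tempfile(fileext = ".json")
  write_template(tpl, path)
  tpl2 <- read_template(path)
  sp <- compound_spec("20", "S", "C", "CF3", "5-CH3")
  m_a <- assemble_molecule(sp, tpl)
  m_b <- assemble_molecule(sp, tpl2)
  expect_equal(m_b$atoms$x, m_a$atoms$x, tolerance = 1e-12)
  expect_equal(m_b$atoms$element, m_a$atoms$element)
  expect_equal(molecular_weight(m_b), molecular_weight(m_a))
})
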