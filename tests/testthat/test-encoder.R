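test_that("an empty molecule rasterizes to an all-zero image", {
  empty <- structure(list(id = "none",
                          atoms = data.frame(element = character(),
                                             x = numeric(), y = numeric(),
                                             scaffold = logical()),
                          bonds = data.frame(i = integer(), j = integer(),
                                             order = integer())),
                     class = "molecule2d")
  img <- rasterize(empty, "electronegativity", small_canvas())
  expect_equal(dim(img), c(120, 160))
  expect_true(all(img == 0))
})

test_that("a single atom paints one disk with the discrete disk area", {
  cv <- small_canvas()
  one <- structure(list(id = "c1",
                        atoms = data.frame(element = "C", x = 0, y = 0,
                                           scaffold = TRUE),
                        bonds = data.frame(i = integer(), j = integer(),
                                           order = integer())),
                   class = "molecule2d")
  img <- rasterize(one, "electronegativity", cv)
  expect_setequal(unique(as.vector(img)), c(0, 2.55))
  # brute-force pixel enumeration of the same disk
  r <- floor(cv$k * 1.70 * cv$scale + 0.5)
  cnt <- 0
  for (dr in -r:r) for (dc in -r:r) if (dr^2 + dc^2 <= r^2) cnt <- cnt + 1
  expect_equal(sum(img == 2.55), cnt)
  # centered at the mapped pixel (origin): row 70, col 72 (0-based)
  expect_equal(img[70 + 1, 72 + 1], 2.55)
})

test_that("foreground pixels carry element property values only", {
  img <- rasterize(assemble_molecule(compound_spec("20", "S", "C", "CF3",
                                                   "5-CH3")),
                   "vdw_radius", small_canvas())
  vals <- setdiff(unique(as.vector(img)), 0)
  expect_true(all(vals %in% element_table()$vdw_radius))
  expect_true(all(vals >= 1.1))  # background 0 is unambiguous
})

test_that("unfold is row-major, inverts with fold, and has length w*h", {
  img <- rasterize(assemble_molecule(compound_spec("1", "S", "CH", "H",
                                                   "H")),
                   "vdw_radius", default_canvas())
  v <- unfold(img)
  expect_length(v, 104400)
  expect_equal(v[seq_len(300)], unclass(img)[1, ])  # first image row first
  expect_equal(fold(v, 300, 348), unclass(img)[, ],
               ignore_attr = TRUE)
  set.seed(42)
  m <- matrix(rnorm(12), 3, 4)
  expect_equal(fold(unfold(m), 4, 3), m)
  expect_equal(unfold(matrix(0, 2, 5)), rep(0, 10))
  expect_error(fold(1:7, 2, 3), "does not match")
})

test_that("descriptor matrix preserves order, masks constants, and is
           deterministic", {
  cv <- small_canvas()
  ser <- mini_series()
  dm1 <- build_descriptor_matrix(ser, "vdw_radius", cv)
  dm2 <- build_descriptor_matrix(ser, "vdw_radius", cv)
  expect_identical(dm1$X, dm2$X)           # byte-identical across runs
  expect_equal(rownames(dm1$X), vapply(ser, `[[`, "", "id"))
  # background pixels (never covered) are masked out
  covered <- colSums(dm1$X != 0) > 0
  expect_true(all(!dm1$column_mask[!covered]))
  # masked-out columns are constant, retained columns vary
  Xm <- masked_matrix(dm1)
  expect_true(all(apply(Xm, 2, function(cl) length(unique(cl))) > 1))
  dropped <- dm1$X[, !dm1$column_mask, drop = FALSE]
  expect_true(all(apply(dropped[, seq_len(50)], 2,
                        function(cl) length(unique(cl))) == 1))
  # duplicate ids rejected
  dup <- c(ser, ser[1])
  class(dup) <- "compound_series"
  expect_error(build_descriptor_matrix(dup, "vdw_radius", cv),
               "duplicate")
})

test_that("two compounds differing in R1 differ only near the R1 slot", {
  cv <- small_canvas()
  tpl <- default_template()
  i1 <- rasterize(assemble_molecule(compound_spec("1", "S", "CH", "H",
                                                  "H"), tpl),
                  "vdw_radius", cv)
  i22 <- rasterize(assemble_molecule(compound_spec("22", "S", "CH", "Br",
                                                   "H"), tpl),
                   "vdw_radius", cv)
  diff_px <- which(unclass(i1) != unclass(i22), arr.ind = TRUE)
  expect_gt(nrow(diff_px), 0)
  # all differing pixels lie inside the union of the two R1-region disks
  # (H/Br on the para carbon), with the para carbon at the slot anchor
  slot <- tpl$slots$R1$pos
  # largest reach: Br bond (1.92 A) + Br disk radius
  reach <- (1.92 + 1.85 * cv$k) * cv$scale + 2
  ctr_col <- cv$origin[1] + slot[1] * cv$scale
  ctr_row <- cv$origin[2] - slot[2] * cv$scale
  d <- sqrt((diff_px[, "col"] - 1 - ctr_col)^2 +
              (diff_px[, "row"] - 1 - ctr_row)^2)
  expect_true(all(d <= reach))
})

test_that("scaffold pixels are identical across all dataset rows", {
  cv <- small_canvas()
  ser <- ppo_compounds()
  dm <- build_descriptor_matrix(ser, "electronegativity", cv)
  # pixels covered by scaffold-only disks of the bare-core compound must
  # not vary unless a substituent disk overlaps; at minimum, the
  # triazolinone carbonyl O pixel is shared by every row
  tpl <- default_template()
  o_atom <- tpl$scaffold[tpl$scaffold$element == "O", ]
  col <- floor(cv$origin[1] + o_atom$x * cv$scale + 0.5)
  row <- floor(cv$origin[2] - o_atom$y * cv$scale + 0.5)
  j <- row * cv$width + col + 1  # row-major index of the O center
  expect_equal(unique(dm$X[, j]), 3.44)
})

test_that("atoms falling outside the canvas raise a named error", {
  tiny <- default_canvas(width = 40L, height = 40L, scale = 8,
                         origin = c(20, 20))
  mol <- assemble_molecule(compound_spec("1", "S", "CH", "H", "H"))
  expect_error(rasterize(mol, "vdw_radius", tiny),
               "does not fit the canvas")
})

test_that("bond sticks are optional and carbon-valued", {
  cv <- small_canvas(draw_bonds = TRUE)
  mol <- assemble_molecule(compound_spec("1", "S", "CH", "H", "H"))
  img_b <- rasterize(mol, "electronegativity", cv)
  img_0 <- rasterize(mol, "electronegativity", small_canvas())
  extra <- unclass(img_b)[unclass(img_b) != unclass(img_0)]
  expect_true(all(extra == 2.55))
  expect_gt(length(extra), 0)
})

test_that("image export writes a PNG and a lossless CSV", {
  img <- rasterize(assemble_molecule(compound_spec("1", "S", "CH", "H",
                                                   "H")),
                   "vdw_radius", small_canvas())
  png_path <- withr::local_tempfile(fileext = ".png")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  export_image(img, png_path, csv_path)
  expect_true(file.exists(png_path))
  back <- as.matrix(read.csv(csv_path, header = FALSE))
  expect_equal(unname(back), unclass(img)[, ], ignore_attr = TRUE)
})
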