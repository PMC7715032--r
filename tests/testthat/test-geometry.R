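test_that("layouts hold exactly the requested populations", {
  lay <- build_layout(120, 250, 80, seed = 3)
  expect_equal(unname(table(lay$population)[c("EC", "DG", "CA3")]),
               c(120, 250, 80), ignore_attr = TRUE)
  for (pop in c("EC", "DG", "CA3")) {
    sub <- layout_population(lay, pop)
    expect_equal(sub$id, 0:(nrow(sub) - 1))
    ext <- attr(lay, "geometry")[[pop]]
    expect_true(all(sub$longitudinal >= 0 &
                      sub$longitudinal <= ext[["longitudinal"]]))
    expect_true(all(sub$transverse >= 0 &
                      sub$transverse <= ext[["transverse"]]))
  }
  expect_true(all(lay$blade[lay$population == "DG"] %in%
                    c("suprapyramidal", "infrapyramidal")))
  expect_true(all(lay$blade[lay$population != "DG"] == "none"))
})

test_that("empty and invalid layout configurations behave as specified", {
  lay0 <- build_layout(0, 0, 0, seed = 1)
  expect_equal(nrow(lay0), 0)
  expect_error(build_layout(-1, 0, 0), "non-negative")
  expect_error(default_geometry(ca3_long = -1), "positive")
})

test_that("layout generation is reproducible per seed", {
  a <- build_layout(50, 60, 70, seed = 11)
  b <- build_layout(50, 60, 70, seed = 11)
  d <- build_layout(50, 60, 70, seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("uniform placement passes a spatial goodness-of-fit check", {
  lay <- build_layout(0, 0, 10000, seed = 7)
  ca3 <- layout_population(lay, "CA3")
  hx <- cut(ca3$longitudinal, seq(0, 10, length.out = 11))
  hy <- cut(ca3$transverse, seq(0, 2, length.out = 11))
  counts <- as.vector(table(hx, hy))
  p <- stats::chisq.test(counts, p = rep(1 / 100, 100))$p.value
  expect_gt(p, 0.01)
})

test_that("section assignment follows the half-open window rules", {
  # septal window contains 7.5 mm; proximal third is CA3c
  s <- assign_section(7.5, 0.1)
  expect_true(any(s$row == "septal" & s$column == "CA3c"))
  # at the 5.0 mm seam the half-open windows hand over exactly:
  # [5, 10) opens (septal) as [0, 5) closes (temporal)
  expect_equal(sort(assign_section(5, 1)$row), c("middle", "septal"))
  expect_equal(sort(assign_section(5 - 1e-9, 1)$row),
               c("middle", "temporal"))
  expect_equal(sort(assign_section(4, 1)$row), c("middle", "temporal"))
  # transverse boundary tie goes to the distal side
  g <- section_grid(2)
  expect_equal(unique(assign_section(5, g$transverse_bounds[1])$column),
               "CA3b")
  expect_error(assign_section(5, 1, subfield = "DG"), "CA3")
})

test_that("every CA3 neuron has one column and at least one row", {
  lay <- build_layout(0, 0, 400, seed = 5)
  memb <- section_membership(lay)
  cols <- c("CA3c", "CA3b", "CA3a")
  col_count <- sapply(cols, function(co)
    rowSums(memb[, grepl(paste0("\\.", co, "$"), colnames(memb)),
                 drop = FALSE]) > 0)
  expect_true(all(rowSums(col_count) == 1))
  rows <- c("septal", "middle", "temporal")
  row_count <- sapply(rows, function(r)
    rowSums(memb[, startsWith(colnames(memb), r), drop = FALSE]) > 0)
  expect_true(all(rowSums(row_count) >= 1))
})
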