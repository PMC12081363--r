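test_that("property cells parse as value, value-with-uncertainty, or missing", {
  out <- parse_property(c("87.5 ± 3", "337.346", "", "415 ± 32.9"))
  expect_equal(out$value, c(87.5, 337.346, NA, 415))
  expect_equal(out$uncertainty, c(3, 0, NA, 32.9))
  expect_error(parse_property("87.5 +- 3"), "cannot parse")
  expect_error(parse_property("two ± 3"), "cannot parse")
})

test_that("packaged descriptor table holds the printed values, separators stripped", {
  tab <- kb_descriptor_values()
  expect_equal(nrow(tab), 20)
  lin <- tab[tab$drug == "Linezolid", ]
  expect_equal(unlist(lin[, c("B1", "B2", "HB1", "HB2")], use.names = FALSE),
               c(268, 356, 1452, 2908))
  expect_equal(tab$HB2[tab$drug == "Clarithromycin"], 10880)
  expect_equal(tab$Hb[tab$drug == "Unasyn"], 20.6357)
})

test_that("join keeps every drug and the documented exclusions blank properties only", {
  d <- load_drug_data()
  expect_equal(nrow(d), 20)
  # the misaligned row keeps its descriptors but loses all property cells
  pen <- d[tolower(d$drug) == "penicillin", ]
  expect_equal(pen$B1, 298)
  expect_true(all(is.na(pen[, c("En", "MW", "MV", "FP", "MR")])))
  # nothing is imputed: known gaps stay missing
  expect_true(is.na(d$En[d$drug == "Avibactam"]))
  expect_true(is.na(d$MR[d$drug == "Clarithromycin"]))

  raw <- load_drug_data(apply_exclusions = FALSE)
  expect_equal(raw$En[tolower(raw$drug) == "penicillin"], 344.390)
})

test_that("cleaning toggles are data-driven and reversible", {
  ex <- default_exclusions()
  expect_equal(ex$default[[1]]$drug, "Penicillin")
  expect_true(all(vapply(c(ex$default, ex$optional),
                         function(r) nzchar(r$reason), logical(1))))

  d1 <- load_drug_data(drop_carbapenem = TRUE)
  expect_true(all(is.na(d1[d1$drug == "Carbapanem",
                           c("En", "MW", "MV", "FP", "MR")])))
  d2 <- load_drug_data(drop_levaquin_mr = TRUE)
  expect_true(is.na(d2$MR[d2$drug == "Levaquin"]))
  expect_false(is.na(d2$MW[d2$drug == "Levaquin"]))
  d3 <- load_drug_data(extra_exclusions = "Linezolid")
  expect_true(is.na(d3$En[d3$drug == "Linezolid"]))
})

test_that("regression rows pair exactly the drugs with both values present", {
  d <- load_drug_data()
  mr <- regression_rows(d, "MR", "B1")
  expect_equal(mr$n, 18)  # Clarithromycin blank; Penicillin row excluded
  expect_length(mr$x, mr$n)
  expect_length(mr$y, mr$n)
  expect_false("Clarithromycin" %in% mr$drugs)

  en <- regression_rows(d, "En", "Hb")
  expect_equal(en$n, 14)  # five printed gaps plus the excluded row

  mw <- regression_rows(d, "MW", "Hb")
  expect_equal(mw$n, 19)

  expect_error(regression_rows(d, "Density", "B1"), "no column")
})

test_that("published partitions are packaged with their printed totals", {
  totals <- c(Linezolid = 26, Unasyn = 27, Cefuroxime = 32, Avibactam = 19)
  for (drug in names(totals)) {
    p <- printed_partition(drug)
    expect_s3_class(p, "edge_partition")
    expect_equal(sum(p$count), unname(totals[drug]), info = drug)
  }
  expect_error(printed_partition("Cefaclor"), "no published partition")
})

test_that("published model-quality reference covers the full grid", {
  ref <- reference_model_quality()
  expect_equal(nrow(ref), 100)  # 4 degrees x 5 descriptors x 5 properties
  # the cells the publication left blank
  blank <- ref[is.na(ref$r_printed), ]
  expect_true(all(blank$descriptor == "HB2" & blank$property == "MW"))
  # the two published statistics are square-consistent in every cell but
  # one (the cubic harmonic-index enthalpy cell carries a stray digit)
  ok <- !is.na(ref$r_printed)
  d <- abs(sqrt(ref$r2_printed[ok]) - ref$r_printed[ok])
  expect_equal(sum(d < 1e-3), sum(ok) - 1)
  outlier <- ref[ok, ][d >= 1e-3, ]
  expect_equal(outlier$degree, 3)
  expect_equal(outlier$descriptor, "Hb")
  expect_equal(outlier$property, "En")
})
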