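#' Parse a physicochemical property cell
#'
#' Property tables print each cell as empty, a bare number, or
#' `"value ± uncertainty"`.  Values are kept exactly as printed (no unit
#' conversion); a bare number gets uncertainty 0 and an empty cell is
#' missing.
#'
#' @param text a character vector of cell strings.
#' @return a data frame with numeric columns `value` and `uncertainty`;
#'   missing cells give `NA` in both.
#' @examples
#' parse_property(c("87.5 ± 3", "337.346", ""))
#' @export
parse_property <- function(text) {
  text <- trimws(as.character(text))
  out <- data.frame(value = rep(NA_real_, length(text)),
                    uncertainty = rep(NA_real_, length(text)))
  num <- "[0-9]+(\\.[0-9]+)?"
  pm <- sprintf("^(%s)\\s*±\\s*(%s)$", num, num)
  bare <- sprintf("^%s$", num)
  for (i in seq_along(text)) {
    cell <- text[i]
    if (is.na(cell) || !nzchar(cell)) next
    if (grepl(pm, cell)) {
      parts <- strsplit(cell, "±")[[1]]
      out$value[i] <- as.numeric(trimws(parts[1]))
      out$uncertainty[i] <- as.numeric(trimws(parts[2]))
    } else if (grepl(bare, cell)) {
      out$value[i] <- as.numeric(cell)
      out$uncertainty[i] <- 0
    } else {
      stop(sprintf("cannot parse property cell '%s'", cell))
    }
  }
  out
}

#' Packaged descriptor and property tables
#'
#' `kb_descriptor_values()` returns the packaged K-Banhatti descriptor
#' table for the 20-drug anti-pneumonia panel (thousands separators
#' already stripped).  `drug_properties()` returns the five
#' physicochemical properties -- enthalpy of vaporization `En` (kJ/mol),
#' molecular weight `MW` (g/mol), molar volume `MV` (cm^3), flash point
#' `FP` (degrees C) and molar refractivity `MR` (cm^3) -- parsed into
#' `<prop>` value and `<prop>_u` uncertainty columns.  Missing cells
#' stay missing; nothing is imputed.
#'
#' @param raw if `TRUE`, `drug_properties()` returns the cells as
#'   printed strings instead of parsed values.
#' @return a tibble with one row per drug.
#' @export
kb_descriptor_values <- function() {
  path <- system.file("extdata", "table5_descriptors.csv",
                      package = "kbanhatti")
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' @rdname kb_descriptor_values
#' @export
drug_properties <- function(raw = FALSE) {
  path <- system.file("extdata", "table6_properties.csv",
                      package = "kbanhatti")
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  if (raw) return(tibble::as_tibble(tab))
  out <- tibble::tibble(drug = tab$drug)
  for (prop in c("En", "MW", "MV", "FP", "MR")) {
    parsed <- parse_property(tab[[prop]])
    out[[prop]] <- parsed$value
    out[[paste0(prop, "_u")]] <- parsed$uncertainty
  }
  out
}

#' Row-exclusion rules for the property regressions
#'
#' Cleaning decisions are encoded as data, not code branches: the
#' packaged JSON lists a default exclusion (the Penicillin row, whose
#' single printed value is a data-entry misalignment) and optional
#' toggles (the chemically implausible Carbapanem molecular weight; the
#' Levaquin molar refractivity whose uncertainty rivals its value), so
#' alternate row sets can be swapped in for sensitivity analysis.
#'
#' @return the exclusion list as a nested list with entries `default`
#'   and `optional`; each rule has `drug`, `scope` and `reason`.
#' @export
default_exclusions <- function() {
  path <- system.file("extdata", "exclusions.json", package = "kbanhatti")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Load the joined descriptor-property dataset
#'
#' Joins the packaged descriptor and property tables by drug name
#' (case-insensitively) and applies the documented cleaning rules:
#' excluded drugs have all their property values set to missing while
#' their descriptor values are kept.
#'
#' @param apply_exclusions apply the default exclusion list (the
#'   misaligned Penicillin row).  Default `TRUE`.
#' @param drop_carbapenem also exclude the Carbapanem row from property
#'   regressions (optional toggle; its printed molecular weight is
#'   chemically implausible).  Default `FALSE`: the value is reproduced
#'   as printed, then questioned via sensitivity analysis.
#' @param drop_levaquin_mr also blank the Levaquin molar refractivity
#'   (uncertainty 70.4 on a value of 91.1).  Default `FALSE`.
#' @param extra_exclusions character vector of additional drug names
#'   whose property values are blanked (sensitivity analysis).
#' @return a tibble with descriptor columns `B1..Hb`, property columns
#'   `En, MW, MV, FP, MR` and their `_u` uncertainties.
#' @export
load_drug_data <- function(apply_exclusions = TRUE,
                           drop_carbapenem = FALSE,
                           drop_levaquin_mr = FALSE,
                           extra_exclusions = character()) {
  desc <- kb_descriptor_values()
  prop <- drug_properties()
  idx <- match(tolower(desc$drug), tolower(prop$drug))
  if (anyNA(idx)) {
    stop(sprintf("drug '%s' has no property row", desc$drug[is.na(idx)][1L]))
  }
  joined <- cbind(desc, prop[idx, setdiff(names(prop), "drug")])
  joined <- tibble::as_tibble(joined)

  props <- c("En", "MW", "MV", "FP", "MR")
  blank_all <- character()
  if (apply_exclusions) {
    rules <- default_exclusions()$default
    blank_all <- c(blank_all,
                   vapply(rules, function(r) r$drug, character(1)))
  }
  if (drop_carbapenem) blank_all <- c(blank_all, "Carbapanem")
  blank_all <- c(blank_all, extra_exclusions)
  for (drug in blank_all) {
    hit <- tolower(joined$drug) == tolower(drug)
    for (p in props) {
      joined[[p]][hit] <- NA_real_
      joined[[paste0(p, "_u")]][hit] <- NA_real_
    }
  }
  if (drop_levaquin_mr) {
    hit <- tolower(joined$drug) == "levaquin"
    joined$MR[hit] <- NA_real_
    joined$MR_u[hit] <- NA_real_
  }
  joined
}

#' Paired rows for one descriptor-property regression
#'
#' Returns the `(x, y)` pairs for exactly those drugs with both the
#' descriptor and the property non-missing after the cleaning rules.
#'
#' @param data a dataset from [load_drug_data()] (or a compatible
#'   tibble, e.g. from [synthetic_qspr_table()]).
#' @param property one of `"En"`, `"MW"`, `"MV"`, `"FP"`, `"MR"` (or any
#'   numeric column of `data`).
#' @param descriptor one of `"B1"`, `"B2"`, `"HB1"`, `"HB2"`, `"Hb"`.
#' @return a list with components `x` (descriptor values), `y` (property
#'   values), `drugs` (names of the retained rows) and `n`.
#' @export
regression_rows <- function(data, property, descriptor) {
  for (col in c(property, descriptor)) {
    if (!col %in% names(data)) stop(sprintf("no column '%s' in data", col))
  }
  x <- data[[descriptor]]
  y <- data[[property]]
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok],
       drugs = if ("drug" %in% names(data)) data$drug[ok] else which(ok),
       n = sum(ok))
}

#' Published edge partitions of the four worked drugs
#'
#' The published partition tables (Linezolid, Unasyn, Cefuroxime,
#' Avibactam) transcribed as packaged CSVs; these anchor the descriptor
#' reference values.  Note the Cefuroxime partition has an odd total
#' degree sum, so no graph realizes it -- it exists only as a partition.
#'
#' @param drug one of `"Linezolid"`, `"Unasyn"`, `"Cefuroxime"`,
#'   `"Avibactam"` (case insensitive).
#' @return an `edge_partition`.
#' @examples
#' banhatti_b1(printed_partition("Linezolid"))  # 268
#' @export
printed_partition <- function(drug) {
  file <- system.file("extdata", "partitions",
                      paste0(tolower(drug), ".csv"), package = "kbanhatti")
  if (!nzchar(file)) {
    stop(sprintf("no published partition for drug '%s'", drug))
  }
  read_partition_csv(file)
}

#' Published model-quality values
#'
#' The published coefficient-of-determination and correlation grid for
#' the 4 model degrees x 5 descriptors x 5 properties, as reference data
#' for the reproduction report.  Cells the publication left blank
#' (second hyper index vs molecular weight) are `NA`.
#'
#' @return a tibble with columns `degree`, `descriptor`, `property`,
#'   `r2_printed`, `r_printed`.
#' @export
reference_model_quality <- function() {
  path <- system.file("extdata", "reference_model_quality.csv",
                      package = "kbanhatti")
  tibble::as_tibble(utils::read.csv(path))
}
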