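#' Fit a polynomial descriptor-property model
#'
#' Ordinary least squares on the raw monomial basis
#' `(x^degree, ..., x, 1)`; degree 1 is the linear model, degrees 2-4
#' the quadratic, cubic and biquadratic models.  Descriptors are not
#' centred or standardized before expansion, so coefficients are on the
#' raw descriptor scale.  Property uncertainties are ignored (ordinary,
#' not weighted, least squares).  The model quality is the unadjusted
#' coefficient of determination `R^2 = 1 - SS_res/SS_tot`, with
#' `r = +sqrt(R^2)`.
#'
#' @param x numeric descriptor values.
#' @param y numeric property values, same length as `x`.
#' @param degree polynomial degree, 1 to 4.
#' @return a `kb_model`: list with `coefficients` (highest power first),
#'   `intercept`, `r_squared`, `r`, `degree`, `n`, and the underlying
#'   `lm` fit.
#' @examples
#' m <- fit_polynomial(c(1, 2, 3), c(3, 5, 7), 1)
#' m$coefficients  # 2
#' m$r_squared     # 1
#' @export
fit_polynomial <- function(x, y, degree) {
  if (!degree %in% 1:4) stop("'degree' must be 1, 2, 3 or 4")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < degree + 2) {
    stop(sprintf("insufficient data: %d rows for a degree-%d fit (need >= %d)",
                 length(x), degree, degree + 2))
  }
  if (length(unique(x)) <= degree) {
    stop("rank-deficient design: too few distinct descriptor values")
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: singular polynomial basis")
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  co <- stats::coef(fit)
  structure(
    list(coefficients = rev(unname(co[-1L])),  # highest power first
         intercept = unname(co[1L]),
         r_squared = r2, r = sqrt(r2),
         degree = degree, n = length(x), fit = fit),
    class = "kb_model"
  )
}

#' @export
print.kb_model <- function(x, ...) {
  cat(sprintf("<kb_model> degree %d, n = %d, R^2 = %.4f, r = %.4f\n",
              x$degree, x$n, x$r_squared, x$r))
  cat("  ", format_model_equation(x), "\n")
  invisible(x)
}

#' @export
predict.kb_model <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  co <- c(object$coefficients, object$intercept)
  vapply(x, function(xi) sum(co * xi^(object$degree:0)), numeric(1))
}

#' Render a fitted model as an equation string
#'
#' Mimics the compact published notation: coefficients in scientific or
#' plain notation to a few significant figures.  Formatting only --
#' stored coefficients keep full precision.
#'
#' @param m a `kb_model`.
#' @param response,predictor labels for the two variables.
#' @param digits significant figures for the printed coefficients.
#' @return a character string such as `"MW = 15.1*Hb + 35.51"`.
#' @export
format_model_equation <- function(m, response = "y", predictor = "x",
                                  digits = 4) {
  co <- c(m$coefficients, m$intercept)
  pows <- m$degree:0
  terms <- character(0)
  for (i in seq_along(co)) {
    val <- signif(co[i], digits)
    mono <- if (pows[i] == 0) "" else if (pows[i] == 1) predictor else
      sprintf("%s^%d", predictor, pows[i])
    lead <- if (i == 1) {
      sprintf("%g", val)
    } else {
      sprintf(" %s %g", if (val < 0) "-" else "+", abs(val))
    }
    terms <- c(terms, paste0(lead, if (nzchar(mono)) "*" else "", mono))
  }
  sprintf("%s = %s", response, paste(terms, collapse = ""))
}

#' Fit the full model grid
#'
#' One fit per (degree, descriptor, property) combination with
#' sufficient data.  Cells that cannot be fitted (too few paired rows,
#' or a degenerate design) are recorded as absent with a reason rather
#' than erroring.
#'
#' @param data dataset from [load_drug_data()] or
#'   [synthetic_qspr_table()].
#' @param degrees subset of `1:4` to fit.
#' @param descriptors,properties column names to cross.
#' @return a `kb_grid`: tibble with one row per cell -- columns
#'   `degree`, `descriptor`, `property`, `n`, `r_squared`, `r`, `note`
#'   and a `model` list-column.
#' @export
build_grid <- function(data, degrees = 1:4,
                       descriptors = c("B1", "B2", "HB1", "HB2", "Hb"),
                       properties = intersect(c("En", "MR", "MV", "FP", "MW"),
                                              names(data))) {
  cells <- expand.grid(degree = degrees, descriptor = descriptors,
                       property = properties, stringsAsFactors = FALSE)
  cells <- cells[order(cells$degree, match(cells$descriptor, descriptors),
                       match(cells$property, properties)), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    deg <- cells$degree[i]; dn <- cells$descriptor[i]; pn <- cells$property[i]
    pairs <- regression_rows(data, pn, dn)
    m <- tryCatch(fit_polynomial(pairs$x, pairs$y, deg),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) {
      tibble::tibble(degree = deg, descriptor = dn, property = pn,
                     n = pairs$n, r_squared = NA_real_, r = NA_real_,
                     note = m, model = list(NULL))
    } else {
      tibble::tibble(degree = deg, descriptor = dn, property = pn,
                     n = m$n, r_squared = m$r_squared, r = m$r,
                     note = NA_character_, model = list(m))
    }
  })
  grid <- do.call(rbind, rows)
  class(grid) <- c("kb_grid", class(grid))
  grid
}

#' Correlation table of a model grid
#'
#' Reshapes the grid into the published layout: one row per
#' (degree, descriptor), one column per property, holding `r`.
#'
#' @param grid a `kb_grid`.
#' @param value which statistic to tabulate, `"r"` or `"r_squared"`.
#' @return a tibble with columns `degree`, `descriptor` and one column
#'   per property.
#' @export
grid_r_table <- function(grid, value = c("r", "r_squared")) {
  value <- match.arg(value)
  props <- unique(grid$property)
  combos <- unique(grid[, c("degree", "descriptor")])
  out <- combos
  for (pn in props) out[[pn]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    for (pn in props) {
      hit <- grid$degree == out$degree[i] &
        grid$descriptor == out$descriptor[i] & grid$property == pn
      if (any(hit)) out[[pn]][i] <- grid[[value]][hit]
    }
  }
  tibble::as_tibble(out)
}

#' Best model per property and reliability ordering
#'
#' For every (property, degree) the descriptor with maximal correlation,
#' plus the global reliability ordering of the four model families by
#' mean `R^2` over all cells.  For nested OLS bases the mean is
#' non-decreasing in degree, so the ordering runs linear through
#' biquadratic.
#'
#' @param grid a `kb_grid`.
#' @return a list with `best` (tibble: property, degree, descriptor, r,
#'   r_squared) and `reliability` (tibble: degree, mean_r2, ordered by
#'   mean_r2).
#' @export
best_models <- function(grid) {
  fitted <- grid[!is.na(grid$r), ]
  combos <- unique(fitted[, c("property", "degree")])
  best <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- fitted[fitted$property == combos$property[i] &
                    fitted$degree == combos$degree[i], ]
    sub[which.max(sub$r), c("property", "degree", "descriptor",
                            "r", "r_squared")]
  }))
  rel <- do.call(rbind, lapply(sort(unique(fitted$degree)), function(d) {
    tibble::tibble(degree = d,
                   mean_r2 = mean(fitted$r_squared[fitted$degree == d]))
  }))
  rel <- rel[order(rel$mean_r2), ]
  list(best = tibble::as_tibble(best), reliability = rel)
}

#' Row-set sensitivity sweep for one grid cell
#'
#' Refits one (descriptor, property, degree) cell under alternative row
#' sets, dropping subsets of the available drugs, and reports which row
#' sets bring `R^2` within `tol` of a target value.  Subsets are
#' searched in order of increasing size and the search stops at the
#' first size that yields any match, so the smallest exclusion set
#' wins; within a size, matches are ordered by `|R^2 - target|`.  The
#' search is exhaustive and deterministic.
#'
#' @param data dataset from [load_drug_data()].
#' @param property,descriptor,degree the cell to refit.
#' @param target target `R^2` (e.g. a published value).
#' @param tol acceptance half-width on `R^2`.  Default 0.02.
#' @param max_drop largest exclusion-subset size to try.  Default 5.
#' @return a tibble of matching row sets with columns `dropped`
#'   (comma-separated drugs), `n_dropped`, `n`, `r_squared`, `delta`;
#'   zero rows if nothing matches.  The first row is the best match.
#' @export
sweep_row_sets <- function(data, property, descriptor, degree, target,
                           tol = 0.02, max_drop = 5) {
  pairs <- regression_rows(data, property, descriptor)
  base <- fit_polynomial(pairs$x, pairs$y, degree)
  hits <- list()
  if (abs(base$r_squared - target) <= tol) {
    hits[[1L]] <- tibble::tibble(dropped = "", n_dropped = 0L, n = base$n,
                                 r_squared = base$r_squared,
                                 delta = base$r_squared - target)
  } else {
    drugs <- sort(pairs$drugs)
    for (k in seq_len(min(max_drop, length(drugs) - degree - 2))) {
      subs <- utils::combn(drugs, k, simplify = FALSE)
      for (s in subs) {
        keep <- !(pairs$drugs %in% s)
        m <- tryCatch(fit_polynomial(pairs$x[keep], pairs$y[keep], degree),
                      error = function(e) NULL)
        if (is.null(m)) next
        if (abs(m$r_squared - target) <= tol) {
          hits[[length(hits) + 1L]] <-
            tibble::tibble(dropped = paste(s, collapse = ","),
                           n_dropped = k, n = m$n,
                           r_squared = m$r_squared,
                           delta = m$r_squared - target)
        }
      }
      if (length(hits) > 0L) break
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(dropped = character(), n_dropped = integer(),
                          n = integer(), r_squared = numeric(),
                          delta = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(abs(out$delta), out$dropped), ]
}

#' Scatter and fitted-curve plot for one model
#'
#' Generic rendering of one descriptor-property cell: observed points
#' plus the fitted polynomial curve.  Needs ggplot2.
#'
#' @param data dataset the model was fitted on.
#' @param property,descriptor,degree the cell to plot.
#' @return a ggplot object.
#' @export
plot_fit <- function(data, property, descriptor, degree = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fit() needs the ggplot2 package")
  }
  pairs <- regression_rows(data, property, descriptor)
  m <- fit_polynomial(pairs$x, pairs$y, degree)
  xs <- seq(min(pairs$x), max(pairs$x), length.out = 200)
  df <- data.frame(x = pairs$x, y = pairs$y)
  line <- data.frame(x = xs, y = predict(m, xs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::labs(
      x = descriptor, y = property,
      title = sprintf("%s ~ poly(%s, %d): R² = %.4f",
                      property, descriptor, degree, m$r_squared)
    )
}
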