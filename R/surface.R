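#' Polynomial response surface of turnover on degradation and shift rate
#'
#' Fits full bivariate polynomials (all terms `d^i v^j` with `i + j` up to
#' the order) of simulated turnover rate on environmental degradation `d`
#' and shift rate `v` by least squares, one fit per candidate order, and
#' selects the order minimising the AIC (Gaussian likelihood, identical data
#' across orders).
#'
#' @param table [factorial_experiment()] output (rows with `NA` rate are
#'   dropped).
#' @param orders Candidate polynomial orders (default `2:4`).
#' @return A `turnover_surface` object: list with `fits` (named list of
#'   `lm`), `aic` (named numeric), `order` (selected), `n` (rows used).
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_surface <- function(table, orders = 2:4) {
  dat <- dplyr::filter(table, !is.na(.data$rate))
  stopifnot(nrow(dat) > 0)
  fits <- lapply(orders, function(k) {
    n_coef <- (k + 1) * (k + 2) / 2
    if (nrow(dat) < n_coef) {
      stop("too few rows (", nrow(dat), ") for order ", k, " (needs ",
           n_coef, ")", call. = FALSE)
    }
    fit <- lm(rate ~ poly(d, v, degree = k, raw = TRUE), data = dat)
    if (fit$rank < n_coef) {
      stop("rank-deficient design for order ", k,
           " (needs more distinct (d, v) levels)", call. = FALSE)
    }
    fit
  })
  names(fits) <- paste0("order", orders)
  aic <- vapply(fits, AIC, 0)
  structure(
    list(fits = fits, aic = aic, orders = orders,
         order = orders[which.min(aic)], n = nrow(dat),
         data = dplyr::select(dat, "d", "v", "rate")),
    class = "turnover_surface"
  )
}

#' @export
print.turnover_surface <- function(x, ...) {
  cat("Polynomial turnover response surface in (d, v)\n")
  cat("  rows fitted:", x$n, "\n")
  cat("  AIC by order:",
      paste(sprintf("%d: %.2f", x$orders, x$aic), collapse = ", "), "\n")
  cat("  selected order:", x$order, "\n")
  invisible(x)
}

#' Tidy a fitted turnover response surface
#'
#' @param x A [fit_surface()] object.
#' @param order Which order's coefficients (default: the selected one).
#' @param ... Unused.
#' @return Tibble of `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.turnover_surface <- function(x, order = x$order, ...) {
  fit <- x$fits[[paste0("order", order)]]
  cf <- summary(fit)$coefficients
  terms <- rownames(cf)
  # poly() names like `poly(d, v, degree = k, raw = TRUE)2.1` -> d^2 v^1
  terms <- sub(".*raw = TRUE\\)(\\d+)\\.(\\d+)$", "d^\\1 v^\\2", terms)
  tibble::tibble(term = terms, estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' One-row-per-order summary of a turnover response surface
#'
#' @param x A [fit_surface()] object.
#' @param ... Unused.
#' @return Tibble: `order`, `df`, `aic`, `r.squared`, `selected`.
#' @export
glance.turnover_surface <- function(x, ...) {
  tibble::tibble(
    order = x$orders,
    df = vapply(x$fits, function(f) f$rank, 0L),
    aic = unname(x$aic),
    r.squared = vapply(x$fits, function(f) summary(f)$r.squared, 0),
    selected = x$orders == x$order
  )
}

#' Predict from a turnover response surface
#'
#' @param object A [fit_surface()] object.
#' @param newdata Data frame with columns `d` and `v` (default: a 40 x 40
#'   grid over the fitted ranges).
#' @param order Polynomial order to use (default: selected).
#' @param ... Unused.
#' @return `newdata` with a `rate` column of predictions.
#' @export
predict.turnover_surface <- function(object, newdata = NULL,
                                     order = object$order, ...) {
  fit <- object$fits[[paste0("order", order)]]
  if (is.null(newdata)) {
    newdata <- tidyr::expand_grid(
      d = seq(min(object$data$d), max(object$data$d), length.out = 40),
      v = seq(min(object$data$v), max(object$data$v), length.out = 40)
    )
  }
  nd <- tibble::as_tibble(newdata)
  # poly() cannot build a basis from a single point; pad and drop
  padded <- if (nrow(nd) == 1) dplyr::bind_rows(nd, nd) else nd
  pred <- unname(predict(fit, newdata = padded))[seq_len(nrow(nd))]
  dplyr::mutate(nd, rate = pred)
}
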