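# Electrophilic-aromatic-substitution descriptors: symmetry averaging of
# ring quantities, inductive/mesomeric pattern classification, orientation
# prediction from vicinal-DI changes, and Hammett correlation.

#' Symmetry-average ring bond quantities
#'
#' A monosubstituted ring has a mirror plane through C1 and C4: `b12` pairs
#' with `b61`, `b23` with `b56`, `b34` with `b45`. Nearly equivalent values
#' can differ slightly on the grid and are averaged; a large intra-pair
#' spread flags a possible mislabelling but is still averaged.
#'
#' @param values named numeric vector with entries b12, b23, b34, b45, b56,
#'   b61
#' @param warn_spread flag threshold for the intra-pair spread
#' @return list: `q12`, `q23`, `q34`, `max_spread`, `flagged`
#' @export
symmetry_average <- function(values, warn_spread = 0.1) {
  need <- c("b12", "b23", "b34", "b45", "b56", "b61")
  if (!all(need %in% names(values)))
    stop("values must be named with all of: ", paste(need, collapse = ", "))
  v <- values[need]
  q <- c(q12 = mean(v[c("b12", "b61")]),
         q23 = mean(v[c("b23", "b56")]),
         q34 = mean(v[c("b34", "b45")]))
  spread <- c(abs(diff(v[c("b12", "b61")])), abs(diff(v[c("b23", "b56")])),
              abs(diff(v[c("b34", "b45")])))
  flagged <- max(spread) > warn_spread
  if (flagged)
    warning("intra-pair spread ", signif(max(spread), 3),
            " exceeds ", warn_spread, "; check the ring labelling")
  list(q12 = unname(q[1]), q23 = unname(q[2]), q34 = unname(q[3]),
       max_spread = max(spread), flagged = flagged)
}

#' Classify the ring response pattern
#'
#' Monotone decay `q12 > q23 > q34` (beyond `eps`) marks an insulator-like,
#' inductively dominated perturbation; an interior maximum at `q23` marks the
#' oscillatory, mesomeric (conjugation-mediated) response; anything else is
#' `mixed`.
#'
#' @param q12,q23,q34 symmetry-averaged ring bond quantities
#' @param eps tolerance (same units as the inputs; 0.01 e for populations)
#' @return one of `"inductive_decay"`, `"mesomeric_oscillatory"`, `"mixed"`
#' @export
classify_pattern <- function(q12, q23, q34, eps = 0.01) {
  if (q12 > q23 + eps && q23 > q34 + eps) return("inductive_decay")
  if (q23 > q12 + eps && q23 > q34 + eps) return("mesomeric_oscillatory")
  "mixed"
}

#' Predict EAS orientation from vicinal-DI changes
#'
#' Activating, ortho/para-directing groups show a (+, -, +) sign pattern of
#' `(dDI(o), dDI(m), dDI(p))` versus benzene; deactivating, meta-directing
#' groups show negative dDI(o) and dDI(p).
#'
#' @param d_o,d_m,d_p changes of DI(o), DI(m), DI(p) versus benzene
#' @param eps sign tolerance
#' @return one of `"ortho_para"`, `"meta"`, `"indeterminate"`
#' @export
predict_orientation <- function(d_o, d_m, d_p, eps = 0.005) {
  if (d_o > eps && d_m < -eps && d_p > eps) return("ortho_para")
  if (d_o < -eps && d_p < -eps) return("meta")
  "indeterminate"
}

#' Read a Hammett substituent-constant table
#'
#' CSV with columns `substituent`, `sigma_m`, `sigma_p` (user-supplied; a
#' standard benzoic-acid table ships as
#' `system.file("extdata", "hammett_sigma.csv", package = "elfiqa")`).
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_hammett_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substituent", "sigma_m", "sigma_p")
  if (!all(need %in% names(tb)))
    stop("Hammett table needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(tb$sigma_m)) || !all(is.finite(tb$sigma_p)))
    stop("non-finite sigma value in Hammett table")
  tb
}

#' Hammett correlation of meta/para delocalization
#'
#' Ordinary least squares of `sigma_m - sigma_p` on `DI(m) - DI(p)` across
#' substituents.
#'
#' @param records data.frame with columns `substituent`, `sigma_m`,
#'   `sigma_p`, `DI_m`, `DI_p`
#' @return object of class `hammett_fit` (wraps the `lm`), with
#'   [tidy.hammett_fit()] and [glance.hammett_fit()] methods
#' @export
hammett_regression <- function(records) {
  need <- c("substituent", "sigma_m", "sigma_p", "DI_m", "DI_p")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  if (nrow(records) < 3) stop("need at least 3 substituents for a regression")
  x <- records$DI_m - records$DI_p
  y <- records$sigma_m - records$sigma_p
  if (stats::sd(x) < 1e-12) stop("zero variance in DI(m) - DI(p); degenerate design")
  fit <- stats::lm(y ~ x)
  structure(list(fit = fit, data = data.frame(substituent = records$substituent,
                                              x = x, y = y,
                                              residual = stats::residuals(fit)),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, y)),
            class = "hammett_fit")
}

#' @export
print.hammett_fit <- function(x, ...) {
  cat("<hammett_fit> sigma_m - sigma_p ~ DI(m) - DI(p)\n")
  cat(sprintf("  slope %.4f  intercept %.4f  r %.4f  (n = %d)\n",
              x$slope, x$intercept, x$r, nrow(x$data)))
  invisible(x)
}

#' Tidy a Hammett fit (term-level estimates)
#' @param x a `hammett_fit`
#' @param ... unused
#' @return data.frame with term, estimate, std.error, statistic, p.value
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.hammett_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  data.frame(term = c("intercept", "slope"),
             estimate = s[, 1], std.error = s[, 2],
             statistic = s[, 3], p.value = s[, 4], row.names = NULL)
}

#' One-row model summary of a Hammett fit
#' @param x a `hammett_fit`
#' @param ... unused
#' @return data.frame with r, r.squared, sigma, nobs
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.hammett_fit <- function(x, ...) {
  s <- summary(x$fit)
  data.frame(r = x$r, r.squared = s$r.squared, sigma = s$sigma,
             nobs = nrow(x$data))
}
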