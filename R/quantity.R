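#' Create a quantity with a standard uncertainty
#'
#' The currency of every derived result in the package: a numeric value, its
#' standard uncertainty, and a symbolic unit tag. Arithmetic between
#' quantities checks unit compatibility and propagates uncertainties by
#' root-sum-square (independent components).
#'
#' @param value Numeric value in the declared unit.
#' @param u Standard uncertainty, same unit, must be >= 0. Defaults to 0
#'   (an exact quantity).
#' @param unit Symbolic unit tag, e.g. `"J/g"`, `"kJ/mol"`, `"K"`, `"g"`.
#'
#' @return An object of class `"qty"`.
#' @examples
#' qty(-393.51, 0.13, "kJ/mol") + qty(-285.830, 0.040, "kJ/mol")
#' @export
qty <- function(value, u = 0, unit = "") {
  stopifnot(is.numeric(value), length(value) == 1L, is.numeric(u), length(u) == 1L)
  if (is.na(u)) u <- 0
  if (u < 0) stop("standard uncertainty must be >= 0", call. = FALSE)
  structure(list(value = as.numeric(value), u = as.numeric(u), unit = unit),
            class = "qty")
}

#' @export
is_qty <- function(x) inherits(x, "qty")

as_qty <- function(x, unit = "") {
  if (is_qty(x)) x else qty(x, 0, unit)
}

check_same_unit <- function(e1, e2, op) {
  if (nzchar(e1$unit) && nzchar(e2$unit) && !identical(e1$unit, e2$unit)) {
    stop(sprintf("incompatible units in `%s`: '%s' vs '%s'", op, e1$unit, e2$unit),
         call. = FALSE)
  }
  if (nzchar(e1$unit)) e1$unit else e2$unit
}

#' @export
Ops.qty <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(qty(-e1$value, e1$u, e1$unit))
    if (.Generic == "+") return(e1)
    stop(sprintf("unary `%s` not defined for qty", .Generic), call. = FALSE)
  }
  q1 <- is_qty(e1); q2 <- is_qty(e2)
  switch(.Generic,
    "+" = ,
    "-" = {
      a <- as_qty(e1); b <- as_qty(e2)
      unit <- check_same_unit(a, b, .Generic)
      v <- if (.Generic == "+") a$value + b$value else a$value - b$value
      qty(v, sqrt(a$u^2 + b$u^2), unit)
    },
    "*" = {
      if (q1 && q2) stop("qty * qty is not defined; scale by a plain number", call. = FALSE)
      q <- if (q1) e1 else e2
      s <- if (q1) e2 else e1
      qty(q$value * s, q$u * abs(s), q$unit)
    },
    "/" = {
      if (!q1 || q2) stop("only qty / number is defined", call. = FALSE)
      qty(e1$value / e2, e1$u / abs(e2), e1$unit)
    },
    "==" = isTRUE(all.equal(as_qty(e1)$value, as_qty(e2)$value)),
    stop(sprintf("`%s` not defined for qty", .Generic), call. = FALSE)
  )
}

#' @export
format.qty <- function(x, digits = NULL, ...) {
  v <- x$value; u <- x$u
  if (!is.null(digits)) {
    v <- round(v, digits); u <- round(u, digits)
  }
  out <- if (u > 0) sprintf("%s ± %s", format(v, ...), format(u, ...)) else format(v, ...)
  if (nzchar(x$unit)) paste(out, x$unit) else out
}

#' @export
print.qty <- function(x, ...) {
  cat("<qty>", format(x, ...), "\n")
  invisible(x)
}

#' Root-sum-square combination of uncertainty components
#'
#' Combines independent uncertainty components as the square root of the sum
#' of their squares, the convention used throughout the uncertainty budgets
#' of combustion and vaporization results.
#'
#' @param components Numeric vector of uncertainty components, all >= 0.
#' @return The combined uncertainty (scalar).
#' @examples
#' rss_combine(c(1.1, 0.8)) # 1.36
#' @export
rss_combine <- function(components) {
  components <- as.numeric(components)
  if (any(is.na(components))) stop("NA uncertainty component", call. = FALSE)
  if (any(components < 0)) stop("uncertainty components must be >= 0", call. = FALSE)
  sqrt(sum(components^2))
}

#' Round a value the way the printed tables do
#'
#' Published thermochemical tables report energies in kJ/mol to one decimal
#' place, with ordinary half-up rounding. Base R's `round()` rounds half to
#' even, which disagrees on boundary cases such as 2875.35, so the report
#' layer uses this helper for all comparisons against printed values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1, the convention for kJ/mol tables).
#' @return Rounded numeric vector.
#' @export
round_table <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
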