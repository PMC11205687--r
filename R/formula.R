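#' Parse a molecular formula in Hill notation
#'
#' Accepts C/H/N/O formulas such as `"C5H7NO"` or `"C6H9NO"`. Counts may be
#' non-integer to accommodate empirical formulas of combustion auxiliaries
#' (the cotton fuse is conventionally written CH1.686O0.843).
#'
#' @param text Formula string; elements restricted to C, H, N, O.
#' @return A named numeric vector of element counts with class
#'   `"chem_formula"`, in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C5H7NO")
#' parse_formula("CH1.686O0.843")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?([0-9]*\\.?[0-9]*)", text))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    bad <- substr(text, 1, 1)
    leftover <- gsub(paste(matched, collapse = "|"), "", text)
    stop(sprintf("malformed formula '%s': cannot parse token '%s'", text,
                 if (nzchar(leftover)) leftover else bad), call. = FALSE)
  }
  counts <- c(C = 0, H = 0, N = 0, O = 0)
  for (tok in matched) {
    el <- sub("[0-9.].*$", "", tok)
    n_str <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n_str)) as.numeric(n_str) else 1
    if (!el %in% c("C", "H", "N", "O")) {
      stop(sprintf("unsupported element '%s' in formula '%s' (only C/H/N/O)", el, text),
           call. = FALSE)
    }
    counts[el] <- counts[el] + n
  }
  structure(counts, class = "chem_formula")
}

as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' @export
format.chem_formula <- function(x, ...) {
  num <- function(n) {
    if (n == 1) "" else if (n == as.integer(n)) as.character(as.integer(n)) else as.character(n)
  }
  parts <- character(0)
  for (el in c("C", "H", "N", "O")) {
    n <- unclass(x)[[el]]
    if (n > 0) parts <- c(parts, paste0(el, num(n)))
  }
  paste(parts, collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format(x), "\n")
  invisible(x)
}

#' Molar mass of a formula
#'
#' Sum of element counts times relative atomic masses. Atomic-mass
#' uncertainties are neglected: the uncertainty budget of combustion
#' thermochemistry is dominated by calorimetric terms several orders of
#' magnitude larger.
#'
#' @param f A `chem_formula` or formula string.
#' @param constants A [thermo_constants()] bundle supplying atomic masses.
#' @return A `qty` in g/mol with u = 0.
#' @examples
#' molar_mass("C5H7NO") # 97.117 g/mol
#' @export
molar_mass <- function(f, constants = thermo_constants()) {
  f <- as_formula(f)
  am <- constants$atomic_masses
  missing_el <- setdiff(names(unclass(f))[unclass(f) > 0], names(am))
  if (length(missing_el)) {
    stop("no atomic mass configured for: ", paste(missing_el, collapse = ", "),
         call. = FALSE)
  }
  m <- sum(unclass(f)[names(am)] * am, na.rm = TRUE)
  qty(m, 0, "g/mol")
}
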