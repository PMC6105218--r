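#' Parse a molecular formula string
#'
#' Converts a formula in Hill notation (e.g. `"C15H12N2O"`) into a named
#' integer vector of element counts. One- and two-letter element symbols are
#' supported; a missing count means 1. Repeated symbols are summed.
#'
#' @param x A single formula string, or an already-parsed named count vector
#'   (returned unchanged after validation).
#' @return Named integer vector of class `ww_formula`, element symbol -> count.
#' @examples
#' parse_formula("C15H12N2O")
#' parse_formula("H2O")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "ww_formula")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(as_ww_formula(x))
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("formula must be a single character string")
  s <- gsub("\\s", "", x)
  if (s == "") return(as_ww_formula(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: '", x, "'")
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  cnts[is.na(cnts)] <- 1L
  counts <- tapply(cnts, syms, sum)
  as_ww_formula(stats::setNames(as.integer(counts), names(counts)))
}

as_ww_formula <- function(v) {
  v <- v[v != 0]
  if (any(v < 0)) stop("element counts must be non-negative")
  unknown <- setdiff(names(v), names(.ww_elements))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  v <- stats::setNames(as.integer(v), names(v))
  if (!length(v)) return(structure(v, class = "ww_formula"))
  structure(v[hill_order(names(v))], class = "ww_formula")
}

hill_order <- function(sym) {
  # C first, H second, everything else alphabetical
  rank <- match(sym, c("C", "H"))
  rank[is.na(rank)] <- 3L
  sym[order(rank, sym)]
}

#' Format a formula in Hill notation
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(f))` is
#' identical to `f`.
#'
#' @param f Formula (string or named count vector).
#' @return A single string in Hill order; counts of 1 are omitted.
#' @examples
#' format_formula(c(O = 1, H = 2))  # "H2O"
#' @export
format_formula <- function(f) {
  f <- parse_formula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.ww_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Sum two formulas element-wise
#'
#' @param f1,f2 Formulas (strings or parsed vectors).
#' @return The combined `ww_formula`.
#' @export
formula_add <- function(f1, f2) {
  f1 <- parse_formula(f1); f2 <- parse_formula(f2)
  all_el <- union(names(f1), names(f2))
  out <- stats::setNames(integer(length(all_el)), all_el)
  out[names(f1)] <- out[names(f1)] + f1
  out[names(f2)] <- out[names(f2)] + f2
  as_ww_formula(out)
}

formula_count <- function(f, element) {
  f <- parse_formula(f)
  if (element %in% names(f)) unname(f[[element]]) else 0L
}
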