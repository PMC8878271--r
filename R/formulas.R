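#' Chemical formula handling
#'
#' Utilities to parse chemical formulas into element counts, write counts
#' back in Hill notation, do element-wise formula arithmetic and compute
#' monoisotopic masses. The supported grammar is a plain sequence of
#' element symbols each optionally followed by a positive integer count
#' (e.g. `"C6H12O6"`); parentheses, hydrates, isotope markers and charge
#' signs are rejected with an informative error.
#'
#' @name formulas
NULL

## Parse a single formula string into a named integer vector. The grammar
## is deliberately strict: anything not matching [A-Z][a-z]?[0-9]* raises.
.parse_formula <- function(x) {
    if (is.na(x))
        stop("formula must not be NA")
    if (!nzchar(x))
        return(stats::setNames(integer(), character()))
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1L]]
    matched <- regmatches(x, list(tokens))[[1L]]
    if (sum(attr(tokens, "match.length")) != nchar(x))
        stop("invalid formula '", x, "': unparseable characters ",
             "(parentheses, charges, isotope markers and hydrates are ",
             "not supported)")
    sym <- sub("[0-9]+$", "", matched)
    cnt <- sub("^[A-Z][a-z]?", "", matched)
    cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
    unknown <- setdiff(sym, names(.element_masses))
    if (length(unknown))
        stop("invalid formula '", x, "': unknown element symbol(s) ",
             paste0("'", unknown, "'", collapse = ", "))
    if (any(cnt < 1L))
        stop("invalid formula '", x, "': element counts must be positive")
    res <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
    stats::setNames(as.integer(res), names(res))
}

#' Count elements in chemical formulas
#'
#' @param x `character` with chemical formulas.
#' @return Named `list` (names `x`) of named integer vectors mapping element
#'   symbol to count. The empty string yields an empty count vector.
#' @examples
#' count_elements(c("C6H12O6", "H2O"))
#' @export
count_elements <- function(x) {
    stats::setNames(lapply(x, .parse_formula), x)
}

.hill_order <- function(symbols) {
    if ("C" %in% symbols) {
        rest <- sort(setdiff(symbols, c("C", "H")))
        c("C", intersect("H", symbols), rest)
    } else sort(symbols)
}

#' Convert element counts to a chemical formula in Hill notation
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically;
#' without carbon, all elements are ordered alphabetically. Counts of 1 are
#' omitted, counts of 0 dropped.
#'
#' @param x Named numeric/integer vector of element counts, or a list of
#'   such vectors.
#' @return `character` of formulas.
#' @examples
#' paste_elements(c(H = 12, C = 6, O = 6))
#' @export
paste_elements <- function(x) {
    if (!is.list(x)) x <- list(x)
    vapply(x, function(cnt) {
        cnt <- cnt[cnt != 0]
        if (!length(cnt)) return("")
        if (any(cnt < 0)) stop("element counts must be non-negative")
        unknown <- setdiff(names(cnt), names(.element_masses))
        if (length(unknown))
            stop("unknown element symbol(s) ",
                 paste0("'", unknown, "'", collapse = ", "))
        ord <- .hill_order(names(cnt))
        cnt <- cnt[ord]
        paste0(names(cnt), ifelse(cnt == 1, "", cnt), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Standardize chemical formulas to Hill notation
#'
#' @param x `character` of formulas.
#' @return `character` of the same length in Hill notation.
#' @examples
#' standardize_formula("H12C6O6")
#' @export
standardize_formula <- function(x) {
    vapply(x, function(f) paste_elements(.parse_formula(f)),
           character(1), USE.NAMES = FALSE)
}

#' Add or subtract chemical formulas element-wise
#'
#' `add_elements()` returns the element-wise sum of two formulas,
#' `subtract_elements()` the difference. Subtraction requires every element
#' count in `y` to be covered by `x`; a would-be negative count raises an
#' error naming the element.
#'
#' @param x,y `character` formulas; recycled to common length.
#' @return `character` of formulas in Hill notation.
#' @examples
#' add_elements("C6H12O6", "H2O")
#' subtract_elements("C6H12O6", "H2O")
#' @export
add_elements <- function(x, y) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n); y <- rep_len(y, n)
    mapply(function(a, b) {
        ca <- .parse_formula(a); cb <- .parse_formula(b)
        all <- union(names(ca), names(cb))
        paste_elements(stats::setNames(
            ifelse(is.na(ca[all]), 0L, ca[all]) +
            ifelse(is.na(cb[all]), 0L, cb[all]), all))
    }, x, y, USE.NAMES = FALSE)
}

#' @rdname add_elements
#' @export
subtract_elements <- function(x, y) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n); y <- rep_len(y, n)
    mapply(function(a, b) {
        ca <- .parse_formula(a); cb <- .parse_formula(b)
        all <- union(names(ca), names(cb))
        d <- ifelse(is.na(ca[all]), 0L, ca[all]) -
             ifelse(is.na(cb[all]), 0L, cb[all])
        if (any(d < 0))
            stop("cannot subtract '", b, "' from '", a, "': negative ",
                 "count for element(s) ",
                 paste0("'", all[d < 0], "'", collapse = ", "))
        paste_elements(stats::setNames(d, all))
    }, x, y, USE.NAMES = FALSE)
}

#' Calculate monoisotopic masses from chemical formulas
#'
#' The mass is the count-weighted sum of the monoisotopic masses of the
#' constituent elements (see [element_masses()]).
#'
#' @param x `character` of formulas.
#' @return `numeric` of masses in Da, named by formula. The empty formula
#'   has mass 0.
#' @examples
#' calculate_mass(c("C27H42O3", "C26H28O11"))
#' @export
calculate_mass <- function(x) {
    vapply(stats::setNames(x, x), function(f) {
        cnt <- .parse_formula(f)
        sum(cnt * .element_masses[names(cnt)])
    }, numeric(1))
}
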