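#' Electrospray adduct definitions and mass/m-z conversion
#'
#' An adduct maps a neutral monoisotopic mass M to an ion m/z through the
#' affine transform `mz = mass_multi * M + mass_add`, where `mass_multi`
#' folds the multimer count and the absolute charge (`n / |z|`) and
#' `mass_add` is the per-charge mass of the gained minus lost species,
#' corrected for the electron mass of the charge state:
#' `mass_add = (sum(gained) - sum(lost) - z * m_e) / |z|`.
#'
#' The registry covers 58 commonly observed electrospray adducts from
#' positive and negative ionization mode, assembled from widely published
#' ESI adduct lists. Each entry is defined compositionally (multimer count,
#' charge, gained and lost formulas) and its numeric transform is computed
#' from the packaged element masses, so the registry is consistent with
#' [calculate_mass()] to sub-ppm accuracy. User-supplied definitions in the
#' same data.frame layout participate identically.
#'
#' @name adducts
NULL

## name, n (multimer count), z (signed charge), gained formula, lost formula
.ADDUCT_COMPOSITION <- local({
    p <- function(name, n, z, gain = "", loss = "")
        data.frame(name = name, n = n, z = z, gain = gain, loss = loss)
    rbind(
        ## -- positive mode, singly charged monomers
        p("[M+H]+",          1L,  1L, "H"),
        p("[M+NH4]+",        1L,  1L, "NH4"),
        p("[M+Na]+",         1L,  1L, "Na"),
        p("[M+K]+",          1L,  1L, "K"),
        p("[M+Li]+",         1L,  1L, "Li"),
        p("[M+CH3OH+H]+",    1L,  1L, "CH4OH"),
        p("[M+ACN+H]+",      1L,  1L, "C2H3NH"),
        p("[M+2ACN+H]+",     1L,  1L, "C4H6N2H"),
        p("[M+ACN+Na]+",     1L,  1L, "C2H3NNa"),
        p("[M+IsoProp+H]+",  1L,  1L, "C3H8OH"),
        p("[M+DMSO+H]+",     1L,  1L, "C2H6OSH"),
        p("[M+2Na-H]+",      1L,  1L, "Na2", "H"),
        p("[M+2K-H]+",       1L,  1L, "K2", "H"),
        p("[M+H-H2O]+",      1L,  1L, "H", "H2O"),
        p("[M+H-2H2O]+",     1L,  1L, "H", "H4O2"),
        p("[M]+",            1L,  1L, "", ""),
        ## -- positive mode, multiply charged
        p("[M+2H]2+",        1L,  2L, "H2"),
        p("[M+H+Na]2+",      1L,  2L, "HNa"),
        p("[M+H+K]2+",       1L,  2L, "HK"),
        p("[M+H+NH4]2+",     1L,  2L, "NH5"),
        p("[M+2Na]2+",       1L,  2L, "Na2"),
        p("[M+ACN+2H]2+",    1L,  2L, "C2H5N"),
        p("[M+2ACN+2H]2+",   1L,  2L, "C4H8N2"),
        p("[M+3H]3+",        1L,  3L, "H3"),
        p("[M+2H+Na]3+",     1L,  3L, "H2Na"),
        p("[M+H+2Na]3+",     1L,  3L, "HNa2"),
        p("[M+3Na]3+",       1L,  3L, "Na3"),
        ## -- positive mode, multimers
        p("[2M+H]+",         2L,  1L, "H"),
        p("[2M+NH4]+",       2L,  1L, "NH4"),
        p("[2M+Na]+",        2L,  1L, "Na"),
        p("[2M+K]+",         2L,  1L, "K"),
        p("[2M+ACN+H]+",     2L,  1L, "C2H3NH"),
        p("[3M+H]+",         3L,  1L, "H"),
        ## -- negative mode, singly charged monomers
        p("[M-H]-",          1L, -1L, "", "H"),
        p("[M-H2O-H]-",      1L, -1L, "", "H3O"),
        p("[M+Na-2H]-",      1L, -1L, "Na", "H2"),
        p("[M+K-2H]-",       1L, -1L, "K", "H2"),
        p("[M+Li-2H]-",      1L, -1L, "Li", "H2"),
        p("[M+Cl]-",         1L, -1L, "Cl"),
        p("[M+Br]-",         1L, -1L, "Br"),
        p("[M+F]-",          1L, -1L, "F"),
        p("[M+HCOO]-",       1L, -1L, "CHO2"),
        p("[M+CH3COO]-",     1L, -1L, "C2H3O2"),
        p("[M+TFA-H]-",      1L, -1L, "C2F3O2"),
        p("[M+HCO3]-",       1L, -1L, "CHO3"),
        p("[M+NO3]-",        1L, -1L, "NO3"),
        p("[M+H2PO4]-",      1L, -1L, "H2O4P"),
        p("[M+HSO4]-",       1L, -1L, "HO4S"),
        p("[M]-",            1L, -1L, "", ""),
        ## -- negative mode, multiply charged
        p("[M-2H]2-",        1L, -2L, "", "H2"),
        p("[M-3H]3-",        1L, -3L, "", "H3"),
        ## -- negative mode, multimers
        p("[2M-H]-",         2L, -1L, "", "H"),
        p("[2M-H2O-H]-",     2L, -1L, "", "H3O"),
        p("[2M+HCOO]-",      2L, -1L, "CHO2"),
        p("[2M+CH3COO]-",    2L, -1L, "C2H3O2"),
        p("[2M+Na-2H]-",     2L, -1L, "Na", "H2"),
        p("[2M+Cl]-",        2L, -1L, "Cl"),
        p("[3M-H]-",         3L, -1L, "", "H")
    )
})

.build_adduct_registry <- function() {
    comp <- .ADDUCT_COMPOSITION
    gain <- calculate_mass(comp$gain)
    loss <- calculate_mass(comp$loss)
    data.frame(
        name = comp$name,
        mass_multi = comp$n / abs(comp$z),
        mass_add = (gain - loss - comp$z * .ELECTRON_MASS) / abs(comp$z),
        charge = comp$z,
        polarity = ifelse(comp$z > 0, "positive", "negative"),
        formula_add = comp$gain,
        formula_sub = comp$loss,
        row.names = NULL
    )
}

#' Built-in adduct registry
#'
#' @param polarity Optional `"positive"` or `"negative"` to filter; `NULL`
#'   (default) returns all 58 definitions.
#' @return `data.frame` with columns `name`, `mass_multi`, `mass_add`,
#'   `charge`, `polarity`, `formula_add`, `formula_sub`.
#' @examples
#' nrow(adduct_registry())
#' adduct_registry("negative")$name
#' @export
adduct_registry <- function(polarity = NULL) {
    reg <- .adduct_registry_cache()
    if (!is.null(polarity)) {
        polarity <- match.arg(polarity, c("positive", "negative"))
        reg <- reg[reg$polarity == polarity, , drop = FALSE]
        rownames(reg) <- NULL
    }
    reg
}

.registry_env <- new.env(parent = emptyenv())
.adduct_registry_cache <- function() {
    if (is.null(.registry_env$reg))
        .registry_env$reg <- .build_adduct_registry()
    .registry_env$reg
}

## Resolve adduct argument (character names or data.frame of definitions)
## into a validated definitions data.frame.
.resolve_adducts <- function(adduct) {
    if (is.character(adduct)) {
        reg <- .adduct_registry_cache()
        idx <- match(adduct, reg$name)
        if (anyNA(idx))
            stop("unknown adduct(s) ",
                 paste0("'", adduct[is.na(idx)], "'", collapse = ", "),
                 ". Available: ", paste(reg$name, collapse = ", "))
        reg[idx, , drop = FALSE]
    } else if (is.data.frame(adduct)) {
        need <- c("name", "mass_multi", "mass_add")
        if (!all(need %in% names(adduct)))
            stop("adduct definition data.frame needs columns ",
                 paste(need, collapse = ", "))
        if (any(adduct$mass_multi <= 0))
            stop("adduct mass_multi must be > 0")
        adduct
    } else stop("'adduct' must be a character vector of adduct names or a ",
                "data.frame of adduct definitions")
}

#' Convert between neutral exact mass and ion m/z
#'
#' `mass2mz()` applies `mz = mass * mass_multi + mass_add` for each adduct;
#' `mz2mass()` inverts it. Both are vectorized over masses and adducts:
#' with a single adduct a numeric vector is returned, with several a
#' mass-by-adduct matrix.
#'
#' @param x `numeric` neutral masses (Da) for `mass2mz()`, m/z values for
#'   `mz2mass()`.
#' @param adduct Adduct name(s) from [adduct_registry()] or a data.frame of
#'   definitions (columns `name`, `mass_multi`, `mass_add`).
#' @return `numeric` (one adduct) or `matrix` (rows `x`, columns adducts).
#' @examples
#' mass2mz(calculate_mass("C27H42O3"), "[M+H]+")
#' mz2mass(415.3207, "[M+H]+")
#' mass2mz(c(100, 200), c("[M+H]+", "[M+Na]+"))
#' @export
mass2mz <- function(x, adduct = "[M+H]+") {
    def <- .resolve_adducts(adduct)
    res <- outer(x, seq_len(nrow(def)),
                 function(m, i) m * def$mass_multi[i] + def$mass_add[i])
    dimnames(res) <- list(names(x), def$name)
    if (nrow(def) == 1L) res[, 1L] else res
}

#' @rdname mass2mz
#' @export
mz2mass <- function(x, adduct = "[M+H]+") {
    def <- .resolve_adducts(adduct)
    res <- outer(x, seq_len(nrow(def)),
                 function(mz, i) (mz - def$mass_add[i]) / def$mass_multi[i])
    if (any(res <= 0))
        stop("resulting neutral mass is not positive for ",
             sum(res <= 0), " value(s); check the adduct assignment")
    dimnames(res) <- list(names(x), def$name)
    if (nrow(def) == 1L) res[, 1L] else res
}
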