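## Minimal periodic-table lookup: the elements that occur in protein
## structures and common cofactors. Standard atomic weights (amu).

.elementTable <- data.frame(
  symbol = c("H", "He", "Li", "B", "C", "N", "O", "F", "Na", "Mg",
             "P", "S", "Cl", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu",
             "Zn", "Se", "Br", "I"),
  Z = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 9L, 11L, 12L,
        15L, 16L, 17L, 19L, 20L, 25L, 26L, 27L, 28L, 29L,
        30L, 34L, 35L, 53L),
  mass = c(1.008, 4.0026, 6.94, 10.81, 12.011, 14.007, 15.999, 18.998,
           22.990, 24.305, 30.974, 32.06, 35.45, 39.098, 40.078,
           54.938, 55.845, 58.933, 58.693, 63.546, 65.38, 78.971,
           79.904, 126.90),
  stringsAsFactors = FALSE
)

#' Atomic number of an element symbol
#' @param symbol character vector of element symbols (case-insensitive).
#' @return integer vector of atomic numbers.
#' @export
elementNumber <- function(symbol) {
  key <- paste0(toupper(substr(symbol, 1, 1)),
                tolower(substr(symbol, 2, 2)))
  idx <- match(key, .elementTable$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .elementTable$Z[idx]
}

#' Element symbol of an atomic number
#' @param Z integer vector of atomic numbers.
#' @return character vector of symbols.
#' @export
elementSymbol <- function(Z) {
  idx <- match(as.integer(Z), .elementTable$Z)
  if (anyNA(idx))
    stop("unknown atomic number(s): ",
         paste(unique(Z[is.na(idx)]), collapse = ", "))
  .elementTable$symbol[idx]
}

#' Standard atomic weight of an atomic number
#' @param Z integer vector of atomic numbers.
#' @return numeric vector, amu.
#' @export
elementMass <- function(Z) {
  idx <- match(as.integer(Z), .elementTable$Z)
  if (anyNA(idx))
    stop("unknown atomic number(s): ",
         paste(unique(Z[is.na(idx)]), collapse = ", "))
  .elementTable$mass[idx]
}
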