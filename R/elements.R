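# Element symbol <-> atomic number tables and the configurable vocabulary.

.PERIODIC <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Mn = 25L, Fe = 26L, Co = 27L,
  Ni = 28L, Cu = 29L, Zn = 30L, As = 33L, Se = 34L, Br = 35L, I = 53L
)

#' Default element vocabulary
#'
#' Atomic numbers the model accepts by default: H, C, N, O, F, P, S, Cl, Br, I.
#' Atoms outside the vocabulary are rejected at parse time rather than mapped
#' to a dummy type.
#'
#' @param extra integer vector of additional atomic numbers to allow.
#' @return sorted integer vector of atomic numbers.
#' @export
default_vocabulary <- function(extra = integer()) {
  sort(unique(c(1L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L, as.integer(extra))))
}

#' Map element symbols to atomic numbers
#'
#' Case-insensitive ("CL" and "Cl" both map to 17). Unknown symbols are an
#' error naming the offending symbol.
#'
#' @param symbols character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
element_number <- function(symbols) {
  s <- trimws(symbols)
  # normalize case: first letter upper, rest lower
  s <- paste0(toupper(substr(s, 1, 1)), tolower(substring(s, 2)))
  z <- .PERIODIC[s]
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}

#' Map atomic numbers to element symbols
#' @param z integer vector of atomic numbers.
#' @return character vector of symbols.
#' @export
element_symbol <- function(z) {
  idx <- match(as.integer(z), .PERIODIC)
  if (anyNA(idx)) {
    stop("no symbol known for atomic number(s): ",
         paste(unique(z[is.na(idx)]), collapse = ", "))
  }
  names(.PERIODIC)[idx]
}

# Error (with a vocabulary message) if any element is outside `vocab`.
check_vocabulary <- function(z, vocab) {
  out <- setdiff(unique(as.integer(z)), as.integer(vocab))
  if (length(out) > 0) {
    lab <- vapply(out, function(zz) {
      if (zz %in% .PERIODIC) paste0(element_symbol(zz), " (Z=", zz, ")")
      else paste0("Z=", zz)
    }, character(1))
    stop("element(s) outside the configured vocabulary: ",
         paste(lab, collapse = ", "))
  }
  invisible(TRUE)
}
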