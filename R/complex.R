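# The unified atomic representation of a protein-ligand system.

#' Construct an atomic complex
#'
#' The container every pipeline stage operates on: atomic numbers, Cartesian
#' coordinates in Angstrom, and a per-atom membership flag (`"protein"` or
#' `"ligand"`), plus an optional pK label (pKi/pKd/pEC50; dimensionless
#' negative log) and an opaque id. Coordinates are never re-centered or
#' re-oriented: the model downstream is E(3)-invariant, so provenance is
#' preserved as-is.
#'
#' @param elements integer vector of atomic numbers.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param membership character vector, each `"protein"` or `"ligand"`.
#' @param label optional numeric pK label (NA if unlabeled).
#' @param id opaque identifier string.
#' @return object of class `atomic_complex`.
#' @export
atomic_complex <- function(elements, coords, membership, label = NA_real_,
                           id = "complex") {
  elements <- as.integer(elements)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3) {
    stop("coords must be an n x 3 numeric matrix")
  }
  storage.mode(coords) <- "double"
  membership <- as.character(membership)
  n <- length(elements)
  if (nrow(coords) != n || length(membership) != n) {
    stop("elements, coords and membership must describe the same atoms ",
         "(lengths ", n, ", ", nrow(coords), ", ", length(membership), ")")
  }
  if (n > 0 && !all(is.finite(coords))) stop("all coordinates must be finite")
  if (!all(membership %in% c("protein", "ligand"))) {
    stop("membership entries must be 'protein' or 'ligand'")
  }
  if (any(elements < 1L)) stop("atomic numbers must be positive")
  dimnames(coords) <- NULL
  structure(
    list(elements = elements, coords = coords, membership = membership,
         label = as.numeric(label)[1], id = as.character(id)[1]),
    class = "atomic_complex"
  )
}

#' @export
print.atomic_complex <- function(x, ...) {
  nl <- sum(x$membership == "ligand")
  np <- sum(x$membership == "protein")
  cat(sprintf("<atomic_complex '%s': %d ligand + %d protein atoms%s>\n",
              x$id, nl, np,
              if (is.na(x$label)) "" else sprintf(", pK = %.3f", x$label)))
  invisible(x)
}

#' Number of atoms in a complex
#' @param x an `atomic_complex`.
#' @export
n_atoms <- function(x) length(x$elements)

ligand_idx <- function(x) which(x$membership == "ligand")
protein_idx <- function(x) which(x$membership == "protein")

#' Truncate a protein to the binding pocket
#'
#' Retains all ligand atoms and exactly those protein atoms whose minimum
#' distance to any ligand atom is at most `radius`. Atom ordering is
#' preserved; `radius = Inf` disables truncation. The default of 8 Angstrom is
#' the 5 Angstrom message cutoff plus margin, so pocket truncation cannot clip
#' the receptive field of the pair readout.
#'
#' @param x an `atomic_complex`.
#' @param radius pocket radius in Angstrom (>= 0).
#' @return an `atomic_complex` with distant protein atoms removed.
#' @export
extract_pocket <- function(x, radius = 8) {
  stopifnot(inherits(x, "atomic_complex"))
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0) {
    stop("radius must be a single non-negative number")
  }
  if (is.infinite(radius)) return(x)
  li <- ligand_idx(x)
  pi_ <- protein_idx(x)
  if (length(pi_) == 0 || length(li) == 0) return(x)
  d2 <- cross_dist2(x$coords[pi_, , drop = FALSE], x$coords[li, , drop = FALSE])
  keep_p <- pi_[sqrt(pmax(apply(d2, 1, min), 0)) <= radius]
  keep <- sort(c(li, keep_p))
  atomic_complex(x$elements[keep], x$coords[keep, , drop = FALSE],
                 x$membership[keep], x$label, x$id)
}

# Squared Euclidean distances between rows of a (n x 3) and rows of b (m x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}
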