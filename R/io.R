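# Structure file I/O: PDB (protein), SDF/MOL2 (ligand), dataset manifests.
#
# Minimal fixed-column readers are implemented here on purpose: the package
# has no compiled or external parsing dependency, and only the coordinate,
# element and record-type fields are consumed.

.WATER_RES <- c("HOH", "WAT", "DOD", "TIP", "SOL")

# Parse ATOM records of a PDB file into a data.frame(z, x, y, z).
# Waters and HETATM records are dropped (the ligand arrives separately as
# SDF/MOL2); of alternate locations only blank or 'A' is kept.
read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) == "ATOM"
  if (!any(keep)) stop("no ATOM records found in PDB file: ", path)
  ln <- lines[keep]
  lineno <- which(keep)
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  ok <- altloc %in% c(" ", "", "A") & !(resname %in% .WATER_RES)
  ln <- ln[ok]
  lineno <- lineno[ok]
  if (length(ln) == 0) stop("no usable ATOM records in PDB file: ", path)
  xs <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0) {
    stop(sprintf("unparseable coordinates in PDB record at line %d of %s",
                 lineno[bad[1]], path))
  }
  sym <- trimws(substr(ln, 77, 78))
  # fall back to the atom-name field when the element column is absent
  miss <- which(sym == "")
  if (length(miss) > 0) {
    nm <- substr(ln[miss], 13, 16)
    sym[miss] <- vapply(nm, pdb_name_element, character(1), USE.NAMES = FALSE)
  }
  data.frame(element = element_number(sym), x = xs, y = ys, z = zs)
}

# Heuristic element from the 4-character PDB atom-name field (cols 13-16):
# a character in column 13 signals a two-letter element, otherwise the first
# alphabetic character of the name is the element.
pdb_name_element <- function(name) {
  first <- substr(name, 1, 1)
  if (grepl("[A-Za-z]", first)) {
    two <- gsub("[^A-Za-z]", "", substr(name, 1, 2))
    if (nchar(two) == 2) return(two)
  }
  letters_only <- gsub("[^A-Za-z]", "", name)
  if (nchar(letters_only) == 0) stop("cannot infer element from atom name: '", name, "'")
  substr(letters_only, 1, 1)
}

# Parse the first molecule of a V2000 SDF/MOL file.
read_sdf_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("truncated SDF file: ", path)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(natoms)) stop("unparseable counts line (line 4) in SDF file: ", path)
  if (natoms == 0) stop("SDF file declares zero atoms (empty ligand): ", path)
  if (length(lines) < 4 + natoms) stop("SDF atom block truncated: ", path)
  blk <- lines[5:(4 + natoms)]
  xs <- suppressWarnings(as.numeric(substr(blk, 1, 10)))
  ys <- suppressWarnings(as.numeric(substr(blk, 11, 20)))
  zs <- suppressWarnings(as.numeric(substr(blk, 21, 30)))
  sym <- trimws(substr(blk, 32, 34))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | sym == "")
  if (length(bad) > 0) {
    stop(sprintf("unparseable SDF atom record at line %d of %s", 4 + bad[1], path))
  }
  data.frame(element = element_number(sym), x = xs, y = ys, z = zs)
}

# Parse the @<TRIPOS>ATOM section of a MOL2 file.
read_mol2_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- which(trimws(lines) == "@<TRIPOS>ATOM")
  if (length(start) == 0) stop("no @<TRIPOS>ATOM section in MOL2 file: ", path)
  start <- start[1] + 1
  ends <- which(startsWith(trimws(lines), "@<TRIPOS>"))
  stop_at <- ends[ends >= start]
  end <- if (length(stop_at) > 0) stop_at[1] - 1 else length(lines)
  blk <- lines[start:end]
  blk <- blk[nzchar(trimws(blk))]
  if (length(blk) == 0) stop("MOL2 file has an empty atom section: ", path)
  fields <- strsplit(trimws(blk), "[[:space:]]+")
  parse_row <- function(f, i) {
    if (length(f) < 6) {
      stop(sprintf("unparseable MOL2 atom record %d in %s", i, path))
    }
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (anyNA(xyz)) stop(sprintf("unparseable MOL2 coordinates in record %d of %s", i, path))
    c(xyz, NA)
  }
  xyz <- t(vapply(seq_along(fields), function(i) parse_row(fields[[i]], i), numeric(4)))[, 1:3, drop = FALSE]
  sym <- vapply(fields, function(f) sub("\\..*$", "", f[6]), character(1))
  data.frame(element = element_number(sym), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Read a protein-ligand complex from structure files
#'
#' The protein is read from PDB (`ATOM` records; waters, hetero records and
#' non-first altlocs dropped), the ligand from SDF or MOL2 chosen by file
#' extension. Hydrogens present in the files are retained; no protonation or
#' preparation is attempted. Every element must belong to `vocab`.
#'
#' @param protein_file path to a PDB file (may be `NULL` for a ligand-only
#'   complex).
#' @param ligand_file path to an SDF (.sdf/.mol) or MOL2 (.mol2) file.
#' @param vocab integer vector of allowed atomic numbers.
#' @param id identifier for the resulting complex.
#' @param label optional pK label.
#' @return an [atomic_complex()].
#' @export
read_complex <- function(protein_file, ligand_file,
                         vocab = default_vocabulary(),
                         id = NULL, label = NA_real_) {
  lig <- switch(tolower(tools::file_ext(ligand_file)),
    "sdf" = read_sdf_atoms(ligand_file),
    "mol" = read_sdf_atoms(ligand_file),
    "mol2" = read_mol2_atoms(ligand_file),
    stop("unsupported ligand format: ", ligand_file)
  )
  prot <- if (is.null(protein_file)) {
    data.frame(element = integer(), x = numeric(), y = numeric(), z = numeric())
  } else {
    read_pdb_atoms(protein_file)
  }
  elements <- c(prot$element, lig$element)
  check_vocabulary(elements, vocab)
  coords <- rbind(as.matrix(prot[, c("x", "y", "z")]),
                  as.matrix(lig[, c("x", "y", "z")]))
  membership <- c(rep("protein", nrow(prot)), rep("ligand", nrow(lig)))
  if (is.null(id)) {
    id <- tools::file_path_sans_ext(basename(ligand_file))
  }
  atomic_complex(elements, coords, membership, label = label, id = id)
}

#' Write the protein atoms of a complex as a PDB file
#'
#' Minimal single-chain PDB writer (one `UNK` residue, element symbols in
#' columns 77-78, coordinates at the format's 1e-3 Angstrom precision).
#'
#' @param x an `atomic_complex`.
#' @param path output file path.
#' @export
write_pdb <- function(x, path) {
  pi_ <- protein_idx(x)
  sym <- element_symbol(x$elements[pi_])
  co <- x$coords[pi_, , drop = FALSE]
  lines <- vapply(seq_along(pi_), function(k) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            k, substr(sym[k], 1, 2), "UNK", "A", 1L,
            co[k, 1], co[k, 2], co[k, 3], 1.0, 0.0, sym[k])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the ligand atoms of a complex as a V2000 SDF file
#' @param x an `atomic_complex`.
#' @param path output file path.
#' @export
write_sdf <- function(x, path) {
  li <- ligand_idx(x)
  if (length(li) == 0) stop("complex has no ligand atoms to write")
  sym <- element_symbol(x$elements[li])
  co <- x$coords[li, , drop = FALSE]
  atom_lines <- vapply(seq_along(li), function(k) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            co[k, 1], co[k, 2], co[k, 3], sym[k])
  }, character(1))
  lines <- c(x$id, "  eqbind", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", length(li), 0L),
             atom_lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `id`, `protein_path`, `ligand_path`,
#' `label`; paths are resolved relative to the manifest's directory. An empty
#' `protein_path` denotes a ligand-only record.
#'
#' @param path manifest CSV path.
#' @param strict if `TRUE` (default) any unreadable record aborts naming its
#'   id; if `FALSE` failing records are skipped with a warning.
#' @param vocab allowed atomic numbers.
#' @return list of labeled [atomic_complex()] objects.
#' @export
read_manifest <- function(path, strict = TRUE, vocab = default_vocabulary()) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "protein_path", "ligand_path", "label")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate ids in manifest: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  out <- vector("list", nrow(tab))
  ok <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pp <- tab$protein_path[i]
    pp <- if (is.na(pp) || !nzchar(pp)) NULL else file.path(base, pp)
    lp <- file.path(base, tab$ligand_path[i])
    res <- tryCatch({
      if (!is.null(pp) && !file.exists(pp)) stop("missing protein file: ", pp)
      if (!file.exists(lp)) stop("missing ligand file: ", lp)
      read_complex(pp, lp, vocab = vocab, id = tab$id[i], label = tab$label[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("manifest record '%s': %s", tab$id[i], conditionMessage(res))
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    } else {
      out[[i]] <- res
      ok[i] <- TRUE
    }
  }
  out[ok]
}

#' Write a dataset manifest plus structure files
#'
#' Writes each complex as `<id>_protein.pdb` + `<id>_ligand.sdf` under `dir`
#' and a `manifest.csv` referencing them, so synthetic data exercises the same
#' I/O stack as real data.
#'
#' @param complexes list of `atomic_complex` (labels taken from each object).
#' @param dir output directory (created if needed).
#' @return path to the manifest file.
#' @export
write_dataset <- function(complexes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(complexes, function(x) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", x$id)
    pp <- paste0(safe, "_protein.pdb")
    lp <- paste0(safe, "_ligand.sdf")
    has_prot <- any(x$membership == "protein")
    if (has_prot) write_pdb(x, file.path(dir, pp))
    write_sdf(x, file.path(dir, lp))
    data.frame(id = x$id, protein_path = if (has_prot) pp else "",
               ligand_path = lp, label = x$label)
  })
  tab <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(tab, mpath, row.names = FALSE)
  mpath
}
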