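## Structure I/O: PDB parsing (via bio3d) into AtomSet, van der Waals radius
## assignment, hetatom/hydrogen stripping, and fixed-column PDB writing for
## synthetic channels.

#' HOLE-style van der Waals radius table
#'
#' The "simple" radius set (C 1.85, N 1.75, O 1.65, S 2.00, P 2.10,
#' H 1.00 Angstrom) shipped as an editable CSV in
#' `inst/extdata/vdw_simple.csv`.
#'
#' @return data.frame with columns `element` and `radius`.
#' @export
defaultVdwTable <- function() {
  path <- system.file("extdata", "vdw_simple.csv", package = "poregate")
  if (nzchar(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    data.frame(element = c("C", "N", "O", "S", "P", "H"),
               radius = c(1.85, 1.75, 1.65, 2.00, 2.10, 1.00),
               stringsAsFactors = FALSE)
  }
}

.elementFromName <- function(atomName) {
  ## first alphabetic character of the PDB atom name, uppercased
  toupper(substring(gsub("[^A-Za-z].*$", "",
                         sub("^[0-9 ]*", "", atomName)), 1L, 1L))
}

.assignVdw <- function(element, table, fallbackRadius) {
  r <- table$radius[match(element, table$element)]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            ": using fallback radius ", fallbackRadius, " A")
    r[is.na(r)] <- fallbackRadius
  }
  r
}

#' Load a structure from PDB into an AtomSet
#'
#' Parses ATOM/HETATM records (first MODEL of multi-model files) and assigns
#' a van der Waals radius per atom from the configured table. All records are
#' kept; use [stripForProfile()] to remove waters, heteroatoms and hydrogens
#' before pore profiling.
#'
#' @param x path to a PDB file, or a character scalar containing PDB text.
#' @param radiusTable data.frame with `element`/`radius` columns
#'   ([defaultVdwTable()] by default).
#' @param fallbackRadius radius (Angstrom) assigned, with a warning, to
#'   elements absent from the table.
#' @return An [AtomSet-class].
#' @export
loadStructure <- function(x, radiusTable = defaultVdwTable(),
                          fallbackRadius = 1.85) {
  path <- x
  if (length(x) == 1L && !file.exists(x) && grepl("\n", x)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(strsplit(x, "\n", fixed = TRUE)[[1L]], path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  missingEl <- is.na(element) | !nzchar(trimws(element))
  element[missingEl] <- .elementFromName(at$elety[missingEl])
  element <- toupper(trimws(element))
  coords <- as.matrix(at[, c("x", "y", "z")])
  chain <- at$chain
  chain[is.na(chain)] <- ""
  atomSet(coords = coords,
          vdw = .assignVdw(element, radiusTable, fallbackRadius),
          element = element, atomName = trimws(at$elety),
          resName = trimws(at$resid), resNo = at$resno, chain = chain,
          record = at$type)
}

#' Strip a structure down to the atoms used for pore profiling
#'
#' Keeps protein ATOM records of one chain, removing waters and all other
#' heteroatoms, and (by default) hydrogens, so radii are computed on heavy
#' atoms only.
#'
#' @param atoms an [AtomSet-class].
#' @param chain chain identifier to retain (NULL keeps all chains).
#' @param dropHydrogens drop element-H atoms (default TRUE).
#' @return The filtered [AtomSet-class].
#' @export
stripForProfile <- function(atoms, chain = NULL, dropHydrogens = TRUE) {
  stopifnot(is(atoms, "AtomSet"))
  keep <- atoms@record == "ATOM" & !(atoms@resName %in% c("HOH", "WAT", "DOD"))
  if (!is.null(chain)) {
    if (!any(atoms@chain == chain)) stop("chain '", chain, "' not present")
    keep <- keep & atoms@chain == chain
  }
  if (dropHydrogens) keep <- keep & !(atoms@element %in% c("H", "D"))
  if (!any(keep)) stop("no atoms left after stripping")
  atoms[keep]
}

#' Write an AtomSet as PDB text
#'
#' Fixed-column ATOM/HETATM records with element-correct columns 77-78, so
#' standard structure tools can read the output.
#'
#' @param atoms an [AtomSet-class].
#' @param path output file; when NULL the text is returned invisibly only.
#' @return invisibly, the PDB text as a single string.
#' @export
writeStructurePdb <- function(atoms, path = NULL) {
  stopifnot(is(atoms, "AtomSet"))
  n <- nAtoms(atoms)
  lines <- vapply(seq_len(n), function(i) {
    nm <- atoms@atomName[i]
    ## PDB convention: 1-2 char element names start in column 14
    nmField <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            atoms@record[i], i %% 100000L, nmField, "", atoms@resName[i],
            substr(atoms@chain[i], 1L, 1L), atoms@resNo[i] %% 10000L, "",
            atoms@coords[i, 1L], atoms@coords[i, 2L], atoms@coords[i, 3L],
            1, 0, atoms@element[i])
  }, character(1L))
  txt <- paste(c(lines, "END"), collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
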