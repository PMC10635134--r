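## Fixed-width PDB reading/writing and atom selection.
##
## Dialect: wwPDB v3.3 column layout; HETATM records are treated identically
## to ATOM; altLoc other than blank/'A' is dropped with a warning; the element
## is inferred from the atom name when the element columns are blank.
## Residue numbers are taken verbatim (author numbering).

## Bondi vdW radii by element; unknown elements fall back to 1.7 A.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
            S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
            MG = 1.73, ZN = 1.39, FE = 1.70, SE = 1.90)

#' van der Waals radius lookup
#'
#' Bondi radii by element symbol; 1.7 Angstrom for unknown elements.  The
#' table can be overridden per call.
#' @param element character vector of element symbols.
#' @param table optional named numeric vector overriding the defaults.
#' @return numeric vector of radii (Angstrom).
#' @export
vdwRadius <- function(element, table = NULL) {
    tab <- .BONDI
    names(tab)[names(tab) == "NA."] <- "NA"
    if (!is.null(table)) tab[names(table)] <- table
    r <- tab[toupper(element)]
    r[is.na(r)] <- 1.7
    unname(r)
}

## infer element symbol from a PDB atom name (columns 13-16)
.elementFromName <- function(name) {
    vapply(name, function(nm) {
        s <- gsub("[0-9' ]", "", nm)
        if (nchar(s) == 0) return("X")
        two <- toupper(substr(s, 1, 2))
        if (two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA"))
            return(two)
        toupper(substr(s, 1, 1))
    }, "", USE.NAMES = FALSE)
}

.numField <- function(txt, lineno, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) | !nzchar(trimws(txt)))
    if (length(bad))
        stop("readPDB: malformed ", what, " field at line ", lineno[bad[1]],
             " ('", txt[bad[1]], "')", call. = FALSE)
    v
}

#' Read a PDB file
#'
#' Parses fixed-width ATOM/HETATM records into a [Structure]; all other
#' record types are ignored.  Malformed coordinate fields raise an error
#' naming the offending line; an empty structure is an error.
#'
#' @param path path to a PDB file.
#' @param radiusTable optional named vdW-radius override (see [vdwRadius]).
#' @return A [Structure].
#' @export
readPDB <- function(path, radiusTable = NULL) {
    if (!file.exists(path)) stop("readPDB: no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- substr(lines, 1, 6)
    keep <- which(rec %in% c("ATOM  ", "HETATM"))
    if (!length(keep)) stop("readPDB: no ATOM/HETATM records in ", path)
    ln <- lines[keep]
    altLoc <- substr(ln, 17, 17)
    drop <- !(altLoc %in% c(" ", "", "A"))
    if (any(drop)) {
        warning("readPDB: dropping ", sum(drop),
                " altLoc records (not blank/'A') in ", basename(path))
        ln <- ln[!drop]; keep <- keep[!drop]
        if (!length(ln)) stop("readPDB: no usable atoms in ", path)
    }
    name <- trimws(substr(ln, 13, 16))
    element <- trimws(substr(ln, 77, 78))
    blank <- !nzchar(element)
    if (any(blank)) element[blank] <- .elementFromName(name[blank])
    atoms <- data.frame(
        serial  = as.integer(.numField(substr(ln, 7, 11), keep, "serial")),
        name    = name,
        element = toupper(element),
        resName = trimws(substr(ln, 18, 20)),
        resSeq  = as.integer(.numField(substr(ln, 23, 26), keep, "residue number")),
        chain   = substr(ln, 22, 22),
        x = .numField(substr(ln, 31, 38), keep, "x coordinate"),
        y = .numField(substr(ln, 39, 46), keep, "y coordinate"),
        z = .numField(substr(ln, 47, 54), keep, "z coordinate"),
        stringsAsFactors = FALSE)
    atoms$vdw <- vdwRadius(atoms$element, radiusTable)
    Structure(atoms, label = basename(path))
}

#' Write a structure to a PDB file
#'
#' Fixed-width ATOM records, coordinates at 3 decimals; round trips through
#' [readPDB] preserve atom order, serials, names, residue numbers and
#' coordinates to the format precision.
#'
#' @param structure A [Structure].
#' @param path output file path.
#' @param hetatm logical: write HETATM instead of ATOM records.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(structure, path, hetatm = FALSE) {
    a <- atoms(structure)
    recname <- if (hetatm) "HETATM" else "ATOM  "
    nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                 sprintf("%-4s", a$name))
    lines <- sprintf("%s%5d %s %-3s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     recname, a$serial, nm, a$resName,
                     ifelse(nzchar(a$chain), a$chain, " "),
                     a$resSeq, a$x, a$y, a$z, 1, 0, a$element)
    writeLines(c(lines, "END"), path)
    invisible(path)
}

#' Subset a structure by residue number and atom name
#'
#' Preserves atom order; an empty selection is legal and returns an empty
#' [Structure].
#'
#' @param structure A [Structure].
#' @param resSeq integer vector of residue numbers, or NULL for all.
#' @param atomNames character vector of atom names, or NULL for all.
#' @return The selected [Structure].
#' @export
selectAtoms <- function(structure, resSeq = NULL, atomNames = NULL) {
    a <- atoms(structure)
    keep <- rep(TRUE, nrow(a))
    if (!is.null(resSeq)) keep <- keep & a$resSeq %in% resSeq
    if (!is.null(atomNames)) keep <- keep & a$name %in% atomNames
    Structure(a[keep, , drop = FALSE], label = structure@label)
}

#' Heavy-atom subset of a structure
#' @param structure A [Structure].
#' @return The [Structure] without hydrogens.
#' @export
heavyAtoms <- function(structure) {
    a <- atoms(structure)
    Structure(a[a$element != "H", , drop = FALSE], label = structure@label)
}
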