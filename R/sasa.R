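## Solvent-accessible surface area (Shrake-Rupley) and the cavity-openness
## progress coordinate.

#' Define the cavity-lining residue set for the openness coordinate
#'
#' The default residue list is the 17 residues lining the ARNT PAS-B internal
#' cavity (F363, S365, F373, I396, R409, S411, F412, V415, V425, F427, F429,
#' M439, T441, S443, I457, C459, N461); the probe radius defaults to the
#' conventional 1.4 Angstrom water probe.
#'
#' @param residues integer vector of residue numbers.
#' @param probeRadius probe sphere radius, Angstrom (> 0).
#' @param nSpherePoints points on the test lattice per atom (>= 60).
#' @param includeHydrogens logical; default heavy atoms only (crystal
#'   structures typically lack hydrogens).
#' @return list of class "CavityDefinition".
#' @export
cavityDefinition <- function(residues = c(363, 365, 373, 396, 409, 411, 412,
                                          415, 425, 427, 429, 439, 441, 443,
                                          457, 459, 461),
                             probeRadius = 1.4, nSpherePoints = 960,
                             includeHydrogens = FALSE) {
    stopifnot(length(residues) > 0, probeRadius > 0, nSpherePoints >= 60)
    structure(list(residues = as.integer(residues), probeRadius = probeRadius,
                   nSpherePoints = as.integer(nSpherePoints),
                   includeHydrogens = includeHydrogens),
              class = "CavityDefinition")
}

## deterministic quasi-uniform unit-sphere lattice (golden-spiral); no RNG
.sphereLattice <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
    cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic golden-spiral lattice of \code{nSpherePoints} test
#' points on each atom's solvent-accessible sphere (radius vdW + probe) and
#' counts the points not buried inside any neighbour's accessible sphere;
#' the accessible fraction scales the sphere area 4*pi*(r+probe)^2.
#'
#' @param structure A [Structure] (>= 1 atom).
#' @param probeRadius probe radius, Angstrom.
#' @param nSpherePoints lattice points per atom.
#' @return list with \code{perAtom} (numeric, Angstrom^2, one value per atom)
#'   and \code{total} (their sum).
#' @export
shrakeRupley <- function(structure, probeRadius = 1.4, nSpherePoints = 960) {
    xyz <- coords(structure)
    n <- nrow(xyz)
    if (n < 1L) stop("shrakeRupley: empty structure")
    rad <- atoms(structure)$vdw + probeRadius
    lattice <- .sphereLattice(nSpherePoints)
    perAtom <- numeric(n)
    ## neighbour search: atom j can occlude i iff |xi-xj| < ri + rj
    for (i in seq_len(n)) {
        d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
        nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
        if (!length(nb)) {
            perAtom[i] <- 4 * pi * rad[i]^2
            next
        }
        pts <- sweep(lattice * rad[i], 2, xyz[i, ], `+`)
        acc <- rep(TRUE, nSpherePoints)
        for (j in nb) {
            if (!any(acc)) break
            dj2 <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
            acc[acc] <- dj2 >= rad[j]^2
        }
        perAtom[i] <- 4 * pi * rad[i]^2 * sum(acc) / nSpherePoints
    }
    list(perAtom = perAtom, total = sum(perAtom))
}

#' Cavity-openness progress coordinate
#'
#' Sum of per-atom SASA over all atoms of the cavity-lining residues,
#' computed in the context of the whole structure (other atoms occlude).
#' This is the 1-D progress coordinate used to drive weighted-ensemble
#' sampling of pocket opening.
#'
#' @param structure A [Structure].
#' @param cavity A [cavityDefinition].
#' @return openness in Angstrom^2.
#' @export
cavityOpenness <- function(structure, cavity = cavityDefinition()) {
    a <- atoms(structure)
    if (!cavity$includeHydrogens) {
        structure <- heavyAtoms(structure)
        a <- atoms(structure)
    }
    missing <- setdiff(cavity$residues, unique(a$resSeq))
    if (length(missing))
        stop("cavityOpenness: residues absent from structure: ",
             paste(missing, collapse = ", "))
    sr <- shrakeRupley(structure, cavity$probeRadius, cavity$nSpherePoints)
    sum(sr$perAtom[a$resSeq %in% cavity$residues])
}
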