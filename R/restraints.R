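## NOE restraint machinery: intensity-class calibration, active-residue
## derivation, heavy-atom extension, effective distances and violations.

#' NOE intensity-class calibration table
#'
#' Upper distance limits of 2.8 / 3.5 / 5.0 Angstrom for strong / medium /
#' weak NOESY cross-peaks; the lower limit is always 1.8 Angstrom (van der
#' Waals contact distance).
#'
#' @param upper named numeric: upper bounds per class, strictly increasing
#'   strong < medium < weak.
#' @param lower common lower bound, Angstrom.
#' @return list of class "CalibrationTable".
#' @export
calibrationTable <- function(upper = c(strong = 2.8, medium = 3.5, weak = 5.0),
                             lower = 1.8) {
    stopifnot(all(c("strong", "medium", "weak") %in% names(upper)))
    u <- upper[c("strong", "medium", "weak")]
    if (!(u[1] < u[2] && u[2] < u[3]))
        stop("calibrationTable: upper bounds must increase strong < medium < weak")
    if (!(lower > 0 && lower < u[1]))
        stop("calibrationTable: lower bound must be positive and below all uppers")
    structure(list(upper = u, lower = lower), class = "CalibrationTable")
}

#' Define a proton group
#'
#' A group of chemically equivalent (or intentionally ambiguous) protons
#' together with the bonded heavy atom of each proton.  Receptor methyl
#' groups list the same carbon for all three protons, so the heavy-atom
#' extension collapses them to a single carbon.
#'
#' @param id group identifier.
#' @param protons character vector of proton atom names (>= 1).
#' @param heavies character vector of bonded heavy-atom names, same length.
#' @param owner "ligand" or "receptor".
#' @param residue receptor residue number (NA for ligand groups).
#' @return list of class "ProtonGroup".
#' @export
protonGroup <- function(id, protons, heavies, owner, residue = NA_integer_) {
    if (length(protons) < 1L || length(heavies) != length(protons))
        stop("protonGroup: protons and heavies must be nonempty and equal length")
    owner <- match.arg(owner, c("ligand", "receptor"))
    structure(list(id = id, protons = protons, heavies = heavies,
                   owner = owner, residue = as.integer(residue)),
              class = "ProtonGroup")
}

.getGroup <- function(groups, id) {
    g <- groups[[id]]
    if (is.null(g)) stop("unknown proton group id: ", id)
    g
}

#' Calibrate classified NOE peaks into interproton distance restraints
#'
#' One restraint per peak: the upper bound is looked up by intensity class
#' and the lower bound is the van der Waals contact distance from the table.
#'
#' @param peaks data.frame with columns \code{ligandGroup},
#'   \code{receptorGroup}, \code{class} ("strong"/"medium"/"weak");
#'   optional \code{lower}/\code{upper} columns override the class lookup.
#' @param groups named list of [protonGroup] records keyed by id.
#' @param table A [calibrationTable].
#' @return A [RestraintSet] of interproton restraints.
#' @export
calibratePeaks <- function(peaks, groups, table = calibrationTable()) {
    if (nrow(peaks) == 0L) return(RestraintSet())
    bad <- setdiff(unique(peaks$class), names(table$upper))
    if (length(bad) && !all(is.na(bad)))
        stop("calibratePeaks: unknown intensity class: ",
             paste(stats::na.omit(bad), collapse = ", "))
    res <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
        lg <- .getGroup(groups, peaks$ligandGroup[i])
        rg <- .getGroup(groups, peaks$receptorGroup[i])
        upper <- unname(table$upper[peaks$class[i]])
        lower <- table$lower
        if (!is.null(peaks$upper) && !is.na(peaks$upper[i])) {
            upper <- peaks$upper[i]           # explicit bounds override class
            if (!is.na(peaks$lower[i])) lower <- peaks$lower[i]
        }
        res[[i]] <- list(
            id = sprintf("%s/%s", lg$id, rg$id),
            groupA = list(owner = "ligand", atoms = lg$protons,
                          residue = NA_integer_, groupId = lg$id),
            groupB = list(owner = "receptor", atoms = rg$protons,
                          residue = rg$residue, groupId = rg$id),
            lower = lower, upper = upper, level = "interproton")
    }
    RestraintSet(res)
}

#' Derive docking-active residues from NOE peaks and site labels
#'
#' Active residues are receptor residues carrying at least one NOE peak AND
#' labelled "cavity"; residues labelled "surface" or "outlier" are excluded
#' (mirroring the exclusion of surface and artifactual contacts from the
#' ambiguous-restraint set).
#'
#' @param peaks peak data.frame (see [calibratePeaks]).
#' @param groups named list of [protonGroup] records.
#' @param siteLabels named character vector: residue number ->
#'   "cavity"/"surface"/"outlier".
#' @return sorted integer vector of active residue numbers (possibly empty,
#'   with a warning when all peak residues are non-cavity).
#' @export
deriveActiveResidues <- function(peaks, groups, siteLabels) {
    if (nrow(peaks) == 0L) return(integer(0))
    resid <- vapply(peaks$receptorGroup,
                    function(id) .getGroup(groups, id)$residue, 1L)
    resid <- unique(resid)
    lab <- siteLabels[as.character(resid)]
    if (any(is.na(lab)))
        stop("deriveActiveResidues: unlabeled residue(s): ",
             paste(resid[is.na(lab)], collapse = ", "))
    active <- sort(resid[lab == "cavity"])
    if (!length(active))
        warning("deriveActiveResidues: no cavity-labelled residues among peaks")
    active
}

#' Extend interproton restraints to heavy-atom distances
#'
#' Each interproton restraint becomes one unambiguous heavy-atom distance per
#' distinct (ligand heavy atom, receptor heavy atom) pair implied by its
#' equivalent protons, with both bounds shifted +1.0 Angstrom to account for
#' the two C-H bonds.  Methyl groups collapse to their single carbon, so a
#' restraint with non-degenerate groups yields exactly one distance.
#'
#' @param restraintSet interproton [RestraintSet] from [calibratePeaks].
#' @param groups named list of [protonGroup] records (for the proton ->
#'   heavy-atom mapping).
#' @param shift bound shift, Angstrom (default +1.0).
#' @return A [RestraintSet] of heavy-atom restraints.
#' @export
extendToHeavyAtoms <- function(restraintSet, groups, shift = 1.0) {
    out <- list()
    for (r in restraints(restraintSet)) {
        if (r$level != "interproton")
            stop("extendToHeavyAtoms: restraint ", r$id, " is not interproton")
        lg <- .getGroup(groups, r$groupA$groupId)
        rg <- .getGroup(groups, r$groupB$groupId)
        if (any(!nzchar(lg$heavies)) || any(!nzchar(rg$heavies)))
            stop("extendToHeavyAtoms: missing heavy-atom mapping in ", r$id)
        la <- unique(lg$heavies); ra <- unique(rg$heavies)
        for (i in seq_along(la)) for (j in seq_along(ra)) {
            out[[length(out) + 1L]] <- list(
                id = sprintf("%s:%s-%s", r$id, la[i], ra[j]),
                groupA = list(owner = "ligand", atoms = la[i],
                              residue = NA_integer_, groupId = lg$id),
                groupB = list(owner = "receptor", atoms = ra[j],
                              residue = rg$residue, groupId = rg$id),
                lower = r$lower + shift, upper = r$upper + shift,
                level = "heavy")
        }
    }
    RestraintSet(out)
}

#' r^-6-summed effective distance between two atom groups
#'
#' d_eff = ( sum_{i in A} sum_{j in B} d_ij^-6 )^(-1/6).  This is the
#' standard ambiguous-restraint aggregate: it never exceeds the minimum
#' pairwise distance and reduces to the plain distance for singleton groups.
#'
#' @param xyzA,xyzB coordinate matrices (n x 3), both nonempty.
#' @return effective distance, Angstrom.
#' @export
effectiveDistance <- function(xyzA, xyzB) {
    xyzA <- matrix(as.numeric(xyzA), ncol = 3)
    xyzB <- matrix(as.numeric(xyzB), ncol = 3)
    if (nrow(xyzA) < 1L || nrow(xyzB) < 1L)
        stop("effectiveDistance: empty group")
    d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) -
        2 * xyzA %*% t(xyzB)
    d2 <- pmax(d2, 0)
    if (any(d2 < 1e-12))
        stop("effectiveDistance: coincident atoms (zero pairwise distance)")
    sum(d2^(-3))^(-1 / 6)
}

.groupCoords <- function(group, receptor, ligand) {
    src <- if (group$owner == "ligand") ligand else receptor
    sel <- selectAtoms(src,
                       resSeq = if (is.na(group$residue)) NULL else group$residue,
                       atomNames = group$atoms)
    if (nAtoms(sel) == 0L)
        stop("cannot resolve atoms ", paste(group$atoms, collapse = ","),
             if (!is.na(group$residue)) paste0(" in residue ", group$residue),
             " (", group$owner, ")")
    coords(sel)
}

#' Evaluate restraint violations for one ligand placement
#'
#' For each restraint the r^-6 effective distance is computed between the
#' resolved atom groups; the violation is
#' max(0, d_eff - upper, lower - d_eff) and a restraint is satisfied when
#' its violation does not exceed \code{tolerance}.
#'
#' @param restraintSet A [RestraintSet].
#' @param receptor receptor [Structure].
#' @param ligand posed ligand [Structure] (already transformed).
#' @param tolerance violation tolerance, Angstrom (default 0.3, the
#'   pose-filter threshold).
#' @return data.frame with columns id, residue, effectiveDistance, lower,
#'   upper, violation, satisfied.
#' @export
evaluateViolations <- function(restraintSet, receptor, ligand,
                               tolerance = 0.3) {
    rs <- restraints(restraintSet)
    n <- length(rs)
    out <- data.frame(id = character(n), residue = integer(n),
                      effectiveDistance = numeric(n), lower = numeric(n),
                      upper = numeric(n), violation = numeric(n),
                      satisfied = logical(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        r <- rs[[i]]
        d <- effectiveDistance(.groupCoords(r$groupA, receptor, ligand),
                               .groupCoords(r$groupB, receptor, ligand))
        v <- max(0, d - r$upper, r$lower - d)
        out$id[i] <- r$id
        out$residue[i] <- r$groupB$residue
        out$effectiveDistance[i] <- d
        out$lower[i] <- r$lower; out$upper[i] <- r$upper
        out$violation[i] <- v
        out$satisfied[i] <- v <= tolerance
    }
    out
}

#' Ensemble restraint satisfaction over a set of poses
#'
#' A restraint counts as satisfied when it is satisfied in at least one pose
#' (the poses jointly cover the restraints, reflecting a ligand that adopts
#' multiple orientations).  Also reports, per receptor residue, whether at
#' least one of its restraints is ensemble-satisfied.
#'
#' @param restraintSet A [RestraintSet].
#' @param receptors list of receptor [Structure]s.
#' @param ligand reference ligand [Structure].
#' @param poses nonempty list of [Pose]s.
#' @param tolerance violation tolerance, Angstrom.
#' @return list with \code{nSatisfied}, \code{nTotal}, \code{satisfied}
#'   (logical per restraint), \code{perResidue} (named logical) and
#'   \code{perPose} (list of violation tables).
#' @export
ensembleSatisfaction <- function(restraintSet, receptors, ligand, poses,
                                 tolerance = 0.3) {
    if (length(poses) == 0L) stop("ensembleSatisfaction: empty pose list")
    perPose <- lapply(poses, function(p) {
        evaluateViolations(restraintSet, receptors[[p@receptorIndex]],
                           applyTransform(p@transform, ligand), tolerance)
    })
    sat <- Reduce(`|`, lapply(perPose, `[[`, "satisfied"))
    resid <- perPose[[1]]$residue
    perResidue <- tapply(sat, resid, any)
    list(nSatisfied = sum(sat), nTotal = length(sat), satisfied = sat,
         perResidue = perResidue[order(as.integer(names(perResidue)))],
         perPose = perPose)
}
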