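## Tab-separated restraint-table dialect and report writers.
##
## peaks TSV columns:  ligand_group receptor_residue receptor_group class
##                     [lower upper]   (explicit bounds override the class)
## groups TSV columns: id owner residue protons heavies
##                     (protons/heavies comma-separated, parallel order)

#' Read a proton-group definition table
#' @param path TSV with columns id, owner, residue, protons, heavies.
#' @return named list of [protonGroup] records keyed by id.
#' @export
readProtonGroups <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
    groups <- list()
    for (i in seq_len(nrow(d))) {
        groups[[d$id[i]]] <- protonGroup(
            id = d$id[i],
            protons = strsplit(d$protons[i], ",", fixed = TRUE)[[1]],
            heavies = strsplit(d$heavies[i], ",", fixed = TRUE)[[1]],
            owner = d$owner[i],
            residue = if (is.na(d$residue[i])) NA_integer_
                      else as.integer(d$residue[i]))
    }
    groups
}

#' Read a classified NOE peak table
#'
#' @param path TSV with columns ligand_group, receptor_residue,
#'   receptor_group, class and optional lower/upper overrides.
#' @param groups optional group list for residue cross-checking.
#' @return peak data.frame with columns ligandGroup, receptorGroup, class,
#'   lower, upper.
#' @export
readNoePeaks <- function(path, groups = NULL) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
    need <- c("ligand_group", "receptor_residue", "receptor_group", "class")
    if (!all(need %in% names(d)))
        stop("readNoePeaks: need columns ", paste(need, collapse = ", "))
    if (!is.null(groups)) {
        for (i in seq_len(nrow(d))) {
            g <- .getGroup(groups, d$receptor_group[i])
            if (!is.na(g$residue) && g$residue != d$receptor_residue[i])
                stop("readNoePeaks: residue mismatch for group ",
                     d$receptor_group[i], " at row ", i)
        }
    }
    data.frame(ligandGroup = d$ligand_group,
               receptorGroup = d$receptor_group,
               class = d$class,
               lower = if ("lower" %in% names(d)) d$lower else NA_real_,
               upper = if ("upper" %in% names(d)) d$upper else NA_real_,
               stringsAsFactors = FALSE)
}

#' Write a violation report as TSV
#' @param report data.frame from [evaluateViolations].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeViolationReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export heavy-atom restraints as a CNS-style assign block
#'
#' Writes one \code{assign (...) (...) d dminus dplus} line per restraint for
#' interoperability with docking/refinement tools; d is the midpoint of the
#' bounds, dminus/dplus the distances to lower/upper.
#'
#' @param restraintSet A [RestraintSet].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportCNSRestraints <- function(restraintSet, path) {
    lines <- vapply(restraints(restraintSet), function(r) {
        selA <- paste(sprintf("name %s", r$groupA$atoms), collapse = " or ")
        selB <- if (is.na(r$groupB$residue))
            paste(sprintf("name %s", r$groupB$atoms), collapse = " or ")
        else paste(sprintf("resid %d and name %s", r$groupB$residue,
                           r$groupB$atoms), collapse = " or ")
        d <- (r$lower + r$upper) / 2
        sprintf("assign (%s) (%s) %.2f %.2f %.2f", selA, selB,
                d, d - r$lower, r$upper - d)
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Write a RestraintSet as TSV
#' @param restraintSet A [RestraintSet].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRestraintTable <- function(restraintSet, path) {
    rs <- restraints(restraintSet)
    d <- data.frame(
        id = vapply(rs, `[[`, "", "id"),
        ligand_atoms = vapply(rs, function(r)
            paste(r$groupA$atoms, collapse = ","), ""),
        receptor_residue = vapply(rs, function(r) r$groupB$residue, 1L),
        receptor_atoms = vapply(rs, function(r)
            paste(r$groupB$atoms, collapse = ","), ""),
        lower = vapply(rs, `[[`, 1, "lower"),
        upper = vapply(rs, `[[`, 1, "upper"),
        level = vapply(rs, `[[`, "", "level"))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
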