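#' Default atom-role assignment rules
#'
#' Role resolution works on atom and residue names through configurable
#' regular expressions, so both CHARMM-convention files and the synthetic
#' generator's files resolve without edits. The defaults follow CHARMM
#' naming: phosphorus atom \code{P} on POPC, terminal acyl carbons
#' C214-C216 / C314-C316 (last three of the sn-2 and sn-1 chains), their
#' hydrogens, water oxygen \code{OW}/\code{OH2}, PE polar-head heavy atom
#' \code{C1}/\code{N}/\code{REF}. Residues not matching POPC, water or ion
#' patterns are treated as permeation enhancers.
#'
#' @return a named list of patterns consumed by \code{\link{buildTopology}}.
#' @export
defaultRoleSpec <- function() {
    list(
        popc_resname   = "^POPC$",
        water_resname  = "^(SOL|TIP3|TIP3P|WAT|HOH|W)$",
        ion_resname    = "^(NA|CL|SOD|CLA|POT|K)$",
        phosphate      = "^P$",
        tail_carbon    = "^C(2(14|15|16)|3(14|15|16))$",
        tail_hydrogen  = "^H(1[456])[RSTXYZ]$",
        water_site     = "^(OW|OH2)$",
        pe_reference   = "^(REF|C1|N)$",
        pe_chain       = "^C[0-9]+$"
    )
}

## First-frame leaflet labels from phosphate z (lipids) or the PE reference
## site z (PEs), split about the median phosphate z.
.initialLeaflets <- function(atoms, roles, xyz) {
    pidx <- match(roles$phosphate, atoms$id)
    zmed <- stats::median(xyz[pidx, 3])
    out <- character(0)
    lip <- atoms$molid[pidx]
    lab <- ifelse(xyz[pidx, 3] >= zmed, "upper", "lower")
    out[as.character(lip)] <- lab
    ref <- match(roles$pe_reference, atoms$id)
    if (length(ref)) {
        pemol <- atoms$molid[ref]
        out[as.character(pemol)] <- ifelse(xyz[ref, 3] >= zmed,
                                           "upper", "lower")
    }
    out
}

#' Build a Topology from an atom table
#'
#' Resolves atom roles from name patterns and, when first-frame coordinates
#' are supplied, assigns initial leaflet labels by the sign of each
#' molecule's phosphate (or PE reference) z relative to the median
#' phosphate z.
#'
#' @param atoms data.frame with columns \code{id}, \code{name},
#'   \code{molid}, \code{resname}.
#' @param roleSpec pattern list, see \code{\link{defaultRoleSpec}}.
#' @param xyz optional first-frame \code{[atom, 3]} coordinates (nm) used
#'   for the initial leaflet assignment.
#' @return a \linkS4class{Topology}
#' @export
buildTopology <- function(atoms, roleSpec = defaultRoleSpec(), xyz = NULL) {
    stopifnot(all(c("id", "name", "molid", "resname") %in% names(atoms)))
    rs <- utils::modifyList(defaultRoleSpec(), roleSpec)
    molkind <- ifelse(grepl(rs$popc_resname, atoms$resname), "POPC",
               ifelse(grepl(rs$water_resname, atoms$resname), "water",
               ifelse(grepl(rs$ion_resname, atoms$resname), "ion", "PE")))
    isPOPC <- molkind == "POPC"
    isPE <- molkind == "PE"
    isW <- molkind == "water"
    roles <- list(
        phosphate          = atoms$id[isPOPC & grepl(rs$phosphate, atoms$name)],
        tail_carbon_last3  = atoms$id[isPOPC & grepl(rs$tail_carbon, atoms$name)],
        tail_hydrogen_last3 = atoms$id[isPOPC & grepl(rs$tail_hydrogen, atoms$name)],
        water_site         = atoms$id[isW & grepl(rs$water_site, atoms$name)],
        pe_reference       = integer(0),
        pe_chain           = atoms$id[isPE & grepl(rs$pe_chain, atoms$name)]
    )
    if (any(isPE)) {
        ## one reference site per PE molecule: first atom matching the
        ## pe_reference pattern, falling back to the molecule's first atom
        ref <- vapply(split(which(isPE), atoms$molid[isPE]), function(ix) {
            hit <- ix[grepl(rs$pe_reference, atoms$name[ix])]
            atoms$id[if (length(hit)) hit[1] else ix[1]]
        }, integer(1))
        roles$pe_reference <- unname(ref)
    }
    if (any(isPOPC) && length(roles$phosphate) == 0L)
        stop("configuration error: phosphate pattern matched no POPC atoms")
    leaflet0 <- character(0)
    if (!is.null(xyz) && length(roles$phosphate))
        leaflet0 <- .initialLeaflets(
            data.frame(id = atoms$id, molid = atoms$molid), roles, xyz)
    new("Topology",
        atoms = data.frame(id = atoms$id, name = atoms$name,
                           molid = atoms$molid, molkind = molkind,
                           stringsAsFactors = FALSE),
        roles = roles, leaflet0 = leaflet0)
}

## molecule ids of a given kind, in first-appearance order
molIds <- function(topology, kind) {
    a <- topology@atoms
    unique(a$molid[a$molkind == kind])
}

## row indices (into the atom table / coords) of a role's atoms
roleIdx <- function(traj, role) {
    top <- if (is(traj, "Trajectory")) traj@topology else traj
    match(roleAtoms(top, role), top@atoms$id)
}
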