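#' Charged side-chain group definitions
#'
#' Representative atoms and charged-group atoms for the four charged residue
#' types, following the common convention for salt-bridge analysis of MD
#' trajectories: Lys NZ, Arg CZ (guanidine N atoms as the group), Asp CG
#' (carboxylate O atoms), Glu CD (carboxylate O atoms).
#'
#' @return named list: for each residue type, \code{polarity}
#'   ("basic"/"acidic"), \code{rep} (representative atom) and \code{group}
#'   (charged-group atom names)
#' @export
chargedGroups <- function() {
  list(
    LYS = list(polarity = "basic",  rep = "NZ", group = c("NZ")),
    ARG = list(polarity = "basic",  rep = "CZ", group = c("NE", "NH1", "NH2")),
    ASP = list(polarity = "acidic", rep = "CG", group = c("OD1", "OD2")),
    GLU = list(polarity = "acidic", rep = "CD", group = c("OE1", "OE2")))
}

.aa1 <- c(LYS = "K", ARG = "R", ASP = "D", GLU = "E")

.groupSpecFor <- function(model, r, spec) {
  rows <- .residueRows(model, r)
  if (!length(rows)) .stopf("residue %s not found in model", .resLabel(r))
  rn <- model@atoms$resName[rows[1]]
  g <- spec[[rn]]
  if (is.null(g))
    .stopf("residue %s (%s) is not a charged type in the group spec",
           .resLabel(r), rn)
  c(g, list(resName = rn, rows = rows))
}

#' Distance between the representative atoms of two charged residues
#'
#' Euclidean distance between the representative atoms (e.g. Lys NZ to Asp
#' CG) of two residues, the convention used for per-frame contact distances.
#'
#' @param model a \linkS4class{StructureModel}
#' @param resA,resB residue selectors, e.g. \code{"I:52"} or
#'   \code{list(chain = "I", resSeq = 52)}
#' @param spec charged-group definitions, see \code{\link{chargedGroups}}
#' @return distance in Angstrom
#' @export
representativeDistance <- function(model, resA, resB, spec = chargedGroups()) {
  ra <- .parseRes(resA); rb <- .parseRes(resB)
  ga <- .groupSpecFor(model, ra, spec); gb <- .groupSpecFor(model, rb, spec)
  pa <- model@coords[.atomRow(model, ra, ga$rep), ]
  pb <- model@coords[.atomRow(model, rb, gb$rep), ]
  .euclid(pa, pb)
}

#' Minimum distance between the charged groups of two residues
#'
#' Minimum pairwise distance between the charged-group atoms of one basic
#' and one acidic residue (e.g. Arg guanidine N atoms to Glu carboxylate O
#' atoms), the convention behind prose-style crystal contact distances.
#'
#' @inheritParams representativeDistance
#' @return minimum distance in Angstrom
#' @export
groupMinDistance <- function(model, resA, resB, spec = chargedGroups()) {
  ra <- .parseRes(resA); rb <- .parseRes(resB)
  ga <- .groupSpecFor(model, ra, spec); gb <- .groupSpecFor(model, rb, spec)
  if (ga$polarity == gb$polarity)
    .stopf("residues %s and %s are both %s; need one basic and one acidic",
           .resLabel(ra), .resLabel(rb), ga$polarity)
  pa <- model@coords[vapply(ga$group, function(nm) .atomRow(model, ra, nm),
                            integer(1)), , drop = FALSE]
  pb <- model@coords[vapply(gb$group, function(nm) .atomRow(model, rb, nm),
                            integer(1)), , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(max(min(d2), 0))
}

# all charged residues of the given chains, as parsed selectors
.chargedResidues <- function(model, chains, spec) {
  a <- model@atoms
  rows <- which(a$chainId %in% chains & a$resName %in% names(spec))
  if (!length(rows)) return(list())
  key <- paste(a$chainId[rows], a$resSeq[rows], a$iCode[rows], sep = "\r")
  first <- rows[!duplicated(key)]
  lapply(first, function(i)
    list(chain = a$chainId[i], resSeq = a$resSeq[i], iCode = a$iCode[i],
         resName = a$resName[i]))
}

#' Detect inter-chain salt bridges
#'
#' Scans all (basic, acidic) residue pairs with one residue in each chain
#' set and reports those whose charged-group minimum distance is at or below
#' \code{cutoff}, sorted by that distance. Both distance conventions are
#' recorded per contact; the contact threshold is set to the measured
#' representative-atom distance (the crystal-structure convention for
#' trajectory occupancy thresholds).
#'
#' @param model a \linkS4class{StructureModel}
#' @param chainsA,chainsB disjoint character vectors of chain ids
#' @param spec charged-group definitions
#' @param cutoff group-minimum distance cutoff, Angstrom
#' @return data.frame with one row per contact: label, chain/residue
#'   identities, measurement atoms, \code{group_min_A},
#'   \code{rep_distance_A} and \code{threshold_A}
#' @export
findSaltBridges <- function(model, chainsA, chainsB, spec = chargedGroups(),
                            cutoff = 4.0) {
  if (!length(chainsA) || !length(chainsB))
    .stopf("empty chain selection")
  if (length(intersect(chainsA, chainsB)))
    .stopf("chain sets must be disjoint")
  if (cutoff <= 0) .stopf("cutoff must be positive")
  resA <- .chargedResidues(model, chainsA, spec)
  resB <- .chargedResidues(model, chainsB, spec)
  out <- list()
  for (ra in resA) for (rb in resB) {
    pa <- spec[[ra$resName]]$polarity
    pb <- spec[[rb$resName]]$polarity
    if (pa == pb) next
    d <- groupMinDistance(model, ra, rb, spec)
    if (d > cutoff) next
    rep <- representativeDistance(model, ra, rb, spec)
    out[[length(out) + 1L]] <- data.frame(
      label = sprintf("%s%d-%s%d",
                      .aa1[[ra$resName]], ra$resSeq,
                      .aa1[[rb$resName]], rb$resSeq),
      chain_a = ra$chain, res_a = ra$resSeq, icode_a = ra$iCode,
      resname_a = ra$resName, atom_a = spec[[ra$resName]]$rep,
      chain_b = rb$chain, res_b = rb$resSeq, icode_b = rb$iCode,
      resname_b = rb$resName, atom_b = spec[[rb$resName]]$rep,
      convention = "group_min",
      group_min_A = d, rep_distance_A = rep, threshold_A = rep,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(label = character(), chain_a = character(),
                      res_a = integer(), icode_a = character(),
                      resname_a = character(), atom_a = character(),
                      chain_b = character(), res_b = integer(),
                      icode_b = character(), resname_b = character(),
                      atom_b = character(), convention = character(),
                      group_min_A = numeric(), rep_distance_A = numeric(),
                      threshold_A = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$group_min_A), , drop = FALSE]
}

#' Convert salt-bridge table rows to ContactDefinition objects
#'
#' @param contacts data.frame as returned by \code{\link{findSaltBridges}}
#' @return list of \linkS4class{ContactDefinition}
#' @export
contactsAsDefinitions <- function(contacts) {
  lapply(seq_len(nrow(contacts)), function(i) {
    r <- contacts[i, ]
    new("ContactDefinition", label = r$label,
        chainA = r$chain_a, resA = as.integer(r$res_a), iCodeA = r$icode_a,
        atomA = r$atom_a,
        chainB = r$chain_b, resB = as.integer(r$res_b), iCodeB = r$icode_b,
        atomB = r$atom_b, threshold = r$threshold_A)
  })
}

#' Build a ContactDefinition
#'
#' @param label contact label
#' @param resA,resB residue selectors (see
#'   \code{\link{representativeDistance}})
#' @param atomA,atomB measurement atom names
#' @param threshold occupancy threshold, Angstrom (typically the
#'   crystal-structure distance of the same contact)
#' @return a \linkS4class{ContactDefinition}
#' @export
contactDefinition <- function(label, resA, atomA, resB, atomB, threshold) {
  ra <- .parseRes(resA); rb <- .parseRes(resB)
  new("ContactDefinition", label = label,
      chainA = ra$chain, resA = ra$resSeq, iCodeA = ra$iCode, atomA = atomA,
      chainB = rb$chain, resB = rb$resSeq, iCodeB = rb$iCode, atomB = atomB,
      threshold = threshold)
}

#' Terminal-excluded C-alpha selection
#'
#' Row indices of the C-alpha atoms of the selected chains, in sequence
#' order, with the first and last \code{terminalExclude} residues of each
#' chain removed (flexible termini are conventionally excluded from RMSD
#' fits).
#'
#' @param model a \linkS4class{StructureModel}
#' @param chains character vector of chain ids
#' @param terminalExclude residues to drop at each end of each chain
#' @return integer vector of atom row indices
#' @export
caMask <- function(model, chains, terminalExclude = 5) {
  if (terminalExclude < 0) .stopf("terminalExclude must be >= 0")
  a <- model@atoms
  out <- integer()
  for (ch in chains) {
    rows <- which(a$chainId == ch & a$name == "CA")
    if (!length(rows)) .stopf("chain '%s' has no CA atoms", ch)
    if (length(rows) < 2 * terminalExclude + 1)
      .stopf("chain '%s' has %d residues, too short for terminal exclusion of %d",
             ch, length(rows), terminalExclude)
    keep <- if (terminalExclude > 0)
      rows[(terminalExclude + 1):(length(rows) - terminalExclude)]
    else rows
    out <- c(out, keep)
  }
  out
}

#' Write a contact table to CSV
#'
#' @param contacts data.frame from \code{\link{findSaltBridges}}
#' @param file output path
#' @export
writeContactTable <- function(contacts, file) {
  utils::write.csv(contacts, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
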