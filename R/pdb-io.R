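#' Parse a PDB-format file or text into structure models
#'
#' Reads ATOM records (HETATM ignored by default) and returns one
#' \linkS4class{StructureModel} per MODEL block, or a single model when the
#' file has none. Alternate locations are resolved by keeping the
#' highest-occupancy record (ties: first encountered); insertion codes are
#' preserved. Parsing is delegated to \code{bio3d::read.pdb} after a
#' line-level sanity check so malformed coordinate fields are reported with
#' their line number.
#'
#' @param file path to a PDB file (ignored when \code{text} is given)
#' @param text optional character scalar/vector holding PDB-format text
#' @param keepHetatm keep HETATM records (default FALSE: heavy-atom protein
#'   analysis ignores waters and ligands)
#' @return list of \linkS4class{StructureModel}
#' @export
parsePDB <- function(file, text = NULL, keepHetatm = FALSE) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(paste(text, collapse = "\n"), file)
  }
  if (!file.exists(file)) .stopf("PDB file '%s' does not exist", file)
  lines <- readLines(file, warn = FALSE)
  coordLines <- grep("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines)))
    .stopf("no ATOM records found in '%s'", file)
  for (i in coordLines) {
    for (k in 0:2) {
      fld <- substr(lines[i], 31 + 8 * k, 38 + 8 * k)
      if (is.na(suppressWarnings(as.numeric(fld))))
        .stopf("malformed coordinate field on line %d: '%s'", i, lines[i])
    }
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
  a <- pdb$atom
  keep <- if (keepHetatm) seq_len(nrow(a)) else which(a$type == "ATOM")
  a <- a[keep, , drop = FALSE]

  alt <- ifelse(is.na(a$alt), "", a$alt)
  ins <- ifelse(is.na(a$insert), "", a$insert)
  occ <- ifelse(is.na(a$o), 1, a$o)
  # alt-loc resolution: highest occupancy wins, tie goes to first record
  key <- paste(a$chain, a$resno, ins, a$resid, a$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_along(key))
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])

  atoms <- data.frame(
    serial = a$eleno[sel],
    name = a$elety[sel],
    altLoc = alt[sel],
    resName = a$resid[sel],
    chainId = ifelse(is.na(a$chain[sel]), "", a$chain[sel]),
    resSeq = a$resno[sel],
    iCode = ins[sel],
    element = ifelse(is.na(a$elesy[sel]), "", a$elesy[sel]),
    occupancy = occ[sel],
    stringsAsFactors = FALSE)

  xyzCols <- bio3d::atom2xyz(keep[sel])
  nModels <- nrow(pdb$xyz)
  lapply(seq_len(nModels), function(m) {
    xyz <- matrix(pdb$xyz[m, xyzCols], ncol = 3, byrow = TRUE)
    new("StructureModel", atoms = atoms, coords = xyz, modelIndex = m)
  })
}

#' Write structure models to a PDB file
#'
#' A single model writes a plain PDB; a list writes MODEL/ENDMDL blocks
#' (all models must share one atom table). Coordinates are written at the
#' standard 3-decimal PDB precision.
#'
#' @param models a \linkS4class{StructureModel} or list thereof
#' @param file output path
#' @return \code{file}, invisibly
#' @export
writePDB <- function(models, file) {
  if (is(models, "StructureModel")) models <- list(models)
  a <- models[[1]]@atoms
  multi <- length(models) > 1
  con <- file(file, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    x <- models[[m]]@coords
    if (nrow(models[[m]]@atoms) != nrow(a))
      .stopf("all models must share one atom table")
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    nm <- a$name
    # PDB atom-name column convention: names of <4 chars start in column 14
    nm <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    writeLines(sprintf(
      "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, nm, substr(paste0(a$altLoc, " "), 1, 1),
      a$resName, substr(paste0(a$chainId, " "), 1, 1), a$resSeq %% 10000L,
      substr(paste0(a$iCode, " "), 1, 1),
      x[, 1], x[, 2], x[, 3], a$occupancy, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
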