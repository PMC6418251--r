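# internal helpers shared across modules

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# run fn() with a temporary RNG seed, restoring global RNG state afterwards
withSeed <- function(seed, fn) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  fn()
}

# parse a residue selector: "I:52", "I:52A" or list(chain=, resSeq=, iCode=)
.parseRes <- function(x) {
  if (is.list(x)) {
    return(list(chain = as.character(x$chain),
                resSeq = as.integer(x$resSeq),
                iCode = if (is.null(x$iCode)) "" else as.character(x$iCode)))
  }
  m <- regmatches(x, regexec("^([^:]+):(-?[0-9]+)([A-Za-z]?)$", x))[[1]]
  if (length(m) != 4)
    .stopf("cannot parse residue selector '%s' (expected 'CHAIN:RESSEQ[ICODE]')", x)
  list(chain = m[2], resSeq = as.integer(m[3]), iCode = m[4])
}

.resLabel <- function(r) sprintf("%s:%d%s", r$chain, r$resSeq, r$iCode)

# rows of the atom table belonging to one residue
.residueRows <- function(model, r) {
  a <- model@atoms
  which(a$chainId == r$chain & a$resSeq == r$resSeq & a$iCode == r$iCode)
}

# single atom row for (residue, atom name); error names the residue
.atomRow <- function(model, r, atomName) {
  rows <- .residueRows(model, r)
  if (!length(rows))
    .stopf("residue %s not found in model", .resLabel(r))
  hit <- rows[model@atoms$name[rows] == atomName]
  if (!length(hit))
    .stopf("atom '%s' not found in residue %s (%s)", atomName, .resLabel(r),
           model@atoms$resName[rows[1]])
  hit[1]
}

.euclid <- function(p, q) sqrt(sum((p - q)^2))

# rotation matrix about an arbitrary unit axis (Rodrigues)
.axisRotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
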