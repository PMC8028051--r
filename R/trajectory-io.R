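## Frame readers.  Two plain-text dialects are supported:
##
## GRO-style series: concatenated fixed-column frames (title line, atom count,
## atom records with residue number/name, atom name, number and x/y/z in nm in
## 8.3f columns, then a box line whose first number is the cubic edge).
## Charges are attached from a separate table mapping atom names to charges.
##
## XYZQ dialect (bit-exact definition): per frame,
##   line 1: integer atom count
##   line 2: comment containing the token "box" followed by the edge in nm
##   then one record per atom: "label x y z q [group]", whitespace-separated,
##   coordinates nm, charge e; the optional sixth token is the charge-group id
##   (default: each atom its own group).  QC atoms keep their file order; their
##   q column is ignored (the quantum center is charge-free in a Frame).

#' Minimum-image convention for a cubic box
#'
#' Wraps each displacement component into the interval (-boxEdge/2,
#' boxEdge/2].  Idempotent; applied inside the electrostatics kernels when
#' periodic boundaries are requested, never on raw coordinates at read time.
#'
#' @param displacement numeric vector or matrix (columns x, y, z), nm.
#' @param boxEdge cubic box side, nm.
#' @return Wrapped displacement(s), same shape as the input.
#' @examples
#' minimumImage(c(3.0, 0, 0), 3.1)   # -0.1 0 0
#' @export
minimumImage <- function(displacement, boxEdge) {
  if (!.is_number(boxEdge) || boxEdge <= 0)
    .stopf("minimumImage: boxEdge must be a single positive number")
  displacement - boxEdge * ceiling(displacement / boxEdge - 0.5)
}

#' Read an atom-name-to-charge table
#'
#' Accepts either two-column whitespace-separated text (`name charge`, `#`
#' comments allowed) or a JSON object mapping names to charges.
#'
#' @param path file path.
#' @return Named numeric vector of charges, e.
#' @export
readChargeTable <- function(path) {
  if (!file.exists(path)) .stopf("charge table not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::read_json(path)
    out <- vapply(tab, as.numeric, numeric(1))
    if (is.null(names(out)) || any(names(out) == ""))
      .stopf("JSON charge table must map atom names to charges")
    return(out)
  }
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
    col.names = c("name", "charge"), colClasses = c("character", "numeric"))
  stats::setNames(df$charge, df$name)
}

.resolve_selection <- function(sel, atom_names, what = "frame") {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > length(atom_names)))
      .stopf("qcSelection index out of range for %d atoms", length(atom_names))
  } else {
    idx <- which(atom_names %in% sel)
  }
  if (!length(idx))
    .stopf("qcSelection matched zero atoms in %s", what)
  idx
}

.parse_xyzq <- function(lines, path) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L)
      .stopf("XYZQ parse error (%s, line %d): expected an atom count", path, i)
    toks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    bpos <- which(tolower(toks) == "box")
    if (!length(bpos) || bpos[1] == length(toks))
      .stopf("XYZQ parse error (%s, line %d): comment must contain 'box <edge>'",
        path, i + 1L)
    edge <- suppressWarnings(as.numeric(toks[bpos[1] + 1L]))
    if (!is.finite(edge))
      .stopf("XYZQ parse error (%s, line %d): bad box edge", path, i + 1L)
    rec <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rec), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 5L))
      .stopf("XYZQ parse error (%s): record needs 'label x y z q'", path)
    lab <- vapply(fields, `[`, character(1), 1L)
    num <- t(vapply(fields, function(f) as.numeric(f[2:5]), numeric(4)))
    grp <- vapply(fields, function(f)
      if (length(f) >= 6L) f[6L] else NA_character_, character(1))
    if (anyNA(grp)) grp <- ifelse(is.na(grp), paste0("a", seq_len(n)), grp)
    frames[[length(frames) + 1L]] <- list(names = lab, xyz = num[, 1:3,
      drop = FALSE], charge = num[, 4L], group = grp, box = edge)
    i <- i + 2L + n
  }
  if (!length(frames)) .stopf("XYZQ file %s contains no frames", path)
  frames
}

.parse_gro <- function(lines, path) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1L)
      .stopf("GRO parse error (%s, line %d): expected an atom count", path,
        i + 1L)
    rec <- lines[(i + 2L):(i + 1L + n)]
    resid <- trimws(substring(rec, 1L, 5L))
    name <- trimws(substring(rec, 11L, 15L))
    xyz <- cbind(
      as.numeric(substring(rec, 21L, 28L)),
      as.numeric(substring(rec, 29L, 36L)),
      as.numeric(substring(rec, 37L, 44L)))
    if (any(!is.finite(xyz)))
      .stopf("GRO parse error (%s): non-numeric coordinate block", path)
    box <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]]))
    if (!length(box) || !is.finite(box[1]))
      .stopf("GRO parse error (%s): bad box line after frame", path)
    frames[[length(frames) + 1L]] <- list(names = name, xyz = xyz,
      charge = NULL, group = resid, box = box[1])
    i <- i + 3L + n
  }
  if (!length(frames)) .stopf("GRO file %s contains no frames", path)
  frames
}

#' Read classical configurations into a frame ensemble
#'
#' Splits every configuration into quantum-center atoms (charge-free) and
#' environment point charges, preserving frame order.  For GRO input the
#' environment charges come from `chargeTablePath` and the charge-group id is
#' the residue number; for XYZQ input charges are taken from the file's `q`
#' column and the optional sixth field is the group id.
#'
#' @param coordPath coordinate series (concatenated GRO frames or XYZQ).
#' @param qcSelection integer atom indices (file order) or character atom
#'   names identifying the quantum center; must match at least one atom.
#' @param chargeTablePath charge table (see [readChargeTable()]); required for
#'   GRO input, ignored for XYZQ.
#' @param format `"auto"` (by extension), `"gro"` or `"xyzq"`.
#' @param label ensemble label, `"reduced"` or `"oxidized"`.
#' @param temperature K.
#' @param variableComposition allow frames with differing environment group
#'   composition.
#' @return A [FrameEnsemble-class].
#' @export
readFrames <- function(coordPath, qcSelection, chargeTablePath = NULL,
                       format = c("auto", "gro", "xyzq"), label = "reduced",
                       temperature = 300, variableComposition = FALSE) {
  format <- match.arg(format)
  if (!file.exists(coordPath)) .stopf("coordinate file not found: %s", coordPath)
  if (format == "auto")
    format <- if (grepl("\\.gro$", coordPath, ignore.case = TRUE)) "gro"
      else "xyzq"
  lines <- readLines(coordPath)
  raw <- if (format == "gro") .parse_gro(lines, coordPath)
    else .parse_xyzq(lines, coordPath)

  qtab <- NULL
  if (format == "gro") {
    if (is.null(chargeTablePath))
      .stopf("GRO input requires a charge table for the environment atoms")
    qtab <- readChargeTable(chargeTablePath)
  }

  frames <- lapply(seq_along(raw), function(fi) {
    fr <- raw[[fi]]
    qc_idx <- .resolve_selection(qcSelection, fr$names,
      sprintf("frame %d of %s", fi, coordPath))
    env_idx <- setdiff(seq_along(fr$names), qc_idx)
    if (format == "gro") {
      q <- qtab[fr$names[env_idx]]
      if (anyNA(q)) {
        missing <- unique(fr$names[env_idx][is.na(q)])
        .stopf("atom(s) %s in %s are missing from the charge table",
          paste(missing, collapse = ", "), coordPath)
      }
    } else q <- fr$charge[env_idx]
    env <- if (length(env_idx))
      data.frame(x = fr$xyz[env_idx, 1L], y = fr$xyz[env_idx, 2L],
        z = fr$xyz[env_idx, 3L], charge = as.numeric(q),
        group = as.character(fr$group[env_idx]))
    else emptyEnv()
    Frame(fr$box, fr$xyz[qc_idx, , drop = FALSE], env)
  })
  FrameEnsemble(label, frames, temperature = temperature,
    chargeMapId = if (format == "gro") basename(chargeTablePath)
      else "xyzq-inline",
    variableComposition = variableComposition)
}

#' Write a frame ensemble in the XYZQ dialect
#'
#' The inverse reader is [readFrames()] with `format = "xyzq"`.  QC atoms are
#' written first with charge 0 and group id `"QC"`; atom labels for the QC are
#' taken from `qcNames`.
#'
#' @param ensemble a [FrameEnsemble-class].
#' @param path output path.
#' @param qcNames character vector of QC atom labels (recycled default "QC1",
#'   "QC2", ...).
#' @return `path`, invisibly.
#' @export
writeXYZQ <- function(ensemble, path, qcNames = NULL) {
  stopifnot(is(ensemble, "FrameEnsemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in ensemble@frames) {
    nqc <- nrow(fr@qcCoords)
    if (is.null(qcNames)) qcNames <- sprintf("QC%d", seq_len(nqc))
    env <- fr@envPoints
    writeLines(as.character(nqc + nrow(env)), con)
    writeLines(sprintf("box %.10g", fr@boxEdge), con)
    for (i in seq_len(nqc))
      writeLines(sprintf("%s %.10g %.10g %.10g 0 QC", qcNames[i],
        fr@qcCoords[i, 1L], fr@qcCoords[i, 2L], fr@qcCoords[i, 3L]), con)
    if (nrow(env))
      writeLines(sprintf("%s %.10g %.10g %.10g %.10g %s",
        rep("ENV", nrow(env)), env$x, env$y, env$z, env$charge,
        as.character(env$group)), con)
  }
  invisible(path)
}
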