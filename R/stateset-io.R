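## On-disk schema for unperturbed state sets: JSON, dialect "pmm-stateset-1".
## Top-level keys: dialect, species_label, total_charge, dipole_unit
## ("e_nm" or "debye"), geometry[] (atom, mass, xyz), states[] (index, energy,
## atomic_charges, permanent_dipole), transition_dipoles (n x n x 3 nested
## arrays).  Lengths nm, charges e, energies eV.

.SCHEMA_DIALECT <- "pmm-stateset-1"

.parse_fail <- function(field, why) {
  .stopf("state-set parse error in field '%s': %s", field, why)
}

#' Read an unperturbed state set from its JSON schema
#'
#' Parses and validates the package's structured-text description of a quantum
#' center: state energies, per-state atomic partial charges, geometry, and the
#' transition-dipole matrix.  Dipoles stored in debye are converted to e nm
#' (1 D = 0.0208194 e nm).  Every class invariant is checked; violations are
#' reported together in a single validation error.
#'
#' @param path path to a state-set JSON file.
#' @param dialect schema version expected; currently only `"pmm-stateset-1"`.
#' @return A validated [ElectronicStateSet-class].
#' @seealso [writeStateSet()] for the inverse operation.
#' @export
readStateSet <- function(path, dialect = .SCHEMA_DIALECT) {
  if (!file.exists(path)) .stopf("state-set file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path),
    error = function(e) .parse_fail("<document>", conditionMessage(e)))
  if (is.null(doc$dialect) || !identical(doc$dialect, dialect))
    .parse_fail("dialect", sprintf("expected '%s', got '%s'", dialect,
      if (is.null(doc$dialect)) "<missing>" else doc$dialect))
  for (f in c("species_label", "total_charge", "geometry", "states",
              "transition_dipoles"))
    if (is.null(doc[[f]])) .parse_fail(f, "missing")

  dip_unit <- if (is.null(doc$dipole_unit)) "e_nm" else doc$dipole_unit
  if (!dip_unit %in% c("e_nm", "debye"))
    .parse_fail("dipole_unit", sprintf("unknown unit '%s'", dip_unit))
  dscale <- if (dip_unit == "debye") .DEBYE else 1

  geom <- tryCatch(do.call(rbind, lapply(doc$geometry, function(a)
    data.frame(atom = a$atom, mass = as.numeric(a$mass),
      x = as.numeric(a$xyz[[1]]), y = as.numeric(a$xyz[[2]]),
      z = as.numeric(a$xyz[[3]])))),
    error = function(e) .parse_fail("geometry", conditionMessage(e)))
  if (is.null(geom) || !nrow(geom)) .parse_fail("geometry", "no atoms")

  ns <- length(doc$states)
  if (!ns) .parse_fail("states", "no states")
  idx <- vapply(doc$states, function(s)
    if (is.null(s$index)) .parse_fail("states.index", "missing")
    else as.integer(s$index), integer(1))
  if (!identical(idx, seq_len(ns) - 1L))
    .parse_fail("states.index", "indices must be 0..n_states-1 in order")
  energies <- vapply(doc$states, function(s)
    if (is.null(s$energy)) .parse_fail("states.energy", "missing")
    else as.numeric(s$energy), numeric(1))
  ac <- t(vapply(doc$states, function(s) {
    q <- as.numeric(unlist(s$atomic_charges))
    if (length(q) != nrow(geom))
      .parse_fail("states.atomic_charges", sprintf(
        "state %d carries %d charges for %d atoms", s$index, length(q),
        nrow(geom)))
    q
  }, numeric(nrow(geom))))
  if (nrow(geom) == 1L) ac <- matrix(as.numeric(ac), nrow = ns)

  td <- array(NA_real_, c(ns, ns, 3L))
  tdl <- doc$transition_dipoles
  if (length(tdl) != ns) .parse_fail("transition_dipoles", "wrong row count")
  for (i in seq_len(ns)) {
    if (length(tdl[[i]]) != ns)
      .parse_fail("transition_dipoles", sprintf("row %d has wrong length", i))
    for (j in seq_len(ns)) {
      v <- as.numeric(unlist(tdl[[i]][[j]]))
      if (length(v) != 3L)
        .parse_fail("transition_dipoles",
          sprintf("element [%d,%d] is not a 3-vector", i, j))
      td[i, j, ] <- v * dscale
    }
  }

  ## cross-check: stated permanent dipoles must equal the matrix diagonal
  pd <- t(vapply(doc$states, function(s)
    as.numeric(unlist(s$permanent_dipole)) * dscale, numeric(3)))
  for (i in seq_len(ns))
    if (max(abs(pd[i, ] - td[i, i, ])) > 1e-9)
      .stopf(paste("state-set validation error: permanent_dipole of state %d",
        "does not match the transition-dipole diagonal"), i - 1L)

  obj <- tryCatch(
    ElectronicStateSet(doc$species_label, doc$total_charge, geom, energies,
      ac, td),
    error = function(e)
      .stopf("state-set validation error: %s", conditionMessage(e)))
  obj
}

#' Write an unperturbed state set to the JSON schema
#'
#' Serializes with 15 significant digits so that
#' `readStateSet(writeStateSet(x))` reproduces every numeric field bitwise at
#' that precision.  Dipoles are always written in e nm.
#'
#' @param x an [ElectronicStateSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStateSet <- function(x, path) {
  stopifnot(is(x, "ElectronicStateSet"))
  validObject(x)
  ns <- nStates(x); g <- geometry(x)
  doc <- list(
    dialect = .SCHEMA_DIALECT,
    species_label = speciesLabel(x),
    total_charge = totalCharge(x),
    dipole_unit = "e_nm",
    geometry = lapply(seq_len(nrow(g)), function(i)
      list(atom = g$atom[i], mass = g$mass[i],
        xyz = c(g$x[i], g$y[i], g$z[i]))),
    states = lapply(seq_len(ns), function(i)
      list(index = i - 1L, energy = x@energies[i],
        atomic_charges = as.numeric(x@atomicCharges[i, ]),
        permanent_dipole = as.numeric(x@transitionDipoles[i, i, ]))),
    transition_dipoles = lapply(seq_len(ns), function(i)
      lapply(seq_len(ns), function(j) as.numeric(x@transitionDipoles[i, j, ])))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(15),
    pretty = TRUE)
  invisible(path)
}
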