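#' Read a charge-annotated structure from a PQR file
#'
#' PQR records are whitespace-separated ATOM/HETATM lines carrying a partial
#' charge and a radius after the coordinates; unlike PDB, the format is
#' defined by token order, not column positions, so aligned-column and
#' single-space dialects parse identically. A malformed record is reported
#' with its line number. The radius column is read but otherwise ignored.
#'
#' @param path path to a PQR file.
#' @return an object of class \code{pqr_structure}: data.frame \code{atoms}
#'   with columns \code{record}, \code{serial}, \code{name}, \code{resname},
#'   \code{resid}, \code{x}, \code{y}, \code{z}, \code{charge},
#'   \code{radius}.
#' @seealso \code{\link{split_probe_environment}} to pull out the probe and
#'   iron and build a \code{\link{charge_environment}} from the rest;
#'   \code{\link{read_pdb_geometry}} for charge-free PDB input.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- which(grepl("^(ATOM|HETATM)", lines))
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  parse_one <- function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    # 10 tokens without a chain identifier, 11 with one
    if (!length(tok) %in% c(10L, 11L))
      stop(sprintf(
        "%s line %d: malformed PQR record (%d fields, need 10 or 11; missing charge/radius columns?)",
        path, i, length(tok)))
    if (length(tok) == 11L) tok <- tok[-5L]
    num <- suppressWarnings(as.numeric(tok[c(2, 5:10)]))
    if (any(!is.finite(num[6:7])))
      stop(sprintf("%s line %d: non-numeric charge/radius column", path, i))
    if (any(!is.finite(num)))
      stop(sprintf("%s line %d: non-numeric field in PQR record", path, i))
    data.frame(record = tok[1], serial = as.integer(num[1]), name = tok[3],
               resname = tok[4], resid = as.integer(num[2]),
               x = num[3], y = num[4], z = num[5],
               charge = num[6], radius = num[7],
               stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(rec, parse_one))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path), class = "pqr_structure")
}

#' Read probe/iron geometry from a plain PDB file
#'
#' PDB files carry no partial charges; the structure is loaded (via
#' \code{bio3d::read.pdb}) for geometry-only use, with every charge set to
#' zero, so \code{\link{split_probe_environment}} can still extract the
#' probe and iron positions.
#'
#' @param path path to a PDB file.
#' @return a \code{pqr_structure} with zero charges.
#' @export
read_pdb_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    record = a$type, serial = a$eleno, name = a$elety,
    resname = a$resid, resid = a$resno,
    x = a$x, y = a$y, z = a$z,
    charge = 0, radius = 0,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, path = path), class = "pqr_structure")
}

#' @export
print.pqr_structure <- function(x, ...) {
  cat(sprintf("PQR structure: %d atoms, net charge %+.4f e (%s)\n",
              nrow(x$atoms), sum(x$atoms$charge), x$path))
  invisible(x)
}

#' Write atoms to a PQR file
#'
#' @param atoms a data.frame with the columns produced by
#'   \code{\link{read_pqr}} (record, serial, name, resname, resid, x, y, z,
#'   charge, radius), or a \code{pqr_structure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pqr <- function(atoms, path) {
  if (inherits(atoms, "pqr_structure")) atoms <- atoms$atoms
  lines <- sprintf(
    "%-6s%5d %-4s %-4s%5d    %8.3f%8.3f%8.3f %8.4f %7.4f",
    atoms$record, atoms$serial, atoms$name, atoms$resname, atoms$resid,
    atoms$x, atoms$y, atoms$z, atoms$charge, atoms$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Split a structure into CO probe, iron position and charge environment
#'
#' Locates the probe C and O atoms (and optionally the heme iron) by atom
#' name and, if given, residue name; all remaining atoms become the
#' point-charge environment.
#'
#' @param pqr a \code{pqr_structure} from \code{\link{read_pqr}}.
#' @param c_name,o_name atom names of the probe carbon and oxygen (defaults
#'   "C", "O").
#' @param fe_name atom name of the iron (default "FE"); set \code{NULL} to
#'   skip. The iron stays part of the environment.
#' @param ligand_resname optional residue name restricting the probe search.
#' @return list with \code{probe} (\code{co_probe}), \code{fe_position}
#'   (or NULL) and \code{env} (\code{charge_environment} of all
#'   non-probe atoms).
#' @export
split_probe_environment <- function(pqr, c_name = "C", o_name = "O",
                                    fe_name = "FE", ligand_resname = NULL) {
  a <- pqr$atoms
  in_ligand <- if (is.null(ligand_resname)) rep(TRUE, nrow(a))
               else a$resname == ligand_resname
  ic <- which(a$name == c_name & in_ligand)
  io <- which(a$name == o_name & in_ligand)
  if (length(ic) != 1L || length(io) != 1L)
    stop(sprintf(
      "probe extraction: found %d '%s' and %d '%s' atoms (need exactly 1 each; use ligand_resname to disambiguate)",
      length(ic), c_name, length(io), o_name))
  probe <- co_probe(unlist(a[ic, c("x", "y", "z")]),
                    unlist(a[io, c("x", "y", "z")]))
  fe_position <- NULL
  if (!is.null(fe_name)) {
    ife <- which(a$name == fe_name)
    if (length(ife) == 1L)
      fe_position <- unlist(a[ife, c("x", "y", "z")], use.names = FALSE)
  }
  keep <- setdiff(seq_len(nrow(a)), c(ic, io))
  env <- charge_environment(as.matrix(a[keep, c("x", "y", "z")]),
                            a$charge[keep],
                            residue_index = a$resid[keep],
                            atom_index = a$serial[keep])
  list(probe = probe, fe_position = fe_position, env = env)
}

# all floats in emitted tables carry 10 significant digits so determinism
# is testable byte-for-byte
.write_table <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  out <- df
  out[is_num] <- lapply(df[is_num], function(x) sprintf("%.10g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  df
}

#' Read / write per-frame field tables
#'
#' CSV with mandated header columns \code{frame}, \code{field},
#' \code{bond_length}; extra columns (e.g. \code{energy}, \code{scheme},
#' \code{q_O}, \code{angle}) pass through.
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_field_table <- function(path)
  .read_table_checked(path, c("frame", "field", "bond_length"))

#' @rdname read_field_table
#' @param df the table to write.
#' @export
write_field_table <- function(df, path) {
  stopifnot(all(c("frame", "field", "bond_length") %in% names(df)))
  .write_table(df, path)
}

#' Read / write per-frame energy tables
#'
#' CSV with mandated header \code{frame}, \code{method}, \code{E_total},
#' \code{E_self}. The interaction energy E_EI is always recomputed as
#' E_total - E_self on read, never trusted from the file.
#'
#' @param path CSV path.
#' @return a data.frame with an added computed \code{E_EI} column.
#' @export
read_energy_table <- function(path) {
  df <- .read_table_checked(path, c("frame", "method", "E_total", "E_self"))
  df$E_EI <- interaction_energy(df$E_total, df$E_self)
  df
}

#' @rdname read_energy_table
#' @param df the table to write (an \code{E_EI} column, if present, is
#'   dropped: it is derived data).
#' @export
write_energy_table <- function(df, path) {
  stopifnot(all(c("frame", "method", "E_total", "E_self") %in% names(df)))
  df$E_EI <- NULL
  .write_table(df, path)
}

#' Read / write angle series tables
#'
#' CSV with mandated header \code{frame}, \code{angle}; a \code{state}
#' column is written from \code{\link{classify_state}}.
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_angle_table <- function(path)
  .read_table_checked(path, c("frame", "angle"))

#' @rdname read_angle_table
#' @param df the table to write.
#' @export
write_angle_table <- function(df, path) {
  stopifnot(all(c("frame", "angle") %in% names(df)))
  df$state <- classify_state(df$angle)
  .write_table(df, path)
}

#' Serialize an EAC fit to JSON
#'
#' @param fit an \code{\link{eac_fit}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_eac_json <- function(fit, path) {
  stopifnot(inherits(fit, "eac_fit"))
  sf <- fit$fit
  obj <- list(
    method_label = fit$model$method_label,
    q_pos = fit$model$q_pos, q_neg = fit$model$q_neg,
    bond_length = fit$model$bond_length,
    slope_pos = sf$slope_pos, intercept_pos = sf$intercept_pos,
    r2_pos = sf$r2_pos, n_pos = sf$n_pos,
    slope_neg = sf$slope_neg, intercept_neg = sf$intercept_neg,
    r2_neg = sf$r2_neg, n_neg = sf$n_neg, n_zero = sf$n_zero,
    k1_k2 = fit$ratio,
    k1_k2_ci = if (is.null(fit$ratio_ci)) NULL else as.numeric(fit$ratio_ci),
    conf = fit$conf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an EAC model back from a serialized fit
#'
#' @param path JSON path written by \code{\link{write_eac_json}}.
#' @return an \code{\link{eac_model}}.
#' @export
read_eac_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  eac_model(obj$q_pos, obj$q_neg, obj$bond_length, obj$method_label)
}
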