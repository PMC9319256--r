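# Shared readers/writers and structured analysis reports. Units are embedded
# in column names (_uM, _s, _ucal, _RU) so that data files cannot silently
# drift between unit conventions.

#' Read and validate a CSV data table against a column schema
#'
#' @param path CSV file path with a header row.
#' @param schema Named character vector mapping required column names to
#'   types (\code{"numeric"}, \code{"integer"} or \code{"character"}).
#' @param allow_extra Allow columns beyond the schema (default FALSE).
#' @return Data frame with typed columns.
#' @export
read_table <- function(path, schema, allow_extra = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(names(schema), names(d))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(d), names(schema))
  if (length(extra) && !allow_extra)
    stop("unexpected column(s): ", paste(extra, collapse = ", "))
  if (!nrow(d)) stop("no rows in ", path)
  out <- d[names(schema)]
  for (col in names(schema)) {
    if (schema[[col]] == "character") next
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   out[[col]][bad[1L]], bad[1L], col))
    if (anyNA(v))
      stop(sprintf("missing value at row %d, column '%s'",
                   which(is.na(v))[1L], col))
    out[[col]] <- if (schema[[col]] == "integer") as.integer(v) else v
  }
  out
}

#' Read a labeled coordinate set from a PDB file
#'
#' Parses a protein structure and exposes chains, residue numbers and
#' backbone atom coordinates. Water and hetero records are excluded by
#' default, matching the convention of using the bare polypeptide host.
#'
#' @param path PDB file path.
#' @param keep_hetero Keep HETATM records other than water (default FALSE).
#' @return Object of class \code{"structure_coords"}: \code{atoms} (data
#'   frame with chain, resno, resid, elety, x, y, z), \code{backbone}
#'   (coordinate matrix of N/CA/C/O atoms), \code{n_residues}.
#' @export
read_structure <- function(path, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("unreadable structure file: ",
                                           path, " (", conditionMessage(e),
                                           ")"))
  a <- pdb$atom
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_hetero) a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("no atoms left after filtering: ", path)
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      elety = a$elety, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  bb <- atoms[atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  backbone <- as.matrix(bb[, c("x", "y", "z")])
  structure(list(atoms = atoms, backbone = backbone,
                 n_residues = length(unique(paste(atoms$chain,
                                                  atoms$resno)))),
            class = "structure_coords")
}

#' @export
print.structure_coords <- function(x, ...) {
  cat(sprintf("structure: %d atoms, %d residues, %d backbone atoms\n",
              nrow(x$atoms), x$n_residues, nrow(x$backbone)))
  invisible(x)
}

#' Structured analysis report
#'
#' A serializable record of one analysis run: module, input digests,
#' parameters, results, warnings, package version and seed. Identical inputs
#' and seed give identical \code{results} blocks.
#'
#' @param module Module name.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param parameters Named list of run parameters.
#' @param results Named list of numeric/character results.
#' @param warnings Character vector of warnings.
#' @param seed Optional integer seed.
#' @return Object of class \code{"analysis_report"}.
#' @export
analysis_report <- function(module, inputs = character(),
                            parameters = list(), results = list(),
                            warnings = character(), seed = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  structure(list(module = module, inputs = digests,
                 parameters = parameters, results = results,
                 warnings = as.character(warnings),
                 software_version = as.character(
                   utils::packageVersion("bindlab")),
                 seed = seed),
            class = "analysis_report")
}

#' Write an analysis report (or any fit summary) to JSON
#'
#' @param report An \code{\link{analysis_report}} or plain list.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
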