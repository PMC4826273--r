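## PDB and measurement-table I/O. Coordinate parsing/writing is delegated to
## bio3d; a pre-scan reports malformed records by line number, which the
## delegate does not.

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns serial, atom, resid, chain, resno,
#'   x, y, z, element, b.
#' @return A \linkS4class{Structure}.
#' @export
Structure <- function(atoms) {
    rownames(atoms) <- NULL
    new("Structure", atoms = atoms)
}

#' Read a protein structure from a PDB file
#'
#' All ATOM/HETATM records are parsed with author residue numbering
#' preserved; coordinates are in Angstrom. Alternate locations are resolved
#' to the first conformer.
#'
#' @param path path to a PDB file.
#' @param dialect coordinate dialect; only \code{"pdb"} is supported.
#' @return A \linkS4class{Structure}.
#' @examples
#' f <- system.file("extdata", "egf11_13_synthetic.pdb", package = "egfarch")
#' s <- readStructure(f)
#' @export
readStructure <- function(path, dialect = c("pdb")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(rec)) stop("no ATOM/HETATM records in ", path)
    for (i in which(rec)) {
        ln <- lines[i]
        coords <- suppressWarnings(as.numeric(c(
            substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
        if (nchar(ln) < 54 || any(is.na(coords)))
            stop("malformed ATOM/HETATM record at line ", i, ": ", ln)
    }
    pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                           verbose = FALSE)
    a <- pdb$atom
    chain <- ifelse(is.na(a$chain), " ", a$chain)
    elem <- a$elesy
    elem[is.na(elem) | elem == ""] <- substr(trimws(a$elety)[is.na(elem) |
                                                            elem == ""], 1, 1)
    Structure(data.frame(
        serial = a$eleno, atom = trimws(a$elety), resid = a$resid,
        chain = chain, resno = a$resno,
        x = a$x, y = a$y, z = a$z,
        element = elem, b = ifelse(is.na(a$b), 0, a$b),
        stringsAsFactors = FALSE))
}

#' Write a Structure to a PDB file
#'
#' Inverse of \code{\link{readStructure}} on coordinates and numbering
#' (coordinates to the PDB's 3 decimals).
#'
#' @param s a \linkS4class{Structure}; must be non-empty.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(s, path) {
    stopifnot(is(s, "Structure"))
    a <- atoms(s)
    if (nrow(a) == 0L) stop("refusing to write an empty structure")
    if (any(abs(c(a$x, a$y, a$z)) > 9999.999))
        stop("coordinates exceed the PDB fixed-width limit (|x| > 9999 A)")
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                     resid = a$resid, eleno = a$serial, elety = a$atom,
                     chain = a$chain, o = rep(1, nrow(a)), b = a$b,
                     elesy = a$element)
    invisible(path)
}

#' Look up one atom's coordinates
#'
#' @param s a \linkS4class{Structure}.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param atom atom name, e.g. "CA".
#' @return numeric(3) position (Angstrom), or NULL if absent; an error if
#'   the lookup is ambiguous.
#' @export
atomCoord <- function(s, chain, resno, atom) {
    a <- atoms(s)
    i <- which(a$chain == chain & a$resno == resno & a$atom == atom)
    if (length(i) == 0L) return(NULL)
    if (length(i) > 1L)
        stop(sprintf("ambiguous atom lookup: %s %d %s matches %d records",
                     chain, resno, atom, length(i)))
    c(a$x[i], a$y[i], a$z[i])
}

## Required-column schemas for the measurement tables the pipeline reads.
tableSchemas <- list(
    rdc = c("residue", "domain", "d_obs_hz", "sigma_hz"),
    hetnoe = c("residue", "i_sat", "i_ref", "noise"),
    titration = c("ca_total", "chelator_total", "protein_total", "signal"))

#' Read a delimited measurement table
#'
#' Reads a header-labelled CSV or TSV (delimiter auto-detected) and checks
#' a required-column schema. All required columns other than \code{domain}
#' must be numeric and finite.
#'
#' @param path file path.
#' @param schema character vector of required column names, or one of
#'   \code{"rdc"}, \code{"hetnoe"}, \code{"titration"} to use the built-in
#'   schema of that table kind.
#' @return data.frame in file row order, with a \code{provenance} attribute
#'   holding the source path.
#' @export
readMeasurementTable <- function(path, schema = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (length(schema) == 1L && schema %in% names(tableSchemas))
        schema <- tableSchemas[[schema]]
    header <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", header)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, strip.white = TRUE)
    missing <- setdiff(schema, names(tab))
    if (length(missing) > 0L)
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    for (col in setdiff(schema, "domain")) {
        v <- tab[[col]]
        if (!is.numeric(v))
            stop("column '", col, "' must be numeric")
        if (any(!is.finite(v)))
            stop("non-finite value in numeric column '", col, "'")
    }
    attr(tab, "provenance") <- normalizePath(path)
    tab
}
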