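#' Read molecules from an SDF (V2000) file
#'
#' Parses a multi-record SD file via ChemmineR and converts each record to the
#' package's [molecule()] model, validating bond indices and element symbols.
#' Coordinates are taken exactly as printed in the file; no geometry
#' optimization is performed.
#'
#' @param path Path to a V2000 SDF file.
#' @return List of [molecule()] objects, one per record, in file order, each
#'   named by the record's molecule-name header line. An empty file yields an
#'   empty list with a warning.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    warning("empty SDF file: ", path, call. = FALSE)
    return(list())
  }
  sdfset <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    rec <- tryCatch({
      sdf <- sdfset[[k]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      elements <- sub("_\\d+$", "", rownames(ab))
      bonds <- if (NROW(bb) > 0) {
        data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
      } else NULL
      nm <- unname(ChemmineR::header(sdf)[["Molecule_Name"]]) %||% ""
      molecule(elements, ab[, 1:3, drop = FALSE], bonds,
               name = trimws(nm), three_d = TRUE)
    }, error = function(e) {
      stop("malformed SDF record ", k, " in ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
    out[[k]] <- rec
  }
  names(out) <- vapply(out, function(m) m$name, character(1))
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' Emits one V2000 molblock per molecule with coordinates printed at
#' four decimal places (the molfile field width), so a read/write round trip
#' preserves structure within print precision.
#'
#' @param molecules List of [molecule()] objects (or a single molecule).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sdf <- function(molecules, path) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in molecules) {
    at <- m$atoms
    b <- m$bonds
    writeLines(c(m$name, "  bcrpsvm", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$element), con)
    if (nrow(b))
      writeLines(sprintf("%3d%3d%3d  0", b$i, b$j, b$order), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read an id/name/SMILES table
#'
#' Delimited text (comma or tab, sniffed from the header) with columns named
#' `id`, `name` and `smiles` (case-insensitive). SMILES strings are returned
#' as text; parsing is deferred to [smiles_to_molecule()] so a bad SMILES
#' surfaces with its row number only when the structure is materialized.
#'
#' @param path Path to the table.
#' @return Data frame with columns `id`, `name`, `smiles`, in file order.
#' @export
read_smiles_table <- function(path) {
  df <- read_delim_sniff(path)
  names(df) <- tolower(names(df))
  for (col in c("id", "name", "smiles")) {
    if (!col %in% names(df))
      stop("SMILES table is missing required column '", col, "'", call. = FALSE)
  }
  out <- data.frame(id = as.character(df$id), name = as.character(df$name),
                    smiles = as.character(df$smiles),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id))
    stop("duplicate compound id in SMILES table: ",
         out$id[duplicated(out$id)][1], call. = FALSE)
  out
}

#' Materialize a molecule from a SMILES string
#'
#' Uses Open Babel (via ChemmineOB) to parse the SMILES, add explicit
#' hydrogens and generate 2D layout coordinates. The result is flagged
#' 2D-only: composition-based descriptors (AAC) work, while 3D descriptors
#' refuse it rather than silently embedding a geometry.
#'
#' @param smiles A single SMILES string.
#' @param name Display name.
#' @param row Optional row number (from a SMILES table) used in error messages.
#' @return A [molecule()] with `three_d = FALSE`.
#' @export
smiles_to_molecule <- function(smiles, name = "", row = NULL) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES parsing requires the ChemmineOB package", call. = FALSE)
  where <- if (is.null(row)) "" else paste0(" (row ", row, ")")
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\t", if (nzchar(name)) name else "mol"),
      options = data.frame(names = c("gen2D", "h"), args = c("", ""))),
    error = function(e) "")
  if (!nzchar(trimws(sdf_txt)))
    stop("unparseable SMILES", where, ": '", smiles, "'", call. = FALSE)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  m <- tryCatch(read_sdf(tf)[[1]],
                error = function(e)
                  stop("unparseable SMILES", where, ": '", smiles, "'",
                       call. = FALSE))
  m$name <- name
  m$three_d <- FALSE
  m
}

#' Read a compound label table
#'
#' Delimited text with an `id` column and a class column named `label` or
#' `class`. Accepted class tokens are `substrate` / `non-substrate` plus
#' common aliases (`s`/`n`, `1`/`0`, `pos`/`neg`, `yes`/`no`).
#'
#' @param path Path to the table.
#' @return Named character vector mapping compound id to `"substrate"` or
#'   `"non-substrate"`.
#' @export
read_label_table <- function(path) {
  df <- read_delim_sniff(path)
  names(df) <- tolower(names(df))
  if (!"id" %in% names(df))
    stop("label table is missing required column 'id'", call. = FALSE)
  lab_col <- intersect(c("label", "class"), names(df))
  if (!length(lab_col))
    stop("label table is missing a 'label' or 'class' column", call. = FALSE)
  ids <- as.character(df$id)
  if (anyDuplicated(ids))
    stop("duplicate compound id in label table: ", ids[duplicated(ids)][1],
         call. = FALSE)
  raw <- as.character(df[[lab_col[1]]])
  labels <- vapply(seq_along(raw), function(r) {
    tryCatch(normalize_labels(raw[r], context = "class"),
             error = function(e)
               stop("unknown class token '", raw[r], "' at row ", r,
                    call. = FALSE))
  }, character(1))
  names(labels) <- ids
  labels
}

#' Assemble a labeled compound set
#'
#' @param structures List of [molecule()] objects (or SMILES strings), named
#'   or matched positionally to `ids`.
#' @param labels Named character vector (id -> class), e.g. from
#'   [read_label_table()].
#' @param ids Compound ids; defaults to structure names.
#' @param provenance Free-text source note.
#' @return Object of class `compound_set`: list with `ids`, `structures`,
#'   `labels`, `provenance`.
#' @export
compound_set <- function(structures, labels, ids = NULL, provenance = "") {
  if (inherits(structures, "molecule")) structures <- list(structures)
  if (is.null(ids)) ids <- names(structures)
  if (is.null(ids) || !all(nzchar(ids)))
    stop("compound ids are required (names of `structures` or `ids=`)",
         call. = FALSE)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate compound ids in compound set", call. = FALSE)
  if (length(structures) != length(ids))
    stop("ids and structures differ in length", call. = FALSE)
  labels <- check_labels(labels, ids)
  names(structures) <- ids
  structure(list(ids = ids, structures = structures, labels = labels,
                 provenance = provenance),
            class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds (%d substrate / %d non-substrate)%s\n",
              length(x$ids),
              sum(x$labels == LABEL_SUBSTRATE),
              sum(x$labels == LABEL_NONSUBSTRATE),
              if (nzchar(x$provenance)) paste0(" — ", x$provenance) else ""))
  invisible(x)
}

#' @export
length.compound_set <- function(x) length(x$ids)
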