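#' Read a labeled matrix from TSV or Matrix Market files
#'
#' TSV layout: first row holds column labels, first column holds row labels,
#' tab-separated, UTF-8. Matrix Market (`mtx`) files carry no labels, so a
#' coordinate file `<path>` must be accompanied by sidecar files
#' `<path minus .mtx>.rows` and `.cols` with one label per line.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @return numeric matrix with rownames/colnames.
#' @export
read_labeled_matrix <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_tf("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE, quote = "",
                            comment.char = "", fileEncoding = "UTF-8")
    M <- as.matrix(df)
    if (!is.numeric(M)) {
      bad <- which(!vapply(df, is.numeric, TRUE))[1]
      stop_tf("parse error in ", path, ": non-numeric cells in column '",
              colnames(df)[bad], "'")
    }
  } else {
    M <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rfile <- paste0(stem, ".rows"); cfile <- paste0(stem, ".cols")
    if (!file.exists(rfile) || !file.exists(cfile))
      stop_tf("mtx file ", path, " needs label sidecars ", rfile, " and ", cfile)
    rl <- readLines(rfile, encoding = "UTF-8")
    cl <- readLines(cfile, encoding = "UTF-8")
    if (length(rl) != nrow(M) || length(cl) != ncol(M))
      stop_tf("label/dimension mismatch for ", path, ": matrix ",
              nrow(M), "x", ncol(M), ", labels ", length(rl), "/", length(cl))
    dimnames(M) <- list(rl, cl)
  }
  M
}

#' Write a labeled matrix to TSV or Matrix Market files
#'
#' Inverse of [read_labeled_matrix()]; `mtx` output writes the coordinate
#' file plus `.rows`/`.cols` label sidecars.
#'
#' @param M numeric matrix with dimnames.
#' @param path destination path.
#' @param format `"tsv"` or `"mtx"` (default from extension).
#' @export
write_labeled_matrix <- function(M, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop_tf("matrix must carry row and column labels")
  if (format == "tsv") {
    df <- data.frame(id = rownames(M), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    Matrix::writeMM(Matrix::Matrix(M, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(M), paste0(stem, ".rows"))
    writeLines(colnames(M), paste0(stem, ".cols"))
  }
  invisible(path)
}

#' Load a data bundle from a YAML configuration
#'
#' The configuration declares the families (name and latent space), the
#' relations (name, kind, row/col family, matrix file and optional format),
#' and optionally default latent dimensions per space:
#'
#' ```yaml
#' dims: {space1: 21, space2: 70, space3: 40}
#' families:
#'   - {name: patients, space: space1}
#'   - {name: cancers,  space: space1}
#' relations:
#'   - {name: diagnosis, kind: NMF, row_family: patients,
#'      col_family: cancers, file: diagnosis.tsv}
#' ```
#'
#' Family entity ids are taken from the first relation file mentioning the
#' family; later files are aligned by label. Relative file paths resolve
#' against the configuration file's directory.
#'
#' @param config_path path to the YAML file.
#' @return a validated [data_bundle()].
#' @export
load_bundle <- function(config_path) {
  if (!file.exists(config_path)) stop_tf("config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  if (is.null(cfg$families) || is.null(cfg$relations))
    stop_tf("config must declare 'families' and 'relations'")

  fam_space <- stats::setNames(
    vapply(cfg$families, function(f) f$space, ""),
    vapply(cfg$families, function(f) f$name, ""))

  fam_ids <- list()
  relations <- lapply(cfg$relations, function(rc) {
    for (field in c("name", "kind", "row_family", "col_family", "file"))
      if (is.null(rc[[field]]))
        stop_tf("relation entry missing field '", field, "'")
    if (!rc$kind %in% c("NMF", "NMTF", "SNMTF"))
      stop_tf("relation '", rc$name, "': unknown kind '", rc$kind, "'")
    fpath <- rc$file
    if (!file.exists(fpath)) fpath <- file.path(base, rc$file)
    M <- read_labeled_matrix(fpath, rc$format %||% "auto")
    for (side in c("row_family", "col_family")) {
      fname <- rc[[side]]
      if (!fname %in% names(fam_space))
        stop_tf("relation '", rc$name, "' references undeclared family '", fname, "'")
      labs <- if (side == "row_family") rownames(M) else colnames(M)
      if (is.null(fam_ids[[fname]])) fam_ids[[fname]] <<- labs
    }
    relation(rc$name, rc$row_family, rc$col_family, rc$kind, M)
  })

  undeclared <- setdiff(names(fam_space), names(fam_ids))
  if (length(undeclared))
    stop_tf("families never seen in any relation file: ",
            paste(undeclared, collapse = ", "))
  families <- lapply(names(fam_space), function(f)
    entity_family(f, fam_ids[[f]], fam_space[[f]]))
  data_bundle(families, relations, space_dims = cfg$dims %||% NULL)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_tf("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_tf("malformed GMT line ", bad[1], " in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path destination path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "description") %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
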