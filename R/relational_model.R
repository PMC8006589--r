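#' Declare an entity family
#'
#' An entity family is an ordered set of uniquely labeled entities (patients,
#' cancer types, genes, pathways, complexes, drugs, ...) assigned to exactly
#' one shared latent space. Families assigned to the same space are embedded
#' with the same latent dimensionality and can substitute for each other in
#' downstream classifiers.
#'
#' @param name family identifier (single string).
#' @param ids character vector of unique entity labels.
#' @param space latent-space identifier, e.g. `"space1"` (patients and cancer
#'   types), `"space2"` (genes, pathways, complexes), `"space3"` (drugs).
#' @return an `entity_family` object.
#' @export
entity_family <- function(name, ids, space) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(space), length(space) == 1L)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_tf("duplicate entity ids in family '", name, "'")
  if (length(ids) == 0L) stop_tf("family '", name, "' has no entities")
  structure(list(name = name, ids = ids, space = space),
            class = "entity_family")
}

#' @export
print.entity_family <- function(x, ...) {
  cat("<entity_family> ", x$name, ": ", length(x$ids),
      " entities in ", x$space, "\n", sep = "")
  invisible(x)
}

#' Declare a typed relation between two entity families
#'
#' A relation wraps one non-negative data matrix and the kind of factorization
#' used to decompose it:
#' \describe{
#'   \item{NMF}{\eqn{R \approx G_a G_b^T}; both families must share one latent
#'     space (e.g. patient x cancer-type diagnosis).}
#'   \item{NMTF}{\eqn{R \approx G_a S G_b^T}; the families must live in
#'     different latent spaces, linked by a central matrix \eqn{S}
#'     (e.g. patient x gene expression).}
#'   \item{SNMTF}{\eqn{A \approx G S G^T}; square symmetric data over a single
#'     family (e.g. a PPI network, drug chemical similarities).}
#' }
#'
#' @param name relation identifier.
#' @param row_family,col_family family names indexing rows and columns.
#' @param kind one of `"NMF"`, `"NMTF"`, `"SNMTF"`.
#' @param matrix non-negative numeric matrix with rownames/colnames equal to
#'   the two families' entity ids (checked when assembled into a bundle).
#' @return a `relation` object.
#' @export
relation <- function(name, row_family, col_family, kind, matrix) {
  kind <- match.arg(kind, c("NMF", "NMTF", "SNMTF"))
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop_tf("relation '", name, "': matrix must be numeric")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop_tf("relation '", name, "': non-finite entries")
  if (min(matrix) < 0)
    stop_tf("relation '", name, "': negative entries not allowed")
  if (kind == "SNMTF") {
    if (row_family != col_family)
      stop_tf("relation '", name, "': SNMTF requires one family on both sides")
    if (nrow(matrix) != ncol(matrix) ||
        max(abs(matrix - t(matrix))) > 1e-9)
      stop_tf("relation '", name, "': SNMTF requires a symmetric matrix")
  }
  structure(list(name = name, row_family = row_family,
                 col_family = col_family, kind = kind, matrix = matrix),
            class = "relation")
}

#' @export
print.relation <- function(x, ...) {
  cat("<relation> ", x$name, " [", x$kind, "]: ",
      x$row_family, " (", nrow(x$matrix), ") x ",
      x$col_family, " (", ncol(x$matrix), "), density ",
      signif(mean(x$matrix != 0), 3), "\n", sep = "")
  invisible(x)
}

#' Assemble families and relations into a validated data bundle
#'
#' The bundle is the multipartite input of the joint factorization: every
#' family is mapped to a latent space and every relation's matrix is aligned
#' (by label, not position) to its families' entity orders. Matrices whose
#' dimnames are a permutation of the family ids are reordered; missing or
#' extra labels are an error.
#'
#' @param families list of [entity_family()] objects.
#' @param relations list of [relation()] objects.
#' @param space_dims named integer vector of default latent dimensionalities
#'   per space (the hyperparameters k1, k2, k3), or `NULL`.
#' @return a `data_bundle`.
#' @export
data_bundle <- function(families, relations, space_dims = NULL) {
  names(families) <- vapply(families, `[[`, "", "name")
  names(relations) <- vapply(relations, `[[`, "", "name")
  if (anyDuplicated(names(families))) stop_tf("duplicate family names")
  if (anyDuplicated(names(relations))) stop_tf("duplicate relation names")
  spaces <- vapply(families, `[[`, "", "space")

  relations <- lapply(relations, function(r) {
    for (side in c("row_family", "col_family"))
      if (!r[[side]] %in% names(families))
        stop_tf("relation '", r$name, "' references unknown family '", r[[side]], "'")
    fr <- families[[r$row_family]]; fc <- families[[r$col_family]]
    if (nrow(r$matrix) != length(fr$ids) || ncol(r$matrix) != length(fc$ids))
      stop_tf("relation '", r$name, "': matrix is ", nrow(r$matrix), "x",
              ncol(r$matrix), " but families have ", length(fr$ids), "/",
              length(fc$ids), " entities")
    r$matrix <- align_to_family(r$matrix, fr, fc, r$name)
    if (r$kind == "NMF" && fr$space != fc$space)
      stop_tf("relation '", r$name, "': NMF requires both families in one space")
    if (r$kind == "NMTF" && fr$space == fc$space)
      stop_tf("relation '", r$name, "': NMTF requires families in different spaces")
    r
  })

  used <- unique(unlist(lapply(relations, function(r) c(r$row_family, r$col_family))))
  orphan <- setdiff(names(families), used)
  if (length(orphan))
    stop_tf("families not used by any relation: ", paste(orphan, collapse = ", "))

  if (!is.null(space_dims)) {
    space_dims <- check_space_dims(space_dims, families, spaces)
  }
  structure(list(families = families, relations = relations,
                 space_dims = space_dims),
            class = "data_bundle")
}

# reorder a matrix so rows/cols follow the family id order; attach dimnames
# when absent (positional data), error on label mismatch otherwise
align_to_family <- function(M, fr, fc, rel_name) {
  if (is.null(rownames(M))) rownames(M) <- fr$ids
  if (is.null(colnames(M))) colnames(M) <- fc$ids
  if (!setequal(rownames(M), fr$ids) || !setequal(colnames(M), fc$ids))
    stop_tf("relation '", rel_name, "': matrix labels do not match family ids")
  M[fr$ids, fc$ids, drop = FALSE]
}

check_space_dims <- function(space_dims, families, spaces) {
  space_dims <- unlist(space_dims)
  storage.mode(space_dims) <- "integer"
  for (s in unique(spaces)) {
    if (is.na(space_dims[s]))
      stop_tf("no latent dimension given for ", s)
    min_n <- min(vapply(families[spaces == s], function(f) length(f$ids), 0L))
    if (space_dims[s] < 1L || space_dims[s] > min_n)
      stop_tf("dimension for ", s, " must be in [1, ", min_n, "]")
  }
  space_dims
}

#' @export
print.data_bundle <- function(x, ...) {
  cat("<data_bundle> ", length(x$families), " families, ",
      length(x$relations), " relations, ",
      length(unique(vapply(x$families, `[[`, "", "space"))), " spaces\n", sep = "")
  for (r in x$relations) print(r)
  invisible(x)
}

#' Validate a data bundle and report violations
#'
#' Reporting companion of [data_bundle()]: instead of stopping at the first
#' problem it lists, per relation, density, negative entries, symmetry
#' deviations for SNMTF relations, kind/space inconsistencies, plus orphan
#' families. Intended for checking externally assembled inputs.
#'
#' @param bundle a `data_bundle`, or an unvalidated list with the same shape
#'   (`families`, `relations`).
#' @return list with elements `ok` (logical), `issues` (data.frame:
#'   relation, type, detail) and `summary` (per-relation data.frame).
#' @export
validate_bundle <- function(bundle) {
  fam <- bundle$families
  names(fam) <- vapply(fam, `[[`, "", "name")
  spaces <- vapply(fam, `[[`, "", "space")
  issues <- list()
  add <- function(relname, type, detail)
    issues[[length(issues) + 1L]] <<- data.frame(
      relation = relname, type = type, detail = detail,
      stringsAsFactors = FALSE)

  summ <- lapply(bundle$relations, function(r) {
    M <- r$matrix
    neg <- which(M < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      add(r$name, "negativity",
          paste0("negative entry at [", neg[1, 1], ",", neg[1, 2], "] (",
                 nrow(neg), " total)"))
    sym_dev <- NA_real_
    if (r$kind == "SNMTF") {
      if (nrow(M) != ncol(M)) {
        add(r$name, "symmetry", "matrix not square")
      } else {
        sym_dev <- max(abs(M - t(M)))
        if (sym_dev > 1e-9)
          add(r$name, "symmetry", paste0("max |A - t(A)| = ", signif(sym_dev, 3)))
      }
      if (r$row_family != r$col_family)
        add(r$name, "kind", "SNMTF relation must be within one family")
    }
    fr <- fam[[r$row_family]]; fc <- fam[[r$col_family]]
    if (!is.null(fr) && !is.null(fc)) {
      if (r$kind == "NMF" && fr$space != fc$space)
        add(r$name, "kind", "NMF families must share a latent space")
      if (r$kind == "NMTF" && fr$space == fc$space)
        add(r$name, "kind", "NMTF families must be in different latent spaces")
      if (nrow(M) != length(fr$ids) || ncol(M) != length(fc$ids))
        add(r$name, "shape", "matrix dimensions do not match family sizes")
    }
    data.frame(relation = r$name, kind = r$kind,
               nrow = nrow(M), ncol = ncol(M),
               density = mean(M != 0), stringsAsFactors = FALSE)
  })

  used <- unique(unlist(lapply(bundle$relations,
                               function(r) c(r$row_family, r$col_family))))
  for (f in setdiff(names(fam), used))
    add("<bundle>", "orphan", paste0("family '", f, "' in no relation"))

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(relation = character(), type = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(ok = nrow(issues) == 0L,
       issues = issues,
       summary = do.call(rbind, summ))
}
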