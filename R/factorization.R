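#' Configuration of a joint factorization fit
#'
#' @param dims named integer vector of latent dimensions per space
#'   (the hyperparameters k1, k2, k3). Each k must lie in
#'   `[1, min family size in that space]`.
#' @param max_iter maximum number of multiplicative-update rounds.
#' @param tol convergence threshold on the relative change of the joint
#'   objective between rounds.
#' @param eps denominator stabilizer added to every multiplicative-update
#'   denominator; guards against division by zero without perturbing the
#'   fixed points materially.
#' @param seed integer seed controlling the random initialization.
#' @param n_restarts number of random restarts; the restart with the lowest
#'   final objective is kept.
#' @return a `fit_config` object.
#' @export
fit_config <- function(dims, max_iter = 500L, tol = 1e-5, eps = 1e-12,
                       seed = 1L, n_restarts = 1L) {
  stopifnot(length(dims) >= 1, all(dims >= 1),
            max_iter >= 1, tol > 0, eps > 0, n_restarts >= 1)
  structure(list(dims = stats::setNames(as.integer(dims), names(dims)),
                 max_iter = as.integer(max_iter), tol = tol, eps = eps,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "fit_config")
}

# k for the space a family lives in
space_of <- function(bundle, fam) bundle$families[[fam]]$space
dim_of <- function(cfg, bundle, fam) cfg$dims[[space_of(bundle, fam)]]

#' Random positive initialization of the factor model
#'
#' All factors are drawn strictly positive uniform; central matrices are then
#' rescaled so each tri-factorized relation's initial reconstruction has the
#' same Frobenius norm as its data matrix, and shared factors of NMF relations
#' are rescaled (two sweeps) toward the same property. Deterministic given
#' `cfg$seed`.
#'
#' @param bundle a [data_bundle()].
#' @param cfg a [fit_config()].
#' @return a `factor_model`: list with `factors` (one non-negative matrix per
#'   family, rows labeled by entity ids), `centrals` (one matrix per
#'   tri-factorized relation), `dims` and `spaces`.
#' @export
init_factors <- function(bundle, cfg) {
  spaces <- vapply(bundle$families, `[[`, "", "space")
  cfg$dims <- check_space_dims(cfg$dims, bundle$families, spaces)
  set.seed(cfg$seed)

  factors <- lapply(bundle$families, function(f) {
    k <- cfg$dims[[f$space]]
    G <- matrix(stats::runif(length(f$ids) * k, min = 0.1, max = 1),
                nrow = length(f$ids), ncol = k)
    rownames(G) <- f$ids
    G
  })

  model <- structure(list(factors = factors, centrals = list(),
                          dims = cfg$dims, spaces = spaces),
                     class = "factor_model")

  # bring NMF reconstructions to the data scale by scaling the column factor
  # (two sweeps to settle families shared between several NMF relations)
  for (sweep in 1:2) {
    for (r in bundle$relations) {
      if (r$kind != "NMF") next
      recon <- model$factors[[r$row_family]] %*% t(model$factors[[r$col_family]])
      ratio <- frob(r$matrix) / frob(recon)
      if (is.finite(ratio) && ratio > 0)
        model$factors[[r$col_family]] <- model$factors[[r$col_family]] * ratio
    }
  }
  # central matrices absorb the scale of tri-factorized relations exactly
  for (r in bundle$relations) {
    if (r$kind == "NMF") next
    ka <- cfg$dims[[space_of(bundle, r$row_family)]]
    kb <- cfg$dims[[space_of(bundle, r$col_family)]]
    S <- matrix(stats::runif(ka * kb, min = 0.1, max = 1), ka, kb)
    if (r$kind == "SNMTF") S <- (S + t(S)) / 2
    recon <- model$factors[[r$row_family]] %*% S %*% t(model$factors[[r$col_family]])
    ratio <- frob(r$matrix) / frob(recon)
    if (is.finite(ratio) && ratio > 0) S <- S * ratio
    model$centrals[[r$name]] <- S
  }
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> factors:",
      paste(sprintf("%s(%dx%d)", names(x$factors),
                    vapply(x$factors, nrow, 0L), vapply(x$factors, ncol, 0L)),
            collapse = ", "),
      "\n  centrals:", paste(names(x$centrals), collapse = ", "), "\n")
  invisible(x)
}

# squared Frobenius residual of one relation under the model
relation_residual2 <- function(r, model) {
  recon <- reconstruct_relation(r, model)
  sum((r$matrix - recon)^2)
}

reconstruct_relation <- function(r, model) {
  Ga <- model$factors[[r$row_family]]
  Gb <- model$factors[[r$col_family]]
  if (r$kind == "NMF") Ga %*% t(Gb)
  else Ga %*% model$centrals[[r$name]] %*% t(Gb)
}

#' Per-relation relative reconstruction errors
#'
#' The squared Frobenius ratio \eqn{\|R_e - \hat R_e\|_F^2 / \|R_e\|_F^2}
#' for every relation — the standard relative reconstruction error of the
#' factorization literature. An exactly recovered relation scores 0.
#'
#' @param bundle a [data_bundle()].
#' @param model a `factor_model` (or `fit_result`).
#' @return named numeric vector, one entry per relation.
#' @export
relative_residuals <- function(bundle, model) {
  if (inherits(model, "fit_result")) model <- model$model
  vapply(bundle$relations, function(r)
    relation_residual2(r, model) / sum(r$matrix^2), 0)
}

#' Joint factorization objective
#'
#' The unweighted sum over relations of squared Frobenius reconstruction
#' errors, \eqn{J = \sum_e \|R_e - \hat R_e\|_F^2}, with \eqn{\hat R} equal to
#' \eqn{G_a G_b^T} (NMF), \eqn{G_a S G_b^T} (NMTF) or \eqn{G S G^T} (SNMTF).
#'
#' @param bundle a [data_bundle()].
#' @param model a `factor_model`.
#' @param per_relation if `TRUE` also attach the per-relation terms as an
#'   attribute `"terms"`.
#' @return non-negative scalar.
#' @export
joint_objective <- function(bundle, model, per_relation = FALSE) {
  terms <- vapply(bundle$relations, relation_residual2, 0, model = model)
  J <- sum(terms)
  if (per_relation) attr(J, "terms") <- terms
  J
}

#' One synchronized round of multiplicative updates
#'
#' Each shared factor is updated in bundle order with the aggregated rule
#' \eqn{G_f \leftarrow G_f \circ \sum_e num_e(f) \oslash (\sum_e den_e(f) +
#' \epsilon)}, where the numerator/denominator gradient terms are summed over
#' every relation incident to the family:
#' NMF: \eqn{num = R G_b}, \eqn{den = G_a G_b^T G_b} (and transposed
#' counterparts); NMTF: \eqn{num = R G_b S^T},
#' \eqn{den = G_a S G_b^T G_b S^T} (and counterparts); SNMTF contributes both
#' gradient halves of the symmetric form. Central matrices then update as
#' \eqn{S \leftarrow S \circ (G_a^T R G_b) \oslash (G_a^T G_a S G_b^T G_b +
#' \epsilon)}; SNMTF centrals are symmetrized afterwards. Non-negativity is
#' preserved by construction.
#'
#' @param bundle a [data_bundle()].
#' @param model a `factor_model`.
#' @param eps denominator stabilizer.
#' @return the updated `factor_model`.
#' @export
update_step <- function(bundle, model, eps = 1e-12) {
  for (fam in names(model$factors)) {
    G <- model$factors[[fam]]
    num <- matrix(0, nrow(G), ncol(G))
    den <- matrix(0, nrow(G), ncol(G))
    touched <- FALSE
    for (r in bundle$relations) {
      if (r$row_family != fam && r$col_family != fam) next
      touched <- TRUE
      R <- r$matrix
      if (r$kind == "NMF") {
        Ga <- model$factors[[r$row_family]]
        Gb <- model$factors[[r$col_family]]
        if (r$row_family == fam) {
          num <- num + R %*% Gb
          den <- den + Ga %*% (t(Gb) %*% Gb)
        }
        if (r$col_family == fam) {
          num <- num + t(R) %*% Ga
          den <- den + Gb %*% (t(Ga) %*% Ga)
        }
      } else if (r$kind == "NMTF") {
        S <- model$centrals[[r$name]]
        Ga <- model$factors[[r$row_family]]
        Gb <- model$factors[[r$col_family]]
        if (r$row_family == fam) {
          num <- num + R %*% Gb %*% t(S)
          den <- den + Ga %*% S %*% (t(Gb) %*% Gb) %*% t(S)
        }
        if (r$col_family == fam) {
          num <- num + t(R) %*% Ga %*% S
          den <- den + Gb %*% t(S) %*% (t(Ga) %*% Ga) %*% S
        }
      } else { # SNMTF: both halves of the symmetric gradient
        S <- model$centrals[[r$name]]
        num <- num + R %*% G %*% t(S) + t(R) %*% G %*% S
        GtG <- t(G) %*% G
        den <- den + G %*% S %*% GtG %*% t(S) + G %*% t(S) %*% GtG %*% S
      }
    }
    if (!touched) next
    model$factors[[fam]] <- G * num / (den + eps)
  }
  for (r in bundle$relations) {
    if (r$kind == "NMF") next
    Ga <- model$factors[[r$row_family]]
    Gb <- model$factors[[r$col_family]]
    S <- model$centrals[[r$name]]
    S <- S * (t(Ga) %*% r$matrix %*% Gb) /
      ((t(Ga) %*% Ga) %*% S %*% (t(Gb) %*% Gb) + eps)
    if (r$kind == "SNMTF") S <- (S + t(S)) / 2
    model$centrals[[r$name]] <- S
  }
  model
}

#' Fit the joint factorization by multiplicative updates
#'
#' Iterates [update_step()] from a random positive initialization until the
#' relative change of the joint objective drops below `cfg$tol` or `max_iter`
#' rounds elapse. With `n_restarts > 1` the fit is repeated from seeds
#' `seed, seed+1, ...` and the restart with the lowest final objective wins.
#'
#' @param bundle a [data_bundle()].
#' @param cfg a [fit_config()]; `cfg$dims` may be omitted if the bundle
#'   carries `space_dims`.
#' @return a `fit_result`: `model`, `objective_trace` (value at init plus one
#'   per round), `converged`, `iterations`.
#' @export
fit_collective <- function(bundle, cfg = NULL) {
  if (is.null(cfg)) {
    if (is.null(bundle$space_dims))
      stop_tf("no fit_config and the bundle carries no default dims")
    cfg <- fit_config(bundle$space_dims)
  }
  best <- NULL
  for (restart in seq_len(cfg$n_restarts)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + restart - 1L
    res <- fit_once(bundle, cfg_r)
    if (is.null(best) ||
        res$objective_trace[length(res$objective_trace)] <
        best$objective_trace[length(best$objective_trace)])
      best <- res
  }
  best
}

fit_once <- function(bundle, cfg) {
  model <- init_factors(bundle, cfg)
  J <- joint_objective(bundle, model)
  trace <- J
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iter)) {
    model <- update_step(bundle, model, eps = cfg$eps)
    J_new <- joint_objective(bundle, model)
    if (!is.finite(J_new))
      stop_tf("objective became non-finite at iteration ", it,
              " (J was ", signif(J, 6), ")")
    trace <- c(trace, J_new)
    iters <- it
    if (abs(J - J_new) < cfg$tol * max(J, .Machine$double.xmin)) {
      converged <- TRUE
      J <- J_new
      break
    }
    J <- J_new
  }
  structure(list(model = model, objective_trace = trace,
                 converged = converged, iterations = iters, config = cfg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  n <- length(x$objective_trace)
  cat("<fit_result> ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged",
      "; objective ", signif(x$objective_trace[1], 5), " -> ",
      signif(x$objective_trace[n], 5), "\n", sep = "")
  invisible(x)
}

#' Grid search over latent dimensionalities
#'
#' Fits every combination of candidate dimensions and scores each fitted
#' model by the macro-F1 of the classifier that assigns every patient to the
#' cosine-nearest cancer-type embedding (the model-selection criterion of the
#' framework). Ties break toward the lexicographically smallest dimension
#' triple.
#'
#' @param bundle a [data_bundle()].
#' @param grid named list of candidate dimension vectors per space, e.g.
#'   `list(space1 = c(2, 5, 10), space2 = ..., space3 = ...)`.
#' @param entity_family name of the family classified (patients).
#' @param centroid_family name of the family providing class centroids
#'   (cancer types).
#' @param truth [Labeling][nearest_centroid_macro_f1()]: named vector mapping
#'   each entity id to its true class (diagnosis).
#' @param cfg_template `fit_config` supplying `max_iter`, `tol`, `seed`, ...
#'   for every grid point (its `dims` are overridden).
#' @return the winning `fit_config`, with the full score table attached as
#'   `attr(, "scores")` (data.frame: one row per grid point, dims + macro_f1)
#'   and the winning fit as `attr(, "fit")`.
#' @export
select_hyperparameters <- function(bundle, grid,
                                   entity_family = "patients",
                                   centroid_family = "cancers",
                                   truth,
                                   cfg_template = fit_config(dims = c(space1 = 2))) {
  spaces <- unique(vapply(bundle$families, `[[`, "", "space"))
  if (!all(spaces %in% names(grid)))
    stop_tf("grid must name every space: ", paste(spaces, collapse = ", "))
  if (any(lengths(grid[spaces]) == 0)) stop_tf("empty candidate list")
  combos <- expand.grid(lapply(grid[spaces], as.integer),
                        KEEP.OUT.ATTRS = FALSE)
  # lexicographic order over dims so the first maximum is the smallest triple
  combos <- combos[do.call(order, combos), , drop = FALSE]
  # drop grid points whose k exceeds the smallest family of the space
  fam_spaces <- vapply(bundle$families, `[[`, "", "space")
  cap <- vapply(spaces, function(s)
    min(vapply(bundle$families[fam_spaces == s], function(f) length(f$ids), 0L)),
    0L)
  feasible <- apply(combos, 1, function(d) all(d <= cap[colnames(combos)]))
  if (!any(feasible)) stop_tf("no feasible grid point for the family sizes")
  if (!all(feasible))
    message(sum(!feasible), " grid points exceed a family size; skipped")
  combos <- combos[feasible, , drop = FALSE]

  scores <- numeric(nrow(combos))
  best_fit <- NULL; best_score <- -Inf
  for (i in seq_len(nrow(combos))) {
    cfg <- cfg_template
    cfg$dims <- stats::setNames(as.integer(combos[i, ]), colnames(combos))
    fitted <- fit_collective(bundle, cfg)
    emb_e <- embeddings(fitted$model, entity_family, normalize = TRUE)
    emb_c <- embeddings(fitted$model, centroid_family, normalize = TRUE)
    scores[i] <- nearest_centroid_macro_f1(emb_e, emb_c, truth)
    if (scores[i] > best_score) {
      best_score <- scores[i]
      best_fit <- fitted
    }
  }
  tab <- cbind(combos, macro_f1 = scores)
  rownames(tab) <- NULL
  best <- which.max(scores)  # first maximum = lexicographically smallest dims
  out <- cfg_template
  out$dims <- stats::setNames(as.integer(combos[best, ]), colnames(combos))
  attr(out, "scores") <- tab
  attr(out, "fit") <- best_fit
  out
}

#' Extract entity embeddings from a fitted model
#'
#' An entity's embedding is its row of the family's shared factor. With
#' `normalize = TRUE` every nonzero row is scaled to unit Euclidean norm
#' (required before concatenation for link prediction, and for all cosine
#' geometry); zero rows stay zero with a warning.
#'
#' @param model a `factor_model` (or `fit_result`).
#' @param family family name.
#' @param normalize scale rows to unit norm?
#' @return an `embedding_set`: list with `family`, `space`, `ids`, `vectors`
#'   (n x k matrix, rownames = ids), `normalized`.
#' @export
embeddings <- function(model, family, normalize = TRUE) {
  if (inherits(model, "fit_result")) model <- model$model
  if (!family %in% names(model$factors)) stop_tf("unknown family '", family, "'")
  V <- model$factors[[family]]
  if (normalize) V <- unit_rows(V)
  structure(list(family = family, space = model$spaces[[family]],
                 ids = rownames(V), vectors = V, normalized = normalize),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("<embedding_set> ", x$family, " (", x$space, "): ",
      nrow(x$vectors), " x ", ncol(x$vectors),
      if (x$normalized) ", unit rows" else "", "\n", sep = "")
  invisible(x)
}

#' Fold in unseen entities by non-negative least squares
#'
#' Computes latent coordinates for entities unseen at training time without
#' refitting: given their data rows in one or more relations incident to the
#' target family, solves, per entity,
#' \deqn{\min_{g \ge 0} \sum_e \| r_e - g M_e^T \|^2}
#' where \eqn{M_e = G_b S_e^T} (NMTF) or \eqn{M_e = G_b} (NMF) is built from
#' the fixed fitted factors of the opposite family. Diagnosis-type relations
#' are naturally excluded by simply not supplying rows for them (they are the
#' prediction target for a new patient).
#'
#' @param model a `factor_model` (or `fit_result`).
#' @param bundle the [data_bundle()] the model was fitted to (provides
#'   relation kinds and orientations).
#' @param new_rows named list: relation name -> matrix of new-entity rows
#'   (n_new x size of the opposite family, oriented with new entities as
#'   rows; supply the transposed slice if the target family indexes columns
#'   of that relation).
#' @param family name of the family the new entities belong to.
#' @return an `embedding_set` (not normalized) for the new entities.
#' @export
fold_in <- function(model, bundle, new_rows, family) {
  if (inherits(model, "fit_result")) model <- model$model
  if (length(new_rows) == 0) stop_tf("no incident relation rows supplied")
  blocks <- list()
  rhs <- list()
  n_new <- NULL
  for (rel_name in names(new_rows)) {
    r <- bundle$relations[[rel_name]]
    if (is.null(r)) stop_tf("unknown relation '", rel_name, "'")
    rows <- as.matrix(new_rows[[rel_name]])
    if (is.null(n_new)) n_new <- nrow(rows)
    if (nrow(rows) != n_new) stop_tf("inconsistent entity counts across relations")
    if (r$row_family == family) {
      other <- r$col_family
      Mb <- model$factors[[other]]
      M <- if (r$kind == "NMF") Mb else Mb %*% t(model$centrals[[rel_name]])
    } else if (r$col_family == family) {
      other <- r$row_family
      Ma <- model$factors[[other]]
      M <- if (r$kind == "NMF") Ma else Ma %*% model$centrals[[rel_name]]
    } else stop_tf("relation '", rel_name, "' does not involve family '", family, "'")
    if (ncol(rows) != nrow(M))
      stop_tf("relation '", rel_name, "': rows must have length ", nrow(M))
    blocks[[rel_name]] <- M
    rhs[[rel_name]] <- rows
  }
  A <- do.call(rbind, blocks)                 # (sum of opposite sizes) x k
  B <- do.call(cbind, rhs)                    # n_new x (sum of opposite sizes)
  k <- ncol(A)
  G <- matrix(0, n_new, k)
  for (i in seq_len(n_new)) {
    b <- as.numeric(B[i, ])
    if (all(b == 0)) next                     # all-zero data -> zero embedding
    G[i, ] <- pracma::lsqnonneg(A, b)$x
  }
  rownames(G) <- rownames(B) %||% paste0("new", seq_len(n_new))
  structure(list(family = family, space = model$spaces[[family]],
                 ids = rownames(G), vectors = G, normalized = FALSE),
            class = "embedding_set")
}

#' Project embeddings of one family into another latent space
#'
#' Uses central matrices of tri-factorized relations as linear maps between
#' latent spaces: the projection of family x is \eqn{G_x S_t^T} where
#' \eqn{S_t} is the (sum of the) named central matrices, oriented
#' `k_target x k_family`. The canonical uses are gene projections into the
#' patient space (`S_t = S_exp + S_mut`) and into the drug space
#' (`S_t = S_dt`).
#'
#' @param model a `factor_model` (or `fit_result`).
#' @param bundle the fitted [data_bundle()].
#' @param family family whose embeddings are projected (e.g. `"genes"`).
#' @param centrals character vector of tri-factorized relation names; their
#'   central matrices are oriented and summed.
#' @return `projected_embeddings`: list with `family`, `target_space`,
#'   `vectors` (n x k_target).
#' @export
feature_space_projection <- function(model, bundle, family, centrals) {
  if (inherits(model, "fit_result")) model <- model$model
  fam_space <- model$spaces[[family]]
  St <- NULL
  target_space <- NULL
  for (rel_name in centrals) {
    S <- model$centrals[[rel_name]]
    if (is.null(S)) stop_tf("no central matrix for relation '", rel_name, "'")
    r <- bundle$relations[[rel_name]]
    rs <- space_of(bundle, r$row_family); cs <- space_of(bundle, r$col_family)
    if (cs == fam_space) { tsp <- rs }                 # S is k_target x k_fam
    else if (rs == fam_space) { S <- t(S); tsp <- cs } # orient to k_target x k_fam
    else stop_tf("relation '", rel_name, "' does not touch space ", fam_space)
    if (is.null(target_space)) target_space <- tsp
    else if (target_space != tsp)
      stop_tf("central matrices map into different spaces")
    St <- if (is.null(St)) S else St + S
  }
  V <- model$factors[[family]] %*% t(St)
  rownames(V) <- rownames(model$factors[[family]])
  structure(list(family = family, target_space = target_space, vectors = V),
            class = "projected_embeddings")
}
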