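#' Concatenated pair features for link prediction
#'
#' A candidate link between a left entity (e.g. a cancer type) and a right
#' entity (e.g. a gene or drug) is represented by the concatenation of their
#' unit-norm embeddings. Normalization is enforced here because it is what
#' makes classifiers transferable between families sharing a latent space.
#'
#' @param emb_left,emb_right normalized `embedding_set`s.
#' @param pairs two-column data.frame or matrix of (left id, right id).
#' @param labels optional binary labels per pair.
#' @return a `pair_dataset`: `pairs` (data.frame), `features`
#'   (n x (k_left + k_right)), `labels`, family/space bookkeeping.
#' @export
pair_features <- function(emb_left, emb_right, pairs, labels = NULL) {
  if (!isTRUE(emb_left$normalized) || !isTRUE(emb_right$normalized))
    stop_tf("embeddings must be unit-normalized (embeddings(..., normalize = TRUE))")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("left", "right")
  bad_l <- setdiff(unique(pairs$left), emb_left$ids)
  bad_r <- setdiff(unique(pairs$right), emb_right$ids)
  if (length(bad_l) || length(bad_r))
    stop_tf("unknown ids: ", paste(c(bad_l, bad_r), collapse = ", "))
  F <- cbind(emb_left$vectors[pairs$left, , drop = FALSE],
             emb_right$vectors[pairs$right, , drop = FALSE])
  colnames(F) <- c(paste0("L", seq_len(ncol(emb_left$vectors))),
                   paste0("R", seq_len(ncol(emb_right$vectors))))
  rownames(F) <- NULL
  if (!is.null(labels)) {
    labels <- as.integer(as.logical(labels))
    stopifnot(length(labels) == nrow(pairs))
  }
  structure(list(left_family = emb_left$family, right_family = emb_right$family,
                 left_space = emb_left$space, right_space = emb_right$space,
                 pairs = pairs, features = F, labels = labels),
            class = "pair_dataset")
}

#' Random fold assignment of known links
#'
#' Cross-validation splits are performed on the set of known (positive)
#' links only; all non-reported pairs form one shared negative pool and are
#' never held out. No class balancing is applied.
#'
#' @param positives data.frame/matrix of positive (left, right) pairs.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector, one fold index per positive pair.
#' @export
cv_folds <- function(positives, n_folds = 10L, seed = 1L) {
  n <- nrow(as.data.frame(positives))
  if (n < n_folds) stop_tf("fewer positives (", n, ") than folds (", n_folds, ")")
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

default_tree_params <- function() {
  list(nrounds = 200L, max_depth = 6L, eta = 0.1, nthread = 1L)
}

xgb_train_quiet <- function(X, y, params, nrounds, seed, watch = NULL,
                            early_stopping = NULL) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  args <- list(params = c(list(objective = "binary:logistic",
                               eval_metric = "logloss",
                               seed = seed), params),
               data = dtrain, nrounds = nrounds, verbose = 0)
  if (!is.null(watch)) {
    args$evals <- list(validation = watch)
    args$early_stopping_rounds <- early_stopping
  }
  do.call(xgboost::xgb.train, args)
}

#' Train the 10-member link-prediction ensemble
#'
#' One gradient-boosted tree classifier per fold: member m is trained on the
#' full dataset minus fold m's positive pairs, which are removed entirely
#' (treated as unknown, not as negatives). The shared negative pool — every
#' non-reported pair — is used unweighted in every member's training set.
#'
#' @param dataset a labeled `pair_dataset` covering positives and the
#'   negative pool.
#' @param folds fold assignment from [cv_folds()] over the dataset's
#'   positives (in order of appearance).
#' @param params tree spec: `nrounds`, `max_depth`, `eta` (defaults 200 /
#'   6 / 0.1).
#' @param seed RNG seed for tree training.
#' @return a `link_ensemble`: `members` (xgboost handles), `fold_of_positive`,
#'   `dataset` reference bits, `params`.
#' @export
train_link_ensemble <- function(dataset, folds, params = list(), seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"), !is.null(dataset$labels))
  params <- utils::modifyList(default_tree_params(), params)
  nrounds <- params$nrounds; params$nrounds <- NULL
  pos_idx <- which(dataset$labels == 1L)
  if (length(folds) != length(pos_idx))
    stop_tf("fold assignment length must equal the number of positives")
  n_folds <- max(folds)
  members <- vector("list", n_folds)
  train_rows <- vector("list", n_folds)
  for (m in seq_len(n_folds)) {
    drop_rows <- pos_idx[folds == m]
    keep <- setdiff(seq_len(nrow(dataset$features)), drop_rows)
    y <- dataset$labels[keep]
    if (length(unique(y)) < 2)
      stop_tf("fold ", m, ": training set has a single class")
    members[[m]] <- xgb_train_quiet(dataset$features[keep, , drop = FALSE],
                                    y, params, nrounds, seed = seed + m)
    train_rows[[m]] <- keep
  }
  structure(list(members = members,
                 train_rows = train_rows,
                 fold_of_positive = folds,
                 positive_index = pos_idx,
                 left_space = dataset$left_space,
                 right_space = dataset$right_space,
                 right_family = dataset$right_family,
                 feature_names = colnames(dataset$features),
                 params = c(params, nrounds = nrounds), seed = seed),
            class = "link_ensemble")
}

ensemble_raw_scores <- function(ensemble, features) {
  vapply(ensemble$members, function(m)
    stats::predict(m, xgboost::xgb.DMatrix(features)),
    numeric(nrow(features)))
}

#' Held-out cross-validation metrics of a link ensemble
#'
#' Member m scores its own held-out positives against the full negative
#' pool; AUROC and AUPRC are computed per fold and summarized as mean and
#' standard deviation.
#'
#' @param ensemble a [train_link_ensemble()] result.
#' @param dataset the `pair_dataset` it was trained on.
#' @return list: `per_fold` (data.frame fold/auroc/auprc), `auroc_mean`,
#'   `auroc_sd`, `auprc_mean`, `auprc_sd`.
#' @export
evaluate_link_cv <- function(ensemble, dataset) {
  neg_idx <- which(dataset$labels == 0L)
  pos_idx <- ensemble$positive_index
  rows <- lapply(seq_along(ensemble$members), function(m) {
    held <- pos_idx[ensemble$fold_of_positive == m]
    idx <- c(held, neg_idx)
    sc <- stats::predict(ensemble$members[[m]],
                         xgboost::xgb.DMatrix(dataset$features[idx, , drop = FALSE]))
    met <- ranking_metrics(sc, c(rep(1L, length(held)), rep(0L, length(neg_idx))))
    data.frame(fold = m, auroc = met$auroc, auprc = met$auprc)
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       auroc_mean = mean(per_fold$auroc), auroc_sd = stats::sd(per_fold$auroc),
       auprc_mean = mean(per_fold$auprc), auprc_sd = stats::sd(per_fold$auprc))
}

#' Rank candidate associations by standardized ensemble scores
#'
#' Scores every (left, right) candidate pair with each ensemble member,
#' z-standardizes each member's scores over the candidate set (a member with
#' zero score spread contributes 0, with a message), averages across members,
#' and ranks descending. Right-side entities with any known association are
#' excluded up front, so the ranking surfaces entities for which no prior
#' knowledge exists.
#'
#' @param ensemble a trained `link_ensemble`.
#' @param emb_left,emb_right normalized `embedding_set`s.
#' @param exclude right-side entity ids to drop (typically all entities with
#'   a known association to any left entity).
#' @param top_n rows of the top-association report attached as
#'   `attr(, "top")` (default 10).
#' @return an `association_ranking` data.frame: left, right, score, rank
#'   (dense, descending score).
#' @export
score_candidates <- function(ensemble, emb_left, emb_right, exclude = character(),
                             top_n = 10L) {
  if (!identical(emb_right$space, ensemble$right_space))
    stop_tf("right embeddings live in ", emb_right$space,
            " but the ensemble was trained on ", ensemble$right_space)
  keep <- setdiff(emb_right$ids, exclude)
  if (length(keep) == 0) stop_tf("all right-side entities excluded")
  cand <- expand.grid(left = emb_left$ids, right = keep,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ds <- pair_features(emb_left,
                      within_ids(emb_right, keep),
                      cand)
  raw <- ensemble_raw_scores(ensemble, ds$features)
  z <- apply(raw, 2, function(s) {
    sdv <- stats::sd(s)
    if (sdv == 0) {
      message("ensemble member with zero score spread contributes 0")
      rep(0, length(s))
    } else (s - mean(s)) / sdv
  })
  cand$score <- rowMeans(z)
  cand$rank <- as.integer(factor(-cand$score, levels = sort(unique(-cand$score))))
  cand <- cand[order(cand$rank), ]
  rownames(cand) <- NULL
  attr(cand, "top") <- utils::head(cand, top_n)
  class(cand) <- c("association_ranking", class(cand))
  cand
}

# restrict an embedding_set to a subset of ids
within_ids <- function(emb, ids) {
  emb$vectors <- emb$vectors[ids, , drop = FALSE]
  emb$ids <- ids
  emb
}

#' Repurpose a trained link ensemble for another entity family
#'
#' Zero-shot transfer: because pathways, complexes and genes share one latent
#' space (as do patients and cancer types), a classifier trained on
#' cancer-gene links can score cancer-pathway or cancer-complex candidates
#' without retraining — the substitute family's unit-norm embeddings are
#' simply fed through the identical scoring path of [score_candidates()].
#'
#' @param ensemble ensemble trained on the original right-side family.
#' @param emb_substitute normalized `embedding_set` of the substitute family;
#'   must live in the same latent space the ensemble was trained on.
#' @param emb_left normalized left-side (cancer-type) `embedding_set`.
#' @param exclude,top_n as in [score_candidates()].
#' @return an `association_ranking`.
#' @export
repurpose <- function(ensemble, emb_substitute, emb_left,
                      exclude = character(), top_n = 10L) {
  if (!identical(emb_substitute$space, ensemble$right_space))
    stop_tf("substitute family lives in ", emb_substitute$space,
            " but the ensemble expects ", ensemble$right_space)
  score_candidates(ensemble, emb_left, emb_substitute,
                   exclude = exclude, top_n = top_n)
}

#' Drug-response prediction experiment
#'
#' Binary classification of patient-drug response records (positive =
#' complete response) from concatenated unit-norm patient and drug
#' embeddings. Records are split 70%/10%/20% into train/validation/test;
#' the validation split drives early stopping on log-loss; the experiment is
#' repeated `repeats` times with fresh splits and summarized as mean and sd
#' of test AUROC/AUPRC. A resample with a single-class test split is
#' redrawn with the next seed (logged).
#'
#' @param emb_patients,emb_drugs normalized `embedding_set`s.
#' @param responses data.frame with columns `patient`, `drug`, `response`
#'   (binary). Combination-therapy records and single-outcome drugs are
#'   expected to be filtered upstream.
#' @param split train/validation/test proportions.
#' @param repeats number of repetitions (default 10).
#' @param seed base RNG seed.
#' @param params tree spec as in [train_link_ensemble()]; `nrounds` acts as
#'   the early-stopping cap.
#' @return a `response_result`: `per_repeat` (repeat, auroc, auprc),
#'   `auroc_mean/sd`, `auprc_mean/sd`, and `models` (one per repeat, for
#'   feature-importance analysis).
#' @export
drug_response_experiment <- function(emb_patients, emb_drugs, responses,
                                     split = c(0.7, 0.1, 0.2), repeats = 10L,
                                     seed = 1L, params = list()) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3)
  params <- utils::modifyList(default_tree_params(), params)
  nrounds <- params$nrounds; params$nrounds <- NULL
  ds <- pair_features(emb_patients, emb_drugs,
                      responses[, c("patient", "drug")],
                      labels = responses$response)
  n <- nrow(ds$features)
  rows <- list(); models <- list()
  rep_seed <- seed
  for (rep_i in seq_len(repeats)) {
    repeat {
      set.seed(rep_seed)
      idx <- sample(n)
      n_tr <- floor(split[1] * n); n_va <- floor(split[2] * n)
      tr <- idx[seq_len(n_tr)]
      va <- idx[n_tr + seq_len(n_va)]
      te <- idx[(n_tr + n_va + 1):n]
      rep_seed <- rep_seed + 1L
      if (length(unique(ds$labels[te])) == 2 &&
          length(unique(ds$labels[tr])) == 2 &&
          length(unique(ds$labels[va])) == 2) break
      message("single-class split redrawn (seed ", rep_seed - 1L, ")")
    }
    dval <- xgboost::xgb.DMatrix(ds$features[va, , drop = FALSE],
                                 label = ds$labels[va])
    mod <- xgb_train_quiet(ds$features[tr, , drop = FALSE], ds$labels[tr],
                           params, nrounds, seed = rep_seed,
                           watch = dval, early_stopping = 20L)
    sc <- stats::predict(mod, xgboost::xgb.DMatrix(ds$features[te, , drop = FALSE]))
    met <- ranking_metrics(sc, ds$labels[te])
    rows[[rep_i]] <- data.frame(rep = rep_i, auroc = met$auroc, auprc = met$auprc)
    models[[rep_i]] <- mod
  }
  per_repeat <- do.call(rbind, rows)
  structure(list(per_repeat = per_repeat,
                 auroc_mean = mean(per_repeat$auroc),
                 auroc_sd = stats::sd(per_repeat$auroc),
                 auprc_mean = mean(per_repeat$auprc),
                 auprc_sd = stats::sd(per_repeat$auprc),
                 models = models,
                 k_left = ncol(emb_patients$vectors),
                 k_right = ncol(emb_drugs$vectors),
                 feature_names = c(paste0("L", seq_len(ncol(emb_patients$vectors))),
                                   paste0("R", seq_len(ncol(emb_drugs$vectors))))),
            class = "response_result")
}

#' Gain-based feature importance and driver-gene recovery
#'
#' Extracts per-feature gain from each trained tree model, averages across
#' models, and splits the result into an importance vector over the patient
#' latent dimensions (`i_patients`, first k1 features) and one over the drug
#' dimensions (`i_drugs`, last k3 features). Genes (or pathways) are then
#' scored in each space by projecting their embeddings through the central
#' matrices ([feature_space_projection()]) and taking the inner product with
#' the corresponding importance vector; the two rankings are evaluated as
#' retrieval of a reference driver-gene set by AUROC/AUPRC.
#'
#' @param models list of xgboost models whose features are the concatenated
#'   (patient, drug) embedding, e.g. `response_result$models`.
#' @param k_left,k_right latent dimensions of the two blocks (k1, k3).
#' @param proj_patient,proj_drug `projected_embeddings` of the scored family
#'   into patient and drug space ([feature_space_projection()]); either may
#'   be `NULL` to skip that space.
#' @param reference ids of reference entities (e.g. known driver genes) for
#'   ranking evaluation; `NULL` skips it.
#' @return an `importance_result`: `i_patients`, `i_drugs`, per-space score
#'   vectors (`scores_patient_space`, `scores_drug_space`) and, given a
#'   reference, `metrics` (data.frame space/auroc/auprc).
#' @export
importance_analysis <- function(models, k_left, k_right,
                                proj_patient = NULL, proj_drug = NULL,
                                reference = NULL) {
  feat <- c(paste0("L", seq_len(k_left)), paste0("R", seq_len(k_right)))
  gains <- sapply(models, function(m) {
    imp <- xgboost::xgb.importance(model = m)
    g <- stats::setNames(rep(0, length(feat)), feat)
    if (!is.null(imp) && nrow(imp) > 0) g[imp$Feature] <- imp$Gain
    g
  })
  avg <- rowMeans(gains)
  i_patients <- unname(avg[seq_len(k_left)])
  i_drugs <- unname(avg[k_left + seq_len(k_right)])

  score_space <- function(proj, ivec) {
    if (is.null(proj)) return(NULL)
    if (ncol(proj$vectors) != length(ivec))
      stop_tf("projection width ", ncol(proj$vectors),
              " does not match importance length ", length(ivec))
    drop(proj$vectors %*% ivec)
  }
  sp <- score_space(proj_patient, i_patients)
  sd_ <- score_space(proj_drug, i_drugs)

  metrics <- NULL
  if (!is.null(reference)) {
    rows <- list()
    for (space in c("patient", "drug")) {
      sc <- if (space == "patient") sp else sd_
      if (is.null(sc)) next
      lab <- as.integer(names(sc) %in% reference)
      met <- ranking_metrics(sc, lab)
      rows[[space]] <- data.frame(space = space, auroc = met$auroc,
                                  auprc = met$auprc)
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
  }
  structure(list(i_patients = i_patients, i_drugs = i_drugs,
                 scores_patient_space = sp, scores_drug_space = sd_,
                 metrics = metrics),
            class = "importance_result")
}
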