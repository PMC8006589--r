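#' Macro-F1 of nearest-centroid classification in cosine geometry
#'
#' Assigns every entity to the cosine-nearest centroid embedding (ties break
#' toward the lexicographically first centroid label) and returns the
#' unweighted mean of per-class F1 scores. Used as the model-selection
#' criterion: each patient should sit closer to its own diagnosis embedding
#' than to any other cancer type.
#'
#' Classes absent from both truth and predictions are skipped; a class with
#' an empty side scores F1 = 0. Zero-vector entities are assigned to the
#' tie-break label with a warning.
#'
#' @param entity_emb `embedding_set` of the classified entities.
#' @param centroid_emb `embedding_set` whose ids are the class labels.
#' @param truth named vector: entity id -> true class label.
#' @return macro-F1 in \[0, 1\]; predicted labels in `attr(, "predicted")`.
#' @export
nearest_centroid_macro_f1 <- function(entity_emb, centroid_emb, truth) {
  X <- entity_emb$vectors
  C <- centroid_emb$vectors
  truth <- truth[rownames(X)]
  if (anyNA(truth)) stop_tf("truth labels missing for some entities")
  D <- suppressWarnings(cosine_distance(X, C))
  # lexicographic tie-break: scan columns in label order, keep first minimum
  ord <- order(colnames(D))
  D <- D[, ord, drop = FALSE]
  pred <- colnames(D)[apply(D, 1, which.min)]
  names(pred) <- rownames(X)
  out <- macro_f1(pred, as.character(truth))
  attr(out, "predicted") <- pred
  out
}

# unweighted mean of per-class F1; classes empty on both sides skipped
macro_f1 <- function(pred, truth) {
  classes <- sort(union(pred, truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1, na.rm = TRUE)
}

#' Macro-F1 of a k-nearest-neighbour classifier in cosine geometry
#'
#' Each test entity receives the majority label among its `k` cosine-nearest
#' training entities (vote ties break toward the lexicographically smallest
#' label). Used to judge whether folded-in entities land among training
#' entities of the same class.
#'
#' @param train_emb,test_emb `embedding_set`s sharing a latent space.
#' @param train_labels named vector: training id -> class.
#' @param test_labels named vector: test id -> class.
#' @param k neighbourhood size (default 10).
#' @return macro-F1; predictions in `attr(, "predicted")`.
#' @export
knn_macro_f1 <- function(train_emb, train_labels, test_emb, test_labels,
                         k = 10L) {
  Xtr <- train_emb$vectors; Xte <- test_emb$vectors
  if (k > nrow(Xtr)) stop_tf("k = ", k, " exceeds training size ", nrow(Xtr))
  train_labels <- as.character(train_labels[rownames(Xtr)])
  test_labels <- as.character(test_labels[rownames(Xte)])
  D <- suppressWarnings(cosine_distance(Xte, Xtr))
  pred <- apply(D, 1, function(d) {
    nb <- train_labels[order(d)[seq_len(k)]]
    tab <- table(nb)
    names(tab)[which.max(tab)]  # ties -> first name = smallest label
  })
  out <- macro_f1(pred, test_labels)
  attr(out, "predicted") <- pred
  out
}

#' Agglomerative clustering of embeddings under cosine distance
#'
#' Hierarchical clustering (average linkage) of the pairwise cosine distance
#' matrix, cut into `n_clusters` groups. Zero vectors are placed at maximal
#' distance 1 from everything, with a warning.
#'
#' @param emb an `embedding_set`.
#' @param n_clusters number of groups to cut the tree into.
#' @param method linkage passed to [stats::hclust()]; average linkage is the
#'   default used throughout.
#' @return named integer vector id -> cluster; the dendrogram is attached as
#'   `attr(, "hclust")`.
#' @export
cosine_hclust <- function(emb, n_clusters, method = "average") {
  X <- emb$vectors
  if (n_clusters > nrow(X)) stop_tf("more clusters than entities")
  D <- cosine_distance(X)
  hc <- stats::hclust(stats::as.dist(D), method = method)
  cl <- stats::cutree(hc, k = n_clusters)
  names(cl) <- rownames(X)
  attr(cl, "hclust") <- hc
  cl
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12[\sum_i
#' \binom{a_i}{2} + \sum_j \binom{b_j}{2}] - E}} with
#' \eqn{E = \sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}/\binom{n}{2}}.
#' Returns 0 when the index equals its expectation (e.g. one partition is a
#' single class).
#'
#' @param a,b labelings: named vectors over the same ids (aligned by name
#'   when both are named).
#' @return scalar ARI, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop_tf("labelings cover different ids")
    b <- b[names(a)]
  } else if (length(a) != length(b)) stop_tf("labelings differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(0)
  (sum_ij - expected) / denom
}

#' Hypergeometric enrichment of clusters in annotation sets
#'
#' For every (cluster, term) pair, the upper-tail hypergeometric p-value of
#' the overlap between the cluster and the term's members, with the
#' background population equal to all clustered ids. Benjamini-Hochberg
#' correction is applied globally across all (cluster, term) tests; a cluster
#' counts as enriched when at least one term survives at `alpha`.
#'
#' @param clusters named vector: id -> cluster.
#' @param annotations named list of character vectors (e.g. from
#'   [read_gmt()]); members outside the clustered population are dropped,
#'   sets left empty are skipped with a message.
#' @param alpha significance threshold on the adjusted p-values.
#' @return list: `table` (cluster, term, overlap, cluster_size, term_size,
#'   p, p_adj, enriched), `fraction_enriched`, `enriched_clusters`, `alpha`.
#' @export
cluster_enrichment <- function(clusters, annotations, alpha = 0.05) {
  population <- names(clusters)
  N <- length(population)
  annotations <- lapply(annotations, intersect, y = population)
  empty <- lengths(annotations) == 0L
  if (any(empty)) {
    message(sum(empty), " empty annotation sets skipped")
    annotations <- annotations[!empty]
  }
  if (length(annotations) == 0L) stop_tf("no usable annotation sets")
  cl_ids <- split(population, clusters)
  # indicator crossproduct gives all overlaps at once
  Mc <- vapply(cl_ids, function(ids) population %in% ids, logical(N))
  Mt <- vapply(annotations, function(ids) population %in% ids, logical(N))
  overlap <- t(Mc) %*% Mt
  csize <- lengths(cl_ids)[rownames(overlap)]
  tsize <- lengths(annotations)[colnames(overlap)]
  grid <- expand.grid(cluster = rownames(overlap), term = colnames(overlap),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$overlap <- as.vector(overlap)
  grid$cluster_size <- csize[grid$cluster]
  grid$term_size <- tsize[grid$term]
  grid$p <- stats::phyper(grid$overlap - 1, grid$term_size,
                          N - grid$term_size, grid$cluster_size,
                          lower.tail = FALSE)
  grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  grid$enriched <- grid$p_adj <= alpha
  enriched_clusters <- unique(grid$cluster[grid$enriched])
  list(table = grid,
       fraction_enriched = length(enriched_clusters) / length(cl_ids),
       enriched_clusters = enriched_clusters,
       alpha = alpha)
}

#' Permutation null for the fraction of enriched clusters
#'
#' Re-runs [cluster_enrichment()] on replicates where cluster sizes are held
#' fixed but ids are randomly reassigned to clusters, and compares the
#' observed fraction of enriched clusters with the null distribution. The
#' empirical p-value uses the add-one correction
#' \eqn{(1 + \#\{rep \ge obs\}) / (1 + n_{reps})} and therefore never
#' returns 0.
#'
#' @param clusters observed labeling (named vector id -> cluster).
#' @param annotations as in [cluster_enrichment()].
#' @param n_reps number of randomized replicates (default 10000).
#' @param seed RNG seed.
#' @param alpha threshold passed through.
#' @return list: `observed`, `replicates` (numeric vector), `p_value`.
#' @export
enrichment_null <- function(clusters, annotations, n_reps = 10000L,
                            seed = 1L, alpha = 0.05) {
  observed <- cluster_enrichment(clusters, annotations, alpha)$fraction_enriched
  set.seed(seed)
  ids <- names(clusters)
  reps <- vapply(seq_len(n_reps), function(i) {
    perm <- stats::setNames(as.vector(clusters)[sample(length(ids))], ids)
    cluster_enrichment(perm, annotations, alpha)$fraction_enriched
  }, 0)
  list(observed = observed, replicates = reps,
       p_value = (1 + sum(reps >= observed)) / (1 + n_reps))
}

#' Intra vs exo membership distances with a Mann-Whitney test
#'
#' Compares the cosine distances between genes and the higher-order entities
#' (pathways, complexes) they belong to ("intra") against distances to
#' entities they are not associated with ("exo"). Embedded genes should sit
#' closer to their own pathways/complexes; significance via the two-sided
#' Mann-Whitney U test (exact when both samples have at most 20 values and
#' no ties).
#'
#' @param gene_emb,set_emb `embedding_set`s in the same latent space.
#' @param membership named list: gene id -> character vector of set ids
#'   (genes with no entry contribute only exo distances).
#' @return list: `intra_mean`, `exo_mean`, `U`, `p_value`, `n_intra`,
#'   `n_exo`.
#' @export
membership_distance_test <- function(gene_emb, set_emb, membership) {
  D <- suppressWarnings(cosine_distance(gene_emb$vectors, set_emb$vectors))
  member <- matrix(FALSE, nrow(D), ncol(D), dimnames = dimnames(D))
  for (g in intersect(names(membership), rownames(D))) {
    sets <- intersect(membership[[g]], colnames(D))
    member[g, sets] <- TRUE
  }
  intra <- D[member]
  exo <- D[!member]
  if (length(intra) == 0 || length(exo) == 0)
    stop_tf("need at least one intra and one exo distance")
  exact <- length(intra) <= 20 && length(exo) <= 20
  wt <- suppressWarnings(stats::wilcox.test(intra, exo, exact = exact,
                                            correct = !exact))
  list(intra_mean = mean(intra), exo_mean = mean(exo),
       U = unname(wt$statistic), p_value = wt$p.value,
       n_intra = length(intra), n_exo = length(exo))
}

#' AUROC and AUPRC of a scored binary ranking
#'
#' AUROC via the tie-corrected Mann-Whitney rank statistic; AUPRC by step
#' integration of the precision-recall curve where tied scores are treated
#' as one atomic threshold block (precision at each distinct threshold,
#' weighted by the recall gained in the block; no interpolation).
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical), same length.
#' @return list with `auroc` and `auprc`.
#' @export
ranking_metrics <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop_tf("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_tf("both classes must be present")
  r <- rank(scores)  # ties averaged: Mann-Whitney correction
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  blocks <- rle(s)$lengths
  end <- cumsum(blocks)
  tp <- cumsum(y)[end]
  fp <- end - tp
  prec <- tp / (tp + fp)
  recall <- tp / n1
  d_recall <- diff(c(0, recall))
  auprc <- sum(prec * d_recall)
  list(auroc = auroc, auprc = auprc)
}

#' Survival stratification by above/below-mean expression with a logrank test
#'
#' Splits a cohort at the mean of one gene's expression values ("higher" if
#' strictly above the mean, "lower" otherwise — a patient exactly at the mean
#' goes to the lower group) and compares survival between the two groups with
#' the standard logrank test.
#'
#' @param expression named numeric vector: patient -> expression of the gene.
#' @param surv data.frame with columns `patient`, `time`, `event`
#'   (1 = event/death, 0 = censored).
#' @return list: `groups` (named vector patient -> "higher"/"lower"),
#'   `n_higher`, `n_lower`, `chisq`, `p_value`, and `km` (a
#'   [survival::survfit()] object with per-group Kaplan-Meier curves).
#' @export
survival_split_logrank <- function(expression, surv) {
  stopifnot(all(c("patient", "time", "event") %in% names(surv)))
  expression <- expression[surv$patient]
  if (anyNA(expression)) stop_tf("expression missing for some patients")
  grp <- ifelse(expression > mean(expression), "higher", "lower")
  if (min(table(factor(grp, levels = c("higher", "lower")))) < 2)
    stop_tf("each stratum needs at least 2 patients")
  df <- data.frame(time = surv$time, event = surv$event, group = grp)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  list(groups = stats::setNames(grp, surv$patient),
       n_higher = sum(grp == "higher"), n_lower = sum(grp == "lower"),
       chisq = unname(sd_$chisq), p_value = p, km = km)
}
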