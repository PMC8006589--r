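make_emb <- function(M, family = "f", space = "s", normalized = FALSE) {
  structure(list(family = family, space = space, ids = rownames(M),
                 vectors = M, normalized = normalized),
            class = "embedding_set")
}

test_that("nearest-centroid macro-F1 matches hand-enumerated confusion counts", {
  # geometry where every entity is nearest its own class centroid
  C <- rbind(A = c(1, 0), B = c(0, 1))
  X <- rbind(p1 = c(0.9, 0.1), p2 = c(0.8, 0.05), p3 = c(0.1, 1), p4 = c(0, 0.7))
  truth <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "B")
  expect_equal(as.numeric(nearest_centroid_macro_f1(make_emb(X), make_emb(C),
                                                    truth)), 1)
  # predictions {A->A, A->B, B->B, B->B}: confusion counts by hand:
  # class A: tp=1 fp=0 fn=1 -> F1 = 2/3; class B: tp=2 fp=1 fn=0 -> F1 = 4/5
  X2 <- rbind(p1 = c(0.9, 0.1), p2 = c(0.1, 0.9),
              p3 = c(0.1, 1), p4 = c(0, 0.7))
  got <- nearest_centroid_macro_f1(make_emb(X2), make_emb(C), truth)
  expect_equal(as.numeric(got), mean(c(2 / 3, 4 / 5)))
  expect_identical(unname(attr(got, "predicted")), c("A", "B", "B", "B"))
  # adversarial: every prediction wrong over 2 classes -> 0
  truth_flip <- c(p1 = "B", p2 = "A", p3 = "A", p4 = "A")
  X3 <- rbind(p1 = c(1, 0), p2 = c(0, 1), p3 = c(0, 1), p4 = c(0, 1))
  expect_equal(as.numeric(nearest_centroid_macro_f1(make_emb(X3), make_emb(C),
                                                    truth_flip)), 0)
})

test_that("kNN classification matches a brute-force neighbour search", {
  set.seed(31)
  n_tr <- 30
  Xtr <- matrix(stats::runif(n_tr * 3), n_tr,
                dimnames = list(paste0("t", 1:n_tr), NULL))
  lab_tr <- stats::setNames(sample(c("u", "v", "w"), n_tr, TRUE),
                            rownames(Xtr))
  Xte <- matrix(stats::runif(8 * 3), 8, dimnames = list(paste0("q", 1:8), NULL))
  lab_te <- stats::setNames(sample(c("u", "v", "w"), 8, TRUE), rownames(Xte))
  for (k in c(1, 5, 10)) {
    got <- knn_macro_f1(make_emb(Xtr), lab_tr, make_emb(Xte), lab_te, k = k)
    # oracle: exhaustive cosine distances, explicit majority with min-label ties
    pred_oracle <- apply(Xte, 1, function(x) {
      d <- apply(Xtr, 1, function(y)
        1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
      nb <- lab_tr[names(sort(d))[seq_len(k)]]
      tab <- sort(table(nb), decreasing = TRUE)
      cands <- names(tab)[tab == max(tab)]
      sort(cands)[1]
    })
    expect_identical(unname(attr(got, "predicted")), unname(pred_oracle))
  }
  # a test point duplicating a training point in a pure neighbourhood
  Xtr2 <- rbind(matrix(rep(c(1, 0, 0), 5), 5, byrow = TRUE) +
                  matrix(stats::runif(15, 0, 0.01), 5),
                matrix(rep(c(0, 1, 0), 5), 5, byrow = TRUE) +
                  matrix(stats::runif(15, 0, 0.01), 5))
  rownames(Xtr2) <- paste0("t", 1:10)
  lab2 <- stats::setNames(rep(c("x", "y"), each = 5), rownames(Xtr2))
  Xte2 <- matrix(Xtr2[2, ], 1, dimnames = list("q", NULL))
  got2 <- knn_macro_f1(make_emb(Xtr2), lab2, make_emb(Xte2),
                       c(q = "x"), k = 5)
  expect_equal(as.numeric(got2), 1)
  expect_error(knn_macro_f1(make_emb(Xtr2), lab2, make_emb(Xte2),
                            c(q = "x"), k = 11), "exceeds")
})

test_that("cosine hierarchical clustering reproduces a naive linkage oracle", {
  # two orthogonal tight bundles split perfectly
  set.seed(7)
  A <- matrix(rep(c(1, 0), 6), 6, byrow = TRUE) + stats::runif(12, 0, 0.02)
  B <- matrix(rep(c(0, 1), 6), 6, byrow = TRUE) + stats::runif(12, 0, 0.02)
  X <- rbind(A, B)
  rownames(X) <- paste0("e", 1:12)
  cl <- cosine_hclust(make_emb(X), 2)
  expect_identical(length(unique(cl[1:6])), 1L)
  expect_identical(length(unique(cl[7:12])), 1L)
  expect_false(cl[1] == cl[7])
  # n clusters = n gives singletons
  cl_n <- cosine_hclust(make_emb(X), 12)
  expect_identical(length(unique(cl_n)), 12L)

  # merge heights of a 12-point fixture equal a hand-rolled O(n^3)
  # average-linkage agglomeration
  set.seed(8)
  Y <- matrix(stats::runif(36), 12, dimnames = list(paste0("p", 1:12), NULL))
  hc <- attr(cosine_hclust(make_emb(Y), 3), "hclust")
  D <- outer(seq_len(12), seq_len(12), Vectorize(function(i, j)
    1 - sum(Y[i, ] * Y[j, ]) / sqrt(sum(Y[i, ]^2) * sum(Y[j, ]^2))))
  groups <- as.list(seq_len(12))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      d <- mean(D[groups[[i]], groups[[j]], drop = FALSE])
      if (d < best[1]) best <- c(d, j, i)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  expect_equal(hc$height, heights, tolerance = 1e-10)
})

test_that("adjusted Rand index agrees with pair enumeration and mclust", {
  a <- c(x1 = 1, x2 = 1, x3 = 1, x4 = 2, x5 = 2, x6 = 3, x7 = 3, x8 = 3)
  b <- c(x1 = "p", x2 = "p", x3 = "q", x4 = "q", x5 = "q", x6 = "r",
         x7 = "r", x8 = "p")
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, rep(1, 8)), 0)
  # brute-force pair-counting oracle
  ids <- names(a)
  agree <- 0; n_pairs <- 0; s_a <- 0; s_b <- 0; s_ab <- 0
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    n_pairs <- n_pairs + 1
    s_a <- s_a + same_a; s_b <- s_b + same_b; s_ab <- s_ab + (same_a && same_b)
  }
  expected <- s_a * s_b / n_pairs
  ari_oracle <- unname((s_ab - expected) / ((s_a + s_b) / 2 - expected))
  expect_equal(adjusted_rand_index(a, b), ari_oracle, tolerance = 1e-12)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(a, b),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  # symmetry and invariance to label renaming
  expect_equal(adjusted_rand_index(b, a), adjusted_rand_index(a, b))
  b2 <- c(p = "K", q = "L", r = "M")[b]
  names(b2) <- names(b)
  expect_equal(adjusted_rand_index(a, b2), adjusted_rand_index(a, b))
})

test_that("hypergeometric enrichment matches the exact combinatorial sum", {
  # population 10, term of 4, cluster of 5 with overlap 3
  pop <- paste0("g", 1:10)
  clusters <- stats::setNames(rep(c("c1", "c2"), c(5, 5)), pop)
  term <- c("g1", "g2", "g3", "g6")  # overlap with c1 = 3
  enr <- cluster_enrichment(clusters, list(t1 = term), alpha = 0.05)
  p_direct <- sum(vapply(3:4, function(i)
    choose(4, i) * choose(6, 5 - i) / choose(10, 5), 0))
  row_c1 <- enr$table[enr$table$cluster == "c1" & enr$table$term == "t1", ]
  expect_equal(row_c1$p, p_direct, tolerance = 1e-10)
  expect_identical(row_c1$overlap, 3)

  # a cluster equal to a full term has the smallest p in its row
  cl2 <- stats::setNames(rep(c("c1", "c2", "c3"), c(4, 3, 3)), pop)
  terms <- list(exact = pop[1:4], other = pop[5:7], wide = pop[c(1, 5, 8)])
  enr2 <- cluster_enrichment(cl2, terms)
  t_c1 <- enr2$table[enr2$table$cluster == "c1", ]
  expect_identical(t_c1$term[which.min(t_c1$p)], "exact")

  # BH step-up on (0.01, 0.02, 0.03) with m = 3 -> all 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  bh_hand <- function(p) { # step-up formula written out
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / rev(seq_len(m))))[ro]
  }
  set.seed(12)
  praw <- stats::runif(25)
  expect_equal(stats::p.adjust(praw, "BH"), bh_hand(praw), tolerance = 1e-12)
  expect_true(all(enr2$table$p_adj >= enr2$table$p))
})

test_that("hypergeometric p equals the exact sum on larger random instances", {
  set.seed(5)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    K <- sample(3:(N / 2), 1)
    n <- sample(3:(N / 2), 1)
    k <- sample(0:min(K, n), 1)
    p_pkg <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_sum <- sum(vapply(k:min(K, n), function(i)
      exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)), 0))
    expect_equal(p_pkg, p_sum, tolerance = 1e-10)
  }
})

test_that("the permutation null behaves as an empirical p-value must", {
  set.seed(44)
  pop <- paste0("g", 1:60)
  modules <- split(pop, rep(1:6, each = 10))
  names(modules) <- paste0("m", 1:6)
  # strongly planted clustering: clusters are the modules themselves
  planted <- stats::setNames(rep(paste0("c", 1:6), each = 10), pop)
  nul <- enrichment_null(planted, modules, n_reps = 200, seed = 9)
  expect_equal(nul$observed, 1)
  expect_lte(nul$p_value, 1 / 201 + 0.02)
  expect_gte(nul$p_value, 1 / 201)  # add-one correction: never below
  # determinism
  nul2 <- enrichment_null(planted, modules, n_reps = 200, seed = 9)
  expect_identical(nul$replicates, nul2$replicates)
  # observed fraction 0 gives p = 1
  no_sig <- stats::setNames(sample(paste0("c", 1:6), 60, TRUE), pop)
  tiny_term <- list(t = pop[c(1, 11, 21, 31, 41, 51)])
  obs <- cluster_enrichment(no_sig, tiny_term)$fraction_enriched
  if (obs == 0) {
    nul3 <- enrichment_null(no_sig, tiny_term, n_reps = 50, seed = 2)
    expect_equal(nul3$p_value, 1)
  }
})

test_that("membership distances separate planted members and match exact MWU", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 1/3 — via embeddings placed
  # at controlled cosine distances from one reference set vector
  th <- function(d) acos(1 - d)
  ang <- th(c(0.1, 0.2, 0.3, 0.4))
  G <- rbind(g1 = c(cos(ang[1]), sin(ang[1])),
             g2 = c(cos(ang[2]), sin(ang[2])),
             g3 = c(cos(ang[3]), sin(ang[3])),
             g4 = c(cos(ang[4]), sin(ang[4])))
  S <- rbind(s1 = c(1, 0))
  res <- membership_distance_test(make_emb(G), make_emb(S),
                                  list(g1 = "s1", g2 = "s1"))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$n_intra, 2)
  expect_equal(res$n_exo, 2)
  expect_lt(res$intra_mean, res$exo_mean)

  # planted world: genes sit nearer their own pathway embedding
  g <- tiny_world(seed = 9)
  fr <- fit_collective(g$bundle, fit_config(g$bundle$space_dims,
                                            max_iter = 200, seed = 9))
  membership <- lapply(g$world$gene_module, function(m) m)
  res2 <- membership_distance_test(embeddings(fr, "genes"),
                                   embeddings(fr, "pathways"), membership)
  expect_lt(res2$intra_mean, res2$exo_mean)
  expect_lt(res2$p_value, 1e-6)
})

test_that("AUROC/AUPRC match pair-counting oracles, with and without ties", {
  expect_equal(ranking_metrics(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)),
               list(auroc = 1, auprc = 1))
  expect_equal(ranking_metrics(rep(0.4, 6), c(1, 0, 1, 0, 0, 1))$auroc, 0.5)
  expect_error(ranking_metrics(1:3, c(1, 1, 1)), "both classes")

  set.seed(17)
  for (i in 1:10) {
    n <- 12
    scores <- sample(c(0.1, 0.2, 0.2, 0.5, 0.7, 0.7, 0.7, round(runif(5), 1)))
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    got <- ranking_metrics(scores, labels)
    # O(n^2) oracle: (concordant + 0.5 * tied) / (n1 * n0)
    conc <- 0; tied <- 0
    for (a in which(labels == 1)) for (b in which(labels == 0)) {
      if (scores[a] > scores[b]) conc <- conc + 1
      else if (scores[a] == scores[b]) tied <- tied + 1
    }
    expect_equal(got$auroc, (conc + tied / 2) / (sum(labels) * sum(!labels)),
                 tolerance = 1e-12)
    # AUPRC oracle: walk distinct thresholds, accumulate precision * d(recall)
    thr <- sort(unique(scores), decreasing = TRUE)
    rec_prev <- 0; ap <- 0
    for (t in thr) {
      sel <- scores >= t
      prec <- sum(labels[sel]) / sum(sel)
      rec <- sum(labels[sel]) / sum(labels)
      ap <- ap + prec * (rec - rec_prev)
      rec_prev <- rec
    }
    expect_equal(got$auprc, ap, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(18)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(ranking_metrics(sc, lb)$auroc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("survival stratification splits at the mean and detects separation", {
  # identical survival in both groups: logrank statistic ~ 0
  surv <- data.frame(patient = paste0("p", 1:20),
                     time = rep(c(1, 2, 3, 4, 5), 4),
                     event = 1)
  expr_vals <- stats::setNames(rep(c(0, 1), 10), surv$patient)
  res <- survival_split_logrank(expr_vals, surv)
  expect_gt(res$p_value, 0.9)
  # boundary rule: value exactly at the mean goes to "lower"
  ev <- stats::setNames(c(rep(0, 8), rep(2, 8), rep(1, 4)), surv$patient)
  res_b <- survival_split_logrank(ev, surv)  # mean = 1: the four 1s go lower
  expect_identical(unname(res_b$groups["p20"]), "lower")
  expect_identical(res_b$n_lower, 12L)
  # non-overlapping event times, all events, n = 40 -> strongly significant
  surv2 <- data.frame(patient = paste0("q", 1:40),
                      time = c(1:20, 101:120), event = 1)
  ex2 <- stats::setNames(rep(c(10, 0), each = 20), surv2$patient)
  res2 <- survival_split_logrank(ex2, surv2)
  expect_lt(res2$p_value, 0.01)
  expect_identical(res2$n_higher, 20L)
  # degenerate stratum errors
  ex3 <- stats::setNames(c(100, rep(0, 39)), surv2$patient)
  expect_error(survival_split_logrank(ex3, surv2), "at least 2")
})
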