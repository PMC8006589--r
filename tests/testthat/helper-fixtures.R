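# Shared fixtures: tiny planted worlds, random typed bundles and the
# cancer-gene pair dataset used across link-prediction tests.

tiny_world <- function(seed = 1) {
  generate_world(world_params(
    n_cancers = 3, patients_per_cancer = 8, n_genes = 60, n_modules = 6,
    n_complexes = 5, n_drugs = 9, seed = seed))
}

# a random small bundle obeying all (kind, space) type rules; sizes and
# content vary with the seed
random_bundle <- function(seed) {
  set.seed(seed)
  n <- sample(4:9, 4, replace = TRUE)
  fams <- list(
    entity_family("famA", paste0("a", seq_len(n[1])), "s1"),
    entity_family("famB", paste0("b", seq_len(n[2])), "s1"),
    entity_family("famC", paste0("c", seq_len(n[3])), "s2"),
    entity_family("famD", paste0("d", seq_len(n[4])), "s3"))
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc), nr, nc)
  symm <- function(nr) { M <- rmat(nr, nr); (M + t(M)) / 2 }
  rels <- list(
    relation("ab", "famA", "famB", "NMF", rmat(n[1], n[2])),
    relation("ac", "famA", "famC", "NMTF", rmat(n[1], n[3])),
    relation("cc", "famC", "famC", "SNMTF", symm(n[3])),
    relation("dc", "famD", "famC", "NMTF", rmat(n[4], n[3])),
    relation("dd", "famD", "famD", "SNMTF", symm(n[4])))
  dims <- c(s1 = sample(2:3, 1), s2 = sample(2:3, 1), s3 = 2L)
  data_bundle(fams, rels, space_dims = pmin(dims, min(n)))
}

# bundle whose relations are exact products of planted rank-2 factors
planted_rank2_bundle <- function(seed) {
  set.seed(seed)
  n <- c(20, 5, 25, 8)
  G <- list(pat = matrix(runif(n[1] * 2), n[1]),
            can = matrix(runif(n[2] * 2), n[2]),
            gen = matrix(runif(n[3] * 2), n[3]),
            drg = matrix(runif(n[4] * 2), n[4]))
  S_exp <- matrix(runif(4), 2)
  S_ppi <- crossprod(matrix(runif(4), 2))
  S_dt <- matrix(runif(4), 2)
  fams <- list(entity_family("pat", sprintf("p%02d", 1:n[1]), "space1"),
               entity_family("can", sprintf("c%d", 1:n[2]), "space1"),
               entity_family("gen", sprintf("g%02d", 1:n[3]), "space2"),
               entity_family("drg", sprintf("d%02d", 1:n[4]), "space3"))
  rels <- list(
    relation("diag", "pat", "can", "NMF", G$pat %*% t(G$can)),
    relation("expr", "pat", "gen", "NMTF", G$pat %*% S_exp %*% t(G$gen)),
    relation("ppi", "gen", "gen", "SNMTF", G$gen %*% S_ppi %*% t(G$gen)),
    relation("dt", "drg", "gen", "NMTF", G$drg %*% S_dt %*% t(G$gen)))
  b <- data_bundle(fams, rels,
                   space_dims = c(space1 = 2, space2 = 2, space3 = 2))
  attr(b, "planted") <- list(G = G, S = list(S_exp, S_ppi, S_dt))
  b
}

# independent reimplementation of the model reconstruction, used as oracle
reconstruct_relation_for_test <- function(r, model) {
  Ga <- model$factors[[r$row_family]]
  Gb <- model$factors[[r$col_family]]
  if (r$kind == "NMF") Ga %*% t(Gb) else Ga %*% model$centrals[[r$name]] %*% t(Gb)
}

# the full candidate cancer x gene pair dataset labeled by planted truth
cancer_gene_dataset <- function(world, fit) {
  emb_c <- embeddings(fit, "cancers")
  emb_g <- embeddings(fit, "genes")
  pos <- planted_truth(world, "cancer-gene")
  pairs <- expand.grid(left = emb_c$ids, right = emb_g$ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lab <- as.integer(paste(pairs$left, pairs$right) %in%
                      paste(pos$left, pos$right))
  pair_features(emb_c, emb_g, pairs, labels = lab)
}

# labels a ranking data.frame against a planted positive pair table
label_ranking <- function(ranking, positives) {
  as.integer(paste(ranking$left, ranking$right) %in%
               paste(positives$left, positives$right))
}
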