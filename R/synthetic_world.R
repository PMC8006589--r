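#' Parameters of a synthetic multipartite world
#'
#' The generator emulates, at reduced scale, the structure of a pan-cancer
#' fusion input: cohorts of patients per cancer type, genes organized in
#' pathway-like modules, protein complexes nested in modules, a
#' planted-partition PPI network, drugs targeting modules, and per-cancer
#' driver genes that shape mutations, associations and drug response.
#'
#' Defaults define the standard small world used throughout the test-bench:
#' 10 cancers x 20 patients, 500 genes in 25 modules, 20 complexes and 50
#' drugs, with moderate expression noise.
#'
#' @param n_cancers number of cancer types.
#' @param patients_per_cancer cohort size per cancer.
#' @param n_genes,n_modules genes and pathway-like modules partitioning them.
#' @param n_complexes protein complexes (within-module gene subsets).
#' @param n_drugs drugs, each targeting one module.
#' @param active_modules_per_cancer modules switched on per cancer type.
#' @param noise_sd Gaussian noise sd on expression (truncated at 0).
#' @param mutation_rate background per-gene mutation probability.
#' @param driver_mutation_rate elevated rate for a cancer's driver genes in
#'   its own cohort.
#' @param driver_fraction fraction of a cancer's active-module genes planted
#'   as its drivers.
#' @param response_noise probability a response outcome is flipped.
#' @param expression_baseline,expression_boost baseline level and additive
#'   boost for genes in a patient's active modules.
#' @param ppi_within,ppi_between planted-partition edge probabilities.
#' @param seed RNG seed; the whole world is deterministic given it.
#' @return a `world_params` list.
#' @export
world_params <- function(n_cancers = 10L, patients_per_cancer = 20L,
                         n_genes = 500L, n_modules = 25L, n_complexes = 20L,
                         n_drugs = 50L, active_modules_per_cancer = 3L,
                         noise_sd = 0.1, mutation_rate = 0.01,
                         driver_mutation_rate = 0.3, driver_fraction = 0.2,
                         response_noise = 0.05,
                         expression_baseline = 1, expression_boost = 2,
                         ppi_within = 0.3, ppi_between = 0.01, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_modules <= p$n_genes, p$n_cancers >= 1,
            p$active_modules_per_cancer <= p$n_modules,
            p$driver_fraction > 0, p$driver_fraction < 1,
            p$noise_sd >= 0, p$mutation_rate >= 0, p$mutation_rate <= 1)
  structure(p, class = "world_params")
}

#' Generate a synthetic world with planted ground truth
#'
#' Deterministic given `params$seed`. Construction: genes are partitioned
#' near-equally into modules; complexes are random within-module subsets;
#' the PPI network is a planted-partition graph (dense within modules,
#' sparse between); each cancer activates a distinct module subset and its
#' drivers are sampled from the active modules; expression is baseline plus
#' an activation boost plus truncated Gaussian noise; mutations are
#' Bernoulli with an elevated rate for a cancer's drivers within its cohort;
#' each drug targets a random subset of one module and drug-drug similarity
#' is the Jaccard index of target sets; a cancer-drug association is planted
#' iff the drug's target module is an active module containing at least one
#' of the cancer's drivers; a patient's response to a drug is positive iff
#' the drug targets an active module of the patient's cancer, flipped with
#' small label noise. A survival table ties shorter survival to higher
#' expression of a designated prognostic driver gene.
#'
#' @param params a [world_params()].
#' @return list with `world` (a `planted_world`: all mechanisms and truths)
#'   and `bundle` (the corresponding 8-relation [data_bundle()]).
#' @export
generate_world <- function(params = world_params()) {
  set.seed(params$seed)
  n_pat <- params$n_cancers * params$patients_per_cancer
  cancers <- sprintf("CA%02d", seq_len(params$n_cancers))
  patients <- sprintf("P%04d", seq_len(n_pat))
  genes <- sprintf("G%04d", seq_len(params$n_genes))
  modules <- sprintf("MOD%02d", seq_len(params$n_modules))
  complexes <- sprintf("CPX%02d", seq_len(params$n_complexes))
  drugs <- sprintf("D%03d", seq_len(params$n_drugs))

  # near-equal random partition of genes into modules
  gene_module <- stats::setNames(
    sample(rep(modules, length.out = params$n_genes)), genes)
  module_genes <- split(genes, gene_module)[modules]

  # complexes: subsets of 3..8 genes within one module
  complex_genes <- stats::setNames(lapply(complexes, function(cx) {
    m <- sample(modules, 1)
    pool <- module_genes[[m]]
    sample(pool, min(length(pool), sample(3:8, 1)))
  }), complexes)

  # cancers activate distinct module subsets
  repeat {
    active <- lapply(seq_len(params$n_cancers), function(i)
      sort(sample(modules, params$active_modules_per_cancer)))
    if (!anyDuplicated(vapply(active, paste, "", collapse = ",")) ||
        choose(params$n_modules, params$active_modules_per_cancer) <
        params$n_cancers) break
  }
  names(active) <- cancers

  drivers <- stats::setNames(lapply(cancers, function(ca) {
    pool <- unlist(module_genes[active[[ca]]], use.names = FALSE)
    sort(sample(pool, max(1L, round(params$driver_fraction * length(pool)))))
  }), cancers)

  diagnosis_of <- stats::setNames(rep(cancers, each = params$patients_per_cancer),
                                  patients)
  # tissues are coarser than cancers: two cancer types share one tissue
  tissue_of_cancer <- stats::setNames(
    sprintf("TIS%02d", ceiling(seq_len(params$n_cancers) / 2)), cancers)
  tissue_of <- stats::setNames(tissue_of_cancer[diagnosis_of], patients)

  # relation matrices ------------------------------------------------------
  diagnosis <- matrix(0, n_pat, params$n_cancers,
                      dimnames = list(patients, cancers))
  diagnosis[cbind(patients, diagnosis_of)] <- 1

  active_gene <- vapply(cancers, function(ca)
    gene_module[genes] %in% active[[ca]], logical(params$n_genes))
  rownames(active_gene) <- genes

  expr <- matrix(params$expression_baseline, n_pat, params$n_genes,
                 dimnames = list(patients, genes))
  expr <- expr + params$expression_boost * t(active_gene[, diagnosis_of])
  expr <- expr + matrix(stats::rnorm(length(expr), sd = params$noise_sd),
                        nrow(expr))
  expr <- pmax(expr, 0)

  mut_p <- matrix(params$mutation_rate, n_pat, params$n_genes,
                  dimnames = list(patients, genes))
  for (ca in cancers)
    mut_p[diagnosis_of == ca, drivers[[ca]]] <- params$driver_mutation_rate
  mutation <- matrix(stats::rbinom(length(mut_p), 1, mut_p), n_pat,
                     dimnames = dimnames(mut_p))

  same_module <- outer(gene_module[genes], gene_module[genes], "==")
  p_edge <- ifelse(same_module, params$ppi_within, params$ppi_between)
  up <- upper.tri(p_edge)
  edges <- matrix(0, params$n_genes, params$n_genes,
                  dimnames = list(genes, genes))
  edges[up] <- stats::rbinom(sum(up), 1, p_edge[up])
  ppi <- edges + t(edges)

  gene_complex <- vapply(complexes, function(cx) genes %in% complex_genes[[cx]],
                         logical(params$n_genes))
  rownames(gene_complex) <- genes
  gene_pathway <- vapply(modules, function(m) gene_module[genes] == m,
                         logical(params$n_genes))
  rownames(gene_pathway) <- genes

  drug_module <- stats::setNames(sample(modules, params$n_drugs, replace = TRUE),
                                 drugs)
  drug_targets <- stats::setNames(lapply(drugs, function(d) {
    pool <- module_genes[[drug_module[[d]]]]
    n_t <- max(2L, round(stats::runif(1, 0.3, 0.7) * length(pool)))
    sort(sample(pool, min(n_t, length(pool))))
  }), drugs)
  drug_target <- vapply(seq_along(drugs), function(i)
    as.numeric(genes %in% drug_targets[[i]]), numeric(params$n_genes))
  drug_target <- t(drug_target)
  dimnames(drug_target) <- list(drugs, genes)

  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  drug_sim <- outer(seq_along(drugs), seq_along(drugs), Vectorize(function(i, j)
    jaccard(drug_targets[[i]], drug_targets[[j]])))
  dimnames(drug_sim) <- list(drugs, drugs)

  # planted association truths --------------------------------------------
  cancer_gene <- do.call(rbind, lapply(cancers, function(ca)
    data.frame(left = ca, right = drivers[[ca]], stringsAsFactors = FALSE)))
  cancer_pathway <- do.call(rbind, lapply(cancers, function(ca)
    data.frame(left = ca, right = active[[ca]], stringsAsFactors = FALSE)))
  cancer_drug <- do.call(rbind, lapply(cancers, function(ca) {
    hit <- vapply(drugs, function(d)
      drug_module[[d]] %in% active[[ca]] &&
        length(intersect(drug_targets[[d]], drivers[[ca]])) > 0, TRUE)
    if (!any(hit)) return(NULL)
    data.frame(left = ca, right = drugs[hit], stringsAsFactors = FALSE)
  }))

  # response mechanism: drug helps iff it targets an active module of the
  # patient's cancer; observed outcome flipped with small probability
  response_true <- function(pat, drg)
    as.integer(drug_module[[drg]] %in% active[[diagnosis_of[[pat]]]])

  # survival: higher expression of a prognostic driver -> shorter survival
  prognostic_gene <- drivers[[1]][1]
  hazard <- 0.02 * exp(0.8 * scale(expr[, prognostic_gene])[, 1])
  surv_time <- stats::rexp(n_pat, rate = hazard)
  cens_time <- stats::rexp(n_pat, rate = 0.01)
  survival <- data.frame(patient = patients,
                         time = pmin(surv_time, cens_time),
                         event = as.integer(surv_time <= cens_time),
                         stringsAsFactors = FALSE)

  families <- list(
    entity_family("patients", patients, "space1"),
    entity_family("cancers", cancers, "space1"),
    entity_family("genes", genes, "space2"),
    entity_family("pathways", modules, "space2"),
    entity_family("complexes", complexes, "space2"),
    entity_family("drugs", drugs, "space3"))
  relations <- list(
    relation("diagnosis", "patients", "cancers", "NMF", diagnosis),
    relation("expression", "patients", "genes", "NMTF", expr),
    relation("mutation", "patients", "genes", "NMTF", mutation),
    relation("ppi", "genes", "genes", "SNMTF", ppi),
    relation("gene_complex", "genes", "complexes", "NMF", gene_complex * 1),
    relation("gene_pathway", "genes", "pathways", "NMF", gene_pathway * 1),
    relation("drug_target", "drugs", "genes", "NMTF", drug_target),
    relation("drug_similarity", "drugs", "drugs", "SNMTF", drug_sim))
  # default dims: k1 = number of cancers, k2 capped by the smallest space-2
  # family (complexes), k3 modest relative to the drug count
  bundle <- data_bundle(families, relations,
                        space_dims = c(
                          space1 = min(params$n_cancers, n_pat),
                          space2 = min(params$n_modules, params$n_complexes),
                          space3 = min(params$n_drugs, 10L)))

  world <- structure(list(
    params = params,
    gene_module = gene_module,
    module_genes = module_genes,
    complex_genes = complex_genes,
    active_modules = active,
    drivers = drivers,
    diagnosis_of = diagnosis_of,
    tissue_of = tissue_of,
    drug_module = drug_module,
    drug_targets = drug_targets,
    cancer_gene = cancer_gene,
    cancer_pathway = cancer_pathway,
    cancer_drug = cancer_drug,
    response_true = response_true,
    prognostic_gene = prognostic_gene,
    survival = survival), class = "planted_world")

  list(world = world, bundle = bundle)
}

#' @export
print.planted_world <- function(x, ...) {
  p <- x$params
  cat("<planted_world> ", p$n_cancers, " cancers x ", p$patients_per_cancer,
      " patients, ", p$n_genes, " genes / ", p$n_modules, " modules, ",
      p$n_complexes, " complexes, ", p$n_drugs, " drugs (seed ", p$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Ground-truth labeled sets from a planted world
#'
#' @param world a `planted_world`.
#' @param task `"cancer-gene"`, `"cancer-pathway"`, `"cancer-drug"` return a
#'   data.frame of positive (left, right) pairs consistent with the planted
#'   mechanism; `"response"` returns sampled (patient, drug, response)
#'   records with the mechanism's noisy outcomes, pre-filtered to drugs with
#'   both outcome classes.
#' @param n_per_patient for `"response"`: drugs sampled per patient.
#' @param seed RNG seed for response sampling/noise.
#' @return data.frame.
#' @export
planted_truth <- function(world, task = c("cancer-gene", "cancer-pathway",
                                          "cancer-drug", "response"),
                          n_per_patient = 10L, seed = 1L) {
  task <- match.arg(task)
  if (task == "cancer-gene") return(world$cancer_gene)
  if (task == "cancer-pathway") return(world$cancer_pathway)
  if (task == "cancer-drug") return(world$cancer_drug)
  set.seed(seed)
  patients <- names(world$diagnosis_of)
  drugs <- names(world$drug_module)
  recs <- do.call(rbind, lapply(patients, function(p) {
    ds <- sample(drugs, min(n_per_patient, length(drugs)))
    data.frame(patient = p, drug = ds,
               response = vapply(ds, function(d) world$response_true(p, d), 0L),
               stringsAsFactors = FALSE)
  }))
  flip <- stats::runif(nrow(recs)) < world$params$response_noise
  recs$response <- ifelse(flip, 1L - recs$response, recs$response)
  # drugs with a single observed outcome class are excluded upstream
  keep_drug <- names(which(vapply(split(recs$response, recs$drug),
                                  function(x) length(unique(x)) == 2, TRUE)))
  recs <- recs[recs$drug %in% keep_drug, ]
  rownames(recs) <- NULL
  recs
}

#' Write a world's bundle and truths to plain-text files
#'
#' Emits the eight relation TSVs plus a bundle YAML config, GMT annotations
#' (modules and complexes), association truth TSVs, diagnosis/tissue labels
#' and the survival table — the on-disk layout the loader and CLI consume.
#'
#' @param generated output of [generate_world()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generated$bundle; world <- generated$world
  rel_cfg <- lapply(bundle$relations, function(r) {
    fn <- paste0(r$name, ".tsv")
    write_labeled_matrix(r$matrix, file.path(dir, fn))
    list(name = r$name, kind = r$kind, row_family = r$row_family,
         col_family = r$col_family, file = fn)
  })
  cfg <- list(
    dims = as.list(bundle$space_dims),
    families = lapply(bundle$families, function(f)
      list(name = f$name, space = f$space)),
    relations = unname(rel_cfg))
  yaml::write_yaml(cfg, file.path(dir, "bundle.yaml"))
  write_gmt(world$module_genes, file.path(dir, "modules.gmt"))
  write_gmt(world$complex_genes, file.path(dir, "complexes.gmt"))
  for (task in c("cancer-gene", "cancer-pathway", "cancer-drug"))
    utils::write.table(planted_truth(world, task),
                       file.path(dir, paste0(gsub("-", "_", task), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  labels <- data.frame(patient = names(world$diagnosis_of),
                       diagnosis = unname(world$diagnosis_of),
                       tissue = unname(world$tissue_of))
  utils::write.table(labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
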