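#' Specification of a synthetic two-class dataset
#'
#' Describes a planted-structure expression matrix emulating the
#' small-sample / many-gene regime of two-class microarray studies:
#' class-independent Gaussian background, a block of informative genes
#' with a mean shift between classes, and groups of near-duplicate genes
#' copied from source genes, plus a matching toy ontology in which each
#' redundancy group shares a leaf term.
#'
#' Defaults state the regime used throughout the test suite: 1000 genes,
#' 20 + 20 samples, 20 informative genes at effect size 2 (in within-class
#' SD units), 5 redundancy groups of 5 near-copies each with copy noise SD
#' 0.3 (copy-to-source correlation about 0.96).
#'
#' @param n_genes total number of genes (background + informative + copies).
#' @param n_samples_per_class samples per class.
#' @param n_informative genes with a planted class-mean shift.
#' @param effect_size mean shift, in within-class SD units.
#' @param n_redundant_groups number of redundancy groups; each group is one
#'   source gene (taken from the informative block) plus `n_copies` copies.
#' @param n_copies near-duplicate copies per group.
#' @param copy_noise_sd SD of the Gaussian noise added to each copy.
#' @param ontology_depth,ontology_branching shape of the balanced `is_a`
#'   tree used by [generate_ontology()].
#' @param unannotated_fraction fraction of genes left out of the annotation
#'   map (exercises the expression-only fallback).
#' @param raw_intensity emit lognormal raw-scale intensities (for testing
#'   [preprocess()]) instead of post-preprocessing-scale values.
#' @param seed integer; fixes all randomness.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L, n_samples_per_class = 20L,
                           n_informative = 20L, effect_size = 2.0,
                           n_redundant_groups = 5L, n_copies = 5L,
                           copy_noise_sd = 0.3,
                           ontology_depth = 3L, ontology_branching = 3L,
                           unannotated_fraction = 0.2,
                           raw_intensity = FALSE, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_class = as.integer(n_samples_per_class),
               n_informative = as.integer(n_informative),
               effect_size = effect_size,
               n_redundant_groups = as.integer(n_redundant_groups),
               n_copies = as.integer(n_copies),
               copy_noise_sd = copy_noise_sd,
               ontology_depth = as.integer(ontology_depth),
               ontology_branching = as.integer(ontology_branching),
               unannotated_fraction = unannotated_fraction,
               raw_intensity = raw_intensity,
               seed = as.integer(seed))
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  if (spec$n_redundant_groups > spec$n_informative && spec$n_redundant_groups > 0)
    stop("need at least one informative source gene per redundancy group")
  n_special <- spec$n_informative + spec$n_redundant_groups * spec$n_copies
  if (n_special > spec$n_genes)
    stop("n_informative + total copies exceeds n_genes")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Background genes are iid standard Gaussian across samples; informative
#' genes add `effect_size` to the positive-class samples; each redundancy
#' group's copies equal their source gene plus Gaussian noise of SD
#' `copy_noise_sd`.  Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expr` (a [gene_expr()], labels normal/tumor) and
#'   `truth` (informative gene ids, redundancy group membership).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_s <- 2L * spec$n_samples_per_class
    labels <- rep(c("normal", "tumor"), each = spec$n_samples_per_class)
    gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
    v <- matrix(rnorm(spec$n_genes * n_s), spec$n_genes, n_s,
                dimnames = list(gene_ids,
                                sprintf("s%02d", seq_len(n_s))))
    informative <- gene_ids[seq_len(spec$n_informative)]
    v[informative, labels == "tumor"] <-
      v[informative, labels == "tumor"] + spec$effect_size

    groups <- list()
    if (spec$n_redundant_groups > 0 && spec$n_copies > 0) {
      copy_start <- spec$n_informative
      for (g in seq_len(spec$n_redundant_groups)) {
        src <- gene_ids[g]           # sources are informative genes
        copies <- gene_ids[copy_start + (g - 1L) * spec$n_copies +
                             seq_len(spec$n_copies)]
        for (cp in copies)
          v[cp, ] <- v[src, ] + rnorm(n_s, sd = spec$copy_noise_sd)
        groups[[paste0("group", g)]] <- c(src, copies)
      }
    }
    if (spec$raw_intensity) v <- exp(v)   # lognormal raw intensities
    list(expr = gene_expr(v, labels, positive_class = "tumor"),
         truth = list(informative = informative, groups = groups))
  })
}

#' Generate a toy ontology and annotations matching a synthetic dataset
#'
#' Builds a balanced `is_a` tree of the requested depth and branching (all
#' in one namespace, BP).  Annotation rules mirror the planted redundancy
#' structure: all members of a redundancy group share one leaf term (so
#' within-group semantic similarity is 1), remaining genes are scattered
#' across the other leaves, and `unannotated_fraction` of the scattered
#' genes carry no annotation at all.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `truth` element of [generate_expression()] (optional;
#'   regenerated from `spec` if missing).
#' @return list with `dag` ([ontology_dag()]), `ann` (annotation list) and
#'   `ic` (the [information_content()] table for the generated corpus).
#' @export
generate_ontology <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$ontology_depth < 2L || spec$ontology_branching < 2L)
    stop("ontology_depth and ontology_branching must both be >= 2")
  if (is.null(truth)) truth <- generate_expression(spec)$truth

  b <- spec$ontology_branching; d <- spec$ontology_depth
  ids <- "T0"; parents <- character(); children <- list(T0 = character())
  level <- "T0"; counter <- 0L
  edges <- NULL
  for (lev in seq_len(d)) {
    nxt <- character()
    for (p in level) {
      for (k in seq_len(b)) {
        counter <- counter + 1L
        id <- sprintf("T%04d", counter)
        ids <- c(ids, id)
        edges <- rbind(edges, data.frame(child = id, parent = p,
                                         stringsAsFactors = FALSE))
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  leaves <- level
  terms <- data.frame(id = ids, name = paste("synthetic term", ids),
                      namespace = "BP", stringsAsFactors = FALSE)
  dag <- ontology_dag(terms, edges)

  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  group_genes <- unlist(truth$groups, use.names = FALSE)
  n_groups <- length(truth$groups)
  if (n_groups > length(leaves))
    stop("not enough leaf terms for the redundancy groups")

  ann <- list()
  with_seed(spec$seed + 104729L, {   # independent stream from the matrix
    group_leaves <- leaves[seq_len(n_groups)]
    for (g in seq_len(n_groups))
      for (gene in truth$groups[[g]]) ann[[gene]] <- group_leaves[g]
    scatter_leaves <- if (n_groups < length(leaves))
      leaves[(n_groups + 1L):length(leaves)] else leaves
    others <- setdiff(gene_ids, group_genes)
    annotate <- runif(length(others)) >= spec$unannotated_fraction
    picked <- sample(scatter_leaves, sum(annotate), replace = TRUE)
    for (i in seq_along(which(annotate)))
      ann[[others[which(annotate)[i]]]] <- picked[i]
  })
  if (length(ann) == 0) {
    ic <- NULL
  } else {
    ic <- information_content(concept_frequency(dag, ann))
  }
  list(dag = dag, ann = ann, ic = ic)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `expr.tsv`, `labels.tsv`, `go.obo`, `ann.tsv` and `truth.json` in
#' the formats the readers of this package accept.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data <- generate_expression(spec)
  go <- generate_ontology(spec, data$truth)
  expr <- data$expr
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = colnames(expr$values),
                         label = as.character(expr$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_obo(go$dag, file.path(dir, "go.obo"))
  ann_tab <- data.frame(gene = rep(names(go$ann),
                                   lengths(go$ann)),
                        term = unlist(go$ann, use.names = FALSE))
  write.table(ann_tab, file.path(dir, "ann.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(data$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' Bundled deterministic fixtures
#'
#' Small instances reused across the test suite:
#' * `tiny_separable` — 50 genes x 20 samples, 3 informative at effect 3.
#' * `duplicates_heavy` — 60 genes x 24 samples, 5 groups x 5 near-copies.
#' * `pure_noise` — 500 genes, 15 + 15 samples, no signal.
#' * `go_fixture` — a 5-term multi-parent DAG with 4 annotated genes, for
#'   semantic-similarity oracle tests.
#'
#' @param name fixture name.
#' @param seed overrides the fixture's default seed.
#' @return `go_fixture`: a list `dag`, `ann`, `ic`; otherwise the
#'   [generate_expression()] output, with a `go` element where relevant.
#' @export
make_fixture <- function(name = c("tiny_separable", "duplicates_heavy",
                                  "pure_noise", "go_fixture"),
                         seed = NULL) {
  name <- match.arg(name)
  if (name == "go_fixture") {
    # A (root) <- B, C; D is_a B; E is_a B and C (multi-parent)
    terms <- data.frame(id = c("A", "B", "C", "D", "E"),
                        name = paste("term", c("A", "B", "C", "D", "E")),
                        namespace = "BP", stringsAsFactors = FALSE)
    edges <- data.frame(child = c("B", "C", "D", "E", "E"),
                        parent = c("A", "A", "B", "B", "C"),
                        stringsAsFactors = FALSE)
    dag <- ontology_dag(terms, edges)
    ann <- list(g1 = "D", g2 = "E", g3 = c("B", "C"), g4 = "C")
    ic <- information_content(concept_frequency(dag, ann))
    return(list(dag = dag, ann = ann, ic = ic))
  }
  spec <- switch(name,
    tiny_separable = synthetic_spec(n_genes = 50L, n_samples_per_class = 10L,
                                    n_informative = 3L, effect_size = 3.0,
                                    n_redundant_groups = 0L, n_copies = 0L,
                                    ontology_depth = 2L,
                                    ontology_branching = 2L,
                                    seed = seed %||% 7L),
    duplicates_heavy = synthetic_spec(n_genes = 60L,
                                      n_samples_per_class = 12L,
                                      n_informative = 10L, effect_size = 2.0,
                                      n_redundant_groups = 5L, n_copies = 5L,
                                      copy_noise_sd = 0.3,
                                      ontology_depth = 3L,
                                      ontology_branching = 2L,
                                      unannotated_fraction = 0.2,
                                      seed = seed %||% 11L),
    pure_noise = synthetic_spec(n_genes = 500L, n_samples_per_class = 15L,
                                n_informative = 0L, effect_size = 0,
                                n_redundant_groups = 0L, n_copies = 0L,
                                seed = seed %||% 3L))
  out <- generate_expression(spec)
  out$spec <- spec
  if (name == "duplicates_heavy")
    out$go <- generate_ontology(spec, out$truth)
  out
}
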