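#' Expression similarity of two genes
#'
#' Pearson correlation of the two genes' expression profiles across
#' samples.  By default the absolute value is returned so that similarity
#' is comparable with the \[0, 1\] redundancy threshold (strong negative
#' correlation is still redundancy); `pearson = "raw"` returns the signed
#' coefficient for strict-fidelity experiments.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @param pearson `"abs"` (default) or `"raw"`.
#' @return similarity in \[0, 1\] (or \[-1, 1\] under `"raw"`).
#' @export
expression_similarity <- function(x, y, pearson = c("abs", "raw")) {
  pearson <- match.arg(pearson)
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance vector")
  r <- cor(x, y)
  if (pearson == "abs") abs(r) else r
}

#' Combined expression + semantic similarity of two genes
#'
#' The average of Pearson expression similarity and Lin gene-level semantic
#' similarity.  When the semantic part is undefined (gene missing from the
#' annotation corpus — the ontology is incomplete), the expression
#' similarity alone is used and the provenance is recorded as
#' `"expression_only"`.
#'
#' @param g1,g2 gene ids present in `expr`.
#' @param expr a [gene_expr()] object.
#' @param go `NULL`, or a list with elements `dag`, `ann`, `ic` (see
#'   [build_similarity()]).
#' @inheritParams expression_similarity
#' @inheritParams gene_semantic_similarity
#' @return a list with `similarity` and `provenance`
#'   (`"combined"` or `"expression_only"`).
#' @export
combined_similarity <- function(g1, g2, expr, go = NULL,
                                pearson = c("abs", "raw"),
                                aggregation = "bma") {
  pearson <- match.arg(pearson)
  stopifnot(inherits(expr, "gene_expr"))
  i <- match(c(g1, g2), rownames(expr$values))
  if (anyNA(i)) stop("gene not in expression matrix")
  s_exp <- expression_similarity(expr$values[i[1L], ], expr$values[i[2L], ],
                                 pearson = pearson)
  s_sem <- if (is.null(go)) NA_real_ else
    gene_semantic_similarity(g1, g2, go$ann, go$dag, go$ic,
                             aggregation = aggregation)
  if (is.na(s_sem))
    list(similarity = s_exp, provenance = "expression_only")
  else
    list(similarity = (s_exp + s_sem) / 2, provenance = "combined")
}

# semantic similarity matrix over genes, computed per unique annotation
# signature (genes sharing the same usable term set get one computation)
semantic_matrix <- function(genes, go, aggregation = "bma") {
  n <- length(genes)
  out <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  ic <- go$ic
  usable <- lapply(genes, function(g) {
    t <- go$ann[[g]]
    if (is.null(t)) return(character())
    sort(t[!is.na(ic$ic[match(t, ic$term)])])
  })
  sig <- vapply(usable, paste, character(1), collapse = "|")
  has <- nzchar(sig)
  if (!any(has)) return(out)
  usig <- unique(sig[has])
  uterms <- lapply(usig, function(s) strsplit(s, "|", fixed = TRUE)[[1L]])
  tm <- term_similarity_matrix(go$dag, ic,
                               unique(unlist(uterms, use.names = FALSE)))
  m <- length(usig)
  ssim <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      v <- aggregate_pair_sims(tm[uterms[[a]], uterms[[b]], drop = FALSE],
                               aggregation)
      ssim[a, b] <- ssim[b, a] <- v
    }
  }
  idx <- match(sig, usig)            # NA for unannotated genes
  hi <- which(has)
  out[hi, hi] <- ssim[idx[hi], idx[hi], drop = FALSE]
  out
}

#' Build a pairwise similarity model for a set of genes
#'
#' Materializes the dense symmetric similarity matrix used by
#' [greedy_reduce()], together with a per-pair provenance matrix recording
#' whether the value combined expression and semantic similarity or fell
#' back to expression alone.
#'
#' @param expr a [gene_expr()] object.
#' @param genes gene ids to include (default: all genes in `expr`).
#' @param go `NULL` for expression-only similarity, or
#'   `list(dag = , ann = , ic = )` with the ontology, annotation map and
#'   information-content table.
#' @param mode `"combined"` (default; averages with the semantic part when
#'   available), `"expression"` (ignore the ontology) or `"semantic"`
#'   (semantic part only; unannotated pairs fall back to expression).
#' @inheritParams expression_similarity
#' @inheritParams gene_semantic_similarity
#' @return an object of class `similarity_model`: list with `S` (matrix,
#'   unit diagonal), `provenance` (character matrix), `mode`, `pearson`,
#'   `aggregation`.
#' @export
build_similarity <- function(expr, genes = NULL, go = NULL,
                             mode = c("combined", "expression", "semantic"),
                             pearson = c("abs", "raw"),
                             aggregation = "bma") {
  mode <- match.arg(mode); pearson <- match.arg(pearson)
  stopifnot(inherits(expr, "gene_expr"))
  if (is.null(genes)) genes <- rownames(expr$values)
  i <- match(genes, rownames(expr$values))
  if (anyNA(i)) stop("gene not in expression matrix: ",
                     paste(genes[is.na(i)], collapse = ", "))
  x <- t(expr$values[i, , drop = FALSE])    # samples x genes
  if (any(apply(x, 2L, sd) == 0)) stop("zero-variance gene")
  r <- cor(x)
  s_exp <- if (pearson == "abs") abs(r) else r

  if (mode == "expression" || is.null(go)) {
    S <- s_exp
    prov <- matrix("expression_only", length(genes), length(genes))
  } else {
    s_sem <- semantic_matrix(genes, go, aggregation)
    def <- !is.na(s_sem)
    S <- ifelse(def,
                if (mode == "semantic") s_sem else (s_exp + s_sem) / 2,
                s_exp)
    prov <- ifelse(def, "combined", "expression_only")
  }
  dimnames(S) <- list(genes, genes)
  dimnames(prov) <- list(genes, genes)
  diag(S) <- 1
  structure(list(S = S, provenance = prov, mode = mode, pearson = pearson,
                 aggregation = aggregation),
            class = "similarity_model")
}

#' @export
print.similarity_model <- function(x, ...) {
  cat(sprintf("similarity_model: %d genes, mode=%s, pearson=%s, %d/%d pairs combined\n",
              nrow(x$S), x$mode, x$pearson,
              sum(x$provenance == "combined" & upper.tri(x$S)),
              sum(upper.tri(x$S))))
  invisible(x)
}

#' Greedy redundancy reduction
#'
#' Walks the ranked gene list from the most discriminative gene down:
#' the current head is kept, and every later gene whose similarity to the
#' kept head is `>= ts` is deleted.  The output preserves input order and
#' every kept pair has similarity `< ts`.
#'
#' @param ranked a `gene_ranking` data.frame (or character vector of gene
#'   ids), most discriminative first.
#' @param ts similarity threshold in \[0, 1\].
#' @param sim a `similarity_model` from [build_similarity()] covering the
#'   ranked genes (a plain similarity matrix is also accepted).
#' @return the reduced ranking, same type as the input.
#' @export
greedy_reduce <- function(ranked, ts, sim) {
  if (!is.numeric(ts) || length(ts) != 1L || ts < 0 || ts > 1)
    stop("ts must be a single value in [0, 1]")
  genes <- if (is.data.frame(ranked)) ranked$gene else as.character(ranked)
  S <- if (inherits(sim, "similarity_model")) sim$S else sim
  if (length(genes) == 0)
    return(if (is.data.frame(ranked)) ranked else character())
  if (!all(genes %in% rownames(S)))
    stop("similarity model does not cover all ranked genes")
  alive <- rep(TRUE, length(genes))
  i <- 1L
  while (i <= length(genes)) {
    if (alive[i]) {
      later <- which(alive & seq_along(genes) > i)
      if (length(later) > 0) {
        drop <- later[S[genes[i], genes[later]] >= ts]
        alive[drop] <- FALSE
      }
    }
    i <- i + 1L
  }
  if (is.data.frame(ranked)) ranked[alive, , drop = FALSE] else genes[alive]
}

#' Tune the redundancy threshold on a grid
#'
#' Evaluates each candidate threshold by external cross-validated accuracy
#' of a pipeline variant (selection re-run inside every training fold, so
#' the per-threshold accuracies are unbiased) and returns the grid value
#' with the highest mean accuracy, ties broken toward the larger threshold
#' (fewer removals).  The default grid is 0.10 to 0.95 in steps of 0.05
#' (18 values).
#'
#' @param expr a preprocessed [gene_expr()] object.
#' @param variant pipeline variant name (see [run_variant()]).
#' @param config pipeline configuration list (see [pipeline_config()]).
#' @param grid candidate thresholds.
#' @param folds,seed cross-validation controls.
#' @return list with `best_ts` and `accuracy` (named per-threshold means).
#' @export
tune_threshold <- function(expr, variant = "fisher_rg", config = pipeline_config(),
                           grid = seq(0.10, 0.95, by = 0.05),
                           folds = 10L, seed = 1L) {
  if (length(grid) < 1L) stop("empty threshold grid")
  acc <- vapply(grid, function(ts) {
    cfg <- config; cfg$ts <- ts
    rep <- external_cv(expr, variant, config = cfg, folds = folds,
                       seed = seed)
    rep$aggregate["accuracy"]
  }, numeric(1))
  names(acc) <- sprintf("%.2f", grid)
  best <- max(acc)
  best_ts <- max(grid[acc == best])  # ties -> larger ts
  list(best_ts = best_ts, accuracy = acc)
}
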