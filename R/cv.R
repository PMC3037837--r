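#' Confusion-matrix metrics
#'
#' Accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP).  A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts named numeric vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative TP/TN/FP/FN")
  tp <- counts["TP"]; tn <- counts["TN"]; fp <- counts["FP"]; fn <- counts["FN"]
  total <- tp + tn + fp + fn
  c(accuracy = if (total > 0) unname((tp + tn) / total) else NA_real_,
    sensitivity = if (tp + fn > 0) unname(tp / (tp + fn)) else NA_real_,
    specificity = if (tn + fp > 0) unname(tn / (tn + fp)) else NA_real_)
}

#' Deterministic (stratified) fold assignment
#'
#' Partitions samples into `folds` test sets as a deterministic function of
#' the labels, fold count and seed.  Stratified by default so that both
#' classes appear in (nearly) every fold even at small sample sizes.
#'
#' @param labels factor of sample classes.
#' @param folds number of folds.
#' @param seed integer seed.
#' @param stratified keep class proportions per fold (default) or plain
#'   random partition.
#' @return list of integer vectors of test-sample indices; every sample
#'   appears in exactly one fold.
#' @export
make_folds <- function(labels, folds = 10L, seed = 1L, stratified = TRUE) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (folds < 2L || folds > n) stop("folds must be in [2, n_samples]")
  if (folds > min(table(labels)))
    warning("more folds than the smallest class size")
  assign <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        assign[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      assign[sample(n)] <- rep_len(seq_len(folds), n)
    }
  })
  lapply(seq_len(folds), function(f) which(assign == f))
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the selection pipeline with the
#' package defaults: Fisher filter size `filter_k = 500`, redundancy
#' threshold `ts = 0.8`, absolute-Pearson expression similarity, best-match
#' average semantic aggregation, SVM cost `C = 1`, RFE step `"auto"`
#' (bottom half while > 100 features, then single elimination), 5 internal
#' folds for subset selection.
#'
#' @param filter_k genes kept by the Fisher filter.
#' @param ts redundancy threshold in \[0, 1\].
#' @param pearson `"abs"` or `"raw"`.
#' @param aggregation `"bma"`, `"max"` or `"avg"`.
#' @param svm_c soft-margin cost.
#' @param rfe_step see [rfe_ranking()].
#' @param inner_folds internal CV folds for [select_best_subset()].
#' @param go `NULL` or `list(dag, ann, ic)` enabling GO-aware similarity.
#' @param stratified stratified outer folds.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_k = 500L, ts = 0.8,
                            pearson = c("abs", "raw"),
                            aggregation = c("bma", "max", "avg"),
                            svm_c = 1, rfe_step = "auto",
                            inner_folds = 5L, go = NULL,
                            stratified = TRUE) {
  structure(list(filter_k = filter_k, ts = ts,
                 pearson = match.arg(pearson),
                 aggregation = match.arg(aggregation),
                 svm_c = svm_c, rfe_step = rfe_step,
                 inner_folds = inner_folds, go = go,
                 stratified = stratified),
            class = "pipeline_config")
}

#' Pipeline variants
#'
#' Registry of stage compositions used in the method comparison:
#' `none` (no selection), `fisher` (filter only), `svmrfe` (RFE + best
#' subset), `fisher_r` / `svmrfe_r` (plus expression-only greedy redundancy
#' reduction), `fisher_rg` / `svmrfe_rg` (redundancy reduction with GO
#' semantic similarity), and the stacked `fisher_svmrfe`,
#' `fisher_r_svmrfe`, `fisher_rg_svmrfe` — the last being the full proposed
#' pipeline.
#'
#' @return character vector of known variant names.
#' @export
variant_registry <- function() {
  c("none", "fisher", "svmrfe", "fisher_r", "fisher_rg",
    "svmrfe_r", "svmrfe_rg", "fisher_svmrfe",
    "fisher_r_svmrfe", "fisher_rg_svmrfe")
}

# run the selection stages of `variant` on (training) data only;
# returns the selected gene ids
select_genes <- function(expr, variant, config, seed = 1L) {
  if (!variant %in% variant_registry())
    stop("unknown variant: ", variant)
  genes <- rownames(expr$values)
  if (variant == "none") return(genes)

  parts <- strsplit(variant, "_", fixed = TRUE)[[1L]]
  lead <- parts[1L]                                  # fisher | svmrfe
  redund <- intersect(parts, c("r", "rg"))
  final_rfe <- length(parts) > 1L && parts[length(parts)] == "svmrfe"

  X <- t(expr$values)                                # samples x genes
  y <- svm_labels(expr)

  ranked <- if (lead == "fisher") {
    rank_genes(expr, k = config$filter_k)$gene
  } else {
    ord <- rfe_ranking(X, y, step = config$rfe_step, C = config$svm_c)
    rev(ord)[seq_len(min(config$filter_k, length(ord)))]
  }

  if (length(redund) == 1L) {
    go <- if (redund == "rg") config$go else NULL
    sim <- build_similarity(expr, genes = ranked, go = go,
                            mode = if (redund == "rg") "combined" else "expression",
                            pearson = config$pearson,
                            aggregation = config$aggregation)
    ranked <- greedy_reduce(ranked, ts = config$ts, sim = sim)
  }

  if (lead == "svmrfe" && !final_rfe) {
    # svmrfe / svmrfe_r / svmrfe_rg: the RFE stage also picks the subset
    if (variant == "svmrfe") {
      ord <- rfe_ranking(X, y, step = config$rfe_step, C = config$svm_c)
      return(as.character(select_best_subset(ord, X, y,
                                             inner_folds = config$inner_folds,
                                             C = config$svm_c, seed = seed)))
    }
    return(ranked)
  }
  if (!final_rfe) return(ranked)

  Xr <- X[, ranked, drop = FALSE]
  ord <- rfe_ranking(Xr, y, step = config$rfe_step, C = config$svm_c)
  as.character(select_best_subset(ord, Xr, y,
                                  inner_folds = config$inner_folds,
                                  C = config$svm_c, seed = seed))
}

fit_and_score <- function(expr_train, expr_test, genes, C) {
  Xtr <- t(expr_train$values[genes, , drop = FALSE])
  Xte <- t(expr_test$values[genes, , drop = FALSE])
  ytr <- svm_labels(expr_train); yte <- svm_labels(expr_test)
  model <- train_linear_svm(Xtr, ytr, C = C)
  pred <- predict(model, Xte)
  c(TP = sum(pred == 1 & yte == 1), TN = sum(pred == -1 & yte == -1),
    FP = sum(pred == 1 & yte == -1), FN = sum(pred == -1 & yte == 1))
}

cv_report <- function(fold_results, fold_assign, seed, variant, config,
                      protocol) {
  agg <- sapply(fold_results, function(fr) metrics(fr$confusion))
  aggregate <- rowMeans(agg, na.rm = TRUE)    # undefined folds excluded
  if (anyNA(agg)) warning("undefined per-fold metric excluded from the mean")
  structure(list(folds = fold_results, aggregate = aggregate,
                 fold_assignment = fold_assign, seed = seed,
                 variant = variant, protocol = protocol,
                 config = config[setdiff(names(config), "go")]),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s, variant=%s, %d folds, seed=%d)\n",
              x$protocol, x$variant, length(x$folds), x$seed))
  cat(sprintf("  accuracy=%.3f sensitivity=%.3f specificity=%.3f\n",
              x$aggregate["accuracy"], x$aggregate["sensitivity"],
              x$aggregate["specificity"]))
  cat(sprintf("  genes selected per fold: %s\n",
              paste(vapply(x$folds, function(f) length(f$selected),
                           integer(1)), collapse = ", ")))
  invisible(x)
}

#' External cross-validation of a selection pipeline
#'
#' The selection-bias-free protocol: samples are partitioned into `folds`
#' stratified test sets, and for every fold the *entire* selection pipeline
#' (filter, redundancy reduction, RFE) is re-run on the training samples
#' only; a linear SVM on the selected genes then classifies the held-out
#' fold.  Aggregate metrics are unweighted means of the per-fold metrics.
#'
#' @param expr a preprocessed [gene_expr()] object.
#' @param variant pipeline variant name, see [variant_registry()].
#' @param folds number of folds (default 10).
#' @param seed integer seed driving the fold assignment and internal CV.
#' @param config a [pipeline_config()].
#' @return a `cv_report`: per-fold selected genes and confusion counts,
#'   aggregate accuracy / sensitivity / specificity, fold assignment, seed.
#' @export
external_cv <- function(expr, variant = "fisher_rg_svmrfe", folds = 10L,
                        seed = 1L, config = pipeline_config()) {
  stopifnot(inherits(expr, "gene_expr"))
  fold_assign <- make_folds(expr$labels, folds = folds, seed = seed,
                            stratified = config$stratified)
  n <- ncol(expr$values)
  fold_results <- lapply(seq_along(fold_assign), function(f) {
    test <- fold_assign[[f]]; train <- setdiff(seq_len(n), test)
    expr_train <- subset_samples(expr, train)
    expr_test <- subset_samples(expr, test)
    sel <- select_genes(expr_train, variant, config,
                        seed = seed * 1000L + f)
    list(fold = f, selected = sel,
         confusion = fit_and_score(expr_train, expr_test, sel,
                                   C = config$svm_c))
  })
  cv_report(fold_results, fold_assign, seed, variant, config, "external")
}

#' Internal (biased) cross-validation
#'
#' The protocol this package exists to avoid: gene selection is run once on
#' the *entire* dataset, and cross-validation covers only the classifier.
#' Because the selected genes have seen the test samples, accuracy is
#' overly optimistic on noise.  Provided for demonstrating selection bias;
#' shares its fold partitioner with [external_cv()], so the same seed gives
#' identical fold assignments in both modes.
#'
#' @inheritParams external_cv
#' @return a `cv_report` (protocol `"internal_biased"`).
#' @export
internal_cv_biased <- function(expr, variant = "fisher_rg_svmrfe",
                               folds = 10L, seed = 1L,
                               config = pipeline_config()) {
  stopifnot(inherits(expr, "gene_expr"))
  fold_assign <- make_folds(expr$labels, folds = folds, seed = seed,
                            stratified = config$stratified)
  n <- ncol(expr$values)
  sel <- select_genes(expr, variant, config, seed = seed * 1000L)
  fold_results <- lapply(seq_along(fold_assign), function(f) {
    test <- fold_assign[[f]]; train <- setdiff(seq_len(n), test)
    list(fold = f, selected = sel,
         confusion = fit_and_score(subset_samples(expr, train),
                                   subset_samples(expr, test), sel,
                                   C = config$svm_c))
  })
  cv_report(fold_results, fold_assign, seed, variant, config,
            "internal_biased")
}

#' Run a pipeline variant: whole-data selection + external CV
#'
#' Convenience wrapper returning both an honest performance estimate
#' (external CV, selection inside training folds) and a final whole-data
#' gene selection — the latter clearly labeled as such, since per-fold
#' selections differ and a single reporting list requires using all data.
#'
#' @inheritParams external_cv
#' @param variant_name pipeline variant name.
#' @return list with `selected` (whole-data selection), `report` (the
#'   external `cv_report`) and `selection_frequency` (per-gene fraction of
#'   folds that selected it).
#' @export
run_variant <- function(expr, variant_name, config = pipeline_config(),
                        folds = 10L, seed = 1L) {
  report <- external_cv(expr, variant_name, folds = folds, seed = seed,
                        config = config)
  selected <- select_genes(expr, variant_name, config, seed = seed)
  freq_tab <- table(unlist(lapply(report$folds, `[[`, "selected")))
  freq <- structure(as.numeric(freq_tab) / length(report$folds),
                    names = names(freq_tab))
  list(selected = selected, report = report, selection_frequency = freq)
}
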