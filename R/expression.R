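#' Two-class expression matrix container
#'
#' Light-weight container for a genes-by-samples expression matrix with
#' binary sample labels, in the style of limma's expression lists.  Row
#' names are gene identifiers (matched case-sensitively after whitespace
#' trimming), column names are sample identifiers.
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   required and unique.
#' @param labels character or factor of per-sample class labels; exactly two
#'   distinct values.
#' @param positive_class which label is the "positive" (e.g. tumor) class.
#'   Defaults to the lexicographically larger label, so that conventional
#'   pairs like normal/tumor or negative/positive resolve as expected.
#' @return an object of class `gene_expr` with elements `values`, `labels`
#'   (factor with the negative class as first level) and `positive_class`.
#' @export
gene_expr <- function(values, labels, positive_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  rownames(values) <- trimws(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifier in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier in expression matrix")
  labels <- trimws(as.character(labels))
  if (length(labels) != ncol(values))
    stop("length(labels) must equal the number of samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("binary classification only: found ", length(lev),
         " distinct label(s): ", paste(lev, collapse = ", "))
  if (is.null(positive_class)) positive_class <- lev[2L]
  if (!positive_class %in% lev)
    stop("unknown label value for positive_class: ", positive_class)
  neg <- setdiff(lev, positive_class)
  labels <- factor(labels, levels = c(neg, positive_class))
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 samples")
  structure(list(values = values, labels = labels,
                 positive_class = positive_class),
            class = "gene_expr")
}

#' @export
print.gene_expr <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("gene_expr: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("positive class: %s\n", x$positive_class))
  invisible(x)
}

#' @export
dim.gene_expr <- function(x) dim(x$values)

# +1/-1 label vector, positive class -> +1
svm_labels <- function(expr) {
  ifelse(expr$labels == expr$positive_class, 1, -1)
}

# subset samples without re-validation: CV test folds may hold fewer than
# 2 samples of a class (the >=2-per-class invariant applies to scoring
# operations, which check it themselves); factor levels are preserved
subset_samples <- function(expr, idx) {
  structure(list(values = expr$values[, idx, drop = FALSE],
                 labels = expr$labels[idx],
                 positive_class = expr$positive_class),
            class = "gene_expr")
}

#' Read a delimited expression table
#'
#' Expects genes in rows: first column gene identifiers, header row sample
#' identifiers.  Labels come either from a sidecar file (two columns:
#' sample id, label; or a single label column in sample order) or from a
#' designated label row inside the table.
#'
#' @param path path to the expression table.
#' @param labels path to a label sidecar file, or the name of a row of the
#'   table holding the labels (e.g. `"class"`).
#' @param sep field separator, tab by default (use `","` for CSV).
#' @param positive_class see [gene_expr()].
#' @return a [gene_expr()] object.
#' @export
read_expression_table <- function(path, labels, sep = "\t",
                                  positive_class = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 3L)
    stop("malformed header: need a gene id column and at least 2 samples")
  ids <- trimws(as.character(tab[[1L]]))
  body <- tab[, -1L, drop = FALSE]

  lab <- NULL
  if (length(labels) == 1L && file.exists(labels)) {
    side <- read.delim(labels, sep = sep, header = FALSE,
                       stringsAsFactors = FALSE)
    if (ncol(side) >= 2L) {
      lab <- trimws(as.character(side[[2L]]))
      names(lab) <- trimws(as.character(side[[1L]]))
      if (!all(colnames(body) %in% names(lab)))
        stop("label file is missing samples: ",
             paste(setdiff(colnames(body), names(lab)), collapse = ", "))
      lab <- lab[colnames(body)]
    } else {
      lab <- trimws(as.character(side[[1L]]))
      if (length(lab) != ncol(body))
        stop("label file has ", length(lab), " labels for ",
             ncol(body), " samples")
    }
  } else {
    hit <- which(ids == labels)
    if (length(hit) != 1L)
      stop("label row '", labels, "' not found in expression table")
    lab <- trimws(as.character(unlist(body[hit, ])))
    ids <- ids[-hit]
    body <- body[-hit, , drop = FALSE]
  }

  if (anyDuplicated(ids)) stop("duplicate gene identifier")
  vals <- suppressWarnings(
    vapply(body, function(col) as.numeric(as.character(col)),
           numeric(nrow(body))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(ids))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell at gene '", ids[bad[1, 1]], "', sample '",
         colnames(body)[bad[1, 2]], "'")
  dimnames(vals) <- list(ids, colnames(body))
  gene_expr(vals, lab, positive_class = positive_class)
}

#' Preprocess an expression matrix
#'
#' Optionally imputes missing values (per-gene mean, a deliberately simple
#' stand-in for ontology-aware imputation, which is out of scope), optionally
#' applies a base-10 log transform, then standardizes each sample column to
#' zero mean and unit variance (the n-1 standard-deviation estimator is used
#' here and everywhere else in the package).
#'
#' @param expr a [gene_expr()] object.
#' @param log10_transform apply `log10` before standardization; all values
#'   must be strictly positive after adding `offset`.
#' @param impute replace missing cells by the gene's mean across samples.
#' @param offset added before the log transform (0 by default).
#' @param per_gene standardize gene rows instead of sample columns
#'   (non-default; the sample-wise convention follows common microarray
#'   practice for these data).
#' @return a preprocessed [gene_expr()] object with no missing values.
#' @export
preprocess <- function(expr, log10_transform = FALSE, impute = FALSE,
                       offset = 0, per_gene = FALSE) {
  stopifnot(inherits(expr, "gene_expr"))
  v <- expr$values
  if (anyNA(v)) {
    if (!impute) stop("missing values present; set impute = TRUE")
    mu <- rowMeans(v, na.rm = TRUE)
    if (anyNA(mu)) stop("gene with all values missing cannot be imputed")
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 1L]]
  }
  if (log10_transform) {
    v <- v + offset
    if (any(v <= 0))
      stop("non-positive value under log10; supply a positive `offset`")
    v <- log10(v)
  }
  scale_vec <- function(x) {
    s <- sd(x)                       # n-1 estimator
    if (s == 0) stop("zero-variance ", if (per_gene) "gene" else "sample",
                     " vector: cannot standardize")
    (x - mean(x)) / s
  }
  if (per_gene) {
    v <- t(apply(v, 1L, scale_vec))
    dimnames(v) <- dimnames(expr$values)
  } else {
    v <- apply(v, 2L, scale_vec)
    rownames(v) <- rownames(expr$values)
  }
  gene_expr(v, as.character(expr$labels),
            positive_class = expr$positive_class)
}
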