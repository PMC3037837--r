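#' Fisher criterion score for one gene
#'
#' \deqn{F(g) = (m_1 - m_2)^2 / (s_1^2 + s_2^2)}
#' where \eqn{m_c}, \eqn{s_c} are the mean and (n-1) standard deviation of
#' the gene's expression in class *c*.  Degenerate cases: both variances
#' zero with equal means gives 0; both variances zero with different means
#' gives `Inf` (such a gene separates the classes perfectly and ranks above
#' every finite score).
#'
#' @param x1,x2 numeric vectors of the gene's values in the two classes,
#'   each of length >= 2.
#' @return a non-negative score (possibly `Inf`).
#' @export
fisher_score <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop("each class needs at least 2 samples")
  num <- (mean(x1) - mean(x2))^2
  den <- var(x1) + var(x2)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else num / den
}

#' Rank genes by the Fisher criterion
#'
#' Scores every gene and keeps the `min(k, n_genes)` highest, most
#' discriminative first.  Ties are broken by original gene order (stable),
#' so the output is deterministic.
#'
#' @param expr a preprocessed [gene_expr()] object.
#' @param k number of genes to keep (default 500).
#' @return a data.frame of class `gene_ranking` with columns `gene` and
#'   `score`, ordered by non-increasing score.
#' @export
rank_genes <- function(expr, k = 500L) {
  stopifnot(inherits(expr, "gene_expr"), k >= 1L)
  pos <- expr$labels == expr$positive_class
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("each class needs at least 2 samples")
  x1 <- expr$values[, pos, drop = FALSE]
  x2 <- expr$values[, !pos, drop = FALSE]
  rvar <- function(m) {              # rowwise n-1 variance
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
  }
  num <- (rowMeans(x1) - rowMeans(x2))^2
  den <- rvar(x1) + rvar(x2)
  score <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  ord <- order(-score)               # stable: ties keep input order
  keep <- ord[seq_len(min(k, length(score)))]
  structure(data.frame(gene = rownames(expr$values)[keep],
                       score = unname(score[keep]),
                       stringsAsFactors = FALSE),
            class = c("gene_ranking", "data.frame"))
}

#' Write a gene ranking as two-column TSV
#'
#' @param ranking a `gene_ranking` (or any data.frame with `gene`, `score`).
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking[, c("gene", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
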