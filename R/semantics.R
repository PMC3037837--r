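#' Annotation-corpus term frequencies
#'
#' The frequency of a term is the number of gene-term annotation instances
#' citing the term or any of its descendants: each instance increments the
#' cited term and every (inclusive) ancestor exactly once, so multiple
#' paths through the DAG never double count.  Frequencies are therefore
#' monotone non-decreasing from any term to its ancestors.
#'
#' @param dag an [ontology_dag()].
#' @param ann annotation list from [read_annotations()] (gene -> term ids).
#' @return data.frame of class `ic_table` with columns `term`, `freq`, and
#'   (after [information_content()]) `prob` and `ic`; attribute `max_freq`.
#' @export
concept_frequency <- function(dag, ann) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (length(ann) == 0) stop("empty annotation corpus")
  freq <- structure(integer(nrow(dag$terms)), names = dag$terms$id)
  for (terms in ann) {
    terms <- unique(terms)
    unknown <- setdiff(terms, dag$terms$id)
    if (length(unknown) > 0)
      stop("annotation to unknown term: ", paste(unknown, collapse = ", "))
    for (t in terms) {
      a <- dag$ancestors[[t]]
      freq[a] <- freq[a] + 1L
    }
  }
  if (all(freq == 0)) stop("empty annotation corpus")
  structure(data.frame(term = names(freq), freq = unname(freq),
                       stringsAsFactors = FALSE),
            max_freq = max(freq),
            class = c("ic_table", "data.frame"))
}

#' Information content from term frequencies
#'
#' `prob = freq / max_freq`; `ic = -log(prob)` (natural log — the base
#' cancels in Lin's ratio).  Terms with zero frequency have undefined
#' information content (`NA`) and are excluded from similarity
#' computations.
#'
#' @param freq_table output of [concept_frequency()].
#' @return the same `ic_table` with `prob` and `ic` columns filled in.
#' @export
information_content <- function(freq_table) {
  stopifnot(inherits(freq_table, "ic_table"))
  max_freq <- attr(freq_table, "max_freq")
  if (is.null(max_freq) || max_freq < 1) stop("max_freq must be >= 1")
  prob <- freq_table$freq / max_freq
  ic <- ifelse(freq_table$freq > 0, -log(prob), NA_real_)
  freq_table$prob <- ifelse(freq_table$freq > 0, prob, NA_real_)
  freq_table$ic <- ic
  freq_table
}

ic_lookup <- function(ic_table, term) {
  i <- match(term, ic_table$term)
  if (is.na(i)) stop("unknown term: ", term)
  ic_table$ic[i]
}

#' Shared information of two terms
#'
#' The information content of the most informative common ancestor
#' (ancestor sets are inclusive: a term is its own ancestor).  If no common
#' ancestor has defined information content (e.g. disjoint namespaces in a
#' multi-root ontology), returns 0 with a warning.
#'
#' @param c1,c2 term ids.
#' @param dag an [ontology_dag()].
#' @param ic an `ic_table` from [information_content()].
#' @return non-negative shared information content.
#' @export
shared_information <- function(c1, c2, dag, ic) {
  a1 <- dag$ancestors[[c1]]; a2 <- dag$ancestors[[c2]]
  if (is.null(a1) || is.null(a2)) stop("unknown term: ",
                                       if (is.null(a1)) c1 else c2)
  common <- intersect(a1, a2)
  vals <- ic$ic[match(common, ic$term)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    warning("no common ancestor with defined information content for ",
            c1, " and ", c2)
    return(0)
  }
  max(vals)
}

#' Lin semantic similarity of two terms
#'
#' \deqn{sim(c_1,c_2) = 2\,Share(c_1,c_2) / (IC(c_1) + IC(c_2))}
#' Defined as 0 when both terms have zero information content (no
#' discriminating information is shared; avoids 0/0).  Errors if either
#' term's information content is undefined (zero corpus frequency).
#'
#' @inheritParams shared_information
#' @return similarity in \[0, 1\].
#' @export
lin_similarity <- function(c1, c2, dag, ic) {
  ic1 <- ic_lookup(ic, c1); ic2 <- ic_lookup(ic, c2)
  if (is.na(ic1)) stop("information content undefined for term ", c1)
  if (is.na(ic2)) stop("information content undefined for term ", c2)
  if (ic1 + ic2 == 0) return(0)
  2 * shared_information(c1, c2, dag, ic) / (ic1 + ic2)
}

# dense Lin similarity matrix over the given usable terms; cross-namespace
# pairs scored 0 (no shared ancestry between GO hierarchies)
term_similarity_matrix <- function(dag, ic, terms) {
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  if (n == 0) return(m)
  ns <- term_namespace(dag, terms)
  icv <- ic$ic[match(terms, ic$term)]
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!identical(ns[i], ns[j])) next
      s <- if (icv[i] + icv[j] == 0) 0 else
        2 * shared_information(terms[i], terms[j], dag, ic) /
          (icv[i] + icv[j])
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}

aggregate_pair_sims <- function(simmat, aggregation) {
  switch(aggregation,
         max = max(simmat),
         average = ,
         avg = mean(simmat),
         bma = ,
         best_match_average =
           (mean(apply(simmat, 1L, max)) + mean(apply(simmat, 2L, max))) / 2,
         stop("unknown aggregation: ", aggregation))
}

#' Gene-level semantic similarity
#'
#' Aggregates Lin term similarities over all pairs of annotation terms of
#' the two genes (cross-namespace pairs contribute 0).  Terms with
#' undefined information content are unusable; a gene with no usable
#' annotation yields `NA` (semantic similarity undefined — callers fall
#' back to expression similarity alone).
#'
#' @param g1,g2 gene ids.
#' @param ann annotation list (gene -> term ids).
#' @param dag an [ontology_dag()].
#' @param ic an `ic_table` from [information_content()].
#' @param aggregation `"bma"` (best-match average, default), `"max"`, or
#'   `"avg"`.
#' @return similarity in \[0, 1\], or `NA` if undefined.
#' @export
gene_semantic_similarity <- function(g1, g2, ann, dag, ic,
                                     aggregation = c("bma", "max", "avg")) {
  aggregation <- match.arg(aggregation)
  usable <- function(g) {
    t <- ann[[g]]
    if (is.null(t)) return(character())
    t[!is.na(ic$ic[match(t, ic$term)])]
  }
  t1 <- usable(g1); t2 <- usable(g2)
  if (length(t1) == 0 || length(t2) == 0) return(NA_real_)
  tm <- term_similarity_matrix(dag, ic, union(t1, t2))
  aggregate_pair_sims(tm[t1, t2, drop = FALSE], aggregation)
}

#' Export an information-content table as TSV
#'
#' @param ic an `ic_table`.
#' @param path output file.
#' @export
write_ic_table <- function(ic, path) {
  write.table(ic, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
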