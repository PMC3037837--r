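# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately written as plain nested loops / direct formula
# transcriptions, independent of the package's implementation paths.

make_expr <- function(values, labels, positive_class = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  gene_expr(values, labels, positive_class = positive_class)
}

# brute-force greedy redundancy reduction: a gene survives iff it is
# below-threshold similar to every previously surviving gene
bf_greedy <- function(genes, S, ts) {
  kept <- character()
  for (g in genes) {
    ok <- TRUE
    for (h in kept) if (S[h, g] >= ts) { ok <- FALSE; break }
    if (ok) kept <- c(kept, g)
  }
  kept
}

# inclusive ancestor set by explicit recursive parent walk (no igraph)
bf_ancestors <- function(term, edges) {
  seen <- character()
  stack <- term
  while (length(stack) > 0) {
    t <- stack[[1L]]; stack <- stack[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, edges$parent[edges$child == t])
  }
  seen
}

bf_shared_information <- function(c1, c2, edges, ic) {
  common <- intersect(bf_ancestors(c1, edges), bf_ancestors(c2, edges))
  vals <- ic$ic[match(common, ic$term)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) 0 else max(vals)
}

# quadprog-based soft-margin SVM dual (tiny ridge for strict positive
# definiteness); the independent route for checking the SMO solver
oracle_svm <- function(X, y, C = 1) {
  n <- nrow(X)
  K <- tcrossprod(X)
  D <- (y %o% y) * K + diag(1e-6, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  w <- drop(crossprod(X, alpha * y))
  # the ridge perturbs bound multipliers by ~1e-4*C: use relative margins
  free <- which(alpha > 1e-3 * C & alpha < C * (1 - 1e-3))
  b <- if (length(free) > 0) {
    mean(y[free] - drop(X[free, , drop = FALSE] %*% w))
  } else {
    f <- drop(X %*% w)
    -(max(f[y == 1 & alpha >= C * (1 - 1e-3)], -Inf) +
        min(f[y == -1 & alpha >= C * (1 - 1e-3)], Inf)) / 2
  }
  list(alpha = alpha, w = w, b = b)
}

# step-1 RFE recomputed from scratch each round with the quadprog SVM;
# same tie-break contract (later original index eliminated first)
bf_rfe <- function(X, y, C = 1) {
  features <- colnames(X)
  remaining <- seq_along(features)
  out <- integer()
  while (length(remaining) > 1L) {
    w <- oracle_svm(X[, remaining, drop = FALSE], y, C)$w
    key <- order(w^2, -remaining)
    drop_i <- key[1L]
    out <- c(out, remaining[drop_i])
    remaining <- remaining[-drop_i]
  }
  features[c(out, remaining)]
}

# KKT / stationarity residuals of a trained model against raw data
kkt_residuals <- function(model, X, y) {
  c(eq4 = max(abs(model$w - drop(crossprod(X, model$alpha * y)))),
    eq5 = abs(sum(y * model$alpha)),
    box = max(c(-model$alpha, model$alpha - model$C)))
}

# random two-class instance with a weak planted signal, for SVM tests
random_svm_instance <- function(seed, n_per_class = 6L, p = 6L,
                                shift = 0.8) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c(-1, 1), each = n_per_class)
  X[y == 1, 1L] <- X[y == 1, 1L] + shift
  list(X = X, y = y)
}

# random similarity matrix instance for greedy oracle checks
random_sim_instance <- function(seed, max_genes = 12L) {
  set.seed(seed)
  n <- sample(2:max_genes, 1L)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  genes <- paste0("g", seq_len(n))
  dimnames(S) <- list(genes, genes)
  list(genes = genes, S = S, ts = runif(1))
}

# random small DAG (possibly multi-parent) plus annotations, for the
# shared-information brute-force property
random_dag_instance <- function(seed, max_terms = 30L) {
  set.seed(seed)
  n <- sample(5:max_terms, 1L)
  ids <- paste0("T", seq_len(n))
  edges <- NULL
  for (i in 2:n) {
    n_par <- sample(1:min(2L, i - 1L), 1L)
    parents <- sample(ids[seq_len(i - 1L)], n_par)
    edges <- rbind(edges, data.frame(child = ids[i], parent = parents,
                                     stringsAsFactors = FALSE))
  }
  terms <- data.frame(id = ids, name = ids, namespace = "BP",
                      stringsAsFactors = FALSE)
  dag <- ontology_dag(terms, edges)
  genes <- paste0("g", seq_len(n))
  ann <- lapply(seq_len(n), function(i) sample(ids, sample(1:2, 1L)))
  names(ann) <- genes
  ic <- information_content(concept_frequency(dag, ann))
  list(dag = dag, edges = edges, ann = ann, ic = ic)
}
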