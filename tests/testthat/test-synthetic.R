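test_that("generation is deterministic and respects the planted structure", {
  spec <- synthetic_spec(n_genes = 80, n_samples_per_class = 8,
                         n_informative = 6, n_redundant_groups = 2,
                         n_copies = 3, seed = 21)
  d1 <- generate_expression(spec)
  d2 <- generate_expression(spec)
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$truth, d2$truth)
  expect_length(d1$truth$informative, 6L)
  expect_length(d1$truth$groups, 2L)
  # planted shift appears in the positive class
  g <- d1$truth$informative[1]
  tumor <- d1$expr$labels == "tumor"
  expect_gt(mean(d1$expr$values[g, tumor]) -
              mean(d1$expr$values[g, !tumor]), 0.5)

  expect_error(synthetic_spec(n_genes = 10, n_informative = 8,
                              n_redundant_groups = 2, n_copies = 5),
               "exceeds n_genes")
})

test_that("zero effect size makes 'informative' genes look like background", {
  inf_sc <- bg_sc <- NULL
  for (s in 1:20) {
    spec <- synthetic_spec(n_genes = 200, n_samples_per_class = 10,
                           n_informative = 10, effect_size = 0,
                           n_redundant_groups = 0, n_copies = 0, seed = s)
    d <- generate_expression(spec)
    r <- rank_genes(d$expr, k = 200)
    sc <- structure(r$score, names = r$gene)
    inf_sc <- c(inf_sc, sc[d$truth$informative])
    bg_sc <- c(bg_sc, sc[setdiff(names(sc), d$truth$informative)])
  }
  expect_gt(stats::wilcox.test(inf_sc, bg_sc)$p.value, 0.01)
})

test_that("noise-free copies duplicate their source exactly", {
  spec <- synthetic_spec(n_genes = 30, n_samples_per_class = 6,
                         n_informative = 3, n_redundant_groups = 1,
                         n_copies = 2, copy_noise_sd = 0, seed = 8)
  d <- generate_expression(spec)
  grp <- d$truth$groups[[1]]
  src <- grp[1]
  for (cp in grp[-1]) {
    expect_identical(d$expr$values[cp, ], d$expr$values[src, ])
    expect_equal(expression_similarity(d$expr$values[cp, ],
                                       d$expr$values[src, ]), 1.0)
  }
})

test_that("generated ontology has the stated shape and annotation rules", {
  spec <- synthetic_spec(n_genes = 40, n_samples_per_class = 6,
                         n_informative = 4, n_redundant_groups = 2,
                         n_copies = 2, ontology_depth = 2,
                         ontology_branching = 2, unannotated_fraction = 0.3,
                         seed = 13)
  d <- generate_expression(spec)
  go <- generate_ontology(spec, d$truth)
  expect_identical(nrow(go$dag$terms), 7L)       # 1 + 2 + 4
  expect_identical(nrow(go$dag$edges), 6L)
  # all members of one redundancy group share a single leaf annotation
  grp <- d$truth$groups[[1]]
  terms <- unique(unlist(go$ann[grp]))
  expect_length(terms, 1L)
  for (agg in c("bma", "max", "avg"))
    expect_equal(gene_semantic_similarity(grp[1], grp[2], go$ann, go$dag,
                                          go$ic, aggregation = agg), 1.0)
  expect_error(generate_ontology(synthetic_spec(ontology_depth = 1)),
               ">= 2")
})

test_that("fully unannotated corpus forces the expression-only fallback", {
  spec <- synthetic_spec(n_genes = 30, n_samples_per_class = 6,
                         n_informative = 3, n_redundant_groups = 0,
                         n_copies = 0, unannotated_fraction = 1.0, seed = 9)
  d <- generate_expression(spec)
  go <- generate_ontology(spec, d$truth)
  expect_length(go$ann, 0L)
  sim <- build_similarity(d$expr, go = NULL)
  expect_true(all(sim$provenance == "expression_only"))
})

test_that("fixtures echo their specifications", {
  ts <- make_fixture("tiny_separable")
  expect_identical(dim(ts$expr$values), c(50L, 20L))
  expect_length(ts$truth$informative, 3L)
  expect_equal(ts$spec$effect_size, 3.0)

  dh <- make_fixture("duplicates_heavy")
  expect_length(dh$truth$groups, 5L)
  expect_true(all(lengths(dh$truth$groups) == 6L))  # source + 5 near-copies

  pn <- make_fixture("pure_noise")
  expect_identical(dim(pn$expr$values), c(500L, 30L))
  expect_length(pn$truth$informative, 0L)

  fx <- make_fixture("go_fixture")
  expect_identical(nrow(fx$dag$terms), 5L)
  expect_error(make_fixture("nope"))
})

test_that("written datasets round-trip through the package readers", {
  dir <- tempfile("synth")
  spec <- synthetic_spec(n_genes = 25, n_samples_per_class = 5,
                         n_informative = 3, n_redundant_groups = 1,
                         n_copies = 2, ontology_depth = 2,
                         ontology_branching = 2, seed = 17)
  write_synthetic_dataset(spec, dir)
  expect_setequal(list.files(dir),
                  c("expr.tsv", "labels.tsv", "go.obo", "ann.tsv",
                    "truth.json"))
  m <- read_expression_table(file.path(dir, "expr.tsv"),
                             file.path(dir, "labels.tsv"),
                             positive_class = "tumor")
  orig <- generate_expression(spec)
  expect_equal(m$values, orig$expr$values, tolerance = 1e-12)
  expect_identical(as.character(m$labels), as.character(orig$expr$labels))
  dag <- read_obo(file.path(dir, "go.obo"))
  ann <- read_annotations(file.path(dir, "ann.tsv"), dag)
  go <- generate_ontology(spec, orig$truth)
  expect_setequal(dag$terms$id, go$dag$terms$id)
  expect_setequal(names(ann), names(go$ann))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$informative, orig$truth$informative)
})

test_that("greedy reduction recovers planted redundancy groups", {
  ok <- 0L; total <- 0L
  for (s in 1:5) {
    dh <- make_fixture("duplicates_heavy", seed = 30 + s)
    r <- rank_genes(dh$expr, k = 60)
    sim <- build_similarity(dh$expr, genes = r$gene, go = dh$go)
    red <- greedy_reduce(r, ts = 0.8, sim = sim)
    sizes <- vapply(dh$truth$groups,
                    function(g) sum(g %in% red$gene), integer(1))
    ok <- ok + sum(sizes >= 1 & sizes <= 2)
    total <- total + length(sizes)
  }
  expect_gte(ok / total, 0.95)
})
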