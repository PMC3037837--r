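test_that("concept_frequency counts instances through ancestors", {
  # root with two children; one annotation instance on each child
  terms <- data.frame(id = c("root", "A", "B"), name = c("r", "a", "b"),
                      namespace = "BP", stringsAsFactors = FALSE)
  edges <- data.frame(child = c("A", "B"), parent = c("root", "root"),
                      stringsAsFactors = FALSE)
  dag <- ontology_dag(terms, edges)
  ft <- concept_frequency(dag, list(g1 = "A", g2 = "B"))
  freq <- structure(ft$freq, names = ft$term)
  expect_identical(freq[["A"]], 1L)
  expect_identical(freq[["B"]], 1L)
  expect_identical(freq[["root"]], 2L)
  expect_identical(attr(ft, "max_freq"), 2L)

  # annotating only the root leaves the leaves at zero
  ft2 <- concept_frequency(dag, list(g1 = "root"))
  freq2 <- structure(ft2$freq, names = ft2$term)
  expect_identical(freq2[["root"]], 1L)
  expect_identical(freq2[["A"]], 0L)

  expect_error(concept_frequency(dag, list()), "empty annotation corpus")
  expect_error(concept_frequency(dag, list(g1 = "XX")), "unknown term")

  # a gene annotated to two terms contributes two instances to shared ancestors
  ft3 <- concept_frequency(dag, list(g1 = c("A", "B")))
  expect_identical(ft3$freq[ft3$term == "root"], 2L)
})

test_that("information_content follows -log(freq/maxFreq)", {
  fx <- make_fixture("go_fixture")
  ic <- fx$ic
  expect_equal(ic$ic[ic$term == "A"], 0)               # freq == maxFreq
  # B has freq 3 of maxFreq 5
  expect_equal(ic$ic[ic$term == "B"], -log(3 / 5))
  # freq = maxFreq/2 gives ln 2 on a constructed corpus
  terms <- data.frame(id = c("r", "c"), name = c("r", "c"), namespace = "BP")
  dag <- ontology_dag(terms, data.frame(child = "c", parent = "r"))
  ic2 <- information_content(concept_frequency(dag, list(g1 = "c", g2 = "r")))
  expect_equal(ic2$ic[ic2$term == "c"], log(2))
  # zero-frequency terms carry undefined (NA) ic, not an error
  ic3 <- information_content(concept_frequency(dag, list(g1 = "r")))
  expect_true(is.na(ic3$ic[ic3$term == "c"]))
})

test_that("ic is monotone non-increasing from a term to its ancestors", {
  for (s in 1:10) {
    inst <- random_dag_instance(s)
    ic <- structure(inst$ic$ic, names = inst$ic$term)
    for (k in seq_len(nrow(inst$edges))) {
      child <- inst$edges$child[k]; parent <- inst$edges$parent[k]
      if (!is.na(ic[child]) && !is.na(ic[parent]))
        expect_gte(ic[[child]], ic[[parent]])
    }
  }
})

test_that("shared_information equals brute-force ancestor enumeration", {
  fx <- make_fixture("go_fixture")
  # self is its own most informative common ancestor
  expect_equal(shared_information("D", "D", fx$dag, fx$ic),
               fx$ic$ic[fx$ic$term == "D"])
  # siblings whose only common ancestor is the root share nothing
  expect_equal(shared_information("B", "C", fx$dag, fx$ic), 0)
  # multi-parent term E: common ancestry with D runs through B
  expect_equal(shared_information("D", "E", fx$dag, fx$ic),
               fx$ic$ic[fx$ic$term == "B"])

  for (s in 1:10) {
    inst <- random_dag_instance(s)
    usable <- inst$ic$term[!is.na(inst$ic$ic)]
    pairs <- expand.grid(c1 = usable, c2 = usable,
                         stringsAsFactors = FALSE)[1:25, ]
    pairs <- pairs[!is.na(pairs$c1) & !is.na(pairs$c2), ]
    for (k in seq_len(nrow(pairs))) {
      expect_equal(
        shared_information(pairs$c1[k], pairs$c2[k], inst$dag, inst$ic),
        bf_shared_information(pairs$c1[k], pairs$c2[k], inst$edges, inst$ic))
    }
  }
})

test_that("lin_similarity matches hand computation and respects bounds", {
  fx <- make_fixture("go_fixture")
  # identical term with positive ic
  expect_equal(lin_similarity("D", "D", fx$dag, fx$ic), 1.0)
  # root-only common ancestry
  expect_equal(lin_similarity("B", "C", fx$dag, fx$ic), 0)
  # hand computation: share(D,E) = ic(B); ic(D) = ic(E) = -ln(1/5)
  icB <- -log(3 / 5); icD <- -log(1 / 5)
  expect_equal(lin_similarity("D", "E", fx$dag, fx$ic), 2 * icB / (2 * icD))
  # both-zero-ic pair is defined as 0
  terms <- data.frame(id = "r", name = "r", namespace = "BP")
  dag1 <- ontology_dag(terms, data.frame(child = character(),
                                         parent = character()))
  ic1 <- information_content(concept_frequency(dag1, list(g1 = "r")))
  expect_equal(lin_similarity("r", "r", dag1, ic1), 0)
  # undefined-ic term errors, naming the term
  terms2 <- data.frame(id = c("r", "c"), name = c("r", "c"), namespace = "BP")
  dag2 <- ontology_dag(terms2, data.frame(child = "c", parent = "r"))
  ic2 <- information_content(concept_frequency(dag2, list(g1 = "r")))
  expect_error(lin_similarity("c", "r", dag2, ic2), "c")

  for (s in 1:5) {
    inst <- random_dag_instance(s)
    usable <- inst$ic$term[!is.na(inst$ic$ic)]
    for (k in 1:10) {
      pr <- sample(usable, 2, replace = TRUE)
      v <- lin_similarity(pr[1], pr[2], inst$dag, inst$ic)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, lin_similarity(pr[2], pr[1], inst$dag, inst$ic))
    }
  }
})

test_that("gene_semantic_similarity aggregates term pairs correctly", {
  fx <- make_fixture("go_fixture")
  # identical single annotation with ic > 0
  ann <- list(gA = "D", gB = "D", gC = c("D", "E"), gD = c("B", "C"))
  for (agg in c("bma", "max", "avg"))
    expect_equal(gene_semantic_similarity("gA", "gB", ann, fx$dag, fx$ic,
                                          aggregation = agg), 1.0)
  # unannotated partner is undefined
  expect_true(is.na(gene_semantic_similarity("gA", "gX", ann, fx$dag, fx$ic)))

  # 2-term vs 2-term against exhaustive pair enumeration
  pairs <- outer(ann$gC, ann$gD,
                 Vectorize(function(a, b) lin_similarity(a, b, fx$dag, fx$ic)))
  expect_equal(gene_semantic_similarity("gC", "gD", ann, fx$dag, fx$ic, "max"),
               max(pairs))
  expect_equal(gene_semantic_similarity("gC", "gD", ann, fx$dag, fx$ic, "avg"),
               mean(pairs))
  bma <- (mean(apply(pairs, 1, max)) + mean(apply(pairs, 2, max))) / 2
  expect_equal(gene_semantic_similarity("gC", "gD", ann, fx$dag, fx$ic, "bma"),
               bma)
  # symmetry
  expect_equal(gene_semantic_similarity("gC", "gD", ann, fx$dag, fx$ic),
               gene_semantic_similarity("gD", "gC", ann, fx$dag, fx$ic))
})

test_that("cross-namespace term pairs contribute zero", {
  terms <- data.frame(id = c("bp_root", "bp_leaf", "mf_root", "mf_leaf"),
                      name = 1:4,
                      namespace = c("BP", "BP", "MF", "MF"))
  edges <- data.frame(child = c("bp_leaf", "mf_leaf"),
                      parent = c("bp_root", "mf_root"))
  dag <- ontology_dag(terms, edges)
  # root annotations keep the leaves below probability 1 (positive ic)
  ann <- list(g1 = "bp_leaf", g2 = "mf_leaf", g3 = c("bp_leaf", "mf_leaf"),
              g4 = "bp_root", g5 = "mf_root")
  ic <- information_content(concept_frequency(dag, ann))
  expect_equal(gene_semantic_similarity("g1", "g2", ann, dag, ic), 0)
  # the mixed gene still matches g1 on the BP side under best-match average
  expect_gt(gene_semantic_similarity("g1", "g3", ann, dag, ic), 0)
})

test_that("write_ic_table exports term/freq/prob/ic columns", {
  fx <- make_fixture("go_fixture")
  f <- tempfile(fileext = ".tsv")
  write_ic_table(fx$ic, f)
  back <- read.delim(f)
  expect_identical(names(back), c("term", "freq", "prob", "ic"))
  expect_equal(back$ic[back$term == "A"], 0)
})
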