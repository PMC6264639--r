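test_that("gene overlap uses half-open coordinates and 1 bp minimum", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      symbol = c("g1", "g2", "g3"),
                      chrom = "chr1",
                      start = c(5999, 6000, 20000),
                      end = c(8000, 8000, 21000),
                      strand = "+", stringsAsFactors = FALSE)
  win <- data.frame(chrom = "chr1", start = 1000, end = 6000)
  ov <- overlap_genes(win, genes)
  expect_equal(ov$gene_ids, "g1")        # 1 bp overlap retrieved
  expect_false("g2" %in% ov$gene_ids)    # half-open abutment is no overlap
  expect_equal(ov$per_window[[1]], "g1")
})

test_that("per-gene window counts report the concentration statistic", {
  genes <- data.frame(gene_id = "long", symbol = "long", chrom = "chr1",
                      start = 0, end = 20000, strand = "+",
                      stringsAsFactors = FALSE)
  wins <- data.frame(chrom = "chr1", start = c(0, 5000, 10000),
                     end = c(5000, 10000, 15000))
  ov <- overlap_genes(wins, genes)
  expect_equal(ov$per_gene$n_windows, 3L)
  expect_equal(ov$per_gene$gene_id, "long")
})

test_that("overlap_genes matches a naive all-pairs oracle", {
  set.seed(19)
  for (i in 1:20) {
    nw <- sample(1:8, 1); ng <- sample(1:10, 1)
    wins <- data.frame(chrom = sample(c("c1", "c2"), nw, replace = TRUE),
                       start = sample(0:50, nw) * 100)
    wins$end <- wins$start + sample(1:10, nw, replace = TRUE) * 100
    genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                        symbol = paste0("g", seq_len(ng)),
                        chrom = sample(c("c1", "c2"), ng, replace = TRUE),
                        start = sample(0:50, ng, replace = TRUE) * 100,
                        stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(1:10, ng, replace = TRUE) * 100
    genes$strand <- "+"
    ov <- overlap_genes(wins, genes)
    naive <- character()
    for (w in seq_len(nw)) {
      for (g in seq_len(ng)) {
        if (wins$chrom[w] == genes$chrom[g] &&
            max(wins$start[w], genes$start[g]) <
            min(wins$end[w], genes$end[g])) {
          naive <- c(naive, genes$gene_id[g])
        }
      }
    }
    expect_equal(ov$gene_ids, sort(unique(naive)))
  }
})

test_that("GFF3 genes are read with explicit 1- to 0-based conversion", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", 1001, 2000, ".", "+", ".",
                     "ID=geneA;Name=SymA", sep = "\t"),
               paste("chr1", "src", "exon", 1001, 1500, ".", "+", ".",
                     "ID=exon1;Parent=geneA", sep = "\t"),
               paste("chr2", "src", "gene", 1, 500, ".", "-", ".",
                     "ID=geneB;Name=SymB", sep = "\t")), f)
  g <- read_genes(f)
  expect_equal(nrow(g), 2L)  # exon row dropped
  expect_equal(g$start, c(1000, 0))  # 1-based closed -> 0-based half-open
  expect_equal(g$end, c(2000, 500))
  expect_equal(g$symbol, c("SymA", "SymB"))
  expect_error(read_genes(withr::local_tempfile(fileext = ".xyz")),
               "cannot guess")
})

test_that("enrichment p-values equal the hypergeometric tail oracle", {
  # k=5, K=10, n=5, N=100: all term genes inside the study set
  bg <- paste0("g", 1:100)
  study <- bg[1:10]
  terms <- term_annotation_set(
    data.frame(term_id = "T1", term_name = "t one", namespace = "BP",
               stringsAsFactors = FALSE),
    list(T1 = bg[1:5]))
  enr <- fisher_enrichment(study, bg, terms)
  expect_equal(enr$p_fisher, hyper_tail_oracle(5, 10, 5, 100),
               tolerance = 1e-12)
  expect_equal(enr$k, 5L)
  # cross-check against the one-sided Fisher exact test
  ft <- stats::fisher.test(matrix(c(5, 5, 0, 90), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(enr$p_fisher, ft$p.value, tolerance = 1e-9)

  # zero study genes in the term -> p = 1
  t0 <- term_annotation_set(
    data.frame(term_id = "T0", term_name = "t zero", namespace = "BP"),
    list(T0 = bg[90:99]))
  expect_equal(fisher_enrichment(bg[1:5], bg, t0)$p_fisher, 1)

  # study equal to background -> p = 1 for every term
  expect_true(all(fisher_enrichment(bg, bg, terms)$p_fisher == 1))

  expect_error(fisher_enrichment(c("zz"), bg, terms), "subset")
})

test_that("random enrichment tables match the oracle and are stable", {
  set.seed(23)
  bg <- paste0("g", 1:60)
  for (i in 1:20) {
    study <- sample(bg, sample(5:30, 1))
    tg <- sample(bg, sample(3:20, 1))
    terms <- term_annotation_set(
      data.frame(term_id = "T", term_name = "t", namespace = "BP"),
      list(T = tg))
    enr <- fisher_enrichment(study, bg, terms)
    expect_equal(enr$p_fisher,
                 hyper_tail_oracle(length(intersect(study, tg)),
                                   length(study), length(tg), 60),
                 tolerance = 1e-12)
    # gene order never matters
    enr2 <- fisher_enrichment(sample(study), sample(bg), terms)
    expect_equal(enr2$p_fisher, enr$p_fisher)
    # adding a term gene to the study never increases the term's p
    extra <- setdiff(tg, study)
    if (length(extra)) {
      enr3 <- fisher_enrichment(c(study, extra[1]), bg, terms)
      expect_lte(enr3$p_fisher, enr$p_fisher + 1e-15)
    }
  }
})

test_that("term tables and min_term_size filtering behave", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tT1\tfirst term\tBP", "g2\tT1\tfirst term\tBP",
               "g3\tT2\tsecond term\tCC"), f)
  ts <- read_gene2term(f)
  expect_equal(nrow(ts$terms), 2L)
  expect_setequal(ts$genes$T1, c("g1", "g2"))
  enr <- fisher_enrichment("g1", c("g1", "g2", "g3"), ts,
                           min_term_size = 2L)
  expect_equal(enr$term_id, "T1")  # T2 too small to test
  # BH is applied within namespaces
  enr2 <- fisher_enrichment("g1", c("g1", "g2", "g3"), ts)
  expect_equal(enr2$p_adj, enr2$p_fisher)  # one term per namespace
})

test_that("OBO parsing and ancestor propagation build the closure", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:2", "name: left",
               "namespace: biological_process",
               "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:3", "name: right",
               "namespace: biological_process",
               "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:4", "name: leaf",
               "namespace: biological_process",
               "is_a: GO:2 ! left", "is_a: GO:3 ! right", "",
               "[Term]", "id: GO:9", "name: gone",
               "is_obsolete: true"), f)
  obo <- read_obo(f)
  expect_equal(nrow(obo$terms), 4L)  # obsolete term skipped
  expect_equal(nrow(obo$edges), 4L)

  direct <- term_annotation_set(
    obo$terms[obo$terms$term_id == "GO:4", ],
    list(`GO:4` = c("geneX")))
  prop <- propagate_terms(direct, obo$edges, terms = obo$terms)
  # diamond: geneX reaches the shared root exactly once
  expect_equal(prop$genes[["GO:1"]], "geneX")
  expect_setequal(names(prop$genes)[vapply(prop$genes, length,
                                           1L) > 0],
                  c("GO:1", "GO:2", "GO:3", "GO:4"))

  # no edges: annotations unchanged
  none <- propagate_terms(direct,
                          data.frame(child = character(),
                                     parent = character()))
  expect_equal(none$genes[["GO:4"]], "geneX")
  expect_equal(length(none$genes), 1L)

  # cycles are detected
  cyc <- data.frame(child = c("GO:2", "GO:1"), parent = c("GO:1", "GO:2"))
  expect_error(propagate_terms(direct, rbind(obo$edges, cyc)), "cycle")
})
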