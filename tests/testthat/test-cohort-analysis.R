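test_that("hypermutation labels follow the strict >1000 / <100 thresholds", {
  got <- label_hypermutation(c(A = 1500, B = 50, C = 500, D = 100,
                               E = 1000, F = 1001, G = 99))
  expect_identical(got$label,
                   c("hyper", "non_hyper", "excluded", "excluded",
                     "excluded", "hyper", "non_hyper"))
})

test_that("a symmetric gene yields normalized ratio 1 and Fisher p 1", {
  calls <- data.frame(gene = "G1",
                      sample_id = c(paste0("H", 1:5), paste0("N", 1:5)),
                      nmd_class = "elicit",
                      source_class = "Nonsense_Mutation",
                      stringsAsFactors = FALSE)
  maf <- data.frame(gene = "G1",
                    sample_id = c(paste0("H", 1:5), paste0("N", 1:5)),
                    variant_class = "Silent", stringsAsFactors = FALSE)
  labels <- label_hypermutation(stats::setNames(
    c(rep(2000, 5), rep(50, 5)), c(paste0("H", 1:5), paste0("N", 1:5))))
  got <- enrichment_per_gene(calls, maf, labels)
  expect_equal(got$a, 5L)
  expect_equal(got$d, 5L)
  expect_equal(got$normalized_ratio, 1)
  expect_equal(got$fisher_p, 1)
})

test_that("per-gene Fisher p matches direct hypergeometric enumeration", {
  # one gene carrying table (10, 1; 1, 10), plus a filler gene so cohort
  # totals differ from the gene's own margins
  h <- paste0("H", 1:40)
  n <- paste0("N", 1:40)
  mk_rows <- function(gene, n_hyper_eli, n_non_eli, n_hyper_sil, n_non_sil) {
    list(calls = data.frame(
           gene = gene,
           sample_id = c(sample(h, n_hyper_eli, TRUE), sample(n, n_non_eli, TRUE)),
           nmd_class = "elicit", source_class = "Nonsense_Mutation",
           stringsAsFactors = FALSE),
         maf = data.frame(
           gene = gene,
           sample_id = c(sample(h, n_hyper_sil, TRUE), sample(n, n_non_sil, TRUE)),
           variant_class = "Silent", stringsAsFactors = FALSE))
  }
  set.seed(1)
  g1 <- mk_rows("G1", 10, 1, 1, 10)
  g2 <- mk_rows("FILLER", 7, 6, 8, 9)
  labels <- label_hypermutation(stats::setNames(
    c(rep(1500, 40), rep(60, 40)), c(h, n)))
  got <- enrichment_per_gene(rbind(g1$calls, g2$calls),
                             rbind(g1$maf, g2$maf), labels)
  row <- got[got$gene == "G1", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(10, 1, 1, 10))
  expect_equal(row$fisher_p, fisher_enum_p(10, 1, 1, 10), tolerance = 1e-12)
  expect_gt(row$normalized_ratio, 1)
})

test_that("reported FDR equals an independent step-up computation", {
  sim <- simulate_cohort_calls(seed = 5, n_null_genes = 60, n_hyper = 20,
                               n_nonhyper = 120)
  got <- enrichment_per_gene(sim$calls, sim$maf,
                             label_hypermutation(sim$counts))
  expect_equal(got$fdr, bh_reference(got$fisher_p), tolerance = 1e-12)
})

test_that("planted permissive genes dominate the enrichment ranking", {
  sim <- simulate_cohort_calls(seed = 11)
  got <- enrichment_per_gene(sim$calls, sim$maf,
                             label_hypermutation(sim$counts))
  sig <- got$gene[got$fdr < 0.05]
  expect_true(all(sim$planted_genes %in% sig))
  expect_lte(sum(!(sig %in% sim$planted_genes)), 1L)
  expect_true(all(got$normalized_ratio[got$gene %in% sim$planted_genes] > 2))
})

test_that("gene-set over-representation matches the closed-form hypergeometric tail", {
  universe <- sprintf("G%03d", 1:100)
  hits <- universe[1:10]
  sets <- list(exact = hits,
               disjoint = universe[51:60],
               partial = c(universe[1:5], universe[61:65]))
  got <- geneset_overrepresentation(hits, universe, sets)
  expect_equal(got$p[got$set_name == "exact"],
               stats::dhyper(10, 10, 90, 10), tolerance = 1e-12)
  expect_equal(got$p[got$set_name == "disjoint"], 1)
  expect_equal(got$p[got$set_name == "partial"],
               sum(stats::dhyper(5:10, 10, 90, 10)), tolerance = 1e-12)
  expect_identical(got$set_name[1], "exact")
  expect_error(geneset_overrepresentation(hits, character(0), sets),
               "universe")
})

test_that("GMT files round-trip into named gene-set lists", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("SET_A\tdesc\tTP53\tNF1\tPTEN",
               "SET_B\tdesc\tAPC\tKDM6A"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("SET_A", "SET_B"))
  expect_identical(sets$SET_A, c("TP53", "NF1", "PTEN"))
  got <- geneset_overrepresentation("TP53", c("TP53", "NF1", "APC"), path)
  expect_equal(nrow(got), 2L)
})

test_that("TSG burden counts each sample once per cancer", {
  ann <- data.frame(sample_id = paste0("S", 1:10),
                    cancer = rep(c("CA1", "CA2"), each = 5),
                    stringsAsFactors = FALSE)
  calls <- data.frame(gene = c("TP53", "TP53", "NF1", "OTHER"),
                      sample_id = c("S1", "S1", "S2", "S6"),
                      nmd_class = c("elicit", "elicit", "elicit", "elicit"),
                      stringsAsFactors = FALSE)
  got <- tsg_burden(calls, c("TP53", "NF1"), ann)
  expect_equal(got$per_cancer$fraction[got$per_cancer$cancer == "CA1"], 0.4)
  expect_equal(got$per_cancer$fraction[got$per_cancer$cancer == "CA2"], 0)
  expect_equal(got$overall, 0.2)
  empty <- tsg_burden(calls[calls$gene == "NONE", ], "TP53", ann)
  expect_equal(empty$overall, 0)
})

test_that("deletion co-occurrence flags perfect association and degenerate strata", {
  samples <- paste0("S", 1:20)
  cnv <- matrix(0L, 1, 20, dimnames = list("G1", samples))
  cnv[1, 1:8] <- -2L
  calls <- data.frame(gene = "G1", sample_id = samples[1:8],
                      nmd_class = "elicit", stringsAsFactors = FALSE)
  got <- deletion_cooccurrence(calls, cnv)
  expect_equal(got$association$n_both, 8)
  expect_equal(got$association$n_neither, 12)
  expect_equal(got$association$fisher_p, fisher_enum_p(8, 0, 0, 12),
               tolerance = 1e-12)
  expect_true(got$rev_comparison$degenerate)

  no_del <- deletion_cooccurrence(
    calls, matrix(0L, 1, 20, dimnames = list("G1", samples)),
    revs = data.frame(gene = "G1", sample_id = samples[1:8],
                      nmd_class = "elicit", rev = runif(8),
                      stringsAsFactors = FALSE))
  expect_true(no_del$rev_comparison$degenerate)
})
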