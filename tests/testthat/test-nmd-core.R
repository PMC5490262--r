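test_that("apply_mutation edits the sequence and shifts downstream junctions", {
  model <- toy_model(make_clean_cds(100), c(150L, 150L))  # junction [150]
  snv <- apply_mutation(model, list(cds_pos = 10L, ref = "C", alt = "A",
                                    mut_type = "snv"))
  expect_equal(nchar(snv$sequence), 300L)
  expect_identical(snv$junction_offsets, 150L)
  expect_identical(substr(snv$sequence, 11, 11), "A")

  del <- apply_mutation(model, list(cds_pos = 10L, ref = "C", alt = "",
                                    mut_type = "del"))
  expect_equal(nchar(del$sequence), 299L)
  expect_identical(del$junction_offsets, 149L)

  ins <- apply_mutation(model, list(cds_pos = 200L, ref = "", alt = "GG",
                                    mut_type = "ins"))
  expect_equal(nchar(ins$sequence), 302L)
  expect_identical(ins$junction_offsets, 150L)

  expect_error(apply_mutation(model, list(cds_pos = 10L, ref = "A",
                                          alt = "C", mut_type = "snv")),
               "ref mismatch")
})

test_that("find_orf takes the most upstream start and the first in-frame stop", {
  expect_equal(find_orf("ATGAAATAA"),
               list(start_offset = 0L, ptc_start = 6L, terminated = TRUE))
  expect_equal(find_orf("CCATGTAA"),
               list(start_offset = 2L, ptc_start = 5L, terminated = TRUE))
  expect_equal(find_orf("ATGAAAAA"),
               list(start_offset = 0L, ptc_start = NA_integer_,
                    terminated = FALSE))
  expect_equal(find_orf("CCCCCC")$start_offset, NA_integer_)
  # widened start set picks the more upstream ATA
  expect_equal(find_orf("ATAATGTAA", start_codons = c("ATG", "ATA"))$start_offset, 0L)
})

test_that("a nonsense SNV deep in a two-exon gene is classified elicit with the expected distances", {
  # 402-nt CDS, junction [350], codon 84 CAA -> TAA via C>T at offset 249
  cds <- make_clean_cds(134, overrides = list(`84` = "CAA"))
  model <- toy_model(cds, c(350L, 52L))
  mut <- list(gene = "G1", sample_id = "S1", source_class = "Nonsense_Mutation",
              cds_pos = 249L, ref = "C", alt = "T", mut_type = "snv")
  call <- classify_nmd(model, mut)
  expect_identical(call$nmd_class, "elicit")
  expect_equal(call$ptc_start, 249L)
  expect_equal(call$d_start, 249L)
  expect_equal(call$d_junction, 98L)   # 350 - 252
  expect_true(call$rule_multi_exon && call$rule_junction && call$rule_startdist)
  expect_identical(oracle_classify(cds, model$junction_offsets, model$n_exons,
                                   249L, "C", "T", "snv"), "elicit")
})

test_that("single-exon PTCs escape and silent/nonstop terminal edits are non-PTC", {
  cds <- make_clean_cds(134, overrides = list(`84` = "CAA"))
  single <- toy_model(cds, 402L)
  call <- classify_nmd(single, list(cds_pos = 249L, ref = "C", alt = "T",
                                    mut_type = "snv"))
  expect_identical(call$nmd_class, "escape")
  expect_false(call$rule_multi_exon)

  model <- toy_model(cds, c(350L, 52L))
  silent <- classify_nmd(model, list(cds_pos = 401L, ref = "A", alt = "G",
                                     mut_type = "snv"))  # TAA -> TAG at end
  expect_identical(silent$nmd_class, "non_ptc")

  nonstop <- classify_nmd(model, list(cds_pos = 399L, ref = "T", alt = "C",
                                      mut_type = "snv"))  # TAA -> CAA
  expect_identical(nonstop$nmd_class, "non_ptc")
  expect_match(nonstop$flags, "nonstop")
})

test_that("an in-frame deletion that juxtaposes a PTC is elicit despite its source class", {
  # codons 80 TGC / 81 AAA: deleting GCA leaves T..AA = TAA at offset 237
  cds <- make_clean_cds(200, overrides = list(`80` = "TGC", `81` = "AAA"))
  model <- toy_model(cds, c(500L, 100L))
  mut <- list(gene = "G1", sample_id = "S1", source_class = "In_Frame_Del",
              cds_pos = 238L, ref = "GCA", alt = "", mut_type = "del")
  call <- classify_nmd(model, mut)
  expect_identical(call$nmd_class, "elicit")
  expect_equal(call$ptc_start, 237L)
  expect_equal(call$d_junction, 497L - 240L)
  expect_identical(oracle_classify(cds, model$junction_offsets, model$n_exons,
                                   238L, "GCA", "", "del"), "elicit")
})

test_that("frameshift deletions are classified identically by the brute-force oracle", {
  cds <- make_clean_cds(200)
  model <- toy_model(cds, c(300L, 300L))
  mut <- list(cds_pos = 27L, ref = substr(cds, 28, 28), alt = "",
              mut_type = "del")
  call <- classify_nmd(model, mut)
  expect_identical(call$nmd_class,
                   oracle_classify(cds, model$junction_offsets, model$n_exons,
                                   mut$cds_pos, mut$ref, mut$alt, "del"))
})

test_that("rule thresholds are strict: d_junction 50/51 and codon-resolved d_start bracket the rules", {
  sg <- simulate_genome(sim_config(seed = 2, n_genes = 0))
  sm <- simulate_mutations(sg$models, sim_config(seed = 2, n_genes = 0,
                                                 n_mutations = 0))
  cds_muts <- sm$truth[sm$truth$boundary, ]
  for (i in seq_len(nrow(cds_muts))) {
    tr <- cds_muts[i, ]
    call <- classify_nmd(sg$models[[tr$gene]],
                         list(cds_pos = tr$cds_pos, ref = tr$ref,
                              alt = tr$alt, mut_type = tr$mut_type))
    expect_identical(call$nmd_class, tr$true_class, label = tr$gene)
    if (!is.na(tr$d_junction_expected))
      expect_equal(call$d_junction, tr$d_junction_expected)
    if (!is.na(tr$d_start_expected))
      expect_equal(call$d_start, tr$d_start_expected)
  }
  # the decisive boundary values really are exercised
  expect_setequal(cds_muts$d_junction_expected[cds_muts$gene %in%
                    c("BND_JUNC50", "BND_JUNC51")], c(50L, 51L))
  expect_setequal(cds_muts$d_start_expected[grepl("BND_START", cds_muts$gene)],
                  c(174L, 198L, 201L))
})

test_that("moving the last junction downstream never flips elicit to escape", {
  classes <- vapply(seq(310L, 890L, by = 20L), function(J) {
    cds <- make_clean_cds(300, overrides = list(`101` = "CAA"))  # 900 nt
    model <- toy_model(cds, c(J, 900L - J))
    classify_nmd(model, list(cds_pos = 300L, ref = "C", alt = "T",
                             mut_type = "snv"))$nmd_class
  }, character(1))
  flips <- rle(classes)
  expect_identical(flips$values, c("escape", "elicit"))
  # strict >50: junction at 353 escapes, 354 elicits (PTC third base at 302)
  expect_identical(classes[which(seq(310L, 890L, by = 20L) == 350L)], "escape")
})

test_that("a zero-shift identity edit is non-PTC (wild-type neutrality)", {
  model <- toy_model(make_clean_cds(150), c(200L, 250L))
  call <- classify_nmd(model, list(cds_pos = 30L,
                                   ref = substr(model$cds_sequence, 31, 31),
                                   alt = substr(model$cds_sequence, 31, 31),
                                   mut_type = "snv"))
  expect_identical(call$nmd_class, "non_ptc")
})

test_that("classify_batch aggregates calls and cross-tabulates against source classes", {
  cds <- make_clean_cds(134, overrides = list(`84` = "CAA"))
  two_exon <- toy_model(cds, c(350L, 52L), gene = "G2")
  single <- toy_model(cds, 402L, gene = "G1")
  models <- list(G1 = single, G2 = two_exon)
  mutations <- data.frame(
    gene = c("G2", "G1", "G2", "G2", "G2"),
    sample_id = paste0("S", 1:5),
    cds_pos = c(249L, 249L, 401L, 399L, 150L),
    ref = c("C", "C", "A", "T", "G"),
    alt = c("T", "T", "G", "C", "C"),
    mut_type = "snv",
    source_class = c("Nonsense_Mutation", "Nonsense_Mutation", "Silent",
                     "Nonstop_Mutation", "Missense_Mutation"),
    stringsAsFactors = FALSE)
  got <- classify_batch(models, mutations)
  expect_equal(nrow(got$calls), 5L)
  tab <- table(got$calls$nmd_class)
  expect_equal(as.integer(tab[c("elicit", "escape", "non_ptc")]),
               c(1L, 1L, 3L))
  expect_equal(sum(got$crosstab), 5L)
  expect_equal(unname(got$crosstab["elicit", "Nonsense_Mutation"]), 1L)

  empty <- classify_batch(models, mutations[0, ])
  expect_equal(nrow(empty$calls), 0L)
})
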