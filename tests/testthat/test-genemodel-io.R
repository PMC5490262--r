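test_that("two-exon genes load with the expected spliced CDS and junction offsets", {
  cds <- make_clean_cds(100)  # 300 nt
  plus <- toy_model(cds, c(150L, 150L), "+", gene = "GP", chrom = "chrP")
  minus <- toy_model(cds, c(150L, 150L), "-", gene = "GM", chrom = "chrM")
  paths <- write_toy_genome(list(plus, minus))
  got <- load_gene_models(paths$gtf, paths$fasta)

  expect_setequal(names(got$models), c("GP", "GM"))
  expect_true(all(got$qc$verdict == "pass"))

  gp <- got$models$GP
  expect_equal(nchar(gp$cds_sequence), 300L)
  expect_identical(gp$cds_sequence, cds)
  expect_identical(gp$junction_offsets, 150L)
  expect_identical(gp$n_exons, 2L)

  # minus strand: spliced CDS is the revcomp of the concatenated genomic
  # intervals, junctions counted from the translation start
  gm <- got$models$GM
  expect_identical(gm$cds_sequence, cds)
  expect_identical(gm$junction_offsets, 150L)
  contig <- readLines(paths$fasta)
  contig <- contig[which(contig == ">chrM") + 1L]
  genomic_concat <- paste(substring(contig, gm$cds_exons$start + 1L,
                                    gm$cds_exons$end), collapse = "")
  expect_identical(gm$cds_sequence, rc(genomic_concat))
})

test_that("single-exon genes have no junction offsets", {
  m <- toy_model(make_clean_cds(100), 300L)
  expect_identical(m$junction_offsets, integer(0))
  expect_identical(m$n_exons, 1L)
})

test_that("canonical isoform selection takes the longest CDS with a deterministic tie-break", {
  mk <- function(tx, n_cod) toy_model(make_clean_cds(n_cod), 3L * n_cod,
                                      gene = "G", tx = tx)
  expect_identical(select_canonical(list(mk("T1", 100), mk("T2", 150)))$transcript_id, "T2")
  expect_identical(select_canonical(list(mk("T9", 100)))$transcript_id, "T9")
  expect_identical(select_canonical(list(mk("Tb", 100), mk("Ta", 100)))$transcript_id, "Ta")
  expect_error(select_canonical(list(mk("T1", 100),
                                     toy_model(make_clean_cds(50), 150L, gene = "H"))),
               "single gene")
})

test_that("wild-type QC flags internal stops, bad starts and missing stops", {
  mk <- function(s) toy_model(s, nchar(s))
  expect_identical(qc_filter(mk("ATGAAATAA"))$verdict, "pass")
  expect_identical(qc_filter(mk("ATGTAAAAATAA"))$verdict, "wt_ptc")
  expect_identical(qc_filter(mk("CTGAAATAA"))$verdict, "no_start")
  expect_identical(qc_filter(mk("ATGAAAAAA"))$verdict, "no_stop")
  expect_identical(qc_filter(mk("ATGAAAAAAC"))$verdict, "no_stop")
})

test_that("junction offsets match an independent re-derivation from exon intervals", {
  sg <- simulate_genome(sim_config(seed = 11, n_genes = 12,
                                   include_boundary = FALSE))
  for (m in sg$models) {
    lens <- m$cds_exons$end - m$cds_exons$start
    n <- length(lens)
    if (n == 1L) {
      expect_identical(m$junction_offsets, integer(0))
      next
    }
    plus_cum <- cumsum(lens)[-n]
    expected <- if (m$strand == "+") plus_cum
                else rev(sum(lens) - plus_cum)
    expect_identical(m$junction_offsets, as.integer(expected))
  }
})

test_that("GTF round-trip preserves CDS sequences and junction offsets", {
  dir <- withr::local_tempdir()
  sg <- simulate_genome(sim_config(seed = 3, n_genes = 6,
                                   include_boundary = FALSE), dir)
  reloaded <- load_gene_models(sg$gtf_path, sg$fasta_path)
  expect_setequal(names(reloaded$models), names(sg$models))
  for (g in names(sg$models)) {
    expect_identical(reloaded$models[[g]]$cds_sequence,
                     sg$models[[g]]$cds_sequence)
    expect_identical(reloaded$models[[g]]$junction_offsets,
                     sg$models[[g]]$junction_offsets)
  }
  # and once more through the package's own writer
  gtf2 <- file.path(dir, "again.gtf")
  write_gene_models_gtf(reloaded$models, gtf2)
  again <- load_gene_models(gtf2, sg$fasta_path)
  for (g in names(sg$models))
    expect_identical(again$models[[g]]$junction_offsets,
                     sg$models[[g]]$junction_offsets)
})

test_that("gene ids mapping to multiple loci are rejected as duplicate_id", {
  cds <- make_clean_cds(100)
  m1 <- toy_model(cds, c(150L, 150L), "+", gene = "GD", tx = "T1", chrom = "chrP")
  m2 <- toy_model(cds, 300L, "+", gene = "GD", tx = "T2", chrom = "chrM")
  paths <- write_toy_genome(list(m1, m2))
  got <- load_gene_models(paths$gtf, paths$fasta)
  expect_identical(got$qc$verdict, "duplicate_id")
  expect_length(got$models, 0L)
})

test_that("annotation referencing a contig absent from the FASTA is a hard error", {
  m <- toy_model(make_clean_cds(100), c(150L, 150L), chrom = "chrP")
  paths <- write_toy_genome(list(m))
  bad <- file.path(dirname(paths$gtf), "bad.gtf")
  writeLines(gsub("chrP", "chrMISSING", readLines(paths$gtf)), bad)
  expect_error(load_gene_models(bad, paths$fasta), "chrMISSING")
})

test_that("BED12 input is parsed to the same models as GTF", {
  cds <- make_clean_cds(100)
  m <- toy_model(cds, c(150L, 150L), "-", gene = "GB", tx = "TB", chrom = "chrB")
  paths <- write_toy_genome(list(m))
  bed <- file.path(dirname(paths$gtf), "toy.bed")
  ex <- m$cds_exons
  line_start <- min(ex$start)
  line_end <- max(ex$end)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                     m$chromosome, line_start, line_end, "GB|TB", m$strand,
                     line_start, line_end, nrow(ex),
                     paste0(paste(ex$end - ex$start, collapse = ","), ","),
                     paste0(paste(ex$start - line_start, collapse = ","), ",")),
             bed)
  got <- load_gene_models(bed, paths$fasta, format = "bed12")
  expect_identical(got$models$GB$cds_sequence, cds)
  expect_identical(got$models$GB$junction_offsets, 150L)
})
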