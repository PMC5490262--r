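# deterministic clean-ORF CDS: ATG + GCT filler + terminal stop, with
# selected codons overridden (names = 1-based codon index)
make_clean_cds <- function(n_codons, stop = "TAA", overrides = list()) {
  codons <- c("ATG", rep("GCT", n_codons - 2L), stop)
  for (nm in names(overrides)) codons[as.integer(nm)] <- overrides[[nm]]
  paste(codons, collapse = "")
}

# independent reverse complement (Biostrings, not package internals)
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# gene_model laid out on a virtual contig with fixed intron gaps
toy_model <- function(cds, tx_lens, strand = "+", gene = "G1",
                      tx = paste0(gene, ".t1"),
                      chrom = "chrT", gap = 100L, origin = 100L) {
  lens_g <- if (strand == "+") tx_lens else rev(tx_lens)
  starts <- origin + c(0L, utils::head(cumsum(lens_g + gap), -1L))
  ex <- data.frame(start = starts, end = starts + lens_g)
  gene_model(gene, tx, chrom, strand, ex, cds)
}

# materialize a contig sequence consistent with a toy_model (intergenic and
# intronic filler is "A")
contig_for <- function(model) {
  n <- max(model$cds_exons$end) + 50L
  chars <- strsplit(strrep("A", n), "")[[1]]
  lens <- model$cds_exons$end - model$cds_exons$start
  tx_order <- if (model$strand == "+") seq_along(lens) else rev(seq_along(lens))
  pos <- 0L
  for (j in tx_order) {
    chunk <- substr(model$cds_sequence, pos + 1L, pos + lens[j])
    if (model$strand == "-") chunk <- rc(chunk)
    chars[(model$cds_exons$start[j] + 1L):model$cds_exons$end[j]] <-
      strsplit(chunk, "")[[1]]
    pos <- pos + lens[j]
  }
  paste(chars, collapse = "")
}

# write FASTA + GTF for a set of toy models sharing distinct contigs
write_toy_genome <- function(models, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "toy.fa")
  gtf <- file.path(dir, "toy.gtf")
  lines <- unlist(lapply(models, function(m)
    c(paste0(">", m$chromosome), contig_for(m))))
  writeLines(lines, fasta)
  gtf_lines <- unlist(lapply(models, function(m) {
    sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; transcript_id \"%s\";",
            m$chromosome, m$cds_exons$start + 1L, m$cds_exons$end,
            m$strand, m$gene_id, m$transcript_id)
  }))
  writeLines(gtf_lines, gtf)
  list(fasta = fasta, gtf = gtf)
}

maf_text_header <- paste("Hugo_Symbol", "Chromosome", "Start_Position",
                         "End_Position", "Reference_Allele",
                         "Tumor_Seq_Allele2", "Variant_Classification",
                         "Tumor_Sample_Barcode", sep = "\t")

write_toy_maf <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.maf")
  writeLines(c(maf_text_header, rows), path)
  path
}

maf_line <- function(gene, chrom, start, end, ref, alt, class, sample) {
  paste(gene, chrom, start, end, ref, alt, class, sample, sep = "\t")
}

# two-sided Fisher p by direct hypergeometric enumeration (independent of
# stats::fisher.test): sum of point probabilities not exceeding the
# observed one (with the conventional 1e-7 relative slack)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  xs <- max(0, k - n2):min(m, k)
  dens <- stats::dhyper(xs, m, n2, k)
  min(1, sum(dens[dens <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)]))
}

# reference Benjamini-Hochberg step-up, written independently of p.adjust
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[ro]
}

# brute-force tie-aware pair-counting estimator P(mut > wt) + 0.5 P(mut = wt)
pair_count_z <- function(wt, mut) {
  wins <- 0
  for (m in mut) for (w in wt)
    wins <- wins + (m > w) + 0.5 * (m == w)
  wins / (length(wt) * length(mut))
}
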