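ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generators. A single integer
#' seed drives all generators deterministically: [simulate_genome()] seeds
#' the RNG at `seed`, [simulate_mutations()] at `seed + 1` and
#' [simulate_expression()] at `seed + 2`, so each stage is independently
#' reproducible.
#'
#' @param seed Master integer seed.
#' @param n_genes Number of random genes (boundary-fixture genes, when
#'   enabled, come on top).
#' @param exon_count_range Inclusive range of CDS exon counts.
#' @param exon_length_range Inclusive range of exon lengths (nt); the last
#'   exon is padded by 0-2 nt so the CDS is a codon multiple.
#' @param n_samples Cohort size.
#' @param n_mutations Size of the random mutation catalogue.
#' @param mutation_mix Named proportions over `nonsense_snv`,
#'   `frameshift_del`, `frameshift_ins`, `inframe_del`, `missense`,
#'   `silent`, `startloss`; must sum to 1.
#' @param nmd_effect_size Downward expression shift, in units of the
#'   background noise SD, applied to samples carrying an NMD-elicit
#'   mutation of the gene.
#' @param background_noise_sd Within-gene expression noise SD (log scale).
#' @param fraction_hyper Fraction of samples simulated as hypermutated by
#'   [simulate_cohort_calls()]-style generators.
#' @param planted_enriched_genes Named numeric vector: genes to enrich for
#'   NMD-elicit mutations in hypermutated samples, value = fold enrichment.
#' @param include_boundary Include the deterministic boundary-fixture genes
#'   and mutations (default `TRUE`).
#' @param planted_filter_cases Plant MAF records designed to be removed by
#'   each mutation filter (default `TRUE`).
#' @param codeletion_fraction Fraction of NMD-elicit mutant samples also
#'   given a copy-number deletion of the gene.
#' @param codeletion_extra_shift Additional downward expression shift (in
#'   noise-SD units) for co-deleted mutants.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L,
                       exon_count_range = c(2L, 6L),
                       exon_length_range = c(120L, 400L),
                       n_samples = 60L, n_mutations = 150L,
                       mutation_mix = c(nonsense_snv = 0.20,
                                        frameshift_del = 0.20,
                                        frameshift_ins = 0.15,
                                        inframe_del = 0.10,
                                        missense = 0.15,
                                        silent = 0.15,
                                        startloss = 0.05),
                       nmd_effect_size = 2,
                       background_noise_sd = 1,
                       fraction_hyper = 0.2,
                       planted_enriched_genes = numeric(0),
                       include_boundary = TRUE,
                       planted_filter_cases = TRUE,
                       codeletion_fraction = 0,
                       codeletion_extra_shift = 1) {
  stopifnot(abs(sum(mutation_mix) - 1) < 1e-8,
            exon_count_range[1] >= 1L,
            exon_length_range[1] >= 9L)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# draw n integers uniformly from [lo, hi], safe for degenerate ranges
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# clean ORF: ATG + sense codons + one terminal stop
random_cds <- function(n_codons, terminal_stop = NULL) {
  stopifnot(n_codons >= 3L)
  if (is.null(terminal_stop)) terminal_stop <- sample(STOP_CODONS, 1L)
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         terminal_stop)
}

# lay one gene out on its own contig; returns contig sequence + gene_model
build_sim_gene <- function(gene_id, transcript_id, contig, cds, tx_lens,
                           strand, intron_range = c(80L, 200L),
                           flank = 50L) {
  stopifnot(sum(tx_lens) == nchar(cds))
  k <- length(tx_lens)
  ends <- cumsum(tx_lens)
  starts <- c(0L, ends[-k])
  chunks <- substring(cds, starts + 1L, ends)
  introns <- if (k > 1L)
    vapply(seq_len(k - 1L),
           function(i) random_dna(sample_range(intron_range[1],
                                               intron_range[2])),
           character(1)) else character(0)
  pieces <- character(0)
  offsets <- integer(k)   # transcript-layout start of each exon chunk
  pos <- 0L
  for (i in seq_len(k)) {
    offsets[i] <- pos
    pieces <- c(pieces, chunks[i])
    pos <- pos + tx_lens[i]
    if (i < k) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  region_tx <- paste(pieces, collapse = "")
  rl <- nchar(region_tx)
  if (strand == "+") {
    region <- region_tx
    ex <- data.frame(start = offsets, end = offsets + tx_lens)
  } else {
    region <- revcomp(region_tx)
    ex <- data.frame(start = rl - (offsets + tx_lens), end = rl - offsets)
  }
  ex <- ex[order(ex$start), ]
  ex$start <- ex$start + flank
  ex$end <- ex$end + flank
  contig_seq <- paste0(random_dna(flank), region, random_dna(flank))
  model <- gene_model(gene_id, transcript_id, contig, strand, ex, cds)
  list(contig_seq = contig_seq, model = model)
}

# deterministic boundary-fixture definitions: gene geometry plus the planted
# nonsense/terminal-codon mutation and its class forced by construction.
# d_start values are constrained to codon multiples (the PTC is in frame
# with the start), so the escape-side start-distance fixtures sit at 174 and
# 198 nt, bracketing the >200 nt rule together with the 201 nt elicit case.
boundary_specs <- function() {
  list(
    list(gene = "BND_JUNC50", tx_lens = c(353L, 247L), strand = "+",
         kind = "nonsense", codon_index = 101L, truth = "escape",
         d_start = 300L, d_junction = 50L),
    list(gene = "BND_JUNC51", tx_lens = c(354L, 246L), strand = "-",
         kind = "nonsense", codon_index = 101L, truth = "elicit",
         d_start = 300L, d_junction = 51L),
    list(gene = "BND_START174", tx_lens = c(500L, 100L), strand = "+",
         kind = "nonsense", codon_index = 59L, truth = "escape",
         d_start = 174L, d_junction = 323L),
    list(gene = "BND_START198", tx_lens = c(500L, 100L), strand = "-",
         kind = "nonsense", codon_index = 67L, truth = "escape",
         d_start = 198L, d_junction = 299L),
    list(gene = "BND_START201", tx_lens = c(500L, 100L), strand = "+",
         kind = "nonsense", codon_index = 68L, truth = "elicit",
         d_start = 201L, d_junction = 296L),
    list(gene = "BND_SINGLE", tx_lens = 600L, strand = "+",
         kind = "nonsense", codon_index = 101L, truth = "escape",
         d_start = 300L, d_junction = NA_integer_),
    list(gene = "BND_TERM", tx_lens = c(300L, 300L), strand = "-",
         kind = "silent_stop", truth = "non_ptc",
         d_start = NA_integer_, d_junction = NA_integer_),
    list(gene = "BND_TERM", tx_lens = c(300L, 300L), strand = "-",
         kind = "nonstop", truth = "non_ptc",
         d_start = NA_integer_, d_junction = NA_integer_))
}

#' Simulate a synthetic genome and gene annotation
#'
#' Generates `n_genes` random multi-exon genes with clean open reading
#' frames (start ATG, single terminal stop, no internal in-frame stop) on
#' one synthetic contig each (`chrS1`, `chrS2`, ...), alternating strands,
#' plus (by default) seven deterministic boundary-fixture genes (`BND_*`)
#' whose geometry realizes the classification edge cases. Every gene passes
#' [qc_filter()] by construction. Output is byte-identical for a given
#' seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `genome.fa` and
#'   `genes.gtf` there.
#' @return List: `models` (named list of [gene_model()]), `genome`
#'   (`DNAStringSet`), and `fasta_path`/`gtf_path` when `dir` was given.
#' @export
simulate_genome <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  contigs <- character(0)
  models <- list()
  ci <- 0L
  for (i in seq_len(config$n_genes)) {
    ci <- ci + 1L
    k <- sample_range(config$exon_count_range[1], config$exon_count_range[2])
    lens <- sample_range(config$exon_length_range[1],
                         config$exon_length_range[2], k)
    lens[k] <- lens[k] + (3L - sum(lens) %% 3L) %% 3L
    cds <- random_cds(sum(lens) %/% 3L)
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("GENE%03d", i)
    g <- build_sim_gene(gid, paste0(gid, ".t1"), paste0("chrS", ci), cds,
                        lens, strand)
    contigs[paste0("chrS", ci)] <- g$contig_seq
    models[[gid]] <- g$model
  }
  if (config$include_boundary) {
    specs <- boundary_specs()
    done <- character(0)
    for (sp in specs) {
      if (sp$gene %in% done) next
      done <- c(done, sp$gene)
      ci <- ci + 1L
      n_cod <- sum(sp$tx_lens) %/% 3L
      cds <- random_cds(n_cod,
                        terminal_stop = if (sp$gene == "BND_TERM") "TAA" else NULL)
      if (identical(sp$kind, "nonsense")) {
        p <- 3L * (sp$codon_index - 1L)
        cds <- paste0(substr(cds, 1L, p), "CAA", substr(cds, p + 4L, nchar(cds)))
      }
      g <- build_sim_gene(sp$gene, paste0(sp$gene, ".t1"),
                          paste0("chrS", ci), cds, sp$tx_lens, sp$strand)
      contigs[paste0("chrS", ci)] <- g$contig_seq
      models[[sp$gene]] <- g$model
    }
  }
  genome <- Biostrings::DNAStringSet(contigs)
  out <- list(models = models, genome = genome)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$fasta_path <- file.path(dir, "genome.fa")
    out$gtf_path <- file.path(dir, "genes.gtf")
    Biostrings::writeXStringSet(genome, out$fasta_path)
    write_gene_models_gtf(models, out$gtf_path)
  }
  out
}

# transcript-space [start, end) bounds of each exon, translation order
tx_exon_bounds <- function(model) {
  lens <- model$cds_exons$end - model$cds_exons$start
  if (model$strand == "-") lens <- rev(lens)
  ends <- cumsum(lens)
  data.frame(start = c(0L, ends[-length(ends)]), end = ends)
}

# all single-substitution sites turning an internal codon into a stop
nonsense_sites <- function(cds) {
  k <- nchar(cds) %/% 3L
  out <- list()
  for (ci in 2:(k - 1L)) {
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    for (p in 1:3) {
      for (b in setdiff(BASES, substr(codon, p, p))) {
        new <- codon
        substr(new, p, p) <- b
        if (new %in% STOP_CODONS)
          out[[length(out) + 1L]] <-
            data.frame(cds_pos = 3L * (ci - 1L) + p - 1L,
                       ref = substr(codon, p, p), alt = b)
      }
    }
  }
  do.call(rbind, out)
}

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# random SNV constrained to be synonymous / missense (no stop gain or loss)
substitution_site <- function(cds, synonymous, max_tries = 500L) {
  n <- nchar(cds)
  for (t in seq_len(max_tries)) {
    pos <- sample(3:(n - 4L), 1L)   # 0-based, avoids first and last codon
    ci <- pos %/% 3L
    codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
    p <- pos - 3L * ci + 1L
    b <- sample(setdiff(BASES, substr(codon, p, p)), 1L)
    new <- codon
    substr(new, p, p) <- b
    if (new %in% STOP_CODONS) next
    same <- codon_aa(new) == codon_aa(codon)
    if (same == synonymous)
      return(data.frame(cds_pos = pos, ref = substr(codon, p, p), alt = b))
  }
  NULL
}

# random indel fully inside one exon (transcript space)
indel_site <- function(model, len, is_insertion) {
  b <- tx_exon_bounds(model)
  for (t in seq_len(50L)) {
    e <- sample(nrow(b), 1L)
    if (is_insertion) {
      if (b$end[e] - b$start[e] < 2L) next
      pos <- sample_range(b$start[e], b$end[e] - 2L)
      return(data.frame(cds_pos = pos, ref = "",
                        alt = random_dna(len)))
    }
    if (b$end[e] - b$start[e] < len) next
    pos <- sample_range(b$start[e], b$end[e] - len)
    return(data.frame(cds_pos = pos,
                      ref = substr(model$cds_sequence, pos + 1L, pos + len),
                      alt = ""))
  }
  NULL
}

maf_class_of <- c(nonsense_snv = "Nonsense_Mutation",
                  missense = "Missense_Mutation",
                  silent = "Silent",
                  frameshift_del = "Frame_Shift_Del",
                  frameshift_ins = "Frame_Shift_Ins",
                  inframe_del = "In_Frame_Del",
                  startloss = "Translation_Start_Site")

# CDS-space mutation -> one MAF row (forward-strand alleles)
maf_row <- function(model, sample_id, cds_pos, ref, alt, mut_type,
                    variant_class) {
  ref_len <- nchar(ref)
  g <- cds_to_genomic(model, cds_pos, mut_type, ref_len)
  fwd <- function(x) {
    if (!nzchar(x)) return("-")
    if (model$strand == "-") revcomp(x) else x
  }
  data.frame(Hugo_Symbol = model$gene_id,
             Chromosome = model$chromosome,
             Start_Position = g[["start"]], End_Position = g[["end"]],
             Reference_Allele = fwd(ref), Tumor_Seq_Allele2 = fwd(alt),
             Variant_Classification = variant_class,
             Tumor_Sample_Barcode = sample_id, stringsAsFactors = FALSE)
}

#' Simulate a mutation catalogue with ground-truth labels
#'
#' Draws a random catalogue over the simulated genes following the
#' configured mutation mix, labels every mutation's expected NMD class with
#' the independent [oracle_classify()] oracle (never the classifier), and
#' appends the deterministic boundary constructs (classes fixed by
#' construction) and, optionally, records planted to be removed by each
#' mutation filter.
#'
#' @param models Named list of [gene_model()]s from [simulate_genome()].
#' @param config The same [sim_config()].
#' @param genome Optional `DNAStringSet`; when given, planted splice/intron
#'   records carry the true genomic reference bases.
#' @return List: `maf` (data.frame in MAF column layout) and `truth`
#'   (data.frame: `maf_index`, `gene`, `sample_id`, `cds_pos`, `ref`, `alt`
#'   (translation orientation), `mut_type`, `variant_class`,
#'   `expected_verdict` (filter verdict), `true_class` (NMD class for kept
#'   records), `d_start_expected`, `d_junction_expected` (boundary
#'   fixtures only), `boundary` flag).
#' @export
simulate_mutations <- function(models, config = sim_config(),
                               genome = NULL) {
  set.seed(config$seed + 1L)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  rand_genes <- names(models)[!startsWith(names(models), "BND_")]
  maf <- list()
  truth <- list()
  add <- function(model, sample_id, cds_pos, ref, alt, mut_type,
                  variant_class, expected_verdict, true_class,
                  d_start = NA_integer_, d_junction = NA_integer_,
                  boundary = FALSE, maf_override = NULL) {
    row <- if (is.null(maf_override))
      maf_row(model, sample_id, cds_pos, ref, alt, mut_type, variant_class)
    else maf_override
    maf[[length(maf) + 1L]] <<- row
    truth[[length(truth) + 1L]] <<- data.frame(
      maf_index = length(maf), gene = row$Hugo_Symbol,
      sample_id = row$Tumor_Sample_Barcode,
      cds_pos = cds_pos, ref = ref, alt = alt, mut_type = mut_type,
      variant_class = variant_class, expected_verdict = expected_verdict,
      true_class = true_class, d_start_expected = d_start,
      d_junction_expected = d_junction, boundary = boundary,
      stringsAsFactors = FALSE)
  }

  ns_cache <- list()
  types <- sample(names(config$mutation_mix), config$n_mutations,
                  replace = TRUE, prob = config$mutation_mix)
  for (ty in types) {
    site <- NULL
    for (t in seq_len(50L)) {
      gid <- sample(rand_genes, 1L)
      m <- models[[gid]]
      site <- switch(ty,
        nonsense_snv = {
          if (is.null(ns_cache[[gid]]))
            ns_cache[[gid]] <- nonsense_sites(m$cds_sequence)
          s <- ns_cache[[gid]]
          if (is.null(s) || nrow(s) == 0L) NULL else s[sample(nrow(s), 1L), ]
        },
        missense = substitution_site(m$cds_sequence, synonymous = FALSE),
        silent = substitution_site(m$cds_sequence, synonymous = TRUE),
        frameshift_del = indel_site(m, sample(1:2, 1L), FALSE),
        frameshift_ins = indel_site(m, sample(1:2, 1L), TRUE),
        inframe_del = indel_site(m, 3L, FALSE),
        startloss = {
          p <- sample(0:2, 1L)
          cur <- substr(m$cds_sequence, p + 1L, p + 1L)
          data.frame(cds_pos = p, ref = cur,
                     alt = sample(setdiff(BASES, cur), 1L))
        })
      if (!is.null(site)) break
    }
    if (is.null(site)) next
    mut_type <- if (ty %in% c("frameshift_del", "inframe_del")) "del"
                else if (ty == "frameshift_ins") "ins" else "snv"
    cls <- oracle_classify(m$cds_sequence, m$junction_offsets, m$n_exons,
                           site$cds_pos, site$ref, site$alt, mut_type)
    add(m, sample(samples, 1L), site$cds_pos, site$ref, site$alt, mut_type,
        maf_class_of[[ty]], "kept", cls)
  }

  if (config$include_boundary && any(startsWith(names(models), "BND_"))) {
    for (sp in boundary_specs()) {
      m <- models[[sp$gene]]
      if (is.null(m)) next
      sid <- sample(samples, 1L)
      L <- nchar(m$cds_sequence)
      if (identical(sp$kind, "nonsense")) {
        p <- 3L * (sp$codon_index - 1L)
        add(m, sid, p, "C", "T", "snv", "Nonsense_Mutation", "kept",
            sp$truth, sp$d_start, sp$d_junction, boundary = TRUE)
      } else if (identical(sp$kind, "silent_stop")) {
        # terminal TAA -> TAG: stop stays at the CDS end
        add(m, sid, L - 1L, "A", "G", "snv", "Silent", "kept", sp$truth,
            boundary = TRUE)
      } else {
        # terminal TAA -> CAA: no stop before the sequence end
        add(m, sid, L - 3L, "T", "C", "snv", "Nonstop_Mutation", "kept",
            sp$truth, boundary = TRUE)
      }
    }
  }

  multi <- rand_genes[vapply(models[rand_genes], `[[`, integer(1),
                             "n_exons") >= 2L]
  if (config$planted_filter_cases && length(multi) > 0L) {
    m <- models[[multi[1L]]]
    sid <- samples[1L]
    contig_seq <- if (!is.null(genome)) as.character(genome[[m$chromosome]])
                  else NULL
    gseq <- function(s1, e1) {  # 1-based inclusive genomic substring
      if (is.null(contig_seq)) paste(rep("A", e1 - s1 + 1L), collapse = "")
      else substr(contig_seq, s1, e1)
    }
    # beyond the gene: excluded non-coding class
    pos <- max(m$cds_exons$end) + 10L
    add(m, sid, NA_integer_, NA_character_, NA_character_, "snv", "3'UTR",
        "class_excluded", NA_character_, maf_override = data.frame(
          Hugo_Symbol = m$gene_id, Chromosome = m$chromosome,
          Start_Position = pos, End_Position = pos,
          Reference_Allele = gseq(pos, pos), Tumor_Seq_Allele2 = "A",
          Variant_Classification = "3'UTR", Tumor_Sample_Barcode = sid,
          stringsAsFactors = FALSE))
    # deletion across the first exon-intron boundary
    e1 <- m$cds_exons$end[1L]
    add(m, sid, NA_integer_, NA_character_, NA_character_, "del",
        "Frame_Shift_Del", "splice_excluded", NA_character_,
        maf_override = data.frame(
          Hugo_Symbol = m$gene_id, Chromosome = m$chromosome,
          Start_Position = e1 - 1L, End_Position = e1 + 2L,
          Reference_Allele = gseq(e1 - 1L, e1 + 2L),
          Tumor_Seq_Allele2 = "-",
          Variant_Classification = "Frame_Shift_Del",
          Tumor_Sample_Barcode = sid, stringsAsFactors = FALSE))
    # reference allele disagreeing with the genome
    p0 <- m$cds_exons$start[1L] + 5L
    true_base <- if (is.null(contig_seq)) "A" else substr(contig_seq, p0 + 1L, p0 + 1L)
    wrong <- setdiff(BASES, true_base)[1L]
    add(m, sid, NA_integer_, NA_character_, NA_character_, "snv",
        "Missense_Mutation", "ref_mismatch", NA_character_,
        maf_override = data.frame(
          Hugo_Symbol = m$gene_id, Chromosome = m$chromosome,
          Start_Position = p0 + 1L, End_Position = p0 + 1L,
          Reference_Allele = wrong,
          Tumor_Seq_Allele2 = setdiff(BASES, c(true_base, wrong))[1L],
          Variant_Classification = "Missense_Mutation",
          Tumor_Sample_Barcode = sid, stringsAsFactors = FALSE))
    # mid-intron substitution: outside the CDS footprint
    ip <- m$cds_exons$end[1L] + 20L
    add(m, sid, NA_integer_, NA_character_, NA_character_, "snv",
        "Missense_Mutation", "outside_cds", NA_character_,
        maf_override = data.frame(
          Hugo_Symbol = m$gene_id, Chromosome = m$chromosome,
          Start_Position = ip, End_Position = ip,
          Reference_Allele = gseq(ip, ip), Tumor_Seq_Allele2 = "C",
          Variant_Classification = "Missense_Mutation",
          Tumor_Sample_Barcode = sid, stringsAsFactors = FALSE))
    # exact repeat of the first catalogue record
    if (length(maf) > 0L) {
      first <- maf[[1L]]
      add(models[[first$Hugo_Symbol]], first$Tumor_Sample_Barcode,
          NA_integer_, NA_character_, NA_character_,
          "snv", first$Variant_Classification, "duplicate", NA_character_,
          maf_override = first)
    }
  }

  list(maf = do.call(rbind, maf), truth = do.call(rbind, truth))
}

#' Simulate expression, copy-number and sample-annotation tables
#'
#' Wild-type expression of gene g in sample s is
#' `N(mu_g, background_noise_sd)` with gene means `mu_g ~ N(8, 1)`
#' (log-scale, RSEM-like). Samples carrying an NMD-elicit mutation of a
#' gene (per the truth table) are shifted down by
#' `nmd_effect_size * background_noise_sd`; co-deleted mutants (when
#' `codeletion_fraction > 0`) additionally by
#' `codeletion_extra_shift * background_noise_sd` and receive a GISTIC-style
#' copy-number call of -2.
#'
#' @param models Named list of [gene_model()]s.
#' @param truth Truth table from [simulate_mutations()] (only rows with
#'   `expected_verdict == "kept"` and `true_class == "elicit"` shift
#'   expression).
#' @param config The same [sim_config()].
#' @return List: `expr` (genes x samples matrix), `cnv` (same shape,
#'   integers in -2..0 here), `annotations` (data.frame `sample_id`,
#'   `cancer`, `cluster`, `msi`).
#' @export
simulate_expression <- function(models, truth, config = sim_config()) {
  set.seed(config$seed + 2L)
  genes <- names(models)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  mu <- stats::rnorm(length(genes), mean = 8, sd = 1)
  expr <- matrix(stats::rnorm(length(genes) * length(samples),
                              mean = rep(mu, times = length(samples)),
                              sd = config$background_noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))
  cnv <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  eli <- truth[truth$expected_verdict == "kept" &
               !is.na(truth$true_class) & truth$true_class == "elicit", ,
               drop = FALSE]
  pairs <- unique(eli[, c("gene", "sample_id")])
  pairs <- pairs[pairs$gene %in% genes & pairs$sample_id %in% samples, ,
                 drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]
    s <- pairs$sample_id[i]
    expr[g, s] <- expr[g, s] -
      config$nmd_effect_size * config$background_noise_sd
    if (config$codeletion_fraction > 0 &&
        stats::runif(1) < config$codeletion_fraction) {
      cnv[g, s] <- -2L
      expr[g, s] <- expr[g, s] -
        config$codeletion_extra_shift * config$background_noise_sd
    }
  }
  annotations <- data.frame(sample_id = samples, cancer = "SYNTH",
                            cluster = NA_character_,
                            msi = stats::runif(length(samples)) < 0.1,
                            stringsAsFactors = FALSE)
  list(expr = expr, cnv = cnv, annotations = annotations)
}

#' Simulate a cohort-level call/label set with planted enrichment
#'
#' Generates a mutation catalogue at the call level for the hypermutation
#' enrichment analysis: hypermutated samples draw their per-sample mutation
#' count above 1,000 and non-hypermutated samples below 100; each mutation
#' is assigned a gene uniformly and a class (NMD-elicit / silent-class /
#' other) by fixed probabilities. In hypermutated samples the planted genes
#' have their NMD-elicit probability multiplied by `fold`.
#'
#' @param seed Integer seed.
#' @param n_null_genes,n_planted Numbers of null and planted genes.
#' @param fold Fold enrichment of elicit mutations for planted genes in the
#'   hypermutated stratum.
#' @param n_hyper,n_nonhyper Sample counts per stratum.
#' @param hyper_range,nonhyper_range Per-sample mutation count ranges.
#' @param p_elicit,p_silent Baseline class probabilities (rest is "other").
#' @return List: `calls` (`gene`, `sample_id`, `nmd_class`,
#'   `source_class`), `maf` (`gene`, `sample_id`, `variant_class`),
#'   `counts` (per-sample totals), `planted_genes`.
#' @export
simulate_cohort_calls <- function(seed = 1L, n_null_genes = 200L,
                                  n_planted = 5L, fold = 5,
                                  n_hyper = 50L, n_nonhyper = 800L,
                                  hyper_range = c(1500L, 2500L),
                                  nonhyper_range = c(50L, 95L),
                                  p_elicit = 0.1, p_silent = 0.3) {
  set.seed(seed)
  stopifnot(fold * p_elicit + p_silent < 1)
  genes <- c(sprintf("PERM%02d", seq_len(n_planted)),
             sprintf("NULL%03d", seq_len(n_null_genes)))
  planted <- genes[seq_len(n_planted)]
  sids <- c(sprintf("H%03d", seq_len(n_hyper)),
            sprintf("N%03d", seq_len(n_nonhyper)))
  n_per <- c(sample_range(hyper_range[1], hyper_range[2], n_hyper),
             sample_range(nonhyper_range[1], nonhyper_range[2], n_nonhyper))
  sample_id <- rep(sids, n_per)
  is_hyper <- rep(c(rep(TRUE, n_hyper), rep(FALSE, n_nonhyper)), n_per)
  N <- length(sample_id)
  gene <- sample(genes, N, replace = TRUE)
  pe <- ifelse(is_hyper & gene %in% planted, fold * p_elicit, p_elicit)
  u <- stats::runif(N)
  class <- ifelse(u < pe, "elicit",
                  ifelse(u < pe + p_silent, "silent", "other"))
  calls <- data.frame(
    gene = gene, sample_id = sample_id,
    nmd_class = ifelse(class == "elicit", "elicit", "non_ptc"),
    source_class = ifelse(class == "elicit", "Nonsense_Mutation",
                          ifelse(class == "silent", "Silent",
                                 "Missense_Mutation")),
    stringsAsFactors = FALSE)
  maf <- data.frame(gene = gene, sample_id = sample_id,
                    variant_class = calls$source_class,
                    stringsAsFactors = FALSE)
  counts <- data.frame(sample_id = sids, n = n_per, stringsAsFactors = FALSE)
  list(calls = calls, maf = maf, counts = counts, planted_genes = planted)
}

#' Write a MAF data.frame to TSV
#' @param maf data.frame in MAF column layout ([simulate_mutations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a genes-by-samples matrix as TSV
#'
#' Layout used for expression and copy-number tables: first column `gene`,
#' remaining columns one per sample.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @return `write_matrix_tsv`: `path`, invisibly. `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
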