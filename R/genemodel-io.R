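#' Construct a gene model
#'
#' A `gene_model` holds one gene's canonical transcript: its ordered CDS exon
#' intervals on the genome, the spliced CDS in translation orientation, and
#' the offsets of the exon-exon junctions internal to the CDS.
#'
#' Coordinates are 0-based half-open throughout. `junction_offsets[k]` is the
#' number of spliced-CDS nucleotides strictly upstream of the k-th junction,
#' counted in translation orientation, so for a minus-strand gene the offsets
#' run from the translation start (highest genomic coordinate) downstream.
#'
#' @param gene_id,transcript_id Identifier strings.
#' @param chromosome Contig name as it appears in the annotation.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons data.frame with integer columns `start`, `end`
#'   (0-based half-open, ascending genomic order, non-overlapping).
#' @param cds_sequence Spliced CDS in translation orientation (for strand
#'   `-`, the reverse complement of the concatenated genomic intervals).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chromosome, strand,
                       cds_exons, cds_sequence) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(cds_exons),
            all(c("start", "end") %in% names(cds_exons)))
  cds_exons <- cds_exons[order(cds_exons$start), c("start", "end"), drop = FALSE]
  cds_exons$start <- as.integer(cds_exons$start)
  cds_exons$end <- as.integer(cds_exons$end)
  rownames(cds_exons) <- NULL
  lens <- cds_exons$end - cds_exons$start
  if (any(lens <= 0L))
    stop("gene ", gene_id, ": empty or inverted CDS exon interval")
  cds_sequence <- toupper(as.character(cds_sequence))
  if (nchar(cds_sequence) != sum(lens))
    stop("gene ", gene_id, ": CDS sequence length ", nchar(cds_sequence),
         " != sum of exon lengths ", sum(lens))
  n <- nrow(cds_exons)
  tx_lens <- if (strand == "+") lens else rev(lens)
  junction_offsets <- if (n > 1L) as.integer(cumsum(tx_lens)[-n]) else integer(0)
  structure(list(gene_id = as.character(gene_id),
                 transcript_id = as.character(transcript_id),
                 chromosome = as.character(chromosome),
                 strand = strand,
                 cds_exons = cds_exons,
                 cds_sequence = cds_sequence,
                 junction_offsets = junction_offsets,
                 n_exons = n),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s\n", x$gene_id,
              x$transcript_id, x$chromosome,
              paste0(x$cds_exons$start[1], "-", x$cds_exons$end[x$n_exons]),
              x$strand))
  cat(sprintf("  CDS %d nt over %d exon(s); junctions at [%s]\n",
              nchar(x$cds_sequence), x$n_exons,
              paste(x$junction_offsets, collapse = ", ")))
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

norm_chrom <- function(x) sub("^chr", "", as.character(x))

read_genome <- function(fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# extract spliced, translation-oriented CDS from a genome DNAStringSet
extract_cds <- function(genome, chromosome, strand, cds_exons) {
  if (!chromosome %in% names(genome))
    stop("chromosome '", chromosome, "' referenced by annotation is not ",
         "present in the FASTA")
  chrom_seq <- genome[[chromosome]]
  if (max(cds_exons$end) > length(chrom_seq))
    stop("CDS interval beyond end of contig '", chromosome, "'")
  chunks <- vapply(seq_len(nrow(cds_exons)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, cds_exons$start[i] + 1L,
                                    cds_exons$end[i]))
  }, character(1))
  spliced <- paste(chunks, collapse = "")
  if (strand == "-") revcomp(spliced) else spliced
}

#' Select the canonical isoform of a gene
#'
#' The canonical transcript is the one with the longest CDS; ties are broken
#' by the lexicographically smallest transcript identifier so the choice is
#' deterministic.
#'
#' @param models Non-empty list of [gene_model()] objects sharing a `gene_id`.
#' @return A single `gene_model`.
#' @export
select_canonical <- function(models) {
  stopifnot(length(models) >= 1L)
  gid <- unique(vapply(models, `[[`, character(1), "gene_id"))
  if (length(gid) != 1L)
    stop("select_canonical() requires models of a single gene, got: ",
         paste(gid, collapse = ", "))
  lens <- vapply(models, function(m) nchar(m$cds_sequence), integer(1))
  cand <- which(lens == max(lens))
  if (length(cand) > 1L) {
    txs <- vapply(models[cand], `[[`, character(1), "transcript_id")
    cand <- cand[order(txs)[1L]]
  }
  models[[cand]]
}

#' Wild-type quality control of a gene model
#'
#' Applies the wild-type pre-filters: genes whose CDS already contains an
#' in-frame stop before the final codon (`wt_ptc`), does not begin with ATG
#' (`no_start`), or does not end with an in-frame stop codon (`no_stop`) are
#' excluded from classification.
#'
#' @param model A [gene_model()].
#' @return data.frame with columns `gene_id`, `transcript_id`, `verdict`
#'   (one of `pass`, `wt_ptc`, `no_start`, `no_stop`), `detail`.
#' @export
qc_filter <- function(model) {
  s <- model$cds_sequence
  n <- nchar(s)
  k <- n %/% 3L
  codons <- if (k > 0L) substring(s, seq(1L, by = 3L, length.out = k),
                                  seq(3L, by = 3L, length.out = k)) else character(0)
  # codons ending strictly before position n are internal
  internal <- if (n %% 3L == 0L && k > 0L) codons[-k] else codons
  verdict <- "pass"
  detail <- ""
  if (any(internal %in% STOP_CODONS)) {
    verdict <- "wt_ptc"
    detail <- paste0("in-frame stop at offset ",
                     3L * (which(internal %in% STOP_CODONS)[1L] - 1L))
  } else if (n < 3L || substr(s, 1L, 3L) != "ATG") {
    verdict <- "no_start"
    detail <- paste0("CDS begins with ", substr(s, 1L, 3L))
  } else if (n %% 3L != 0L || !(codons[k] %in% STOP_CODONS)) {
    verdict <- "no_stop"
    detail <- if (n %% 3L != 0L) "CDS length not a multiple of 3"
              else paste0("final codon ", codons[k])
  }
  data.frame(gene_id = model$gene_id, transcript_id = model$transcript_id,
             verdict = verdict, detail = detail, stringsAsFactors = FALSE)
}

parse_gtf_transcripts <- function(annotation_path) {
  gr <- rtracklayer::import(annotation_path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features found in ", annotation_path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id))
    stop("GTF CDS records lack gene_id/transcript_id attributes")
  df <- data.frame(gene_id = mc$gene_id, transcript_id = mc$transcript_id,
                   chromosome = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  split(df, df$transcript_id)
}

parse_bed12_transcripts <- function(annotation_path) {
  gr <- rtracklayer::import(annotation_path, format = "bed")
  if (is.null(S4Vectors::mcols(gr)$blocks))
    stop("BED input lacks block (BED12) columns")
  out <- list()
  for (i in seq_along(gr)) {
    nm <- S4Vectors::mcols(gr)$name[i]
    ids <- strsplit(nm, "|", fixed = TRUE)[[1]]
    gid <- ids[1L]
    tid <- if (length(ids) > 1L) ids[2L] else ids[1L]
    blocks <- S4Vectors::mcols(gr)$blocks[[i]]
    # blocks are 1-based relative to the (1-based) line start
    abs_start <- GenomicRanges::start(gr)[i] - 1L  # 0-based line start
    out[[tid]] <- data.frame(
      gene_id = gid, transcript_id = tid,
      chromosome = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      start = abs_start + IRanges::start(blocks) - 1L,
      end = abs_start + IRanges::end(blocks),
      stringsAsFactors = FALSE)
  }
  out
}

#' Load gene models from annotation + genome
#'
#' Reads CDS exon structures from a GTF (feature type `CDS`) or BED12 file,
#' extracts the spliced CDS of every transcript from the genome FASTA,
#' selects one canonical isoform per gene (longest CDS, ties by transcript
#' id), and applies the wild-type quality filters. Genes whose transcripts
#' map to more than one contig or strand are rejected with verdict
#' `duplicate_id`.
#'
#' @param annotation_path Path to a GTF or BED12 file.
#' @param fasta_path Path to the genome FASTA (contig names must cover the
#'   annotation).
#' @param format `"auto"` (by file extension), `"gtf"` or `"bed12"`.
#' @return A list with `models` (named list of passing [gene_model()]s, by
#'   `gene_id`) and `qc` (data.frame, one row per gene: `gene_id`,
#'   `transcript_id`, `verdict` in `pass`/`wt_ptc`/`no_start`/`no_stop`/
#'   `duplicate_id`, `detail`).
#' @export
load_gene_models <- function(annotation_path, fasta_path,
                             format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed[0-9]*$", annotation_path, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  genome <- read_genome(fasta_path)
  txs <- if (format == "gtf") parse_gtf_transcripts(annotation_path)
         else parse_bed12_transcripts(annotation_path)

  tx_models <- lapply(txs, function(df) {
    chrom <- unique(df$chromosome)
    strand <- unique(df$strand)
    if (length(chrom) != 1L || length(strand) != 1L)
      stop("transcript ", df$transcript_id[1L],
           " spans multiple contigs or strands")
    gene_model(df$gene_id[1L], df$transcript_id[1L], chrom, strand,
               df[, c("start", "end")],
               extract_cds(genome, chrom, strand,
                           df[order(df$start), c("start", "end")]))
  })

  by_gene <- split(tx_models,
                   vapply(tx_models, `[[`, character(1), "gene_id"))
  models <- list()
  qc <- vector("list", length(by_gene))
  for (i in seq_along(by_gene)) {
    gid <- names(by_gene)[i]
    g <- by_gene[[i]]
    locus <- unique(vapply(g, function(m)
      paste0(m$chromosome, m$strand), character(1)))
    if (length(locus) != 1L) {
      qc[[i]] <- data.frame(gene_id = gid,
                            transcript_id = g[[1L]]$transcript_id,
                            verdict = "duplicate_id",
                            detail = "gene id maps to multiple loci",
                            stringsAsFactors = FALSE)
      next
    }
    canon <- select_canonical(g)
    rep <- qc_filter(canon)
    qc[[i]] <- rep
    if (rep$verdict == "pass") models[[gid]] <- canon
  }
  list(models = models, qc = do.call(rbind, qc))
}

#' Write gene models back to GTF
#'
#' One `CDS` feature per exon, with `gene_id` and `transcript_id` attributes
#' and correct reading-frame phase. Re-loading the file with
#' [load_gene_models()] reproduces the CDS sequences and junction offsets.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$cds_exons
    lens <- ex$end - ex$start
    tx_order <- if (m$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    cum <- c(0L, cumsum(lens[tx_order]))[seq_len(nrow(ex))]
    phase <- (3L - cum %% 3L) %% 3L
    phase_genomic <- integer(nrow(ex))
    phase_genomic[tx_order] <- phase
    data.frame(chromosome = m$chromosome, start = ex$start, end = ex$end,
               strand = m$strand, phase = phase_genomic,
               gene_id = m$gene_id, transcript_id = m$transcript_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chromosome,
    IRanges::IRanges(df$start + 1L, df$end),
    strand = df$strand,
    source = "nmdcall", type = "CDS", score = NA_real_,
    phase = as.integer(df$phase),
    gene_id = df$gene_id, transcript_id = df$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write a QC report TSV
#'
#' @param qc data.frame as returned in `load_gene_models()$qc`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
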