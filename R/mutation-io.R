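#' Read a TCGA-style MAF file
#'
#' Accepts the standard tab-separated Mutation Annotation Format dialect.
#' Column names are matched case-insensitively; `Start_position` /
#' `Start_Position` spellings are both accepted. Chromosome names are
#' normalized by stripping a leading `chr` prefix.
#'
#' @param path Path to a MAF (TSV with header).
#' @return data.frame with columns `gene`, `chromosome`, `start`, `end`
#'   (1-based inclusive), `ref_allele`, `alt_allele` (`"-"` for pure
#'   insertions/deletions), `variant_class`, `sample_id`, in file order.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  lower <- tolower(names(df))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(tolower(cand), lower)
      if (!is.na(i)) return(i)
    }
    stop("MAF is missing mandatory column '", c(...)[1L], "'")
  }
  out <- data.frame(
    gene = df[[pick("Hugo_Symbol", "gene")]],
    chromosome = norm_chrom(df[[pick("Chromosome")]]),
    start = as.integer(df[[pick("Start_Position", "Start_position")]]),
    end = as.integer(df[[pick("End_Position", "End_position")]]),
    ref_allele = toupper(df[[pick("Reference_Allele")]]),
    alt_allele = toupper(df[[pick("Tumor_Seq_Allele2", "Tumor_Allele")]]),
    variant_class = normalize_class(df[[pick("Variant_Classification")]]),
    sample_id = df[[pick("Tumor_Sample_Barcode", "sample_id")]],
    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad))
    stop("malformed MAF record at data line ", bad[1L],
         ": invalid start/end coordinates")
  out
}

maf_mut_type <- function(ref, alt) {
  if (ref == "-" && alt != "-") return("ins")
  if (alt == "-" && ref != "-") return("del")
  if (ref == "-" && alt == "-") return("invalid")
  if (nchar(ref) == 1L && nchar(alt) == 1L) return("snv")
  "delins"
}

# exon index (ascending genomic order) containing 0-based genomic pos, or NA
exon_index <- function(model, g0) {
  ex <- model$cds_exons
  i <- which(ex$start <= g0 & g0 < ex$end)
  if (length(i) == 1L) i else NA_integer_
}

# 0-based genomic position -> 0-based spliced-CDS offset (translation orient.)
genomic_to_cds <- function(model, g0) {
  i <- exon_index(model, g0)
  if (is.na(i)) return(NA_integer_)
  ex <- model$cds_exons
  lens <- ex$end - ex$start
  cum0 <- c(0L, cumsum(lens))
  plus_off <- cum0[i] + (g0 - ex$start[i])
  total <- sum(lens)
  if (model$strand == "+") as.integer(plus_off) else as.integer(total - 1L - plus_off)
}

# 0-based spliced-CDS offset -> 0-based genomic position
cds_offset_to_genomic <- function(model, toff) {
  ex <- model$cds_exons
  lens <- ex$end - ex$start
  total <- sum(lens)
  stopifnot(toff >= 0L, toff < total)
  plus_off <- if (model$strand == "+") toff else total - 1L - toff
  cum0 <- c(0L, cumsum(lens))
  i <- findInterval(plus_off, cum0, rightmost.closed = FALSE)
  as.integer(ex$start[i] + plus_off - cum0[i])
}

#' Map a CDS-space mutation back to genomic MAF coordinates
#'
#' Inverse of the lift performed by [filter_and_map()]; used to verify that
#' coordinate mapping round-trips on both strands.
#'
#' @param model A [gene_model()].
#' @param cds_pos 0-based spliced-CDS offset (for insertions, the flanked
#'   base after which the insertion occurs in translation orientation).
#' @param mut_type One of `"snv"`, `"del"`, `"ins"`, `"delins"`.
#' @param ref_len Length of the reference allele (0 for insertions).
#' @return Named integer vector `c(start, end)`, 1-based inclusive, matching
#'   MAF conventions (flanking bases for insertions).
#' @export
cds_to_genomic <- function(model, cds_pos, mut_type, ref_len) {
  g0 <- cds_offset_to_genomic(model, cds_pos)
  if (mut_type == "ins") {
    if (model$strand == "+") return(c(start = g0 + 1L, end = g0 + 2L))
    return(c(start = g0, end = g0 + 1L))
  }
  if (model$strand == "+")
    return(c(start = g0 + 1L, end = g0 + as.integer(ref_len)))
  c(start = g0 + 2L - as.integer(ref_len), end = g0 + 1L)
}

#' Filter MAF records and lift them into spliced-CDS coordinates
#'
#' Applies the mutation-level exclusion filters and maps each surviving
#' mutation into 0-based spliced-CDS coordinates in translation orientation.
#' Filters, in order of precedence per record:
#' \describe{
#'   \item{class_excluded}{`Variant_Classification` in `Splice_Site`,
#'     `3'UTR`, `5'UTR`, `IGR`, `Intron`, `RNA`.}
#'   \item{gene_unknown}{gene symbol with no loaded (QC-passing) model.}
#'   \item{duplicate}{exact repeat of an earlier record (same gene, sample,
#'     coordinates and alleles); the first occurrence is processed, extras
#'     are dropped.}
#'   \item{outside_cds / splice_excluded}{genomic footprint entirely outside
#'     the CDS exons, or not contained in a single CDS exon (touching an
#'     exon-intron boundary).}
#'   \item{ref_mismatch}{reference allele disagreeing with the CDS sequence.}
#' }
#' Alleles are taken as reported on the forward genomic strand and are
#' reverse-complemented for minus-strand genes. Distinct mutations in the
#' same gene and sample are all retained.
#'
#' @param records data.frame from [read_maf()].
#' @param models Named list of [gene_model()]s (by `gene_id`), e.g.
#'   `load_gene_models()$models`.
#' @return List with `mutations` (data.frame: `gene`, `sample_id`, `cds_pos`,
#'   `ref`, `alt` (translation orientation, `""` where empty), `mut_type`,
#'   `source_class`, `maf_index`) and `report` (data.frame: `index`,
#'   `verdict`, `detail`; one row per input record).
#' @export
filter_and_map <- function(records, models) {
  n <- nrow(records)
  verdict <- character(n)
  detail <- character(n)
  keep <- vector("list", n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  model_chroms <- vapply(models, function(m) norm_chrom(m$chromosome),
                         character(1))

  for (i in seq_len(n)) {
    r <- records[i, ]
    if (r$variant_class %in% EXCLUDED_CLASSES) {
      verdict[i] <- "class_excluded"
      detail[i] <- r$variant_class
      next
    }
    m <- models[[r$gene]]
    if (is.null(m)) {
      verdict[i] <- "gene_unknown"
      detail[i] <- "no loaded model for gene symbol"
      next
    }
    key <- paste(r$gene, r$sample_id, r$chromosome, r$start, r$end,
                 r$ref_allele, r$alt_allele, sep = "\r")
    if (!is.null(seen[[key]])) {
      verdict[i] <- "duplicate"
      detail[i] <- paste0("repeat of record ", seen[[key]])
      next
    }
    seen[[key]] <- i
    if (norm_chrom(m$chromosome) != r$chromosome) {
      verdict[i] <- "outside_cds"
      detail[i] <- "record on a different contig than the gene model"
      next
    }
    type <- maf_mut_type(r$ref_allele, r$alt_allele)
    if (type == "invalid") {
      verdict[i] <- "outside_cds"
      detail[i] <- "both alleles empty"
      next
    }
    if (type == "ins") {
      i1 <- exon_index(m, r$start - 1L)
      i2 <- exon_index(m, r$end - 1L)
    } else {
      i1 <- exon_index(m, r$start - 1L)
      i2 <- exon_index(m, r$end - 1L)
    }
    if (is.na(i1) && is.na(i2)) {
      ex <- m$cds_exons
      overlaps <- any(r$start - 1L < ex$end & r$end > ex$start)
      if (overlaps) {
        verdict[i] <- "splice_excluded"
        detail[i] <- "footprint straddles an exon boundary"
      } else {
        verdict[i] <- "outside_cds"
        detail[i] <- "footprint outside CDS exons"
      }
      next
    }
    if (is.na(i1) || is.na(i2) || i1 != i2) {
      verdict[i] <- "splice_excluded"
      detail[i] <- "footprint not contained in a single CDS exon"
      next
    }
    anchor0 <- if (m$strand == "+") r$start - 1L else r$end - 1L
    cds_pos <- genomic_to_cds(m, anchor0)
    ref <- if (r$ref_allele == "-") "" else r$ref_allele
    alt <- if (r$alt_allele == "-") "" else r$alt_allele
    if (m$strand == "-") {
      if (nzchar(ref)) ref <- revcomp(ref)
      if (nzchar(alt)) alt <- revcomp(alt)
    }
    if (type != "ins") {
      extracted <- substr(m$cds_sequence, cds_pos + 1L, cds_pos + nchar(ref))
      if (!identical(extracted, ref)) {
        verdict[i] <- "ref_mismatch"
        detail[i] <- paste0("MAF ref ", ref, " vs CDS ", extracted)
        next
      }
    }
    verdict[i] <- "kept"
    keep[[i]] <- data.frame(gene = r$gene, sample_id = r$sample_id,
                            cds_pos = cds_pos, ref = ref, alt = alt,
                            mut_type = type,
                            source_class = r$variant_class,
                            maf_index = i, stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
  if (is.null(mutations))
    mutations <- data.frame(gene = character(0), sample_id = character(0),
                            cds_pos = integer(0), ref = character(0),
                            alt = character(0), mut_type = character(0),
                            source_class = character(0),
                            maf_index = integer(0), stringsAsFactors = FALSE)
  list(mutations = mutations,
       report = data.frame(index = seq_len(n), verdict = verdict,
                           detail = detail, stringsAsFactors = FALSE))
}

#' Per-sample counts of filtered (kept) mutations
#'
#' Convenience tally feeding [label_hypermutation()].
#'
#' @param report `filter_and_map()` output (or any data.frame with a
#'   `sample_id` column when `report` already holds kept mutations).
#' @param records The MAF data.frame the report refers to.
#' @return data.frame `sample_id`, `n`.
#' @export
count_filtered_mutations <- function(report, records) {
  kept <- records$sample_id[report$report$verdict == "kept"]
  tab <- table(kept)
  data.frame(sample_id = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
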