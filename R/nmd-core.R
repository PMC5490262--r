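#' Apply a mutation to a spliced CDS
#'
#' Edits the wild-type spliced CDS and recomputes the exon-exon junction
#' offsets in mutated coordinates: every junction strictly downstream of the
#' edit point is shifted by the net length change. Mutations whose footprint
#' crosses a junction are excluded upstream, so no junction can be deleted.
#'
#' @param model A [gene_model()] that passed QC.
#' @param mut One kept mutation: a list or one-row data.frame with `cds_pos`,
#'   `ref`, `alt`, `mut_type` as produced by [filter_and_map()].
#' @return List with `sequence` (mutated CDS), `junction_offsets` (mutated
#'   coordinates) and `shift` (`nchar(alt) - nchar(ref)`).
#' @export
apply_mutation <- function(model, mut) {
  s <- model$cds_sequence
  n <- nchar(s)
  pos <- as.integer(mut$cds_pos)
  ref <- as.character(mut$ref)
  alt <- as.character(mut$alt)
  type <- as.character(mut$mut_type)
  shift <- nchar(alt) - nchar(ref)
  if (type == "ins") {
    stopifnot(pos >= 0L, pos < n - 1L)
    sequence <- paste0(substr(s, 1L, pos + 1L), alt, substr(s, pos + 2L, n))
  } else {
    stopifnot(pos >= 0L, pos + nchar(ref) <= n)
    found <- substr(s, pos + 1L, pos + nchar(ref))
    if (!identical(found, ref))
      stop("internal ref mismatch in ", model$gene_id, " at CDS offset ", pos,
           ": expected ", ref, ", CDS has ", found)
    sequence <- paste0(substr(s, 1L, pos), alt,
                       substr(s, pos + nchar(ref) + 1L, n))
  }
  j <- model$junction_offsets
  if (length(j) && type %in% c("del", "delins")) {
    inside <- j > pos & j < pos + nchar(ref)
    if (any(inside))
      stop("mutation footprint deletes across a junction (should have been ",
           "splice-excluded upstream)")
  }
  j <- ifelse(j > pos, j + shift, j)
  list(sequence = sequence, junction_offsets = as.integer(j),
       shift = as.integer(shift))
}

#' Locate the relocated open reading frame
#'
#' Scans the (possibly mutated) spliced CDS for the most upstream start
#' codon, then walks in-frame triplets until the first stop codon
#' (TGA/TAA/TAG).
#'
#' @param seq DNA string.
#' @param start_codons Codons accepted as starts (default `"ATG"`).
#' @return List `start_offset` (0-based, or `NA` if no start codon),
#'   `ptc_start` (0-based offset of the first in-frame stop, or `NA`),
#'   `terminated` (`FALSE` when translation runs off the end of the
#'   sequence).
#' @export
find_orf <- function(seq, start_codons = "ATG") {
  n <- nchar(seq)
  start <- NA_integer_
  for (codon in start_codons) {
    hit <- regexpr(codon, seq, fixed = TRUE)[1L]
    if (hit > 0L) start <- min(start, hit - 1L, na.rm = TRUE)
  }
  if (is.na(start))
    return(list(start_offset = NA_integer_, ptc_start = NA_integer_,
                terminated = FALSE))
  first <- seq.int(start + 1L, n - 2L, by = 3L)
  if (start + 3L > n) first <- integer(0)
  codons <- substring(seq, first, first + 2L)
  stop_i <- which(codons %in% STOP_CODONS)
  if (length(stop_i) == 0L)
    return(list(start_offset = start, ptc_start = NA_integer_,
                terminated = FALSE))
  list(start_offset = start, ptc_start = as.integer(first[stop_i[1L]] - 1L),
       terminated = TRUE)
}

#' Classify one mutation under the NMD rules
#'
#' Builds the mutated spliced CDS, relocates the ORF from the most upstream
#' start codon, finds the first in-frame termination codon, and applies the
#' three positional rules:
#' \itemize{
#'   \item the gene has at least two exons;
#'   \item the termination codon lies more than `junction_min_bp` (default
#'     50) nt upstream of the last exon-exon junction;
#'   \item the termination codon lies more than `start_min_bp` (default 200)
#'     nt downstream of the start codon.
#' }
#' A termination codon is premature (a PTC) iff its third base is not the
#' final base of the mutated sequence. A mutation whose PTC satisfies all
#' three rules is `elicit`; with a PTC but a failed rule, `escape`; with no
#' PTC (normal stop, no stop at all, or no start codon), `non_ptc`.
#'
#' Distances follow fixed anchors: `d_start` is first-base-of-start to
#' first-base-of-PTC; `d_junction` is from the base after the PTC's third
#' base to the last junction, both in mutated coordinates.
#'
#' @param model A QC-passing [gene_model()].
#' @param mut One kept mutation (see [apply_mutation()]), with `gene`,
#'   `sample_id` and `source_class` fields if available.
#' @param config An [nmd_config()].
#' @return One-row data.frame: `gene`, `sample_id`, `source_class`,
#'   `nmd_class` (`elicit`/`escape`/`non_ptc`), `start_offset`, `ptc_start`,
#'   `d_start`, `d_junction`, `rule_multi_exon`, `rule_junction`,
#'   `rule_startdist` (logical, `NA` when no PTC), `flags` (comma-separated
#'   subset of `no_start_codon`, `nonstop`, `start_relocated`).
#' @export
classify_nmd <- function(model, mut, config = nmd_config()) {
  ms <- apply_mutation(model, mut)
  orf <- find_orf(ms$sequence, config$start_codons)
  flags <- character(0)
  nmd_class <- NA_character_
  d_start <- NA_integer_
  d_junction <- NA_integer_
  r_multi <- NA
  r_junc <- NA
  r_start <- NA

  if (is.na(orf$start_offset)) {
    nmd_class <- "non_ptc"
    flags <- "no_start_codon"
  } else {
    if (orf$start_offset > 0L) flags <- c(flags, "start_relocated")
    if (!orf$terminated) {
      nmd_class <- "non_ptc"
      flags <- c(flags, "nonstop")
    } else {
      ptc_end <- orf$ptc_start + 2L
      d_start <- orf$ptc_start - orf$start_offset
      if (length(ms$junction_offsets))
        d_junction <- ms$junction_offsets[length(ms$junction_offsets)] -
          (ptc_end + 1L)
      premature <- ptc_end != nchar(ms$sequence) - 1L
      if (!premature) {
        nmd_class <- "non_ptc"
      } else {
        r_multi <- model$n_exons >= 2L
        r_junc <- !is.na(d_junction) && d_junction > config$junction_min_bp
        r_start <- d_start > config$start_min_bp
        nmd_class <- if (r_multi && r_junc && r_start) "elicit" else "escape"
      }
    }
  }
  data.frame(
    gene = model$gene_id,
    sample_id = if (!is.null(mut$sample_id)) as.character(mut$sample_id) else NA_character_,
    source_class = if (!is.null(mut$source_class)) as.character(mut$source_class) else NA_character_,
    nmd_class = nmd_class,
    start_offset = orf$start_offset,
    ptc_start = orf$ptc_start,
    d_start = d_start,
    d_junction = d_junction,
    rule_multi_exon = r_multi,
    rule_junction = r_junc,
    rule_startdist = r_start,
    flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Classify a batch of mutations
#'
#' Runs [classify_nmd()] over a kept-mutation table and cross-tabulates the
#' NMD verdicts against the original MAF variant classes, the package's
#' analogue of comparing the re-annotation with the source annotation.
#' Multiple mutations within one gene and sample are classified
#' independently against the wild-type CDS.
#'
#' @param models Named list of [gene_model()]s by `gene_id`.
#' @param mutations data.frame of kept mutations ([filter_and_map()]).
#' @param config An [nmd_config()].
#' @return List with `calls` (one [classify_nmd()] row per mutation) and
#'   `crosstab` (`table` of `nmd_class` by `source_class`).
#' @export
classify_batch <- function(models, mutations, config = nmd_config()) {
  if (nrow(mutations) == 0L) {
    empty <- classify_nmd(models[[1L]],
                          list(cds_pos = 0L, ref = substr(models[[1L]]$cds_sequence, 1, 1),
                               alt = substr(models[[1L]]$cds_sequence, 1, 1),
                               mut_type = "snv"), config)[0, ]
    return(list(calls = empty,
                crosstab = table(nmd_class = character(0),
                                 source_class = character(0))))
  }
  rows <- lapply(seq_len(nrow(mutations)), function(i) {
    classify_nmd(models[[mutations$gene[i]]], mutations[i, ], config)
  })
  calls <- do.call(rbind, rows)
  list(calls = calls,
       crosstab = table(nmd_class = calls$nmd_class,
                        source_class = calls$source_class))
}

#' Write NMD calls to TSV
#'
#' @param calls data.frame of calls from [classify_batch()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
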