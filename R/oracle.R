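#' Brute-force reference classification of a CDS mutation
#'
#' An independent re-derivation of the NMD verdict used by the test suite as
#' an oracle against [classify_nmd()]. It works on raw inputs only (CDS
#' string, junction offsets, exon count, CDS-space mutation), edits the
#' sequence as a character vector, finds the most upstream start codon by an
#' explicit scan, walks triplets one by one to the first stop, and checks
#' the three rules directly. It deliberately shares no code with the
#' classifier.
#'
#' @param cds Wild-type spliced CDS string (translation orientation).
#' @param junction_offsets Ascending integer junction offsets (wild-type
#'   coordinates).
#' @param n_exons Number of CDS exons.
#' @param cds_pos 0-based CDS offset of the mutation (flanked base for
#'   insertions).
#' @param ref,alt Alleles in translation orientation (`""` where empty).
#' @param mut_type `"snv"`, `"del"`, `"ins"` or `"delins"`.
#' @param start_codons,junction_min_bp,start_min_bp Rule parameters, as in
#'   [nmd_config()].
#' @return `"elicit"`, `"escape"` or `"non_ptc"`.
#' @export
oracle_classify <- function(cds, junction_offsets, n_exons, cds_pos, ref,
                            alt, mut_type, start_codons = "ATG",
                            junction_min_bp = 50, start_min_bp = 200) {
  chars <- strsplit(cds, "")[[1]]
  ref_chars <- if (nzchar(ref)) strsplit(ref, "")[[1]] else character(0)
  alt_chars <- if (nzchar(alt)) strsplit(alt, "")[[1]] else character(0)
  if (mut_type == "ins") {
    new_chars <- append(chars, alt_chars, after = cds_pos + 1L)
  } else {
    if (!identical(chars[(cds_pos + 1L):(cds_pos + length(ref_chars))],
                   ref_chars))
      stop("oracle: ref does not match CDS")
    head_part <- if (cds_pos > 0L) chars[1:cds_pos] else character(0)
    tail_start <- cds_pos + length(ref_chars) + 1L
    tail_part <- if (tail_start <= length(chars))
      chars[tail_start:length(chars)] else character(0)
    new_chars <- c(head_part, alt_chars, tail_part)
  }
  shift <- length(alt_chars) - length(ref_chars)
  junctions <- integer(0)
  for (j in junction_offsets)
    junctions <- c(junctions, if (j > cds_pos) j + shift else j)

  n <- length(new_chars)
  stops <- c("TGA", "TAA", "TAG")
  start0 <- NA_integer_
  i <- 1L
  while (i <= n - 2L) {
    codon <- paste(new_chars[i:(i + 2L)], collapse = "")
    if (codon %in% start_codons) { start0 <- i - 1L; break }
    i <- i + 1L
  }
  if (is.na(start0)) return("non_ptc")
  ptc0 <- NA_integer_
  i <- start0 + 1L
  while (i + 2L <= n) {
    codon <- paste(new_chars[i:(i + 2L)], collapse = "")
    if (codon %in% stops) { ptc0 <- i - 1L; break }
    i <- i + 3L
  }
  if (is.na(ptc0)) return("non_ptc")
  ptc_end0 <- ptc0 + 2L
  if (ptc_end0 == n - 1L) return("non_ptc")
  d_start <- ptc0 - start0
  ok_junction <- FALSE
  if (length(junctions) > 0L) {
    d_junction <- junctions[length(junctions)] - (ptc_end0 + 1L)
    ok_junction <- d_junction > junction_min_bp
  }
  if (n_exons >= 2L && ok_junction && d_start > start_min_bp) "elicit"
  else "escape"
}
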