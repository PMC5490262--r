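#' Classifier configuration
#'
#' Bundles the tunable thresholds of the NMD classification rules.
#'
#' @param junction_min_bp Minimum distance (nt, exclusive) from the base after
#'   the PTC's third base to the last exon-exon junction for the junction rule
#'   to hold ("more than 50 bp upstream"). Default 50.
#' @param start_min_bp Minimum distance (nt, exclusive) from the first base of
#'   the start codon to the first base of the PTC for the start-distance rule
#'   to hold ("more than 200 bp downstream"). Default 200.
#' @param start_codons Character vector of codons accepted as translation
#'   starts when relocating the ORF. Default `"ATG"`; `c("ATG", "ATA")` widens
#'   the scan to the non-canonical ATA initiator.
#' @return A list of class `nmd_config`.
#' @examples
#' nmd_config()
#' nmd_config(start_codons = c("ATG", "ATA"))
#' @export
nmd_config <- function(junction_min_bp = 50L, start_min_bp = 200L,
                       start_codons = "ATG") {
  stopifnot(is.numeric(junction_min_bp), length(junction_min_bp) == 1L,
            is.numeric(start_min_bp), length(start_min_bp) == 1L,
            is.character(start_codons), length(start_codons) >= 1L,
            all(nchar(start_codons) == 3L))
  structure(list(junction_min_bp = as.integer(junction_min_bp),
                 start_min_bp = as.integer(start_min_bp),
                 start_codons = toupper(start_codons)),
            class = "nmd_config")
}

STOP_CODONS <- c("TGA", "TAA", "TAG")

# MAF variant classes excluded from classification (splice / non-coding)
EXCLUDED_CLASSES <- c("Splice_Site", "3'UTR", "5'UTR", "IGR", "Intron", "RNA")

# MAF classes treated as neutral ("silent") in hypermutation enrichment
SILENT_CLASSES <- c("Silent", "3'UTR", "5'UTR", "Intron", "RNA")

# normalize typographic primes so 3'UTR / 3'UTR compare equal
normalize_class <- function(x) {
  x <- gsub("′", "'", x)
  gsub("’", "'", x)
}
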