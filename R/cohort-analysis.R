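#' Label samples by hypermutation status
#'
#' Hypermutated samples carry more than 1,000 filtered mutations;
#' non-hypermutated ones fewer than 100. Samples in between are excluded
#' from enrichment contrasts.
#'
#' @param counts data.frame with `sample_id` and `n` (filtered mutation
#'   counts, see [count_filtered_mutations()]), or a named numeric vector.
#' @return data.frame: `sample_id`, `n_filtered_mutations`, `label`
#'   (`hyper`/`non_hyper`/`excluded`).
#' @export
label_hypermutation <- function(counts) {
  if (!is.data.frame(counts))
    counts <- data.frame(sample_id = names(counts), n = as.numeric(counts),
                         stringsAsFactors = FALSE)
  label <- ifelse(counts$n > 1000, "hyper",
                  ifelse(counts$n < 100, "non_hyper", "excluded"))
  data.frame(sample_id = counts$sample_id,
             n_filtered_mutations = as.integer(counts$n),
             label = label, stringsAsFactors = FALSE)
}

#' Per-gene enrichment of NMD-elicit mutations in hypermutated samples
#'
#' For every gene, counts NMD-elicit mutations (from the calls) and
#' neutral "silent-class" mutations (`Silent`, `3'UTR`, `5'UTR`, `Intron`,
#' `RNA`, from the unfiltered MAF) in the hypermutated and non-hypermutated
#' strata, forming the 2x2 table (a, b; c, d). The enrichment measure is a
#' double quotient normalized by the cohort-wide totals of each mutation
#' type per stratum (with 1/2 pseudo-counts), which masks the global excess
#' of, and negative selection on, NMD-elicit mutations:
#' \deqn{((a+\frac12)/(A_h+\frac12)) / ((b+\frac12)/(S_h+\frac12))}
#' divided by the analogous non-hyper quotient. Significance is a two-sided
#' Fisher exact test on (a, b; c, d), Benjamini-Hochberg adjusted across
#' genes.
#'
#' @param calls NMD call data.frame (`gene`, `sample_id`, `nmd_class`).
#' @param maf MAF-style data.frame (`gene`, `sample_id`, `variant_class`)
#'   providing the silent-class counts.
#' @param labels [label_hypermutation()] output.
#' @param mode `"mutations"` counts mutations (default); `"samples"` counts
#'   mutated samples.
#' @return data.frame: `gene`, `a`, `b`, `c`, `d`, `normalized_ratio`,
#'   `fisher_p`, `fdr`, sorted by `fdr`.
#' @export
enrichment_per_gene <- function(calls, maf, labels,
                                mode = c("mutations", "samples")) {
  mode <- match.arg(mode)
  lab <- stats::setNames(labels$label, labels$sample_id)
  eli <- calls[calls$nmd_class == "elicit" &
               lab[calls$sample_id] %in% c("hyper", "non_hyper"), ,
               drop = FALSE]
  sil <- maf[normalize_class(maf$variant_class) %in% SILENT_CLASSES &
             lab[maf$sample_id] %in% c("hyper", "non_hyper"), ,
             drop = FALSE]
  if (mode == "samples") {
    eli <- eli[!duplicated(eli[, c("gene", "sample_id")]), , drop = FALSE]
    sil <- sil[!duplicated(sil[, c("gene", "sample_id")]), , drop = FALSE]
  }
  eli_h <- lab[eli$sample_id] == "hyper"
  sil_h <- lab[sil$sample_id] == "hyper"
  genes <- sort(unique(c(eli$gene, sil$gene)))
  cnt <- function(df, hyper_mask, hyper) {
    t <- table(factor(df$gene[hyper_mask == hyper], levels = genes))
    as.integer(t)
  }
  a <- cnt(eli, eli_h, TRUE)
  b <- cnt(sil, sil_h, TRUE)
  c_ <- cnt(eli, eli_h, FALSE)
  d <- cnt(sil, sil_h, FALSE)
  A_h <- sum(a); S_h <- sum(b); A_n <- sum(c_); S_n <- sum(d)
  q_h <- ((a + 0.5) / (A_h + 0.5)) / ((b + 0.5) / (S_h + 0.5))
  q_n <- ((c_ + 0.5) / (A_n + 0.5)) / ((d + 0.5) / (S_n + 0.5))
  ratio <- q_h / q_n
  p <- vapply(seq_along(genes), function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, a = a, b = b, c = c_, d = d,
                    normalized_ratio = ratio, fisher_p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  out[order(out$fdr, out$fisher_p), ]
}

#' Read a GMT gene-set file
#'
#' @param path Tab-separated GMT: set name, description, then member genes.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Gene-set over-representation of significant genes
#'
#' One-sided hypergeometric upper-tail test of the overlap between the
#' significant gene list and each set (restricted to the universe),
#' Benjamini-Hochberg adjusted across sets.
#'
#' @param significant Character vector of hit genes (subset of `universe`).
#' @param universe Character vector of all tested genes.
#' @param sets Named list of gene sets ([read_gmt()]) or a GMT path.
#' @return data.frame: `set_name`, `overlap`, `set_size`, `universe_size`,
#'   `hit_count`, `p`, `fdr`, sorted by `p`.
#' @export
geneset_overrepresentation <- function(significant, universe, sets) {
  if (is.character(sets) && length(sets) == 1L && file.exists(sets))
    sets <- read_gmt(sets)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  significant <- intersect(unique(significant), universe)
  U <- length(universe)
  H <- length(significant)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(s, significant))
    p <- stats::phyper(k - 1, H, U - H, length(s), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               universe_size = U, hit_count = H, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Per-cancer burden of NMD-elicit mutations in tumour suppressor genes
#'
#' Fraction of samples per cancer carrying at least one NMD-elicit mutation
#' in a tumour suppressor gene, plus the pooled overall fraction.
#'
#' @param calls NMD call data.frame (`gene`, `sample_id`, `nmd_class`).
#' @param tsg_list Character vector of tumour suppressor gene symbols.
#' @param annotations data.frame `sample_id`, `cancer` (the denominator is
#'   all annotated samples).
#' @return List `per_cancer` (data.frame `cancer`, `n_affected`,
#'   `n_samples`, `fraction`) and `overall` (single pooled fraction).
#' @export
tsg_burden <- function(calls, tsg_list, annotations) {
  stopifnot(length(tsg_list) > 0L)
  hit_samples <- unique(calls$sample_id[calls$nmd_class == "elicit" &
                                        calls$gene %in% tsg_list])
  per <- lapply(split(annotations$sample_id, annotations$cancer),
                function(s) {
    data.frame(n_affected = length(intersect(s, hit_samples)),
               n_samples = length(s))
  })
  per_cancer <- do.call(rbind, per)
  per_cancer <- data.frame(cancer = rownames(per_cancer), per_cancer,
                           row.names = NULL, stringsAsFactors = FALSE)
  per_cancer$fraction <- per_cancer$n_affected / per_cancer$n_samples
  list(per_cancer = per_cancer,
       overall = sum(per_cancer$n_affected) / sum(per_cancer$n_samples))
}

#' Co-occurrence of NMD-elicit mutations and locus deletions
#'
#' Per gene, tests association between carrying an NMD-elicit mutation and
#' carrying a copy-number deletion across samples (two-sided Fisher exact
#' test, BH-adjusted across genes), and compares the REV of NMD-elicit
#' mutants with versus without a co-occurring deletion (one-sided MWW,
#' co-deleted hypothesized lower).
#'
#' @param calls NMD call data.frame.
#' @param cnv Genes x samples thresholded copy-number matrix (-2..2).
#' @param revs Optional [rev_table()] output for the elicit calls.
#' @param deletion_threshold Deletion call when CNV value <= this (default
#'   -1; set -2 for deep deletions only).
#' @return List `association` (data.frame `gene`, `n_both`, `n_mut_only`,
#'   `n_del_only`, `n_neither`, `fisher_p`, `fdr`) and `rev_comparison`
#'   (list with medians and `p_mww`, or `degenerate = TRUE` when a stratum
#'   is empty).
#' @export
deletion_cooccurrence <- function(calls, cnv, revs = NULL,
                                  deletion_threshold = -1L) {
  samples <- colnames(cnv)
  eli <- calls[calls$nmd_class == "elicit", , drop = FALSE]
  genes <- sort(intersect(unique(eli$gene), rownames(cnv)))
  rows <- lapply(genes, function(g) {
    mut <- samples %in% eli$sample_id[eli$gene == g]
    del <- cnv[g, samples] <= deletion_threshold
    tab <- matrix(c(sum(mut & del), sum(mut & !del),
                    sum(!mut & del), sum(!mut & !del)), nrow = 2,
                  byrow = TRUE)
    data.frame(gene = g, n_both = tab[1, 1], n_mut_only = tab[1, 2],
               n_del_only = tab[2, 1], n_neither = tab[2, 2],
               fisher_p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  association <- do.call(rbind, rows)
  if (!is.null(association))
    association$fdr <- stats::p.adjust(association$fisher_p, method = "BH")

  rev_comparison <- list(degenerate = TRUE, p_mww = NA_real_,
                         median_codel = NA_real_, median_nodel = NA_real_)
  if (!is.null(revs)) {
    rv <- revs[revs$nmd_class == "elicit" & !is.na(revs$rev) &
               revs$gene %in% rownames(cnv) &
               revs$sample_id %in% samples, , drop = FALSE]
    if (nrow(rv)) {
      codel <- mapply(function(g, s) cnv[g, s] <= deletion_threshold,
                      rv$gene, rv$sample_id)
      if (any(codel) && any(!codel)) {
        rev_comparison <- list(
          degenerate = FALSE,
          p_mww = suppressWarnings(
            stats::wilcox.test(rv$rev[codel], rv$rev[!codel],
                               alternative = "less")$p.value),
          median_codel = stats::median(rv$rev[codel]),
          median_nodel = stats::median(rv$rev[!codel]))
      }
    }
  }
  list(association = association, rev_comparison = rev_comparison)
}
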