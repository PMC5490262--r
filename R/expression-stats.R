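#' Build the mutation- and CNV-free background expression set
#'
#' The background for a gene in a cancer is the expression of that gene in
#' same-cancer samples carrying no somatic mutation of any class in the gene
#' and, when copy-number calls are supplied, a thresholded CNV value of 0.
#' When a cluster label is supplied (and present in the annotations), the
#' background is further restricted to that expression cluster.
#'
#' @param gene Gene identifier (must be a row of `expr`).
#' @param cancer Cancer label to condition on.
#' @param expr Numeric matrix of log-scale expression, genes x samples.
#' @param annotations data.frame with `sample_id`, `cancer`, optionally
#'   `cluster`.
#' @param mutations data.frame of all filtered mutations (columns `gene`,
#'   `sample_id`); any record in the gene disqualifies the sample.
#' @param cnv Optional genes x samples integer matrix of GISTIC-style
#'   thresholded calls in -2..2.
#' @param cluster Optional cluster label restricting the background.
#' @param min_n Minimum background size; below it the background is
#'   undefined. Default 8.
#' @return List `gene`, `cancer`, `values` (named numeric vector), `n`, and
#'   `reason` (`NA` or `"insufficient background"`).
#' @export
build_background <- function(gene, cancer, expr, annotations, mutations,
                             cnv = NULL, cluster = NULL, min_n = 8L) {
  if (!gene %in% rownames(expr))
    stop("gene '", gene, "' absent from expression matrix")
  samples <- annotations$sample_id[annotations$cancer == cancer]
  if (!is.null(cluster) && "cluster" %in% names(annotations)) {
    samples <- intersect(samples,
                         annotations$sample_id[!is.na(annotations$cluster) &
                                               annotations$cluster == cluster])
  }
  samples <- intersect(samples, colnames(expr))
  mutated <- unique(mutations$sample_id[mutations$gene == gene])
  samples <- setdiff(samples, mutated)
  if (!is.null(cnv) && gene %in% rownames(cnv)) {
    called <- colnames(cnv)[cnv[gene, ] != 0]
    samples <- setdiff(samples, called)
  }
  values <- expr[gene, samples]
  if (length(samples) < min_n)
    return(list(gene = gene, cancer = cancer, values = numeric(0), n = 0L,
                reason = "insufficient background"))
  list(gene = gene, cancer = cancer, values = values,
       n = length(values), reason = NA_character_)
}

#' Relative expression of variant (REV)
#'
#' The REV of a mutant sample is the midrank R of its expression value
#' within the background set augmented by the value itself, normalized as
#' R/(n+1) where n is the background size; it lies in (0, 1] and is uniform
#' on \{k/(n+1)\} when the mutant is exchangeable with the background. Low
#' REV means low expression relative to wild type.
#'
#' @param mutant_value Expression value of the mutant sample.
#' @param background A [build_background()] result.
#' @return List `rank`, `rev`, `background_n` (all `NA` if the background is
#'   undefined).
#' @export
rev_score <- function(mutant_value, background) {
  if (background$n == 0L)
    return(list(rank = NA_real_, rev = NA_real_, background_n = 0L))
  pooled <- c(unname(background$values), mutant_value)
  r <- rank(pooled)[length(pooled)]
  list(rank = r, rev = r / (background$n + 1), background_n = background$n)
}

#' REV of every call in a batch
#'
#' Convenience wrapper: builds the per-gene/cancer background once and
#' scores each mutation's sample.
#'
#' @inheritParams build_background
#' @param calls data.frame of NMD calls (needs `gene`, `sample_id`,
#'   `nmd_class`, `source_class`).
#' @return data.frame: `gene`, `sample_id`, `nmd_class`, `source_class`,
#'   `rev`, `rank`, `background_n` (REV `NA` where the sample lacks
#'   expression data or the background is undefined).
#' @export
rev_table <- function(calls, expr, annotations, mutations, cnv = NULL,
                      min_n = 8L) {
  ann <- annotations
  cancer_of <- stats::setNames(ann$cancer, ann$sample_id)
  key <- paste(calls$gene, cancer_of[calls$sample_id], sep = "\r")
  bg_cache <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- calls$gene[i]
    s <- calls$sample_id[i]
    res <- list(rank = NA_real_, rev = NA_real_, background_n = NA_integer_)
    if (g %in% rownames(expr) && s %in% colnames(expr) &&
        !is.na(cancer_of[s])) {
      k <- key[i]
      bg <- bg_cache[[k]]
      if (is.null(bg)) {
        cl <- if ("cluster" %in% names(ann)) ann$cluster[ann$sample_id == s][1L] else NULL
        if (!is.null(cl) && is.na(cl)) cl <- NULL
        bg <- build_background(g, cancer_of[[s]], expr, ann, mutations,
                               cnv = cnv, cluster = cl, min_n = min_n)
        bg_cache[[k]] <- bg
      }
      res <- rev_score(expr[g, s], bg)
    }
    out[[i]] <- data.frame(gene = g, sample_id = s,
                           nmd_class = calls$nmd_class[i],
                           source_class = calls$source_class[i],
                           rev = res$rev, rank = res$rank,
                           background_n = res$background_n,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare REV distributions between two mutation groups
#'
#' Reports the group medians, their ratio, a Mann-Whitney-Wilcoxon test and
#' a Welch t-test (one-sided by default, with group A hypothesized lower).
#'
#' @param rev_a,rev_b Numeric REV vectors (NAs dropped).
#' @param alternative `"less"` (A stochastically lower than B) or
#'   `"two.sided"`.
#' @return List `median_a`, `median_b`, `ratio_of_medians` (`NA` when
#'   `median_b` is 0), `p_mww`, `p_ttest`, `degenerate` (`TRUE` when a test
#'   could not be computed, e.g. zero variance).
#' @export
rev_group_compare <- function(rev_a, rev_b,
                              alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  rev_a <- rev_a[!is.na(rev_a)]
  rev_b <- rev_b[!is.na(rev_b)]
  stopifnot(length(rev_a) > 0L, length(rev_b) > 0L)
  med_a <- stats::median(rev_a)
  med_b <- stats::median(rev_b)
  ratio <- if (med_b == 0) NA_real_ else med_a / med_b
  degenerate <- FALSE
  p_mww <- tryCatch(
    suppressWarnings(  # ties: normal approximation with tie correction
      stats::wilcox.test(rev_a, rev_b, alternative = alternative)$p.value),
    error = function(e) NA_real_)
  p_t <- tryCatch(
    stats::t.test(rev_a, rev_b, alternative = alternative)$p.value,
    error = function(e) NA_real_)
  if (is.na(p_mww) || is.na(p_t)) degenerate <- TRUE
  list(median_a = med_a, median_b = med_b, ratio_of_medians = ratio,
       p_mww = p_mww, p_ttest = p_t, degenerate = degenerate)
}

#' Gene-level NMD z-score
#'
#' Pools the wild-type and NMD-elicit mutant expression values, midranks
#' them, and derives the Mann-Whitney U statistic of the mutant group.
#' The z-score is U_mut normalized by N1*N2, i.e. the tie-corrected
#' probability that a mutant sample out-expresses a wild-type sample; it
#' lies in [0, 1] and low values mean depressed mutant expression. Genes
#' with fewer than three mutant samples are discarded. Tiers: z <= 0.3
#' sensitive; 0.3 < z <= 0.4 intermediate; z > 0.4 insensitive.
#'
#' @param wt_values Expression of wild-type samples (length N1 >= 1).
#' @param mut_values Expression of NMD-elicit mutant samples (length N2).
#' @return List `N1`, `N2`, `U1` (wild-type U), `U2` (mutant U), `z`,
#'   `tier`, `reason` (`NA`, or `"fewer than 3 NMD-elicit mutants"` when the
#'   gene is discarded, in which case the statistics are `NA`).
#' @export
nmd_zscore <- function(wt_values, mut_values) {
  n1 <- length(wt_values)
  n2 <- length(mut_values)
  if (n2 < 3L)
    return(list(N1 = n1, N2 = n2, U1 = NA_real_, U2 = NA_real_,
                z = NA_real_, tier = NA_character_,
                reason = "fewer than 3 NMD-elicit mutants"))
  stopifnot(n1 >= 1L)
  r <- rank(c(wt_values, mut_values))
  u2 <- sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2
  u1 <- n1 * n2 - u2
  z <- u2 / (n1 * n2)
  list(N1 = n1, N2 = n2, U1 = u1, U2 = u2, z = z,
       tier = zscore_tier(z), reason = NA_character_)
}

#' NMD-sensitivity tier of a z-score
#'
#' @param z Numeric vector of z-scores in [0, 1].
#' @return Character vector: `"sensitive"` (z <= 0.3), `"intermediate"`
#'   (0.3 < z <= 0.4) or `"insensitive"` (z > 0.4).
#' @export
zscore_tier <- function(z) {
  ifelse(z <= 0.3, "sensitive",
         ifelse(z <= 0.4, "intermediate", "insensitive"))
}

#' Gene x cancer z-score table
#'
#' For every gene and cancer with at least three NMD-elicit mutant samples,
#' contrasts their expression with the mutation- and CNV-free wild-type
#' samples of the same cancer.
#'
#' @inheritParams rev_table
#' @return data.frame: `gene`, `cancer`, `N1`, `N2`, `U1`, `U2`, `z`,
#'   `tier`.
#' @export
zscore_table <- function(calls, expr, annotations, mutations, cnv = NULL) {
  elicit <- calls[calls$nmd_class == "elicit", , drop = FALSE]
  cancer_of <- stats::setNames(annotations$cancer, annotations$sample_id)
  elicit$cancer <- cancer_of[elicit$sample_id]
  elicit <- elicit[!is.na(elicit$cancer), , drop = FALSE]
  combos <- unique(elicit[, c("gene", "cancer")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$gene[i]
    ca <- combos$cancer[i]
    if (!g %in% rownames(expr)) next
    mut_samples <- unique(elicit$sample_id[elicit$gene == g &
                                           elicit$cancer == ca])
    mut_samples <- intersect(mut_samples, colnames(expr))
    bg <- build_background(g, ca, expr, annotations, mutations, cnv = cnv,
                           min_n = 1L)
    res <- nmd_zscore(bg$values, expr[g, mut_samples])
    if (!is.na(res$reason)) next
    out[[length(out) + 1L]] <- data.frame(
      gene = g, cancer = ca, N1 = res$N1, N2 = res$N2, U1 = res$U1,
      U2 = res$U2, z = res$z, tier = res$tier, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(0), cancer = character(0),
                      N1 = integer(0), N2 = integer(0), U1 = numeric(0),
                      U2 = numeric(0), z = numeric(0), tier = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
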