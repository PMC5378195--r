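#' Log2 transform and median-center peptide areas
#'
#' Raw chromatographic peak areas are log2 transformed and the per-sample
#' median of the transformed values is subtracted, so every sample's median
#' normalized value is exactly 0. Non-positive areas cannot be log
#' transformed and are treated as missing (dropped with a message). Row
#' order within samples is preserved.
#'
#' @param quant Data frame with columns `peptide`, `protein`, `sample`,
#'   `condition`, `area`.
#' @return The same table with `area` replaced by a numeric `value` column
#'   of normalized log2 intensities.
#' @export
log2_median_normalize <- function(quant) {
  require_columns(quant, c("peptide", "protein", "sample", "condition",
                           "area"), "quant table")
  area <- as.numeric(quant$area)
  bad <- !is.finite(area) | area <= 0
  if (any(bad)) {
    message(sum(bad), " non-positive or missing area(s) treated as missing")
    quant <- quant[!bad, , drop = FALSE]
    area <- area[!bad]
  }
  value <- log2(area)
  med <- tapply(value, quant$sample, stats::median)
  value <- value - med[quant$sample]
  out <- quant[, c("peptide", "protein", "sample", "condition")]
  out$value <- as.numeric(value)
  rownames(out) <- NULL
  out
}

#' Drop proteins identified by fewer than two peptides
#'
#' Quantification is only trusted for proteins supported by at least two
#' distinct peptide identifications (counted across the whole table).
#'
#' @param quant Normalized quant table (see [log2_median_normalize()]); any
#'   table with `peptide` and `protein` columns works.
#' @return The filtered table.
#' @export
two_peptide_filter <- function(quant) {
  require_columns(quant, c("peptide", "protein"), "quant table")
  if (nrow(quant) == 0L) return(quant)
  n_pep <- tapply(quant$peptide, quant$protein,
                  function(p) length(unique(p)))
  keep_prot <- names(n_pep)[n_pep >= 2L]
  out <- quant[quant$protein %in% keep_prot, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize peptide values to one value per protein and sample
#'
#' The protein-level summary is the median of the protein's peptide values
#' in that sample; peptides missing in a sample are ignored, and a protein
#' with no observed peptide in a sample gets no summary row there. The
#' number of distinct peptides per protein is attached as the
#' `"n_peptides"` attribute for downstream reporting.
#'
#' @param quant Normalized (and usually [two_peptide_filter()]ed) table with
#'   a `value` column.
#' @return Data frame `protein`, `sample`, `condition`, `value`; one row per
#'   observed (protein, sample).
#' @export
summarize_protein <- function(quant) {
  require_columns(quant, c("peptide", "protein", "sample", "condition",
                           "value"), "normalized quant table")
  if (nrow(quant) == 0L) {
    out <- data.frame(protein = character(), sample = character(),
                      condition = character(), value = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_peptides") <- integer()
    return(out)
  }
  key <- paste(quant$protein, quant$sample, sep = "\r")
  idx <- split(seq_len(nrow(quant)), key)
  idx <- idx[order(names(idx))]
  first <- vapply(idx, `[`, 0L, 1L)
  out <- data.frame(
    protein = quant$protein[first],
    sample = quant$sample[first],
    condition = quant$condition[first],
    value = vapply(idx, function(r) stats::median(quant$value[r]), 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  n_pep <- tapply(quant$peptide, quant$protein,
                  function(p) length(unique(p)))
  attr(out, "n_peptides") <- setNames(as.integer(n_pep), names(n_pep))
  out
}

#' Per-protein differential abundance between two conditions
#'
#' For each protein with at least two summarized samples in both groups,
#' computes `log2fc = mean(group1) - mean(group2)`, a two-sided Welch
#' two-sample t-test p-value, and Benjamini-Hochberg adjusted p-values
#' across all tested proteins of the contrast. Proteins quantified in fewer
#' than two samples of either group are skipped with a warning (no
#' imputation is performed). When both groups have zero variance the test
#' is degenerate: p is 1 when the means agree and 0 otherwise.
#'
#' @param summaries Output of [summarize_protein()].
#' @param contrast Character vector of two condition labels
#'   `c(cond1, cond2)`; the fold change is `mean(cond1) - mean(cond2)`.
#' @param n_peptides Optional named integer vector of peptide support per
#'   protein; defaults to the `"n_peptides"` attribute of `summaries`.
#' @return Data frame `protein`, `contrast`, `log2fc`, `p`, `p_adj`,
#'   `n_peptides`, one row per tested protein (sorted by protein id).
#' @export
test_differential <- function(summaries, contrast,
                              n_peptides = attr(summaries, "n_peptides")) {
  require_columns(summaries, c("protein", "sample", "condition", "value"),
                  "protein summaries")
  if (length(contrast) != 2L) {
    stop("contrast must name exactly two conditions", call. = FALSE)
  }
  cond_of <- tapply(summaries$condition, summaries$sample,
                    function(x) unique(x))
  if (any(lengths(cond_of) != 1L)) {
    stop("every sample must map to exactly one condition", call. = FALSE)
  }
  use <- summaries[summaries$condition %in% contrast, , drop = FALSE]
  proteins <- sort(unique(use$protein))
  samples <- sort(unique(use$sample))
  m <- matrix(NA_real_, nrow = length(proteins), ncol = length(samples),
              dimnames = list(proteins, samples))
  m[cbind(match(use$protein, proteins), match(use$sample, samples))] <-
    use$value
  cond <- vapply(samples, function(s) as.character(cond_of[[s]]), "")
  g1 <- m[, cond == contrast[1L], drop = FALSE]
  g2 <- m[, cond == contrast[2L], drop = FALSE]
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  testable <- n1 >= 2L & n2 >= 2L
  if (any(!testable)) {
    warning(sum(!testable),
            " protein(s) skipped: fewer than 2 samples in a group",
            call. = FALSE)
  }
  g1 <- g1[testable, , drop = FALSE]
  g2 <- g2[testable, , drop = FALSE]
  n1 <- n1[testable]
  n2 <- n2[testable]
  m1 <- rowMeans(g1, na.rm = TRUE)
  m2 <- rowMeans(g2, na.rm = TRUE)
  v1 <- rowSums((g1 - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2, na.rm = TRUE) / (n2 - 1)
  log2fc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(length(log2fc))
  pos <- se2 > 0
  if (any(pos)) {
    tstat <- log2fc[pos] / sqrt(se2[pos])
    dfree <- se2[pos]^2 /
      (v1[pos]^2 / (n1[pos]^2 * (n1[pos] - 1)) +
         v2[pos]^2 / (n2[pos]^2 * (n2[pos] - 1)))
    p[pos] <- 2 * stats::pt(-abs(tstat), df = dfree)
  }
  p[!pos] <- ifelse(log2fc[!pos] == 0, 1, 0)
  prot <- proteins[testable]
  np <- if (is.null(n_peptides)) rep(NA_integer_, length(prot)) else {
    out <- n_peptides[prot]
    out[is.na(out)] <- NA_integer_
    as.integer(out)
  }
  data.frame(
    protein = prot,
    contrast = paste0(contrast[1L], "_vs_", contrast[2L]),
    log2fc = unname(log2fc),
    p = unname(p),
    p_adj = unname(stats::p.adjust(p, method = "BH")),
    n_peptides = unname(np),
    stringsAsFactors = FALSE
  )
}

#' Significant, unique and shared protein sets for two injury contrasts
#'
#' @param stats1,stats2 Outputs of [test_differential()] for the two
#'   injury-vs-control contrasts.
#' @param alpha Significance level on the adjusted p-value (strictly below).
#' @return List with `sig1`, `sig2` (significant proteins per contrast),
#'   `unique1`, `unique2` (set differences) and `shared` (intersection),
#'   each a sorted character vector.
#' @export
significant_sets <- function(stats1, stats2, alpha = 0.05) {
  sig1 <- sort(stats1$protein[stats1$p_adj < alpha])
  sig2 <- sort(stats2$protein[stats2$p_adj < alpha])
  list(sig1 = sig1, sig2 = sig2,
       unique1 = setdiff(sig1, sig2),
       unique2 = setdiff(sig2, sig1),
       shared = intersect(sig1, sig2))
}

#' Rank genes by log2 fold change
#'
#' Genes are ordered by log2 fold change, descending; ties are broken by
#' gene identifier, ascending, which makes the ranking fully deterministic.
#'
#' @param stats Output of [test_differential()] (one row per protein).
#' @return An object of class `ranked_list`: data frame `gene`, `score`
#'   sorted as described.
#' @export
make_ranking <- function(stats) {
  require_columns(stats, c("protein", "log2fc"), "protein stats")
  if (anyDuplicated(stats$protein)) {
    stop("duplicate protein ids in ranking input", call. = FALSE)
  }
  ord <- order(-stats$log2fc, stats$protein)
  out <- data.frame(gene = stats$protein[ord], score = stats$log2fc[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}
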