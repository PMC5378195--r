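#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom keeping a running sum: at a gene
#' belonging to the signature ("hit") the sum increases by
#' `|score|^weight_exponent / N_R` where `N_R` is the sum of those weights
#' over all hits; at a miss it decreases by `1 / (N - N_hits)`. The
#' enrichment score (ES) is the signed maximum deviation of the running sum
#' from zero and always lies in `[-1, 1]`. With `weight_exponent = 0` the
#' statistic reduces to the classic (unweighted) Kolmogorov-Smirnov form.
#' If every hit has zero score (possible only with a positive exponent),
#' hits fall back to equal weights `1 / N_hits`.
#'
#' @param ranking A [make_ranking()] result (data frame `gene`, `score`,
#'   descending).
#' @param genes Character vector: the signature. Only genes present in the
#'   ranked universe count; an empty overlap yields `es = NA` (unscored),
#'   and a signature covering the whole universe is an error (the miss
#'   decrement is undefined).
#' @param weight_exponent Non-negative weight on `|score|`; default 1
#'   (classic weighted GSEA).
#' @return List with `es`, `n_overlap`, `running_sum` (length-N profile)
#'   and `peak` (index of the extreme deviation).
#' @export
#' @examples
#' r <- structure(data.frame(gene = paste0("g", 1:6),
#'                           score = c(3, 2, 1, -1, -2, -3)),
#'                class = c("ranked_list", "data.frame"))
#' enrichment_score(r, c("g1", "g4"))$es  # 0.75
enrichment_score <- function(ranking, genes, weight_exponent = 1) {
  stopifnot(is.data.frame(ranking), all(c("gene", "score") %in%
                                          names(ranking)))
  if (anyDuplicated(ranking$gene)) {
    stop("ranked list contains duplicate genes", call. = FALSE)
  }
  if (weight_exponent < 0) stop("weight_exponent must be >= 0", call. = FALSE)
  n <- nrow(ranking)
  hit <- ranking$gene %in% genes
  nh <- sum(hit)
  if (nh == 0L) {
    return(list(es = NA_real_, n_overlap = 0L, running_sum = NULL,
                peak = NA_integer_))
  }
  if (nh == n) {
    stop("signature covers the entire ranked universe; ",
         "the miss decrement is undefined", call. = FALSE)
  }
  w <- abs(ranking$score)^weight_exponent
  rs <- running_sum_stat(w, which(hit), n, return_profile = TRUE)
  list(es = rs$es, n_overlap = nh, running_sum = rs$profile, peak = rs$peak)
}

# Core running-sum statistic shared by the observed score and the
# permutation null; hot path, so kept free of data-frame bookkeeping.
running_sum_stat <- function(w, hit_idx, n, return_profile = FALSE) {
  nh <- length(hit_idx)
  nr <- sum(w[hit_idx])
  inc <- rep.int(-1 / (n - nh), n)
  inc[hit_idx] <- if (nr > 0) w[hit_idx] / nr else 1 / nh
  profile <- cumsum(inc)
  peak <- which.max(abs(profile))
  if (return_profile) {
    list(es = profile[peak], peak = peak, profile = profile)
  } else {
    profile[peak]
  }
}

#' Gene-label permutation null for the enrichment score
#'
#' Each permutation draws a uniform random gene set of size
#' `|signature ∩ universe|` from the ranked universe and records its
#' enrichment score on the same ranked list. This is a gene-label
#' permutation (random signatures), not a sample permutation, which is the
#' appropriate null when a single ranked list is scored per signature and
#' group sizes are too small to permute at depth.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer; when given, results are reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranking, genes, n_perm = 10000, seed = NULL,
                             weight_exponent = 1) {
  stopifnot(n_perm >= 1)
  n <- nrow(ranking)
  nh <- sum(ranking$gene %in% genes)
  if (nh == 0L || nh == n) {
    stop("signature overlap with the universe must be in [1, N-1]",
         call. = FALSE)
  }
  w <- abs(ranking$score)^weight_exponent
  with_rng_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      running_sum_stat(w, sample.int(n, nh), n)
    }, numeric(1))
  })
}

#' Normalized enrichment score and permutation p-value
#'
#' Normalization is sign-matched: `nes = es / mean(|null es|)` over null
#' scores of the same sign as `es`, which accounts for the size of the gene
#' set being tested. The p-value is rank-based with add-one smoothing,
#' `p = (1 + #{null : |null| >= |es|, same sign}) / (1 + #same-sign nulls)`,
#' so it can never be exactly zero at finite permutation depth. A zero
#' enrichment score, or an empty same-sign null set, is reported as `p = 1`.
#'
#' @param es Observed enrichment score.
#' @param nulls Numeric vector of null enrichment scores (at least 100 for
#'   a reportable p-value; fewer trigger a warning).
#' @return List with `nes` and `p`.
#' @export
gsea_significance <- function(es, nulls) {
  if (is.na(es)) return(list(nes = NA_real_, p = NA_real_))
  if (length(nulls) < 100L) {
    warning("fewer than 100 permutations; p-value is unreliable",
            call. = FALSE)
  }
  if (es == 0) return(list(nes = 0, p = 1))
  match_sign <- if (es > 0) nulls[nulls > 0] else nulls[nulls < 0]
  if (length(match_sign) == 0L) {
    warning("no null scores matching the observed sign; p set to 1",
            call. = FALSE)
    return(list(nes = NA_real_, p = 1))
  }
  list(nes = es / mean(abs(match_sign)),
       p = (1 + sum(abs(match_sign) >= abs(es))) / (1 + length(match_sign)))
}

#' Benjamini-Hochberg FDR over GSEA permutation p-values
#'
#' Applied across all (motive, variant) tests of one contrast.
#'
#' @param results Data frame with a `p` column.
#' @return The same data frame with an `fdr` column.
#' @export
gsea_fdr <- function(results) {
  require_columns(results, "p", "GSEA results")
  results$fdr <- stats::p.adjust(results$p, method = "BH")
  results
}

#' Score a signature set against a ranked list
#'
#' Runs [enrichment_score()], [permutation_null()] and
#' [gsea_significance()] for every signature and applies [gsea_fdr()]
#' across them. Signatures with no gene in the ranked universe are reported
#' unscored (`es = NA`); a signature covering the whole universe is likewise
#' reported unscored with a warning rather than aborting the batch. A
#' signature overlapping more than half the universe triggers a warning
#' (enrichment against the rest of the list becomes uninformative).
#' Direction is the sign of the enrichment score: positive means the
#' signature concentrates at the top of the ranking ("up" for the contrast
#' as ordered).
#'
#' @param ranking A [make_ranking()] result.
#' @param sigset A `signature_set` (or any data frame with `motive`,
#'   `variant` and a `genes` list-column).
#' @param n_perm Permutations per signature.
#' @param seed Optional base seed; signature `i` uses `seed + i - 1`.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Data frame `motive`, `variant`, `n_overlap`, `es`, `nes`, `p`,
#'   `fdr`, `direction`, `n_perm`, `seed`.
#' @export
gsea <- function(ranking, sigset, n_perm = 10000, seed = NULL,
                 weight_exponent = 1) {
  stopifnot(is.data.frame(sigset),
            all(c("motive", "variant", "genes") %in% names(sigset)))
  n <- nrow(ranking)
  out <- vector("list", nrow(sigset))
  n_large <- 0L
  for (i in seq_len(nrow(sigset))) {
    genes <- sigset$genes[[i]]
    nh <- sum(ranking$gene %in% genes)
    if (nh > n / 2) n_large <- n_large + 1L
    if (nh == 0L || nh == n) {
      if (nh == n) {
        warning("signature '", sigset$motive[i], "|", sigset$variant[i],
                "' covers the whole ranked universe; left unscored",
                call. = FALSE)
      }
      out[[i]] <- data.frame(
        motive = sigset$motive[i], variant = sigset$variant[i],
        n_overlap = nh, es = NA_real_, nes = NA_real_, p = NA_real_,
        direction = NA_character_, stringsAsFactors = FALSE)
      next
    }
    es <- enrichment_score(ranking, genes, weight_exponent)$es
    nulls <- permutation_null(ranking, genes, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else seed + i - 1L,
                              weight_exponent = weight_exponent)
    sig <- gsea_significance(es, nulls)
    out[[i]] <- data.frame(
      motive = sigset$motive[i], variant = sigset$variant[i],
      n_overlap = nh, es = es, nes = sig$nes, p = sig$p,
      direction = if (es > 0) "up" else if (es < 0) "down" else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (n_large > 0L) {
    warning(n_large, " signature(s) overlap more than half the measured ",
            "universe; their enrichment is weakly informative", call. = FALSE)
  }
  res <- do.call(rbind, out)
  res <- gsea_fdr(res)
  res$n_perm <- n_perm
  res$seed <- if (is.null(seed)) NA_integer_ else seed
  rownames(res) <- NULL
  res
}
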