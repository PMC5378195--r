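default_contrasts <- function() {
  list(c("DA", "Ctrl"), c("RA", "Ctrl"), c("DA", "RA"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full enrichment pipeline
#'
#' Orchestrates catalog loading, interactome assembly, signature expansion,
#' differential abundance and permutation GSEA for every contrast, and
#' returns the motive x (contrast, variant) enrichment matrix. Deterministic
#' given the inputs and `seed`: the per-contrast GSEA seed is
#' `seed + 1000 * (contrast index - 1)`.
#'
#' `config` is a named list:
#' \describe{
#'   \item{catalog}{path to a motive TSV or a [motive_catalog()];}
#'   \item{interactions}{path to an interaction TSV or a
#'     [parse_interactions()] result;}
#'   \item{quant}{path to a quant TSV or a quant data frame;}
#'   \item{synthetic}{alternatively, a [synthetic_spec()] replacing all
#'     three inputs;}
#'   \item{alpha}{significance level, default 0.05;}
#'   \item{n_perm}{permutations per signature, default 10000;}
#'   \item{seed}{integer seed (required);}
#'   \item{confidence_threshold}{high-confidence filter, default 0.5;}
#'   \item{weight_exponent}{GSEA weight, default 1;}
#'   \item{contrasts}{list of condition pairs; default DA vs Ctrl, RA vs
#'     Ctrl, DA vs RA — the fold change is always first minus second;}
#'   \item{outdir}{optional directory for all intermediate artifacts and a
#'     manifest with MD5 checksums.}
#' }
#'
#' @param config Named list, see Details.
#' @return An object of class `enrichment_matrix`: list with `results`
#'   (long data frame: `contrast`, `category`, `motive`, `variant`,
#'   `n_overlap`, `es`, `nes`, `p`, `fdr`, `direction`, `sig_p`, `sig_fdr`),
#'   `stats` (per-contrast differential-abundance tables), `sigsets`,
#'   `unique_sets` (unique/shared significant proteins for the first two
#'   contrasts) and the effective parameters.
#' @export
run_pipeline <- function(config) {
  alpha <- config$alpha %||% 0.05
  n_perm <- config$n_perm %||% 10000
  threshold <- config$confidence_threshold %||% 0.5
  weight_exponent <- config$weight_exponent %||% 1
  contrasts <- config$contrasts %||% default_contrasts()
  seed <- config$seed
  if (is.null(seed)) stop("[config] a seed is required", call. = FALSE)
  seed <- as.integer(seed)
  outdir <- config$outdir

  sim <- NULL
  if (!is.null(config$synthetic)) {
    sim <- stage("synthetic_data", simulate_study(
      config$synthetic,
      dir = if (!is.null(outdir)) file.path(outdir, "inputs")))
    catalog <- sim$catalog
    records <- sim$interactions$records
    complexes <- sim$interactions$complexes
    quant <- sim$quant
    g_binary <- sim$g_binary
    g_expanded <- sim$g_expanded
  } else {
    catalog <- stage("motive_catalog", {
      if (inherits(config$catalog, "motive_catalog")) config$catalog
      else load_motive_table(config$catalog)
    })
    parsed <- stage("interactome", {
      if (is.list(config$interactions) &&
            !is.null(config$interactions$records)) config$interactions
      else parse_interactions(config$interactions)
    })
    records <- parsed$records
    complexes <- parsed$complexes
    quant <- stage("diff_abundance", {
      if (is.data.frame(config$quant)) config$quant
      else read_tsv(config$quant)
    })
    g_binary <- stage("interactome",
                      build_interactome(records, list(), mode = "binary"))
    g_expanded <- stage("interactome",
                        build_interactome(records, complexes,
                                          mode = "expanded"))
  }

  sigset <- stage("signature_builder",
                  build_signatures(catalog, g_binary, g_expanded, threshold))

  norm <- stage("diff_abundance", log2_median_normalize(quant))
  norm <- stage("diff_abundance", two_peptide_filter(norm))
  summaries <- stage("diff_abundance", summarize_protein(norm))

  stats_list <- list()
  results <- list()
  for (ci in seq_along(contrasts)) {
    ctr <- contrasts[[ci]]
    label <- paste0(ctr[1L], "_vs_", ctr[2L])
    st <- stage("diff_abundance", test_differential(summaries, ctr))
    stats_list[[label]] <- st
    ranking <- stage("diff_abundance", make_ranking(st))
    res <- stage("gsea_engine",
                 gsea(ranking, sigset, n_perm = n_perm,
                      seed = seed + 1000L * (ci - 1L),
                      weight_exponent = weight_exponent))
    res$contrast <- label
    results[[label]] <- res
  }
  results <- do.call(rbind, results)

  # order rows: contrast, category (regenerative block first), catalog
  # position, variant in canonical order
  motive_order <- vapply(catalog$motives, `[[`, "", "name")
  category_of <- setNames(vapply(catalog$motives, `[[`, "", "category"),
                          motive_order)
  results$category <- unname(category_of[results$motive])
  contrast_labels <- vapply(contrasts,
                            function(x) paste0(x[1L], "_vs_", x[2L]), "")
  ord <- order(match(results$contrast, contrast_labels),
               match(results$category, c("regenerative", "degenerative")),
               match(results$motive, motive_order),
               match(results$variant, variant_labels()))
  results <- results[ord, c("contrast", "category", "motive", "variant",
                            "n_overlap", "es", "nes", "p", "fdr",
                            "direction", "n_perm", "seed")]
  results$sig_p <- !is.na(results$p) & results$p < alpha
  results$sig_fdr <- !is.na(results$fdr) & results$fdr < alpha
  rownames(results) <- NULL

  unique_sets <- if (length(stats_list) >= 2L) {
    significant_sets(stats_list[[1L]], stats_list[[2L]], alpha = alpha)
  }

  out <- structure(list(
    results = results, stats = stats_list, sigset = sigset,
    unique_sets = unique_sets, catalog = catalog,
    params = list(alpha = alpha, n_perm = n_perm, seed = seed,
                  confidence_threshold = threshold,
                  weight_exponent = weight_exponent,
                  contrasts = contrast_labels),
    truth = if (!is.null(sim)) sim$truth
  ), class = "enrichment_matrix")

  if (!is.null(outdir)) {
    stage("workflow_report", write_pipeline_artifacts(
      out, g_binary, g_expanded, outdir))
  }
  out
}

write_pipeline_artifacts <- function(m, g_binary, g_expanded, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_lines(m$params)
  write_interactome(g_binary, file.path(outdir, "interactome_binary.tsv"),
                    header_lines = prov)
  write_interactome(g_expanded, file.path(outdir, "interactome_expanded.tsv"),
                    header_lines = prov)
  write_gmt(m$sigset, file.path(outdir, "signatures.gmt"))
  for (label in names(m$stats)) {
    write_tsv(m$stats[[label]],
              file.path(outdir, paste0("stats_", label, ".tsv")),
              header_lines = prov)
  }
  render_matrix(m, file.path(outdir, "results.tsv"))
  files <- c("interactome_binary.tsv", "interactome_expanded.tsv",
             "signatures.gmt", paste0("stats_", names(m$stats), ".tsv"),
             "results.tsv")
  inputs_dir <- file.path(outdir, "inputs")
  if (dir.exists(inputs_dir)) {
    files <- c(files, file.path("inputs", list.files(inputs_dir)))
  }
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

#' Write the enrichment matrix as a TSV
#'
#' Writes the long-format matrix (one row per motive, contrast and network
#' variant, motives grouped by category in catalog order) with a
#' provenance comment header. Significant cells are those with
#' `sig_p`/`sig_fdr` TRUE; the direction column carries up/down.
#'
#' @param m An `enrichment_matrix` from [run_pipeline()], or its `results`
#'   data frame.
#' @param path Output path.
#' @return The written data frame, invisibly.
#' @export
render_matrix <- function(m, path) {
  df <- if (inherits(m, "enrichment_matrix")) m$results else m
  prov <- if (inherits(m, "enrichment_matrix")) provenance_lines(m$params)
          else character()
  write_tsv(df, path, header_lines = prov)
  invisible(df)
}

#' Read back an enrichment matrix TSV
#'
#' Inverse of [render_matrix()] (numeric and logical columns restored).
#'
#' @param path Path written by [render_matrix()].
#' @return The results data frame.
#' @export
parse_matrix <- function(path) {
  df <- read_tsv(path)
  for (col in intersect(c("n_overlap", "es", "nes", "p", "fdr", "n_perm",
                          "seed"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in intersect(c("sig_p", "sig_fdr"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  r <- x$results
  cat(sprintf("enrichment matrix: %d motives x %d contrasts x %d variants\n",
              length(unique(r$motive)), length(unique(r$contrast)),
              length(unique(r$variant))))
  cat(sprintf("significant cells (p < %g): %d; (FDR < %g): %d\n",
              x$params$alpha, sum(r$sig_p), x$params$alpha,
              sum(r$sig_fdr)))
  invisible(x)
}

#' Compact wide view of an enrichment matrix
#'
#' One row per motive, one column per (contrast, variant); cells show the
#' direction of significant results (`up`/`down`, suffixed with `*` when
#' also below the FDR threshold) and are empty otherwise.
#'
#' @param m An `enrichment_matrix`.
#' @return A character data frame.
#' @export
matrix_wide <- function(m) {
  stopifnot(inherits(m, "enrichment_matrix"))
  r <- m$results
  cell <- ifelse(r$sig_p,
                 paste0(r$direction, ifelse(r$sig_fdr, "*", "")), "")
  col <- paste(r$contrast, r$variant, sep = "|")
  motives <- unique(r$motive)
  cols <- unique(col)
  wide <- matrix("", nrow = length(motives), ncol = length(cols),
                 dimnames = list(motives, cols))
  wide[cbind(match(r$motive, motives), match(col, cols))] <- cell
  out <- data.frame(motive = motives, wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Heatmap of an enrichment matrix
#'
#' Tile plot of signed `-log10(p)` (positive = up), faceted by contrast.
#' Requires ggplot2.
#'
#' @param m An `enrichment_matrix`.
#' @return A ggplot object.
#' @export
plot_enrichment_matrix <- function(m) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  r <- m$results
  r$signed_logp <- ifelse(is.na(r$p), NA,
                          -log10(pmax(r$p, 1e-10)) *
                            ifelse(r$direction == "down", -1, 1))
  r$motive <- factor(r$motive, levels = rev(unique(r$motive)))
  r$variant <- factor(r$variant, levels = variant_labels())
  ggplot2::ggplot(r, ggplot2::aes(x = .data$variant, y = .data$motive,
                                  fill = .data$signed_logp)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "signed -log10 p") +
    ggplot2::labs(x = "network variant", y = NULL)
}
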