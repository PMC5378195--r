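#' k-step neighborhood of a seed set in an interactome
#'
#' First-degree networks add the direct interactors of the seeds; second
#' degree networks add one more level (interactors of the interactors).
#' Seeds absent from the interactome are retained in the returned gene set
#' (they simply have no interactors), so a network variant can never be
#' smaller than the seed list.
#'
#' @param g An `interactome` (see [build_interactome()]).
#' @param seeds Character vector of gene identifiers.
#' @param k Neighborhood order, 1 or 2.
#' @return A list with `genes` (sorted character vector, always a superset
#'   of `seeds`) and `edges` (the induced subgraph: all interactome edges
#'   with both endpoints in `genes`).
#' @export
k_neighborhood <- function(g, seeds, k) {
  stopifnot(inherits(g, "interactome"))
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2", call. = FALSE)
  seeds <- unique(as.character(seeds))
  nodes <- unique(c(g$edges$a, g$edges$b))
  present <- intersect(seeds, nodes)
  if (length(present) == 0L) {
    return(list(genes = sort(seeds), edges = empty_edges()))
  }
  ig <- as_igraph(g)
  nb <- igraph::ego(ig, order = k, nodes = present, mode = "all")
  reached <- unique(unlist(lapply(nb, names), use.names = FALSE))
  genes <- sort(unique(c(seeds, reached)))
  keep <- g$edges$a %in% genes & g$edges$b %in% genes
  sub <- g$edges[keep, , drop = FALSE]
  rownames(sub) <- NULL
  list(genes = genes, edges = sub)
}

variant_labels <- function() {
  c("seeds", "hc_deg1", "hc_deg2", "bin_deg1", "bin_deg2", "all")
}

#' Build the six signature variants for every motive
#'
#' For each motive the seed set is expanded into six gene-set variants:
#' \describe{
#'   \item{seeds}{the seed set itself;}
#'   \item{hc_deg1, hc_deg2}{first/second-degree neighborhoods over the
#'     expanded interactome after [filter_high_confidence()] at `threshold`;}
#'   \item{bin_deg1, bin_deg2}{first/second-degree neighborhoods over the
#'     binary interactome, unfiltered;}
#'   \item{all}{the second-degree neighborhood over the unfiltered union of
#'     the binary and expanded interactomes.}
#' }
#' Every variant contains the motive's seeds, so the containment chains
#' `seeds <= hc_deg1 <= hc_deg2 <= all` and `seeds <= bin_deg1 <= bin_deg2
#' <= all` hold by construction.
#'
#' @param catalog A [motive_catalog()].
#' @param g_binary Binary-mode `interactome`.
#' @param g_expanded Expanded-mode `interactome` (complex-derived edges
#'   included).
#' @param threshold Confidence threshold for the high-confidence variants.
#' @return An object of class `signature_set`: a data frame with columns
#'   `motive`, `category`, `variant`, `n_genes` and list-columns `genes`
#'   and `edges` (induced subgraph; empty for the `seeds` variant).
#' @export
build_signatures <- function(catalog, g_binary, g_expanded, threshold = 0.5) {
  stopifnot(inherits(catalog, "motive_catalog"),
            inherits(g_binary, "interactome"),
            inherits(g_expanded, "interactome"))
  if (length(catalog$motives) == 0L) {
    stop("cannot build signatures from an empty catalog", call. = FALSE)
  }
  g_hc <- filter_high_confidence(g_expanded, threshold)
  g_all <- interactome_union(g_binary, g_expanded)

  rows <- list()
  for (m in catalog$motives) {
    seeds <- m$seeds
    per_variant <- list(
      seeds = list(genes = sort(unique(seeds)), edges = empty_edges()),
      hc_deg1 = k_neighborhood(g_hc, seeds, 1L),
      hc_deg2 = k_neighborhood(g_hc, seeds, 2L),
      bin_deg1 = k_neighborhood(g_binary, seeds, 1L),
      bin_deg2 = k_neighborhood(g_binary, seeds, 2L),
      all = k_neighborhood(g_all, seeds, 2L)
    )
    for (v in variant_labels()) {
      rows[[length(rows) + 1L]] <- list(
        motive = m$name, category = m$category, variant = v,
        genes = per_variant[[v]]$genes, edges = per_variant[[v]]$edges)
    }
  }
  sigset <- data.frame(
    motive = vapply(rows, `[[`, "", "motive"),
    category = vapply(rows, `[[`, "", "category"),
    variant = vapply(rows, `[[`, "", "variant"),
    n_genes = vapply(rows, function(r) length(r$genes), 0L),
    stringsAsFactors = FALSE
  )
  sigset$genes <- lapply(rows, `[[`, "genes")
  sigset$edges <- lapply(rows, `[[`, "edges")
  class(sigset) <- c("signature_set", "data.frame")
  sigset
}

#' Extract one signature's gene set
#'
#' @param sigset A `signature_set`.
#' @param motive Motive name.
#' @param variant One of the six variant labels.
#' @return Character vector of genes.
#' @export
signature_genes <- function(sigset, motive, variant) {
  stopifnot(inherits(sigset, "signature_set"))
  i <- which(sigset$motive == motive & sigset$variant == variant)
  if (length(i) != 1L) {
    stop("no signature for motive '", motive, "', variant '", variant, "'",
         call. = FALSE)
  }
  sigset$genes[[i]]
}

#' Write a signature set in GMT format
#'
#' One line per (motive, variant): `name<TAB>description<TAB>gene...`, with
#' `name = "<motive>|<variant>"` and the motive category as description.
#' Gene identifiers or motive names containing tabs (or motive names
#' containing the `|` separator) are rejected.
#'
#' @param sigset A `signature_set` from [build_signatures()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigset, path) {
  stopifnot(inherits(sigset, "signature_set"))
  if (nrow(sigset) == 0L) stop("empty signature set", call. = FALSE)
  if (any(grepl("[\t|]", sigset$motive))) {
    stop("motive names must not contain tab or '|'", call. = FALSE)
  }
  genes <- unlist(sigset$genes, use.names = FALSE)
  if (any(grepl("\t", genes, fixed = TRUE))) {
    stop("gene identifiers must not contain tab characters", call. = FALSE)
  }
  lines <- vapply(seq_len(nrow(sigset)), function(i) {
    paste(c(paste0(sigset$motive[i], "|", sigset$variant[i]),
            sigset$category[i], sigset$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT file written by [write_gmt()]
#'
#' @param path Path to a GMT file.
#' @return A `signature_set`-shaped data frame (without subgraph edges).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  name <- vapply(parts, `[[`, "", 1L)
  mv <- strsplit(name, "|", fixed = TRUE)
  out <- data.frame(
    motive = vapply(mv, `[[`, "", 1L),
    category = vapply(parts, `[[`, "", 2L),
    variant = vapply(mv, function(x) if (length(x) > 1L) x[[2L]] else "", ""),
    n_genes = vapply(parts, function(x) length(x) - 2L, 0L),
    stringsAsFactors = FALSE
  )
  out$genes <- lapply(parts, function(x) x[-(1:2)])
  out$edges <- rep(list(empty_edges()), nrow(out))
  class(out) <- c("signature_set", "data.frame")
  out
}
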