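#' Construct a motive catalog
#'
#' A motive is a literature-curated biological process represented by a
#' non-empty set of seed gene identifiers and assigned to one of two
#' categories, `"regenerative"` or `"degenerative"`. Identifiers are treated
#' as opaque, case-sensitive strings; no ontology mapping is attempted.
#'
#' @param motive Character vector of motive names (unique).
#' @param category Character vector, one of `"regenerative"` /
#'   `"degenerative"` per motive.
#' @param seeds List of character vectors, one per motive; duplicates within
#'   a motive are collapsed with a warning.
#' @param provenance Free-text note on where the catalog came from.
#' @return An object of class `motive_catalog`: a list with elements
#'   `motives` (ordered list of `list(name, category, seeds)`) and
#'   `provenance`.
#' @seealso [load_motive_table()], [catalog_tallies()]
#' @export
#' @examples
#' cat <- motive_catalog(c("anoikis", "regeneration"),
#'                       c("degenerative", "regenerative"),
#'                       list(c("G1", "G2"), c("G2", "G3", "G4")))
#' catalog_tallies(cat)
motive_catalog <- function(motive, category, seeds, provenance = "") {
  if (length(motive) == 0L) {
    stop("a motive catalog must contain at least one motive", call. = FALSE)
  }
  if (length(category) != length(motive) || length(seeds) != length(motive)) {
    stop("motive, category and seeds must have equal length", call. = FALSE)
  }
  if (anyDuplicated(motive)) {
    stop("motive names must be unique within a catalog: ",
         paste(unique(motive[duplicated(motive)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !category %in% c("regenerative", "degenerative")
  if (any(bad)) {
    stop("unknown category label(s): ",
         paste(unique(category[bad]), collapse = ", "),
         " (expected 'regenerative' or 'degenerative')", call. = FALSE)
  }
  motives <- vector("list", length(motive))
  for (i in seq_along(motive)) {
    s <- as.character(seeds[[i]])
    s <- s[nzchar(s)]
    if (length(s) == 0L) {
      stop("motive '", motive[i], "' has an empty seed list", call. = FALSE)
    }
    if (anyDuplicated(s)) {
      warning("motive '", motive[i], "': ", sum(duplicated(s)),
              " duplicate seed(s) collapsed", call. = FALSE)
      s <- unique(s)
    }
    motives[[i]] <- list(name = motive[i], category = category[i], seeds = s)
  }
  structure(list(motives = motives, provenance = provenance),
            class = "motive_catalog")
}

#' Load a motive catalog from a TSV file
#'
#' Expected columns: `motive`, `category`, `seeds` (semicolon-separated gene
#' identifiers), UTF-8, header required. Row order is preserved. An optional
#' alias map (TSV with columns `id`, `canonical`) is applied to the seed
#' identifiers at load, which is the only identifier normalization performed.
#'
#' @param path Path to the catalog TSV.
#' @param alias_map Optional path to an alias TSV (`id`, `canonical`) or a
#'   data frame with those columns.
#' @return A [motive_catalog()].
#' @export
load_motive_table <- function(path, alias_map = NULL) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  df <- read_tsv(path)
  require_columns(df, c("motive", "category", "seeds"), "motive table")
  seeds <- strsplit(df$seeds, ";", fixed = TRUE)
  seeds <- lapply(seeds, function(s) trimws(s))
  if (!is.null(alias_map)) {
    am <- if (is.character(alias_map)) read_tsv(alias_map) else alias_map
    require_columns(am, c("id", "canonical"), "alias map")
    lookup <- setNames(as.character(am$canonical), as.character(am$id))
    seeds <- lapply(seeds, function(s) {
      hit <- s %in% names(lookup)
      s[hit] <- lookup[s[hit]]
      s
    })
  }
  motive_catalog(df$motive, df$category, seeds, provenance = path)
}

#' Write a motive catalog to TSV
#'
#' Inverse of [load_motive_table()]: reloading the written file round-trips
#' the seed sets exactly.
#'
#' @param catalog A [motive_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motive_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "motive_catalog"))
  df <- data.frame(
    motive = vapply(catalog$motives, `[[`, "", "name"),
    category = vapply(catalog$motives, `[[`, "", "category"),
    seeds = vapply(catalog$motives,
                   function(m) paste(m$seeds, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Summary tallies of a motive catalog
#'
#' @param catalog A [motive_catalog()].
#' @return A list with `n_motives`, `n_per_category` (named integer vector
#'   over both categories), `total_seats` (sum of per-motive seed counts;
#'   seeds shared between motives are counted once per motive) and
#'   `unique_seeds` (size of the union of all seed sets).
#' @export
catalog_tallies <- function(catalog) {
  stopifnot(inherits(catalog, "motive_catalog"))
  sizes <- vapply(catalog$motives, function(m) length(m$seeds), 0L)
  cats <- vapply(catalog$motives, `[[`, "", "category")
  all_seeds <- unlist(lapply(catalog$motives, `[[`, "seeds"),
                      use.names = FALSE)
  n_per_category <- vapply(c(regenerative = "regenerative",
                             degenerative = "degenerative"),
                           function(k) sum(cats == k), 0L)
  list(
    n_motives = length(catalog$motives),
    n_per_category = n_per_category,
    total_seats = sum(sizes),
    unique_seeds = length(unique(all_seeds))
  )
}

#' @export
print.motive_catalog <- function(x, ...) {
  t <- catalog_tallies(x)
  cat(sprintf(
    "motive catalog: %d motives (%d regenerative, %d degenerative), %d seats, %d unique seeds\n",
    t$n_motives, t$n_per_category[["regenerative"]],
    t$n_per_category[["degenerative"]], t$total_seats, t$unique_seeds))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.data.frame.motive_catalog <- function(x, ...) {
  data.frame(
    motive = vapply(x$motives, `[[`, "", "name"),
    category = vapply(x$motives, `[[`, "", "category"),
    n_seeds = vapply(x$motives, function(m) length(m$seeds), 0L),
    stringsAsFactors = FALSE
  )
}

#' Seed set of one motive
#'
#' @param catalog A [motive_catalog()].
#' @param name Motive name.
#' @return Character vector of seed identifiers.
#' @export
motive_seeds <- function(catalog, name) {
  stopifnot(inherits(catalog, "motive_catalog"))
  idx <- match(name, vapply(catalog$motives, `[[`, "", "name"))
  if (is.na(idx)) stop("no motive named '", name, "' in catalog", call. = FALSE)
  catalog$motives[[idx]]$seeds
}
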