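#' Parse interaction records from a MITAB-like TSV
#'
#' The canonical exchange format is a tab-separated file with columns
#' `id_a`, `id_b_or_members`, `record_type` (`pair` or `complex`), `bait`
#' (optional, complex rows only), `method_class` (`binary_capable` or
#' `complex_derived`), `publication_ids` (pipe-separated identifiers) and
#' `source_db`. Pair rows become direct interaction records; complex rows
#' carry a semicolon-separated member list in `id_b_or_members` and are
#' expanded later by [expand_complex()].
#'
#' Self-loop pair rows are dropped with a warning. Malformed rows are logged
#' and skipped, or raise an error when `strict = TRUE`.
#'
#' @param path Path to the TSV file.
#' @param strict Raise on malformed rows instead of skipping them.
#' @return A list with `records` (data frame of direct interaction records:
#'   `a`, `b`, `method_class`, `publication_ids`, `source_db`, `origin`) and
#'   `complexes` (list of `list(members, bait, publication_ids, source_db)`).
#' @export
parse_interactions <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("interaction file not found: ", path,
                               call. = FALSE)
  if (file.size(path) == 0) {
    return(list(records = empty_records(), complexes = list()))
  }
  df <- read_tsv(path)
  if (nrow(df) == 0L) {
    return(list(records = empty_records(), complexes = list()))
  }
  require_columns(df, c("id_a", "id_b_or_members", "record_type",
                        "method_class", "publication_ids", "source_db"),
                  "interaction table")
  if (is.null(df$bait)) df$bait <- ""

  bad_row <- function(i, why) {
    msg <- sprintf("interaction row %d skipped: %s", i, why)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  unknown <- which(!df$record_type %in% c("pair", "complex"))
  for (i in unknown) {
    bad_row(i, paste0("unknown record_type '", df$record_type[i], "'"))
  }

  is_pair <- df$record_type == "pair"
  empty_part <- is_pair & (!nzchar(df$id_a) | !nzchar(df$id_b_or_members))
  for (i in which(empty_part)) bad_row(i, "pair row with empty participant")
  bad_method <- is_pair & !empty_part &
    !df$method_class %in% c("binary_capable", "complex_derived")
  for (i in which(bad_method)) {
    bad_row(i, paste0("unknown method_class '", df$method_class[i], "'"))
  }
  self <- is_pair & !empty_part & !bad_method &
    df$id_a == df$id_b_or_members
  if (any(self)) {
    warning(sum(self), " self-loop pair record(s) dropped", call. = FALSE)
  }
  keep <- is_pair & !empty_part & !bad_method & !self
  records <- data.frame(
    a = df$id_a[keep], b = df$id_b_or_members[keep],
    method_class = df$method_class[keep],
    publication_ids = df$publication_ids[keep],
    source_db = df$source_db[keep], origin = "direct",
    stringsAsFactors = FALSE)

  complexes <- list()
  for (i in which(df$record_type == "complex")) {
    members <- trimws(strsplit(df$id_b_or_members[i], ";", fixed = TRUE)[[1]])
    members <- unique(members[nzchar(members)])
    if (length(members) < 2L) {
      bad_row(i, "complex with fewer than 2 members")
      next
    }
    bait <- df$bait[i]
    if (nzchar(bait) && !bait %in% members) {
      bad_row(i, paste0("bait '", bait, "' not among complex members"))
      next
    }
    complexes[[length(complexes) + 1L]] <- list(
      members = members,
      bait = if (nzchar(bait)) bait else NULL,
      publication_ids = df$publication_ids[i],
      source_db = df$source_db[i])
  }
  list(records = records, complexes = complexes)
}

empty_records <- function() {
  data.frame(a = character(), b = character(), method_class = character(),
             publication_ids = character(), source_db = character(),
             origin = character(), stringsAsFactors = FALSE)
}

#' Expand a protein complex into binary interaction records
#'
#' Affinity-purification complexes are converted to pairwise records using
#' the spoke model when the bait is known (bait-prey edges, `n - 1` edges for
#' `n` members) and the matrix model otherwise (all unordered member pairs,
#' `n (n - 1) / 2` edges). For two-member complexes the models coincide.
#'
#' @param cx A complex: `list(members, bait = NULL, publication_ids = "",
#'   source_db = "")`, `members` a character vector of length >= 2, `bait`
#'   either `NULL` or one of the members.
#' @return Data frame of complex-derived interaction records with `origin`
#'   `"spoke"` or `"matrix"`.
#' @export
#' @examples
#' expand_complex(list(members = c("A", "B", "C", "D"), bait = "A"))
expand_complex <- function(cx) {
  members <- unique(as.character(cx$members))
  if (length(members) < 2L) {
    stop("a complex needs at least 2 distinct members", call. = FALSE)
  }
  bait <- cx$bait
  if (!is.null(bait) && !bait %in% members) {
    stop("bait '", bait, "' is not a complex member", call. = FALSE)
  }
  if (!is.null(bait)) {
    others <- setdiff(members, bait)
    a <- rep(bait, length(others))
    b <- others
    origin <- "spoke"
  } else {
    idx <- utils::combn(length(members), 2L)
    a <- members[idx[1L, ]]
    b <- members[idx[2L, ]]
    origin <- "matrix"
  }
  data.frame(a = a, b = b, method_class = "complex_derived",
             publication_ids = cx$publication_ids %||% "",
             source_db = cx$source_db %||% "",
             origin = origin, stringsAsFactors = FALSE)
}

#' Evidence weight and confidence score of an interaction
#'
#' Each edge gets a deterministic score in `[0, 1]`:
#' `score = clamp(w_method + 0.1 * min(n_publications - 1, 4), 0, 1)` with
#' `w_method = 0.7` for binary-capable evidence, `0.5` for spoke-derived and
#' `0.4` for matrix-derived complex evidence; an edge with mixed evidence
#' takes the maximum weight. The score is monotone non-decreasing in the
#' number of distinct supporting publications and ranks binary evidence
#' above spoke above matrix at equal publication support, which makes the
#' 0.5 high-confidence threshold meaningful.
#'
#' @param method_class Character vector (`binary_capable`/`complex_derived`).
#' @param origin Character vector (`direct`/`spoke`/`matrix`).
#' @param n_publications Integer vector of distinct publication counts
#'   (0 allowed for synthetic records and treated as 1 for scoring).
#' @param weights Named numeric: method weights for `binary`, `spoke`,
#'   `matrix`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' score_confidence("binary_capable", "direct", 1)   # 0.7
#' score_confidence("complex_derived", "matrix", 1)  # 0.4
score_confidence <- function(method_class, origin, n_publications,
                             weights = c(binary = 0.7, spoke = 0.5,
                                         matrix = 0.4)) {
  w <- ifelse(method_class == "binary_capable", weights[["binary"]],
              ifelse(origin == "matrix", weights[["matrix"]],
                     weights[["spoke"]]))
  npub <- pmax(as.numeric(n_publications), 1)
  pmin(1, pmax(0, w + 0.1 * pmin(npub - 1, 4)))
}

#' Assemble an interactome from interaction records
#'
#' In `binary` mode only direct records backed by binary-capable detection
#' methods are used; complexes are ignored. In `expanded` mode all direct
#' records are combined with the spoke/matrix expansion of every complex.
#' Records are canonicalized to undirected edges (lexicographically smaller
#' identifier first), self-loops are dropped with a warning, and duplicate
#' edges are aggregated: publication counts use distinct publication
#' identifiers across all supporting records, origins and method classes are
#' unioned, and each aggregated edge is scored with [score_confidence()]
#' using its best evidence class.
#'
#' @param records Data frame of direct interaction records (see
#'   [parse_interactions()]).
#' @param complexes List of complexes (see [parse_interactions()]).
#' @param mode `"binary"` or `"expanded"`.
#' @param weights Passed to [score_confidence()].
#' @return An object of class `interactome`: `list(mode, edges)` where
#'   `edges` has columns `a`, `b`, `n_publications`, `method_classes`,
#'   `origins` (comma-separated), `score`.
#' @export
build_interactome <- function(records, complexes = list(),
                              mode = c("binary", "expanded"),
                              weights = c(binary = 0.7, spoke = 0.5,
                                          matrix = 0.4)) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    use <- records[records$origin == "direct" &
                     records$method_class == "binary_capable", , drop = FALSE]
  } else {
    expanded <- lapply(complexes, expand_complex)
    use <- rbind(records, do.call(rbind, c(list(empty_records()), expanded)))
  }
  if (nrow(use) == 0L) {
    return(structure(list(mode = mode, edges = empty_edges()),
                     class = "interactome"))
  }
  cp <- canonicalize_pairs(use$a, use$b)
  self <- cp$a == cp$b
  if (any(self)) {
    warning(sum(self), " self-loop record(s) dropped during assembly",
            call. = FALSE)
    use <- use[!self, , drop = FALSE]
    cp$a <- cp$a[!self]
    cp$b <- cp$b[!self]
  }
  key <- factor(paste(cp$a, cp$b, sep = "\r"))  # levels sort lexicographically
  lev <- levels(key)
  first <- match(lev, key)

  # distinct publication identifiers per aggregated edge
  pub_list <- strsplit(use$publication_ids, "|", fixed = TRUE)
  np_rec <- lengths(pub_list)
  pub_edge <- rep(as.integer(key), np_rec)
  pub_id <- unlist(pub_list, use.names = FALSE)
  ok <- nzchar(pub_id)
  pub_edge <- pub_edge[ok]
  pub_id <- pub_id[ok]
  dup <- duplicated(paste(pub_edge, pub_id, sep = "\r"))
  npub <- integer(length(lev))
  if (any(!dup)) {
    cnt <- rowsum(rep(1L, sum(!dup)), pub_edge[!dup])
    npub[as.integer(rownames(cnt))] <- cnt[, 1L]
  }

  has_binary <- rowsum((use$method_class == "binary_capable") + 0L, key)[, 1L] > 0L
  has_nonmatrix <- rowsum((use$origin != "matrix") + 0L, key)[, 1L] > 0L
  multi <- tabulate(as.integer(key), nbins = length(lev)) > 1L
  collapse_unique <- function(x) {
    # fast path: edges supported by a single record keep its value as-is
    out <- x[first]
    if (any(multi)) {
      sub <- as.integer(key) %in% which(multi)
      out[multi] <- vapply(split(x[sub], droplevels(key[sub])),
                           function(v) paste(sort(unique(v)), collapse = ","),
                           "")
    }
    out
  }
  # best evidence wins: binary > spoke (or any direct) > matrix
  score <- ifelse(has_binary,
                  score_confidence("binary_capable", "direct", npub, weights),
                  ifelse(has_nonmatrix,
                         score_confidence("complex_derived", "spoke", npub,
                                          weights),
                         score_confidence("complex_derived", "matrix", npub,
                                          weights)))
  edges <- data.frame(a = cp$a[first], b = cp$b[first],
                      n_publications = npub,
                      method_classes = unname(collapse_unique(use$method_class)),
                      origins = unname(collapse_unique(use$origin)),
                      score = unname(score), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(mode = mode, edges = edges), class = "interactome")
}

empty_edges <- function() {
  data.frame(a = character(), b = character(), n_publications = integer(),
             method_classes = character(), origins = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Keep only high-confidence interactions
#'
#' Removes every edge with a confidence score strictly below `threshold`
#' (an edge scored exactly at the threshold is retained). The node set of
#' the filtered interactome is the set of endpoints of surviving edges.
#'
#' @param g An `interactome`.
#' @param threshold Confidence threshold in `[0, 1]`; default 0.5.
#' @return A filtered `interactome`.
#' @export
filter_high_confidence <- function(g, threshold = 0.5) {
  stopifnot(inherits(g, "interactome"))
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  g$edges <- g$edges[g$edges$score >= threshold, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Union of two interactomes
#'
#' Edge-wise union with publication counts taken as the per-edge maximum and
#' origins/method classes unioned. Used to build the unfiltered "ALL"
#' network variant.
#'
#' @param g1,g2 `interactome` objects.
#' @return An `interactome` with `mode = "union"`.
#' @export
interactome_union <- function(g1, g2) {
  stopifnot(inherits(g1, "interactome"), inherits(g2, "interactome"))
  both <- rbind(g1$edges, g2$edges)
  if (nrow(both) == 0L) {
    return(structure(list(mode = "union", edges = empty_edges()),
                     class = "interactome"))
  }
  key <- factor(paste(both$a, both$b, sep = "\r"))
  first <- match(levels(key), key)
  collapse_csv <- function(x) {
    vapply(split(x, key), function(v) {
      paste(sort(unique(unlist(strsplit(v, ",", fixed = TRUE)))),
            collapse = ",")
    }, "")
  }
  edges <- data.frame(
    a = both$a[first], b = both$b[first],
    n_publications = unname(vapply(split(both$n_publications, key), max, 0)),
    method_classes = unname(collapse_csv(both$method_classes)),
    origins = unname(collapse_csv(both$origins)),
    score = unname(vapply(split(both$score, key), max, 0)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(mode = "union", edges = edges), class = "interactome")
}

#' Nodes of an interactome
#' @param g An `interactome`.
#' @return Sorted character vector of node identifiers.
#' @export
interactome_nodes <- function(g) {
  stopifnot(inherits(g, "interactome"))
  sort(unique(c(g$edges$a, g$edges$b)))
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome (%s): %d edges, %d nodes\n", x$mode,
              nrow(x$edges), length(interactome_nodes(x))))
  invisible(x)
}

as_igraph <- function(g) {
  stopifnot(inherits(g, "interactome"))
  if (nrow(g$edges) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::graph_from_data_frame(g$edges[, c("a", "b")], directed = FALSE)
}

#' Write a scored interactome as a TSV edge list
#'
#' @param g An `interactome`.
#' @param path Output path.
#' @param header_lines Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path, header_lines = character()) {
  stopifnot(inherits(g, "interactome"))
  write_tsv(g$edges[, c("a", "b", "score", "n_publications", "origins")],
            path, header_lines = header_lines)
}
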