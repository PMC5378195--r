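# Shared fixtures and independent oracles, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- catalog fixtures -------------------------------------------------------

toy_catalog <- function() {
  motive_catalog(
    motive = c("repair", "decay", "stress"),
    category = c("regenerative", "degenerative", "degenerative"),
    seeds = list(c("A", "B"), c("C", "D", "E"), c("B", "F"))
  )
}

write_catalog_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

table1_fixture_path <- function() {
  system.file("extdata", "motives_table1_synthetic.tsv",
              package = "motivenet")
}

# --- interaction fixtures ---------------------------------------------------

interaction_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id_a = r$id_a %||% "", id_b_or_members = r$id_b,
               record_type = r$type %||% "pair", bait = r$bait %||% "",
               method_class = r$method %||% "binary_capable",
               publication_ids = r$pubs %||% "P1",
               source_db = r$db %||% "dbA", stringsAsFactors = FALSE)
  }))
}

write_interactions_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pair_records <- function(a, b, method = "binary_capable", pubs = NULL) {
  n <- length(a)
  data.frame(a = a, b = b, method_class = rep_len(method, n),
             publication_ids = rep_len(pubs %||% paste0("P", seq_len(n)), n),
             source_db = rep_len("dbA", n), origin = rep_len("direct", n),
             stringsAsFactors = FALSE)
}

# interactome from a plain edge list, all binary with 1 publication each
edge_interactome <- function(a, b) {
  build_interactome(pair_records(a, b), list(), mode = "binary")
}

# --- quant fixtures ---------------------------------------------------------

quant_row <- function(peptide, protein, sample, condition, area) {
  data.frame(peptide = peptide, protein = protein, sample = sample,
             condition = condition, area = area, stringsAsFactors = FALSE)
}

# complete quant table: one row per peptide x sample, values supplied as a
# named list protein -> peptide matrix (peptides x samples)
quant_from_values <- function(values, samples, conditions) {
  out <- NULL
  for (prot in names(values)) {
    m <- values[[prot]]
    for (i in seq_len(nrow(m))) {
      out <- rbind(out, quant_row(paste0(prot, "_p", i), prot, samples,
                                  conditions, 2^m[i, ]))
    }
  }
  out
}

# --- independent oracles ----------------------------------------------------

# Naive O(N * |sig|) running-sum enrichment score, written directly from the
# definition; intentionally independent of the package's implementation.
oracle_es <- function(genes, scores, sig, p = 1) {
  n <- length(genes)
  hit <- genes %in% sig
  nh <- sum(hit)
  stopifnot(nh >= 1, nh < n)
  nr <- sum(abs(scores[hit])^p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + (if (nr > 0) abs(scores[i])^p / nr else 1 / nh)
    } else {
      cur <- cur - 1 / (n - nh)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# Brute-force k-step neighborhood by repeated adjacency scans.
oracle_neighborhood <- function(edges_a, edges_b, seeds, k) {
  reach <- intersect(seeds, c(edges_a, edges_b))
  for (step in seq_len(k)) {
    nb <- c(edges_b[edges_a %in% reach], edges_a[edges_b %in% reach])
    reach <- union(reach, nb)
  }
  sort(union(seeds, reach))
}

# deterministic ranked list over n genes
toy_ranking <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  make_ranking(data.frame(protein = genes, log2fc = scores,
                          stringsAsFactors = FALSE))
}
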