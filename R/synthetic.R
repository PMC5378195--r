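#' Specification for a synthetic study
#'
#' Bundles every parameter of the synthetic benchmark: interactome topology,
#' complex records, motive catalog shape, and the peptide-level noise model
#' with an optional planted group effect. All generators are pure functions
#' of the spec (including its `seed`), so identical specs reproduce
#' identical data byte for byte.
#'
#' Defaults mirror the study design the pipeline targets: a scale-free
#' interactome, 19 motives with 3-56 seeds split 10 regenerative / 9
#' degenerative, three conditions (uninjured control plus two injury
#' models) with 5 animals each, a planted log2 effect of 1.0 on the first
#' motive's high-confidence first-degree network in the `DA` condition, and
#' log-normal peptide noise of 0.5 on the log2 scale. The interactome
#' (16000 genes, the scale of a proteome-wide interaction map) is
#' deliberately much larger than the detected proteome (7.5% of genes,
#' about 1200 proteins, appear in the quant table, the scale of a label-free
#' LC-MS/MS experiment): network signatures restricted to the measured
#' universe are then small, weakly overlapping slices, as in real data.
#' Conflating the two scales makes neighborhood signatures strongly
#' correlated through shared hubs and is not representative.
#'
#' @param n_genes Number of interactome genes.
#' @param graph_model `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"`.
#' @param mean_degree Target mean degree of the binary interactome.
#' @param n_complexes Number of protein-complex records; every other one
#'   has a declared bait (spoke expansion), the rest none (matrix).
#' @param complex_size_range Integer range of complex sizes.
#' @param n_motives Number of motives in the generated catalog.
#' @param seed_size_range Integer range of per-motive seed counts.
#' @param off_graph_fraction Fraction of seeds replaced by identifiers
#'   absent from the interactome (exercises the isolated-seed path).
#' @param planted_motive Name of the motive carrying the planted effect
#'   (`NULL` for a global-null data set).
#' @param planted_variant Network variant whose gene set receives the
#'   effect (default `"hc_deg1"`).
#' @param affected_condition Condition in which planted proteins are
#'   shifted.
#' @param conditions Condition labels; the first is the control.
#' @param n_samples Samples (animals) per condition.
#' @param detected_fraction Fraction of proteins (interactome genes and
#'   off-graph seeds) detected in the quant table; detection is a uniform
#'   protein-level subset drawn once per study.
#' @param effect_delta Planted shift in log2 units.
#' @param noise_sd Per-measurement noise sd in log2 units (0 allowed for
#'   the noiseless limit).
#' @param peptides_per_protein Integer range of peptides per protein.
#' @param baseline_mean,baseline_sd Protein baseline log2 abundance model.
#' @param peptide_offset_sd Sd of the per-peptide ionization offset
#'   (constant across samples, so it cancels in fold changes).
#' @param publication_rate Poisson rate: publications per record are
#'   `1 + Poisson(rate)`.
#' @param confidence_threshold Threshold used when the planted variant
#'   needs the high-confidence interactome.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_genes = 16000,
                           graph_model = c("scale_free", "erdos_renyi"),
                           mean_degree = 4,
                           n_complexes = 600,
                           complex_size_range = c(3L, 8L),
                           n_motives = 19,
                           seed_size_range = c(3L, 56L),
                           off_graph_fraction = 0.05,
                           planted_motive = "motive_01",
                           planted_variant = "hc_deg1",
                           affected_condition = "DA",
                           conditions = c("Ctrl", "DA", "RA"),
                           n_samples = 5,
                           detected_fraction = 0.075,
                           effect_delta = 1.0,
                           noise_sd = 0.5,
                           peptides_per_protein = c(2L, 5L),
                           baseline_mean = 5,
                           baseline_sd = 1,
                           peptide_offset_sd = 0.3,
                           publication_rate = 0.5,
                           confidence_threshold = 0.5,
                           seed = 1L) {
  graph_model <- match.arg(graph_model)
  spec <- list(n_genes = as.integer(n_genes), graph_model = graph_model,
               mean_degree = mean_degree, n_complexes = as.integer(n_complexes),
               complex_size_range = as.integer(complex_size_range),
               n_motives = as.integer(n_motives),
               seed_size_range = as.integer(seed_size_range),
               off_graph_fraction = off_graph_fraction,
               planted_motive = planted_motive,
               planted_variant = planted_variant,
               affected_condition = affected_condition,
               conditions = conditions, n_samples = as.integer(n_samples),
               detected_fraction = detected_fraction,
               effect_delta = effect_delta, noise_sd = noise_sd,
               peptides_per_protein = as.integer(peptides_per_protein),
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               peptide_offset_sd = peptide_offset_sd,
               publication_rate = publication_rate,
               confidence_threshold = confidence_threshold,
               seed = as.integer(seed))
  if (spec$n_genes < spec$mean_degree + 1) {
    stop("n_genes must exceed mean_degree + 1", call. = FALSE)
  }
  if (spec$seed_size_range[2L] > spec$n_genes) {
    stop("seed_size_range exceeds n_genes", call. = FALSE)
  }
  if (spec$complex_size_range[1L] < 2L) {
    stop("complexes need at least 2 members", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$detected_fraction <= 0 || spec$detected_fraction > 1) {
    stop("detected_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(c(spec$n_motives, spec$n_samples, spec$n_complexes) < 1L)) {
    stop("counts must be positive", call. = FALSE)
  }
  if (!spec$planted_variant %in% variant_labels()) {
    stop("planted_variant must be one of: ",
         paste(variant_labels(), collapse = ", "), call. = FALSE)
  }
  if (!spec$affected_condition %in% spec$conditions) {
    stop("affected_condition must be one of the condition labels",
         call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic interactome
#'
#' Binary records follow a preferential-attachment (scale-free) or
#' Erdos-Renyi degree structure at the requested mean degree; complexes are
#' random member sets, alternately with and without a declared bait;
#' publication counts per record are `1 + Poisson(publication_rate)` with
#' globally distinct synthetic publication identifiers.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genes` (identifier vector), `records` (direct
#'   interaction records, all binary-capable), `complexes` (list of complex
#'   records) and `table` (the combined canonical interaction TSV as a data
#'   frame, see [parse_interactions()]).
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed, {
    n <- spec$n_genes
    genes <- sprintf("G%05d", seq_len(n))
    g <- if (spec$graph_model == "scale_free") {
      igraph::sample_pa(n, power = 1,
                        m = max(1L, round(spec$mean_degree / 2)),
                        directed = FALSE)
    } else {
      igraph::sample_gnm(n, round(n * spec$mean_degree / 2))
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    keep <- el[, 1L] != el[, 2L]
    el <- el[keep, , drop = FALSE]
    a <- genes[el[, 1L]]
    b <- genes[el[, 2L]]
    npub <- 1L + stats::rpois(length(a), spec$publication_rate)
    pub_ids <- split(sprintf("PUB%07d", seq_len(sum(npub))),
                     rep(seq_along(npub), npub))
    pubs <- vapply(pub_ids, paste, "", collapse = "|")
    records <- data.frame(a = a, b = b, method_class = "binary_capable",
                          publication_ids = pubs, source_db = "synthdb",
                          origin = "direct", stringsAsFactors = FALSE)
    complexes <- vector("list", spec$n_complexes)
    pub_counter <- sum(npub)
    for (i in seq_len(spec$n_complexes)) {
      size <- sample(seq(spec$complex_size_range[1L],
                         spec$complex_size_range[2L]), 1L)
      members <- sample(genes, size)
      pub_counter <- pub_counter + 1L
      complexes[[i]] <- list(
        members = members,
        bait = if (i %% 2L == 1L) members[1L] else NULL,
        publication_ids = sprintf("PUB%07d", pub_counter),
        source_db = "synthdb")
    }
    table <- rbind(
      data.frame(id_a = records$a, id_b_or_members = records$b,
                 record_type = "pair", bait = "",
                 method_class = records$method_class,
                 publication_ids = records$publication_ids,
                 source_db = records$source_db, stringsAsFactors = FALSE),
      do.call(rbind, lapply(complexes, function(cx) {
        data.frame(id_a = "", id_b_or_members = paste(cx$members,
                                                      collapse = ";"),
                   record_type = "complex", bait = cx$bait %||% "",
                   method_class = "complex_derived",
                   publication_ids = cx$publication_ids,
                   source_db = cx$source_db, stringsAsFactors = FALSE)
      }))
    )
    list(genes = genes, records = records, complexes = complexes,
         table = table)
  })
}

#' Generate a synthetic motive catalog
#'
#' Seed sets are sampled from the interactome genes, with a configurable
#' fraction replaced by off-graph identifiers; categories are split about
#' 10:9 regenerative to degenerative, mirroring the catalog shape the
#' pipeline is designed for.
#'
#' @param spec A [synthetic_spec()].
#' @param genes Gene identifiers of the interactome (from
#'   [generate_interactome()]).
#' @return A [motive_catalog()].
#' @export
generate_motives <- function(spec, genes) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$seed_size_range[2L] > length(genes)) {
    stop("seed_size_range exceeds the number of interactome genes",
         call. = FALSE)
  }
  with_rng_seed(spec$seed + 1L, {
    nm <- spec$n_motives
    n_reg <- round(nm * 10 / 19)
    names_ <- sprintf("motive_%02d", seq_len(nm))
    cats <- c(rep("regenerative", n_reg), rep("degenerative", nm - n_reg))
    off_counter <- 0L
    seeds <- vector("list", nm)
    for (i in seq_len(nm)) {
      size <- sample(seq(spec$seed_size_range[1L], spec$seed_size_range[2L]),
                     1L)
      s <- sample(genes, size)
      off <- stats::runif(size) < spec$off_graph_fraction
      if (any(off)) {
        s[off] <- sprintf("OFF%04d", off_counter + seq_len(sum(off)))
        off_counter <- off_counter + sum(off)
      }
      seeds[[i]] <- s
    }
    motive_catalog(names_, cats, seeds,
                   provenance = sprintf("synthetic (seed %d)", spec$seed))
  })
}

#' Generate a synthetic peptide quantification table
#'
#' Per protein: a baseline log2 abundance, a per-peptide ionization offset
#' (constant across samples), and per-measurement Gaussian noise on the
#' log2 scale; proteins of the planted gene set additionally receive
#' `effect_delta` in the affected condition. Areas are `2^value`, i.e. the
#' noise is log-normal on the raw scale. In the noiseless limit
#' (`noise_sd = 0`) the planted log2 fold change is recovered exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param proteins Character vector: the candidate universe; a uniform
#'   subset of size `detected_fraction * length(proteins)` (at least 2) is
#'   detected and quantified.
#' @param planted_genes Character vector of proteins carrying the effect
#'   (empty for a global null). Only detected planted proteins appear in
#'   the table; the truth ledger records both flags.
#' @return List with `quant` (data frame `peptide`, `protein`, `sample`,
#'   `condition`, `area`) and `truth` (per-protein ground-truth table).
#' @export
generate_quant <- function(spec, proteins, planted_genes = character()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed + 2L, {
    detected <- sort(sample(proteins,
                            max(2L, round(spec$detected_fraction *
                                            length(proteins)))))
    all_proteins <- proteins
    proteins <- detected
    np <- length(proteins)
    planted <- proteins %in% planted_genes
    baseline <- stats::rnorm(np, spec$baseline_mean, spec$baseline_sd)
    n_pep <- sample(seq(spec$peptides_per_protein[1L],
                        spec$peptides_per_protein[2L]), np, replace = TRUE)
    pep_protein <- rep(seq_len(np), n_pep)
    pep_id <- paste0(proteins[pep_protein], "_p",
                     unlist(lapply(n_pep, seq_len), use.names = FALSE))
    pep_offset <- stats::rnorm(length(pep_id), 0, spec$peptide_offset_sd)
    samples <- paste0(rep(spec$conditions, each = spec$n_samples), "_s",
                      rep(seq_len(spec$n_samples), length(spec$conditions)))
    sample_cond <- rep(spec$conditions, each = spec$n_samples)
    n_pep_total <- length(pep_id)
    n_samp <- length(samples)
    # long table: peptides x samples
    row_pep <- rep(seq_len(n_pep_total), times = n_samp)
    row_samp <- rep(seq_len(n_samp), each = n_pep_total)
    prot_idx <- pep_protein[row_pep]
    effect <- ifelse(planted[prot_idx] &
                       sample_cond[row_samp] == spec$affected_condition,
                     spec$effect_delta, 0)
    value <- baseline[prot_idx] + effect + pep_offset[row_pep] +
      stats::rnorm(length(row_pep), 0, spec$noise_sd)
    quant <- data.frame(
      peptide = pep_id[row_pep],
      protein = proteins[prot_idx],
      sample = samples[row_samp],
      condition = sample_cond[row_samp],
      area = 2^value,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      protein = all_proteins,
      detected = all_proteins %in% proteins,
      planted = all_proteins %in% planted_genes,
      effect_log2 = ifelse(all_proteins %in% planted_genes,
                           spec$effect_delta, 0),
      affected_condition = spec$affected_condition,
      n_peptides = ifelse(all_proteins %in% proteins,
                          n_pep[match(all_proteins, proteins)], 0L),
      stringsAsFactors = FALSE
    )
    list(quant = quant, truth = truth)
  })
}

# Resolve the planted gene set for a spec without building all signatures.
planted_signature <- function(spec, catalog, g_binary, g_expanded) {
  if (is.null(spec$planted_motive)) return(character())
  seeds <- motive_seeds(catalog, spec$planted_motive)
  switch(spec$planted_variant,
         seeds = sort(unique(seeds)),
         hc_deg1 = k_neighborhood(filter_high_confidence(
           g_expanded, spec$confidence_threshold), seeds, 1L)$genes,
         hc_deg2 = k_neighborhood(filter_high_confidence(
           g_expanded, spec$confidence_threshold), seeds, 2L)$genes,
         bin_deg1 = k_neighborhood(g_binary, seeds, 1L)$genes,
         bin_deg2 = k_neighborhood(g_binary, seeds, 2L)$genes,
         all = k_neighborhood(interactome_union(g_binary, g_expanded),
                              seeds, 2L)$genes)
}

#' Generate a complete synthetic study
#'
#' Chains [generate_interactome()], [generate_motives()] and
#' [generate_quant()], resolving the planted gene set from the requested
#' motive and network variant, and optionally writes all input files plus a
#' ground-truth ledger to a directory.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; created if missing. Writes
#'   `interactions.tsv`, `motives.tsv`, `quant.tsv` and `truth.tsv`.
#' @return List with `spec`, `genes`, `interactions` (records, complexes,
#'   table), `catalog`, `g_binary`, `g_expanded`, `planted_genes`, `quant`,
#'   `truth` and (when written) `paths`.
#' @export
simulate_study <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  inter <- generate_interactome(spec)
  catalog <- generate_motives(spec, inter$genes)
  if (!is.null(spec$planted_motive)) {
    known <- vapply(catalog$motives, `[[`, "", "name")
    if (!spec$planted_motive %in% known) {
      stop("planted motive '", spec$planted_motive,
           "' is not in the generated catalog", call. = FALSE)
    }
  }
  g_binary <- build_interactome(inter$records, list(), mode = "binary")
  g_expanded <- build_interactome(inter$records, inter$complexes,
                                  mode = "expanded")
  planted <- planted_signature(spec, catalog, g_binary, g_expanded)
  off_graph <- setdiff(unlist(lapply(catalog$motives, `[[`, "seeds"),
                              use.names = FALSE), inter$genes)
  universe <- c(inter$genes, sort(off_graph))
  gq <- generate_quant(spec, universe, planted)
  out <- list(spec = spec, genes = inter$genes, interactions = inter,
              catalog = catalog, g_binary = g_binary,
              g_expanded = g_expanded, planted_genes = planted,
              quant = gq$quant, truth = gq$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(interactions = file.path(dir, "interactions.tsv"),
               motives = file.path(dir, "motives.tsv"),
               quant = file.path(dir, "quant.tsv"),
               truth = file.path(dir, "truth.tsv"))
    write_tsv(inter$table, paths[["interactions"]])
    write_motive_table(catalog, paths[["motives"]])
    write_tsv(gq$quant, paths[["quant"]])
    write_tsv(gq$truth, paths[["truth"]])
    out$paths <- paths
  }
  out
}
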