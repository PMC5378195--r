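# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Keeps every generator a pure function of (spec, seed).
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Lexicographic canonicalization of undirected pairs: smaller id first.
canonicalize_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  list(a = a, b = b)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

write_tsv <- function(x, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Provenance header written at the top of every pipeline artifact.
# Deliberately timestamp-free so that re-runs with the same inputs and seed
# are byte-identical.
provenance_lines <- function(params) {
  vals <- vapply(params, function(v) paste(format(v), collapse = ","), "")
  c(paste0("motivenet ", as.character(utils::packageVersion("motivenet"))),
    paste0(names(vals), "=", vals))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
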