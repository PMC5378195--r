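test_that("parser separates pairs from complexes and enforces invariants", {
  p <- write_interactions_tsv(interaction_df(
    list(id_a = "A", id_b = "B"),
    list(id_a = "B", id_b = "C"),
    list(id_a = "C", id_b = "D"),
    list(id_b = "A;B;C", type = "complex", bait = "A",
         method = "complex_derived")))
  parsed <- parse_interactions(p)
  expect_identical(nrow(parsed$records), 3L)
  expect_identical(length(parsed$complexes), 1L)
  expect_identical(parsed$complexes[[1]]$bait, "A")

  p_self <- write_interactions_tsv(interaction_df(
    list(id_a = "A", id_b = "A"),
    list(id_a = "A", id_b = "B")))
  expect_warning(parsed2 <- parse_interactions(p_self), "self-loop")
  expect_identical(nrow(parsed2$records), 1L)

  p_bad <- write_interactions_tsv(interaction_df(
    list(id_a = "A", id_b = "B", type = "mystery"),
    list(id_a = "A", id_b = "B")))
  expect_warning(parsed3 <- parse_interactions(p_bad), "unknown record_type")
  expect_identical(nrow(parsed3$records), 1L)
  expect_error(suppressWarnings(parse_interactions(p_bad, strict = TRUE)),
               "unknown record_type")
})

test_that("empty interaction file parses to empty lists", {
  header_only <- interaction_df(list(id_a = "A", id_b = "B"))[0, ]
  p <- write_interactions_tsv(header_only)
  parsed <- parse_interactions(p)
  expect_identical(nrow(parsed$records), 0L)
  expect_identical(length(parsed$complexes), 0L)
  # a zero-byte file counts as empty too
  p0 <- tempfile()
  file.create(p0)
  parsed0 <- parse_interactions(p0)
  expect_identical(nrow(parsed0$records), 0L)
})

test_that("spoke and matrix expansion produce the expected edge counts", {
  for (n in 2:8) {
    members <- LETTERS[seq_len(n)]
    spoke <- expand_complex(list(members = members, bait = members[1]))
    expect_identical(nrow(spoke), n - 1L)
    expect_true(all(spoke$origin == "spoke"))
    matrix_ <- expand_complex(list(members = members))
    expect_identical(nrow(matrix_), as.integer(n * (n - 1) / 2))
    expect_true(all(matrix_$origin == "matrix"))
    # spoke edges are a subset of matrix edges on the same member set
    canon <- function(df) {
      cp <- t(apply(df[, c("a", "b")], 1, sort))
      paste(cp[, 1], cp[, 2])
    }
    expect_true(all(canon(spoke) %in% canon(matrix_)))
  }
  # n = 2 degeneracy: both models give the single edge
  s2 <- expand_complex(list(members = c("A", "B"), bait = "A"))
  m2 <- expand_complex(list(members = c("A", "B")))
  expect_identical(sort(c(s2$a, s2$b)), sort(c(m2$a, m2$b)))
  expect_error(expand_complex(list(members = "A")), "at least 2")
  expect_error(expand_complex(list(members = c("A", "B"), bait = "Z")),
               "not a complex member")
})

test_that("binary mode excludes complexes; expanded mode unions them", {
  records <- pair_records("B", "C")
  cx <- list(list(members = c("A", "B", "C"), bait = "A",
                  publication_ids = "P9", source_db = "dbB"))
  g_bin <- build_interactome(records, cx, mode = "binary")
  expect_identical(nrow(g_bin$edges), 1L)
  g_exp <- build_interactome(records, cx, mode = "expanded")
  expect_identical(nrow(g_exp$edges), 3L)   # B-C direct, A-B and A-C spoke
  expect_setequal(interactome_nodes(g_exp), c("A", "B", "C"))
  # an edge reported both directly and via a complex merges into one record
  overlap <- build_interactome(pair_records("A", "B"), cx,
                               mode = "expanded")
  ab <- overlap$edges[overlap$edges$a == "A" & overlap$edges$b == "B", ]
  expect_identical(nrow(ab), 1L)
  expect_identical(ab$n_publications, 2L)
  expect_identical(ab$origins, "direct,spoke")
})

test_that("duplicate edges aggregate distinct publications", {
  records <- rbind(
    pair_records("A", "B", pubs = "P1"),
    pair_records("B", "A", pubs = "P2"),   # same edge, reversed, new pub
    pair_records("A", "B", pubs = "P1"))   # redundant row, same pub
  g <- build_interactome(records, list(), mode = "binary")
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$n_publications, 2L)
})

test_that("assembly is idempotent under record duplication", {
  records <- pair_records(c("A", "B", "C"), c("B", "C", "D"))
  g1 <- build_interactome(records, list(), mode = "binary")
  g2 <- build_interactome(rbind(records, records), list(), mode = "binary")
  expect_identical(g1$edges[, c("a", "b")], g2$edges[, c("a", "b")])
  expect_identical(g1$edges$n_publications, g2$edges$n_publications)
})

test_that("confidence scores follow the evidence hierarchy", {
  expect_equal(score_confidence("binary_capable", "direct", 1), 0.7)
  expect_equal(score_confidence("complex_derived", "spoke", 1), 0.5)
  expect_equal(score_confidence("complex_derived", "matrix", 1), 0.4)
  # monotone non-decreasing in publications, capped at 1
  for (mc in list(c("binary_capable", "direct"),
                  c("complex_derived", "spoke"),
                  c("complex_derived", "matrix"))) {
    s <- score_confidence(mc[1], mc[2], 1:10)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
  # mixed evidence takes the best class: a binary + matrix edge scores 0.7
  records <- pair_records("A", "B", pubs = "P1")
  cx <- list(list(members = c("A", "B"), bait = NULL,
                  publication_ids = "P1", source_db = "dbB"))
  g <- build_interactome(records, cx, mode = "expanded")
  expect_equal(g$edges$score, 0.7)
})

test_that("high-confidence filter keeps the boundary and is monotone", {
  records <- rbind(pair_records("A", "B", pubs = "P1"),          # 0.7
                   pair_records("E", "F", pubs = "P1"))
  cx <- list(list(members = c("C", "D"), bait = NULL,
                  publication_ids = "P2", source_db = "x"),      # matrix 0.4
              list(members = c("G", "H"), bait = "G",
                   publication_ids = "P3", source_db = "x"))     # spoke 0.5
  g <- build_interactome(records[1, ], cx, mode = "expanded")
  expect_setequal(g$edges$score, c(0.7, 0.4, 0.5))
  kept <- filter_high_confidence(g, 0.5)
  expect_identical(nrow(kept$edges), 2L)          # 0.5 retained, 0.4 removed
  expect_identical(nrow(filter_high_confidence(g, 0)$edges), nrow(g$edges))
  expect_identical(nrow(filter_high_confidence(g, 1)$edges), 0L)
  expect_error(filter_high_confidence(g, 1.5), "\\[0, 1\\]")
  # edge-set monotonicity in the threshold
  thresholds <- seq(0, 1, by = 0.1)
  sizes <- vapply(thresholds,
                  function(t) nrow(filter_high_confidence(g, t)$edges), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("interactome round-trips through its TSV edge list", {
  g <- edge_interactome(c("A", "B"), c("B", "C"))
  p <- tempfile(fileext = ".tsv")
  write_interactome(g, p, header_lines = "fixture")
  back <- read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
  expect_identical(back$a, g$edges$a)
  expect_identical(back$b, g$edges$b)
  expect_equal(back$score, g$edges$score)
})
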