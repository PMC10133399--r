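test_that("edge tables de-duplicate, drop self-loops and canonicalize", {
  p <- tempfile()
  writeLines(c("source\ttarget\ttype\tdirected",
               "G2\tG1\tbinding\tFALSE",
               "G1\tG2\tbinding\tFALSE",   # same undirected edge, swapped
               "G1\tG3\tbinding\tFALSE",
               "G1\tG1\tactivation\tFALSE", # self-loop
               "G3\tG4\tbinding\tFALSE"), p)
  expect_warning(net <- load_edge_table(p), "1 self-loop")
  expect_equal(nrow(net), 3L)
  expect_true(all(net$source <= net$target))
})

test_that("exact duplicate rows collapse (5 rows with 1 duplicate -> 4 edges)", {
  p <- tempfile()
  writeLines(c("source\ttarget",
               "A\tB", "A\tB", "B\tC", "C\tD", "D\tE"), p)
  net <- load_edge_table(p)
  expect_equal(nrow(net), 4L)
})

test_that("canonical undirected edge set is row-order invariant", {
  rows <- c("G1\tG5\tb\tFALSE", "G2\tG4\tb\tFALSE", "G5\tG3\tb\tFALSE",
            "G4\tG1\tb\tFALSE")
  key_of <- function(rows) {
    p <- tempfile()
    writeLines(c("source\ttarget\ttype\tdirected", rows), p)
    net <- load_edge_table(p)
    sort(paste(net$source, net$target, sep = "|"))
  }
  set.seed(42)
  for (i in 1:5)
    expect_identical(key_of(sample(rows)), key_of(rows))
})

test_that("directed edges keep their orientation", {
  p <- tempfile()
  writeLines(c("source\ttarget\ttype\tdirected", "G9\tG1\tregulates\tTRUE"), p)
  net <- load_edge_table(p)
  expect_identical(net$source, "G9")
  expect_identical(net$target, "G1")
})

test_that("SIF dialect is read as undirected source<TAB>type<TAB>target", {
  p <- tempfile()
  writeLines(c("G2\tactivation\tG1", "G1\tbinding\tG3"), p)
  net <- load_edge_table(p, dialect = "sif")
  expect_equal(nrow(net), 2L)
  expect_identical(net$interaction_type, c("activation", "binding"))
  expect_true(all(net$source <= net$target))
  expect_false(any(net$directed))
})

test_that("network edge list round-trips through write_edge_table", {
  p <- write_tiny_network()
  net <- load_edge_table(p)
  p2 <- tempfile()
  write_edge_table(net, p2)
  net2 <- load_edge_table(p2)
  expect_identical(as.data.frame(net2), as.data.frame(net))
})

test_that("identifier mapping translates endpoints and reports unmapped ids", {
  net <- as_meta_network(
    data.frame(source = c("e1", "e1"), target = c("e2", "e9")),
    id_space = "entrez")
  mapping <- c(e1 = "GENE1", e2 = "GENE2")
  out <- suppressMessages(map_identifiers(net, mapping, TRUE))
  keys <- paste(out$source, out$target, sep = "|")
  expect_setequal(keys, c("GENE1|GENE2", "GENE1|e9"))
  expect_identical(attr(out, "unmapped"), "e9")
  expect_identical(attr(out, "id_space"), "symbol")
  # flag off -> identity
  expect_identical(map_identifiers(net, mapping, FALSE), net)
  expect_error(map_identifiers(net, character(0), TRUE), "empty")
  sym_net <- as_meta_network(data.frame(source = "A", target = "B"))
  expect_error(map_identifiers(sym_net, mapping, TRUE), "Entrez")
})

test_that("id mapping loader enforces single-valued mappings", {
  p <- tempfile()
  writeLines(c("entrez\tsymbol", "1\tTP53", "2\tKDR"), p)
  m <- load_id_mapping(p)
  expect_identical(m[["1"]], "TP53")
  writeLines(c("entrez\tsymbol", "1\tTP53", "1\tOTHER"), p)
  expect_error(load_id_mapping(p), "single-valued")
})

test_that("restriction to measured genes drops edges, is idempotent, errors on disjoint", {
  net <- as_meta_network(data.frame(source = c("A", "B"),
                                    target = c("B", "C")))
  expr <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  r <- suppressMessages(restrict_to_measured_genes(net, expr))
  expect_equal(nrow(r), 1L)
  expect_identical(r$source, "A")
  expect_identical(suppressMessages(restrict_to_measured_genes(r, expr)), r)
  expr_all <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  expect_identical(restrict_to_measured_genes(net, expr_all), net)
  expr_none <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("S1", "S2")))
  expect_error(restrict_to_measured_genes(net, expr_none),
               class = "deggs_input_error")
})

test_that("an empty edge set after cleaning is a hard error", {
  p <- tempfile()
  writeLines(c("source\ttarget", "G1\tG1"), p)
  expect_warning(expect_error(load_edge_table(p), "no edges"))
})
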