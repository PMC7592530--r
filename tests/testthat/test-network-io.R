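test_that("edge-list reading removes self-loops and duplicates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tC", "A\tB"), f)
  net <- read_edge_list(f)
  ed <- igraph::as_data_frame(net, what = "edges")
  expect_setequal(paste(ed$from, ed$to), c("A B", "B C"))
  expect_equal(igraph::vcount(net), 3)
  expect_true(any(grepl("1 self-loop", network_provenance(net))))
})

test_that("vertex-only rows can introduce (and then lose) isolated genes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "D"), f)
  net <- read_edge_list(f)
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_true(any(grepl("1 isolated", network_provenance(net))))
})

test_that("edge-list header detection and CSV separators work", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "A\tB"), f)
  expect_equal(igraph::ecount(read_edge_list(f)), 1)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("A,B", "B,C"), f2)
  expect_equal(igraph::ecount(read_edge_list(f2)), 2)
  # forcing no header keeps the first row as data
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2", "A\tB"), f3)
  expect_equal(igraph::vcount(read_edge_list(f3, header = "no")), 4)
})

test_that("malformed and empty edge lists raise informative errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "C\t"), f)
  expect_error(read_edge_list(f), "line 2")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(character(), f2)
  expect_error(read_edge_list(f2), "empty")
})

test_that("constructed networks satisfy the container invariants on random input", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    ed <- data.frame(from = sprintf("g%d", sample.int(12, n, TRUE)),
                     to = sprintf("g%d", sample.int(12, n, TRUE)))
    net <- tryCatch(interaction_network(ed), error = function(e) NULL)
    if (is.null(net)) next  # all edges were self-loops
    expect_false(any(igraph::which_loop(net)))
    expect_false(igraph::any_multiple(net))
    expect_true(all(igraph::degree(net, mode = "all") >= 1))
  }
})

test_that("merging networks is order-independent", {
  nets <- list(
    interaction_network(data.frame(from = c("A", "B"), to = c("B", "C"))),
    interaction_network(data.frame(from = c("B", "X"), to = c("C", "Y"))),
    interaction_network(data.frame(from = "C", to = "A")))
  key <- function(n) {
    ed <- igraph::as_data_frame(n, what = "edges")
    sort(paste(ed$from, ed$to))
  }
  m1 <- merge_networks(nets)
  m2 <- merge_networks(rev(nets))
  expect_identical(key(m1), key(m2))
  expect_setequal(igraph::V(m1)$name, igraph::V(m2)$name)
  expect_identical(key(m1), sort(c("A B", "B C", "C A", "X Y")))
})

test_that("KGML relations are extracted, filtered and merged with union semantics", {
  entries <- data.frame(id = 1:4,
                        name = c("hsa:111", "hsa:222", "cpd:C00001", "hsa:333"),
                        type = c("gene", "gene", "compound", "gene"))
  rel <- data.frame(entry1 = c(1, 2, 1), entry2 = c(2, 3, 4),
                    type = c("PPrel", "PCrel", "PPrel"))
  f1 <- write_kgml_fixture(tempfile(fileext = ".xml"), entries, rel)
  net <- read_kgml(f1)
  ed <- igraph::as_data_frame(net, what = "edges")
  # 3 relations, 1 with a compound endpoint -> 2 edges survive
  expect_setequal(paste(ed$from, ed$to), c("hsa:111 hsa:222", "hsa:111 hsa:333"))

  # a second file sharing the 111->222 relation adds nothing new
  f2 <- write_kgml_fixture(tempfile(fileext = ".xml"),
                           entries[1:2, ], data.frame(entry1 = 1, entry2 = 2,
                                                      type = "PPrel"))
  net2 <- read_kgml(c(f1, f2))
  expect_equal(igraph::ecount(net2), 2)

  # self-relation collapses to a self-loop and is dropped
  f3 <- write_kgml_fixture(tempfile(fileext = ".xml"), entries[1:2, ],
                           data.frame(entry1 = c(1, 1), entry2 = c(1, 2),
                                      type = "PPrel"))
  expect_equal(igraph::ecount(read_kgml(f3)), 1)
})

test_that("KGML group entries expand to their member genes", {
  entries <- data.frame(id = 1:3,
                        name = c("hsa:1", "hsa:2", "undefined"),
                        type = c("gene", "gene", "group"))
  rel <- data.frame(entry1 = 3, entry2 = 1, type = "PPrel")
  # group 3 contains only gene 2, so the relation is 2 -> 1
  f <- write_kgml_fixture(tempfile(fileext = ".xml"), entries, rel,
                          groups = list("3" = 2))
  ed <- igraph::as_data_frame(read_kgml(f), what = "edges")
  expect_identical(paste(ed$from, ed$to), "hsa:2 hsa:1")
})

test_that("metabolic KGML files are skipped unless requested", {
  entries <- data.frame(id = 1:2, name = c("hsa:1", "hsa:2"),
                        type = c("gene", "gene"))
  rel <- data.frame(entry1 = 1, entry2 = 2, type = "ECrel")
  f <- write_kgml_fixture(tempfile(fileext = ".xml"), entries, rel,
                          metabolic = TRUE)
  expect_error(suppressMessages(read_kgml(f)), "no usable")
  expect_equal(igraph::ecount(read_kgml(f, include_metabolic = TRUE)), 1)
})

test_that("KGML gene IDs are converted via the mapping table, unmapped kept", {
  entries <- data.frame(id = 1:2, name = c("hsa:111", "hsa:222"),
                        type = c("gene", "gene"))
  rel <- data.frame(entry1 = 1, entry2 = 2, type = "PPrel")
  f <- write_kgml_fixture(tempfile(fileext = ".xml"), entries, rel)
  map <- data.frame(id = "hsa:111", symbol = "MAPK1")
  expect_warning(net <- read_kgml(f, id_map = map), "not in mapping")
  ed <- igraph::as_data_frame(net, what = "edges")
  expect_identical(paste(ed$from, ed$to), "MAPK1 hsa:222")
})

test_that("unparseable KGML names the offending file", {
  f <- tempfile(fileext = ".xml")
  writeLines("<pathway><entry", f)
  expect_error(read_kgml(f), basename(f), fixed = TRUE)
})

test_that("GMT reading applies set semantics and validates structure", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tsource2\tC\tD"), f)
  sets <- read_gmt(f)
  expect_length(sets, 2)
  expect_setequal(sets$S1$members, c("A", "B"))
  expect_setequal(sets$S2$members, c("C", "D"))
  expect_identical(sets$S2$source, "source2")

  f2 <- tempfile(fileext = ".gmt"); writeLines(character(), f2)
  expect_error(read_gmt(f2), "empty")
  f3 <- tempfile(fileext = ".gmt"); writeLines(c("S1\tdesc\tA", "bad\tline"), f3)
  expect_error(read_gmt(f3), "line 2")
  f4 <- tempfile(fileext = ".gmt")
  writeLines(c("S1\td\tA", "S1\td\tB"), f4)
  expect_error(read_gmt(f4), "duplicate")
})

test_that("GMT reader agrees with fgsea's reader on a fixture", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tB\tD"), f)
  mine <- lapply(read_gmt(f), `[[`, "members")
  ref <- fgsea::gmtPathways(f)
  expect_identical(lapply(ref, sort), lapply(mine, sort)[names(ref)])
})

test_that("GMT round-trips through write_gmt", {
  sets <- as_gene_sets(list(gene_set("S1", c("A", "B"), source = "d1"),
                            gene_set("S2", c("C", "D", "E"))))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(lapply(back, `[[`, "members"),
                   lapply(sets, `[[`, "members"))
})

test_that("graph serialization round-trips for TSV and GraphML", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("S1", "S2"), to = c("S2", "S3"),
               weight = c(1.4, 2.25), p_value = c(0.001, 0.02)))
  for (fmt in c("tsv", "graphml")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_graph_file(g, f, format = fmt)
    back <- read_graph_file(f, format = fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    ed0 <- igraph::as_data_frame(g, what = "edges")
    ed1 <- igraph::as_data_frame(back, what = "edges")
    ed1 <- ed1[order(ed1$from), ]
    expect_equal(ed1$weight, ed0$weight)
    expect_identical(paste(ed1$from, ed1$to), paste(ed0$from, ed0$to))
  }
})

test_that("DOT export contains weighted edge statements", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("S1", "S2"), to = c("S2", "S3"),
               weight = c(1.4, 2.0)))
  f <- tempfile(fileext = ".dot")
  write_graph_file(g, f, format = "dot")
  txt <- readLines(f)
  expect_length(grep("->", txt), 2)
  expect_true(any(grepl("weight", txt)))
})

test_that("writing rejects unknown formats and empty graphs", {
  g <- igraph::graph_from_data_frame(data.frame(from = "A", to = "B"))
  expect_error(write_graph_file(g, tempfile(), format = "gexf"))
  empty <- igraph::make_empty_graph()
  expect_error(write_graph_file(empty, tempfile(), format = "tsv"), "empty")
})
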