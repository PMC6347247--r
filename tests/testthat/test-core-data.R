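test_that("age schemas enforce ordering, uniqueness and boundary cutoffs", {
  expect_error(age_schema(character(0), integer(0)), "at least one")
  expect_error(age_schema(c("a", "a"), c(0, 5)), "unique")
  expect_error(age_schema(c("a", "b"), c(5, 5)), "strictly increasing")

  s18 <- default_age_schema()
  expect_equal(n_groups(s18), 18L)
  expect_equal(s18$labels[c(1L, 13L, 18L)], c("0-4", "60-64", "85+"))

  reg <- tiny_registry(n_areas = 2L, n_groups = 3L)  # bounds 0, 10, 20
  cut <- restrict_to_age(reg$events, reg$population, 20L)
  expect_equal(n_groups(cut$events$schema), 2L)
  expect_equal(cut$events$counts, reg$events$counts[, 1:2])
  expect_error(restrict_to_age(reg$events, reg$population, 15L),
               "nearest boundaries: 10, 20")
  # cutoff beyond the top bound is the identity
  same <- restrict_to_age(reg$events, reg$population, 100L)
  expect_identical(same$events$counts, reg$events$counts)
})

test_that("under-65 cutoff on the default schema keeps 13 groups and commutes with aggregation", {
  set.seed(11)
  s <- default_age_schema()
  ids <- paste0("m", 1:4)
  ev <- event_table(ids, matrix(rpois(4 * 18, 3), 4), s)
  pop <- population_table(ids, matrix(1000, 4, 18), s, 5)
  cut <- restrict_to_age(ev, pop, 65L)
  expect_equal(n_groups(cut$events$schema), 13L)
  expect_equal(max(cut$events$schema$lower_bounds), 60L)
  # restrict-then-sum equals sum-then-restrict over areas
  expect_equal(colSums(cut$events$counts), colSums(ev$counts)[1:13])
  expect_equal(sum(event_totals(cut$events)), sum(ev$counts[, 1:13]))
})

test_that("event tables validate counts and read from CSV dialects", {
  expect_error(event_table(c("A", "A"), c(1, 2)), "duplicate")
  expect_error(event_table("A", -1), "non-negative")
  expect_error(event_table("A", 1.5), "integers")

  p <- write_tmp_csv(c("area_id,total", "A,3", "B,0"))
  ev <- suppressMessages(read_event_table(p))
  expect_equal(event_totals(ev), c(A = 3, B = 0))

  expect_error(suppressMessages(
    read_event_table(write_tmp_csv(c("area_id,total", "A,-1")))),
    "non-negative")
  expect_error(suppressMessages(
    read_event_table(write_tmp_csv(c("area_id,total", "A,x1")))),
    "row 1, column 'total'")
  expect_error(suppressMessages(
    read_event_table(write_tmp_csv(c("area_id,total", "A,1", "A,2")))),
    "duplicate")
})

test_that("age-stratified event CSVs parse per-group and total correctly", {
  s18 <- default_age_schema()
  set.seed(3)
  counts <- rpois(18, 2)
  counts[5] <- counts[5] + 29 - sum(counts)  # force a known total
  if (any(counts < 0)) counts <- abs(counts)
  header <- paste(c("area_id", s18$labels), collapse = ",")
  p <- write_tmp_csv(c(header, paste(c("A", counts), collapse = ",")))
  ev <- suppressMessages(read_event_table(p, s18))
  expect_equal(unname(event_totals(ev)), sum(counts))
  expect_equal(as.numeric(ev$counts[1, ]), counts)

  # missing cells are zero-filled with a log message
  p2 <- write_tmp_csv(c("area_id,total", "A,", "B,2"))
  msgs <- capture_messages(ev2 <- read_event_table(p2))
  expect_match(msgs, "missing cell", all = FALSE)
  expect_equal(event_totals(ev2), c(A = 0, B = 2))
})

test_that("population tables compute person-years and validate their inputs", {
  s <- age_schema("all", 0)
  pop <- population_table("A", matrix(1000), s, period_years = 5)
  expect_equal(as.numeric(person_years(pop)), 5000)
  expect_error(population_table("A", matrix(1000), s, 0), "positive")
  expect_error(population_table(c("A", "A"), matrix(1, 2, 1), s, 5),
               "duplicate")

  p <- write_tmp_csv(c("area_id,g1,g2", "A,100,200"))
  pt <- suppressMessages(read_population_table(p, tiny_schema(2L), 5))
  expect_equal(as.numeric(person_years(pt)), c(500, 1000))
  expect_error(suppressMessages(
    read_population_table(p, tiny_schema(3L), 5)), "schema mismatch")
})

test_that("event and population tables round-trip through CSV exactly", {
  reg <- tiny_registry(n_areas = 4L, n_groups = 3L)
  pe <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  write_event_table(reg$events, pe)
  write_population_table(reg$population, pp)
  ev2 <- suppressMessages(read_event_table(pe, reg$schema))
  pop2 <- suppressMessages(read_population_table(pp, reg$schema, 5))
  expect_equal(ev2$counts, reg$events$counts)
  expect_equal(pop2$counts, reg$population$counts)
  expect_identical(ev2$area_ids, reg$events$area_ids)
})

test_that("adjacency graphs reject self-loops, keep isolates and count components", {
  g <- adjacency_graph(c("A", "B", "C"), cbind("A", "B"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$n_components, 2L)
  expect_equal(neighbor_lists(g)[[3L]], integer(0))
  expect_error(adjacency_graph(c("A", "B"), cbind("A", "A")), "elf-loop")
  expect_error(adjacency_graph(c("A", "B"), cbind("A", "Z")), "absent")
  # duplicate and reversed edges collapse
  g2 <- adjacency_graph(c("A", "B"), rbind(c("A", "B"), c("B", "A")))
  expect_equal(nrow(g2$edges), 1L)
})

test_that("GAL files parse, symmetrize one-sided listings and round-trip", {
  # 2x2 rook lattice written symmetrically
  gal <- c("4", "n1 2", "n2 n3", "n2 2", "n1 n4", "n3 2", "n1 n4",
           "n4 2", "n2 n3")
  gal_path <- tempfile(fileext = ".gal")
  writeLines(gal, gal_path)
  g <- suppressMessages(read_adjacency(gal_path))
  expect_equal(nrow(g$edges), 4L)
  expect_equal(g$n_components, 1L)

  # one-sided listing symmetrized with a warning
  gal1 <- c("2", "a 1", "b", "b 0")
  path1 <- tempfile(fileext = ".gal"); writeLines(gal1, path1)
  expect_warning(g1 <- suppressMessages(read_adjacency(path1)),
                 "symmetriz")
  expect_equal(nrow(g1$edges), 1L)

  # symmetrization is idempotent: re-reading the symmetric write-out
  # changes nothing and warns about nothing
  path2 <- tempfile(fileext = ".gal")
  write_gal(g1, path2)
  expect_no_warning(g2 <- suppressMessages(read_adjacency(path2)))
  expect_equal(g2$edges, g1$edges)

  # neighbour ids must exist; self-loops are rejected
  bad <- tempfile(fileext = ".gal")
  writeLines(c("1", "a 1", "zz"), bad)
  expect_error(suppressMessages(read_adjacency(bad)), "absent")
  loop <- tempfile(fileext = ".gal")
  writeLines(c("1", "a 1", "a"), loop)
  expect_error(suppressMessages(read_adjacency(loop)), "elf-loop")
})

test_that("edge-list CSVs are accepted as an adjacency dialect", {
  p <- write_tmp_csv(c("from,to", "A,B", "B,C"))
  g <- suppressMessages(read_adjacency(p, area_ids = c("A", "B", "C", "D")))
  expect_equal(length(g$area_ids), 4L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$n_components, 2L)  # D isolated
})

test_that("adjacency graphs round-trip through GAL exactly", {
  set.seed(99)
  for (i in 1:5) {
    g <- random_graph(sample(3:8, 1L))
    path <- tempfile(fileext = ".gal")
    write_gal(g, path)
    g2 <- suppressMessages(read_adjacency(path))
    expect_equal(g2$edges, g$edges)
    expect_identical(g2$area_ids, g$area_ids)
  }
})
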