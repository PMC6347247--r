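# shared fixture builders: everything generated in code, nothing on disk

tiny_schema <- function(n = 2L) {
  age_schema(paste0("g", seq_len(n)), seq(0L, by = 10L, length.out = n))
}

# small event/population pair on a shared schema
tiny_registry <- function(n_areas = 3L, n_groups = 2L, period = 5,
                          seed = 42L) {
  set.seed(seed)
  s <- tiny_schema(n_groups)
  ids <- LETTERS[seq_len(n_areas)]
  pop <- matrix(sample(500:2000, n_areas * n_groups, replace = TRUE),
                nrow = n_areas)
  ev <- matrix(rpois(n_areas * n_groups, 5), nrow = n_areas)
  list(schema = s,
       events = event_table(ids, ev, s),
       population = population_table(ids, pop, s, period))
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Erdos-Renyi-ish random graph over n named nodes (may be disconnected)
random_graph <- function(n, p = 0.4) {
  ids <- paste0("v", seq_len(n))
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  adjacency_graph(ids, cbind(ids[pairs[keep, 1L]], ids[pairs[keep, 2L]]))
}

expect_silent_messages <- function(expr) {
  expect_no_warning(suppressMessages(expr))
}
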