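test_that("the generator is deterministic and validates its configuration", {
  cfg <- sim_config(n_sequences = 50, n_positions = 20,
                    networks = list(list(level = 1, positions = c(3, 8),
                                         keyword = "activity")),
                    seed = 44)
  a <- simulate_family(cfg)
  b <- simulate_family(cfg)
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  write_alignment(a$msa, fa); write_alignment(b$msa, fb)
  expect_identical(readLines(fa), readLines(fb))   # same seed, same bytes
  c2 <- simulate_family(sim_config(n_sequences = 50, n_positions = 20,
                                   networks = cfg$networks, seed = 45))
  expect_false(identical(a$msa$mat, c2$msa$mat))
  # invalid configs are rejected before any simulation
  expect_error(sim_config(subgroup_weights = c(0.5, 0.6)),
               class = "config_error")
  expect_error(sim_config(n_positions = 20,
                          networks = list(
                            list(level = 1, positions = c(3, 8),
                                 keyword = "a"),
                            list(level = 1, positions = c(8, 12),
                                 keyword = "b"))),
               class = "config_error")
  expect_error(sim_config(n_positions = 10,
                          networks = list(list(level = 1, positions = 30,
                                               keyword = "a"))),
               class = "config_error")
  expect_error(sim_config(networks = list(list(level = 2, positions = 3,
                                               keyword = "a"))),
               class = "config_error")
})

test_that("deterministic coupling and pure background behave as designed", {
  # p_cons 1, no gaps, 2 groups, one 2-position network: perfect coupling
  cfg <- sim_config(n_sequences = 200, n_positions = 6,
                    subgroup_weights = c(0.5, 0.5),
                    networks = list(list(level = 1, positions = c(2, 5),
                                         keyword = "activity")),
                    p_cons = 1, gap_rate = 0, seed = 3)
  sim <- simulate_family(cfg)
  core <- derive_core_positions(sim$msa, 1)
  expect_equal(nmi_score(sim$msa, core, 2, 5, cma_config("nmi")), 1)
  # background-only family: no pair scores high at large n
  bg <- simulate_family(sim_config(n_sequences = 5000, n_positions = 12,
                                   networks = list(), seed = 8))
  bcore <- derive_core_positions(bg$msa)
  bmat <- compute_cma_matrix(bg$msa, bcore, cma_config("nmi"))
  expect_lt(max(bmat$scores, na.rm = TRUE), 0.05)
})

test_that("planted networks dominate the background score distribution", {
  sim <- simulate_family(sim_config(n_sequences = 2000, n_positions = 60,
                                    networks = list(list(
                                      level = 1,
                                      positions = seq(5, 55, by = 10),
                                      keyword = "activity")),
                                    p_cons = 0.95, seed = 19))
  x <- sim$msa
  core <- derive_core_positions(x)
  mat <- compute_cma_matrix(x, core, cma_config("sca"))
  d3 <- match(planted_positions(sim), core)
  within <- mat$scores[d3, d3][upper.tri(diag(length(d3)))]
  bg_mask <- upper.tri(mat$scores)
  bg_mask[d3, d3] <- FALSE
  background <- mat$scores[bg_mask]
  background <- background[!is.na(background)]
  expect_gt(min(within), quantile(background, 0.99))
})

test_that("the synthetic corpus is recovered exactly by the mining pipeline", {
  sim <- simulate_family(sim_config(n_sequences = 120, n_positions = 30,
                                    gap_rate = 0.02,
                                    networks = list(list(
                                      level = 1, positions = c(4, 11, 18),
                                      keyword = "enantioselectivity")),
                                    seed = 12))
  core <- derive_core_positions(sim$msa)
  corpus <- simulate_corpus(sim, core, seed = 5)
  mined <- mine_articles(corpus$articles, sim$msa, core,
                         corpus$article_seq,
                         keyword_exprs = c("enantioselectivity",
                                           "stability", "buffer",
                                           "temperature", "yield"))
  expect_equal(nrow(mined$rejected), 0)
  tab <- build_annotation_table(mined$records, n_mut = 2)
  expect_equal(tab$d3_number, corpus$truth_table$d3_number)
  expect_equal(tab$keyword, corpus$truth_table$keyword)
  expect_equal(tab$n_articles, corpus$truth_table$n_articles)
  # a threshold above the per-position article count empties the table
  expect_equal(nrow(build_annotation_table(mined$records, n_mut = 99)), 0)
  # noise mentions appear in single articles and are filtered out
  noisy <- simulate_corpus(sim, core, noise_mentions = 15, seed = 6)
  mined2 <- mine_articles(noisy$articles, sim$msa, core,
                          noisy$article_seq,
                          keyword_exprs = c("enantioselectivity",
                                            "stability", "buffer",
                                            "temperature", "yield"))
  tab2 <- build_annotation_table(mined2$records, n_mut = 2)
  expect_equal(tab2$d3_number, noisy$truth_table$d3_number)
  expect_equal(tab2$n_articles, noisy$truth_table$n_articles)
})

test_that("simulation runs serialize to a self-contained directory", {
  sim <- simulate_family(sim_config(n_sequences = 40, n_positions = 15,
                                    networks = list(list(
                                      level = 1, positions = c(3, 9),
                                      keyword = "activity")),
                                    seed = 77))
  corpus <- simulate_corpus(sim, seed = 77)
  dir <- file.path(tempdir(), "sim_run_77")
  write_simulation(sim, dir, corpus)
  expect_true(file.exists(file.path(dir, "alignment.fasta")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "expected_annotations.tsv")))
  expect_gt(length(list.files(file.path(dir, "articles"),
                              pattern = "\\.txt$")), 0)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, 77)
  back <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_equal(back$mat, sim$msa$mat)
})
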