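cfg_nmi <- cma_config(method = "nmi", min_pairs = 2)
cfg_sca <- cma_config(method = "sca", min_pairs = 2, min_subset = 1)

test_that("normalized mutual information matches its defining cases", {
  x <- coupled_msa(2)  # (A,A,C,C) vs (D,D,E,E)
  core <- derive_core_positions(x, 1)
  expect_equal(nmi_score(x, core, 1, 2, cfg_nmi), 1)
  # one conserved column: score 0 with any partner
  y <- msa(c("AD", "AD", "AE", "AE"), ids = paste0("s", 1:4))
  cy <- derive_core_positions(y, 1)
  expect_equal(nmi_score(y, cy, 1, 2, cfg_nmi), 0)
  # mixed column pair, frozen from the brute-force oracle
  z <- msa(c("AD", "AD", "AE", "CE"), ids = paste0("s", 1:4))
  cz <- derive_core_positions(z, 1)
  expect_equal(nmi_score(z, cz, 1, 2, cfg_nmi), 0.3836885, tolerance = 1e-6)
  # insufficient complete pairs -> undefined, not zero
  g <- msa(c("AD", "A-", "-E"), ids = paste0("s", 1:3))
  cg <- derive_core_positions(g, 1)
  expect_true(is.na(nmi_score(g, cg, 1, 2, cma_config("nmi", min_pairs = 2))))
})

test_that("nmi agrees with a brute-force oracle over enumerated small columns", {
  # all pairs of length-4 columns over a 3-letter alphabet
  cols <- expand.grid(rep(list(c("A", "C", "D")), 4),
                      stringsAsFactors = FALSE)
  cols <- as.matrix(cols)
  set.seed(1)
  pick <- sample(nrow(cols), 40)
  for (i in pick) {
    for (j in sample(nrow(cols), 6)) {
      a <- cols[i, ]; b <- cols[j, ]
      x <- msa(paste0(a, b), ids = paste0("s", 1:4))
      core <- derive_core_positions(x, 1)
      expect_equal(nmi_score(x, core, 1, 2, cfg_nmi), brute_nmi(a, b),
                   tolerance = 1e-10)
    }
  }
})

test_that("nmi is 1 exactly when the lower-entropy column is determined by the other", {
  ent <- function(v) { p <- table(v) / length(v); -sum(p * log2(p)) }
  is_fun <- function(from, to)        # every `from` value maps to one `to`
    !any(duplicated(unique(cbind(from, to))[, 1]))
  set.seed(42)
  for (rep in 1:80) {
    n <- sample(3:6, 1)
    a <- sample(c("A", "C", "D"), n, replace = TRUE)
    b <- sample(c("E", "F"), n, replace = TRUE)
    x <- msa(paste0(a, b), ids = paste0("s", seq_len(n)))
    core <- derive_core_positions(x, 1)
    s <- nmi_score(x, core, 1, 2, cfg_nmi)
    ha <- ent(a); hb <- ent(b)
    if (ha == 0 || hb == 0) { expect_equal(s, 0); next }
    saturated <- (is_fun(b, a) && ha <= hb) || (is_fun(a, b) && hb <= ha)
    if (saturated) expect_equal(s, 1)
    else expect_lt(s, 1 - 1e-12)
  }
})

test_that("statistical coupling score follows the perturbation definition", {
  x <- coupled_msa(10)
  core <- derive_core_positions(x, 1)
  cfg <- cma_config("sca", min_pairs = 2, min_subset = 5)
  # perfectly coupled 50/50 blocks: each conditional is a point mass at
  # total-variation distance 1/2 from the marginal
  expect_equal(sca_score(x, core, 1, 2, cfg), 0.5)
  # conserved column scores 0 in both directions
  y <- msa(rep(c("AD", "AE"), 10), ids = paste0("s", 1:20))
  cy <- derive_core_positions(y, 1)
  expect_equal(sca_score(y, cy, 1, 2, cfg), 0)
  # no residue reaches min_subset: score 0 with a warning
  z <- msa(c("AD", "CE", "FG", "HI"), ids = paste0("s", 1:4))
  cz <- derive_core_positions(z, 1)
  expect_warning(s <- sca_score(z, cz, 1, 2,
                                cma_config("sca", min_pairs = 2,
                                           min_subset = 3)),
                 "min_subset")
  expect_equal(s, 0)
})

test_that("independent columns score near zero at large n", {
  set.seed(77)
  a <- sample(c("A", "C", "D", "E", "F", "G"), 10000, replace = TRUE)
  b <- sample(c("K", "L", "M", "N", "P", "Q"), 10000, replace = TRUE)
  x <- msa(paste0(a, b), ids = sprintf("s%05d", 1:10000))
  core <- derive_core_positions(x, 1)
  expect_lt(sca_score(x, core, 1, 2, cma_config("sca")), 0.05)
  expect_lt(nmi_score(x, core, 1, 2, cma_config("nmi")), 0.05)
})

test_that("the score matrix is symmetric, consistent and order-invariant", {
  x <- iid_msa(60, 8, seed = 5, gap_rate = 0.1)
  core <- derive_core_positions(x, 0.3)
  for (cfg in list(cma_config("sca", min_pairs = 5),
                   cma_config("nmi", min_pairs = 5))) {
    mat <- compute_cma_matrix(x, core, cfg)
    expect_true(all(mat$scores == t(mat$scores), na.rm = TRUE))
    expect_true(all(is.na(diag(mat$scores))))
    sc <- mat$scores[upper.tri(mat$scores)]
    expect_true(all(sc[!is.na(sc)] >= 0 & sc[!is.na(sc)] <= 1))
    # matrix entries equal the pairwise calls
    for (p in list(c(1, 2), c(2, 5), c(3, 8))) {
      single <- if (cfg$method == "nmi")
        nmi_score(x, core, p[1], p[2], cfg)
      else suppressWarnings(sca_score(x, core, p[1], p[2], cfg))
      expect_equal(mat$scores[p[1], p[2]], single)
    }
    # row order must not matter
    perm <- sample(x$n)
    xp <- msa(apply(x$mat[perm, ], 1, paste, collapse = ""),
              ids = x$ids[perm])
    matp <- compute_cma_matrix(xp, derive_core_positions(xp, 0.3), cfg)
    expect_equal(matp$scores, mat$scores)
  }
})

test_that("gappy pairs are flagged undefined rather than zero", {
  rows <- c(rep("AD", 30), rep("A-", 30))
  rows2 <- sub("A", "C", rows[16:45])
  x <- msa(c(rows[1:15], rows2, rows[46:60]), ids = sprintf("s%02d", 1:60))
  core <- derive_core_positions(x, 0.6)
  mat <- compute_cma_matrix(x, core, cma_config("nmi", min_pairs = 40))
  expect_true(is.na(mat$scores[1, 2]))
  expect_equal(mat$n_pairs[1, 2], 30L)
})

test_that("score edge lists round-trip through TSV", {
  x <- iid_msa(50, 6, seed = 8)
  core <- derive_core_positions(x, 1)
  mat <- compute_cma_matrix(x, core, cma_config("sca"))
  p <- tempfile(fileext = ".tsv")
  write_scores(mat, p)
  back <- read_scores(p)
  expect_equal(back$scores, mat$scores, tolerance = 1e-12)
  expect_equal(back$method, "sca")
  df <- read.delim(p)
  expect_equal(nrow(df), choose(6, 2))
  expect_true(all(df$pos_i < df$pos_j))
})

test_that("cutoff calibration is deterministic and separates planted signal", {
  sim <- simulate_family(sim_config(n_sequences = 800, n_positions = 40,
                                    networks = list(list(
                                      level = 1, positions = c(5, 15, 25),
                                      keyword = "activity")),
                                    seed = 3))
  x <- sim$msa
  core <- derive_core_positions(x)
  cfg <- cma_config("sca")
  c1 <- calibrate_cutoff(x, core, cfg, seed = 10)
  c2 <- calibrate_cutoff(x, core, cfg, seed = 10)
  expect_equal(c1, c2)
  mat <- compute_cma_matrix(x, core, cfg)
  d3 <- match(planted_positions(sim), core)
  within <- mat$scores[d3, d3][upper.tri(diag(length(d3)))]
  expect_true(all(within > c1))
})
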