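#' Configuration for correlated mutation analysis
#'
#' @param method scoring method: `"sca"` (perturbation-based statistical
#'   coupling analysis, the default) or `"nmi"` (normalized mutual
#'   information).
#' @param min_pairs minimum number of sequences that must be non-gap at both
#'   columns of a pair for the score to be defined (default 20).
#' @param min_subset minimum count a residue must reach at the perturbed
#'   column before its conditional distribution contributes to the SCA score
#'   (default 5).
#' @param subset_ids optional character vector restricting the analysis to a
#'   subset of sequence ids.
#' @return object of class `cma_config`.
#' @export
cma_config <- function(method = c("sca", "nmi"), min_pairs = 20L,
                       min_subset = 5L, subset_ids = NULL) {
  method <- match.arg(method)
  min_pairs <- as.integer(min_pairs)
  min_subset <- as.integer(min_subset)
  if (min_pairs < 2L) cn_stop("min_pairs must be >= 2", "config_error")
  if (min_subset < 1L) cn_stop("min_subset must be >= 1", "config_error")
  structure(list(method = method, min_pairs = min_pairs,
                 min_subset = min_subset, subset_ids = subset_ids),
            class = "cma_config")
}

# Integer-encode the core columns of an alignment: residues 1..20 by
# alphabetical one-letter code, 0 for gap or X.
encode_core <- function(x, core, subset_ids = NULL) {
  rows <- if (is.null(subset_ids)) seq_len(x$n)
          else vapply(subset_ids, row_index, integer(1L), x = x)
  m <- x$mat[rows, as.integer(core), drop = FALSE]
  enc <- match(m, AA_STANDARD, nomatch = 0L)
  dim(enc) <- dim(m)
  enc
}

# Joint 20x20 count table of two encoded columns over pairwise-complete
# rows (non-gap at both), returned as a length-400 count vector in
# row-major order over (residue at i, residue at j).
joint_counts <- function(xi, xj) {
  ok <- xi > 0L & xj > 0L
  tabulate((xi[ok] - 1L) * 20L + xj[ok], nbins = 400L)
}

# Normalized mutual information from a length-400 joint count vector.
# MI (log base 2) divided by min(H_i, H_j); 0 when either column is
# conserved (min entropy 0); NA when fewer than min_pairs complete pairs.
nmi_from_counts <- function(counts, min_pairs) {
  n <- sum(counts)
  if (n < min_pairs) return(NA_real_)
  tab <- matrix(counts, nrow = 20L, byrow = TRUE)
  pi_ <- rowSums(tab) / n
  pj_ <- colSums(tab) / n
  hi <- -sum(pi_[pi_ > 0] * log2(pi_[pi_ > 0]))
  hj <- -sum(pj_[pj_ > 0] * log2(pj_[pj_ > 0]))
  hmin <- min(hi, hj)
  if (hmin == 0) return(0)
  nz <- which(tab > 0, arr.ind = TRUE)
  p <- tab[nz] / n
  mi <- sum(p * log2(p / (pi_[nz[, 1L]] * pj_[nz[, 2L]])))
  # clamp tiny negative rounding and cap at the normalizing entropy
  min(max(mi, 0) / hmin, 1)
}

# Perturbation-based SCA score from a length-400 joint count vector.
# For each residue a at the perturbed column with count >= min_subset, the
# deviation d_a is the total-variation distance between the conditional
# distribution at the other column given a and that column's marginal; the
# directed score is the count-weighted mean of d_a over qualifying a, and
# the symmetric score averages both directions. Returns c(score, flagged)
# where flagged = 1 when neither direction had a qualifying residue.
sca_from_counts <- function(counts, min_pairs, min_subset) {
  n <- sum(counts)
  if (n < min_pairs) return(c(NA_real_, 0))
  tab <- matrix(counts, nrow = 20L, byrow = TRUE)
  directed <- function(tab) {
    ni <- rowSums(tab)
    fj <- colSums(tab) / n
    qual <- which(ni >= min_subset)
    if (length(qual) == 0L) return(NA_real_)
    cond <- tab[qual, , drop = FALSE] / ni[qual]
    d <- 0.5 * rowSums(abs(cond - rep(fj, each = length(qual))))
    sum(ni[qual] / sum(ni[qual]) * d)
  }
  dij <- directed(tab)
  dji <- directed(t(tab))
  if (is.na(dij) && is.na(dji)) return(c(0, 1))
  c(mean(c(dij, dji), na.rm = TRUE), 0)
}

#' Normalized mutual information between two core positions
#'
#' Mutual information (log base 2) of the joint residue distribution over
#' sequences non-gap at both columns, normalized by the smaller of the two
#' column entropies. A conserved column yields 0 with any partner; fewer
#' than `min_pairs` complete pairs yields `NA` (undefined, never coerced
#' to 0).
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param i,j 3D numbers of the two positions (`i != j`).
#' @param config a [cma_config()] (the `method` field is ignored here).
#' @return numeric score in \[0, 1\], or `NA` when undefined.
#' @export
nmi_score <- function(x, core, i, j, config = cma_config()) {
  enc <- pair_encode(x, core, i, j, config)
  nmi_from_counts(joint_counts(enc[, 1L], enc[, 2L]), config$min_pairs)
}

#' Statistical coupling score between two core positions
#'
#' Perturbation-style statistical coupling analysis: conditioning on each
#' sufficiently frequent residue at one column, the score measures how far
#' the residue distribution at the other column moves from its marginal
#' (total-variation distance), weighted by residue frequency, averaged over
#' both perturbation directions. Bounded in \[0, 1\]; a conserved column
#' scores 0 with any partner.
#'
#' @inheritParams nmi_score
#' @return numeric score in \[0, 1\], or `NA` when undefined. When no
#'   residue reaches `min_subset` in either direction the score is 0 and a
#'   warning is issued.
#' @export
sca_score <- function(x, core, i, j, config = cma_config()) {
  enc <- pair_encode(x, core, i, j, config)
  res <- sca_from_counts(joint_counts(enc[, 1L], enc[, 2L]),
                         config$min_pairs, config$min_subset)
  if (!is.na(res[1L]) && res[2L] == 1)
    warning("no residue reaches min_subset in either direction; score set to 0")
  res[1L]
}

pair_encode <- function(x, core, i, j, config) {
  stopifnot(inherits(x, "msa"))
  if (i == j) cn_stop("i and j must differ", "config_error")
  for (k in c(i, j))
    if (k < 1L || k > length(core))
      cn_stop("3D number out of range", "range_error")
  encode_core(x, core[c(i, j)], config$subset_ids)
}

#' Compute the full pairwise correlated-mutation score matrix
#'
#' Scores all unordered pairs of core positions with the configured method.
#' Gap handling is pairwise-complete: for each pair, sequences gapped at
#' either column are dropped. Pairs with fewer than `min_pairs` complete
#' sequences are flagged undefined (`NA`), never coerced to 0.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param config a [cma_config()].
#' @return object of class `cma_matrix`: list with `positions` (3D
#'   numbers), `columns` (alignment columns), `scores` (symmetric K x K
#'   matrix, `NA` diagonal and undefined pairs), `n_pairs` (complete-pair
#'   counts), `flagged` (logical matrix, SCA pairs scored 0 for lack of a
#'   qualifying residue), `method`, `n_sequences`.
#' @export
compute_cma_matrix <- function(x, core, config = cma_config()) {
  stopifnot(inherits(x, "msa"), inherits(config, "cma_config"))
  K <- length(core)
  if (K < 2L) cn_stop("need at least 2 core positions", "empty_core_error")
  enc <- encode_core(x, core, config$subset_ids)
  scores <- matrix(NA_real_, K, K)
  npairs <- matrix(0L, K, K)
  flagged <- matrix(FALSE, K, K)
  nmi <- config$method == "nmi"
  for (i in seq_len(K - 1L)) {
    xi <- enc[, i]
    for (j in (i + 1L):K) {
      cnt <- joint_counts(xi, enc[, j])
      n <- sum(cnt)
      npairs[i, j] <- npairs[j, i] <- n
      if (nmi) {
        s <- nmi_from_counts(cnt, config$min_pairs)
      } else {
        r <- sca_from_counts(cnt, config$min_pairs, config$min_subset)
        s <- r[1L]
        if (!is.na(s) && r[2L] == 1) flagged[i, j] <- flagged[j, i] <- TRUE
      }
      scores[i, j] <- scores[j, i] <- s
    }
  }
  dn <- as.character(seq_len(K))
  dimnames(scores) <- dimnames(npairs) <- dimnames(flagged) <- list(dn, dn)
  structure(list(positions = seq_len(K), columns = as.integer(core),
                 scores = scores, n_pairs = npairs, flagged = flagged,
                 method = config$method, n_sequences = nrow(enc)),
            class = "cma_matrix")
}

#' Construct a correlated-mutation score matrix from raw scores
#'
#' Programmatic constructor used when scores come from an edge-list file or
#' are assembled directly (e.g. for simulation studies). The matrix is
#' symmetrized from its upper triangle.
#'
#' @param scores symmetric numeric matrix in \[0, 1\] with `NA` for
#'   undefined entries; the diagonal is ignored.
#' @param positions integer 3D numbers labelling the rows/columns
#'   (default `1:K`).
#' @param method method tag to record.
#' @param n_pairs optional matrix of complete-pair counts.
#' @param n_sequences number of sequences the scores were computed from.
#' @return a `cma_matrix` object.
#' @export
cma_matrix <- function(scores, positions = seq_len(nrow(scores)),
                       method = "sca", n_pairs = NULL, n_sequences = NA_integer_) {
  scores <- as.matrix(scores)
  K <- nrow(scores)
  stopifnot(ncol(scores) == K, length(positions) == K)
  scores[lower.tri(scores)] <- t(scores)[lower.tri(scores)]
  diag(scores) <- NA_real_
  ok <- scores[!is.na(scores)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 1))
    cn_stop("scores must lie in [0, 1]", "input_error")
  if (is.null(n_pairs)) n_pairs <- matrix(NA_integer_, K, K)
  dn <- as.character(positions)
  dimnames(scores) <- dimnames(n_pairs) <- list(dn, dn)
  structure(list(positions = as.integer(positions), columns = NA_integer_,
                 scores = scores, n_pairs = n_pairs,
                 flagged = matrix(FALSE, K, K), method = method,
                 n_sequences = as.integer(n_sequences)),
            class = "cma_matrix")
}

#' @export
print.cma_matrix <- function(x, ...) {
  sc <- x$scores[upper.tri(x$scores)]
  cat(sprintf("Correlated mutation matrix (%s): %d positions, %d sequences\n",
              x$method, length(x$positions), x$n_sequences))
  cat(sprintf("  defined pairs: %d of %d; score range %.3f .. %.3f\n",
              sum(!is.na(sc)), length(sc),
              suppressWarnings(min(sc, na.rm = TRUE)),
              suppressWarnings(max(sc, na.rm = TRUE))))
  invisible(x)
}

#' Write a score matrix as a long-format TSV edge list
#'
#' One row per unordered pair `i < j` with columns `pos_i`, `pos_j`,
#' `score`, `n_pairs`, `method`; undefined scores are written as `NA`.
#'
#' @param mat a `cma_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(mat, path) {
  stopifnot(inherits(mat, "cma_matrix"))
  K <- length(mat$positions)
  idx <- which(upper.tri(mat$scores), arr.ind = TRUE)
  df <- data.frame(pos_i = mat$positions[idx[, 1L]],
                   pos_j = mat$positions[idx[, 2L]],
                   score = mat$scores[idx],
                   n_pairs = mat$n_pairs[idx],
                   method = mat$method)
  df <- df[order(df$pos_i, df$pos_j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix from a TSV edge list
#'
#' @param path a TSV written by [write_scores()].
#' @return a `cma_matrix`.
#' @export
read_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pos_i", "pos_j", "score")
  if (!all(need %in% names(df)))
    cn_stop("score file lacks pos_i/pos_j/score columns", "input_error")
  positions <- sort(unique(c(df$pos_i, df$pos_j)))
  K <- length(positions)
  scores <- matrix(NA_real_, K, K)
  npairs <- matrix(NA_integer_, K, K)
  ii <- match(df$pos_i, positions)
  jj <- match(df$pos_j, positions)
  scores[cbind(ii, jj)] <- df$score
  scores[cbind(jj, ii)] <- df$score
  if (!is.null(df$n_pairs)) {
    npairs[cbind(ii, jj)] <- df$n_pairs
    npairs[cbind(jj, ii)] <- df$n_pairs
  }
  method <- if (!is.null(df$method)) df$method[1L] else "unknown"
  cma_matrix(scores, positions, method = method, n_pairs = npairs)
}

#' Calibrate a network cutoff from a column-permutation null
#'
#' Estimates the level that correlated-mutation scores reach between
#' unrelated columns by destroying all inter-column dependence: each core
#' column's residues are independently permuted across sequences
#' (preserving every marginal composition and the gap structure within a
#' column), a random set of position pairs is scored, and the cutoff is a
#' safety margin above the largest null score observed. Because the null
#' level of both scorers rises as the number of sequences falls, calibrate
#' at the smallest subset size that will be analysed when the cutoff is to
#' be shared across a subsampling scan.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param config a [cma_config()].
#' @param n_rows calibrate on a random subsample of this many sequences
#'   (default: all). Use the smallest subset size of a planned scan.
#' @param n_pairs number of random position pairs to score under the null
#'   (default 200).
#' @param margin multiplicative safety margin on the maximum null score
#'   (default 1.25).
#' @param seed RNG seed for the permutation and pair sampling.
#' @return numeric cutoff, with the null scores attached as attribute
#'   `null_scores`.
#' @export
calibrate_cutoff <- function(x, core, config = cma_config(), n_rows = NULL,
                             n_pairs = 200L, margin = 1.25, seed = 1L) {
  stopifnot(inherits(x, "msa"))
  K <- length(core)
  if (K < 2L) cn_stop("need at least 2 core positions", "empty_core_error")
  with_seed(seed, {
    enc <- encode_core(x, core, config$subset_ids)
    if (!is.null(n_rows) && n_rows < nrow(enc))
      enc <- enc[sample.int(nrow(enc), n_rows), , drop = FALSE]
    for (k in seq_len(K)) enc[, k] <- enc[sample.int(nrow(enc)), k]
    pairs <- unique(t(replicate(n_pairs, sort(sample.int(K, 2L)))))
    null <- apply(pairs, 1L, function(p) {
      cnt <- joint_counts(enc[, p[1L]], enc[, p[2L]])
      if (config$method == "nmi") nmi_from_counts(cnt, config$min_pairs)
      else sca_from_counts(cnt, config$min_pairs, config$min_subset)[1L]
    })
    null <- null[!is.na(null)]
    if (length(null) == 0L)
      cn_stop("no defined null scores; alignment too gappy or too small",
              "calibration_error")
    structure(min(margin * max(null), 1), null_scores = null)
  })
}
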