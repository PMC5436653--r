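#' Keyword enrichment score of a network
#'
#' Over-representation of keyword-annotated positions inside a network:
#' \deqn{Escore = (K_n / K_t) \cdot (N_t / N_n)}
#' where \eqn{N_n} is the number of network positions, \eqn{N_t} the total
#' number of (core) alignment positions, \eqn{K_n} the number of network
#' positions annotated with the keyword and \eqn{K_t} the total number of
#' annotated positions. A score of 1 means the keyword is spread as
#' expected by chance; values well above 1 indicate that the network
#' concentrates positions tied to that function.
#'
#' A keyword with no annotated positions gives an *undefined* result
#' (status `"undefined_keyword"`, score `NA`), and an empty network gives
#' status `"empty_network"`; neither is a zero.
#'
#' @param network_positions integer vector of network positions (or a
#'   `coevo_network`).
#' @param keyword_positions integer vector of positions annotated with the
#'   keyword.
#' @param total_positions integer vector of all core positions (or a
#'   single integer count `N_t`, in which case positions `1..N_t` are
#'   assumed).
#' @return object of class `enrichment_result`: list with `K_n`, `K_t`,
#'   `N_n`, `N_t`, `escore`, `status`.
#' @export
escore <- function(network_positions, keyword_positions, total_positions) {
  if (inherits(network_positions, "coevo_network"))
    network_positions <- network_positions$nodes
  if (length(total_positions) == 1L && total_positions[1L] > 0 &&
      is.numeric(total_positions))
    total_positions <- seq_len(total_positions)
  np <- unique(as.integer(network_positions))
  kp <- unique(as.integer(keyword_positions))
  tp <- unique(as.integer(total_positions))
  if (!all(np %in% tp) || !all(kp %in% tp))
    cn_stop("network and keyword positions must be subsets of the total positions",
            "input_error")
  Kn <- length(intersect(np, kp)); Kt <- length(kp)
  Nn <- length(np); Nt <- length(tp)
  status <- "ok"; es <- NA_real_
  if (Nn == 0L) status <- "empty_network"
  else if (Kt == 0L) status <- "undefined_keyword"
  else es <- (Kn / Kt) * (Nt / Nn)
  structure(list(K_n = Kn, K_t = Kt, N_n = Nn, N_t = Nt, escore = es,
                 status = status),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("Escore %.3f (Kn %d / Kt %d, Nn %d / Nt %d)\n",
                x$escore, x$K_n, x$K_t, x$N_n, x$N_t))
  else
    cat(sprintf("Escore undefined: %s\n", x$status))
  invisible(x)
}

#' Keyword enrichment as a function of the score cutoff
#'
#' For each cutoff the network is rebuilt from the score matrix and the
#' enrichment of the keyword over the union of all component node sets is
#' computed (per-component enrichment is available by passing a single
#' component's positions to [escore()] directly). Cutoffs at which the
#' network is empty are marked, not zeroed.
#'
#' @param mat a `cma_matrix`.
#' @param annotations an `annotation_table`.
#' @param keyword keyword expression.
#' @param cutoffs increasing numeric vector of cutoffs (default 0.50 to
#'   0.95 in steps of 0.05).
#' @return object of class `enrichment_curve`: data frame with columns
#'   `cutoff`, `K_n`, `K_t`, `N_n`, `N_t`, `escore`, `status`.
#' @export
enrichment_curve <- function(mat, annotations, keyword,
                             cutoffs = seq(0.50, 0.95, by = 0.05)) {
  stopifnot(inherits(mat, "cma_matrix"))
  if (is.unsorted(cutoffs, strictly = TRUE))
    cn_stop("cutoffs must be strictly increasing", "config_error")
  kp <- annotation_positions(annotations, keyword)
  rows <- lapply(cutoffs, function(ct) {
    net <- build_network(mat, ct)
    r <- escore(net$nodes, kp, mat$positions)
    data.frame(cutoff = ct, K_n = r$K_n, K_t = r$K_t, N_n = r$N_n,
               N_t = r$N_t, escore = r$escore, status = r$status)
  })
  structure(do.call(rbind, rows), keyword = tolower(keyword),
            class = c("enrichment_curve", "data.frame"))
}

#' @export
plot.enrichment_curve <- function(x, ...) {
  ok <- x$status == "ok"
  plot(x$cutoff[ok], x$escore[ok], type = "b", pch = 16,
       xlab = "CMA score cutoff", ylab = "Escore",
       main = sprintf("Keyword enrichment: %s", attr(x, "keyword")), ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Permutation p-value for a keyword enrichment
#'
#' Significance of an observed enrichment under random placement of the
#' network: `n_perm` position sets of the same size as the network are
#' drawn uniformly from the core positions and the enrichment recomputed;
#' the p-value is `(1 + #{permuted escore >= observed}) / (n_perm + 1)`.
#'
#' @param mat a `cma_matrix`.
#' @param annotations an `annotation_table`.
#' @param keyword keyword expression.
#' @param cutoff score cutoff at which the network is built.
#' @param n_perm number of permutations (>= 100; default 999).
#' @param seed RNG seed.
#' @return list with `p_value`, `observed` (an `enrichment_result`) and
#'   `n_perm`; `p_value` is `NA` when the observed enrichment is
#'   undefined.
#' @export
permutation_pvalue <- function(mat, annotations, keyword, cutoff,
                               n_perm = 999L, seed = 1L) {
  stopifnot(inherits(mat, "cma_matrix"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) cn_stop("n_perm must be >= 100", "config_error")
  net <- build_network(mat, cutoff)
  kp <- annotation_positions(annotations, keyword)
  obs <- escore(net$nodes, kp, mat$positions)
  if (obs$status != "ok")
    return(list(p_value = NA_real_, observed = obs, n_perm = n_perm))
  total <- mat$positions
  Nn <- obs$N_n
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      rnd <- sample(total, Nn)
      escore(rnd, kp, total)$escore >= obs$escore
    }, logical(1L)))
  })
  list(p_value = (1 + hits) / (n_perm + 1), observed = obs,
       n_perm = n_perm)
}

#' Write an enrichment table as TSV
#'
#' @param curve an `enrichment_curve` (or any data frame of enrichment
#'   rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(curve, path) {
  df <- as.data.frame(curve)
  df$keyword <- attr(curve, "keyword")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
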