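#' Sub-alignment of sequences carrying a residue at a core position
#'
#' Selects the sequences that have `residue` at the core column with 3D
#' number `d3_number`. Columns are never renumbered, so 3D numbers remain
#' comparable between the full alignment and any subset; by construction
#' the conditioning position is fully conserved in the subset and
#' therefore drops out of every correlated-mutation network computed on
#' it.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param d3_number 3D number of the conditioning position.
#' @param residue single upper-case amino acid letter.
#' @param min_sequences warn when the subset is smaller than this
#'   (default 50); small subsets give noisy correlation scores.
#' @return an `msa` containing only the selected rows.
#' @export
subset_by_residue <- function(x, core, d3_number, residue,
                              min_sequences = 50L) {
  stopifnot(inherits(x, "msa"))
  residue <- toupper(residue)
  if (!residue %in% AA_STANDARD)
    cn_stop(sprintf("'%s' is not a standard amino acid", residue),
            "input_error")
  if (d3_number < 1L || d3_number > length(core))
    cn_stop("3D number out of range", "range_error")
  col <- core[[d3_number]]
  rows <- which(x$mat[, col] == residue)
  if (length(rows) == 0L)
    cn_stop(sprintf("no sequence carries %s at 3D position %d", residue,
                    d3_number), "empty_subset_error")
  if (length(rows) < min_sequences)
    warning(sprintf("subset has only %d sequences (< %d); correlation scores will be noisy",
                    length(rows), min_sequences))
  msa_rows(x, rows)
}

#' Random sequence subsets of an alignment
#'
#' Uniform sampling without replacement. Each subset is reproducible from
#' `(seed, fraction index, replicate index)` alone, so individual subsets
#' can be regenerated without rerunning the whole scan.
#'
#' @param x an `msa` object.
#' @param fractions numeric vector of subset fractions in (0, 1].
#' @param replicates number of replicate subsets per fraction.
#' @param seed master RNG seed.
#' @return list of `msa` objects with attributes `fraction` and
#'   `replicate` on each element; subsets that would contain fewer than 2
#'   sequences are skipped with a warning. Fraction 1 returns the full
#'   alignment with row order preserved.
#' @export
random_subsets <- function(x, fractions, replicates = 1L, seed = 1L) {
  stopifnot(inherits(x, "msa"))
  if (any(fractions <= 0 | fractions > 1))
    cn_stop("fractions must lie in (0, 1]", "config_error")
  out <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    size <- round(f * x$n)
    if (size < 2L) {
      warning(sprintf("fraction %.4f yields fewer than 2 sequences; skipped", f))
      next
    }
    for (r in seq_len(replicates)) {
      sub <- if (f == 1) x else
        with_seed(subseed(seed, fi, r),
                  msa_rows(x, sort(sample.int(x$n, size))))
      attr(sub, "fraction") <- f
      attr(sub, "replicate") <- r
      out[[length(out) + 1L]] <- sub
    }
  }
  out
}

#' Network robustness under random subsampling
#'
#' For each random subset the correlated-mutation matrix and the network
#' at the *same* cutoff are recomputed (on the same core columns; 3D
#' numbers are never re-derived) and the node set is compared with the
#' full-alignment network by F-measure. This reproduces the question of
#' how many sequences an alignment needs before its co-evolution network
#' stabilizes.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param config a [cma_config()].
#' @param cutoff network score cutoff shared by the full alignment and
#'   every subset (see [calibrate_cutoff()]).
#' @param fractions subset fractions in (0, 1].
#' @param replicates replicates per fraction.
#' @param seed master RNG seed.
#' @param reference optional `coevo_network` to compare against; default
#'   is the network of `x` itself at `cutoff`.
#' @return object of class `robustness_scan`: data frame with columns
#'   `fraction`, `replicate`, `n_sequences`, `f_measure`.
#' @export
robustness_scan <- function(x, core, config = cma_config(), cutoff,
                            fractions, replicates = 1L, seed = 1L,
                            reference = NULL) {
  if (is.null(reference)) {
    full_mat <- compute_cma_matrix(x, core, config)
    reference <- build_network(full_mat, cutoff)
  }
  if (length(reference$nodes) == 0L)
    cn_stop("full-alignment network is empty at this cutoff; nothing to compare against",
            "empty_network_error")
  subs <- random_subsets(x, fractions, replicates, seed)
  rows <- lapply(subs, function(sub) {
    m <- compute_cma_matrix(sub, core, config)
    net <- build_network(m, cutoff)
    data.frame(fraction = attr(sub, "fraction"),
               replicate = attr(sub, "replicate"),
               n_sequences = sub$n,
               f_measure = f_measure(net$nodes, reference$nodes)$f_measure)
  })
  structure(do.call(rbind, rows), cutoff = cutoff,
            method = config$method,
            class = c("robustness_scan", "data.frame"))
}

#' Summarize a robustness scan per fraction
#'
#' @param object a `robustness_scan`.
#' @param ... unused.
#' @return data frame with columns `fraction`, `n_sequences`,
#'   `mean_f_measure`, `sd_f_measure`, `replicates`.
#' @export
summary.robustness_scan <- function(object, ...) {
  agg <- aggregate(f_measure ~ fraction + n_sequences, data = object,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  data.frame(fraction = agg$fraction, n_sequences = agg$n_sequences,
             mean_f_measure = agg$f_measure[, "mean"],
             sd_f_measure = agg$f_measure[, "sd"],
             replicates = as.integer(agg$f_measure[, "n"]))
}

#' Write scan report and summary TSVs
#'
#' @param scan a `robustness_scan`.
#' @param path output path for the per-replicate report; the summary is
#'   written next to it with suffix `"_summary"`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  spath <- sub("(\\.[^.]*)?$", "_summary\\1", path)
  write.table(summary(scan), spath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
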