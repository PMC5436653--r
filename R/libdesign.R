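# Translate concrete DNA triplets with the standard genetic code.
translate_triplets <- function(triplets) {
  unname(Biostrings::GENETIC_CODE[triplets])
}

# Expand a single degenerate codon to its concrete triplets.
expand_one_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L)
    cn_stop(sprintf("codon '%s' is not a triplet", codon), "codon_error")
  sym <- strsplit(codon, "")[[1L]]
  if (!all(sym %in% names(IUPAC_NT)))
    cn_stop(sprintf("invalid IUPAC symbol in codon '%s'", codon),
            "codon_error")
  g <- expand.grid(IUPAC_NT[[sym[1L]]], IUPAC_NT[[sym[2L]]],
                   IUPAC_NT[[sym[3L]]], stringsAsFactors = FALSE)
  paste0(g[[1L]], g[[2L]], g[[3L]])
}

#' Amino acids encoded by a set of degenerate codons
#'
#' Expands each IUPAC-degenerate codon to its concrete triplets,
#' translates them with the standard genetic code, and returns the union
#' of encoded amino acids. Stop codons in the expansion are reported via
#' the `has_stop` attribute.
#'
#' @param codons character vector of degenerate codons (IUPAC nucleotide
#'   codes), e.g. `c("TKG", "TWT")`.
#' @return sorted character vector of one-letter amino acids, with
#'   attribute `has_stop`.
#' @export
expand_codons <- function(codons) {
  trip <- unlist(lapply(codons, expand_one_codon), use.names = FALSE)
  aa <- translate_triplets(trip)
  structure(sort(unique(setdiff(aa, "*"))), has_stop = any(aa == "*"))
}

# Candidate table of all 15^3 degenerate codons with their encoded amino
# acid sets, built once per session.
.codon_env <- new.env(parent = emptyenv())
all_degenerate_codons <- function() {
  if (is.null(.codon_env$tab)) {
    syms <- names(IUPAC_NT)
    g <- expand.grid(syms, syms, syms, stringsAsFactors = FALSE)
    codons <- paste0(g[[1L]], g[[2L]], g[[3L]])
    sets <- lapply(codons, function(cd) {
      aa <- translate_triplets(expand_one_codon(cd))
      list(aa = sort(unique(aa)), stop = any(aa == "*"))
    })
    .codon_env$tab <- list(
      codons = codons,
      aa = lapply(sets, `[[`, "aa"),
      stop = vapply(sets, `[[`, logical(1L), "stop"))
  }
  .codon_env$tab
}

#' The k most frequent residues at a position
#'
#' @param dist a `residue_distribution` (see [column_distribution()]) or a
#'   named count vector.
#' @param k number of residues to select (default 4, the usual library
#'   breadth per position); frequency ties are broken alphabetically.
#' @return character vector of at most `k` amino acids, in decreasing
#'   frequency order.
#' @export
top_k_residues <- function(dist, k = 4L) {
  counts <- if (inherits(dist, "residue_distribution")) dist$counts
            else dist
  if (k < 1L) cn_stop("k must be >= 1", "config_error")
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    cn_stop("empty residue distribution", "input_error")
  ord <- order(-counts, names(counts))
  names(counts)[ord][seq_len(min(k, length(counts)))]
}

#' Design a minimal degenerate-codon set encoding exactly a target set
#'
#' Searches all IUPAC-degenerate codons whose expansion is stop-free and
#' encodes only amino acids of the target, then finds a minimum-cardinality
#' combination whose joint encoded set equals the target exactly — no
#' off-target amino acids, no stop codons. Among minimal solutions the
#' lexicographically smallest codon list is returned. When no exact cover
#' of at most `max_codons` codons exists, the exact mode fails; with
#' `allow_superset = TRUE` a smallest-cardinality cover encoding a minimal
#' superset of the target is returned instead, flagged via the `exact`
#' attribute.
#'
#' @param target_aa character vector of one-letter amino acids to encode.
#' @param max_codons maximum number of codons in the set (default 3).
#' @param allow_superset fall back to a superset design when no exact
#'   design exists (default `FALSE`).
#' @return character vector of degenerate codons with attributes
#'   `encoded` (the encoded amino acid set) and `exact`.
#' @export
design_codons <- function(target_aa, max_codons = 3L,
                          allow_superset = FALSE) {
  target <- sort(unique(toupper(target_aa)))
  if (length(target) == 0L || !all(target %in% AA_STANDARD))
    cn_stop("target must be a non-empty set of standard amino acids",
            "input_error")
  if (max_codons < 1L) cn_stop("max_codons must be >= 1", "config_error")
  tab <- all_degenerate_codons()
  keep <- !tab$stop & vapply(tab$aa, function(s) all(s %in% target),
                             logical(1L))
  cands <- tab$codons[keep]
  sets <- tab$aa[keep]
  sol <- search_cover(cands, sets, target, max_codons, exact = TRUE)
  if (!is.null(sol))
    return(structure(sol, encoded = target, exact = TRUE))
  if (!allow_superset)
    cn_stop(sprintf("no exact stop-free design of <= %d codons encodes {%s}",
                    max_codons, paste(target, collapse = ",")),
            "infeasible_design_error")
  keep <- !tab$stop
  sol <- search_cover(tab$codons[keep], tab$aa[keep], target, max_codons,
                      exact = FALSE)
  if (is.null(sol))
    cn_stop("no stop-free superset design found", "infeasible_design_error")
  structure(sol, encoded = expand_codons(sol), exact = FALSE)
}

# Minimum-cardinality cover search. In exact mode every candidate encodes
# a subset of the target and the union must equal it; in superset mode the
# union must contain the target, and among minimal-size solutions the one
# with fewest off-target amino acids wins. Ties broken by the
# lexicographically smallest sorted codon list.
search_cover <- function(cands, sets, target, max_codons, exact) {
  # one representative codon (lexicographically smallest) per distinct set
  key <- vapply(sets, paste, character(1L), collapse = "")
  ord <- order(key, cands)
  first <- !duplicated(key[ord])
  reps <- cands[ord][first]
  rsets <- sets[ord][first]
  nr <- length(reps)
  if (nr == 0L) return(NULL)
  best <- NULL; best_extra <- Inf
  for (size in seq_len(min(max_codons, nr))) {
    combos <- combn(nr, size)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      un <- sort(unique(unlist(rsets[idx], use.names = FALSE)))
      ok <- if (exact) identical(un, target) else all(target %in% un)
      if (!ok) next
      codons <- sort(reps[idx])
      extra <- length(setdiff(un, target))
      if (is.null(best) || extra < best_extra ||
          (extra == best_extra &&
           paste(codons, collapse = "/") < paste(best, collapse = "/"))) {
        best <- codons; best_extra <- extra
      }
    }
    if (!is.null(best)) break  # minimal cardinality found
  }
  best
}

#' Per-position design of a mutant library
#'
#' @param d3_number 3D number of the position.
#' @param codons character vector of degenerate codons used at the
#'   position.
#' @param wild_type wild-type amino acid at the position (optional). A
#'   warning is issued when the encoded set does not include it, since the
#'   wild-type variant is then absent from the library at this position.
#' @return object of class `position_design`: list with `d3_number`,
#'   `codons`, `encoded`, `wild_type`.
#' @export
position_design <- function(d3_number, codons, wild_type = NA_character_) {
  enc <- expand_codons(codons)
  if (attr(enc, "has_stop"))
    cn_stop("codon expansion contains a stop codon", "codon_error")
  if (!is.na(wild_type) && !(toupper(wild_type) %in% enc))
    warning(sprintf("wild-type %s at position %d is not encoded by the design",
                    wild_type, d3_number))
  structure(list(d3_number = as.integer(d3_number), codons = codons,
                 encoded = as.character(enc),
                 wild_type = toupper(wild_type)),
            class = "position_design")
}

#' Combinatorial mutant library design
#'
#' A library consists of one jointly randomized position group, whose
#' variants combine full-factorially, plus independently randomized
#' positions, whose variants add.
#'
#' @param joint list of [position_design()] objects randomized together.
#' @param independent list of [position_design()] objects randomized one
#'   at a time.
#' @return object of class `library_design`.
#' @export
library_design <- function(joint = list(), independent = list()) {
  all_pos <- c(joint, independent)
  if (length(all_pos) == 0L)
    cn_stop("library design needs at least one position", "input_error")
  if (!all(vapply(all_pos, inherits, logical(1L), "position_design")))
    cn_stop("joint and independent must contain position_design objects",
            "input_error")
  structure(list(joint = joint, independent = independent),
            class = "library_design")
}

#' Number of variants in a library design
#'
#' The jointly randomized group contributes the product of its per-position
#' encoded-set sizes (full factorial, wild-type-equivalent combinations
#' included); each independently randomized position adds its encoded-set
#' size.
#'
#' @param design a `library_design`.
#' @return integer variant count.
#' @export
count_variants <- function(design) {
  stopifnot(inherits(design, "library_design"))
  sizes <- function(lst) vapply(lst, function(p) length(p$encoded),
                                integer(1L))
  joint <- if (length(design$joint)) prod(sizes(design$joint)) else 0L
  indep <- if (length(design$independent))
    sum(sizes(design$independent)) else 0L
  as.integer(joint + indep)
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("Mutant library design: %d joint + %d independent positions, %d variants\n",
              length(x$joint), length(x$independent), count_variants(x)))
  show <- function(p, group)
    cat(sprintf("  %-11s %4d  %-12s -> %s%s\n", group, p$d3_number,
                paste(p$codons, collapse = "/"),
                paste(p$encoded, collapse = ","),
                if (!is.na(p$wild_type))
                  sprintf("  (wt %s)", p$wild_type) else ""))
  for (p in x$joint) show(p, "joint")
  for (p in x$independent) show(p, "independent")
  invisible(x)
}

#' Design a library from residue distributions at network positions
#'
#' Convenience wrapper: for each position take the `k` most frequent
#' residues from the alignment and design a minimal exact degenerate-codon
#' set encoding them.
#'
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param joint_positions integer 3D numbers randomized combinatorially.
#' @param independent_positions integer 3D numbers randomized one at a
#'   time.
#' @param k residues per position (default 4).
#' @param wild_type_id optional sequence id whose residues are recorded as
#'   wild type.
#' @param max_codons per-position codon budget (default 3).
#' @return a `library_design`.
#' @export
design_library <- function(x, core, joint_positions,
                           independent_positions = integer(0), k = 4L,
                           wild_type_id = NULL, max_codons = 3L) {
  mk <- function(p) {
    dist <- column_distribution(x, core, p)
    target <- top_k_residues(dist, k)
    wt <- if (is.null(wild_type_id)) NA_character_
          else map_3d_to_residue(x, core, wild_type_id, p)$aa
    position_design(p, design_codons(target, max_codons = max_codons),
                    wild_type = wt)
  }
  library_design(joint = lapply(joint_positions, mk),
                 independent = lapply(independent_positions, mk))
}

#' Write a library design as TSV
#'
#' Columns `d3_number`, `group`, `codons` (slash-separated),
#' `encoded_aas` (comma-separated), `wild_type`, followed by a comment
#' line with the variant count.
#'
#' @param design a `library_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "library_design"))
  row <- function(p, group)
    data.frame(d3_number = p$d3_number, group = group,
               codons = paste(p$codons, collapse = "/"),
               encoded_aas = paste(p$encoded, collapse = ","),
               wild_type = p$wild_type)
  df <- rbind(do.call(rbind, lapply(design$joint, row, "joint")),
              do.call(rbind, lapply(design$independent, row,
                                    "independent")))
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# variants\t%d", count_variants(design)), con)
  invisible(path)
}
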