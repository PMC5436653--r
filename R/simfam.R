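#' Configuration of the synthetic super-family generator
#'
#' The generator emulates the statistical structure that drives correlated
#' mutation analysis in real super-families: sequences fall into
#' functional subgroups, and at the positions of a planted co-evolving
#' network each sequence carries its subgroup's consensus residue with
#' probability `p_cons` (else a uniformly random other residue), so
#' network columns covary through the hidden subgroup label while
#' background columns draw independently from per-column residue profiles.
#' Nested sub-subgroups support a second, layered network that is carried
#' by the subgroup structure *within one* top-level group and is invisible
#' in the full family, mirroring the way conditioning an alignment on a
#' hub residue exposes deeper networks.
#'
#' Defaults describe the reference study condition used throughout the
#' package's own analyses: 5000 sequences, 150 core-like positions, 8
#' equally likely subgroups, one planted 12-position network, consensus
#' probability 0.9 and 5% gaps.
#'
#' @param n_sequences number of sequences.
#' @param n_positions number of alignment columns (all low-gap, i.e.
#'   core-like).
#' @param subgroup_weights top-level subgroup probabilities (sum to 1).
#' @param nested_weights optional sub-subgroup probabilities (single
#'   vector, shared by every top-level group), required for level-2
#'   networks.
#' @param networks list of planted networks; each a list with `level` (1
#'   or 2), `positions` (disjoint integer sets), `keyword` (character) and,
#'   for level 2, `parent` (index of the top-level group that carries the
#'   network).
#' @param p_cons probability that a sequence carries its group's consensus
#'   residue at a network position (default 0.9).
#' @param gap_rate iid gap probability per cell (default 0.05).
#' @param dirichlet_conc symmetric Dirichlet concentration for background
#'   column profiles (default 0.5; smaller = more skewed columns).
#' @param seed RNG seed; the whole simulation is deterministic given the
#'   config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sequences = 5000L, n_positions = 150L,
                       subgroup_weights = rep(1 / 8, 8),
                       nested_weights = NULL,
                       networks = list(list(
                         level = 1L,
                         positions = round(seq(10, n_positions - 10,
                                               length.out = 12L)),
                         keyword = "enantioselectivity")),
                       p_cons = 0.9, gap_rate = 0.05,
                       dirichlet_conc = 0.5, seed = 1L) {
  n_sequences <- as.integer(n_sequences)
  n_positions <- as.integer(n_positions)
  if (abs(sum(subgroup_weights) - 1) > 1e-8)
    cn_stop("subgroup weights must sum to 1", "config_error")
  if (length(subgroup_weights) > 20L)
    cn_stop("at most 20 subgroups (distinct consensus residues required)",
            "config_error")
  if (!is.null(nested_weights)) {
    if (abs(sum(nested_weights) - 1) > 1e-8)
      cn_stop("nested weights must sum to 1", "config_error")
    if (length(nested_weights) > 20L)
      cn_stop("at most 20 nested subgroups", "config_error")
  }
  if (p_cons < 0 || p_cons > 1) cn_stop("p_cons must be in [0,1]",
                                        "config_error")
  if (gap_rate < 0 || gap_rate >= 1) cn_stop("gap_rate must be in [0,1)",
                                             "config_error")
  all_pos <- unlist(lapply(networks, `[[`, "positions"))
  if (anyDuplicated(all_pos))
    cn_stop("planted network position sets must be disjoint",
            "config_error")
  if (length(all_pos) && (min(all_pos) < 1L || max(all_pos) > n_positions))
    cn_stop("planted positions out of range", "config_error")
  for (nw in networks) {
    if (!nw$level %in% c(1L, 2L))
      cn_stop("network level must be 1 or 2", "config_error")
    if (nw$level == 2L) {
      if (is.null(nested_weights))
        cn_stop("level-2 networks require nested_weights", "config_error")
      if (is.null(nw$parent) || nw$parent < 1L ||
          nw$parent > length(subgroup_weights))
        cn_stop("level-2 networks need a valid parent group index",
                "config_error")
    }
  }
  structure(list(n_sequences = n_sequences, n_positions = n_positions,
                 subgroup_weights = subgroup_weights,
                 nested_weights = nested_weights, networks = networks,
                 p_cons = p_cons, gap_rate = gap_rate,
                 dirichlet_conc = dirichlet_conc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Replace a fraction (1 - p_cons) of consensus residues by a uniformly
# random *other* residue: adding 1..19 modulo 20 to the consensus index
# is uniform over the 19 alternatives.
mutate_from_consensus <- function(cons_idx, p_cons) {
  n <- length(cons_idx)
  res <- cons_idx
  miss <- which(runif(n) >= p_cons)
  if (length(miss))
    res[miss] <- (cons_idx[miss] - 1L +
                    sample.int(19L, length(miss), replace = TRUE)) %% 20L + 1L
  res
}

#' Simulate a synthetic protein super-family
#'
#' Draws an aligned family under a [sim_config()]: each sequence samples a
#' top-level subgroup (and a nested sub-subgroup when configured), emits
#' its group's consensus residue with probability `p_cons` at planted
#' network positions, draws iid from a column-specific Dirichlet profile
#' at background positions, and finally receives iid gaps. Level-2 network
#' positions behave like background outside the parent group, so their
#' covariation is diluted in the full family and emerges only in the
#' conditioned sub-alignment. Deterministic given the config (same seed,
#' same bytes).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_family`: list with `msa` (an [msa()]) and
#'   `truth` (subgroup labels, planted networks with consensus
#'   assignments, background profiles, the config).
#' @export
simulate_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_sequences
    L <- config$n_positions
    G <- length(config$subgroup_weights)
    top <- sample.int(G, n, replace = TRUE, prob = config$subgroup_weights)
    sub <- if (!is.null(config$nested_weights))
      sample.int(length(config$nested_weights), n, replace = TRUE,
                 prob = config$nested_weights)
    else rep(NA_integer_, n)
    idx <- matrix(0L, n, L)
    network_pos <- integer(0)
    networks <- config$networks
    for (k in seq_along(networks)) {
      nw <- networks[[k]]
      pos <- as.integer(nw$positions)
      network_pos <- c(network_pos, pos)
      if (nw$level == 1L) {
        cons <- matrix(0L, G, length(pos))
        for (p in seq_along(pos)) cons[, p] <- sample.int(20L, G)
        for (p in seq_along(pos))
          idx[, pos[p]] <- mutate_from_consensus(cons[top, p],
                                                 config$p_cons)
      } else {
        # Outside the parent group the same subgroup-consensus mixture is
        # emitted with an independently resampled label per cell, so every
        # column's marginal is identical family-wide and the coupling
        # exists only inside the parent group: the layer is statistically
        # invisible until the alignment is conditioned on the parent.
        S <- length(config$nested_weights)
        cons <- matrix(0L, S, length(pos))
        for (p in seq_along(pos)) cons[, p] <- sample.int(20L, S)
        inpar <- top == nw$parent
        for (p in seq_along(pos)) {
          lab <- sample.int(S, n, replace = TRUE,
                            prob = config$nested_weights)
          lab[inpar] <- sub[inpar]
          idx[, pos[p]] <- mutate_from_consensus(cons[lab, p],
                                                 config$p_cons)
        }
      }
      networks[[k]]$consensus <- matrix(AA_STANDARD[cons], nrow = nrow(cons))
    }
    profiles <- matrix(NA_real_, 20L, L)
    for (p in setdiff(seq_len(L), network_pos)) {
      prof <- rgamma(20L, config$dirichlet_conc)
      prof <- prof / sum(prof)
      profiles[, p] <- prof
      idx[, p] <- sample.int(20L, n, replace = TRUE, prob = prof)
    }
    chars <- matrix(AA_STANDARD[idx], n, L)
    if (config$gap_rate > 0)
      chars[matrix(runif(n * L) < config$gap_rate, n, L)] <- "-"
    ids <- sprintf("seq%05d", seq_len(n))
    rows <- apply(chars, 1L, paste, collapse = "")
    structure(list(
      msa = msa(rows, ids = ids),
      truth = list(top_group = setNames(top, ids),
                   subgroup = setNames(sub, ids),
                   networks = networks,
                   background_profiles = profiles,
                   config = config)),
      class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic super-family: %d sequences x %d positions, %d subgroups, %d planted network(s), p_cons %.2f, gap rate %.2f (seed %d)\n",
              cfg$n_sequences, cfg$n_positions,
              length(cfg$subgroup_weights), length(cfg$networks),
              cfg$p_cons, cfg$gap_rate, cfg$seed))
  invisible(x)
}

#' Planted positions of a simulated family
#'
#' @param sim a `sim_family`.
#' @param level network level to extract (default 1).
#' @return sorted integer vector of planted positions at that level.
#' @export
planted_positions <- function(sim, level = 1L) {
  stopifnot(inherits(sim, "sim_family"))
  nets <- Filter(function(nw) nw$level == level, sim$truth$networks)
  sort(unlist(lapply(nets, `[[`, "positions")))
}

# Format one mutation mention in one of the three supported dialects.
format_mention <- function(wt, resnum, mut, dialect) {
  switch(dialect,
         compact = sprintf("%s%d%s", wt, resnum, mut),
         threeletter = sprintf("%s%d%s", AA_THREE[[wt]], resnum,
                               AA_THREE[[mut]]),
         phrase = sprintf("%s%d was mutated to %s", AA_THREE[[wt]],
                          resnum, AA_THREE[[mut]]))
}

#' Simulate a mutation-sentence article corpus
#'
#' Emits plain-text articles whose sentences mention point mutations that
#' are valid against the simulated alignment (the stated wild type matches
#' the studied sequence) at planted network positions, co-occurring with
#' the network's keyword. Each planted position is mentioned in
#' `articles_per_position` distinct articles, so a perfect mining pass
#' followed by the distinct-article filter recovers the planted
#' annotations. Noise is injected two ways: `keyword_noise` is the
#' probability that a planted sentence's keyword is replaced by a decoy,
#' and `noise_mentions` extra sentences mention random positions with
#' decoy keywords (each such pair occurs in a single article only). The
#' three mention dialects are cycled through deterministically.
#'
#' @param sim a `sim_family`.
#' @param core a `core_positions` object for `sim$msa` (default: derived
#'   with [derive_core_positions()] defaults).
#' @param n_articles total number of articles (default: two per planted
#'   position).
#' @param articles_per_position distinct articles mentioning each planted
#'   position (default 2).
#' @param keyword_noise per-sentence probability of replacing the planted
#'   keyword with a decoy (default 0).
#' @param noise_mentions number of decoy sentences (default 0).
#' @param decoy_keywords decoy keyword pool.
#' @param n_mut distinct-article threshold used for the expected table
#'   (default 2).
#' @param seed RNG seed.
#' @return object of class `sim_corpus`: list with `articles` (named
#'   character vector of texts), `article_seq` (named map article id to
#'   studied sequence id), `records` (the ground-truth mined records) and
#'   `truth_table` (expected [build_annotation_table()] output at
#'   `n_mut`).
#' @export
simulate_corpus <- function(sim, core = NULL, n_articles = NULL,
                            articles_per_position = 2L,
                            keyword_noise = 0, noise_mentions = 0L,
                            decoy_keywords = c("stability", "buffer",
                                               "temperature", "yield"),
                            n_mut = 2L, seed = 1L) {
  stopifnot(inherits(sim, "sim_family"))
  x <- sim$msa
  if (is.null(core)) core <- derive_core_positions(x)
  planted <- lapply(sim$truth$networks, function(nw)
    list(positions = match(as.integer(nw$positions), core),
         keyword = tolower(nw$keyword)))
  for (p in planted)
    if (anyNA(p$positions))
      cn_stop("a planted position is not a core column; cannot mention it",
              "config_error")
  n_planted <- sum(lengths(lapply(planted, `[[`, "positions")))
  if (is.null(n_articles))
    n_articles <- max(2L, articles_per_position * n_planted)
  aids <- sprintf("art%03d", seq_len(n_articles))
  dialects <- c("compact", "threeletter", "phrase")
  with_seed(seed, {
    sentences <- setNames(vector("list", n_articles), aids)
    recs <- list()
    slot <- 0L
    add_mention <- function(aid, d3, keyword) {
      # pick a sequence with a residue (not a gap) at the column
      col <- core[[d3]]
      cand <- which(x$mat[, col] != "-")
      sid <- x$ids[sample(cand, 1L)]
      info <- map_3d_to_residue(x, core, sid, d3)
      wt <- info$aa
      mut <- AA_STANDARD[(match(wt, AA_STANDARD) - 1L +
                            sample.int(19L, 1L)) %% 20L + 1L]
      slot <<- slot + 1L
      men <- format_mention(wt, info$residue_number, mut,
                            dialects[(slot %% 3L) + 1L])
      sent <- sprintf("In %s the substitution %s clearly altered the %s of the enzyme.",
                      sid, men, keyword)
      sentences[[aid]] <<- c(sentences[[aid]], sent)
      recs[[length(recs) + 1L]] <<-
        data.frame(d3_number = d3, keyword = keyword, article_id = aid,
                   seq_id = sid, wt = wt,
                   position = info$residue_number, mut = mut)
      sid
    }
    art_seq <- setNames(rep(NA_character_, n_articles), aids)
    k <- 0L
    for (nw in planted) {
      for (d3 in nw$positions) {
        for (r in seq_len(articles_per_position)) {
          aid <- aids[(k %% n_articles) + 1L]
          k <- k + 1L
          kw <- if (keyword_noise > 0 && runif(1L) < keyword_noise)
            sample(decoy_keywords, 1L) else nw$keyword
          add_mention(aid, d3, kw)
        }
      }
    }
    if (noise_mentions > 0L) {
      for (b in seq_len(noise_mentions)) {
        aid <- sample(aids, 1L)
        d3 <- sample(seq_along(core), 1L)
        add_mention(aid, d3, sample(decoy_keywords, 1L))
      }
    }
    records <- do.call(rbind, recs)
    # an article studies one protein: re-key every mention in an article
    # to a single sequence that is gap-free at all mentioned columns
    for (aid in aids) {
      rws <- which(records$article_id == aid)
      if (length(rws) == 0L) next
      cols <- core[records$d3_number[rws]]
      ok <- which(rowSums(x$mat[, cols, drop = FALSE] == "-") == 0L)
      sid <- x$ids[ok[sample.int(length(ok), 1L)]]
      art_seq[[aid]] <- sid
      new_sent <- character(length(rws))
      for (q in seq_along(rws)) {
        r <- rws[q]
        info <- map_3d_to_residue(x, core, sid, records$d3_number[r])
        records$seq_id[r] <- sid
        records$wt[r] <- info$aa
        records$position[r] <- info$residue_number
        # keep the substitution non-silent against the new wild type
        records$mut[r] <- AA_STANDARD[(match(info$aa, AA_STANDARD) - 1L +
                                         sample.int(19L, 1L)) %% 20L + 1L]
        slot <- slot + 1L
        men <- format_mention(info$aa, info$residue_number,
                              records$mut[r],
                              dialects[(slot %% 3L) + 1L])
        new_sent[q] <- sprintf("In %s the substitution %s clearly altered the %s of the enzyme.",
                               sid, men, records$keyword[r])
      }
      sentences[[aid]] <- new_sent
    }
    articles <- vapply(aids, function(aid) {
      body <- sentences[[aid]]
      if (is.null(body)) body <- "No mutations were characterized in this study."
      paste(c(sprintf("This article reports mutagenesis of %s.",
                      if (is.na(art_seq[[aid]])) "the enzyme"
                      else art_seq[[aid]]), body), collapse = " ")
    }, character(1L))
    rownames(records) <- NULL
    structure(list(articles = articles, article_seq = art_seq,
                   records = records,
                   truth_table = build_annotation_table(records, n_mut)),
              class = "sim_corpus")
  })
}

#' Write a simulated family and corpus to a run directory
#'
#' Emits `alignment.fasta`, `truth.json`, an `articles/` directory (one
#' `.txt` per article plus `manifest.tsv`) and
#' `expected_annotations.tsv`.
#'
#' @param sim a `sim_family`.
#' @param dir output directory (created if needed).
#' @param corpus optional `sim_corpus`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, corpus = NULL) {
  stopifnot(inherits(sim, "sim_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(sim$msa, file.path(dir, "alignment.fasta"))
  truth <- list(
    top_group = as.list(sim$truth$top_group),
    subgroup = as.list(sim$truth$subgroup),
    networks = lapply(sim$truth$networks, function(nw)
      nw[intersect(names(nw), c("level", "positions", "keyword",
                                "parent"))]),
    config = unclass(sim$truth$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(corpus)) {
    adir <- file.path(dir, "articles")
    dir.create(adir, showWarnings = FALSE)
    for (aid in names(corpus$articles))
      writeLines(corpus$articles[[aid]], file.path(adir,
                                                   paste0(aid, ".txt")))
    write.table(data.frame(article_id = names(corpus$article_seq),
                           seq_id = unname(corpus$article_seq)),
                file.path(adir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_annotation_table(corpus$truth_table,
                           file.path(dir, "expected_annotations.tsv"))
  }
  invisible(dir)
}
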