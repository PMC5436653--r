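# Shared fixture builders. Everything is generated in code; no data files.

# Write a FASTA file from named sequences, return its path.
write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) writeLines(c(paste0(">", id), seqs[[id]]), con)
  path
}

# Alignment of two perfectly coupled blocks over `n` sequences:
# column 1 determines column 2 (A<->D, C<->E).
coupled_msa <- function(n_per_block = 10L) {
  rows <- c(rep("AD", n_per_block), rep("CE", n_per_block))
  msa(rows, ids = sprintf("s%03d", seq_along(rows)))
}

# Random alignment with iid uniform columns (no covariation), seeded.
iid_msa <- function(n, L, seed, gap_rate = 0) {
  set.seed(seed)
  chars <- matrix(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                           "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                           "W", "Y"), n * L, replace = TRUE), n, L)
  if (gap_rate > 0)
    chars[matrix(runif(n * L) < gap_rate, n, L)] <- "-"
  msa(apply(chars, 1L, paste, collapse = ""),
      ids = sprintf("s%04d", seq_len(n)))
}

# Score matrix with a given set of edges at weight `hi`, rest `lo`.
block_score_matrix <- function(K, edges, hi = 0.9, lo = 0.1,
                               method = "sca") {
  s <- matrix(lo, K, K)
  for (e in edges) s[e[1], e[2]] <- s[e[2], e[1]] <- hi
  diag(s) <- NA
  cma_matrix(s, method = method)
}

# Independent brute-force mutual information oracle: plain double loop
# over residue pairs, no shared code with the package internals.
brute_mi <- function(a, b) {
  ok <- a != "-" & b != "-"
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  mi <- 0
  for (ra in unique(a)) for (rb in unique(b)) {
    pab <- mean(a == ra & b == rb)
    if (pab > 0) mi <- mi + pab * log2(pab / (mean(a == ra) * mean(b == rb)))
  }
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  list(mi = mi, h = c(ent(a), ent(b)), n = n)
}

brute_nmi <- function(a, b) {
  r <- brute_mi(a, b)
  hmin <- min(r$h)
  if (hmin == 0) 0 else max(r$mi, 0) / hmin
}

# Independent connected-components oracle: boolean transitive closure.
closure_components <- function(nodes, edges) {
  K <- length(nodes)
  adj <- diag(TRUE, K)
  for (e in edges) {
    i <- match(e[1], nodes); j <- match(e[2], nodes)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(r) paste(sort(nodes[r]),
                                                  collapse = ",")))
  lapply(strsplit(comps, ","), as.integer)
}
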