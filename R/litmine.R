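# Abbreviations whose trailing period must not end a sentence.
ABBREVIATIONS <- c("e.g.", "i.e.", "et al.", "Fig.", "cf.", "vs.")

#' Split article text into sentences
#'
#' Deterministic splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an uppercase letter. Periods inside the common
#' abbreviations "e.g.", "i.e.", "et al.", "Fig.", "cf." and "vs." are
#' protected. The sentence is the co-occurrence unit for mutation mentions
#' and keywords.
#'
#' @param text a character scalar of plain text.
#' @return character vector of sentences (empty for empty input).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(character(0))
  text <- gsub("\\s+", " ", text)
  for (ab in ABBREVIATIONS) {
    prot <- gsub(".", "\x01", ab, fixed = TRUE)
    text <- gsub(ab, prot, text, fixed = TRUE)
  }
  parts <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z])", perl = TRUE)[[1L]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Regular expressions for the three mutation-mention dialects.
.aa1 <- paste(AA_STANDARD, collapse = "")
.aa3 <- paste(AA_THREE, collapse = "|")
RX_COMPACT <- sprintf("\\b([%s])([0-9]+)([%s])\\b", .aa1, .aa1)
RX_THREE <- sprintf("\\b(%s)([0-9]+)(%s)\\b", .aa3, .aa3)
RX_PHRASE <- sprintf(
  "\\b(%s)\\s?([0-9]+)\\s+(?:was|were|is|are|has been|had been)\\s+(?:mutated|substituted|replaced|changed)\\s+(?:to|by|with|into)\\s+(?:an?\\s+)?(%s)\\b",
  .aa3, .aa3)

three_to_one <- function(x) {
  names(AA_THREE)[match(tolower(x), tolower(AA_THREE))]
}

#' Extract mutation mentions from a sentence
#'
#' Recognizes three dialects of point-mutation mentions: the compact form
#' `S127P`, the three-letter form `Glu422Lys` (residue names matched
#' case-insensitively) and the phrase form `"Trp58 was mutated to Ala"`
#' (verb variants mutated/substituted/replaced/changed, connectors
#' to/by/with/into). Duplicate mentions of the same substitution within a
#' sentence are deduplicated. Silent substitutions (wild type equal to
#' mutant) are flagged, not dropped.
#'
#' @param sentence a single sentence.
#' @param article_id identifier of the article the sentence came from.
#' @return data frame with columns `wt`, `position`, `mut`, `article_id`,
#'   `sentence`, `dialect`, `silent`; zero rows when nothing matches.
#' @export
extract_mentions <- function(sentence, article_id = NA_character_) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  grab <- function(rx, dialect, ignore.case) {
    m <- regmatches(sentence, gregexpr(rx, sentence, perl = TRUE,
                                       ignore.case = ignore.case))[[1L]]
    if (length(m) == 0L) return(NULL)
    parts <- regmatches(m, regexec(rx, m, perl = TRUE,
                                   ignore.case = ignore.case))
    do.call(rbind, lapply(parts, function(p) {
      wt <- if (nchar(p[2L]) == 1L) p[2L] else three_to_one(p[2L])
      mu <- if (nchar(p[4L]) == 1L) p[4L] else three_to_one(p[4L])
      data.frame(wt = wt, position = as.integer(p[3L]), mut = mu,
                 dialect = dialect)
    }))
  }
  out <- rbind(grab(RX_PHRASE, "phrase", TRUE),
               grab(RX_THREE, "threeletter", TRUE),
               grab(RX_COMPACT, "compact", FALSE))
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(wt = character(0), position = integer(0),
                      mut = character(0), article_id = character(0),
                      sentence = character(0), dialect = character(0),
                      silent = logical(0)))
  out <- out[out$position >= 1L & !is.na(out$wt) & !is.na(out$mut), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("wt", "position", "mut")]), , drop = FALSE]
  out$article_id <- article_id
  out$sentence <- sentence
  out$silent <- out$wt == out$mut
  rownames(out) <- NULL
  out[, c("wt", "position", "mut", "article_id", "sentence", "dialect",
          "silent")]
}

#' Detect keyword expressions in a sentence
#'
#' A keyword expression is a single stem or a conjunction `"a AND b"`.
#' Stems match case-insensitively as word prefixes ("increase" matches
#' "increased"); a conjunction matches only when all of its stems match
#' the sentence.
#'
#' @param sentence a single sentence.
#' @param keyword_exprs character vector of expressions.
#' @return character vector of the matched expressions (canonical
#'   lower-case form).
#' @export
detect_keywords <- function(sentence, keyword_exprs) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  keyword_exprs <- tolower(keyword_exprs)
  hit <- vapply(keyword_exprs, function(expr) {
    stems <- trimws(strsplit(expr, " and ", fixed = TRUE)[[1L]])
    if (length(stems) == 0L || any(!nzchar(stems)) ||
        any(grepl("\\s", stems)))
      cn_stop(sprintf("malformed keyword expression '%s'", expr),
              "keyword_parse_error")
    all(vapply(stems, function(s)
      grepl(paste0("\\b", s), sentence, ignore.case = TRUE,
            perl = TRUE), logical(1L)))
  }, logical(1L))
  unname(keyword_exprs[hit])
}

#' Validate a mutation mention against a sequence and map it to a 3D number
#'
#' Checks that the sequence's residue at the mentioned position (in the
#' sequence's own numbering, i.e. after its offset) equals the stated wild
#' type, then maps the position to its 3D number. Mentions failing the wild
#' type check, falling outside the sequence, or mapping to a non-core
#' column are rejected with a typed reason; rejection is a value, not an
#' error, so mined tables can be filtered and audited.
#'
#' @param mention one row of the data frame returned by
#'   [extract_mentions()] (or any list with `wt`, `position`, `mut`).
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param seq_id id of the sequence the article refers to.
#' @return list with `ok`; on success also `d3_number`, `wt`, `mut`,
#'   `column`; on failure `reason` in `"out_of_range"`, `"wt_mismatch"`,
#'   `"not_core"`.
#' @export
validate_and_map <- function(mention, x, core, seq_id) {
  i <- row_index(x, seq_id)
  pos <- as.integer(mention$position)
  k <- pos - x$offsets[[seq_id]]
  row <- x$mat[i, ]
  nongap <- which(row != "-")
  if (k < 1L || k > length(nongap))
    return(list(ok = FALSE, reason = "out_of_range"))
  col <- nongap[k]
  if (row[[col]] != mention$wt)
    return(list(ok = FALSE, reason = "wt_mismatch",
                observed = row[[col]]))
  d3 <- match(col, core)
  if (is.na(d3))
    return(list(ok = FALSE, reason = "not_core", column = col))
  list(ok = TRUE, d3_number = as.integer(d3), wt = mention$wt,
       mut = mention$mut, column = col)
}

#' Read a directory of plain-text articles
#'
#' One file per article; the file name (without extension) is the article
#' id.
#'
#' @param dir directory of `.txt` files.
#' @return named character vector of article texts.
#' @export
read_articles <- function(dir) {
  if (!dir.exists(dir)) cn_stop(sprintf("no such directory: %s", dir),
                                "input_error")
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  texts <- vapply(files, function(f)
    paste(readLines(f, warn = FALSE), collapse = " "), character(1L))
  names(texts) <- sub("\\.txt$", "", basename(files))
  texts
}

#' Mine articles for validated, keyword-annotated mutation records
#'
#' Full text-mining pass: split each article into sentences, extract
#' mutation mentions, detect keywords in the mention's sentence, validate
#' each mention against the sequence the article refers to, and map it to
#' a 3D number. Silent substitutions are excluded by default.
#'
#' @param texts named character vector of article texts (names = article
#'   ids), e.g. from [read_articles()].
#' @param x an `msa` object.
#' @param core a `core_positions` object.
#' @param article_seq named character vector mapping article id to the
#'   sequence id the article refers to.
#' @param keyword_exprs keyword expressions for [detect_keywords()].
#' @param include_silent keep silent substitutions (default `FALSE`).
#' @return list with `records` (data frame `d3_number`, `keyword`,
#'   `article_id`, `wt`, `position`, `mut`, `sentence`) and `rejected`
#'   (data frame of rejected mentions with `reason`).
#' @export
mine_articles <- function(texts, x, core, article_seq, keyword_exprs,
                          include_silent = FALSE) {
  stopifnot(!is.null(names(texts)))
  recs <- list(); rej <- list()
  for (aid in names(texts)) {
    sid <- article_seq[[aid]]
    if (is.null(sid) || is.na(sid))
      cn_stop(sprintf("no sequence id for article '%s'", aid),
              "input_error")
    for (sent in split_sentences(texts[[aid]])) {
      men <- extract_mentions(sent, aid)
      if (nrow(men) == 0L) next
      kws <- detect_keywords(sent, keyword_exprs)
      for (r in seq_len(nrow(men))) {
        m <- men[r, ]
        if (m$silent && !include_silent) next
        v <- validate_and_map(m, x, core, sid)
        if (!v$ok) {
          rej[[length(rej) + 1L]] <-
            data.frame(article_id = aid, seq_id = sid, wt = m$wt,
                       position = m$position, mut = m$mut,
                       reason = v$reason)
          next
        }
        if (length(kws) == 0L) next
        recs[[length(recs) + 1L]] <-
          data.frame(d3_number = v$d3_number, keyword = kws,
                     article_id = aid, wt = m$wt, position = m$position,
                     mut = m$mut, sentence = sent)
      }
    }
  }
  empty_rec <- data.frame(d3_number = integer(0), keyword = character(0),
                          article_id = character(0), wt = character(0),
                          position = integer(0), mut = character(0),
                          sentence = character(0))
  empty_rej <- data.frame(article_id = character(0), seq_id = character(0),
                          wt = character(0), position = integer(0),
                          mut = character(0), reason = character(0))
  list(records = if (length(recs)) do.call(rbind, recs) else empty_rec,
       rejected = if (length(rej)) do.call(rbind, rej) else empty_rej)
}

#' Build the article-count-filtered annotation table
#'
#' Groups validated records by (3D position, keyword), counts distinct
#' supporting articles, and retains pairs supported by at least `n_mut`
#' articles. The retained article ids are kept as an audit trail.
#'
#' @param records data frame with columns `d3_number`, `keyword`,
#'   `article_id` (e.g. `mine_articles()$records`).
#' @param n_mut minimum number of distinct articles per (position,
#'   keyword) pair (default 2).
#' @return data frame of class `annotation_table` with columns
#'   `d3_number`, `keyword`, `n_articles`, `article_ids` (comma-joined),
#'   and attribute `n_mut`.
#' @export
build_annotation_table <- function(records, n_mut = 2L) {
  n_mut <- as.integer(n_mut)
  if (n_mut < 1L) cn_stop("n_mut must be >= 1", "config_error")
  need <- c("d3_number", "keyword", "article_id")
  if (!all(need %in% names(records)))
    cn_stop("records need d3_number, keyword, article_id columns",
            "input_error")
  out <- data.frame(d3_number = integer(0), keyword = character(0),
                    n_articles = integer(0), article_ids = character(0))
  if (nrow(records)) {
    records$keyword <- tolower(records$keyword)
    key <- interaction(records$d3_number, records$keyword, drop = TRUE)
    grp <- split(records, key)
    rows <- lapply(grp, function(g) {
      arts <- sort(unique(g$article_id))
      data.frame(d3_number = g$d3_number[1L], keyword = g$keyword[1L],
                 n_articles = length(arts),
                 article_ids = paste(arts, collapse = ","))
    })
    out <- do.call(rbind, rows)
    out <- out[out$n_articles >= n_mut, , drop = FALSE]
    out <- out[order(out$d3_number, out$keyword), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, n_mut = n_mut,
            class = c("annotation_table", "data.frame"))
}

#' Positions annotated with a keyword
#'
#' @param annotations an `annotation_table`.
#' @param keyword keyword expression (canonical lower-case form).
#' @return sorted integer vector of 3D positions.
#' @export
annotation_positions <- function(annotations, keyword) {
  stopifnot(inherits(annotations, "annotation_table"))
  sort(unique(annotations$d3_number[annotations$keyword ==
                                      tolower(keyword)]))
}

#' Write an annotation table as TSV
#'
#' @param annotations an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an annotation table from TSV
#'
#' @param path a TSV written by [write_annotation_table()].
#' @param n_mut threshold recorded on the returned object (the file is
#'   assumed to be already filtered).
#' @return an `annotation_table`.
#' @export
read_annotation_table <- function(path, n_mut = 2L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(df, n_mut = as.integer(n_mut),
            class = c("annotation_table", "data.frame"))
}
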