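test_that("sentence splitting respects boundaries and abbreviation guards", {
  expect_equal(split_sentences("It worked. Then it failed."),
               c("It worked.", "Then it failed."))
  expect_equal(split_sentences("Smith et al. showed S127P. Activity rose."),
               c("Smith et al. showed S127P.", "Activity rose."))
  expect_length(split_sentences("See Fig. 3 for details e.g. panel B."), 1)
  expect_equal(split_sentences(""), character(0))
  expect_equal(split_sentences("   "), character(0))
  # lowercase after the period does not split (not a sentence start)
  expect_length(split_sentences("pH 7.5 buffer was used."), 1)
})

test_that("the three mutation-mention dialects are recognized", {
  m1 <- extract_mentions("the S127P mutation increased specificity", "a1")
  expect_equal(nrow(m1), 1)
  expect_equal(m1$wt, "S"); expect_equal(m1$position, 127L)
  expect_equal(m1$mut, "P"); expect_equal(m1$dialect, "compact")

  m2 <- extract_mentions("Glu422Lys reduced activity", "a1")
  expect_equal(unlist(m2[1, c("wt", "mut")], use.names = FALSE),
               c("E", "K"))
  expect_equal(m2$position, 422L)
  expect_equal(m2$dialect, "threeletter")

  m3 <- extract_mentions("Trp58 was mutated to Ala", "a1")
  expect_equal(unlist(m3[1, c("wt", "mut")], use.names = FALSE),
               c("W", "A"))
  expect_equal(m3$position, 58L)
  expect_equal(m3$dialect, "phrase")

  # verb and connector variants
  m4 <- extract_mentions("Ser11 was replaced by Gly in all variants", "a")
  expect_equal(m4$mut, "G")
  # no match -> empty frame, not an error
  expect_equal(nrow(extract_mentions("No mutations were made.", "a")), 0)
  # case-insensitive three-letter names; compact stays case-sensitive
  expect_equal(extract_mentions("the GLU422LYS variant", "a")$wt, "E")
  expect_equal(nrow(extract_mentions("model s127p here", "a")), 0)
})

test_that("duplicate dialects of one substitution collapse; silent flagged", {
  m <- extract_mentions("S127P (Ser127Pro) improved binding", "a1")
  expect_equal(nrow(m), 1)
  s <- extract_mentions("the control A10A construct", "a1")
  expect_true(s$silent)
  multi <- extract_mentions("both S127P and Glu422Lys were active", "a1")
  expect_equal(nrow(multi), 2)
  # extraction is order-independent across sentences
  s1 <- "S127P raised activity."
  s2 <- "Glu422Lys lowered activity."
  a <- rbind(extract_mentions(s1, "x"), extract_mentions(s2, "x"))
  b <- rbind(extract_mentions(s2, "x"), extract_mentions(s1, "x"))
  expect_equal(a[order(a$position), c("wt", "position", "mut")],
               b[order(b$position), c("wt", "position", "mut")],
               ignore_attr = TRUE)
})

test_that("keyword expressions match as prefixes, conjunctions need all stems", {
  expect_equal(detect_keywords("increased activity toward esters",
                               "activity AND increase"),
               "activity and increase")
  expect_equal(detect_keywords("activity was abolished",
                               "activity AND increase"),
               character(0))
  expect_equal(detect_keywords("Specificity shifted", "specificity"),
               "specificity")
  expect_equal(detect_keywords("the cofactor dissociated",
                               c("specificity", "cofactor")),
               "cofactor")
  # prefix, not substring: "activity" must not fire on "reactivity"
  expect_equal(detect_keywords("reactivity changed", "activity"),
               character(0))
  expect_error(detect_keywords("text", "bad expr AND "),
               class = "keyword_parse_error")
})

test_that("mentions are validated against the sequence and mapped to 3D numbers", {
  x <- msa(c(p1 = "MS-KW", p2 = "MSAKW", p3 = "MSAK-"),
           offsets = c(0L, 10L, 0L))
  core <- derive_core_positions(x, 0.3)  # columns 1,2,4,5
  men <- data.frame(wt = "K", position = 3L, mut = "R")
  v <- validate_and_map(men, x, core, "p1")
  expect_true(v$ok)
  expect_equal(v$d3_number, 3L)
  # same residue in the homolog under its own numbering -> same 3D number
  v2 <- validate_and_map(data.frame(wt = "K", position = 14L, mut = "R"),
                         x, core, "p2")
  expect_equal(v2$d3_number, v$d3_number)
  expect_equal(validate_and_map(data.frame(wt = "G", position = 3L,
                                           mut = "R"), x, core,
                                "p1")$reason, "wt_mismatch")
  expect_equal(validate_and_map(data.frame(wt = "K", position = 99L,
                                           mut = "R"), x, core,
                                "p1")$reason, "out_of_range")
  # gap-rich column 3 is not core: the homolog's residue 13 is rejected
  v3 <- validate_and_map(data.frame(wt = "A", position = 13L, mut = "G"),
                         x, core, "p2")
  expect_false(v3$ok)
  expect_equal(v3$reason, "not_core")
})

test_that("non-core mentions are rejected with a typed reason", {
  x <- msa(c(p1 = "MS-KW", p2 = "MSAKW", p3 = "MSAK-"))
  core <- derive_core_positions(x, 0.3)
  expect_false(3L %in% as.integer(core))
  v <- validate_and_map(data.frame(wt = "A", position = 3L, mut = "G"),
                        x, core, "p2")
  expect_false(v$ok)
  expect_equal(v$reason, "not_core")
  expect_error(validate_and_map(data.frame(wt = "A", position = 3L,
                                           mut = "G"), x, core, "zz"),
               class = "unknown_id_error")
})

test_that("the annotation table applies the distinct-article threshold", {
  recs <- data.frame(
    d3_number = c(17L, 17L, 17L, 17L, 23L),
    keyword = c("specificity", "specificity", "specificity", "activity",
                "activity"),
    article_id = c("A1", "A2", "A1", "A1", "A3"))
  tab <- build_annotation_table(recs, n_mut = 2)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$d3_number, 17L)
  expect_equal(tab$keyword, "specificity")
  expect_equal(tab$n_articles, 2L)      # A1 counted once
  expect_equal(tab$article_ids, "A1,A2")
  # n_mut 1 retains every observed pair
  expect_equal(nrow(build_annotation_table(recs, n_mut = 1)), 3)
  # single-article support is dropped at the default threshold
  one <- recs[recs$article_id == "A3", ]
  expect_equal(nrow(build_annotation_table(one, n_mut = 2)), 0)
  expect_error(build_annotation_table(recs, n_mut = 0),
               class = "config_error")
  expect_equal(annotation_positions(tab, "SPECIFICITY"), 17L)
  # TSV round trip
  p <- tempfile(fileext = ".tsv")
  write_annotation_table(tab, p)
  back <- read_annotation_table(p)
  expect_equal(back$d3_number, tab$d3_number)
  expect_equal(back$article_ids, tab$article_ids)
})
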