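test_that("translation follows the standard code with ambiguity and partial-codon rules", {
  expect_identical(translate_seq("ATGGCC", 0, "+"), "MA")
  expect_identical(translate_seq("ATGNGC", 0, "+"), "MX")
  expect_identical(translate_seq("ATGGCCT", 0, "+"), "MA")
  expect_identical(translate_seq("ATGTAA", 0, "+"), "M*")
  # reverse strand: revcomp of CAT is ATG
  expect_identical(translate_seq("CAT", 0, "-"), "M")
})

test_that("find_longest_orf handles the canonical cases", {
  o <- find_longest_orf("CCATGAAATAGCC")
  expect_equal(o$start, 2)
  expect_equal(o$end, 11)
  expect_equal(o$frame, 2)
  expect_identical(o$protein, "MK")
  o2 <- find_longest_orf("ATGTAA")
  expect_equal(c(o2$start, o2$end), c(0, 6))
  expect_identical(o2$protein, "M")
  expect_null(find_longest_orf("CCCCCC"))
})

test_that("find_longest_orf agrees with exhaustive enumeration on random sequences", {
  # oracle: test every (strand, start, end) with end-start divisible by 3,
  # ATG start, no internal stop, stop or sequence end at the 3' end
  orf_oracle <- function(s) {
    L <- nchar(s)
    best <- NULL
    for (strand in c("+", "-")) {
      w <- if (strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      for (st in 0:(L - 3)) {
        if (substr(w, st + 1, st + 3) != "ATG") next
        for (en in seq(st + 3, L, by = 3)) {
          p <- translate_seq(substr(w, st + 1, en), 0, "+")
          body <- substr(p, 1, nchar(p) - 1)
          last <- substr(p, nchar(p), nchar(p))
          if (grepl("\\*", body)) next   # internal stop
          # valid ORF must be maximal to the right: either ends at a stop
          # codon or runs to where no full codon remains
          closed <- last == "*"
          open_ended <- !closed && (en + 3 > L)
          if (!closed && !open_ended) next
          len <- en - st
          if (is.null(best) || len > best$len) best <- list(len = len)
        }
      }
    }
    if (is.null(best)) NULL else best$len
  }
  set.seed(99)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
               collapse = "")
    o <- find_longest_orf(s)
    expect_equal(if (is.null(o)) NULL else o$length_nt, orf_oracle(s),
                 info = s)
  }
})

test_that("trim_utrs returns exactly the ORF translation with a _cds id", {
  s <- c(tx1 = "CCATGAAATAGCC")
  o <- find_longest_orf(s)
  p <- trim_utrs(s, o)
  expect_identical(unname(p), "MK")
  expect_identical(names(p), "tx1_cds")
  # whole-sequence ORF is an identity transform of the translation
  s2 <- c(tx2 = "ATGGCCTAA")
  o2 <- find_longest_orf(s2)
  expect_identical(unname(trim_utrs(s2, o2)), "MA")
  o_bad <- o
  o_bad$end <- 99L
  expect_error(trim_utrs(s, o_bad), "out of bounds")
})

test_that("local alignment reproduces hand-computed BLOSUM62 scores", {
  h <- local_align(c(q = "MKV"), c(s = "MKV"))
  expect_equal(h$score, 14)  # 5 + 5 + 4 on the BLOSUM62 diagonal
  expect_equal(h$identity, 1)
  expect_equal(h$query_span, c(0L, 3L))
  h0 <- local_align("AAAA", "TTTT")
  expect_equal(h0$score, 0)
  expect_equal(h0$query_span, c(0L, 0L))
})

test_that("local alignment is symmetric and self-score is maximal", {
  set.seed(5)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "M", "K", "V", "L")
  for (i in 1:10) {
    a <- paste(sample(aa, 8, TRUE), collapse = "")
    b <- paste(sample(aa, 8, TRUE), collapse = "")
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
    expect_gte(local_align(a, a)$score, local_align(a, b)$score)
  }
})

test_that("Smith-Waterman equals brute-force substring alignment for short strings", {
  set.seed(31)
  mat <- blosum62_test()
  aa <- c("A", "R", "N", "M", "K", "V")
  for (i in 1:12) {
    a <- paste(sample(aa, sample(3:6, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:6, 1), TRUE), collapse = "")
    expect_equal(local_align(a, b)$score, sw_brute(a, b, mat), info = paste(a, b))
  }
})

test_that("best_hit ranks by score and flags unique winners by margin", {
  targets <- c(t1 = "MKVLARNDCQ", t2 = "WWFFYYPPGG", t3 = "MKVLARNDCQ")
  h1 <- best_hit(c(q = "MKVLARNDCQ"), targets[c("t1", "t2")])
  expect_identical(h1$subject[1], "t1")
  expect_true(attr(h1, "unique_best"))
  # exact tie between two identical targets
  h2 <- best_hit(c(q = "MKVLARNDCQ"), targets[c("t1", "t3")])
  expect_false(attr(h2, "unique_best"))
})

test_that("single-copy assignment resolves synthetic families and defers paralogs", {
  cfg <- clock_study_config(
    genes = data.frame(gene = c("per", "tim", "Clk", "cyc", "dbt", "jet"),
                       group = c("TTFL", "TTFL", "TTFL", "TTFL", "PTM", "PTM"),
                       n_sites = 120L, multiplier = 1),
    dropout = list(), seed = 14)
  ds <- simulate_clock_study(cfg)
  refs <- vapply(ds$families, function(f) unname(f$msa$seqs["Aaegypti"]),
                 character(1))
  qry <- vapply(ds$families, function(f) unname(f$msa$seqs["Wsmithii"]),
                character(1))
  names(qry) <- sprintf("contig%02d", seq_along(qry))
  asn <- assign_single_copy(qry, refs)
  expect_true(all(asn$status == "assigned"))
  expect_identical(asn$candidate,
                   sprintf("contig%02d", match(asn$gene, names(refs))))
  # declared multi-gene family is deferred to tree-based assignment
  asn2 <- assign_single_copy(qry, refs,
                             multigene_families = list(cry = c("per", "tim")))
  expect_identical(asn2$status[asn2$gene %in% c("per", "tim")],
                   c("deferred", "deferred"))
  # a reference with no counterpart in the query set is absent
  asn3 <- assign_single_copy(qry[1:3], c(refs[1:3], missing_gene = "WWWWYYYY"),
                             min_score = 50)
  expect_identical(asn3$status[asn3$gene == "missing_gene"], "absent")
})
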