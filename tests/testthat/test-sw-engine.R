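scheme <- scoring_scheme()

test_that("oracle reproduces frozen worked-example scores", {
  expect_equal(as.integer(sw_score_oracle("AW", "AW", scheme)), 15L)
  # frozen golden, computed ahead of time with two independent aligners
  expect_equal(as.integer(sw_score_oracle("HEAGAWGHEE", "PAWHEAE", scheme)),
               18L)
  alt <- scoring_scheme(first_gap = "open+extend")
  expect_equal(as.integer(sw_score_oracle("HEAGAWGHEE", "PAWHEAE", alt)), 17L)
})

test_that("empty sequences score zero under the boundary conditions", {
  expect_equal(as.integer(sw_score_oracle(integer(0), "ACDEF", scheme)), 0L)
  expect_equal(as.integer(sw_score_oracle("ACDEF", integer(0), scheme)), 0L)
})

test_that("oracle is symmetric and agrees with an independent aligner", {
  set.seed(111)
  for (conv in c("open", "open+extend")) {
    sch <- scoring_scheme(first_gap = conv)
    for (i in 1:25) {
      a <- random_protein(sample(1:60, 1))
      b <- random_protein(sample(1:60, 1))
      ours <- as.integer(sw_score_oracle(a, b, sch))
      expect_equal(ours, as.integer(sw_score_oracle(b, a, sch)))
      expect_equal(ours, bios_local_score(a, b, sch))
    }
  }
})

test_that("appending residues to a subject never decreases its score", {
  set.seed(112)
  q <- random_protein(40)
  for (i in 1:15) {
    s <- random_protein(sample(5:40, 1))
    longer <- paste0(s, random_protein(sample(1:10, 1)))
    expect_gte(as.integer(sw_score_oracle(q, longer, scheme)),
               as.integer(sw_score_oracle(q, s, scheme)))
  }
})

test_that("query profile equals direct matrix lookups and fits the cache bound", {
  set.seed(113)
  q <- random_protein(80)
  prof <- build_query_profile(q, scheme)
  codes <- encode_sequence(q)
  for (j in seq_along(codes)) {
    expect_equal(unname(prof$table[j, ]), unname(scheme$matrix[codes[j] + 1L, ]))
  }
  p356 <- build_query_profile(random_protein(356), scheme)
  expect_equal(p356$bytes, 356L * 23L)
  expect_lte(p356$bytes, 8L * 1024L)
  expect_gt(build_query_profile(random_protein(357), scheme)$bytes, 8L * 1024L)
  expect_error(build_query_profile(c(0L, SEQ_TERM), scheme),
               class = "swlane_domain_error")
  expect_error(build_query_profile("", scheme), class = "swlane_usage_error")
})

test_that("lane stepper reproduces oracle scores across terminators", {
  set.seed(114)
  q <- random_protein(12)
  prof <- build_query_profile(q, scheme)
  s1 <- random_protein(9)
  s2 <- random_protein(14)
  stream <- c(encode_sequence(s1), SEQ_TERM, encode_sequence(s2), GROUP_TERM,
              PAD, PAD)
  st <- lane_state(prof)
  got <- integer(0)
  for (code in stream) {
    step <- lane_advance(st, code, prof, scheme)
    st <- step$state
    if (!is.null(step$emitted)) got <- c(got, step$emitted$score)
  }
  expect_equal(got, c(as.integer(sw_score_oracle(q, s1, scheme)),
                      as.integer(sw_score_oracle(q, s2, scheme))))
})

test_that("PAD leaves the lane state untouched", {
  q <- "ACDEF"
  prof <- build_query_profile(q, scheme)
  st <- lane_advance(lane_state(prof), encode_sequence("W"), prof,
                     scheme)$state
  after <- lane_advance(st, PAD, prof, scheme)
  expect_null(after$emitted)
  expect_identical(after$state, st)
})

test_that("engine scores equal the oracle for every sequence and layout", {
  set.seed(115)
  recs <- random_records(120, 1, 60)
  q <- random_protein(35)
  want <- oracle_scores(q, recs, scheme)
  for (lanes in c(1L, 16L)) {
    for (subset in c(1L, 8L)) {
      for (mode in c("equal", "set-local")) {
        db <- pack_database(recs, lanes = lanes, subset_length = subset,
                            mode = mode)
        expect_equal(engine_scores(db, q, scheme), want)
      }
    }
  }
})

test_that("duplicate sequences get identical scores", {
  set.seed(116)
  s <- random_protein(25)
  recs <- data.frame(id = c("d1", "d2", "d3"), description = "",
                     residues = c(s, random_protein(25), s))
  db <- pack_database(recs, lanes = 2, subset_length = 2)
  hits <- search_packed(db, random_protein(20), scheme)
  hits <- hits[order(hits$db_order), ]
  expect_equal(hits$score[1], hits$score[3])
})

test_that("scores saturate at the 16-bit maximum and are flagged", {
  w <- strrep("W", 6000)  # 6000 * 11 exceeds 65535
  o <- sw_score_oracle(w, w, scheme)
  expect_equal(as.integer(o), 65535L)
  expect_true(attr(o, "saturated"))
  recs <- data.frame(id = "w", description = "", residues = w)
  db <- pack_database(recs, lanes = 1, subset_length = 1)
  hits <- search_packed(db, w, scheme)
  expect_equal(hits$score, 65535L)
  expect_true(hits$saturated)
})

test_that("a planted query is the top hit among unrelated sequences", {
  set.seed(117)
  q <- random_protein(50)
  recs <- rbind(random_records(40, 20, 60),
                data.frame(id = "planted", description = "the query itself",
                           residues = q))
  db <- pack_database(recs, lanes = 16, subset_length = 8)
  hits <- search_packed(db, q, scheme)
  best <- top_hits(hits, 1)
  expect_equal(best$seq_id, "planted")
  expect_equal(best$score, as.integer(sw_score_oracle(q, q, scheme)))
})

test_that("top_hits ranks by score with database order as tie-break", {
  hits <- data.frame(seq_id = c("a", "b", "c", "d"),
                     score = c(5L, 9L, 7L, 9L),
                     saturated = FALSE, db_order = 1:4,
                     stringsAsFactors = FALSE)
  two <- top_hits(hits, 2)
  expect_equal(two$seq_id, c("b", "d"))
  expect_equal(two$rank, 1:2)
  expect_equal(nrow(top_hits(hits, 0)), 0L)
  expect_equal(top_hits(hits, 99)$seq_id, c("b", "d", "c", "a"))
})

test_that("top-hit FASTA export round trips ids in rank order", {
  set.seed(118)
  recs <- random_records(30, 10, 40)
  db <- pack_database(recs, lanes = 4, subset_length = 2)
  ranked <- top_hits(search_packed(db, random_protein(25), scheme), 10)
  tf <- withr::local_tempfile(fileext = ".fasta")
  export_top_fasta(ranked, recs, tf)
  back <- read_fasta(tf)
  expect_equal(back$id, ranked$seq_id)
  expect_match(back$description, "score=\\d+")
  export_top_fasta(ranked[integer(0), ], recs, tf)
  expect_equal(nrow(read_fasta(tf)), 0L)
})
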