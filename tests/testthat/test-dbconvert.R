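perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

test_that("sorting is by descending length and stable on ties", {
  recs <- data.frame(id = c("a", "b", "c"), description = "",
                     residues = c("AAAAA", "AA", "AAAAAAAAA"))
  expect_equal(sort_by_length(recs)$id, c("c", "a", "b"))
  ties <- data.frame(id = c("x", "y", "z"), description = "",
                     residues = c("AAA", "CCC", "AAAA"))
  expect_equal(sort_by_length(ties)$id, c("z", "x", "y"))
})

test_that("length sorting minimizes the maximum adjacent length difference", {
  set.seed(104)
  for (i in 1:10) {
    lens <- sample(1:30, sample(2:6, 1), replace = TRUE)
    sorted_gap <- max(abs(diff(sort(lens, decreasing = TRUE))))
    brute <- min(vapply(perms(lens),
                        function(p) max(abs(diff(p))), 0))
    expect_equal(sorted_gap, brute)
  }
})

test_that("uniform-length input packs into one set with no padding", {
  recs <- random_records(16, 10, 10)
  db <- pack_database(recs, lanes = 16, subset_length = 1)
  expect_equal(length(db$sets), 1L)
  expect_equal(db$stream_lengths, 11L)  # 10 residues + GROUP_TERM
  expect_equal(sum(db$sets[[1]] == PAD), 0L)
  expect_equal(nrow(db$index), 16L)
  expect_equal(sort(db$index$lane), 1:16)
})

test_that("leftover sequences are appended where their length + terminator fits", {
  recs <- data.frame(id = c("s4", "s2", "s1a", "s1b"), description = "",
                     residues = c("AAAA", "CC", "D", "E"))
  db <- pack_database(recs, lanes = 2, subset_length = 1)
  expect_equal(db$target_length, 4L)
  expect_equal(nrow(db$index), 4L)
  expect_equal(length(db$sets), 2L)
  set1 <- db$index[db$index$set == 1L, ]
  # set 1 holds the length-4 and length-2 seeds plus one appended length-1
  expect_setequal(set1$seq_id, c("s4", "s2", "s1a"))
  expect_equal(set1$offset[set1$seq_id == "s1a"], 4L)  # after "CC" + SEQ_TERM
  expect_true(verify_roundtrip(recs, db)$ok)
})

test_that("a sequence longer than an explicit target is a packing error", {
  recs <- data.frame(id = "long", description = "", residues = strrep("A", 9))
  err <- expect_error(pack_database(recs, lanes = 2, target_length = 5),
                      class = "swlane_usage_error")
  expect_match(conditionMessage(err), "target")
})

test_that("interlacing follows the subset window layout and inverts exactly", {
  g <- matrix(c(encode_sequence("ABCD"), encode_sequence("EFGH")), ncol = 2)
  out <- interlace(g, 2)
  expect_equal(out, encode_sequence("ABEFCDGH"))
  expect_equal(deinterlace(out, 2, 2), g)
  single <- matrix(encode_sequence("ACDEFG"), ncol = 1)
  expect_equal(interlace(single, 3), as.integer(single))
  expect_equal(deinterlace(integer(0), 4, 2), matrix(integer(0), 0, 4))
  expect_error(deinterlace(1:10, 4, 2), class = "swlane_format_error")
})

test_that("interlace/deinterlace are mutual inverses for random layouts", {
  set.seed(105)
  for (i in 1:20) {
    lanes <- sample(c(1L, 2L, 4L, 16L), 1)
    subset <- sample(c(1L, 2L, 8L), 1)
    nwin <- sample(1:6, 1)
    m <- matrix(sample(0L:25L, lanes * subset * nwin, replace = TRUE),
                ncol = lanes)
    expect_equal(deinterlace(interlace(m, subset), lanes, subset), m)
  }
})

test_that("packing recovers every input sequence exactly once", {
  set.seed(106)
  for (i in 1:15) {
    recs <- random_records(sample(1:60, 1), 1, 50)
    lanes <- sample(c(1L, 2L, 16L), 1)
    subset <- sample(c(1L, 2L, 8L), 1)
    mode <- sample(c("equal", "set-local"), 1)
    db <- pack_database(recs, lanes = lanes, subset_length = subset,
                        mode = mode)
    expect_true(verify_roundtrip(recs, db)$ok)
    expect_equal(nrow(db$index), nrow(recs))
  }
})

test_that("equal mode equalizes stream lengths; set-local follows set seeds", {
  set.seed(107)
  recs <- random_records(70, 1, 120)
  eq <- pack_database(recs, lanes = 16, subset_length = 8, mode = "equal")
  expect_true(all(eq$stream_lengths == eq$stream_lengths[1]))
  expect_equal(eq$stream_lengths[1],
               as.integer(ceiling((eq$target_length + 1) / 8) * 8))
  sl <- pack_database(recs, lanes = 16, subset_length = 8,
                      mode = "set-local")
  seed_len <- vapply(seq_along(sl$sets), function(s) {
    max(sl$index$length[sl$index$set == s])
  }, 0L)
  expect_equal(sl$stream_lengths,
               as.integer(ceiling((seed_len + 1) / 8) * 8))
  expect_true(all(sl$stream_lengths <= eq$stream_lengths[1]))
})

test_that("packed binary round trips and carries the DOPA magic", {
  set.seed(108)
  recs <- random_records(40, 1, 50)
  db <- pack_database(recs, lanes = 4, subset_length = 2)
  tf <- withr::local_tempfile()
  write_packed(db, tf)
  expect_equal(readBin(tf, "raw", 4), charToRaw("DOPA"))
  back <- read_packed(tf)
  expect_equal(back$sets, db$sets)
  expect_equal(back$stream_lengths, db$stream_lengths)
  expect_equal(back$index, db$index)
  expect_equal(back$mode, db$mode)
  expect_equal(back$target_length, db$target_length)
  expect_equal(back$residue_total, db$residue_total)
})

test_that("corrupt packed files are rejected with named failures", {
  set.seed(109)
  recs <- random_records(10, 1, 30)
  db <- pack_database(recs, lanes = 2, subset_length = 2)
  tf <- withr::local_tempfile()
  write_packed(db, tf)
  raw <- readBin(tf, "raw", file.info(tf)$size)

  bad <- withr::local_tempfile()
  writeBin(c(charToRaw("NOPE"), raw[-(1:4)]), bad)
  expect_error(read_packed(bad), class = "swlane_format_error")

  ver <- withr::local_tempfile()
  raw2 <- raw; raw2[5] <- as.raw(9)
  writeBin(raw2, ver)
  file.copy(paste0(tf, ".idx"), paste0(ver, ".idx"))
  err <- expect_error(read_packed(ver), class = "swlane_format_error")
  expect_match(conditionMessage(err), "version 9")
  expect_match(conditionMessage(err), "version 1")

  trunc <- withr::local_tempfile()
  writeBin(raw[1:20], trunc)
  expect_error(read_packed(trunc), class = "swlane_format_error")
})

test_that("round-trip verification flags corrupted streams and reports padding", {
  set.seed(110)
  recs <- random_records(24, 5, 30)
  db <- pack_database(recs, lanes = 4, subset_length = 2)
  expect_true(verify_roundtrip(recs, db)$ok)
  db$sets[[1]][3] <- (db$sets[[1]][3] + 1L) %% 23L
  expect_false(verify_roundtrip(recs, db)$ok)

  const <- random_records(8, 12, 12)
  for (mode in c("equal", "set-local")) {
    cdb <- pack_database(const, lanes = 4, subset_length = 1, mode = mode)
    expect_equal(verify_roundtrip(const, cdb)$pad_fraction, 0)
  }
})
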