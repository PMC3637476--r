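test_that("the seed index records every k-mer occurrence", {
  idx <- build_index(c(ref1 = "ACGTACGTACGTACG"), k = 11)
  expect_equal(nrow(idx$table), 5L)  # L - k + 1

  idx2 <- build_index(c(a = strrep("ACGT", 10), b = strrep("ACGT", 10)), k = 11)
  expect_setequal(unique(idx2$table$ref), c("a", "b"))

  expect_error(build_index(character(0)), "empty")
  expect_warning(idx3 <- build_index(c(long = strrep("ACGT", 10), tiny = "ACGT")),
                 "shorter than k")
  expect_equal(names(idx3$refs), "long")
})

test_that("exact substrings map at identity 1 on either strand", {
  set.seed(1)
  ref <- random_seq(600)
  idx <- build_index(c(putA = ref))
  read <- substr(ref, 101, 250)

  a <- map_read(read, idx)
  expect_equal(a$identity, 1)
  expect_equal(a$strand, "+")
  expect_equal(a$ref_start, 100L)
  expect_equal(a$ref_end, 250L)
  expect_equal(a$aln_frac, 1)

  b <- map_read(revcomp(read), idx)
  expect_equal(b$identity, 1)
  expect_equal(b$strand, "-")
  expect_equal(b$ref_start, 100L)
  # pileup pairs are reported in reference orientation on both strands
  expect_identical(b$pairs, a$pairs)
})

test_that("the 98 percent identity threshold separates 2 from 5 substitutions", {
  set.seed(2)
  ref <- random_seq(600)
  idx <- build_index(c(putA = ref))
  read <- substr(ref, 201, 350)

  r5 <- read
  for (p in c(30, 60, 90, 110, 130)) r5 <- mutate_at(r5, p)
  expect_null(map_read(r5, idx, min_identity = 0.98))  # 145/150 < 0.98

  r2 <- read
  for (p in c(50, 100)) r2 <- mutate_at(r2, p)
  a <- map_read(r2, idx, min_identity = 0.98)
  expect_equal(a$identity, 148 / 150)
  expect_equal(a$n_mismatch, 2L)
})

test_that("every reference maps onto itself over its full length", {
  set.seed(3)
  refs <- setNames(vapply(c(150, 200, 350), random_seq, character(1)),
                   c("p1", "p2", "p3"))
  idx <- build_index(refs)
  for (id in names(refs)) {
    a <- map_read(refs[[id]], idx)
    expect_equal(a$put_id, id)
    expect_equal(a$identity, 1)
    expect_equal(a$ref_start, 0L)
    expect_equal(a$ref_end, nchar(refs[[id]]))
  }
})

test_that("banded identity agrees with a full dynamic-programming oracle", {
  set.seed(4)
  for (case in 1:25) {
    ref <- random_seq(sample(120:200, 1))
    idx <- build_index(setNames(ref, "ref"))
    L <- nchar(ref)
    rl <- sample(60:(L - 10), 1)
    st <- sample(L - rl, 1)
    read <- substr(ref, st, st + rl - 1)
    kind <- sample(c("exact", "subs", "del", "ins"), 1)
    if (kind == "subs") {
      for (p in sample(seq(10, rl - 10), sample(1:2, 1))) read <- mutate_at(read, p)
    } else if (kind == "del") {
      p <- sample(seq(15, rl - 15), 1)
      read <- paste0(substr(read, 1, p - 1), substr(read, p + 1, rl))
    } else if (kind == "ins") {
      p <- sample(seq(15, rl - 15), 1)
      read <- paste0(substr(read, 1, p), sample(c("A", "C", "G", "T"), 1),
                     substr(read, p + 1, rl))
    }
    a <- map_read(read, idx, min_identity = 0, min_aln_frac = 0)
    o <- oracle_local_align(read, ref)
    expect_equal(a$identity, o$identity, tolerance = 1e-12,
                 info = sprintf("case %d (%s)", case, kind))
    expect_equal(a$n_match, o$n_match, info = sprintf("case %d (%s)", case, kind))
  }
})

test_that("identity is strand-symmetric", {
  set.seed(5)
  ref <- random_seq(400)
  idx <- build_index(c(r = ref))
  for (i in 1:10) {
    read <- substr(ref, 51, 220)
    for (p in sample(20:150, sample(0:3, 1))) read <- mutate_at(read, p)
    f <- map_read(read, idx, min_identity = 0, min_aln_frac = 0)
    r <- map_read(revcomp(read), idx, min_identity = 0, min_aln_frac = 0)
    expect_equal(f$identity, r$identity)
    expect_setequal(c(f$strand, r$strand), c("+", "-"))
  }
})

test_that("ties break deterministically toward the smallest reference id", {
  set.seed(6)
  seqv <- random_seq(300)
  idx <- build_index(c(zz = seqv, aa = seqv))
  a <- map_read(substr(seqv, 50, 200), idx)
  expect_equal(a$put_id, "aa")
})

test_that("map_reads keeps unmapped ids and writes a readable TSV", {
  set.seed(7)
  ref <- random_seq(500)
  idx <- build_index(c(putA = ref))
  reads <- data.frame(
    read_id = c("hit_DCNC", "miss_DCNC"),
    sequence = c(substr(ref, 51, 250), random_seq(200)),
    library = "DCNC", stringsAsFactors = FALSE
  )
  aln <- map_reads(reads, idx)
  expect_equal(aln$read_id, "hit_DCNC")
  expect_equal(attr(aln, "unmapped"), "miss_DCNC")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(aln, tsv)
  back <- read.delim(tsv)
  expect_equal(back$ref_start, 51L)  # 1-based in the export
})
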