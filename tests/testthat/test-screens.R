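test_that("the treatment partition follows member library codes", {
  members <- data.frame(
    isotig_id = c("i1", "i1", "i2", "i3", "i3", "i3"),
    library = c("DCNC", "DINS", "DCNM", "DCNC", "DCNM", "DIWS"),
    stringsAsFactors = FALSE
  )
  p <- partition_by_treatment(members)
  grp <- setNames(p$group, p$isotig_id)
  expect_equal(grp[["i1"]], "cs")
  expect_equal(grp[["i2"]], "m")
  expect_equal(grp[["i3"]], "cms")
  expect_equal(nrow(p), length(unique(members$isotig_id)))

  expect_error(partition_by_treatment(members, isotig_ids = c("i1", "i2", "i3", "i4")),
               "without member reads")
  expect_error(partition_by_treatment(data.frame(isotig_id = "x", library = "XXXX")),
               "unknown library")
})

test_that("group summaries cover all seven groups with exact percentages", {
  members <- data.frame(isotig_id = c("i1", "i2", "i3"),
                        library = c("DCNC", "DCNC", "DCNC"))
  p <- partition_by_treatment(members)
  lens <- c(i1 = 100, i2 = 200, i3 = 600)
  g <- summarize_groups(p, lens)
  expect_equal(g$group, c("c", "m", "s", "cm", "cs", "ms", "cms"))
  expect_equal(g$percent_of_all[g$group == "c"], 100)
  expect_equal(g$mean_length[g$group == "c"], 300)
  expect_equal(sum(g$percent_of_all), 100)

  hits <- data.frame(isotig_id = "i1", db = "nr", hit = TRUE)
  g2 <- summarize_groups(p, lens, hits)
  expect_equal(g2$pct_hit_nr[g2$group == "c"], 100 / 3)
})

test_that("hit rates rise with length when hits are length-dependent", {
  set.seed(50)
  n <- 600
  lens <- sample(150:2500, n, replace = TRUE)
  ids <- sprintf("i%03d", 1:n)
  p_hit <- plogis((lens - 800) / 300)
  hits <- data.frame(isotig_id = ids, db = "nr", hit = runif(n) < p_hit)
  members <- data.frame(isotig_id = rep(ids, each = 2),
                        library = sample(LIBRARY_CODES, 2 * n, replace = TRUE))
  part <- partition_by_treatment(members)
  g <- summarize_groups(part, setNames(lens, ids), hits)
  g <- g[g$n_isotigs > 0, ]
  expect_gt(cor(g$mean_length, g$pct_hit_nr), 0)
})

test_that("length bins split at the documented boundaries", {
  lens <- c(a = 500, b = 501, c = 1000, d = 1001, e = 1999, f = 2000, g = 120)
  tab <- summarize_by_length_bins(lens)
  expect_equal(tab$bin, c("<501", "501-1000", "1001-1999", ">=2000"))
  expect_equal(tab$n_puts, c(2L, 2L, 2L, 1L))
  expect_equal(sum(tab$n_puts), length(lens))

  one <- summarize_by_length_bins(c(x = 700, y = 700, z = 700))
  expect_equal(one$n_puts[one$bin == "501-1000"], 3L)
  expect_equal(sum(one$n_puts > 0), 1L)

  expect_error(summarize_by_length_bins(lens, breaks = c(500, 500)),
               "strictly increasing")
})

test_that("keyword screening counts distinct isotigs per term and overall", {
  hits <- blast_hit_set(data.frame(
    query = c("i1", "i1", "i2", "i3"),
    subject = c("s1", "s2", "s3", "s4"),
    description = c("putative water-stress induced protein",
                    "DREB1A transcription factor",
                    "dehydration-responsive element binding DREB1B",
                    "unrelated kinase"),
    evalue = c(1e-30, 1e-20, 1e-40, 1e-10), bitscore = 100,
    q_start = 1, q_end = 300, frame = 1, s_start = 1, s_end = 100
  ))
  part <- data.frame(isotig_id = c("i1", "i2", "i3"), group = c("cs", "m", "c"))
  scr <- keyword_screen(hits, c("Water-stress", "DREB1"), part,
                        isogroups = c(i1 = "g1", i2 = "g1", i3 = "g2"))
  counts <- scr$counts
  expect_equal(counts[counts$term == "Water-stress", "cs"], 1L)
  expect_equal(counts[counts$term == "DREB1", "cs"], 1L)   # substring match
  expect_equal(counts[counts$term == "DREB1", "m"], 1L)
  # i1 matches two terms but counts once in the distinct total
  expect_equal(scr$n_distinct_isotigs, 2L)
  expect_equal(scr$n_distinct_isogroups, 1L)
  # best hit per (term, isotig) is the smallest e-value
  best_i1 <- scr$candidates[scr$candidates$keyword == "DREB1" &
                              scr$candidates$isotig_id == "i1", ]
  expect_equal(best_i1$subject, "s2")
  expect_error(keyword_screen(hits, character(0)), "non-empty")
})

test_that("the length-reads correlation behaves at its extremes", {
  expect_equal(length_reads_correlation(c(100, 200, 400, 800),
                                        c(1, 2, 4, 8))$r, 1)
  set.seed(51)
  indep <- length_reads_correlation(sample(100:2000, 1000, replace = TRUE),
                                    sample(1:200, 1000, replace = TRUE))
  expect_lt(abs(indep$r), 0.1)

  flat <- length_reads_correlation(rep(100, 5), 1:5)
  expect_true(is.na(flat$r))
  expect_error(length_reads_correlation(1:2, 1:2), "at least 3")
})

test_that("reads sampled uniformly per base correlate with length", {
  tx <- generate_transcriptome(25, isoforms_per_gene = 1,
                               len_params = list(min = 200, max = 2000),
                               treatment_profiles = "cms", seed = 52)
  # per-base-uniform sampling: transcript draw weighted by length
  set.seed(53)
  lens <- tx$transcripts$length
  draws <- table(sample(seq_along(lens), 4000, replace = TRUE, prob = lens))
  r <- length_reads_correlation(lens[as.integer(names(draws))],
                                as.integer(draws))
  expect_gt(r$r, 0)
  expect_lt(r$p_value, 0.01)
})

test_that("distinct nucleotides count shared contigs once", {
  mk_put <- function(spans, contig_len, puts) {
    structure(list(puts = puts, contig_spans = spans, contig_len = contig_len),
              class = "put_set")
  }
  puts <- data.frame(put_id = c("iA", "iB"), kind = "isotig",
                     isogroup_id = "g1", length = c(500, 500),
                     sequence = strrep("A", 500), stringsAsFactors = FALSE)
  spans <- data.frame(
    isoform_id = c("iA", "iA", "iB", "iB"),
    contig_id = c("shared", "uA", "shared", "uB"),
    start = c(0L, 300L, 0L, 300L), end = c(300L, 500L, 300L, 500L)
  )
  ps <- mk_put(spans, c(shared = 300L, uA = 200L, uB = 200L), puts)
  expect_equal(distinct_nucleotides(ps), 700L)

  # no sharing: total equals summed PUT length (including a singleton)
  puts2 <- rbind(puts, data.frame(put_id = "sg1", kind = "singleton",
                                  isogroup_id = "isg_sg1", length = 150,
                                  sequence = strrep("A", 150)))
  spans2 <- data.frame(isoform_id = c("iA", "iB"), contig_id = c("cA", "cB"),
                       start = 0L, end = 500L)
  ps2 <- mk_put(spans2, c(cA = 500L, cB = 500L), puts2)
  expect_equal(distinct_nucleotides(ps2), 1150L)

  # duplicated span listings do not double count
  ps3 <- mk_put(rbind(spans, spans[1, ]), c(shared = 300L, uA = 200L, uB = 200L), puts)
  expect_equal(distinct_nucleotides(ps3), 700L)

  # inconsistent contig lengths are an input error
  bad <- spans; bad$end[3] <- 310L
  expect_error(distinct_nucleotides(mk_put(bad, c(shared = 300L), puts)),
               "inconsistent")
})

test_that("polymorphism level implements the density identity", {
  z <- polymorphism_level(0, 1e6)
  expect_equal(z$percent, 0)
  expect_true(is.na(z$per_bp))

  d <- polymorphism_level(27688, 27688 * 2530)
  expect_equal(round(d$percent, 2), 0.04)
  expect_equal(d$per_bp, 2530)
  expect_equal(d$percent * d$per_bp, 100)

  s <- polymorphism_level(155269, 27688 * 2530)
  expect_equal(round(s$percent, 2), 0.22)
  expect_error(polymorphism_level(5, 0), "positive")
})
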