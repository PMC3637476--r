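test_that("a single-isoform gene of fixed length is one full-length contig", {
  tx <- generate_transcriptome(1, isoforms_per_gene = 1,
                               len_params = list(min = 500, max = 500), seed = 7)
  expect_equal(nrow(tx$transcripts), 1L)
  expect_equal(tx$transcripts$length, 500L)
  expect_equal(nrow(tx$contig_spans), 1L)
  expect_equal(tx$contig_spans$start, 0L)
  expect_equal(tx$contig_spans$end, 500L)
})

test_that("transcriptome generation is deterministic under a fixed seed", {
  a <- generate_transcriptome(50, isoforms_per_gene = 1:3, seed = 1)
  b <- generate_transcriptome(50, isoforms_per_gene = 1:3, seed = 1)
  expect_identical(a, b)
  c2 <- generate_transcriptome(50, isoforms_per_gene = 1:3, seed = 2)
  expect_false(identical(a$transcripts$sequence, c2$transcripts$sequence))
})

test_that("isoforms of one gene share at least one contig and tile cleanly", {
  tx <- generate_transcriptome(10, isoforms_per_gene = 2, seed = 3)
  sp <- tx$contig_spans
  for (g in unique(tx$transcripts$gene_id)) {
    isos <- tx$transcripts$isoform_id[tx$transcripts$gene_id == g]
    expect_length(isos, 2L)
    shared <- Reduce(intersect, lapply(isos, function(i) sp$contig_id[sp$isoform_id == i]))
    expect_gt(length(shared), 0)
  }
  # spans tile each isoform without gaps or overlaps, and shared contigs
  # carry identical subsequence
  for (i in tx$transcripts$isoform_id) {
    s <- sp[sp$isoform_id == i, ]
    expect_equal(s$start, c(0L, head(s$end, -1L)))
    expect_equal(max(s$end), tx$transcripts$length[tx$transcripts$isoform_id == i])
  }
  seqs <- setNames(tx$transcripts$sequence, tx$transcripts$isoform_id)
  sp$piece <- substr(seqs[sp$isoform_id], sp$start + 1L, sp$end)
  pieces <- tapply(sp$piece, sp$contig_id, unique)
  expect_true(all(lengths(pieces) == 1L))
  expect_true(all(tx$transcripts$length >= 100))
})

test_that("planted variant categories follow their frequency contracts", {
  tx <- generate_transcriptome(8, isoforms_per_gene = 1,
                               len_params = list(min = 600, max = 800), seed = 2)
  v <- plant_variants(tx, 10, category_mix = c("ci/ci" = 1), seed = 4)
  expect_equal(nrow(v), 10L)
  expect_true(all(v$coastal_freq > 0 & v$coastal_freq < 1))
  expect_true(all(v$interior_freq > 0 & v$interior_freq < 1))
  expect_true(all(v$allele_a != v$allele_b))

  v2 <- plant_variants(tx, 6, category_mix = c("c/i" = 1), seed = 5)
  expect_true(all((v2$coastal_freq == 0 & v2$interior_freq == 1) |
                    (v2$coastal_freq == 1 & v2$interior_freq == 0)))

  v0 <- plant_variants(tx, 0, seed = 1)
  expect_equal(nrow(v0), 0L)

  mix <- c("ci/ci" = 0.5, "ci/c" = 0.3, "c/c" = 0.2)
  v3 <- plant_variants(tx, 10, category_mix = mix, seed = 6)
  expect_equal(as.list(table(v3$intended_category)),
               list("c/c" = 2L, "ci/c" = 3L, "ci/ci" = 5L))
  # allele_a is the transcript base at the planted position
  seqs <- setNames(tx$transcripts$sequence, tx$transcripts$isoform_id)
  expect_equal(unname(substr(seqs[v3$isoform_id], v3$position + 1, v3$position + 1)),
               v3$allele_a)
})

test_that("noise-free reads are exact substrings honouring treatment profiles", {
  tx <- generate_transcriptome(6, isoforms_per_gene = 1,
                               len_params = list(min = 500, max = 700),
                               treatment_profiles = c("c", "s", "cms"), seed = 9)
  v <- plant_variants(tx, 0, seed = 1)
  plan <- library_plan("DCNS", n_reads = 120, mean_len = 200, sd_len = 40)
  rs <- simulate_library_reads(tx, v, plan, seed = 11)
  expect_equal(nrow(rs$reads), 120L)
  seqs <- setNames(tx$transcripts$sequence, tx$transcripts$isoform_id)
  for (i in seq_len(nrow(rs$reads))) {
    tr <- rs$truth[i, ]
    frag <- rs$reads$sequence[i]
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(frag, substr(seqs[[tr$isoform_id]], tr$start + 1L, tr$end))
  }
  # a severe-stress library never samples control-only transcripts
  prof <- setNames(tx$transcripts$treatment_profile, tx$transcripts$isoform_id)
  expect_true(all(grepl("s", prof[rs$truth$isoform_id])))
})

test_that("read lengths centre on the configured 338 bp mean", {
  tx <- generate_transcriptome(3, isoforms_per_gene = 1,
                               len_params = list(min = 3000, max = 3000),
                               treatment_profiles = "cms", seed = 1)
  plan <- library_plan("DCNC", n_reads = 10000)
  rs <- simulate_library_reads(tx, plant_variants(tx, 0), plan, seed = 2)
  lens <- nchar(rs$reads$sequence)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 338), 3 * se + 1)  # +1 bp: truncation at 50 shifts the mean slightly
})

test_that("variety-private variants exclude the other variety's libraries", {
  tx <- generate_transcriptome(4, isoforms_per_gene = 1,
                               len_params = list(min = 600, max = 700),
                               treatment_profiles = "cms", seed = 3)
  v <- plant_variants(tx, 2, category_mix = c("c/c" = 0.5, "ci/ci" = 0.5), seed = 8)
  host_cc <- v$isoform_id[v$intended_category == "c/c"]
  plan_i <- library_plan("DINC", n_reads = 200, mean_len = 150, sd_len = 20)
  rs <- simulate_library_reads(tx, v, plan_i, seed = 4)
  expect_false(any(rs$truth$isoform_id %in% host_cc))
})

test_that("the assembly fixture conserves reads and keeps library bookkeeping", {
  tx <- generate_transcriptome(6, isoforms_per_gene = 1:2, seed = 5)
  v <- plant_variants(tx, 5, seed = 5)
  plans <- default_library_plans(n_reads = 40, error_sub = 0, n_rate = 0,
                                 polyA_artifact_rate = 0)
  rs <- simulate_read_sets(tx, v, plans, seed = 6)

  at0 <- emit_assembly_fixture(rs, tx, 0, 0, seed = 7)
  expect_equal(nrow(at0$singletons), 0L)
  expect_setequal(at0$isotigs$isotig_id, unique(at0$members$isotig_id))

  at <- emit_assembly_fixture(rs, tx, fp_singleton_rate = 0.08,
                              true_singleton_rate = 0.05, seed = 7)
  expect_equal(nrow(at$members) + nrow(at$singletons) + length(at$too_short),
               nrow(rs$reads))
  expect_true(all(c("fp", "true") %in% at$singletons$label))
  # every member read carries its library code
  lib_truth <- setNames(rs$reads$library, rs$reads$read_id)
  expect_identical(at$members$library, unname(lib_truth[at$members$read_id]))
  # no isotig lost all of its members
  expect_true(all(at$isotigs$isotig_id %in% at$members$isotig_id))
})

test_that("read simulation and fixtures are reproducible end to end", {
  tx <- generate_transcriptome(4, seed = 2)
  v <- plant_variants(tx, 4, seed = 2)
  plans <- default_library_plans(n_reads = 20)
  a <- simulate_read_sets(tx, v, plans, seed = 3)
  b <- simulate_read_sets(tx, v, plans, seed = 3)
  expect_identical(a, b)
  expect_identical(emit_assembly_fixture(a, tx, 0.05, 0.02, seed = 4),
                   emit_assembly_fixture(b, tx, 0.05, 0.02, seed = 4))
})
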