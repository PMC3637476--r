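test_that("pileups carry one row per aligned non-gap base", {
  set.seed(20)
  ref <- random_seq(400)
  idx <- build_index(c(putA = ref))
  r1 <- substr(ref, 101, 300)
  r2 <- mutate_at(substr(ref, 151, 350), 20)
  aln <- map_reads(data.frame(read_id = c("a_DCNC", "b_DINS"),
                              sequence = c(r1, r2),
                              library = c("DCNC", "DINS")), idx,
                   min_identity = 0.9)
  pile <- build_pileup(aln, c(putA = ref))
  expect_equal(nrow(pile), 400L)  # 200 + 200 aligned bases
  cov <- pile[, .N, by = pos]
  expect_true(all(cov$N <= 2))
  # the mutated position shows two alleles with count 1 each
  two <- pile[, .(n_alleles = length(unique(base))), by = pos][n_alleles == 2]
  expect_equal(nrow(two), 1L)
  expect_equal(two$pos, 150L + 19L)
})

test_that("the per-allele support rule controls calling", {
  called <- call_snps(site_pileup(c(A = 3, G = 3)))
  expect_equal(nrow(called), 1L)
  expect_equal(called$allele1, "A")
  expect_equal(called$allele2, "G")
  expect_equal(c(called$n1, called$n2), c(3L, 3L))

  expect_equal(nrow(call_snps(site_pileup(c(A = 10, G = 2)))), 0L)
  expect_equal(nrow(call_snps(site_pileup(c(A = 2, G = 2, C = 2)))), 0L)

  # a third allele at threshold flags the call and the top two are kept
  multi <- call_snps(site_pileup(c(A = 6, G = 5, C = 3)))
  expect_true(multi$multiallelic)
  expect_setequal(c(multi$allele1, multi$allele2), c("A", "G"))

  # allele order is canonical, independent of counts
  rev_counts <- call_snps(site_pileup(c(T = 9, C = 4)))
  expect_equal(rev_counts$allele1, "C")
  expect_lt(rev_counts$n1, rev_counts$n2)
})

test_that("no depth-5 site is callable under the 3+3 rule", {
  # exhaustive: every composition of 5 reads over the four nucleotides
  comps <- expand.grid(A = 0:5, C = 0:5, G = 0:5, T = 0:5)
  comps <- comps[rowSums(comps) == 5, ]
  for (r in seq_len(nrow(comps))) {
    counts <- unlist(comps[r, ])
    counts <- counts[counts > 0]
    expect_equal(nrow(call_snps(site_pileup(counts))), 0L)
  }
  # depth six is the minimum callable coverage
  expect_equal(nrow(call_snps(site_pileup(c(A = 3, C = 3)))), 1L)
})

test_that("consensus requires agreement of every callset", {
  p1 <- site_pileup(c(A = 4, G = 4), put = "p1", pos = 5L)
  p2 <- site_pileup(c(C = 3, T = 5), put = "p1", pos = 9L)
  both <- rbind(p1, p2)
  attr(both, "class") <- class(p1)
  cs_all <- call_snps(both)      # two SNPs
  cs_one <- call_snps(p1)        # only the first

  cons <- intersect_callsets(list(cs_all, cs_all, cs_all))
  expect_equal(nrow(cons), 2L)
  expect_equal(unique(cons$n_callsets), 3L)

  cons2 <- intersect_callsets(list(cs_all, cs_all, cs_one))
  expect_equal(nrow(cons2), 1L)
  expect_equal(cons2$pos, 5L)

  expect_error(intersect_callsets(list(cs_all)), "at least two")
})

test_that("consensus size matches brute-force key intersection", {
  set.seed(30)
  mk <- function(keys) {
    rows <- lapply(keys, function(k) {
      parts <- strsplit(k, ":")[[1]]
      site_pileup(setNames(c(4, 4), c(parts[3], parts[4])),
                  put = parts[1], pos = as.integer(parts[2]))
    })
    p <- data.table::rbindlist(rows)
    data.table::setattr(p, "class", c("pileup", class(p)))
    call_snps(p)
  }
  all_keys <- sprintf("p%d:%d:A:G", rep(1:4, each = 4), rep(c(3, 9, 15, 21), 4))
  shared <- sample(all_keys, 2)
  k1 <- union(shared, sample(setdiff(all_keys, shared), 3))  # 5 calls
  k2 <- union(shared, sample(setdiff(all_keys, shared), 5))  # 7 calls
  k3 <- union(shared, sample(setdiff(all_keys, shared), 4))  # 6 calls
  sets <- list(mk(k1), mk(k2), mk(k3))
  expected <- Reduce(intersect, list(k1, k2, k3))
  cons <- intersect_callsets(sets)
  expect_equal(nrow(cons), length(expected))
  got <- sprintf("%s:%d:%s:%s", cons$put_id, cons$pos, cons$allele1, cons$allele2)
  expect_setequal(got, expected)
})

test_that("consensus support is the union of callset supports", {
  pA <- site_pileup(c(A = 4, G = 3), libs = list(A = "DCNC", G = "DINS"))
  pB <- site_pileup(c(A = 6, G = 3), libs = list(A = "DCWM", G = "DINS"))
  cons <- intersect_callsets(list(call_snps(pA), call_snps(pB)))
  expect_equal(cons$n1, length(union(call_snps(pA)$support1[[1]],
                                     call_snps(pB)$support1[[1]])))
})

test_that("provenance pooling maps nine ordered pairs onto six groups", {
  origins <- c("c", "i", "ci")
  pairs <- expand.grid(o1 = origins, o2 = origins, stringsAsFactors = FALSE)
  cats <- mapply(pool_provenance, pairs$o1, pairs$o2)
  expect_equal(length(cats), 9L)
  expect_setequal(unique(cats), PROVENANCE_CATEGORIES)
  # symmetry under allele swap
  expect_identical(unname(cats), unname(mapply(pool_provenance, pairs$o2, pairs$o1)))
  expect_error(pool_provenance("x", "c"), "origins")
})

test_that("provenance classification decodes library codes per allele", {
  snp <- call_snps(site_pileup(c(A = 4, G = 4),
                               libs = list(A = c("DCNC", "DINS"),
                                           G = c("DCWM", "DIWC"))))
  expect_equal(classify_provenance(snp)$provenance_category, "ci/ci")

  snp2 <- call_snps(site_pileup(c(A = 4, G = 4),
                                libs = list(A = c("DCNC", "DCWS"),
                                            G = c("DCNM", "DINC"))))
  expect_equal(classify_provenance(snp2)$provenance_category, "ci/c")

  snp3 <- call_snps(site_pileup(c(C = 3, T = 3),
                                libs = list(C = "DCNC", T = "DINS")))
  expect_equal(classify_provenance(snp3)$provenance_category, "c/i")

  tab <- summarize_provenance(classify_provenance(snp))
  expect_equal(sum(tab$n_snps), 1L)
  expect_equal(nrow(tab), 6L)
})

test_that("external VCF callsets convert with coordinate shift and filters", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=put1,length=500>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "put1\t42\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:5,4",    # kept
    "put1\t60\t.\tC\tT\t50\tPASS\t.\tGT:AD\t0/1:9,2",    # fails 3+3
    "put1\t70\t.\tG\tA,C\t50\tPASS\t.\tGT:AD\t1/2:3,3",  # multi-allelic
    "put1\t80\t.\tGA\tG\t50\tPASS\t.\tGT:AD\t0/1:5,5"    # indel
  ), vcf)
  cs <- read_external_callset(vcf, c(put1 = strrep("ACGT", 125)))
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$pos, 41L)  # 0-based internally
  expect_equal(c(cs$allele1, cs$allele2), c("A", "G"))
  expect_equal(attr(cs, "n_dropped_support"), 1L)
  expect_equal(attr(cs, "n_dropped_multiallelic"), 1L)
  expect_equal(attr(cs, "n_dropped_indel"), 1L)

  expect_error(read_external_callset(vcf, c(other = strrep("ACGT", 125))),
               "unknown PUT")
})

test_that("consensus VCF export round-trips through the external reader", {
  snp <- classify_provenance(
    intersect_callsets(list(
      call_snps(site_pileup(c(A = 4, G = 4),
                            libs = list(A = c("DCNC", "DINS"),
                                        G = c("DCWM", "DIWC")))),
      call_snps(site_pileup(c(A = 5, G = 3),
                            libs = list(A = "DCNC", G = "DIWC"))))))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(snp, vcf, put_lengths = c(put1 = 500L))
  txt <- readLines(vcf)
  expect_true(any(grepl("CATEGORY=ci/ci", txt)))
  back <- read_external_callset(vcf, c(put1 = strrep("ACGT", 125)),
                                min_allele_support = 0)
  expect_equal(back$pos, snp$pos)
  expect_equal(back$allele1, snp$allele1)
})
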