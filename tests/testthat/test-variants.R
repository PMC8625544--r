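# VCF IO, normalization, MNP decomposition, depth filter, frequencies,
# region classification.

write_test_vcf <- function(lines, dp = TRUE) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.3",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "A3", sep = "\t"),
    lines), path)
  path
}

test_that("read_vcf parses records and genotypes; write_vcf round-trips", {
  p <- write_test_vcf(c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:20\t0/0:9\t1/1:30",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0/0:15\t./.:.\t0/1:7",
    "1\t300\t.\tG\tGA\t.\tPASS\t.\tGT:DP\t0/0:12\t0/1:22\t0/0:18"))
  x <- read_vcf(p)
  expect_identical(nrow(x$variants), 3L)
  expect_identical(x$variants$class, c("SNP", "SNP", "insertion"))
  expect_identical(x$genotypes$a1[1, ], c(A1 = 0L, A2 = 0L, A3 = 1L))
  expect_identical(unname(x$genotypes$depth[2, "A3"]), 7L)
  expect_true(is.na(x$genotypes$a1[2, "A2"]))

  out <- tempfile(fileext = ".vcf")
  write_vcf(x$genotypes, out)
  y <- read_vcf(out)
  expect_identical(y$variants, x$variants)
  expect_identical(y$genotypes$a1, x$genotypes$a1)
  expect_identical(y$genotypes$a2, x$genotypes$a2)
  expect_identical(y$genotypes$depth, x$genotypes$depth)
})

test_that("multi-allelic records split; absent DP means unknown depth", {
  p <- write_test_vcf(
    "1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/2", dp = FALSE)
  x <- read_vcf(p)
  expect_identical(nrow(x$variants), 2L)
  expect_identical(x$variants$alt, c("G", "T"))
  # calls carrying the other alternate become missing for the split record
  expect_identical(unname(x$genotypes$a1[1, "A1"]), 0L)
  expect_identical(unname(x$genotypes$a2[1, "A1"]), 1L)
  expect_true(is.na(x$genotypes$a2[1, "A2"]))
  expect_true(all(is.na(x$genotypes$depth)))
  # unknown depth: the filter keeps every call
  f <- filter_by_depth(x$genotypes, 8)
  expect_identical(f$a1, x$genotypes$a1)
})

test_that("depth filter drops calls below threshold, keeps the boundary", {
  p <- write_test_vcf(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:7\t0/1:8\t1/1:50")
  gm <- read_vcf(p)$genotypes
  f <- filter_by_depth(gm, 8)
  expect_true(is.na(f$a1[1, "A1"]))       # depth 7 -> missing
  expect_identical(unname(f$a1[1, "A2"]), 0L)     # depth 8 -> retained
  expect_identical(unname(f$a2[1, "A3"]), 1L)
  expect_identical(filter_by_depth(gm, 0)$a1, gm$a1)   # identity
})

test_that("variant normalization trims flanks and keeps indel anchors", {
  expect_identical(vr("1", 50, "CAT", "CGT")[, c("pos", "ref", "alt")],
                   data.frame(pos = 51L, ref = "A", alt = "G"))
  r <- vr("1", 10, "CA", "CTTA")
  expect_identical(r$pos, 10L)
  expect_identical(r$ref, "C")
  expect_identical(r$alt, "CTT")
  expect_identical(r$class, "insertion")
})

test_that("MNP decomposition splits positionally and by alignment", {
  m <- vr("1", 100, "AT", "GC")
  d <- decompose_mnp(m)
  expect_identical(d$pos, c(100L, 101L))
  expect_identical(d$ref, c("A", "T"))
  expect_identical(d$alt, c("G", "C"))
  expect_true(all(d$class == "SNP"))

  # insertion inside a complex record, left-aligned with a VCF anchor
  r <- vr("1", 10, "CA", "CTTA")
  d2 <- decompose_mnp(r)
  expect_identical(nrow(d2), 1L)
  expect_identical(d2$pos, 10L)
  expect_identical(d2$alt, "CTT")

  # atomic records pass through unchanged
  s <- vr("1", 5, "A", "T")
  expect_identical(decompose_mnp(s), s)
})

test_that("decomposed records reconstruct the alternate haplotype", {
  set.seed(421)
  for (rep in seq_len(1000)) {
    n_ref <- sample(2:8, 1)
    ref <- paste0(sample(c("A", "C", "G", "T"), n_ref, TRUE),
                  collapse = "")
    # random edit: substitutions plus an optional indel
    alt <- strsplit(ref, "")[[1]]
    k <- sample(n_ref, sample(1:n_ref, 1))
    alt[k] <- sample(c("A", "C", "G", "T"), length(k), TRUE)
    if (runif(1) < 0.5) {
      at <- sample(length(alt), 1)
      ins <- paste0(sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE),
                    collapse = "")
      alt <- append(alt, strsplit(ins, "")[[1]], after = at)
    } else if (length(alt) > 2) {
      at <- sample(length(alt) - 1, 1)
      alt <- alt[-(at:(at + 1))]
    }
    alt <- paste0(alt, collapse = "")
    if (alt == ref || nchar(alt) == 0) next
    rec <- normalize_variant("1", 1000L, ref, alt)
    parts <- decompose_mnp(rec)
    # oracle: apply the atomic records to the original reference string
    rebuilt <- apply_records(ref, 1000L, parts)
    expect_identical(rebuilt, paste0(substr(ref, 1, rec$pos - 1000L),
                                     rec$alt,
                                     substr(ref, rec$pos - 1000L +
                                              nchar(rec$ref) + 1,
                                            nchar(ref))))
  }
})

test_that("allele frequency counts alleles over non-missing calls", {
  # 27 diploid animals, exactly one heterozygote -> 1/54, displayed 0.02
  a1 <- matrix(0L, 1, 27); a2 <- matrix(0L, 1, 27)
  a2[1, 13] <- 1L
  gm <- genotype_matrix(vr("6", 85533780, "C", "T"),
                        sprintf("X%02d", 1:27), a1, a2)
  f <- allele_frequency(gm, 1)
  expect_equal(f$frequency, 1 / 54)
  expect_identical(f$display, 0.02)

  # all homozygous reference -> 0
  a2[1, 13] <- 0L
  gm0 <- genotype_matrix(vr("6", 85533780, "C", "T"),
                         sprintf("X%02d", 1:27), a1, a2)
  expect_identical(allele_frequency(gm0, 1)$display, 0)

  # 10 animals: 3 hom-alt + 4 het -> 10/20
  b1 <- matrix(c(rep(1L, 3), rep(0L, 7)), 1)
  b2 <- matrix(c(rep(1L, 3), rep(1L, 4), rep(0L, 3)), 1)
  gm2 <- genotype_matrix(vr("1", 1, "A", "G"), sprintf("Y%02d", 1:10),
                         b1, b2)
  expect_equal(allele_frequency(gm2, 1)$frequency, 0.5)
})

test_that("group frequencies weighted by group size give the overall one", {
  fx <- milk_fixture()
  gm <- fx$coh$genotypes
  groups <- unique(gm$animals$group)
  for (v in c(1L, 5L, 10L)) {
    parts <- vapply(groups, function(g) {
      n <- sum(gm$animals$group == g)
      c(allele_frequency(gm, v, g)$frequency, n)
    }, numeric(2))
    overall <- allele_frequency(gm, v, "ALL")$frequency
    expect_equal(sum(parts[1, ] * parts[2, ]) / sum(parts[2, ]), overall)
  }
})

test_that("region classification follows the splice-window rule", {
  m <- toy_gene("+")
  # intron is 51..60 after the exon-1 donor; 5 bases in -> splice region
  expect_identical(classify_region(vr("Z", 55, "G", "T"), m),
                   "splice_region")
  expect_identical(classify_region(vr("Z", 40, "A", "G"), m), "coding")
  expect_identical(classify_region(vr("Z", 5, "A", "G"), m), "5_upstream")
  expect_identical(classify_region(vr("Z", 25, "T", "G"), m), "5utr")
  expect_identical(classify_region(vr("Z", 95, "G", "T"), m), "3utr")
})
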