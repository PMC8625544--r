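# Allele catalog loading and milk protein allele assignment.

test_that("the shipped catalog has the 17 characterized alleles", {
  cat <- load_catalog(milk_catalog_path())
  expect_identical(n_alleles(cat), 17L)
  expect_setequal(names(cat$genes),
                  c("CSN1S1", "CSN2", "CSN1S2", "CSN3", "LALBA", "LGB"))
  expect_setequal(names(cat$genes$CSN2$definitions), c("A1", "A2", "L"))
  expect_setequal(names(cat$genes$LGB$definitions), c("B", "B1", "K"))
  expect_identical(cat$genes$CSN3$reference_allele, "B")
})

test_that("malformed catalogs are rejected", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\tallele_name", empty)
  expect_error(load_catalog(empty), "empty|columns")
  # two alleles with identical site-allele sets
  dup <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tallele_name\tchrom\tpos\tref\talt\trequired_allele\tstatus",
    "G1\tA\t1\t100\tC\tT\tC\treference",
    "G1\tB\t1\t100\tC\tT\tC\tknown"), dup)
  expect_error(load_catalog(dup), "identical site-allele set")
})

make_gm <- function(cat, genotypes) {
  # genotypes: list animal -> named vector "chrom:pos:alt" -> dosage
  sites <- do.call(rbind, lapply(cat$genes, function(g) {
    cbind(g$sites, gene = g$gene)
  }))
  keys <- paste0(sites$chrom, ":", sites$pos, ":", sites$alt)
  n <- length(genotypes)
  a1 <- matrix(0L, nrow(sites), n)
  a2 <- matrix(0L, nrow(sites), n)
  for (j in seq_along(genotypes)) {
    for (k in names(genotypes[[j]])) {
      i <- match(k, keys)
      d <- genotypes[[j]][[k]]
      a1[i, j] <- as.integer(d >= 1)
      a2[i, j] <- as.integer(d >= 2)
    }
  }
  variants <- data.frame(chrom = sites$chrom, pos = sites$pos, id = ".",
                         ref = sites$ref, alt = sites$alt,
                         class = variant_class(sites$ref, sites$alt),
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, names(genotypes), a1, a2,
                  groups = data.frame(animal_id = names(genotypes),
                                      group = "G"))
}

test_that("assignment matches the worked single-gene cases", {
  cat <- load_catalog(milk_catalog_path())
  gm <- make_gm(cat, list(
    a_hom_alt = c("6:85451298:G" = 2),               # CSN2 A2/A2
    b_b1 = c("11:103259232:T" = 1, "11:103257970:C" = 1),  # LGB B/B1
    c_ref = c(),                                     # reference everywhere
    d_novel = c("11:103257970:C" = 2)))              # syn alone: no allele
  a2 <- assign_alleles(cat, gm, "CSN2")
  expect_identical(a2$allele1[1], "A2")
  expect_identical(a2$allele2[1], "A2")
  expect_identical(a2$phase_confidence[1], "exact")

  lgb <- assign_alleles(cat, gm, "LGB")
  expect_identical(c(lgb$allele1[2], lgb$allele2[2]), c("B", "B1"))
  expect_identical(lgb$allele1[3], "B")              # hom-ref -> B/B
  expect_identical(lgb$allele1[4], "unresolved-novel")
  expect_match(lgb$note[4], "observed site alleles")

  csn3 <- assign_alleles(cat, gm, "CSN3")
  expect_identical(c(csn3$allele1[3], csn3$allele2[3]), c("B", "B"))
})

test_that("assignment is invariant to variant row order", {
  cat <- load_catalog(milk_catalog_path())
  gm <- make_gm(cat, list(
    x = c("6:85656736:C" = 1, "6:85656772:A" = 1),
    y = c("6:85656736:C" = 2, "6:85656772:A" = 2)))
  t1 <- assign_alleles(cat, gm, "CSN3")
  perm <- sample(nrow(gm$variants))
  gm2 <- gm
  gm2$variants <- gm2$variants[perm, ]
  gm2$a1 <- gm2$a1[perm, , drop = FALSE]
  gm2$a2 <- gm2$a2[perm, , drop = FALSE]
  t2 <- assign_alleles(cat, gm2, "CSN3")
  expect_identical(t1[, c("allele1", "allele2")],
                   t2[, c("allele1", "allele2")])
})

test_that("allele-name frequencies: direct counts and simple cases", {
  cat <- load_catalog(milk_catalog_path())
  # one animal A1/A2 -> 0.50 each
  gm1 <- make_gm(cat, list(solo = c("6:85451298:G" = 1)))
  typed <- assign_alleles(cat, gm1, "CSN2")
  f <- allele_frequencies_by_group(typed)
  expect_equal(f$Total[f$allele == "A1"], 0.5)
  expect_equal(f$Total[f$allele == "A2"], 0.5)

  # 20 animals with 8 B1 alleles among 40 -> 0.20
  gen <- c(lapply(1:4, function(i) c("11:103259232:T" = 2,
                                     "11:103257970:C" = 2)),
           lapply(5:20, function(i) c()))
  names(gen) <- sprintf("s%02d", 1:20)
  gm2 <- make_gm(cat, gen)
  t2 <- assign_alleles(cat, gm2, "LGB")
  f2 <- allele_frequencies_by_group(t2)
  expect_equal(f2$Total[f2$allele == "B1"], 0.20)
  expect_equal(f2$Total[f2$allele == "B"], 0.80)
})

test_that("per-group allele frequencies sum to one over resolved animals", {
  fx <- milk_fixture()
  gm <- fx$coh$genotypes
  cat <- fx$ref$catalog
  typed <- lapply(names(cat$genes), function(g) assign_alleles(cat, gm, g))
  f <- allele_frequencies_by_group(typed)
  for (g in unique(f$gene)) {
    sub <- f[f$gene == g, ]
    for (col in setdiff(names(sub), c("gene", "allele"))) {
      s <- sum(sub[[col]], na.rm = TRUE)
      if (s > 0) expect_equal(s, 1, tolerance = 1e-9)
    }
  }
})

test_that("planted allele pairs are recovered from a clean cohort", {
  cfg <- milk_sim_config(seed = 915L, groups = c(Crossbreed = 200L),
                         depth_range = c(20L, 60L), planted = NULL)
  ref <- generate_reference(cfg, dir = file.path(tempdir(), "milkvar_rec"))
  coh <- generate_cohort(ref)
  gm <- coh$genotypes
  cat <- ref$catalog
  correct <- 0L; total <- 0L
  for (g in names(cat$genes)) {
    typed <- assign_alleles(cat, gm, g)
    truth <- coh$truth_alleles[coh$truth_alleles$gene == g, ]
    truth <- truth[match(typed$animal, truth$animal), ]
    resolved <- typed$phase_confidence %in% c("exact", "em_phased")
    total <- total + sum(resolved)
    correct <- correct + sum(resolved &
                               typed$allele1 == truth$allele1 &
                               typed$allele2 == truth$allele2)
    # animals heterozygous at <= 1 defining site must be exact and right
    exact <- typed$phase_confidence == "exact"
    expect_true(all(typed$allele1[exact] == truth$allele1[exact]))
    expect_true(all(typed$allele2[exact] == truth$allele2[exact]))
  }
  expect_gte(correct / total, 0.99)
})
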