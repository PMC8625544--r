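# Coding consequence prediction and protein-change notation.

test_that("SNP consequences: missense, synonymous, stop gained", {
  m <- toy_gene("+")
  # codon 2 is GCT (Ala) at genomic 34..36; C>T at base 2 -> GTT (Val)
  cc <- predict_consequence(vr("Z", 35, "C", "T"), m)
  expect_identical(cc$kind, "missense")
  expect_identical(cc$precursor_change, "p.Ala2Val")
  # wobble position: GCT -> GCC stays Ala
  cs <- predict_consequence(vr("Z", 36, "T", "C"), m)
  expect_identical(cs$kind, "synonymous")
  expect_identical(cs$precursor_change, "p.Ala2")
  # codon 4 AAA (Lys) at 40..42; A>T at base 1 -> TAA stop
  cg <- predict_consequence(vr("Z", 40, "A", "T"), m)
  expect_identical(cg$kind, "stop_gained")
  expect_identical(cg$precursor_change, "p.Lys4*")
  # wrong reference allele is a hard error
  expect_error(predict_consequence(vr("Z", 35, "G", "T"), m),
               "reference allele mismatch")
})

test_that("every coding SNP is exactly one of syn/mis/stop-gained", {
  m <- toy_gene("+")
  n <- nchar(m$cds_sequence)
  for (p in seq_len(n - 3)) {            # skip the stop codon itself
    gpos <- cds_to_genomic(m, p)
    g <- attr(m, "genome")
    refb <- milkvar:::genome_region(g, "Z", gpos, gpos)
    for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
      cc <- predict_consequence(vr("Z", gpos, refb, altb), m)
      expect_true(cc$kind %in% c("synonymous", "missense", "stop_gained"))
    }
  }
})

test_that("the beta-lactoglobulin insertion gives p.Thr92Asnfs*13", {
  fx <- milk_fixture()
  lgb <- fx$ref$models$LGB
  cc <- predict_consequence(vr("11", 103257980, "A", "AA"), lgb)
  expect_identical(cc$kind, "frameshift")
  expect_identical(cc$mature_change, "p.Thr92Asnfs*13")
  expect_identical(cc$precursor_change, "p.Thr108Asnfs*13")
  expect_identical(truncated_length(cc, "mature"), 104L)
  expect_identical(truncated_length(cc, "precursor"), 120L)
  # mutant product is 74 residues shorter than the 178-residue precursor
  precursor_len <- nchar(lgb$cds_sequence) %/% 3L - 1L
  expect_identical(precursor_len, 178L)
  expect_identical(precursor_len - truncated_length(cc, "mature"), 74L)
})

test_that("mature and precursor numbering differ by the gene offset", {
  fx <- milk_fixture()
  for (case in list(list(g = "CSN3", rec = vr("6", 85656526, "C", "T")),
                    list(g = "LGB", rec = vr("11", 103259232, "C", "T")),
                    list(g = "CSN2", rec = vr("6", 85451298, "T", "G")))) {
    m <- fx$ref$models[[case$g]]
    cc <- predict_consequence(case$rec, m)
    expect_identical(cc$precursor_pos - cc$mature_pos,
                     as.integer(milk_offsets()[[case$g]]))
  }
})

test_that("formatting covers the published notations and signal peptide", {
  fx <- milk_fixture()
  cc <- predict_consequence(vr("6", 85656526, "C", "T"),
                            fx$ref$models$CSN3)
  expect_identical(format_protein_change(cc, "mature"), "p.Ala66Val")
  expect_identical(format_protein_change(cc, "precursor"), "p.Ala87Val")
  syn <- predict_consequence(vr("11", 103257970, "T", "C"),
                             fx$ref$models$LGB)
  expect_identical(format_protein_change(syn, "mature"), "p.Asn88")
  # a change within the signal peptide has no mature numbering
  m <- fx$ref$models$CSN2
  # precursor residue 2 (well inside the 50-residue pre-region): codon 2
  # base 2 is CDS position 5, on the minus strand
  gpos <- cds_to_genomic(m, 5)
  g <- attr(m, "genome")
  refb <- milkvar:::genome_region(g, "6", gpos, gpos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  cc2 <- predict_consequence(vr("6", gpos, refb, altb), m)
  expect_identical(cc2$mature_pos, "pre-mature region")
  expect_error(format_protein_change(cc2, "mature"), "signal peptide")
})

test_that("parsed frameshift notation gives the truncation arithmetic", {
  p <- parse_protein_change("p.Thr92Asnfs*13")
  expect_identical(p$kind, "frameshift")
  expect_identical(truncated_length(p), 104L)
  expect_identical(truncated_length(parse_protein_change("p.Met1Xaafs*1")),
                   1L)
  expect_identical(parse_protein_change("p.Ala66Val")$kind, "missense")
  expect_identical(parse_protein_change("p.Asn88")$kind, "synonymous")
})

test_that("random indels match a mutate-and-translate oracle", {
  set.seed(77)
  checked <- 0L
  while (checked < 50L) {
    m <- sim_gene(n_exons = sample(2:4, 1), n_codons = sample(20:50, 1),
                  strand = sample(c("+", "-"), 1))
    g <- attr(m, "genome")
    n <- nchar(m$cds_sequence)
    p <- sample(seq(4, n - 4), 1)        # keep start/stop codons intact
    gpos <- cds_to_genomic(m, p)
    refb <- milkvar:::genome_region(g, m$chrom, gpos, gpos)
    if (stats::runif(1) < 0.5) {
      ins <- sample(c("A", "C", "G", "T"), 1)
      rec <- vr(m$chrom, gpos, refb, paste0(refb, ins))
    } else {
      nxt <- gpos + 1L
      # deletion of the next base; skip if it crosses a splice junction
      if (!is.numeric(genomic_to_cds(m, nxt))) next
      nxtb <- milkvar:::genome_region(g, m$chrom, nxt, nxt)
      rec <- vr(m$chrom, gpos, paste0(refb, nxtb), refb)
    }
    cc <- predict_consequence(rec, m)
    # oracle: edit the transcript sequence directly and re-translate
    tx <- m$tx_seq
    ti <- match(rec$pos, m$tx_pos)
    minus <- m$strand == "-"
    if (rec$class == "insertion") {
      insseq <- substr(rec$alt, 2, nchar(rec$alt))
      at <- if (minus) ti - 1L else ti
      tx2 <- paste0(substr(tx, 1, at),
                    if (minus) milkvar:::revcomp(insseq) else insseq,
                    substr(tx, at + 1L, nchar(tx)))
    } else {
      didx <- sort(match(rec$pos + seq_len(nchar(rec$ref) - 1L), m$tx_pos))
      tx2 <- paste0(substr(tx, 1, didx[1] - 1L),
                    substr(tx, didx[length(didx)] + 1L, nchar(tx)))
    }
    cds_start <- m$cds_tx_idx[1]
    prot_oracle <- milkvar:::translate_dna(substr(tx2, cds_start,
                                                  nchar(tx2)))
    stop_at <- regexpr("*", prot_oracle, fixed = TRUE)
    oracle_prod <- if (stop_at > 0) substr(prot_oracle, 1, stop_at - 1L)
      else prot_oracle
    expect_identical(cc$kind, "frameshift")
    expect_identical(cc$alt_product, oracle_prod)
    if (!cc$no_stop) {
      expect_identical(truncated_length(cc, "precursor"),
                       nchar(oracle_prod))
    }
    checked <- checked + 1L
  }
})

test_that("splice-region flag equals brute-force junction distances", {
  m <- toy_gene("+")
  ex <- m$exons[order(m$exons$start), ]
  junctions <- c(ex$end[-nrow(ex)] + 0.5, ex$start[-1] - 0.5)
  for (pos in (min(ex$start) - 5):(max(ex$end) + 5)) {
    rec <- vr("Z", pos, "A", "G")       # alleles irrelevant to the flag
    got <- flag_splice_region(rec, m)
    in_intron <- any(pos > ex$end[-nrow(ex)] & pos < ex$start[-1])
    in_exon <- any(pos >= ex$start & pos <= ex$end)
    dist <- min(abs(pos - junctions))
    want <- (in_intron && dist <= 8) || (in_exon && dist <= 3)
    expect_identical(got, want)
  }
})
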