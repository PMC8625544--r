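# Variant and genotype handling: VCF IO, normalization, MNP decomposition,
# the read-depth genotype filter, allele frequencies and region classes.

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
    ifelse(nchar(alt) > nchar(ref), "insertion",
      ifelse(nchar(alt) < nchar(ref), "deletion", "MNP")))
}

#' Normalize a variant record
#'
#' Trims shared trailing bases, then shared leading bases (keeping one
#' anchor base for insertions/deletions), adjusting the position.
#'
#' @param chrom,pos,ref,alt,id Fields of the record.
#' @return One-row data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `class`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, id = ".") {
  if (ref == alt) stop("ref and alt alleles are identical")
  # trim shared suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix; both alleles keep at least one base, which leaves
  # the anchor base in place for insertions/deletions
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  data.frame(chrom = chrom, pos = as.integer(pos), id = id,
             ref = ref, alt = alt, class = variant_class(ref, alt),
             stringsAsFactors = FALSE)
}

# --- VCF IO ----------------------------------------------------------------

#' Read a VCF into variant records and a genotype matrix
#'
#' Multi-allelic sites are split into bi-allelic records; genotype calls
#' carrying a different alternate allele are set missing for the split
#' record. Per-call depth is taken from the `DP` FORMAT field when present
#' (`NA` = unknown).
#'
#' @param path Path to a VCF (4.x, plain text or gzip).
#' @param groups Optional path to a two-column TSV (`animal_id`, `group`) or
#'   a data.frame with those columns.
#' @return A list with `variants` (data.frame: chrom, pos, id, ref, alt,
#'   class) and `genotypes`, a `genotype_matrix` object.
#' @export
read_vcf <- function(path, groups = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {               # single record comes back a vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  n_var <- nrow(fix)
  if (is.null(n_var) || n_var == 0) {
    return(list(variants = empty_variants(), genotypes = genotype_matrix(
      empty_variants(), character(0), NULL, NULL, groups)))
  }
  gt_raw <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "GT") else NULL
  dp_raw <- if (ncol(v@gt) > 1 && "DP" %in%
                unlist(strsplit(v@gt[1, "FORMAT"], ":"))) {
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  } else NULL
  animals <- if (is.null(gt_raw)) character(0) else colnames(gt_raw)

  recs <- list(); a1 <- list(); a2 <- list(); dp <- list()
  for (i in seq_len(n_var)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    g <- if (is.null(gt_raw)) NULL else gt_raw[i, , drop = TRUE]
    parsed <- if (is.null(g)) NULL else parse_gt(g)
    for (k in seq_along(alts)) {
      rec <- normalize_variant(fix$CHROM[i], as.integer(fix$POS[i]),
                               fix$REF[i], alts[k],
                               id = ifelse(is.na(fix$ID[i]), ".", fix$ID[i]))
      recs[[length(recs) + 1L]] <- rec
      if (!is.null(parsed)) {
        conv <- function(a) ifelse(is.na(a), NA_integer_,
                 ifelse(a == 0L, 0L, ifelse(a == k, 1L, NA_integer_)))
        a1[[length(a1) + 1L]] <- conv(parsed$a1)
        a2[[length(a2) + 1L]] <- conv(parsed$a2)
        dp[[length(dp) + 1L]] <- if (is.null(dp_raw)) {
          rep(NA_integer_, length(animals))
        } else as.integer(dp_raw[i, ])
      }
    }
  }
  variants <- do.call(rbind, recs)
  gm <- genotype_matrix(
    variants, animals,
    if (length(a1)) do.call(rbind, a1) else NULL,
    if (length(a2)) do.call(rbind, a2) else NULL,
    groups, depth = if (length(dp)) do.call(rbind, dp) else NULL)
  list(variants = variants, genotypes = gm)
}

empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0), class = character(0),
             stringsAsFactors = FALSE)
}

parse_gt <- function(g) {
  parts <- strsplit(g, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else NA_character_
  }, character(1))))
  list(a1 = a1, a2 = a2)
}

#' Genotype matrix container
#'
#' Diploid calls for `n` variants x `m` animals as two 0/1 allele-index
#' matrices (`NA` = missing) plus a per-call depth matrix.
#'
#' @param variants Variant data.frame (see [read_vcf()]).
#' @param animals Character vector of animal IDs.
#' @param a1,a2 Integer matrices (variants x animals) of allele indices.
#' @param groups Optional group assignment (TSV path or data.frame with
#'   columns `animal_id`, `group`).
#' @param depth Optional integer depth matrix.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(variants, animals, a1, a2, groups = NULL,
                            depth = NULL) {
  m <- length(animals)
  n <- nrow(variants)
  if (is.null(a1)) a1 <- matrix(NA_integer_, n, m)
  if (is.null(a2)) a2 <- matrix(NA_integer_, n, m)
  if (is.null(depth)) depth <- matrix(NA_integer_, n, m)
  dimnames(a1) <- dimnames(a2) <- dimnames(depth) <-
    list(NULL, animals)
  grp <- rep(NA_character_, m)
  if (!is.null(groups)) {
    if (is.character(groups)) {
      groups <- utils::read.table(groups, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    }
    grp <- groups$group[match(animals, groups$animal_id)]
  }
  structure(list(variants = variants, animals = data.frame(
    id = animals, group = grp, stringsAsFactors = FALSE),
    a1 = a1, a2 = a2, depth = depth), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d animals (%s)\n",
              nrow(x$variants), nrow(x$animals),
              paste(sprintf("%s=%d", names(table(x$animals$group)),
                            table(x$animals$group)), collapse = ", ")))
  invisible(x)
}

#' Write variant records and genotypes as VCF 4.3
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.3",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$animals$id), collapse = "\t")), con)
  for (i in seq_len(nrow(v))) {
    calls <- vapply(seq_len(nrow(gm$animals)), function(j) {
      g <- if (is.na(gm$a1[i, j]) || is.na(gm$a2[i, j])) "./." else
        paste0(gm$a1[i, j], "/", gm$a2[i, j])
      d <- if (is.na(gm$depth[i, j])) "." else as.character(gm$depth[i, j])
      paste0(g, ":", d)
    }, character(1))
    writeLines(paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i],
                       ".", "PASS", ".", "GT:DP", calls), collapse = "\t"),
               con)
  }
  invisible(path)
}

# --- depth filter ----------------------------------------------------------

#' Set genotype calls below a depth threshold to missing
#'
#' Calls whose read depth is known and below `min_depth` become missing;
#' calls with unknown depth are kept.
#'
#' @param gm A `genotype_matrix`.
#' @param min_depth Minimum read depth (default 8).
#' @return The filtered `genotype_matrix`.
#' @export
filter_by_depth <- function(gm, min_depth = 8) {
  stopifnot(min_depth >= 0)
  drop <- !is.na(gm$depth) & gm$depth < min_depth
  gm$a1[drop] <- NA_integer_
  gm$a2[drop] <- NA_integer_
  gm
}

# --- allele frequency ------------------------------------------------------

#' Alternate-allele frequency of a variant in a group
#'
#' Missing calls are excluded from the denominator. The display value rounds
#' half away from zero to two decimals.
#'
#' @param gm A `genotype_matrix`.
#' @param variant Row index into `gm$variants`.
#' @param group Group label, or `"ALL"` for the whole cohort.
#' @return List with `frequency` (exact, in `[0,1]`; `NA` when the group has
#'   no non-missing calls) and `display` (2-decimal rounded).
#' @export
allele_frequency <- function(gm, variant, group = "ALL") {
  sel <- if (identical(group, "ALL")) rep(TRUE, nrow(gm$animals)) else
    !is.na(gm$animals$group) & gm$animals$group == group
  a1 <- gm$a1[variant, sel]
  a2 <- gm$a2[variant, sel]
  ok <- !is.na(a1) & !is.na(a2)
  if (!any(ok)) return(list(frequency = NA_real_, display = NA_real_))
  f <- sum(a1[ok] + a2[ok]) / (2 * sum(ok))
  list(frequency = f, display = round_half_up(f, 2))
}

# --- MNP decomposition -----------------------------------------------------

# Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2) with a
# traceback that prefers placing gaps as early (leftmost) as possible.
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + if (av[i] == bv[j]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap)
    }
  }
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] + gap) {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    } else {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    }
  }
  list(a = ra, b = rb, score = S[n + 1, m + 1])
}

#' Decompose a multi-nucleotide or complex variant into atomic records
#'
#' Equal-length multi-nucleotide substitutions are split positionally into
#' SNPs. Length-changing (complex) records are aligned globally (match +1,
#' mismatch -1, gap -2) and alignment columns are classified into SNPs,
#' insertions and deletions; indels are left-aligned and VCF-anchored.
#' Jointly applying the returned records to the reference reproduces the
#' alternate haplotype. Already-atomic records are returned unchanged.
#'
#' @param record One-row variant data.frame (see [normalize_variant()]).
#' @return data.frame of atomic variant records.
#' @export
decompose_mnp <- function(record) {
  ref <- record$ref; alt <- record$alt
  if (record$class %in% c("SNP") ||
      (record$class %in% c("insertion", "deletion") &&
       (nchar(ref) == 1 || nchar(alt) == 1))) {
    return(record)
  }
  out <- list()
  emit_snp <- function(pos, r, a) {
    out[[length(out) + 1L]] <<- data.frame(
      chrom = record$chrom, pos = pos, id = record$id, ref = r, alt = a,
      class = "SNP", stringsAsFactors = FALSE)
  }
  if (nchar(ref) == nchar(alt)) {
    rv <- strsplit(ref, "")[[1]]; av <- strsplit(alt, "")[[1]]
    for (k in which(rv != av)) emit_snp(record$pos + k - 1L, rv[k], av[k])
    return(do.call(rbind, out))
  }
  al <- nw_align(ref, alt)
  ra <- al$a; rb <- al$b
  ref_off <- cumsum(ra != "-")            # 1-based ref offset at column
  rv <- strsplit(ref, "")[[1]]
  events <- list()
  k <- 1L
  while (k <= length(ra)) {
    if (ra[k] != "-" && rb[k] != "-") {
      if (ra[k] != rb[k]) {
        events[[length(events) + 1L]] <- list(type = "snp",
                                              off = ref_off[k],
                                              r = ra[k], a = rb[k])
      }
      k <- k + 1L
    } else if (ra[k] == "-") {            # insertion run
      run <- k
      while (run <= length(ra) && ra[run] == "-") run <- run + 1L
      events[[length(events) + 1L]] <- list(
        type = "ins", off = if (k == 1L) 0L else ref_off[k - 1L],
        seq = paste0(rb[k:(run - 1L)], collapse = ""))
      k <- run
    } else {                              # deletion run
      run <- k
      while (run <= length(ra) && rb[run] == "-") run <- run + 1L
      events[[length(events) + 1L]] <- list(type = "del", off = ref_off[k],
                                            len = run - k)
      k <- run
    }
  }
  shift <- length(events) == 1L           # left-align lone indels only
  for (e in events) {
    if (e$type == "snp") {
      emit_snp(record$pos + e$off - 1L, e$r, e$a)
    } else if (e$type == "ins") {
      ins <- e$seq; a_off <- e$off
      if (shift) {
        while (a_off >= 1L &&
               rv[a_off] == substr(ins, nchar(ins), nchar(ins))) {
          ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                        substr(ins, 1, nchar(ins) - 1))
          a_off <- a_off - 1L
        }
      }
      if (a_off >= 1L) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = record$chrom, pos = record$pos + a_off - 1L,
          id = record$id, ref = rv[a_off], alt = paste0(rv[a_off], ins),
          class = "insertion", stringsAsFactors = FALSE)
      } else {                            # no left anchor: right-anchor
        out[[length(out) + 1L]] <- data.frame(
          chrom = record$chrom, pos = record$pos, id = record$id,
          ref = rv[1], alt = paste0(ins, rv[1]),
          class = "insertion", stringsAsFactors = FALSE)
      }
    } else {
      d_off <- e$off; len <- e$len
      if (shift) {
        while (d_off - 1L >= 1L && d_off + len - 1L <= length(rv) &&
               rv[d_off - 1L] == rv[d_off + len - 1L]) {
          d_off <- d_off - 1L
        }
      }
      if (d_off - 1L >= 1L) {             # left anchor
        a_off <- d_off - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = record$chrom, pos = record$pos + a_off - 1L,
          id = record$id,
          ref = paste0(rv[a_off:(d_off + len - 1L)], collapse = ""),
          alt = rv[a_off], class = "deletion", stringsAsFactors = FALSE)
      } else {                            # deletion at start: right-anchor
        nxt <- d_off + len
        out[[length(out) + 1L]] <- data.frame(
          chrom = record$chrom, pos = record$pos + d_off - 1L,
          id = record$id,
          ref = paste0(rv[d_off:nxt], collapse = ""), alt = rv[nxt],
          class = "deletion", stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- merge_leading_cluster(res, record$pos, rv[1])
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# A leading insertion has no left anchor and must right-anchor on the
# record's first reference base; if another event is anchored on that same
# base the records would overlap, so the cluster is folded into a single
# indel record.
merge_leading_cluster <- function(res, p0, b) {
  idx <- which(res$pos == p0)
  if (length(idx) <= 1) return(res)
  rows <- res[idx, , drop = FALSE]
  lead <- which(rows$class == "insertion" & nchar(rows$alt) > 1 &
                  substr(rows$alt, nchar(rows$alt), nchar(rows$alt)) == b &
                  substr(rows$alt, 1, 1) != b)
  if (length(lead) == 0) return(res)
  pre <- substr(rows$alt[lead], 1, nchar(rows$alt[lead]) - 1)
  mid <- b
  post <- ""
  refspan <- b
  for (j in setdiff(seq_len(nrow(rows)), lead)) {
    if (rows$class[j] == "SNP") {
      mid <- rows$alt[j]
    } else if (rows$class[j] == "insertion") {
      post <- substr(rows$alt[j], 2, nchar(rows$alt[j]))
    } else {                              # deletion anchored on base 1
      refspan <- rows$ref[j]
    }
  }
  merged <- data.frame(
    chrom = rows$chrom[1], pos = p0, id = rows$id[1], ref = refspan,
    alt = paste0(pre, mid, post),
    class = variant_class(refspan, paste0(pre, mid, post)),
    stringsAsFactors = FALSE)
  rbind(res[-idx, , drop = FALSE], merged)
}

# --- region classification -------------------------------------------------

#' Classify a variant's transcript region
#'
#' One tag per (variant, transcript): `5_upstream`, `5utr`, `coding`,
#' `intron`, `splice_region`, `3utr` or `3_downstream`. The splice-region
#' rule is positional: within `intron_window` bases into an intron or
#' `exonic_window` bases into an exon from a junction.
#'
#' @param record One-row variant data.frame.
#' @param model A [transcript_model()].
#' @param intron_window,exonic_window Splice-region windows (defaults 8
#'   and 3).
#' @return The region tag (character scalar).
#' @export
classify_region <- function(record, model, intron_window = 8,
                            exonic_window = 3) {
  if (flag_splice_region(record, model, donor_window = intron_window,
                         acceptor_window = intron_window,
                         exonic_window = exonic_window)) {
    return("splice_region")
  }
  tag <- genomic_to_cds(model, record$pos)
  if (is.numeric(tag)) return("coding")
  switch(tag, upstream = "5_upstream", downstream = "3_downstream", tag)
}

#' Flag variants in splice-region windows
#'
#' TRUE when the position lies within `donor_window`/`acceptor_window` bases
#' into an intron from its donor/acceptor junction, or within
#' `exonic_window` bases into an exon from a junction.
#'
#' @param record One-row variant data.frame.
#' @param model A [transcript_model()].
#' @param donor_window,acceptor_window,exonic_window Window sizes in bases.
#' @return Logical scalar.
#' @export
flag_splice_region <- function(record, model, donor_window = 8,
                               acceptor_window = 8, exonic_window = 3) {
  pos <- record$pos
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  if (nrow(ex) < 2) return(FALSE)
  plus <- model$strand == "+"
  for (i in seq_len(nrow(ex) - 1)) {
    int_lo <- ex$end[i] + 1L
    int_hi <- ex$start[i + 1] - 1L
    if (int_lo > int_hi) next
    # donor = intron end abutting the transcriptionally upstream exon
    if (plus) {
      donor <- int_lo:min(int_hi, int_lo + donor_window - 1L)
      accept <- max(int_lo, int_hi - acceptor_window + 1L):int_hi
    } else {
      donor <- max(int_lo, int_hi - donor_window + 1L):int_hi
      accept <- int_lo:min(int_hi, int_lo + acceptor_window - 1L)
    }
    if (pos %in% donor || pos %in% accept) return(TRUE)
  }
  if (exonic_window > 0) {
    for (i in seq_len(nrow(ex))) {
      near_start <- i > 1 &&
        pos >= ex$start[i] && pos <= ex$start[i] + exonic_window - 1L
      near_end <- i < nrow(ex) &&
        pos <= ex$end[i] && pos >= ex$end[i] - exonic_window + 1L
      if (near_start || near_end) return(TRUE)
    }
  }
  FALSE
}
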