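# Coding consequence prediction with precursor and mature (signal-peptide
# aware) protein numbering, including frameshift/premature-stop arithmetic.
#
# Frameshift notation follows the milk protein literature's counting: in
# p.Thr92Asnfs*13 the 13 counts the changed residues 92..104 inclusive, so
# the last residue before the novel stop sits at 92 + 13 - 1 = 104.

#' Predict the protein consequence of a coding variant
#'
#' The reference and alternate coding sequences are translated with the
#' standard genetic code; frameshifted products read on through the 3'UTR
#' until the first stop codon in the new frame.
#'
#' @param record One-row variant data.frame (atomic SNP/insertion/deletion;
#'   VCF-anchored, forward-strand alleles).
#' @param model A [transcript_model()].
#' @param offsets Precursor offsets, see [milk_offsets()].
#' @return A `consequence_record` with the kind (`synonymous`, `missense`,
#'   `stop_gained`, `frameshift`, `inframe_indel`), the first changed
#'   residue in precursor and mature numbering, frameshift fields and
#'   formatted protein-change notations.
#' @export
predict_consequence <- function(record, model, offsets = milk_offsets()) {
  if (record$class == "MNP") {
    stop("decompose MNP records with decompose_mnp() first")
  }
  cds_len <- nchar(model$cds_sequence)
  cseq <- paste0(model$cds_sequence, model$utr3_seq)
  cpos <- c(model$cds_genome_pos, model$utr3_pos)
  minus <- model$strand == "-"
  tx_allele <- function(x) if (minus) revcomp(x) else x

  check_base <- function(idx, fwd_base) {
    want <- if (minus) complement_base(fwd_base) else fwd_base
    have <- substr(cseq, idx, idx)
    if (have != want) {
      stop(sprintf(
        "reference allele mismatch for %s at %s:%d (VCF says %s, model has %s)",
        model$gene, record$chrom, record$pos, fwd_base,
        if (minus) complement_base(have) else have))
    }
  }

  if (record$class == "SNP") {
    i <- match(record$pos, cpos)
    if (is.na(i) || i > cds_len) stop("variant is not in the CDS")
    check_base(i, record$ref)
    edited <- cseq
    substr(edited, i, i) <- tx_allele(record$alt)
    net <- 0L
    snp_idx <- i
  } else if (record$class == "insertion") {
    ins <- substr(record$alt, 2, nchar(record$alt))
    i <- match(record$pos, cpos)
    if (is.na(i)) stop("insertion anchor is not in the transcript")
    check_base(i, record$ref)
    # inserted bases land between forward positions pos and pos+1, which in
    # transcript order is after index i (+) or before index i (-)
    at <- if (minus) i - 1L else i
    if (at < 1L || at >= cds_len) stop("variant is not in the CDS")
    edited <- paste0(substr(cseq, 1, at), tx_allele(ins),
                     substr(cseq, at + 1L, nchar(cseq)))
    net <- nchar(ins)
    snp_idx <- NA_integer_
  } else {                               # deletion
    del <- substr(record$ref, 2, nchar(record$ref))
    gpos <- record$pos + seq_len(nchar(del))
    idx <- match(gpos, cpos)
    if (anyNA(idx)) stop("deleted bases are not all in the transcript")
    idx <- sort(idx)
    if (any(diff(idx) != 1L)) stop("deletion spans a splice junction")
    if (idx[1] > cds_len) stop("variant is not in the CDS")
    have <- substr(cseq, idx[1], idx[length(idx)])
    want <- if (minus) revcomp(del) else del
    if (have != want) {
      stop(sprintf(
        "reference allele mismatch for %s at %s:%d (VCF says %s, model has %s)",
        model$gene, record$chrom, record$pos, del,
        if (minus) revcomp(have) else have))
    }
    edited <- paste0(substr(cseq, 1, idx[1] - 1L),
                     substr(cseq, idx[length(idx)] + 1L, nchar(cseq)))
    net <- -nchar(del)
    snp_idx <- NA_integer_
  }

  ref_prot <- translate_dna(model$cds_sequence)
  ref_aa_seq <- sub("\\*.*$", "", ref_prot)

  if (record$class == "SNP") {
    res <- as.integer(ceiling(snp_idx / 3))
    alt_prot <- translate_dna(substr(edited, 1, cds_len))
    ref_aa <- substr(ref_prot, res, res)
    alt_aa <- substr(alt_prot, res, res)
    kind <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gained" else "missense"
    cons <- new_consequence(record, model, kind, res, ref_aa, alt_aa,
                            terminal_offset = NA_integer_,
                            no_stop = FALSE, offsets = offsets)
    return(cons)
  }

  if (net %% 3L == 0L) {
    alt_prot <- translate_dna(substr(edited, 1, cds_len + net))
    alt_aa_seq <- sub("\\*.*$", "", alt_prot)
    fc <- first_difference(ref_aa_seq, alt_aa_seq)
    ref_aa <- if (fc <= nchar(ref_aa_seq)) substr(ref_aa_seq, fc, fc) else "*"
    alt_aa <- if (fc <= nchar(alt_aa_seq)) substr(alt_aa_seq, fc, fc) else "*"
    return(new_consequence(record, model, "inframe_indel", fc, ref_aa,
                           alt_aa, terminal_offset = NA_integer_,
                           no_stop = FALSE, offsets = offsets))
  }

  # frameshift: translate the edited sequence through the first stop in the
  # shifted frame (may extend into the 3'UTR)
  alt_prot <- translate_dna(edited)
  stop_at <- regexpr("*", alt_prot, fixed = TRUE)
  no_stop <- stop_at < 0
  alt_aa_seq <- if (no_stop) alt_prot else substr(alt_prot, 1, stop_at - 1L)
  fc <- first_difference(ref_aa_seq, alt_aa_seq)
  ref_aa <- if (fc <= nchar(ref_aa_seq)) substr(ref_aa_seq, fc, fc) else "*"
  alt_aa <- if (fc <= nchar(alt_aa_seq)) substr(alt_aa_seq, fc, fc) else "*"
  # terminal offset counts the changed residues through the last one
  # before the novel stop; when the shift immediately yields a stop codon
  # there are none and the record is formatted as a plain stop ("p.Xn*")
  term <- if (no_stop || fc > nchar(alt_aa_seq)) NA_integer_ else
    nchar(alt_aa_seq) - fc + 1L
  new_consequence(record, model, "frameshift", fc, ref_aa, alt_aa,
                  terminal_offset = term, no_stop = no_stop,
                  offsets = offsets, alt_product = alt_aa_seq)
}

first_difference <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    av <- strsplit(a, "")[[1]][1:n]
    bv <- strsplit(b, "")[[1]][1:n]
    d <- which(av != bv)
    if (length(d) > 0) return(d[1])
  }
  if (nchar(a) == nchar(b)) stop("products are identical")
  n + 1L
}

new_consequence <- function(record, model, kind, fc, ref_aa, alt_aa,
                            terminal_offset, no_stop, offsets,
                            alt_product = NULL) {
  mat <- if (model$gene %in% names(offsets)) {
    precursor_to_mature(model$gene, fc, offsets)
  } else {
    # fall back to the offset stored on the model itself
    m <- as.integer(fc) - model$precursor_offset
    if (m <= 0L) "pre-mature region" else m
  }
  x <- structure(list(
    variant = record, gene = model$gene,
    transcript_id = model$transcript_id, kind = kind,
    precursor_pos = as.integer(fc),
    mature_pos = mat,                      # integer or "pre-mature region"
    ref_aa = ref_aa, alt_aa = alt_aa,
    terminal_offset = terminal_offset, no_stop = no_stop,
    alt_product = alt_product,
    precursor_offset = model$precursor_offset
  ), class = "consequence_record")
  x$precursor_change <- format_protein_change(x, "precursor")
  x$mature_change <- if (is.numeric(mat)) {
    format_protein_change(x, "mature")
  } else NA_character_
  x
}

#' @export
print.consequence_record <- function(x, ...) {
  cat(sprintf("<consequence> %s %s:%d %s>%s  %s  %s (mature %s)\n",
              x$gene, x$variant$chrom, x$variant$pos, x$variant$ref,
              x$variant$alt, x$kind, x$precursor_change,
              ifelse(is.na(x$mature_change), x$mature_pos, x$mature_change)))
  invisible(x)
}

#' Format a protein change in precursor or mature numbering
#'
#' Three-letter amino-acid codes: missense `p.Ala66Val`, synonymous
#' `p.Asn88`, stop gained `p.Gln12*`, frameshift `p.Thr92Asnfs*13`.
#'
#' @param cons A `consequence_record` (or the result of
#'   [parse_protein_change()]).
#' @param numbering `"precursor"` or `"mature"`.
#' @return The notation string.
#' @export
format_protein_change <- function(cons, numbering = c("mature",
                                                      "precursor")) {
  numbering <- match.arg(numbering)
  if (cons$kind == "non_coding") stop("record is non-coding")
  pos <- if (numbering == "precursor") cons$precursor_pos else {
    if (!is.numeric(cons$mature_pos)) {
      stop("residue lies in the signal peptide; use precursor numbering")
    }
    cons$mature_pos
  }
  r3 <- aa_three(cons$ref_aa)
  a3 <- aa_three(cons$alt_aa)
  switch(cons$kind,
    synonymous = sprintf("p.%s%d", r3, pos),
    missense = sprintf("p.%s%d%s", r3, pos, a3),
    stop_gained = sprintf("p.%s%d*", r3, pos),
    frameshift = {
      if (identical(cons$alt_aa, "*")) sprintf("p.%s%d*", r3, pos)
      else if (cons$no_stop) sprintf("p.%s%d%sfs(no-stop)", r3, pos, a3)
      else sprintf("p.%s%d%sfs*%d", r3, pos, a3, cons$terminal_offset)
    },
    inframe_indel = sprintf("p.%s%d%s", r3, pos,
      if (cons$variant$class == "deletion") "del" else "ins"),
    stop("unknown kind '", cons$kind, "'"))
}

#' Parse frameshift (and simple substitution) protein notation
#'
#' Accepts strings like `"p.Thr92Asnfs*13"`, `"p.Ala66Val"`, `"p.Asn88"`.
#' The position is taken in whatever numbering the string uses.
#'
#' @param x Notation string.
#' @return A list compatible with [truncated_length()] and
#'   [format_protein_change()].
#' @export
parse_protein_change <- function(x) {
  m <- regexec("^p\\.([A-Za-z]{3})([0-9]+)(?:([A-Za-z]{3})fs\\*([0-9]+)|([A-Za-z]{3}|\\*))?$",
               x)[[1]]
  if (m[1] < 0) stop("cannot parse protein change '", x, "'")
  g <- regmatches(x, list(regexec(
    "^p\\.([A-Za-z]{3})([0-9]+)(?:([A-Za-z]{3})fs\\*([0-9]+)|([A-Za-z]{3}|\\*))?$",
    x)[[1]]))[[1]]
  ref3 <- g[2]; pos <- as.integer(g[3])
  inv <- names(AA3)
  to1 <- function(a3) {
    if (!nzchar(a3)) return("")
    if (a3 == "*") return("*")
    i <- match(a3, AA3)
    if (is.na(i)) stop("unknown amino acid code '", a3, "'")
    inv[i]
  }
  if (nzchar(g[4])) {
    list(kind = "frameshift", precursor_pos = pos, mature_pos = pos,
         first_changed = pos, ref_aa = to1(g[2]), alt_aa = to1(g[4]),
         terminal_offset = as.integer(g[5]), no_stop = FALSE)
  } else if (nzchar(g[6])) {
    kind <- if (g[6] == "*") "stop_gained" else "missense"
    list(kind = kind, precursor_pos = pos, mature_pos = pos,
         first_changed = pos, ref_aa = to1(g[2]),
         alt_aa = if (g[6] == "*") "*" else to1(g[6]),
         terminal_offset = NA_integer_, no_stop = FALSE)
  } else {
    list(kind = "synonymous", precursor_pos = pos, mature_pos = pos,
         first_changed = pos, ref_aa = to1(g[2]), alt_aa = to1(g[2]),
         terminal_offset = NA_integer_, no_stop = FALSE)
  }
}

#' Position of the last residue before a frameshift's novel stop
#'
#' `first_changed_residue + terminal_offset - 1`, in the numbering the
#' record's positions use. For `p.Thr92Asnfs*13` this is 104.
#'
#' @param cons A frameshift `consequence_record` or
#'   [parse_protein_change()] result.
#' @param numbering `"mature"` or `"precursor"` (for parsed notation the
#'   position is used as given).
#' @return Integer position, or the character tag `"no-stop"` when the new
#'   reading frame reaches the transcript end without a stop codon.
#' @export
truncated_length <- function(cons, numbering = c("mature", "precursor")) {
  numbering <- match.arg(numbering)
  if (cons$kind != "frameshift") stop("not a frameshift record")
  if (isTRUE(cons$no_stop)) return("no-stop")
  pos <- if (numbering == "precursor") cons$precursor_pos else {
    if (is.numeric(cons$mature_pos)) cons$mature_pos else cons$precursor_pos
  }
  if (identical(cons$alt_aa, "*")) return(as.integer(pos - 1L))
  as.integer(pos + cons$terminal_offset - 1L)
}
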