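# Named milk protein alleles: catalog loading, per-animal assignment with
# intermediate/novel logic, and per-group allele-name frequencies.

#' Load a milk protein allele catalog
#'
#' The catalog is data, not code: a TSV with columns `gene`, `allele_name`,
#' `chrom`, `pos`, `ref`, `alt`, `required_allele`, `status` and one row per
#' (allele, defining site). `required_allele` must equal the site's `ref` or
#' `alt`; alleles omitting one of their gene's sites are completed with the
#' reference allele at that site. Lines starting with `#` are comments.
#'
#' @param path Path to the catalog TSV.
#' @return An `allele_catalog`: per gene, the defining sites
#'   (position-ordered) and each named allele's required-allele vector.
#' @export
load_catalog <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot read allele catalog: ",
                             conditionMessage(e)))
  need <- c("gene", "allele_name", "chrom", "pos", "ref", "alt",
            "required_allele", "status")
  if (nrow(tab) == 0 || !all(need %in% names(tab))) {
    stop("allele catalog is empty or lacks required columns")
  }
  genes <- list()
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, , drop = FALSE]
    sites <- unique(sub[, c("chrom", "pos", "ref", "alt")])
    sites <- sites[order(sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
    key <- paste0(sites$chrom, ":", sites$pos, ":", sites$alt)
    defs <- list()
    status <- character(0)
    for (a in unique(sub$allele_name)) {
      rows <- sub[sub$allele_name == a, , drop = FALSE]
      req <- sites$ref                       # default reference at each site
      names(req) <- key
      rk <- paste0(rows$chrom, ":", rows$pos, ":", rows$alt)
      if (anyDuplicated(rk)) {
        stop("duplicate defining site for allele '", a, "' of gene '", g, "'")
      }
      req[match(rk, key)] <- rows$required_allele
      wrong <- req != sites$ref & req != sites$alt
      if (any(wrong)) {
        stop("required allele of '", g, "^", a,
             "' matches neither ref nor alt at ",
             paste(key[wrong], collapse = ", "))
      }
      defs[[a]] <- as.integer(req == sites$alt)   # 0 = ref, 1 = alt
      status[a] <- rows$status[1]
    }
    sig <- vapply(defs, paste0, character(1), collapse = "")
    if (anyDuplicated(sig)) {
      dup <- names(defs)[duplicated(sig) | duplicated(sig, fromLast = TRUE)]
      stop("alleles of gene '", g, "' share an identical site-allele set: ",
           paste(dup, collapse = ", "))
    }
    ref_allele <- names(defs)[vapply(defs, function(d) all(d == 0L),
                                     logical(1))]
    genes[[g]] <- list(gene = g, sites = sites, definitions = defs,
                       status = status,
                       reference_allele =
                         if (length(ref_allele)) ref_allele[1] else NA)
  }
  structure(list(genes = genes), class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat(sprintf("<allele_catalog> %d genes, %d named alleles\n",
              length(x$genes),
              sum(vapply(x$genes, function(g) length(g$definitions),
                         integer(1)))))
  for (g in x$genes) {
    cat(sprintf("  %s: %s (%d sites)\n", g$gene,
                paste(names(g$definitions), collapse = ", "),
                nrow(g$sites)))
  }
  invisible(x)
}

#' Count of named alleles in a catalog
#' @param catalog An `allele_catalog`.
#' @return Integer.
#' @export
n_alleles <- function(catalog) {
  sum(vapply(catalog$genes, function(g) length(g$definitions), integer(1)))
}

# Match the catalog's defining sites to variant rows of a genotype matrix.
# Sites absent from the matrix are taken as monomorphic reference (the
# usual VCF convention: invariant sites are not emitted).
site_rows <- function(catalog_gene, gm) {
  s <- catalog_gene$sites
  vapply(seq_len(nrow(s)), function(i) {
    hit <- which(gm$variants$chrom == s$chrom[i] &
                 gm$variants$pos == s$pos[i] &
                 gm$variants$ref == s$ref[i] &
                 gm$variants$alt == s$alt[i])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

#' Assign named milk protein alleles to animals
#'
#' Each chromosome copy is matched to the catalog definition consistent with
#' its site alleles. Animals heterozygous at more than one defining site of
#' a gene are phased with the EM estimator over the gene's sites when the
#' posterior discriminates; otherwise flagged `ambiguous`. Site-allele
#' combinations matching no definition are reported `unresolved-novel` (the
#' observed combination is attached in `note`), never force-matched.
#'
#' @param catalog An `allele_catalog`.
#' @param gm A `genotype_matrix`.
#' @param gene Gene symbol present in the catalog.
#' @param use_em Phase multi-site heterozygotes with [em_haplotypes()]
#'   (default TRUE).
#' @return data.frame with columns `animal`, `group`, `gene`, `allele1`,
#'   `allele2`, `phase_confidence` (`exact`, `em_phased`, `ambiguous`,
#'   `unresolved`), `note`. EM pair posteriors for non-exact animals are
#'   attached as attribute `posteriors`.
#' @export
assign_alleles <- function(catalog, gm, gene, use_em = TRUE) {
  cg <- catalog$genes[[gene]]
  if (is.null(cg)) stop("gene '", gene, "' not in catalog")
  rows <- site_rows(cg, gm)
  n_sites <- length(rows)
  n_animal <- nrow(gm$animals)

  # dosage per animal; absent rows = homozygous reference
  dos <- matrix(0L, n_animal, n_sites)
  for (j in seq_len(n_sites)) {
    if (!is.na(rows[j])) {
      dos[, j] <- gm$a1[rows[j], ] + gm$a2[rows[j], ]
    }
  }

  defs <- cg$definitions
  def_str <- vapply(defs, paste0, character(1), collapse = "")
  pair_grid <- expand.grid(i = seq_along(defs), j = seq_along(defs))
  pair_grid <- pair_grid[pair_grid$i <= pair_grid$j, , drop = FALSE]

  em_fit <- NULL
  get_em <- function() {
    if (is.null(em_fit) && use_em) {
      ok <- !apply(is.na(dos), 1, any)
      if (sum(ok) > 0) {
        em_fit <<- tryCatch(em_haplotypes(dos[ok, , drop = FALSE]),
                            error = function(e) NULL)
        if (!is.null(em_fit)) {
          names(em_fit$posterior) <- gm$animals$id[ok]
        }
      }
    }
    em_fit
  }

  out <- data.frame(animal = gm$animals$id, group = gm$animals$group,
                    gene = rep(gene, n_animal),
                    allele1 = rep(NA_character_, n_animal),
                    allele2 = rep(NA_character_, n_animal),
                    phase_confidence = rep(NA_character_, n_animal),
                    note = rep("", n_animal), stringsAsFactors = FALSE)
  if (n_animal == 0) {
    attr(out, "posteriors") <- list()
    return(out)
  }
  posteriors <- list()

  for (i in seq_len(n_animal)) {
    g <- dos[i, ]
    if (anyNA(g)) {
      out$phase_confidence[i] <- "unresolved"
      out$note[i] <- "missing genotype at defining site"
      next
    }
    ok_pairs <- which(vapply(seq_len(nrow(pair_grid)), function(k) {
      all(defs[[pair_grid$i[k]]] + defs[[pair_grid$j[k]]] == g)
    }, logical(1)))
    if (length(ok_pairs) == 0) {
      out$allele1[i] <- "unresolved-novel"
      out$allele2[i] <- "unresolved-novel"
      out$phase_confidence[i] <- "unresolved"
      out$note[i] <- paste0("observed site alleles: ",
                            paste0(ifelse(g == 0, cg$sites$ref,
                                   ifelse(g == 2, cg$sites$alt,
                                   paste0(cg$sites$ref, "/", cg$sites$alt))),
                                   collapse = ","))
      next
    }
    pick <- function(k, conf) {
      pair <- sort(c(names(defs)[pair_grid$i[k]],
                     names(defs)[pair_grid$j[k]]))
      out$allele1[i] <<- pair[1]
      out$allele2[i] <<- pair[2]
      out$phase_confidence[i] <<- conf
    }
    if (length(ok_pairs) == 1) {
      pick(ok_pairs, "exact")
      next
    }
    # >1 consistent unordered pair: needs phasing
    fit <- get_em()
    post <- if (!is.null(fit)) fit$posterior[[out$animal[i]]] else NULL
    if (!is.null(post)) {
      w <- vapply(ok_pairs, function(k) {
        h1 <- def_str[pair_grid$i[k]]; h2 <- def_str[pair_grid$j[k]]
        sum(post$weight[(post$h1 == h1 & post$h2 == h2) |
                        (post$h1 == h2 & post$h2 == h1)])
      }, numeric(1))
      posteriors[[out$animal[i]]] <- data.frame(
        allele1 = pmin(names(defs)[pair_grid$i[ok_pairs]],
                       names(defs)[pair_grid$j[ok_pairs]]),
        allele2 = pmax(names(defs)[pair_grid$i[ok_pairs]],
                       names(defs)[pair_grid$j[ok_pairs]]),
        weight = if (sum(w) > 0) w / sum(w) else
          rep(1 / length(w), length(w)),
        stringsAsFactors = FALSE)
      best <- which.max(w)
      near_tie <- sum(abs(w - max(w)) < 1e-9) > 1
      pick(ok_pairs[best], if (near_tie || max(w) == 0) "ambiguous"
                           else "em_phased")
    } else {
      pick(ok_pairs[1], "ambiguous")
      posteriors[[out$animal[i]]] <- data.frame(
        allele1 = pmin(names(defs)[pair_grid$i[ok_pairs]],
                       names(defs)[pair_grid$j[ok_pairs]]),
        allele2 = pmax(names(defs)[pair_grid$i[ok_pairs]],
                       names(defs)[pair_grid$j[ok_pairs]]),
        weight = rep(1 / length(ok_pairs), length(ok_pairs)),
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "posteriors") <- posteriors
  out
}

#' Per-group frequencies of named alleles
#'
#' Frequency = allele count / (2 x resolved animals in the group). Animals
#' phased by EM or left ambiguous contribute their EM-weighted fractional
#' pair counts; unresolved animals are excluded from the denominator.
#'
#' @param typed Output of [assign_alleles()] (one gene), or a list of such
#'   data.frames (several genes, rbind-ed).
#' @param groups Optional character vector of group labels to report
#'   (default: those present), in addition to `Total`.
#' @return data.frame `gene`, `allele`, one column per group, `Total`.
#' @export
allele_frequencies_by_group <- function(typed, groups = NULL) {
  if (is.list(typed) && !is.data.frame(typed)) {
    posts <- do.call(c, lapply(typed, attr, "posteriors"))
    tabs <- typed
  } else {
    posts <- attr(typed, "posteriors")
    tabs <- list(typed)
  }
  out <- list()
  for (tab in tabs) {
    gene <- tab$gene[1]
    post <- attr(tab, "posteriors") %||% posts
    grp <- unique(stats::na.omit(tab$group))
    if (!is.null(groups)) grp <- intersect(groups, grp)
    resolved <- tab$phase_confidence %in% c("exact", "em_phased", "ambiguous")
    alleles <- sort(unique(stats::na.omit(c(tab$allele1, tab$allele2,
      unlist(lapply(post, function(p) c(p$allele1, p$allele2)))))))
    alleles <- setdiff(alleles, "unresolved-novel")
    freq <- matrix(0, length(alleles), length(grp) + 1,
                   dimnames = list(alleles, c(grp, "Total")))
    denom <- stats::setNames(numeric(length(grp) + 1), c(grp, "Total"))
    for (i in which(resolved)) {
      targets <- c(if (!is.na(tab$group[i])) tab$group[i], "Total")
      p <- post[[tab$animal[i]]]
      denom[targets] <- denom[targets] + 1
      if (tab$phase_confidence[i] == "exact" || is.null(p)) {
        for (a in c(tab$allele1[i], tab$allele2[i])) {
          freq[a, targets] <- freq[a, targets] + 1
        }
      } else {
        for (k in seq_len(nrow(p))) {
          freq[p$allele1[k], targets] <-
            freq[p$allele1[k], targets] + p$weight[k]
          freq[p$allele2[k], targets] <-
            freq[p$allele2[k], targets] + p$weight[k]
        }
      }
    }
    f <- sweep(freq, 2, pmax(2 * denom, 1e-300), "/")
    f[, denom == 0] <- NA
    out[[gene]] <- data.frame(gene = rep(gene, length(alleles)),
                              allele = alleles,
                              as.data.frame(f), check.names = FALSE,
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Variant rows of the casein-cluster defining sites
#'
#' Convenience lookup of the catalog's defining sites for the casein genes
#' within a genotype matrix, for use with [select_sites()] and
#' [em_haplotypes()].
#'
#' @param catalog An `allele_catalog`.
#' @param gm A `genotype_matrix`.
#' @param genes Genes to include (default: the casein cluster).
#' @return Integer vector of variant row indices (sites absent from the
#'   matrix are dropped).
#' @export
casein_sites <- function(catalog, gm,
                         genes = c("CSN1S1", "CSN2", "CSN1S2", "CSN3")) {
  unlist(lapply(intersect(genes, names(catalog$genes)), function(g) {
    r <- site_rows(catalog$genes[[g]], gm)
    r[!is.na(r)]
  }))
}

#' Build a haplotype labeller from an allele catalog
#'
#' Translates "0"/"1" site-haplotype strings over the selected sites into
#' hyphenated allele-name labels (e.g. `"B-A1-A-B"`), gene by gene in
#' genomic order. A gene with no selected site contributes its reference
#' allele name; a within-gene site combination matching no definition is
#' labelled `"gene?"`.
#'
#' @param catalog An `allele_catalog`.
#' @param gm The `genotype_matrix` the sites index into.
#' @param sites Variant row indices (as passed to [em_haplotypes()]).
#' @param gene_order Genes to include, in label order (default: catalog
#'   genes with at least one matched site, genomic order).
#' @return A function mapping a haplotype string to a label.
#' @export
haplotype_labeller <- function(catalog, gm, sites,
                               gene_order = NULL) {
  # map each selected site to (gene, index within that gene's sites)
  site_gene <- rep(NA_character_, length(sites))
  site_slot <- rep(NA_integer_, length(sites))
  for (g in names(catalog$genes)) {
    rows <- site_rows(catalog$genes[[g]], gm)
    hit <- match(sites, rows)
    site_gene[!is.na(hit)] <- g
    site_slot[!is.na(hit)] <- hit[!is.na(hit)]
  }
  if (anyNA(site_gene)) {
    stop("some haplotype sites are not defining sites of any catalog gene")
  }
  if (is.null(gene_order)) {
    first_pos <- tapply(gm$variants$pos[sites], site_gene, min)
    gene_order <- names(sort(first_pos))
  }
  function(hap) {
    bits <- as.integer(strsplit(hap, "")[[1]])
    parts <- vapply(gene_order, function(g) {
      sel <- which(site_gene == g)
      defs <- catalog$genes[[g]]$definitions
      if (length(sel) == 0) {
        return(catalog$genes[[g]]$reference_allele)
      }
      slots <- site_slot[sel]
      match_def <- vapply(defs, function(d) {
        all(d[slots] == bits[sel])
      }, logical(1))
      # among matching definitions prefer the one whose remaining (unseen)
      # sites are reference, i.e. the least-derived consistent allele
      cand <- names(defs)[match_def]
      if (length(cand) == 0) return(paste0(g, "?"))
      if (length(cand) > 1) {
        extra <- vapply(cand, function(a) {
          sum(defs[[a]][-slots])
        }, numeric(1))
        cand <- cand[order(extra)]
      }
      cand[1]
    }, character(1))
    paste(parts, collapse = "-")
  }
}
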