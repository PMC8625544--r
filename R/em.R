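# Maximum-likelihood haplotype frequency estimation from unphased diploid
# genotypes by expectation-maximization, over the defining sites of the
# casein cluster (or any set of bi-allelic sites).

#' Select sites for haplotype construction by minor allele frequency
#'
#' Sites whose overall minor-allele frequency reaches the threshold are
#' kept (the boundary value is included), ordered by genomic position.
#'
#' @param gm A `genotype_matrix`.
#' @param sites Candidate variant row indices (default: all SNP rows).
#' @param maf_threshold Minimum overall minor-allele frequency (default
#'   0.05).
#' @return Integer vector of variant row indices, position-ordered.
#' @export
select_sites <- function(gm, sites = which(gm$variants$class == "SNP"),
                         maf_threshold = 0.05) {
  keep <- vapply(sites, function(i) {
    f <- allele_frequency(gm, i, "ALL")$frequency
    !is.na(f) && min(f, 1 - f) >= maf_threshold - 1e-12
  }, logical(1))
  sel <- sites[keep]
  if (length(sel) == 0) {
    warning("no sites pass the minor-allele-frequency threshold")
    return(integer(0))
  }
  sel[order(gm$variants$chrom[sel], gm$variants$pos[sel])]
}

# 0/1/2 alt-allele dosage matrix (individuals x sites) for selected rows
dosage_matrix <- function(gm, sites) {
  d <- t(gm$a1[sites, , drop = FALSE] + gm$a2[sites, , drop = FALSE])
  rownames(d) <- gm$animals$id
  colnames(d) <- paste0(gm$variants$chrom[sites], ":",
                        gm$variants$pos[sites])
  d
}

# All haplotype pairs compatible with one genotype vector (0/1/2 dosages).
# Haplotypes are "0"/"1" strings over the sites.
compatible_pairs <- function(geno) {
  het <- which(geno == 1L)
  base <- ifelse(geno == 2L, 1L, 0L)
  if (length(het) == 0) {
    h <- paste0(base, collapse = "")
    return(list(list(h1 = h, h2 = h)))
  }
  n_free <- length(het) - 1L
  out <- vector("list", 2^n_free)
  for (k in seq_len(2^n_free)) {
    bits <- as.integer(intToBits(k - 1L))[seq_len(max(n_free, 1L))]
    h1 <- base; h2 <- base
    h1[het[1]] <- 1L; h2[het[1]] <- 0L   # fix first het to break symmetry
    if (n_free > 0) {
      for (j in seq_len(n_free)) {
        h1[het[j + 1L]] <- bits[j]
        h2[het[j + 1L]] <- 1L - bits[j]
      }
    }
    out[[k]] <- list(h1 = paste0(h1, collapse = ""),
                     h2 = paste0(h2, collapse = ""))
  }
  out
}

#' Estimate haplotype frequencies by expectation-maximization
#'
#' The E-step weights each individual's compatible haplotype pairs
#' proportional to `p_h1 * p_h2` (doubled for heterozygous pairs); the
#' M-step sets each haplotype's frequency to its expected allele count over
#' `2n`. Initialization is uniform over the haplotypes occurring in any
#' compatible expansion. Individuals with a missing genotype at any site are
#' excluded.
#'
#' @param geno Either a `genotype_matrix` (with `sites` giving variant rows)
#'   or an individuals-x-sites 0/1/2 dosage matrix.
#' @param sites Variant row indices when `geno` is a `genotype_matrix`.
#' @param tol Convergence tolerance on `max |delta p|` (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param labels Optional function mapping a "0"/"1" haplotype string to a
#'   display label (e.g. allele names via [haplotype_labeller()]).
#' @param n_start Number of EM starts: the first from the uniform
#'   initialization, the rest from random points on the simplex (the
#'   likelihood can be multimodal). Default 1 (no restarts); set a seed
#'   before calling for reproducible restarts.
#' @return An object of class `haplo_em` with components `frequencies`
#'   (named, sorted decreasing), `loglik` (trace), `iterations`,
#'   `converged`, `posterior` (per-individual data.frames of compatible
#'   pairs and weights), `n` (individuals used) and `sites`.
#' @examples
#' g <- rbind(c(0, 0), c(1, 1), c(2, 2))  # 3 individuals, 2 sites
#' fit <- em_haplotypes(g)
#' coef(fit)
#' @export
em_haplotypes <- function(geno, sites = NULL, tol = 1e-8, max_iter = 1000,
                          labels = NULL, n_start = 1) {
  site_names <- NULL
  if (inherits(geno, "genotype_matrix")) {
    stopifnot(!is.null(sites))
    d <- dosage_matrix(geno, sites)
    site_names <- colnames(d)
  } else {
    d <- as.matrix(geno)
    site_names <- colnames(d)
  }
  complete <- stats::complete.cases(d)
  d <- d[complete, , drop = FALSE]
  n <- nrow(d)
  if (n == 0) stop("no individuals with complete genotypes at the sites")

  # collapse identical genotype patterns: EM cost depends on the number of
  # distinct multilocus genotypes, not on n
  pat_key <- apply(d, 1, paste0, collapse = ",")
  upat <- !duplicated(pat_key)
  patterns <- d[upat, , drop = FALSE]
  pat_of <- match(pat_key, pat_key[upat])
  pat_n <- as.numeric(tabulate(pat_of, nbins = nrow(patterns)))

  expansions <- apply(patterns, 1, compatible_pairs, simplify = FALSE)
  haps <- sort(unique(unlist(lapply(expansions, function(e) {
    unlist(lapply(e, function(p) c(p$h1, p$h2)))
  }))))

  # per-pattern integer-indexed pair tables
  pair_idx <- lapply(expansions, function(e) {
    cbind(i1 = match(vapply(e, `[[`, character(1), "h1"), haps),
          i2 = match(vapply(e, `[[`, character(1), "h2"), haps))
  })

  run_em <- function(p0) {
    p <- p0
    loglik <- numeric(0)
    converged <- FALSE
    weights <- NULL
    for (iter in seq_len(max_iter)) {
      counts <- stats::setNames(numeric(length(haps)), haps)
      ll <- 0
      weights <- vector("list", length(pair_idx))
      for (i in seq_along(pair_idx)) {
        ij <- pair_idx[[i]]
        w <- p[ij[, 1]] * p[ij[, 2]] * ifelse(ij[, 1] == ij[, 2], 1, 2)
        tot <- sum(w)
        if (tot <= 0) {                   # degenerate start; re-seed flat
          w <- rep(1 / length(w), length(w))
          tot <- 1
        } else {
          ll <- ll + pat_n[i] * log(tot)
          w <- w / tot
        }
        weights[[i]] <- w
        wk <- pat_n[i] * w
        for (k in seq_len(nrow(ij))) {
          counts[ij[k, 1]] <- counts[ij[k, 1]] + wk[k]
          counts[ij[k, 2]] <- counts[ij[k, 2]] + wk[k]
        }
      }
      p_new <- counts / (2 * n)
      loglik <- c(loglik, ll)
      if (max(abs(p_new - p)) < tol) {
        p <- p_new
        converged <- TRUE
        break
      }
      p <- p_new
    }
    list(p = p, loglik = loglik, converged = converged, weights = weights)
  }

  uniform <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
  best <- run_em(uniform)
  if (n_start > 1) {
    # random restarts: the likelihood can be multimodal; draws come from
    # the caller's RNG stream (seed before calling for reproducibility)
    for (s in seq_len(n_start - 1)) {
      g <- -log(stats::runif(length(haps)))     # flat Dirichlet draw
      cand <- run_em(stats::setNames(g / sum(g), haps))
      if (cand$loglik[length(cand$loglik)] >
          best$loglik[length(best$loglik)] + 1e-12) {
        best <- cand
      }
    }
  }
  p <- best$p
  loglik <- best$loglik
  converged <- best$converged
  weights <- best$weights

  posterior <- lapply(pat_of, function(i) {
    ij <- pair_idx[[i]]
    data.frame(h1 = haps[ij[, 1]], h2 = haps[ij[, 2]],
               weight = weights[[i]], stringsAsFactors = FALSE)
  })
  names(posterior) <- rownames(d)

  nm <- haps
  if (!is.null(labels)) nm <- vapply(haps, labels, character(1))
  freq <- stats::setNames(as.numeric(p), nm)
  structure(list(
    frequencies = sort(freq, decreasing = TRUE),
    haplotypes = stats::setNames(haps, nm),
    loglik = loglik, iterations = length(loglik), converged = converged,
    posterior = posterior, n = n, sites = site_names
  ), class = "haplo_em")
}

#' @export
print.haplo_em <- function(x, ...) {
  cat(sprintf(
    "<haplo_em> %d haplotypes over %d sites, n = %d, logLik = %.4f (%s in %d iterations)\n",
    length(x$frequencies), length(x$sites %||% NA), x$n,
    x$loglik[length(x$loglik)],
    if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' @export
coef.haplo_em <- function(object, ...) object$frequencies

#' @export
logLik.haplo_em <- function(object, ...) {
  structure(object$loglik[length(object$loglik)],
            df = length(object$frequencies) - 1L, class = "logLik")
}

#' @export
summary.haplo_em <- function(object, ...) {
  cat(sprintf("EM haplotype frequency fit: n = %d individuals, %d sites\n",
              object$n, length(object$sites)))
  cat(sprintf("logLik %.4f after %d iterations (%s)\n",
              object$loglik[length(object$loglik)], object$iterations,
              if (object$converged) "converged" else "not converged"))
  print(data.frame(haplotype = names(object$frequencies),
                   frequency = round(object$frequencies, 4),
                   row.names = NULL))
  invisible(object)
}

#' Per-group and overall haplotype frequency tables
#'
#' One EM run per group plus one for the whole cohort (`Total` column).
#'
#' @param gm A `genotype_matrix` with group labels.
#' @param sites Variant row indices of the haplotype sites.
#' @param labels Optional haplotype labeller (see [haplotype_labeller()]).
#' @param min_group Groups smaller than this (complete individuals) are
#'   skipped with a warning (default 2).
#' @param ... Passed to [em_haplotypes()].
#' @return A `haplotype_table`: data.frame with one row per haplotype and
#'   one frequency column per group plus `Total`, sorted by `Total`. The
#'   per-group `haplo_em` fits are attached as attribute `fits`.
#' @export
group_haplotype_frequencies <- function(gm, sites, labels = NULL,
                                        min_group = 2, ...) {
  if (length(sites) == 0) {
    warning("no haplotype sites; skipping EM")
    return(structure(data.frame(haplotype = character(0)),
                     class = c("haplotype_table", "data.frame")))
  }
  groups <- unique(stats::na.omit(gm$animals$group))
  fits <- list()
  for (g in groups) {
    sub <- subset_animals(gm, gm$animals$group == g)
    n_complete <- sum(stats::complete.cases(dosage_matrix(sub, sites)))
    if (n_complete < min_group) {
      warning("group '", g, "' has fewer than ", min_group,
              " complete individuals; skipped")
      next
    }
    fits[[g]] <- em_haplotypes(sub, sites, labels = labels, ...)
  }
  fits[["Total"]] <- em_haplotypes(gm, sites, labels = labels, ...)

  hap_names <- unique(unlist(lapply(fits, function(f) names(f$frequencies))))
  tab <- data.frame(haplotype = hap_names, stringsAsFactors = FALSE)
  for (g in names(fits)) {
    tab[[g]] <- as.numeric(fits[[g]]$frequencies[hap_names])
    tab[[g]][is.na(tab[[g]])] <- 0
  }
  tab <- tab[order(-tab$Total), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("haplotype_table", "data.frame"), fits = fits)
}

subset_animals <- function(gm, keep) {
  gm$animals <- gm$animals[keep, , drop = FALSE]
  gm$a1 <- gm$a1[, keep, drop = FALSE]
  gm$a2 <- gm$a2[, keep, drop = FALSE]
  gm$depth <- gm$depth[, keep, drop = FALSE]
  gm
}

#' Format a haplotype table for display
#'
#' Frequencies are printed to two decimals, with values below `min_display`
#' shown as `"<0.01"`. Optionally keeps only haplotypes reaching
#' `row_threshold` in at least one group (the published table's row rule).
#'
#' @param tab A `haplotype_table`.
#' @param min_display Display floor (default 0.01).
#' @param row_threshold If non-`NULL`, keep rows with a frequency of at
#'   least this in at least one column (e.g. 0.05).
#' @return A character data.frame ready for writing.
#' @export
format_haplotype_table <- function(tab, min_display = 0.01,
                                   row_threshold = NULL) {
  num_cols <- setdiff(names(tab), "haplotype")
  if (!is.null(row_threshold)) {
    keep <- apply(as.matrix(tab[num_cols]), 1,
                  function(r) any(r >= row_threshold - 1e-12))
    tab <- tab[keep, , drop = FALSE]
  }
  out <- data.frame(haplotype = tab$haplotype, stringsAsFactors = FALSE)
  for (g in num_cols) {
    v <- round_half_up(tab[[g]], 2)
    out[[g]] <- ifelse(tab[[g]] > 0 & v < min_display, "<0.01",
                       sprintf("%.2f", v))
  }
  out
}
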