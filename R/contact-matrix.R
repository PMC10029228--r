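#' Contact matrix container
#'
#' A symmetric, binned Hi-C contact map stored as sparse upper-triangle
#' triples (`bin1 <= bin2`, 0-based global bin ids) together with its bin
#' table. Bins tile chromosomes contiguously at a fixed resolution.
#'
#' @param bins bin table as from [genome_bins()].
#' @param pixels data.frame with columns `bin1`, `bin2`, `count`.
#' @param resolution bin width in bp.
#' @param normalization one of `"raw"`, `"ice"`, `"hicnorm"`, `"ice+hicnorm"`.
#' @param weights optional per-bin balancing weights (NA for masked bins).
#' @param covariates optional per-bin covariate table (effective length, GC,
#'   mappability) used by [hicnorm_lite()].
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, pixels, resolution, normalization = "raw",
                           weights = NULL, covariates = NULL) {
  stopifnot(all(c("chrom", "start", "end", "bin_id") %in% names(bins)),
            all(c("bin1", "bin2", "count") %in% names(pixels)))
  n <- nrow(bins)
  if (nrow(pixels)) {
    if (any(pixels$bin1 < 0 | pixels$bin1 >= n | pixels$bin2 < 0 | pixels$bin2 >= n))
      stop("pixel references a bin id outside the bin table")
    swap <- pixels$bin1 > pixels$bin2
    if (any(swap)) {
      tmp <- pixels$bin1[swap]
      pixels$bin1[swap] <- pixels$bin2[swap]
      pixels$bin2[swap] <- tmp
    }
    key <- paste(pixels$bin1, pixels$bin2)
    if (anyDuplicated(key)) {
      agg <- tapply(pixels$count, key, function(v) {
        if (length(unique(v)) > 1L)
          stop("duplicate triples with conflicting values")
        v[1]
      })
      first <- !duplicated(key)
      pixels <- pixels[first, , drop = FALSE]
      pixels$count <- as.numeric(agg[paste(pixels$bin1, pixels$bin2)])
    }
    if (normalization == "raw" && any(!is.finite(pixels$count) | pixels$count < 0))
      stop("raw counts must be finite and >= 0")
    pixels <- pixels[order(pixels$bin1, pixels$bin2), , drop = FALSE]
    rownames(pixels) <- NULL
  }
  structure(list(bins = bins, pixels = pixels,
                 resolution = as.integer(resolution),
                 normalization = normalization,
                 weights = weights, covariates = covariates),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%d chrom) @ %d bp, %d pixels, %s\n",
              nrow(x$bins), length(unique(x$bins$chrom)), x$resolution,
              nrow(x$pixels), x$normalization))
  invisible(x)
}

# bin ids (0-based) of one chromosome
chrom_bin_ids <- function(x, chrom) x$bins$bin_id[x$bins$chrom == chrom]

#' Densify a contact matrix
#'
#' @param x a `contact_matrix`.
#' @param chrom optional chromosome name; when given only the cis block of
#'   that chromosome is returned.
#' @return a symmetric dense matrix (bins in table order).
#' @export
cm_dense <- function(x, chrom = NULL) {
  ids <- if (is.null(chrom)) x$bins$bin_id else chrom_bin_ids(x, chrom)
  n <- length(ids)
  off <- min(ids)
  m <- matrix(0, n, n)
  p <- x$pixels
  keep <- p$bin1 %in% ids & p$bin2 %in% ids
  p <- p[keep, , drop = FALSE]
  i <- p$bin1 - off + 1L
  j <- p$bin2 - off + 1L
  m[cbind(i, j)] <- p$count
  m[cbind(j, i)] <- p$count
  m
}

# dense symmetric matrix (one chromosome) -> pixel data.frame with global ids
dense_to_pixels <- function(m, id_offset = 0L, drop_zero = TRUE) {
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  v <- m[idx]
  if (drop_zero) {
    keep <- is.finite(v) & v != 0
    idx <- idx[keep, , drop = FALSE]
    v <- v[keep]
  }
  data.frame(bin1 = idx[, 1] + id_offset - 1L,
             bin2 = idx[, 2] + id_offset - 1L, count = v)
}

#' Read / write contact matrices
#'
#' Sparse triple TSV (`bin_i TAB bin_j TAB value`, 0-based ids) plus a BED4
#' bin table (`chrom start end bin_id`). The round trip is lossless.
#'
#' @param triples_path,bins_path file paths.
#' @param normalization tag recorded on the returned matrix.
#' @return [read_matrix()] returns a `contact_matrix`; [write_matrix()]
#'   returns its input invisibly.
#' @export
read_matrix <- function(triples_path, bins_path, normalization = "raw") {
  bins <- utils::read.table(bins_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "bin_id"),
                            colClasses = c("character", "integer", "integer", "integer"))
  px <- utils::read.table(triples_path, sep = "\t", header = FALSE,
                          col.names = c("bin1", "bin2", "count"))
  res <- max(bins$end - bins$start)
  contact_matrix(bins, px, res, normalization = normalization)
}

#' @rdname read_matrix
#' @param x a `contact_matrix`.
#' @export
write_matrix <- function(x, triples_path, bins_path) {
  utils::write.table(x$pixels, triples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(x$bins[, c("chrom", "start", "end", "bin_id")], bins_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' ICE matrix balancing
#'
#' Iterative correction: per-bin multiplicative biases are estimated so that
#' the corrected matrix `count / (b_i * b_j)` has (near-)equal unmasked row
#' sums. Bins in the lowest `mask_quantile` of nonzero marginals (and
#' zero-marginal bins) are masked and excluded; their corrected values and
#' weights are reported as missing, never as zero.
#'
#' @param x raw `contact_matrix`.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the coefficient of variation of
#'   unmasked row sums.
#' @param mask_quantile marginal-count quantile below which bins are masked.
#' @return a `contact_matrix` with `normalization = "ice"` and per-bin
#'   `weights` (NA for masked bins).
#' @export
ice_balance <- function(x, max_iter = 200, tol = 1e-5, mask_quantile = 0.02) {
  n <- nrow(x$bins)
  p <- x$pixels
  if (!nrow(p) || all(p$count == 0)) stop("cannot balance an all-zero matrix")
  i1 <- p$bin1 + 1L
  i2 <- p$bin2 + 1L
  marg <- tapply_sum(p$count, i1, n)
  off <- i1 != i2
  marg <- marg + tapply_sum(p$count[off], i2[off], n)
  cutoff <- stats::quantile(marg[marg > 0], mask_quantile)
  mask <- marg <= 0 | marg < cutoff
  target <- mean(marg[!mask])
  b <- rep(1, n)
  it_max <- 0L
  # biases are estimated per chromosome on cis counts (a cis-only matrix is
  # block-diagonal, so components are balanced independently), then rescaled
  # so unmasked row sums equalize genome-wide
  chrom_of <- x$bins$chrom
  cis <- chrom_of[i1] == chrom_of[i2]
  for (ch in unique(chrom_of)) {
    ids <- which(chrom_of == ch)
    keep <- cis & i1 %in% ids & i2 %in% ids & !(mask[i1] | mask[i2])
    if (!any(keep)) next
    pi1 <- i1[keep]; pi2 <- i2[keep]; pc <- p$count[keep]
    poff <- pi1 != pi2
    un <- ids[!mask[ids]]
    for (it in seq_len(max_iter)) {
      val <- pc / (b[pi1] * b[pi2])
      s <- tapply_sum(val, pi1, n) + tapply_sum(val[poff], pi2[poff], n)
      su <- s[un]
      m <- mean(su)
      cv <- stats::sd(su) / m
      if (is.finite(cv) && cv < tol) break
      d <- s / m
      d[d == 0 | !is.finite(d)] <- 1
      b[un] <- b[un] * d[un]
    }
    it_max <- max(it_max, it)
    b[un] <- b[un] * sqrt(m / target)
  }
  val <- p$count / (b[i1] * b[i2])
  val[mask[i1] | mask[i2]] <- NA_real_
  out <- x
  out$pixels$count <- val
  out$normalization <- "ice"
  w <- b
  w[mask] <- NA_real_
  out$weights <- w
  # converged coefficient of variation of unmasked cis row sums, genome-wide
  vv <- val
  vv[!cis | is.na(val)] <- 0
  s_all <- tapply_sum(vv, i1, n) + tapply_sum(vv[off & cis], i2[off & cis], n)
  su <- s_all[!mask]
  attr(out, "ice_cv") <- stats::sd(su) / mean(su)
  attr(out, "ice_iter") <- it_max
  out
}

# fast grouped sum into a length-n vector
tapply_sum <- function(v, idx, n) {
  out <- numeric(n)
  if (length(v)) {
    s <- rowsum(v, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Poisson-regression covariate normalization (HiCNorm-style)
#'
#' Per chromosome, cis counts are regressed on the logs of pairwise covariate
#' products (effective length, GC, mappability) with distance-decile fixed
#' effects absorbed, via a Poisson GLM; normalized value = count / fitted
#' mean. Constant covariates are dropped from the design; a fully singular
#' design falls back to identity normalization with a warning.
#'
#' @param x a `contact_matrix` (raw or ICE-balanced; NA values are skipped).
#' @param covariates data.frame with columns `bin_id`, `len`, `gc`, `map`
#'   (strictly positive on unmasked bins); defaults to covariates attached to
#'   the matrix.
#' @return a `contact_matrix` with updated normalization tag.
#' @export
hicnorm_lite <- function(x, covariates = NULL) {
  covariates <- covariates %||% x$covariates
  if (is.null(covariates)) stop("no covariates supplied or attached")
  cv <- covariates[match(x$bins$bin_id, covariates$bin_id), ]
  out <- x
  fit_coefs <- list()
  for (chrom in unique(x$bins$chrom)) {
    ids <- chrom_bin_ids(x, chrom)
    sel <- which(out$pixels$bin1 %in% ids & out$pixels$bin2 %in% ids)
    if (!length(sel)) next
    px <- out$pixels[sel, ]
    ok <- is.finite(px$count)
    i <- match(px$bin1, x$bins$bin_id)
    j <- match(px$bin2, x$bins$bin_id)
    d <- abs(px$bin2 - px$bin1)
    df <- data.frame(
      y = px$count,
      llen = log(cv$len[i] * cv$len[j]),
      lgc  = log(cv$gc[i] * cv$gc[j]),
      lmap = log(cv$map[i] * cv$map[j]),
      dd = factor(dd_decile(d)))
    terms <- c("llen", "lgc", "lmap")
    terms <- terms[vapply(terms, function(t) stats::sd(df[[t]][ok]) > 1e-12, TRUE)]
    if (!length(terms)) { # fully degenerate design: global scaling only
      warning(sprintf("constant covariates on %s; identity normalization", chrom))
      next
    }
    if (nlevels(droplevels(df$dd[ok])) > 1L) terms <- c(terms, "dd")
    form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(form, family = stats::poisson(),
                                       data = df[ok, , drop = FALSE]))
    mu <- stats::predict(fit, newdata = df, type = "response")
    newv <- px$count / mu
    # keep overall scale comparable to input
    newv <- newv * mean(px$count[ok]) / mean(newv[ok])
    out$pixels$count[sel] <- newv
    fit_coefs[[chrom]] <- stats::coef(fit)
  }
  out$normalization <- if (x$normalization == "ice") "ice+hicnorm" else "hicnorm"
  attr(out, "hicnorm_coefs") <- fit_coefs
  out
}

dd_decile <- function(d) {
  q <- unique(stats::quantile(d, probs = seq(0, 1, 0.1)))
  if (length(q) < 3) return(rep(1L, length(d)))
  as.integer(cut(d, breaks = q, include.lowest = TRUE))
}

#' Observed / expected transform
#'
#' Divides every cis value by the mean value of its distance diagonal within
#' its chromosome (missing values excluded from the mean and propagated).
#' Per-diagonal means of the output equal 1 for non-empty diagonals.
#'
#' @param x a balanced `contact_matrix`.
#' @return a `contact_matrix` of O/E values (trans pixels are dropped).
#' @export
observed_expected <- function(x) {
  chrom_of <- x$bins$chrom[match(x$pixels$bin1, x$bins$bin_id)]
  chrom_of2 <- x$bins$chrom[match(x$pixels$bin2, x$bins$bin_id)]
  cis <- chrom_of == chrom_of2
  p <- x$pixels[cis, , drop = FALSE]
  pc <- chrom_of[cis]
  out <- x
  newv <- p$count
  for (chrom in unique(x$bins$chrom)) {
    ids <- chrom_bin_ids(x, chrom)
    n <- length(ids)
    m <- matrix(NA_real_, n, n)
    sel <- pc == chrom
    i <- p$bin1[sel] - min(ids) + 1L
    j <- p$bin2[sel] - min(ids) + 1L
    m[cbind(i, j)] <- p$count[sel]
    # unobserved pairs among unmasked bins count as zero in the diagonal mean
    masked <- if (!is.null(x$weights)) is.na(x$weights[ids + 1L]) else rep(FALSE, n)
    d <- j - i
    dmean <- vapply(sort(unique(d)), function(dd) {
      ii <- seq_len(n - dd)
      jj <- ii + dd
      ok <- !(masked[ii] | masked[jj])
      v <- m[cbind(ii[ok], jj[ok])]
      v[is.na(v)] <- 0
      mean(v)
    }, numeric(1))
    names(dmean) <- sort(unique(d))
    e <- dmean[as.character(d)]
    nv <- p$count[sel] / ifelse(e > 0, e, NA_real_)
    newv[sel] <- nv
  }
  out$pixels <- p
  out$pixels$count <- newv
  out$normalization <- paste0(x$normalization, "+oe")
  out
}

#' Trans-contact enrichment between chromosome pairs
#'
#' For each chromosome pair, observed = total trans contacts between the
#' pair; expected = product of the chromosomes' trans marginals over the
#' total trans sum, rescaled globally so that the expected values sum to the
#' observed total; score = log2(observed / expected).
#'
#' @param x a `contact_matrix` with at least two chromosomes.
#' @return symmetric data.frame (`chrom1`, `chrom2`, `observed`, `expected`,
#'   `score`) with one row per unordered pair.
#' @export
trans_enrichment <- function(x) {
  chroms <- unique(x$bins$chrom)
  if (length(chroms) < 2) stop("trans enrichment requires >= 2 chromosomes")
  c1 <- x$bins$chrom[match(x$pixels$bin1, x$bins$bin_id)]
  c2 <- x$bins$chrom[match(x$pixels$bin2, x$bins$bin_id)]
  tr <- which(c1 != c2 & is.finite(x$pixels$count))
  if (!length(tr) || sum(x$pixels$count[tr]) == 0)
    stop("matrix has no trans contacts")
  obs <- stats::aggregate(count ~ a + b,
    data = data.frame(a = pmin(c1[tr], c2[tr]), b = pmax(c1[tr], c2[tr]),
                      count = x$pixels$count[tr]), FUN = sum)
  pairs <- expand.grid(chrom1 = chroms, chrom2 = chroms,
                       stringsAsFactors = FALSE)
  pairs <- pairs[match(pairs$chrom1, chroms) < match(pairs$chrom2, chroms), ]
  key <- paste(pmin(obs$a, obs$b), pmax(obs$a, obs$b))
  qkey <- paste(pmin(pairs$chrom1, pairs$chrom2), pmax(pairs$chrom1, pairs$chrom2))
  pairs$observed <- obs$count[match(qkey, key)]
  pairs$observed[is.na(pairs$observed)] <- 0
  marg <- vapply(chroms, function(ch)
    sum(pairs$observed[pairs$chrom1 == ch | pairs$chrom2 == ch]), numeric(1))
  total <- sum(pairs$observed)
  raw_exp <- marg[pairs$chrom1] * marg[pairs$chrom2] / total
  pairs$expected <- raw_exp * total / sum(raw_exp)
  pairs$score <- log2(pairs$observed / pairs$expected)
  rownames(pairs) <- NULL
  pairs
}

# Two-sided van Elteren stratified rank-sum: per-stratum Wilcoxon rank-sum
# statistics combined as a tie-corrected normal deviate. Strata where either
# group is absent contribute nothing.
stratified_ranksum <- function(values, in_group1, strata) {
  num <- 0
  varsum <- 0
  for (s in unique(strata)) {
    sel <- strata == s
    g <- in_group1[sel]
    n1 <- sum(g); n2 <- sum(!g)
    if (n1 == 0 || n2 == 0) next
    v <- values[sel]
    N <- n1 + n2
    r <- rank(v)
    U <- sum(r[g]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
    vU <- n1 * n2 / 12 * ((N + 1) - tiecorr)
    if (vU <= 0) next
    num <- num + (U - n1 * n2 / 2)
    varsum <- varsum + vU
  }
  if (varsum <= 0) return(NA_real_)
  z <- num / sqrt(varsum)
  2 * stats::pnorm(-abs(z))
}

#' Origin-stratified cis distance decay
#'
#' Assigns every cis pair of a chromosome to the same- or different-ancestral-
#' origin stratum via the origin segments covering the two bin midpoints,
#' summarizes mean normalized contact in log2-spaced distance bins, and
#' tests the two origin strata within each distance bin with a two-sided
#' rank-sum test stratified by exact bin distance (van Elteren combination
#' of per-distance Wilcoxon statistics, tie-corrected). Stratification is
#' essential: within a coarse log2 bin the two origin groups have different
#' exact-distance compositions, and count distributions at different
#' distances are not exchangeable even after rescaling.
#'
#' @param x a normalized `contact_matrix`.
#' @param origins data.frame of origin segments (`chrom`, `start`, `end`,
#'   `anc_chrom`) tiling each chromosome.
#' @param chrom chromosome to analyze (default: all with >1 origin, plus a
#'   flag for single-origin chromosomes).
#' @param n_dist_bins number of log2-spaced distance strata.
#' @return data.frame with per distance bin: mean contact and pair count per
#'   stratum and the rank-sum p-value (NA where a stratum is empty).
#' @export
cis_decay_by_origin <- function(x, origins, chrom = NULL, n_dist_bins = 8) {
  chroms <- chrom %||% unique(x$bins$chrom)
  res <- x$resolution
  out <- list()
  for (ch in chroms) {
    ids <- chrom_bin_ids(x, ch)
    seg <- origins[origins$chrom == ch, , drop = FALSE]
    b <- x$bins[x$bins$chrom == ch, ]
    mid <- (b$start + b$end) / 2
    idx <- findInterval(mid, seg$start)
    anc <- seg$anc_chrom[pmax(idx, 1L)]
    if (length(unique(anc)) < 2)
      attr(out, "single_origin") <- c(attr(out, "single_origin"), ch)
    sel <- x$pixels$bin1 %in% ids & x$pixels$bin2 %in% ids &
      x$pixels$bin1 != x$pixels$bin2 & is.finite(x$pixels$count)
    p <- x$pixels[sel, ]
    i <- match(p$bin1, b$bin_id)
    j <- match(p$bin2, b$bin_id)
    same <- anc[i] == anc[j]
    d <- (p$bin2 - p$bin1) * res
    lo <- log2(2 * res)
    hi <- log2(max(d) + 1)
    brk <- 2^seq(lo, hi, length.out = n_dist_bins + 1)
    db <- cut(d, breaks = c(0, brk[-1]), labels = FALSE)
    for (k in sort(unique(db))) {
      vs <- p$count[db == k & same]
      vd <- p$count[db == k & !same]
      pv <- if (length(vs) >= 2 && length(vd) >= 2)
        stratified_ranksum(p$count[db == k], same[db == k], d[db == k])
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, dist_bin = k, dist_mid = sqrt(max(brk[k], res) * brk[k + 1]),
        mean_same = if (length(vs)) mean(vs) else NA_real_,
        mean_diff = if (length(vd)) mean(vd) else NA_real_,
        n_same = length(vs), n_diff = length(vd), p = pv)
    }
  }
  res_df <- do.call(rbind, out)
  attr(res_df, "single_origin") <- attr(out, "single_origin")
  res_df
}
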