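#' SNP-index statistics per site
#'
#' For each site let M be the allele of the dominant-phenotype parent and
#' P that of the recessive-phenotype parent. The SNP-index of a bulk is
#' the fraction of its reads at the site carrying the M allele:
#' `snp_index_dom = Maa / (Maa + Paa)` in the dominant (black) bulk and
#' `snp_index_rec = Mab / (Mab + Pab)` in the recessive (yellow) bulk,
#' with `delta = snp_index_dom - snp_index_rec`. A bulk whose M + P depth
#' is zero yields `NA` for that index (and for `delta`); missing values
#' propagate, they are never imputed as zero.
#'
#' @param sites a [snp_sites()] table.
#' @return data.frame with columns `snp_index_dom`, `snp_index_rec`,
#'   `delta`, one row per site.
#' @export
snp_index <- function(sites) {
  stopifnot(inherits(sites, "snp_sites"))
  p1 <- toupper(sites$p1_allele)
  p2 <- toupper(sites$p2_allele)
  if (nrow(sites) > 0 && (!all(p1 %in% BASES) || !all(p2 %in% BASES))) {
    stop("snp_index: parental alleles must be single bases in {A,C,G,T}",
         call. = FALSE)
  }
  dom <- as.matrix(sites[paste0("dom_", BASES)])
  rec <- as.matrix(sites[paste0("rec_", BASES)])
  i1 <- match(p1, BASES)
  i2 <- match(p2, BASES)
  n <- nrow(sites)
  pick <- function(m, idx) m[cbind(seq_len(n), idx)]
  Maa <- pick(dom, i1); Paa <- pick(dom, i2)
  Mab <- pick(rec, i1); Pab <- pick(rec, i2)
  idx_dom <- ifelse(Maa + Paa > 0, Maa / (Maa + Paa), NA_real_)
  idx_rec <- ifelse(Mab + Pab > 0, Mab / (Mab + Pab), NA_real_)
  data.frame(snp_index_dom = idx_dom, snp_index_rec = idx_rec,
             delta = idx_dom - idx_rec)
}

#' Euclidean-distance statistic per site
#'
#' The ED statistic contrasts the two bulks' base compositions at a site:
#' `ed = sqrt(sum_b (f_b(dom) - f_b(rec))^2)` over the four bases, with
#' `f_b` the within-bulk base frequency (depth of base b over the bulk's
#' total depth), so `ed` is bounded by `sqrt(2)`. `ed5 = ed^5` sharpens
#' peaks against background noise. `mode = "depth"` instead uses the raw
#' read depths in place of frequencies (unbounded; provided for
#' completeness). A bulk with zero total depth yields `NA`, never 0.
#'
#' @param sites a [snp_sites()] table.
#' @param mode `"frequency"` (default) or `"depth"`.
#' @return data.frame with columns `ed`, `ed5`.
#' @export
euclidean_distance <- function(sites, mode = c("frequency", "depth")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sites, "snp_sites"))
  dom <- as.matrix(sites[paste0("dom_", BASES)])
  rec <- as.matrix(sites[paste0("rec_", BASES)])
  if (mode == "frequency") {
    dt <- rowSums(dom); rt <- rowSums(rec)
    dom <- dom / dt
    rec <- rec / rt
    ed <- sqrt(rowSums((dom - rec)^2))
    ed[dt == 0 | rt == 0] <- NA_real_
  } else {
    ed <- sqrt(rowSums((dom - rec)^2))
  }
  data.frame(ed = ed, ed5 = ed^5)
}

#' Per-SNP association statistics
#'
#' Computes both association statistics for every site and returns the
#' per-SNP table used by the smoothing and region-calling stages.
#'
#' @param sites a [snp_sites()] table.
#' @param ed_mode passed to [euclidean_distance()].
#' @return data.frame with columns `chrom`, `pos`, `snp_index_dom`,
#'   `snp_index_rec`, `delta`, `ed`, `ed5`, class `association_result`.
#' @export
associate <- function(sites, ed_mode = "frequency") {
  out <- cbind(data.frame(chrom = sites$chrom, pos = sites$pos,
                          stringsAsFactors = FALSE),
               snp_index(sites), euclidean_distance(sites, ed_mode))
  class(out) <- c("association_result", "data.frame")
  out
}

#' Sliding-window mean of a per-SNP statistic
#'
#' Windows hold a fixed number of consecutive SNPs (default 200) and
#' advance by `step` SNPs (default 1); they never span chromosomes.
#' Missing values are excluded from each window's mean. The reported
#' window position is the median physical position of its SNPs. A
#' chromosome with fewer than `window_n` SNPs contributes one whole-
#' chromosome window.
#'
#' @param values numeric statistic per SNP (NA allowed).
#' @param chrom chromosome label per SNP.
#' @param pos physical position per SNP; input must be sorted by
#'   (chrom, pos).
#' @param window_n SNPs per window.
#' @param step SNPs between successive window starts.
#' @return data.frame with columns `chrom`, `pos` (median bp), `stat`
#'   (window mean), `n` (non-missing SNPs in the window).
#' @export
sliding_window_mean <- function(values, chrom, pos, window_n = 200L,
                                step = 1L) {
  stopifnot(length(values) == length(chrom), length(values) == length(pos),
            window_n >= 1L, step >= 1L)
  res <- lapply(split(seq_along(values), chrom), function(ii) {
    ii <- ii[order(pos[ii])]
    v <- values[ii]; p <- pos[ii]
    n <- length(ii)
    starts <- if (n < window_n) 1L else seq.int(1L, n - window_n + 1L, by = step)
    w <- if (n < window_n) n else window_n
    stat <- numeric(length(starts)); mid <- numeric(length(starts))
    cnt <- integer(length(starts))
    for (k in seq_along(starts)) {
      j <- starts[k]:(starts[k] + w - 1L)
      stat[k] <- mean(v[j], na.rm = TRUE)
      cnt[k] <- sum(!is.na(v[j]))
      mid[k] <- stats::median(p[j])
    }
    stat[cnt == 0L] <- NA_real_
    data.frame(chrom = chrom[ii[1]], pos = mid, stat = stat, n = cnt,
               start_index = starts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

tricube <- function(u) {
  w <- (1 - abs(u)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

loess_fit_one <- function(x, y, span) {
  n <- length(x)
  q <- floor(span * n)
  if (q < 3L) return(NULL)
  fitted <- numeric(n)
  trace_L <- 0
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    if (h <= 0) return(NULL)
    w <- tricube(d / h)
    use <- which(w > 0)
    if (length(use) < 2L) return(NULL)
    xu <- x[use] - x[i]
    wu <- w[use]
    # row of the smoother matrix: e1' (X'WX)^{-1} X'W with X = [1, x - x_i]
    s0 <- sum(wu); s1 <- sum(wu * xu); s2 <- sum(wu * xu^2)
    det <- s0 * s2 - s1^2
    li <- if (det <= .Machine$double.eps * s0 * s2 + 1e-300) wu / s0
          else (s2 - s1 * xu) * wu / det
    fitted[i] <- sum(li * y[use])
    self <- match(i, use)
    trace_L <- trace_L + li[self]
  }
  list(fitted = fitted, trace_L = trace_L)
}

#' Local linear regression with AICc span selection
#'
#' Degree-1 local regression with tricube weights over the `span * n`
#' nearest neighbours of each point, fitted at every candidate span in
#' `span_grid`; the returned fit minimises the corrected Akaike
#' information criterion
#' `AICc = log(sigma^2) + 1 + 2 (tr(L) + 1) / (n - tr(L) - 2)`,
#' where `L` is the smoother matrix and `sigma^2` the mean squared
#' residual. Intended to be applied per chromosome (x strictly
#' increasing). Missing `y` values are excluded from the fit and carried
#' through as `NA` in `fitted`.
#'
#' @param x predictor (physical positions), strictly increasing on the
#'   non-missing subset.
#' @param y response (e.g. ED^5 per SNP); NA allowed.
#' @param span_grid candidate spans in (0, 1]; spans giving local windows
#'   of fewer than 3 points are skipped.
#' @return list with class `loess_fit`: `span`, `fitted` (aligned with
#'   the input, NA where y was missing), `trace_L`, `aicc`, and
#'   `aicc_grid` (one row per evaluated span).
#' @export
loess_fit_aicc <- function(x, y, span_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(x) == length(y), length(span_grid) >= 1)
  ok <- !is.na(y) & !is.na(x)
  xs <- as.numeric(x[ok]); ys <- as.numeric(y[ok])
  n <- length(xs)
  if (n < 10L) stop("loess_fit_aicc: need at least 10 non-missing points",
                    call. = FALSE)
  if (is.unsorted(xs, strictly = TRUE)) {
    stop("loess_fit_aicc: x must be strictly increasing", call. = FALSE)
  }
  grid <- data.frame(span = span_grid, aicc = NA_real_, trace_L = NA_real_)
  best <- NULL
  for (k in seq_along(span_grid)) {
    fit <- loess_fit_one(xs, ys, span_grid[k])
    if (is.null(fit)) next
    denom <- n - fit$trace_L - 2
    if (denom <= 0) next
    sigma2 <- mean((ys - fit$fitted)^2)
    aicc <- log(sigma2) + 1 + 2 * (fit$trace_L + 1) / denom
    grid$aicc[k] <- aicc
    grid$trace_L[k] <- fit$trace_L
    if (is.null(best) || aicc < best$aicc) {
      best <- list(span = span_grid[k], fit = fit, aicc = aicc)
    }
  }
  if (is.null(best)) stop("loess_fit_aicc: no valid span in span_grid",
                          call. = FALSE)
  fitted <- rep(NA_real_, length(y))
  fitted[ok] <- best$fit$fitted
  structure(list(span = best$span, fitted = fitted,
                 trace_L = best$fit$trace_L, aicc = best$aicc,
                 aicc_grid = grid),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("loess_fit: span %.2f, tr(L) %.2f, AICc %.4f, n %d\n",
              x$span, x$trace_L, x$aicc, sum(!is.na(x$fitted))))
  invisible(x)
}

#' Smooth association statistics genome-wide
#'
#' Adds the two smoothed series used for region calling: the sliding-
#' window mean of delta(SNP-index) and the per-chromosome AICc-loess fit
#' of ED^5. Sites on unplaced/"unknown" chromosomes keep their per-SNP
#' statistics but are excluded from windows and smoothing. With
#' `step = 1` the window mean is also aligned back onto the per-SNP table
#' (`window_delta` at each window's centre SNP).
#'
#' @param assoc an [associate()] table, sorted by (chrom, pos).
#' @param window_n,window_step window size and step in SNPs.
#' @param span_grid candidate loess spans.
#' @return list: `assoc` (input plus `window_delta` and `loess_ed5`
#'   columns), `delta_windows` (the window profile), `loess` (per-
#'   chromosome `loess_fit` objects).
#' @export
smooth_association <- function(assoc, window_n = 200L, window_step = 1L,
                               span_grid = seq(0.05, 0.95, by = 0.05)) {
  keep <- !is_unknown_chrom(assoc$chrom)
  assoc$window_delta <- NA_real_
  assoc$loess_ed5 <- NA_real_

  sub <- which(keep)
  dw <- sliding_window_mean(assoc$delta[sub], assoc$chrom[sub],
                            assoc$pos[sub], window_n, window_step)
  # align window means onto centre SNPs of the per-SNP table
  for (ch in unique(dw$chrom)) {
    ii <- sub[assoc$chrom[sub] == ch]
    ii <- ii[order(assoc$pos[ii])]
    wch <- dw[dw$chrom == ch, ]
    w <- min(window_n, length(ii))
    centre <- wch$start_index + (w - 1L) %/% 2L
    assoc$window_delta[ii[centre]] <- wch$stat
  }

  fits <- list()
  for (ch in unique(assoc$chrom[sub])) {
    ii <- sub[assoc$chrom[sub] == ch]
    ii <- ii[order(assoc$pos[ii])]
    fit <- loess_fit_aicc(assoc$pos[ii], assoc$ed5[ii], span_grid)
    assoc$loess_ed5[ii] <- fit$fitted
    fits[[ch]] <- fit
  }
  list(assoc = assoc, delta_windows = dw[c("chrom", "pos", "stat", "n")],
       loess = fits)
}
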