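#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples (the Rogers-Huff composite-LD r^2; no phasing required, and
#' identical to haplotype r^2 for phased data under Hardy-Weinberg).
#'
#' @param x,y Dosage vectors at the two sites.
#' @return r^2 in `[0, 1]`, or `NA` when fewer than two samples are complete
#'   or either site is monomorphic among the shared samples.
#' @export
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Distance-binned LD decay curve
#'
#' All intra-chromosomal site pairs separated by at most `max_dist` bp
#' contribute r^2 to the uniform-width distance bin containing their bp
#' separation. Bins can optionally be capped at `max_pairs_per_bin` pairs by
#' uniform (seeded) subsampling for tractability on dense data.
#'
#' @param gm A [geno_matrix()] (subset the samples first to analyze one
#'   population or group).
#' @param max_dist Maximum pair separation in bp. Default 300000.
#' @param bin_width Bin width in bp. Default 5000.
#' @param max_pairs_per_bin Optional cap on pairs per bin. Default `Inf`.
#' @param seed Seed for the subsampling draw (only used when the cap binds).
#' @return An `ld_curve`: a tibble with `bin_start`, `bin_end`, `midpoint`,
#'   `n_pairs`, `mean_r2`, carrying `r2_max`, `half_max` and
#'   `linkage_distance` as attributes (see [linkage_distance()]).
#' @export
ld_decay_curve <- function(gm, max_dist = 300000, bin_width = 5000,
                           max_pairs_per_bin = Inf, seed = 1) {
  pairs <- purrr::map_dfr(unique(gm$chrom), function(ch) {
    on_ch <- which(gm$chrom == ch)
    pos <- gm$pos[on_ch]
    sep_pairs(pos, max_dist) |>
      dplyr::mutate(i = on_ch[.data$i], j = on_ch[.data$j])
  })
  if (nrow(pairs) == 0) {
    warn("ld_decay_curve: no eligible site pairs")
    bins <- empty_bins(max_dist, bin_width) |>
      dplyr::mutate(n_pairs = 0L, mean_r2 = NA_real_) |>
      dplyr::select(-"bin")
    return(new_ld_curve(bins))
  }
  pairs$bin <- pmin(floor(pairs$dist / bin_width),
                    ceiling(max_dist / bin_width) - 1)
  if (is.finite(max_pairs_per_bin)) {
    set.seed(seed)
    pairs <- pairs |>
      dplyr::group_by(.data$bin) |>
      dplyr::slice_sample(n = max_pairs_per_bin) |>
      dplyr::ungroup()
  }
  pairs$r2 <- pair_r2(gm$dosage, pairs$i, pairs$j)
  bins <- empty_bins(max_dist, bin_width) |>
    dplyr::left_join(
      pairs |>
        dplyr::filter(!is.na(.data$r2)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2)),
      by = "bin"
    ) |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L)) |>
    dplyr::select(-"bin")
  new_ld_curve(bins)
}

empty_bins <- function(max_dist, bin_width) {
  starts <- (seq_len(ceiling(max_dist / bin_width)) - 1) * bin_width
  tibble(
    bin = seq_along(starts) - 1,
    bin_start = starts, bin_end = starts + bin_width,
    midpoint = starts + bin_width / 2
  )
}

new_ld_curve <- function(bins) {
  out <- structure(bins, class = c("ld_curve", class(tibble())))
  r2m <- if (all(is.na(bins$mean_r2 %||% NA))) NA_real_ else
    max(bins$mean_r2, na.rm = TRUE)
  attr(out, "r2_max") <- r2m
  attr(out, "half_max") <- r2m / 2
  attr(out, "linkage_distance") <- linkage_distance(out)
  out
}

## r^2 for many site pairs; vectorized fast path when nothing is missing
pair_r2 <- function(dosage, i, j) {
  if (!anyNA(dosage)) {
    n <- ncol(dosage)
    mu <- rowMeans(dosage)
    s <- sqrt(rowSums((dosage - mu)^2))
    poly <- s > 0
    z <- (dosage - mu) / ifelse(s == 0, 1, s)
    r2 <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])^2
    r2[!poly[i] | !poly[j]] <- NA_real_
    return(pmin(r2, 1))
  }
  purrr::map2_dbl(i, j, function(a, b) genotype_r2(dosage[a, ], dosage[b, ]))
}

## site pairs with separation in (0, max_dist], positions sorted ascending
sep_pairs <- function(pos, max_dist) {
  m <- length(pos)
  if (m < 2) return(tibble(i = integer(), j = integer(), dist = numeric()))
  upper <- findInterval(pos + max_dist, pos)
  counts <- upper - seq_len(m)
  i <- rep.int(seq_len(m), pmax(counts, 0L))
  j <- unlist(lapply(seq_len(m), function(k) {
    if (counts[k] > 0) seq.int(k + 1L, upper[k]) else integer(0)
  }))
  tibble(i = i, j = j, dist = pos[j] - pos[i])
}

#' Linkage distance at half-maximum r^2
#'
#' The working "linked range" summary: `half_max = r2_max / 2` with `r2_max`
#' the maximum binned mean r^2, and the linkage distance the midpoint of the
#' first bin (in increasing distance) whose mean r^2 has dropped to or below
#' `half_max`.
#'
#' @param curve An `ld_curve` from [ld_decay_curve()].
#' @return The linkage distance in bp, or `NA` (with a message) when the
#'   curve never reaches half-maximum within its range.
#' @export
linkage_distance <- function(curve) {
  ok <- !is.na(curve$mean_r2)
  if (!any(ok)) return(NA_real_)
  r2_max <- max(curve$mean_r2[ok])
  half <- r2_max / 2
  idx <- which(ok & curve$mean_r2 <= half)
  if (length(idx) == 0) {
    inform("linkage_distance: curve never drops to half-maximum within range")
    return(NA_real_)
  }
  curve$midpoint[min(idx)]
}

#' Exponential decay length of an LD curve
#'
#' Fits `mean_r2 ~ a * exp(-midpoint / ell) + c` by nonlinear least squares
#' and returns the decay length `ell` in bp.
#'
#' @param curve An `ld_curve`.
#' @return Fitted decay length (bp).
#' @export
ld_decay_scale <- function(curve) {
  d <- dplyr::filter(as_tibble(curve), !is.na(.data$mean_r2))
  if (nrow(d) < 4) abort("too few bins to fit a decay scale")
  fit <- stats::nls(
    mean_r2 ~ a * exp(-midpoint / ell) + c0,
    data = d,
    start = list(a = max(d$mean_r2) - min(d$mean_r2),
                 ell = max(d$midpoint) / 4,
                 c0 = min(d$mean_r2)),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  )
  unname(stats::coef(fit)[["ell"]])
}

#' @export
print.ld_curve <- function(x, ...) {
  cat(sprintf(
    "<ld_curve> %d bins; r2_max = %.4g, half_max = %.4g, linkage distance = %s bp\n",
    nrow(x), attr(x, "r2_max"), attr(x, "half_max"),
    format(attr(x, "linkage_distance"))
  ))
  NextMethod()
}

#' Plot an LD decay curve
#'
#' @param object An `ld_curve`.
#' @param ... Unused.
#' @return A ggplot: binned mean r^2 against distance, with the half-maximum
#'   level and linkage distance marked.
#' @export
autoplot.ld_curve <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$midpoint / 1000, .data$mean_r2)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = attr(object, "half_max"),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2))
  ld <- attr(object, "linkage_distance")
  if (!is.na(ld)) {
    p <- p + ggplot2::geom_vline(xintercept = ld / 1000,
                                 linetype = "dotted", color = "red3")
  }
  p
}
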