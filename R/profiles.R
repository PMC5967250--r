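# Binned feature profiles: 1D probability-density profiles with
# peak-of-reference normalization (npdf), peak-normalized 2D histograms,
# peak finding, interval masses and two-set comparison.

#' Build a 1D binned density profile
#'
#' Bins feature values into half-open bins `[edge, edge + width)` anchored
#' at `anchor` (0 degrees for angles, 0.0 A for dBlock) and converts
#' counts to densities `count / (N * bin_width)`, so the densities
#' integrate to 1. The default bin widths are 5 degrees for angles and
#' 0.05 A for block lengths.
#'
#' @param values Numeric vector of feature values; `NA`s must already be
#'   removed.
#' @param bin_width Bin width (degrees or Angstrom).
#' @param anchor Origin of the bin grid (default 0).
#' @param feature Feature label: `"phi"`, `"psi"`, `"chi1"` or
#'   `"dblock"`.
#' @return Object of class `pdf_profile` with elements `feature`,
#'   `bin_width`, `anchor`, `breaks`, `mids`, `counts`, `density`,
#'   `n_total`.
#' @export
build_pdf <- function(values, bin_width = NULL, anchor = 0,
                      feature = c("dblock", "phi", "psi", "chi1")) {
  feature <- match.arg(feature)
  if (is.null(bin_width)) {
    bin_width <- if (feature == "dblock") 0.05 else 5
  }
  stopifnot(bin_width > 0)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("cannot build a profile from no values")
  lo_edge <- anchor + floor((min(values) - anchor) / bin_width) * bin_width
  hi_edge <- anchor + (floor((max(values) - anchor) / bin_width) + 1) * bin_width
  breaks <- seq(lo_edge, hi_edge, by = bin_width)
  idx <- floor((values - lo_edge) / bin_width) + 1L
  idx[idx > length(breaks) - 1L] <- length(breaks) - 1L  # fp guard at top edge
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  n <- length(values)
  structure(list(feature = feature, bin_width = bin_width, anchor = anchor,
                 breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
                 counts = counts, density = counts / (n * bin_width),
                 n_total = n),
            class = "pdf_profile")
}

#' @export
print.pdf_profile <- function(x, ...) {
  cat(sprintf("<pdf_profile> %s: %d values in %d bins of %g, range [%g, %g)\n",
              x$feature, x$n_total, length(x$counts), x$bin_width,
              x$breaks[1L], x$breaks[length(x$breaks)]))
  invisible(x)
}

# put two profiles of the same feature/width/anchor on a common bin grid
.align_profiles <- function(a, b) {
  stopifnot(a$feature == b$feature, a$bin_width == b$bin_width,
            isTRUE(all.equal(a$anchor %% a$bin_width,
                             b$anchor %% b$bin_width)))
  lo <- min(a$breaks[1L], b$breaks[1L])
  hi <- max(a$breaks[length(a$breaks)], b$breaks[length(b$breaks)])
  breaks <- seq(lo, hi, by = a$bin_width)
  embed <- function(p) {
    off <- round((p$breaks[1L] - lo) / p$bin_width)
    counts <- integer(length(breaks) - 1L)
    counts[seq_along(p$counts) + off] <- p$counts
    p$breaks <- breaks
    p$mids <- breaks[-length(breaks)] + p$bin_width / 2
    p$counts <- counts
    p$density <- counts / (p$n_total * p$bin_width)
    p
  }
  list(embed(a), embed(b))
}

#' Normalize a pair of profiles by the reference's highest peak
#'
#' Divides both densities by the reference profile's peak density, so the
#' reference curve has maximum exactly 1 and the target curve is
#' expressed relative to the reference's modal density (it may exceed 1).
#'
#' @param target,reference `pdf_profile`s of the same feature, bin width
#'   and anchor.
#' @param ref_id Identifier stored on both normalized curves.
#' @return List with elements `target` and `reference`, each of class
#'   `npdf` (a `pdf_profile` plus `values` and `ref_id`).
#' @export
normalize_by_reference <- function(target, reference, ref_id = "reference") {
  al <- .align_profiles(target, reference)
  target <- al[[1L]]; reference <- al[[2L]]
  peak <- max(reference$density)
  if (peak <= 0) stop("reference profile has no mass; cannot normalize")
  as_npdf <- function(p) {
    # the reference's modal bin divides by itself, so its maximum is
    # exactly 1 in floating point
    p$values <- p$density / peak
    p$ref_id <- ref_id
    class(p) <- c("npdf", "pdf_profile")
    p
  }
  list(target = as_npdf(target), reference = as_npdf(reference))
}

#' Peak-normalized 2D histogram of two features
#'
#' Bins record pairs (default phi on x, dBlock on y) on a fixed grid (5
#' degrees by 0.05 A by default) and normalizes the count matrix by its
#' own maximum, so every cell holds the population ratio relative to the
#' histogram's most popular conformation.
#'
#' @param records A `conformation_records` data frame (or any data frame
#'   with the feature columns).
#' @param x,y Feature column names.
#' @param x_width,y_width Bin widths; defaults are 5 (angles) and 0.05
#'   (dblock), chosen per feature.
#' @return Object of class `hist2d` with `counts` and `ratio` matrices
#'   (rows = x bins), bin vectors, and `n_total`.
#' @export
build_hist2d <- function(records, x = "phi", y = "dblock",
                         x_width = NULL, y_width = NULL) {
  default_width <- function(f) if (f == "dblock") 0.05 else 5
  if (is.null(x_width)) x_width <- default_width(x)
  if (is.null(y_width)) y_width <- default_width(y)
  xv <- records[[x]]; yv <- records[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) == 0L) stop("no records with both features present")
  grid1 <- function(v, w) {
    lo <- floor(min(v) / w) * w
    seq(lo, (floor(max(v) / w) + 1) * w, by = w)
  }
  xb <- grid1(xv, x_width); yb <- grid1(yv, y_width)
  xi <- pmin(floor((xv - xb[1L]) / x_width) + 1L, length(xb) - 1L)
  yi <- pmin(floor((yv - yb[1L]) / y_width) + 1L, length(yb) - 1L)
  counts <- matrix(0L, nrow = length(xb) - 1L, ncol = length(yb) - 1L)
  for (i in seq_along(xi)) counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1L
  structure(list(xfeature = x, yfeature = y,
                 xbreaks = xb, ybreaks = yb,
                 xmids = xb[-length(xb)] + x_width / 2,
                 ymids = yb[-length(yb)] + y_width / 2,
                 counts = counts, ratio = counts / max(counts),
                 n_total = length(xv)),
            class = "hist2d")
}

#' @export
print.hist2d <- function(x, ...) {
  m <- which(x$counts == max(x$counts), arr.ind = TRUE)[1L, ]
  cat(sprintf(
    "<hist2d> (%s, %s): %d records on %d x %d grid; modal cell (%g, %g)\n",
    x$xfeature, x$yfeature, x$n_total, nrow(x$counts), ncol(x$counts),
    x$xmids[m[1L]], x$ymids[m[2L]]))
  invisible(x)
}

#' Find peaks in a binned profile
#'
#' Local maxima of the profile's values: bins strictly greater than both
#' neighbours (profile ends compare only against the existing neighbour;
#' plateau ties are resolved to the leftmost bin of the run), kept when
#' their height is at least `min_prominence` times the global maximum.
#'
#' @param profile A `pdf_profile` or `npdf`.
#' @param min_prominence Height threshold as a fraction of the global
#'   maximum (default 0.05, which suppresses single-count noise bins at
#'   realistic sample sizes).
#' @return Data frame with columns `center` (bin center) and `height`
#'   (profile value), ordered by decreasing height.
#' @export
find_peaks <- function(profile, min_prominence = 0.05) {
  v <- if (!is.null(profile$values)) profile$values else profile$density
  n <- length(v)
  if (n == 0L) stop("empty profile")
  r <- rle(v)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  is_peak <- r$values > left & r$values > right
  centers <- profile$mids[run_start[is_peak]]
  heights <- r$values[is_peak]
  keep <- heights >= min_prominence * max(v)
  out <- data.frame(center = centers[keep], height = heights[keep])
  out[order(-out$height), , drop = FALSE]
}

#' Population ratio between two cells of a 2D histogram
#'
#' The count of cell `a` divided by the count of cell `b`; with `b`
#' omitted, `b` is the histogram's modal cell, matching the "ratio to the
#' most popular conformation" reading of a peak-normalized histogram.
#'
#' @param hist A `hist2d`.
#' @param cell_a,cell_b Length-2 vectors `(x value, y value)` locating a
#'   cell by any point inside it; `cell_b = NULL` uses the modal cell.
#' @return Ratio as a fraction (1 = as popular as the modal cell).
#' @export
population_ratio <- function(hist, cell_a, cell_b = NULL) {
  locate <- function(cell) {
    xi <- findInterval(cell[1L], hist$xbreaks, rightmost.closed = FALSE)
    yi <- findInterval(cell[2L], hist$ybreaks, rightmost.closed = FALSE)
    if (xi < 1L || xi > nrow(hist$counts) || yi < 1L || yi > ncol(hist$counts)) {
      stop("cell (", cell[1L], ", ", cell[2L], ") is outside the histogram grid")
    }
    c(xi, yi)
  }
  a <- locate(cell_a)
  b <- if (is.null(cell_b)) {
    which(hist$counts == max(hist$counts), arr.ind = TRUE)[1L, ]
  } else {
    locate(cell_b)
  }
  denom <- hist$counts[b[1L], b[2L]]
  if (denom == 0L) stop("reference cell has zero count; ratio undefined")
  hist$counts[a[1L], a[2L]] / denom
}

#' Fraction of a profile's mass inside an interval
#'
#' Mass of the half-open interval `(lo, hi]` as a fraction of the total
#' count; bins partially covered by the interval contribute
#' proportionally to the overlap.
#'
#' @param profile A `pdf_profile`.
#' @param lo,hi Interval bounds (`lo < hi`).
#' @return Fraction in `[0, 1]`.
#' @export
interval_mass <- function(profile, lo, hi) {
  stopifnot(lo < hi)
  bl <- profile$breaks[-length(profile$breaks)]
  bu <- profile$breaks[-1L]
  overlap <- pmax(0, pmin(bu, hi) - pmax(bl, lo))
  sum(profile$counts * overlap / profile$bin_width) / profile$n_total
}

#' Compare two record sets for one residue type
#'
#' For each requested feature, builds the two profiles on the package's
#' standard grids, normalizes both by set A's peak (A is the reference,
#' as when a large crystallographic set anchors the scale), finds peaks,
#' and lists the contiguous intervals where B's normalized curve exceeds
#' A's over at least `min_run` consecutive bins, with both sets' interval
#' masses. This is the per-residue "set B above set A" comparison used to
#' flag systematic shifts (e.g. towards shorter block lengths).
#'
#' @param records_a,records_b `conformation_records` data frames;
#'   set A is the reference.
#' @param res_type Residue type to compare.
#' @param features Feature columns to compare.
#' @param min_prominence Peak threshold, see [find_peaks()].
#' @param min_run Minimum number of consecutive exceeding bins for an
#'   interval to be reported (default 2, so single-bin noise does not
#'   produce calls).
#' @return Object of class `set_comparison`: per feature a list with
#'   `npdf_a`, `npdf_b`, `peaks_a`, `peaks_b` and `exceedance` (data
#'   frame with `lo`, `hi`, `mass_a`, `mass_b`), or the string
#'   `"not comparable"` when a set has no records of the type.
#' @export
compare_sets <- function(records_a, records_b, res_type,
                         features = c("phi", "psi", "chi1", "dblock"),
                         min_prominence = 0.05, min_run = 2L) {
  sub_a <- records_a[records_a$res_type == res_type, , drop = FALSE]
  sub_b <- records_b[records_b$res_type == res_type, , drop = FALSE]
  out <- list(res_type = res_type,
              n_a = nrow(sub_a), n_b = nrow(sub_b), features = list())
  for (f in features) {
    va <- sub_a[[f]][!is.na(sub_a[[f]])]
    vb <- sub_b[[f]][!is.na(sub_b[[f]])]
    if (length(va) == 0L || length(vb) == 0L) {
      out$features[[f]] <- "not comparable"
      next
    }
    pa <- build_pdf(va, feature = f)
    pb <- build_pdf(vb, feature = f)
    np <- normalize_by_reference(pb, pa, ref_id = "set_a")
    npdf_a <- np$reference
    npdf_b <- np$target
    excess <- npdf_b$values > npdf_a$values
    runs <- rle(excess)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sel <- which(runs$values & runs$lengths >= min_run)
    exceedance <- if (length(sel)) {
      do.call(rbind, lapply(sel, function(j) {
        lo <- npdf_a$breaks[starts[j]]
        hi <- npdf_a$breaks[ends[j] + 1L]
        data.frame(lo = lo, hi = hi,
                   mass_a = interval_mass(npdf_a, lo, hi),
                   mass_b = interval_mass(npdf_b, lo, hi))
      }))
    } else {
      data.frame(lo = numeric(), hi = numeric(),
                 mass_a = numeric(), mass_b = numeric())
    }
    out$features[[f]] <- list(
      npdf_a = npdf_a, npdf_b = npdf_b,
      peaks_a = find_peaks(npdf_a, min_prominence),
      peaks_b = find_peaks(npdf_b, min_prominence),
      exceedance = exceedance)
  }
  class(out) <- "set_comparison"
  out
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("<set_comparison> %s: %d vs %d records\n",
              x$res_type, x$n_a, x$n_b))
  for (f in names(x$features)) {
    fc <- x$features[[f]]
    if (identical(fc, "not comparable")) {
      cat(sprintf("  %s: not comparable\n", f))
      next
    }
    ex <- fc$exceedance
    cat(sprintf("  %s: %d B-above-A interval(s)%s\n", f, nrow(ex),
                if (nrow(ex)) paste0(": ",
                  paste(sprintf("(%g, %g]", ex$lo, ex$hi), collapse = " ")) else ""))
  }
  invisible(x)
}

#' Serialize a profile or histogram as a delimited text table
#'
#' Writes bin centers and values so that any plot can be regenerated
#' from text.
#'
#' @param x A `pdf_profile`, `npdf` or `hist2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  if (inherits(x, "hist2d")) {
    grid <- expand.grid(x_mid = x$xmids, y_mid = x$ymids)
    grid$count <- as.vector(x$counts)
    grid$ratio <- as.vector(x$ratio)
    utils::write.table(grid, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(mid = x$mids, count = x$counts, density = x$density)
    if (!is.null(x$values)) df$npdf <- x$values
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
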