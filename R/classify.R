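#' Categorize HET sites by their bias geometry
#'
#' A site's position in the NMB-NAB plane, plus its mismapped-read count,
#' determines its category:
#' \enumerate{
#'   \item inside the circle of radius `radius` about the origin: `balanced`;
#'   \item else, NMB and NAB nonzero with the same sign and
#'     `slope_lo <= NAB/NMB <= slope_hi` (the wedge around the diagonal, both
#'     quadrants, bounds inclusive): `loss` - reads of one allele failed to
#'     map;
#'   \item else, `|NMB| <= radius` and `|NAB| > radius` (mapping unbiased,
#'     assignment biased): `flux` when more than `flux_reads` reads aligned in
#'     from elsewhere, `local` otherwise;
#'   \item anything else: `outlier`.
#' }
#'
#' @param NMB,NAB numeric vectors (mapping/assignment balance minus
#'   simulation balance).
#' @param n_mismapped integer vector of mismapped-read counts.
#' @param radius balanced-circle radius (default 0.1).
#' @param slope_hi,slope_lo loss-wedge slope bounds (defaults 2 and 1/2).
#' @param flux_reads mismapped-read threshold separating flux from local
#'   (default 5; "more than" is strict).
#' @return character vector of categories; `NA` where NMB or NAB is `NA`.
#' @export
classify_site <- function(NMB, NAB, n_mismapped, radius = 0.1,
                          slope_hi = 2, slope_lo = 0.5, flux_reads = 5L) {
  n <- length(NMB)
  stopifnot(length(NAB) == n, length(n_mismapped) == n)
  out <- rep(NA_character_, n)
  ok <- !is.na(NMB) & !is.na(NAB)
  r <- sqrt(NMB^2 + NAB^2)
  balanced <- ok & r <= radius
  # inclusive wedge bounds, in product form so exact boundary points
  # (e.g. NAB = 2 * NMB) are not lost to division rounding
  eps <- 1e-9
  loss <- ok & !balanced & (NMB * NAB > 0) &
    abs(NAB) <= slope_hi * abs(NMB) + eps &
    abs(NAB) >= slope_lo * abs(NMB) - eps
  vert <- ok & !balanced & !loss & abs(NMB) <= radius & abs(NAB) > radius
  flux <- vert & n_mismapped > flux_reads
  local <- vert & !flux
  outlier <- ok & !balanced & !loss & !vert
  out[balanced] <- "balanced"
  out[loss] <- "loss"
  out[flux] <- "flux"
  out[local] <- "local"
  out[outlier] <- "outlier"
  out
}

#' Append bias categories to a balance table
#'
#' @param balances output of [site_balance()].
#' @param assigner which NAB to use: `"context"` (default) or `"naive"`.
#' @inheritParams classify_site
#' @return the balance table with a `category` column.
#' @export
classify_balance <- function(balances, assigner = c("context", "naive"),
                             radius = 0.1, slope_hi = 2, slope_lo = 0.5,
                             flux_reads = 5L) {
  assigner <- match.arg(assigner)
  nab <- if (assigner == "context") balances$NAB else balances$NAB_naive
  b <- copy(balances)
  b[, category := classify_site(NMB, nab, n_mismapped, radius = radius,
                                slope_hi = slope_hi, slope_lo = slope_lo,
                                flux_reads = flux_reads)]
  b[]
}

#' Category counts, split by SNVs versus gaps
#'
#' @param classified output of [classify_balance()].
#' @return data.table with rows SNV/gap x category counts (all five
#'   categories always present; zero when empty).
#' @export
summarize_categories <- function(classified) {
  cats <- c("balanced", "loss", "flux", "local", "outlier")
  grid <- CJ(type = c("SNV", "gap"), category = cats)
  if (nrow(classified) == 0L) {
    grid[, n := 0L]
    return(grid[])
  }
  x <- classified[!is.na(category)]
  x[, type := ifelse(var_class == "SNV", "SNV", "gap")]
  tab <- x[, .N, by = .(type, category)]
  out <- tab[grid, on = c("type", "category")]
  out[is.na(N), N := 0L]
  setnames(out, "N", "n")
  out[]
}

#' NMB-NAB diagnostic scatter plot
#'
#' Sites coloured by category, with the balanced circle and the loss-wedge
#' slope lines drawn; one panel per SNV/gap class.
#'
#' @param classified output of [classify_balance()].
#' @param radius,slope_hi,slope_lo geometry to draw (match the classifier).
#' @param file optional output path (PNG or PDF by extension).
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_nmb_nab <- function(classified, radius = 0.1, slope_hi = 2,
                         slope_lo = 0.5, file = NULL) {
  cols <- c(balanced = "#2ca02c", loss = "#ff7f0e", flux = "#1f77b4",
            local = "#9467bd", outlier = "#7f7f7f")
  b <- classified[!is.na(NMB) & !is.na(NAB)]
  b <- copy(b)[, type := ifelse(var_class == "SNV", "SNV", "gap")]
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- data.frame(x = radius * cos(th), y = radius * sin(th))
  p <- ggplot2::ggplot(b, ggplot2::aes(x = NMB, y = NAB, colour = category)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = x, y = y),
                       inherit.aes = FALSE, linewidth = 0.3) +
    ggplot2::geom_abline(slope = slope_hi, intercept = 0, linetype = 3,
                         linewidth = 0.3) +
    ggplot2::geom_abline(slope = slope_lo, intercept = 0, linetype = 3,
                         linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = cols, drop = FALSE) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::facet_wrap(~type) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
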