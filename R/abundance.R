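# qPCR standard-curve fitting and conversion of marker-gene copy numbers to
# cell densities. amoA is single-copy in all known ammonia-oxidizing archaea,
# so copies per gram translate directly to cells per gram and, through the
# porosity and grain density of the rock, to cells per cm^3 of pore space.

#' qPCR dilution series
#'
#' @param copies_per_ul Input quantities of the standard, copies/ul
#'   (strictly positive).
#' @param cq Quantification-cycle values, same length.
#' @param replicate_id Optional replicate labels.
#' @return A list of class `dilution_series`.
#' @export
dilution_series <- function(copies_per_ul, cq, replicate_id = NULL) {
  stopifnot(length(copies_per_ul) == length(cq),
            all(is.finite(copies_per_ul)), all(copies_per_ul > 0),
            all(is.finite(cq)))
  if (!is.null(replicate_id)) stopifnot(length(replicate_id) == length(cq))
  structure(list(copies_per_ul = copies_per_ul, cq = cq,
                 replicate_id = replicate_id),
            class = "dilution_series")
}

#' Read a dilution series from TSV
#'
#' Expects columns `copies_per_ul` and `cq`; an optional `replicate_id`
#' column is carried through.
#'
#' @param path TSV file path.
#' @return A [dilution_series()].
#' @export
read_dilution_series <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(c("copies_per_ul", "cq") %in% names(tab)))
  dilution_series(tab$copies_per_ul, tab$cq,
                  if ("replicate_id" %in% names(tab)) tab$replicate_id)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Cq against log10(copies/ul). The
#' amplification efficiency derives from the slope as
#' \eqn{E = 10^{-1/slope} - 1} (E = 1 is perfect doubling each cycle; a 10x
#' dilution series at 100% efficiency has slope -3.3219 = -1/log10(2)).
#'
#' @param series A [dilution_series()] with at least 3 distinct dilution
#'   levels.
#' @param detection_limit Assay detection limit in copies per gram, carried
#'   as metadata into [quantify()] (default 150, typical for rock samples).
#' @return A list of class `standard_curve` with `slope` (cycles per log10
#'   copies), `intercept` (cycles at 1 copy/ul), `efficiency`, `r_squared`,
#'   and `detection_limit`.
#' @examples
#' s <- make_qpcr_series(seed = 1, efficiency = 0.99, noise_sd = 0)
#' fit_standard_curve(s)$efficiency  # 0.99
#' @export
fit_standard_curve <- function(series, detection_limit = 150) {
  stopifnot(inherits(series, "dilution_series"))
  if (length(unique(series$copies_per_ul)) < 3) {
    stop("need at least 3 distinct dilution levels")
  }
  x <- log10(series$copies_per_ul)
  fit <- stats::lm(series$cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(series$cq) == 0) 1 else
    1 - sum(stats::residuals(fit)^2) /
        sum((series$cq - mean(series$cq))^2)
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 detection_limit = detection_limit),
            class = "standard_curve")
}

#' Absolute quantification: copies per gram of sample
#'
#' Inverts the standard curve at the measured Cq to copies per ul of
#' template, scales to the whole DNA extract (`elution_volume` /
#' `template_volume`), and normalizes by the extracted sample mass. Values
#' below the detection limit are flagged, not zeroed or censored, since
#' non-detects still carry information.
#'
#' @param fit A [fit_standard_curve()] result.
#' @param cq Measured quantification cycle(s); vectorized.
#' @param elution_volume DNA extract volume, ul (default 100, a typical
#'   spin-kit elution).
#' @param template_volume Template volume per reaction, ul. No default: the
#'   reaction setup must be stated explicitly.
#' @param sample_mass Extracted sample mass, g (default 0.5).
#' @return A data.frame with columns `cq`, `copies_per_g`,
#'   `below_detection`.
#' @export
quantify <- function(fit, cq, elution_volume = 100, template_volume,
                     sample_mass = 0.5) {
  stopifnot(inherits(fit, "standard_curve"))
  if (any(!is.finite(cq))) stop("cq must be finite")
  if (elution_volume <= 0 || template_volume <= 0) stop("volumes must be > 0")
  if (sample_mass <= 0) stop("sample_mass must be > 0")
  copies_per_ul <- 10^((cq - fit$intercept) / fit$slope)
  copies_per_g <- copies_per_ul * elution_volume / template_volume / sample_mass
  data.frame(cq = cq, copies_per_g = copies_per_g,
             below_detection = copies_per_g < fit$detection_limit)
}

#' Convert copies per gram of rock to cells per cm^3 of pore space
#'
#' With a single marker-gene copy per cell, the cell density in the habitable
#' pore volume is
#' \deqn{cells\,cm^{-3} = \frac{copies\,g^{-1} \times \rho_{grain}}
#'   {\phi \times copies\,cell^{-1}},}
#' where \eqn{\phi} is the rock porosity and \eqn{\rho_{grain}} the grain
#' density of the solid (g/cm\eqn{^3}). Defaults are the basalt values of 4%
#' porosity, 3 g/cm\eqn{^3}, and one copy per cell.
#'
#' @param copies_per_gram Gene copies per gram of rock (>= 0).
#' @param porosity Rock porosity, fraction in (0, 1); default 0.04.
#' @param grain_density Grain density, g/cm\eqn{^3}; default 3.
#' @param copies_per_cell Marker copies per cell (>= 1); default 1
#'   (single-copy amoA).
#' @return Cells per cm\eqn{^3} of pore space.
#' @examples
#' copies_to_pore_cell_density(1e2)  # 7.5e3
#' copies_to_pore_cell_density(1e4)  # 7.5e5
#' @export
copies_to_pore_cell_density <- function(copies_per_gram, porosity = 0.04,
                                        grain_density = 3,
                                        copies_per_cell = 1) {
  if (porosity <= 0 || porosity >= 1) stop("porosity must be in (0, 1)")
  stopifnot(grain_density > 0, copies_per_cell >= 1,
            all(copies_per_gram >= 0))
  copies_per_gram * grain_density / porosity / copies_per_cell
}

#' Taxon cell density in seawater from a fraction chain
#'
#' Multiplies a total cell abundance by an ordered chain of proportions
#' (e.g. archaeal fraction, then clade fraction within archaea), with
#' 1 mL = 1 cm\eqn{^3} made explicit: the result is per cm\eqn{^3}.
#'
#' @param total_cells_per_ml Total cell abundance, cells/mL.
#' @param fractions Numeric vector of proportions in \[0, 1\], applied in
#'   order; empty vector returns the total unchanged.
#' @return Cells per cm\eqn{^3}.
#' @examples
#' seawater_taxon_density(2.2e4, 0.0115)  # 253
#' @export
seawater_taxon_density <- function(total_cells_per_ml, fractions = numeric(0)) {
  stopifnot(total_cells_per_ml >= 0,
            all(fractions >= 0), all(fractions <= 1))
  total_cells_per_ml * prod(fractions)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Cq = %.4f + %.4f log10(copies/ul)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.3f, R^2 %.4f, detection limit %g copies/g\n",
              x$efficiency, x$r_squared, x$detection_limit))
  invisible(x)
}
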