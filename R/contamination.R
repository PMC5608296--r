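# Estimation and subtraction of intraepithelial-lymphocyte (IEL) signal
# admixed into observed IEC expression profiles, based on a panel of T-cell
# marker genes that pure epithelium does not express.

#' Marker panel for the contaminating population
#'
#' @param marker_ids Unique gene identifiers expressed only in the target
#'   population. Defaults to the six T-lymphocyte-specific genes CD3D, CD3G,
#'   CD2, CD7, CD8A and CD247.
#' @param target_population Label of the contaminating population.
#' @return A list of class `marker_panel`.
#' @export
marker_panel <- function(marker_ids = DEFAULT_MARKERS,
                         target_population = "IEL") {
  if (length(marker_ids) == 0L) stop("marker panel must be non-empty")
  if (anyDuplicated(marker_ids)) stop("marker identifiers must be unique")
  structure(list(marker_ids = as.character(marker_ids),
                 target_population = target_population),
            class = "marker_panel")
}

.iel_reference_profile <- function(iel) {
  if (is.matrix(iel)) {
    .check_matrix(iel, "iel reference")
    apply(iel, 1L, stats::median)
  } else {
    if (is.null(names(iel))) stop("IEL reference profile must be named by gene")
    iel
  }
}

#' Estimate the IEL admixture fraction from marker signals
#'
#' For each marker, the ratio of its (zero-clamped) IEC signal to its IEL
#' reference signal estimates the admixture fraction, because pure epithelium
#' does not express the marker. Ratios are pooled by the median, both across
#' markers (on the per-marker median IEC signal) and across markers within
#' each sample; both summaries are reported since the admixture may vary by
#' sample.
#'
#' @param iec Gene-by-sample matrix of observed IEC signals (AU).
#' @param iel_reference Named per-gene IEL profile, or an IEL gene-by-sample
#'   matrix (summarized by per-gene medians).
#' @param panel A [marker_panel()] (or character vector of marker ids).
#' @return An object of class `contamination_estimate` with
#'   `per_marker_ratio`, `per_sample_fraction`, `pooled_fraction` (median of
#'   per-marker ratios, clamped to \[0, 1\]) and `method`.
#' @export
estimate_contamination <- function(iec, iel_reference,
                                   panel = marker_panel()) {
  .check_matrix(iec, "iec")
  if (is.character(panel)) panel <- marker_panel(panel)
  stopifnot(inherits(panel, "marker_panel"))
  ref <- .iel_reference_profile(iel_reference)

  markers <- panel$marker_ids
  missing_iec <- setdiff(markers, rownames(iec))
  if (length(missing_iec))
    stop("marker(s) missing from IEC matrix: ",
         paste(missing_iec, collapse = ", "))
  missing_ref <- setdiff(markers, names(ref))
  if (length(missing_ref))
    stop("marker(s) missing from IEL reference: ",
         paste(missing_ref, collapse = ", "))
  ref_m <- ref[markers]
  if (all(ref_m <= 0))
    stop("degenerate IEL reference: all marker signals are zero")
  if (any(ref_m <= 0)) {
    warning("dropping marker(s) with zero IEL reference signal: ",
            paste(markers[ref_m <= 0], collapse = ", "))
    markers <- markers[ref_m > 0]
    ref_m <- ref_m[markers]
  }

  sig <- pmax(iec[markers, , drop = FALSE], 0)
  per_marker <- apply(sig, 1L, stats::median) / ref_m
  per_sample <- pmin(pmax(apply(sig / ref_m, 2L, stats::median), 0), 1)
  structure(list(
    per_marker_ratio = per_marker,
    per_sample_fraction = per_sample,
    pooled_fraction = min(max(stats::median(per_marker), 0), 1),
    method = "median",
    markers = markers
  ), class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat("IEL contamination estimate (pooled fraction ",
      sprintf("%.3f", x$pooled_fraction), ")\n", sep = "")
  cat("per-marker ratios:\n")
  print(round(x$per_marker_ratio, 4))
  cat("per-sample fractions:\n")
  print(round(x$per_sample_fraction, 4))
  invisible(x)
}

#' Subtract admixed IEL signal from IEC profiles
#'
#' Subtracts `fraction` times the IEL reference signal from every observed IEC
#' signal and clamps negatives to zero, the correction applied with a fixed
#' 10% in the original screen. Genes absent from the IEL reference pass
#' through unchanged. When the observed profiles arise from convex mixing
#' ((1-f) pure + f IEL), plain subtraction leaves the pure signal scaled by
#' (1-f); `rescale = TRUE` divides by (1-f) afterwards, inverting the mixing
#' model exactly.
#'
#' @param iec Gene-by-sample matrix of observed IEC signals (AU).
#' @param iel_reference Named per-gene IEL profile or IEL matrix.
#' @param fraction Admixture fraction in \[0, 1\]; a scalar applied to every
#'   sample or a vector with one fraction per sample (default 0.10).
#' @param rescale Divide by (1 - fraction) after subtraction (default `FALSE`,
#'   matching the plain-subtraction rule).
#' @return The corrected matrix, same shape and dimnames as `iec`.
#' @export
correct_contamination <- function(iec, iel_reference, fraction = 0.10,
                                  rescale = FALSE) {
  .check_matrix(iec, "iec")
  ref <- .iel_reference_profile(iel_reference)
  if (any(fraction < 0 | fraction > 1)) stop("fraction must lie in [0, 1]")
  if (length(fraction) == 1L) fraction <- rep(fraction, ncol(iec))
  if (length(fraction) != ncol(iec))
    stop("fraction must be a scalar or one value per sample")
  if (rescale && any(fraction >= 1))
    stop("rescale requires fractions strictly below 1")

  ref_aligned <- stats::setNames(numeric(nrow(iec)), rownames(iec))
  common <- intersect(rownames(iec), names(ref))
  ref_aligned[common] <- ref[common]

  corrected <- iec - outer(ref_aligned, fraction)
  if (rescale) corrected <- sweep(corrected, 2L, 1 - fraction, `/`)
  corrected <- pmax(corrected, 0)
  dimnames(corrected) <- dimnames(iec)
  corrected
}
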