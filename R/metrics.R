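#' Masked spatial average
#'
#' Mean of `f` over the nodes where `mask_field > threshold` — the discrete
#' Riemann quotient of the two area integrals (the cell area cancels). The
#' interior-region convention uses the tumor density with threshold 1; the
#' whole-tumor convention uses threshold 0.1.
#'
#' @param f An `an_field` to average.
#' @param mask_field An `an_field` defining the mask.
#' @param threshold Mask threshold.
#' @return A single number.
#' @export
masked_average <- function(f, mask_field, threshold) {
  check_same_grid(f, mask_field)
  sel <- mask_field$values > threshold
  if (!any(sel))
    stop("empty mask: no nodes with mask field > ", threshold)
  mean(f$values[sel])
}

#' Equivalent-disc tumor radius
#'
#' `sqrt(area / pi)` where area is the number of nodes with `n > threshold`
#' times the cell area `h^2`. Returns 0 for an empty mask.
#'
#' @param n Tumor density `an_field`.
#' @param threshold Edge threshold (default 0.1).
#' @return Radius in cm.
#' @export
tumor_radius <- function(n, threshold = 0.1) {
  cnt <- sum(n$values > threshold)
  sqrt(cnt * n$grid$h^2 / pi)
}

#' Microvascular density reduction
#'
#' `1 - mean(m_after)/mean(m_before)` over a common tumor mask; the quantity
#' the antiangiogenic dose is calibrated against (target: 50 percent).
#'
#' @param m_before,m_after Vessel density `an_field`s.
#' @param tumor_mask Logical matrix (or `an_field` + threshold pair via
#'   `mask_field`/`threshold`) selecting tumor nodes.
#' @return Fractional reduction (positive = loss of vessels).
#' @export
mvd_reduction <- function(m_before, m_after, tumor_mask) {
  check_same_grid(m_before, m_after)
  if (inherits(tumor_mask, "an_field")) tumor_mask <- tumor_mask$values > 0.1
  if (!any(tumor_mask)) stop("empty tumor mask")
  base <- mean(m_before$values[tumor_mask])
  if (base == 0) stop("baseline MVD is zero; reduction undefined")
  1 - mean(m_after$values[tumor_mask]) / base
}

trapezoid <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Cross-case exposure and extravasation report
#'
#' Compares simulation results against the chemotherapy-alone baseline
#' (`case2`). Total drug exposure per unit area is the time integral
#' (trapezoid over the recorded samples) of the interior-masked mean drug
#' concentration; the extravasation-rate integral uses the interior-masked
#' mean of `Gamma_b (1 - sigma_d) d_v`. Improvements are ratios minus one.
#'
#' @param results Named list of `an_sim_result`s; must contain `"case2"`.
#' @return A data.frame with one row per case: `case`, `exposure`,
#'   `improvement`, `extrav_integral`, `extrav_ratio`, `min_avg_ifp`.
#' @export
exposure_and_improvement <- function(results) {
  if (!("case2" %in% names(results)))
    stop("results must include the chemotherapy-alone baseline 'case2'")
  one <- function(res) {
    met <- res$metrics
    ok <- is.finite(met$avg_interior_d)
    expo <- trapezoid(met$t[ok], met$avg_interior_d[ok])
    okx <- is.finite(met$avg_interior_extrav)
    extrav <- trapezoid(met$t[okx],
                        met$avg_interior_extrav[okx] * met$plasma_d[okx])
    okp <- is.finite(met$avg_ifp)
    c(exposure = expo, extrav_integral = extrav,
      min_avg_ifp = if (any(okp)) min(met$avg_ifp[okp]) else NA_real_)
  }
  vals <- t(vapply(results, one, numeric(3)))
  base <- vals["case2", ]
  data.frame(
    case = names(results),
    exposure = vals[, "exposure"],
    improvement = vals[, "exposure"] / base["exposure"] - 1,
    extrav_integral = vals[, "extrav_integral"],
    extrav_ratio = vals[, "extrav_integral"] / base["extrav_integral"],
    min_avg_ifp = vals[, "min_avg_ifp"],
    row.names = NULL
  )
}
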