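#' Percent cytotoxicity from a luminescence triplet
#'
#' Luciferized target cells emit light in proportion to the number still
#' alive, so cytotoxicity is read off the luminescence of the co-culture
#' relative to two controls: maximal lysis (1% triton X-100) and targets
#' alone (0:1 effector:target). The value is
#' \deqn{100 \times \left(1 - \frac{sample - max\_lysis}{target\_only -
#'   max\_lysis}\right)}
#' and is deliberately not clipped to [0, 100]: assay noise can push it
#' slightly outside and that structure is preserved for downstream
#' attribution (reports may clip for display).
#'
#' @param lum_sample luminescence of the effector/target co-culture.
#' @param lum_max_lysis luminescence of the triton maximal-lysis control.
#' @param lum_target_only luminescence of the target-only (0:1) control.
#' @return Percent cytotoxicity (vectorized).
#' @export
#' @examples
#' percent_cytotoxicity(2000, 2000, 40000)   # 100: sample at max lysis
#' percent_cytotoxicity(40000, 2000, 40000)  # 0: sample at target-only
percent_cytotoxicity <- function(lum_sample, lum_max_lysis, lum_target_only) {
  if (any(lum_target_only == lum_max_lysis)) {
    stop("degenerate controls: target-only (", lum_target_only[1],
         ") equals max-lysis (", lum_max_lysis[1], ")")
  }
  100 * (1 - (lum_sample - lum_max_lysis) / (lum_target_only - lum_max_lysis))
}

#' Assemble an effector-to-target cytotoxicity curve
#'
#' Converts a set of luminescence readings for one sample into a
#' `cytotox_curve`: percent cytotoxicity per E:T ratio, duplicate ratios
#' averaged.
#'
#' @param readings data.frame with columns `sample_id`, `et_ratio`,
#'   `lum_sample`, `lum_max_lysis`, `lum_target_only`.
#' @return An object of class `cytotox_curve`: data.frame with `et_ratio`
#'   and `pct_cytotoxicity`, plus a `sample_id` attribute.
#' @export
build_curve <- function(readings) {
  need <- c("sample_id", "et_ratio", "lum_sample", "lum_max_lysis",
            "lum_target_only")
  if (!all(need %in% names(readings))) {
    stop("readings must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(readings$sample_id)
  if (length(ids) != 1L) {
    stop("mixed sample_ids in readings: ", paste(ids, collapse = ", "))
  }
  pct <- percent_cytotoxicity(readings$lum_sample, readings$lum_max_lysis,
                              readings$lum_target_only)
  agg <- stats::aggregate(list(pct_cytotoxicity = pct),
                          by = list(et_ratio = readings$et_ratio), FUN = mean)
  agg <- agg[order(agg$et_ratio), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("cytotox_curve", "data.frame"), sample_id = ids)
}

#' @export
print.cytotox_curve <- function(x, ...) {
  cat("Cytotoxicity curve for sample '", attr(x, "sample_id"), "'\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Percent cytotoxicity of a curve at one E:T ratio
#'
#' Exact ratio match required; no interpolation.
#'
#' @param curve a [build_curve()] result.
#' @param et_ratio ratio to look up.
#' @return Percent cytotoxicity at that ratio.
#' @export
curve_at <- function(curve, et_ratio) {
  i <- which(abs(curve$et_ratio - et_ratio) < 1e-12)
  if (!length(i)) {
    stop("curve for '", attr(curve, "sample_id"), "' has no ", et_ratio,
         ":1 point")
  }
  curve$pct_cytotoxicity[i[1]]
}
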