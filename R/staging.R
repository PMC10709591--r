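#' Clinical T categories for early-stage lung adenocarcinoma
#'
#' Ordered factor levels used throughout: Tis < T1mi < T1a < T1b < T1c < T2a.
#'
#' @return Character vector of category levels in order.
#' @export
t_categories <- function() c("Tis", "T1mi", "T1a", "T1b", "T1c", "T2a")

#' Assign the clinical T category from total and solid size
#'
#' Size-based rule table of the 8th-edition TNM system for stage 0-I
#' adenocarcinoma, driven by the solid-component size:
#' \itemize{
#'   \item solid = 0 and total <= 30 mm: Tis (adenocarcinoma in situ);
#'   \item 0 < solid <= 5 mm and total <= 30 mm: T1mi (minimally invasive);
#'   \item otherwise by solid size: <= 10 mm T1a, <= 20 mm T1b,
#'     <= 30 mm T1c, <= 40 mm T2a.
#' }
#' Category bounds are inclusive upper bounds. A pure ground-glass lesion
#' with total > 30 mm falls outside the Tis definition and is assigned T1a
#' (solid size 0 <= 10 mm); this convention is documented, not claimed to be
#' universal.
#'
#' @param total_mm,solid_mm sizes in mm; vectors recycle. Must satisfy
#'   `0 <= solid_mm <= total_mm <= 40` (the cohort is stage 0-I).
#' @return An ordered factor over [t_categories()].
#' @export
assign_t <- function(total_mm, solid_mm) {
  n <- max(length(total_mm), length(solid_mm))
  total_mm <- rep_len(total_mm, n); solid_mm <- rep_len(solid_mm, n)
  if (any(!is.finite(total_mm)) || any(!is.finite(solid_mm)))
    stop("sizes must be finite")
  if (any(solid_mm < 0)) stop("solid_mm must be >= 0")
  if (any(solid_mm > total_mm + 1e-9)) stop("solid_mm must not exceed total_mm")
  if (any(total_mm > 40 + 1e-9))
    stop("total_mm > 40 mm is outside the stage 0-I rule table")
  out <- character(n)
  for (i in seq_len(n)) {
    s <- solid_mm[i]; t <- total_mm[i]
    out[i] <-
      if (s == 0 && t <= 30) "Tis"
      else if (s > 0 && s <= 5 && t <= 30) "T1mi"
      else if (s <= 10) "T1a"
      else if (s <= 20) "T1b"
      else if (s <= 30) "T1c"
      else "T2a"
  }
  factor(out, levels = t_categories(), ordered = TRUE)
}
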