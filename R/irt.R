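# iRT retention-time normalization.
#
# Spiked-in landmark peptides with fixed, instrument-independent iRT
# coordinates anchor a linear map from observed retention time (seconds)
# to the iRT scale. The map must be strictly increasing (positive slope);
# a negative slope indicates a reversed gradient and is an error.

#' Reference iRT coordinates of the 11 landmark peptides
#'
#' The standard commercial RT-normalization kit: 11 synthetic peptides
#' spanning the elution range, with iRT values fixed by convention
#' (0 and 100 anchor the scale).
#'
#' @return data.frame with columns `sequence` and `irt`.
#' @export
default_irt_reference <- function() {
  data.frame(
    sequence = c("LGGNEQVTR", "GAGSSEPVTGLDAK", "VEATFGVDESNAK",
                 "YILAGVENSK", "TPVISGGPYEYR", "TPVITGAPYEYR",
                 "DGLDAASYYAPVR", "ADVTPADFSEWSK", "GTFIIDPGGVIR",
                 "GTFIIDPAAVIR", "LFLQFGAQGSPFLK"),
    irt = c(-24.92, 0.00, 12.39, 19.79, 28.71, 33.38, 42.26, 54.62,
            70.52, 87.23, 100.00),
    stringsAsFactors = FALSE
  )
}

#' Fit the RT -> iRT normalization line
#'
#' Least-squares fit of reference iRT on observed retention time over the
#' landmark peptides common to both tables.
#'
#' @param observed data.frame with `sequence` and `rt_seconds` columns.
#' @param reference data.frame with `sequence` and `irt` columns (default
#'   [default_irt_reference()]).
#' @return Object of class `irt_model`: `slope`, `intercept`, `r_squared`,
#'   `n_landmarks`.
#' @examples
#' ref <- default_irt_reference()
#' obs <- data.frame(sequence = ref$sequence, rt_seconds = 2 * ref$irt + 5)
#' fit_irt(obs, ref)  # slope 0.5, intercept -2.5
#' @export
fit_irt <- function(observed, reference = default_irt_reference()) {
  m <- merge(observed[, c("sequence", "rt_seconds")],
             reference[, c("sequence", "irt")], by = "sequence")
  if (nrow(m) < 2)
    stop("need >= 2 common landmark peptides, found ", nrow(m), call. = FALSE)
  fit <- stats::lm(irt ~ rt_seconds, data = m)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive iRT slope: gradient reversed or degenerate landmarks",
         call. = FALSE)
  # suppress summary.lm's "essentially perfect fit" warning at zero noise
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (is.nan(r2)) 1 else r2,
                 n_landmarks = nrow(m)),
            class = "irt_model")
}

#' Map retention times to iRT
#' @param model An `irt_model`.
#' @param rt_seconds Numeric vector of retention times.
#' @return iRT values.
#' @export
apply_irt <- function(model, rt_seconds) {
  model$intercept + model$slope * rt_seconds
}

#' Map iRT values back to retention time
#' @param model An `irt_model`.
#' @param irt Numeric vector of iRT values.
#' @return Retention times in seconds.
#' @export
invert_irt <- function(model, irt) {
  (irt - model$intercept) / model$slope
}

#' @export
print.irt_model <- function(x, ...) {
  cat(sprintf("iRT model: iRT = %.6g + %.6g * rt_s (R^2 = %.4f, %d landmarks)\n",
              x$intercept, x$slope, x$r_squared, x$n_landmarks))
  invisible(x)
}
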