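# Flow-cytometry index statistics: tonic signaling index, exhaustion
# score, relative normalisation, Pearson association, and 4PL EC50 fits.
#
# Inputs are pre-gated summary MFIs (mean fluorescence intensity per
# marker per sample, measured within the GFP-positive gate); raw FCS
# event processing is out of scope.

check_mfi <- function(mfi, needed) {
  miss <- setdiff(needed, names(mfi))
  if (length(miss))
    stop("missing marker(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(unlist(mfi[needed])) | unlist(mfi[needed]) < 0))
    stop("MFI values must be finite and >= 0")
  if (mfi$GFP <= 0)
    stop("GFP MFI must be > 0 (index is GFP-normalised)")
}

#' Tonic signaling index
#'
#' `MFI(CD69) / MFI(GFP)`: CD69 upregulation (early T-cell activation)
#' normalised by GFP (a CAR-expression reporter), measured on
#' CAR-transduced cells without antigen stimulation.  Invariant to common
#' rescaling of both MFIs (instrument gain).
#'
#' @param mfi Named list/vector of marker MFIs; needs `CD69` and `GFP`.
#' @return Numeric index (unitless, >= 0).
#' @examples
#' tonic_index(c(CD69 = 2000, GFP = 1000))  # 2
#' @export
tonic_index <- function(mfi) {
  mfi <- as.list(mfi)
  check_mfi(mfi, c("CD69", "GFP"))
  unname(mfi$CD69 / mfi$GFP)
}

#' Exhaustion score
#'
#' Mean of the GFP-normalised MFIs of the three canonical exhaustion
#' markers:
#' `(MFI(PD1)/MFI(GFP) + MFI(LAG3)/MFI(GFP) + MFI(TIM3)/MFI(GFP)) / 3`.
#'
#' @param mfi Named list/vector with `PD1`, `LAG3`, `TIM3`, `GFP`.
#' @return Numeric score (unitless, >= 0).
#' @examples
#' exhaustion_score(c(PD1 = 100, LAG3 = 200, TIM3 = 300, GFP = 100))  # 2
#' @export
exhaustion_score <- function(mfi) {
  mfi <- as.list(mfi)
  check_mfi(mfi, c("PD1", "LAG3", "TIM3", "GFP"))
  unname((mfi$PD1 + mfi$LAG3 + mfi$TIM3) / (3 * mfi$GFP))
}

#' Normalise index values against a reference sample
#'
#' Divides every value by the reference sample's value, so the reference
#' maps to 1.0 (e.g. indexes of cells grown in high-salt medium relative
#' to the regular-medium sample).
#'
#' @param values Numeric vector, optionally named.
#' @param reference Name or position of the reference value.
#' @return Numeric vector of relative values.
#' @export
relative_index <- function(values, reference = 1L) {
  ref <- if (is.character(reference)) values[[reference]]
         else values[[as.integer(reference)]]
  if (is.null(ref) || is.na(ref))
    stop("reference value absent")
  if (ref == 0) stop("reference value is 0; cannot normalise")
  values / ref
}

#' Pearson association with two-tailed p-value and linear fit
#'
#' Product-moment correlation; the p-value comes from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-tailed.  Slope and intercept are the ordinary least-squares fit of
#' y on x.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return Object of class `association_result`: list with `n`, `r`,
#'   `r2`, `p`, `slope`, `intercept`.
#' @export
pearson_association <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  slope <- sum(xc * yc) / sum(xc^2)
  structure(list(n = n, r = r, r2 = r^2, p = p, slope = slope,
                 intercept = mean(y) - slope * mean(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association> n=%d r=%.4f r2=%.4f p=%.4g  y = %.4g + %.4g x\n",
    x$n, x$r, x$r2, x$p, x$intercept, x$slope))
  invisible(x)
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Least-squares fit of
#' `resp = bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`
#' (so the fitted response at `conc = ec50` is exactly the half-maximum).
#' The EC50 is estimated on the log scale to enforce positivity.
#' Initialisation: bottom = min(resp), top = max(resp), hill = 1, with the
#' geometric mean of the concentrations plus five log-spaced alternatives
#' as EC50 starts; the converged fit with the lowest residual sum of
#' squares wins.  The 95% CI on EC50 comes from the asymptotic covariance
#' of log(EC50).
#'
#' @param conc Concentrations (nM), all > 0, at least 5 distinct values.
#' @param resp Responses (arbitrary units).
#' @return Object of class `dose_response_fit`: list with `bottom`,
#'   `top`, `ec50`, `hill`, `ci95_ec50` (length-2), `rss`, `fitted`,
#'   and `model` (the nls object).
#' @export
fit_4pl <- function(conc, resp) {
  stopifnot(is.numeric(conc), is.numeric(resp),
            length(conc) == length(resp))
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(unique(conc)) < 5)
    stop("need at least 5 distinct concentrations")
  dat <- data.frame(conc = conc, resp = resp)
  gm <- exp(mean(log(conc)))
  starts_ec50 <- unique(c(gm, exp(seq(log(min(conc)), log(max(conc)),
                                      length.out = 5))))
  best <- NULL
  diag_msgs <- character(0)
  for (e0 in starts_ec50) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + (exp(lec50) / conc)^hill),
        data = dat,
        start = list(bottom = min(resp), top = max(resp),
                     lec50 = log(e0), hill = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diag_msgs <<- c(diag_msgs, conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("4PL fit failed to converge from all starts:\n  ",
         paste(unique(diag_msgs), collapse = "\n  "))
  cf <- coef(best$fit)
  se_lec50 <- tryCatch(sqrt(vcov(best$fit)["lec50", "lec50"]),
                       error = function(e) NA_real_)
  ci <- exp(cf[["lec50"]] + c(-1, 1) * qnorm(0.975) * se_lec50)
  bottom <- cf[["bottom"]]; top <- cf[["top"]]; hill <- cf[["hill"]]
  # canonical orientation: report top >= bottom with positive hill
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  structure(list(bottom = bottom, top = top,
                 ec50 = exp(cf[["lec50"]]), hill = hill,
                 ci95_ec50 = ci, rss = best$rss,
                 fitted = fitted(best$fit), model = best$fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<4PL fit> EC50 = %.4g nM (95%% CI %.4g-%.4g), hill = %.3g,",
           " range [%.4g, %.4g]\n"),
    x$ec50, x$ci95_ec50[1], x$ci95_ec50[2], x$hill, x$bottom, x$top))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (object$ec50 / conc)^object$hill)
}

#' Read an assay MFI table
#'
#' Accepts wide form (one column per marker: `sample_id`, optional
#' `group`, then marker columns) or long form (`sample_id`, optional
#' `group`, `marker`, `mfi`).  TSV or CSV, by extension or `sep`.
#'
#' @param path Table path.
#' @param sep Field separator; default inferred (`,` for `.csv`, else
#'   tab).
#' @return Wide-form data.frame with `sample_id`, `group`, marker
#'   columns.
#' @export
read_assay_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!"sample_id" %in% names(d))
    stop("missing column: sample_id")
  if (!"group" %in% names(d)) d$group <- "all"
  if (all(c("marker", "mfi") %in% names(d))) {          # long -> wide
    wide <- reshape(d[, c("sample_id", "group", "marker", "mfi")],
                    idvar = c("sample_id", "group"),
                    timevar = "marker", direction = "wide")
    names(wide) <- sub("^mfi\\.", "", names(wide))
    rownames(wide) <- NULL
    d <- wide
  }
  d
}

#' Per-sample indexes for an assay table
#'
#' Computes the tonic signaling index (when CD69 is present) and the
#' exhaustion score (when PD1/LAG3/TIM3 are present) for every row of a
#' wide-form assay table, optionally normalised within `group` against a
#' reference sample.
#'
#' @param tab Wide-form data.frame (see [read_assay_table]).
#' @param relative_to Optional `sample_id` used as the within-group
#'   reference for relative indexes.
#' @return data.frame with `sample_id`, `group`, computed index columns
#'   and, with `relative_to`, their `rel_` counterparts.
#' @export
assay_indexes <- function(tab, relative_to = NULL) {
  stopifnot("sample_id" %in% names(tab), "GFP" %in% names(tab))
  out <- data.frame(sample_id = tab$sample_id,
                    group = if ("group" %in% names(tab)) tab$group
                            else "all",
                    stringsAsFactors = FALSE)
  if ("CD69" %in% names(tab))
    out$tonic_index <- vapply(seq_len(nrow(tab)), function(i)
      tonic_index(tab[i, , drop = FALSE]), numeric(1))
  if (all(c("PD1", "LAG3", "TIM3") %in% names(tab)))
    out$exhaustion_score <- vapply(seq_len(nrow(tab)), function(i)
      exhaustion_score(tab[i, , drop = FALSE]), numeric(1))
  if (!is.null(relative_to)) {
    for (col in intersect(c("tonic_index", "exhaustion_score"),
                          names(out))) {
      out[[paste0("rel_", col)]] <- NA_real_
      for (g in unique(out$group)) {
        sel <- out$group == g
        ref <- which(out$sample_id[sel] == relative_to)
        if (length(ref) == 0)
          stop("reference sample '", relative_to, "' absent from group '",
               g, "'")
        out[[paste0("rel_", col)]][sel] <-
          relative_index(out[[col]][sel], ref[1])
      }
    }
  }
  out
}
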