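#' Construct a dose-response dataset
#'
#' Long-format uptake-inhibition data for one compound against one target:
#' dose in nM, response in percent of uninhibited uptake, one row per
#' replicate measurement.
#'
#' @param dose numeric vector of doses (nM, strictly positive).
#' @param response numeric vector of % uptake, same length.
#' @param replicate integer replicate index per row (default all 1).
#' @param compound_id compound identifier.
#' @param target target name, `"SGLT1"` or `"SGLT2"`.
#' @return object of class `dose_response_dataset` (a data.frame with
#'   attributes `compound_id` and `target`).
#' @export
dose_response_dataset <- function(dose, response, replicate = 1L,
                                  compound_id = "compound",
                                  target = c("SGLT2", "SGLT1")) {
  target <- match.arg(target)
  if (any(dose <= 0)) stop("doses must be strictly positive")
  if (length(response) != length(dose)) stop("dose/response length mismatch")
  if (!all(is.finite(response))) stop("responses must be finite")
  if (length(unique(dose)) < 4L)
    stop("at least 4 distinct doses are required")
  df <- data.frame(dose = dose, response = response,
                   replicate = rep_len(as.integer(replicate), length(dose)))
  structure(df, compound_id = compound_id, target = target,
            class = c("dose_response_dataset", "data.frame"))
}

.pl4 <- function(l, top, bottom, hill, lic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (l - lic50)))
}

#' Fit a sigmoidal (four-parameter logistic) dose-response model
#'
#' Fits \deqn{y = bottom + \frac{top - bottom}{1 + (dose/IC_{50})^{hill}}}
#' to pooled % uptake data by bounded Levenberg-Marquardt least squares in
#' log10-dose space, with deterministic grid-seeded initialisation (no
#' randomness). Parameter bounds follow the GraphPad-style convention:
#' top in [80, 120] %, bottom in [-10, 20] %, Hill slope in [0.3, 5].
#'
#' Flat data whose response range falls below `noise_floor` is flagged
#' `no_inhibition` and not fitted. A fitted IC50 outside the dose span
#' widened by two decades is flagged `extrapolated`.
#'
#' @param data a [dose_response_dataset], or a data.frame with columns
#'   `dose` (nM) and `response` (%).
#' @param fix_bottom fix the lower asymptote (e.g. `0` for a 3-parameter
#'   fit); `NULL` (default) fits all four parameters.
#' @param noise_floor minimum response range (%) regarded as evidence of
#'   inhibition (default 10).
#' @return object of class `ic50_fit` with components `ic50` (nM), `hill`,
#'   `top`, `bottom`, `se_log_ic50`, `converged`, `rss`, `no_inhibition`,
#'   `extrapolated`, `data`, and the underlying `nls` fit.
#' @seealso [selectivity_ratio()], [generate_assay()]
#' @export
fit_ic50 <- function(data, fix_bottom = NULL, noise_floor = 10) {
  df <- as.data.frame(data)
  stopifnot(all(c("dose", "response") %in% names(df)))
  if (any(df$dose <= 0)) stop("doses must be strictly positive")
  if (!all(is.finite(df$response))) stop("responses must be finite")
  if (length(unique(df$dose)) < 4L)
    stop("at least 4 distinct doses are required")
  l <- log10(df$dose)
  y <- df$response
  dose_means <- tapply(y, l, mean)
  out <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
              bottom = NA_real_, se_log_ic50 = NA_real_,
              converged = FALSE, rss = NA_real_,
              no_inhibition = FALSE, extrapolated = FALSE,
              data = df, fit = NULL, fix_bottom = fix_bottom)
  if (diff(range(dose_means)) < noise_floor) {
    out$no_inhibition <- TRUE
    return(structure(out, class = "ic50_fit"))
  }
  lo <- c(top = 80, bottom = -10, hill = 0.3, lic50 = min(l) - 3)
  hi <- c(top = 120, bottom = 20, hill = 5, lic50 = max(l) + 3)
  top0 <- min(max(max(dose_means), lo["top"]), hi["top"])
  bot0 <- min(max(min(dose_means), lo["bottom"]), hi["bottom"])
  if (!is.null(fix_bottom)) bot0 <- fix_bottom
  # coarse deterministic grid: pick the best few starts by direct RSS
  grid <- expand.grid(lic50 = seq(min(l) - 1, max(l) + 1, by = 0.25),
                      hill = c(0.5, 1, 2))
  grid$rss <- vapply(seq_len(nrow(grid)), function(i)
    sum((y - .pl4(l, top0, bot0, grid$hill[i], grid$lic50[i]))^2),
    numeric(1))
  starts <- grid[order(grid$rss), ][seq_len(3), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- if (is.null(fix_bottom)) {
      tryCatch(minpack.lm::nlsLM(
        y ~ .pl4(l, top, bottom, hill, lic50),
        start = list(top = unname(top0), bottom = unname(bot0),
                     hill = starts$hill[i], lic50 = starts$lic50[i]),
        lower = unname(lo), upper = unname(hi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    } else {
      tryCatch(minpack.lm::nlsLM(
        y ~ .pl4(l, top, fix_bottom, hill, lic50),
        start = list(top = unname(top0), hill = starts$hill[i],
                     lic50 = starts$lic50[i]),
        lower = unname(lo[c("top", "hill", "lic50")]),
        upper = unname(hi[c("top", "hill", "lic50")]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit,
                                                               rss = rss)
    }
  }
  if (is.null(best)) return(structure(out, class = "ic50_fit"))
  cf <- stats::coef(best$fit)
  out$fit <- best$fit
  out$rss <- best$rss
  out$top <- unname(cf["top"])
  out$bottom <- if (is.null(fix_bottom)) unname(cf["bottom"]) else fix_bottom
  out$hill <- unname(cf["hill"])
  out$ic50 <- 10^unname(cf["lic50"])
  out$se_log_ic50 <- tryCatch(
    sqrt(diag(stats::vcov(best$fit))[["lic50"]]),
    error = function(e) NA_real_)
  out$converged <- TRUE
  out$extrapolated <- cf["lic50"] < min(l) - 2 || cf["lic50"] > max(l) + 2
  structure(out, class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat("<ic50_fit> sigmoidal dose-response (4PL)\n")
  if (x$no_inhibition) {
    cat("  no inhibition: response range below the noise floor\n")
  } else if (!x$converged) {
    cat("  fit did not converge\n")
  } else {
    cat(sprintf("  IC50 = %s nM%s\n", signif(x$ic50, digits),
                if (x$extrapolated) " (extrapolated beyond dose span)" else ""))
    cat(sprintf("  Hill = %s  top = %s%%  bottom = %s%%  RSS = %s\n",
                signif(x$hill, digits), signif(x$top, digits),
                signif(x$bottom, digits), signif(x$rss, digits)))
  }
  invisible(x)
}

#' @export
summary.ic50_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    cat(sprintf("  se(log10 IC50) = %s\n", signif(object$se_log_ic50, 3)))
    cat(sprintf("  n = %d observations, %d distinct doses\n",
                nrow(object$data), length(unique(object$data$dose))))
  }
  invisible(object)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit")
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  .pl4(log10(dose), object$top, object$bottom, object$hill,
       log10(object$ic50))
}

#' @export
residuals.ic50_fit <- function(object, ...) {
  if (!object$converged) stop("no residuals for an unconverged fit")
  object$data$response - predict(object)
}

#' @export
fitted.ic50_fit <- function(object, ...) predict(object)

#' @export
simulate.ic50_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sdres <- sqrt(object$rss / max(1, nrow(object$data) - 4))
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, sdres),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.ic50_fit <- function(x, main = "dose-response fit", ...) {
  graphics::plot(x$data$dose, x$data$response, log = "x",
                 xlab = "dose [nM]", ylab = "% uptake", main = main, ...)
  if (x$converged) {
    dg <- 10^seq(log10(min(x$data$dose)), log10(max(x$data$dose)),
                 length.out = 200)
    graphics::lines(dg, predict(x, data.frame(dose = dg)), col = "red3")
    graphics::abline(v = x$ic50, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Target-selectivity ratio from a pair of IC50 values
#'
#' Selectivity is the SGLT1 IC50 divided by the SGLT2 IC50; large values
#' mean preferential SGLT2 inhibition. The integer view rounds half away
#' from zero, matching the printed-table convention.
#'
#' @param ic50_sglt1 IC50 against SGLT1 (nM).
#' @param ic50_sglt2 IC50 against SGLT2 (nM).
#' @return object of class `selectivity_result`: `ic50_sglt1`,
#'   `ic50_sglt2`, `selectivity` (raw ratio) and `selectivity_int`
#'   (rounded integer view).
#' @export
selectivity_ratio <- function(ic50_sglt1, ic50_sglt2) {
  if (ic50_sglt1 <= 0 || ic50_sglt2 <= 0)
    stop("IC50 values must be positive")
  r <- ic50_sglt1 / ic50_sglt2
  structure(list(ic50_sglt1 = ic50_sglt1, ic50_sglt2 = ic50_sglt2,
                 selectivity = r,
                 selectivity_int = round_half_away(r)),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("IC50 SGLT1 %g nM / IC50 SGLT2 %g nM = %g-fold selectivity\n",
              x$ic50_sglt1, x$ic50_sglt2, x$selectivity_int))
  invisible(x)
}

#' Assemble an activity table from per-target fits
#'
#' Summarises, per compound, the mean and SD of the fitted (or supplied)
#' IC50s for each target and the SGLT1/SGLT2 selectivity where both targets
#' are present. Input order is preserved. Each entry of `fits` is a list
#' with `id`, `sglt2` (required) and optionally `sglt1`; each target slot
#' may hold a single `ic50_fit`, a list of replicate fits, or bare numeric
#' IC50 values.
#'
#' @param fits list of per-compound entries as described above.
#' @return data.frame: compound_id, ic50_sglt2, sd_sglt2, ic50_sglt1,
#'   sd_sglt1, selectivity (integer view, NA when SGLT1 absent).
#' @export
summarize_activity <- function(fits) {
  get_ic50s <- function(slot) {
    if (is.null(slot)) return(NULL)
    if (inherits(slot, "ic50_fit")) slot <- list(slot)
    if (is.numeric(slot)) return(as.numeric(slot))
    vapply(slot, function(f) {
      if (!f$converged) stop("unconverged fit in activity table")
      f$ic50
    }, numeric(1))
  }
  rows <- lapply(fits, function(entry) {
    if (is.null(entry$sglt2))
      stop("compound '", entry$id, "' lacks an SGLT2 fit")
    i2 <- get_ic50s(entry$sglt2)
    i1 <- get_ic50s(entry$sglt1)
    sel <- if (is.null(i1)) NA_real_ else
      selectivity_ratio(mean(i1), mean(i2))$selectivity_int
    data.frame(compound_id = entry$id,
               ic50_sglt2 = mean(i2),
               sd_sglt2 = if (length(i2) > 1) stats::sd(i2) else NA_real_,
               ic50_sglt1 = if (is.null(i1)) NA_real_ else mean(i1),
               sd_sglt1 = if (!is.null(i1) && length(i1) > 1)
                 stats::sd(i1) else NA_real_,
               selectivity = sel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write dose-response tables as CSV
#'
#' Columns: compound_id, target, dose_nM, response_pct, replicate.
#'
#' @param path CSV path.
#' @return `read_dose_response_csv` returns a list of
#'   [dose_response_dataset]s, one per (compound_id, target) pair.
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "target", "dose_nM", "response_pct", "replicate")
  if (!all(req %in% names(df)))
    stop("dose-response CSV needs columns: ", paste(req, collapse = ", "))
  key <- paste(df$compound_id, df$target, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g)
    dose_response_dataset(g$dose_nM, g$response_pct, g$replicate,
                          compound_id = g$compound_id[1],
                          target = g$target[1]))
}

#' @rdname read_dose_response_csv
#' @param datasets a [dose_response_dataset] or list of them.
#' @export
write_dose_response_csv <- function(datasets, path) {
  if (inherits(datasets, "dose_response_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d)
    data.frame(compound_id = attr(d, "compound_id"),
               target = attr(d, "target"),
               dose_nM = d$dose, response_pct = d$response,
               replicate = d$replicate, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
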