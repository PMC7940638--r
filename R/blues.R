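#' Best linear unbiased estimates (BLUEs) of variety yield
#'
#' Fits trial records with variety as a fixed effect and management,
#' management:year, management:year:variety and management:year:location as
#' independent random effects (the management covariate is a 0/1 property
#' of the variety marking the trial-regime switch), then extracts estimated
#' marginal variety means. When the random-effect fit is degenerate (e.g.
#' noise-free synthetic trials with zero residual variance) the model falls
#' back to a fixed-effects fit, which gives identical BLUEs in the balanced
#' noise-free case.
#'
#' @param trials data.frame with columns `variety_id`, `year`, `location`,
#'   `management` (0/1) and `yield` (see [simulate_vcu_trials()]).
#' @return object of class `BlueResult`: `blues` data.frame (`variety_id`,
#'   `blue`, `se`), `varcomp` data.frame of random-effect variances, and
#'   `model` (`"lmm"` or `"fixed"`).
#' @export
yield_blues <- function(trials) {
  need <- c("variety_id", "year", "location", "management", "yield")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(trials) == 0) stop("empty trial records")
  if (!all(trials$management %in% c(0, 1))) {
    stop("management must be coded 0/1")
  }
  dat <- data.frame(variety_id = factor(trials$variety_id),
                    year = factor(trials$year),
                    location = factor(trials$location),
                    management = factor(trials$management),
                    yield = trials$yield)
  dropped <- setdiff(unique(trials$variety_id), levels(dat$variety_id))
  if (length(dropped)) message(length(dropped), " varieties without trials dropped")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(yield ~ variety_id + (1 | management) +
                   (1 | management:year) +
                   (1 | management:year:variety_id) +
                   (1 | management:year:location),
                 data = dat,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
    error = function(e) NULL)
  model <- "lmm"
  if (is.null(fit)) {
    fit <- stats::lm(yield ~ variety_id, data = dat)
    model <- "fixed"
  }
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(fit, "variety_id", lmer.df = "asymptotic")))
  blues <- data.frame(variety_id = as.character(em$variety_id),
                      blue = em$emmean, se = em$SE)
  vc <- if (model == "lmm") {
    v <- as.data.frame(lme4::VarCorr(fit))
    data.frame(term = v$grp, variance = v$vcov)
  } else {
    data.frame(term = "Residual", variance = summary(fit)$sigma^2)
  }
  structure(list(blues = blues, varcomp = vc, model = model),
            class = "BlueResult")
}

#' @export
print.BlueResult <- function(x, ...) {
  cat(sprintf("BlueResult (%s model): %d variety BLUEs\n",
              x$model, nrow(x$blues)))
  print(utils::head(x$blues, 5), row.names = FALSE)
  invisible(x)
}
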